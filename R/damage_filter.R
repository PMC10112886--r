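# Substitution-type classification of SNPs and the two ancient-DNA filters:
# the molecular-damage filter (drop C/T and G/A transitions plus indels,
# transform damage-compatible heterozygotes) and the transversion-only filter.
# Both return exact accounting so filtered tables can be audited row by row.

#' Classify a biallelic site by substitution type
#'
#' The category is assigned from the unordered ref/alt pair: `{C,T}` pairs are
#' deamination-compatible transitions (`transition_CT`), `{G,A}` pairs
#' likewise (`transition_GA`), any allele longer than one base is an `indel`,
#' remaining purine-pyrimidine pairs are `transversion`. `other_transition`
#' is unreachable for plain A/C/G/T SNPs and is only returned defensively for
#' non-standard allele codes.
#'
#' @param ref,alt allele strings (vectorised).
#' @return Character vector of categories.
#' @export
#' @examples
#' classify_site(c("C", "A", "AC"), c("T", "T", "A"))
classify_site <- function(ref, alt) {
  if (any(ref == alt)) stop("ref and alt alleles must differ")
  out <- rep("other_transition", length(ref))
  indel <- nchar(ref) > 1L | nchar(alt) > 1L
  lo <- pmin(ref, alt)
  hi <- pmax(ref, alt)
  out[lo == "C" & hi == "T"] <- "transition_CT"
  out[lo == "A" & hi == "G"] <- "transition_GA"
  tv <- !indel &
    ((ref %in% c("A", "G") & alt %in% c("C", "T")) |
       (ref %in% c("C", "T") & alt %in% c("A", "G")))
  out[tv] <- "transversion"
  out[indel] <- "indel"
  out
}

#' Transform damage-compatible heterozygotes
#'
#' At a C/T site a heterozygote becomes homozygous C; at a G/A site it becomes
#' homozygous G (the variant without a damage pattern). All other genotypes
#' are unchanged. Genotypes are alt-allele dosage.
#'
#' @param genotype dosage vector (0/1/2, NA allowed).
#' @param ref,alt site alleles (vectorised, recycled against `genotype`).
#' @return Transformed dosage vector.
#' @export
transform_het <- function(genotype, ref, alt) {
  cat_ <- classify_site(ref, alt)
  keep_allele <- ifelse(cat_ == "transition_CT", "C",
                        ifelse(cat_ == "transition_GA", "G", NA))
  het <- !is.na(genotype) & genotype == 1L & !is.na(keep_allele)
  genotype[het] <- ifelse(ref[het] == keep_allele[het], 0L, 2L)
  genotype
}

filter_accounting <- function(category, removed, het_transformed = 0L) {
  acc <- list(total = length(category),
              removed_ct = sum(removed & category == "transition_CT"),
              removed_ga = sum(removed & category == "transition_GA"),
              removed_indel = sum(removed & category == "indel"),
              removed_other = sum(removed & !category %in%
                                    c("transition_CT", "transition_GA",
                                      "indel")),
              het_transformed = as.integer(het_transformed),
              retained = sum(!removed))
  stopifnot(acc$retained == acc$total - acc$removed_ct - acc$removed_ga -
              acc$removed_indel - acc$removed_other)
  structure(acc, class = "filter_accounting")
}

#' @export
print.filter_accounting <- function(x, ...) {
  cat("sites:", x$total,
      "| removed C<->T:", x$removed_ct,
      "G<->A:", x$removed_ga,
      "indel:", x$removed_indel,
      "| het transformed:", x$het_transformed,
      "| retained:", x$retained, "\n")
  invisible(x)
}

site_frame <- function(x) {
  if (inherits(x, "genotype_panel")) x$sites else x
}

drop_sites <- function(x, keep) {
  if (inherits(x, "genotype_panel")) {
    x$sites <- x$sites[keep, , drop = FALSE]
    rownames(x$sites) <- NULL
    x$geno <- x$geno[keep, , drop = FALSE]
    x
  } else {
    out <- x[keep, , drop = FALSE]
    rownames(out) <- NULL
    out
  }
}

#' Molecular-damage filter
#'
#' Removes all indel sites and all deamination-compatible transitions (C/T and
#' G/A pairs), the SNP classes that post-mortem damage can mimic. In the
#' relaxed mode (`strict = FALSE`) damage-pair SNPs are retained when
#' supported by more than one read (ancient calls with a `depth` column) or
#' when diploid (panels), with heterozygotes transformed to the undamaged
#' homozygote via [transform_het()]; indels are always removed.
#'
#' @param x a [genotype_panel()] or an [ancient_calls()]-style data.frame with
#'   `ref`/`alt` columns (optionally `depth`).
#' @param strict logical; the default `TRUE` reproduces the strict published
#'   accounting.
#' @return List with `filtered` (same class as `x`) and `accounting`
#'   (a `filter_accounting`).
#' @export
apply_damage_filter <- function(x, strict = TRUE) {
  sites <- site_frame(x)
  category <- classify_site(sites$ref, sites$alt)
  damage_pair <- category %in% c("transition_CT", "transition_GA")
  removed <- damage_pair | category == "indel"
  n_het <- 0L
  if (!strict) {
    supported <- if (!inherits(x, "genotype_panel") && "depth" %in% names(sites))
      sites$depth > 1L
    else
      rep(TRUE, length(category))
    removed <- (damage_pair & !supported) | category == "indel"
    if (inherits(x, "genotype_panel")) {
      rows <- which(damage_pair & !removed)
      if (length(rows)) {
        g <- x$geno[rows, , drop = FALSE]
        n_het <- sum(g == 1L, na.rm = TRUE)
        x$geno[rows, ] <- apply(g, 2, transform_het,
                                ref = sites$ref[rows], alt = sites$alt[rows])
      }
    }
  }
  list(filtered = drop_sites(x, !removed),
       accounting = filter_accounting(category, removed, n_het))
}

#' Transversion-only filter
#'
#' Retains transversion SNPs only: every transition (whatever its
#' orientation) and every indel is removed. This is the damage-robust subset
#' used to check that damage filtering does not bias downstream statistics.
#'
#' @inheritParams apply_damage_filter
#' @return List with `filtered` and `accounting`.
#' @export
apply_transversion_filter <- function(x) {
  sites <- site_frame(x)
  category <- classify_site(sites$ref, sites$alt)
  removed <- category != "transversion"
  list(filtered = drop_sites(x, !removed),
       accounting = filter_accounting(category, removed))
}

#' Estimate positional misincorporation profiles
#'
#' Per-position C-to-T rate from the 5' end and G-to-A rate from the 3' end,
#' computed as mismatching terminal observations over opportunities; positions
#' with no opportunities are reported as `NA`, not 0. The comparison base is
#' the simulation truth carried in the read set (`true_base`) or a caller
#' supplied per-site reference base.
#'
#' @param reads a `read_set`.
#' @param max_pos number of terminal positions to profile.
#' @param ref optional per-site reference base vector (indexed by
#'   `reads$site`) used instead of `reads$true_base`.
#' @return A `damage_profile` list: `pos5`, `pos3` (rates), `opp5`, `opp3`
#'   (opportunity counts), `background` (mismatch rate outside the two damage
#'   channels).
#' @export
estimate_damage_profile <- function(reads, max_pos = 15, ref = NULL) {
  if (!nrow(reads)) stop("empty read set")
  truth <- if (is.null(ref)) reads$true_base else ref[reads$site]
  pos5 <- opp5 <- rep(NA_real_, max_pos)
  pos3 <- opp3 <- rep(NA_real_, max_pos)
  for (k in seq_len(max_pos)) {
    o5 <- truth == "C" & reads$offset5 == k
    opp5[k] <- sum(o5)
    if (opp5[k] > 0) pos5[k] <- sum(o5 & reads$base == "T") / opp5[k]
    o3 <- truth == "G" & reads$offset3 == k
    opp3[k] <- sum(o3)
    if (opp3[k] > 0) pos3[k] <- sum(o3 & reads$base == "A") / opp3[k]
  }
  other <- !(truth == "C") & !(truth == "G")
  background <- if (any(other))
    sum(reads$base[other] != truth[other]) / sum(other)
  else NA_real_
  structure(list(pos5 = pos5, pos3 = pos3, opp5 = opp5, opp3 = opp3,
                 background = background),
            class = "damage_profile")
}

#' @export
print.damage_profile <- function(x, ...) {
  cat("5' C->T:", paste(round(head(x$pos5, 5), 3), collapse = " "), "...\n")
  cat("3' G->A:", paste(round(head(x$pos3, 5), 3), collapse = " "), "...\n")
  cat("background:", signif(x$background, 3), "\n")
  invisible(x)
}
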