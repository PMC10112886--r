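# Domain containers and readers/writers for the formats the pipeline touches.
# Coordinates are 1-based inclusive internally (VCF convention); BED input is
# converted exactly once on read. Genotypes are stored as alternate-allele
# dosage: 0, 1, 2 or NA (missing).

VALID_BASES <- c("A", "C", "G", "T")

site_key <- function(chrom, pos) paste(chrom, pos, sep = ":")

validate_sites <- function(sites) {
  stopifnot(is.data.frame(sites),
            all(c("chrom", "pos", "ref", "alt") %in% names(sites)))
  if (any(sites$pos < 1)) stop("site positions must be >= 1")
  if (any(sites$ref == sites$alt)) stop("ref and alt alleles must differ")
  ok <- function(a) nchar(a) > 1L | a %in% VALID_BASES
  if (!all(ok(sites$ref) & ok(sites$alt)))
    stop("alleles must be A/C/G/T or multi-base (indel)")
  invisible(sites)
}

#' Construct a genotype panel
#'
#' A `genotype_panel` holds a sites-by-samples matrix of diploid genotypes
#' (alternate-allele dosage 0/1/2, `NA` = missing) together with per-sample
#' population labels. Sites are kept sorted by (chrom, pos) and must be
#' biallelic.
#'
#' @param sites data.frame with columns `chrom`, `pos` (1-based), `ref`, `alt`.
#' @param geno integer matrix, `nrow(sites)` x number of samples; column names
#'   are sample IDs.
#' @param populations named character vector mapping every sample ID to a
#'   population label.
#' @return An object of class `genotype_panel` with elements `sites`, `geno`,
#'   `samples`, `populations`.
#' @export
genotype_panel <- function(sites, geno, populations) {
  validate_sites(sites)
  geno <- as.matrix(geno)
  if (nrow(geno) != nrow(sites))
    stop("genotype matrix rows must equal number of sites")
  samples <- colnames(geno)
  if (is.null(samples) || anyDuplicated(samples))
    stop("genotype matrix must have unique sample column names")
  if (!all(samples %in% names(populations)))
    stop("every sample needs a population label")
  if (!all(geno %in% c(0L, 1L, 2L, NA)))
    stop("genotypes must be dosage 0/1/2 or NA")
  o <- order(sites$chrom, sites$pos)
  sites <- sites[o, , drop = FALSE]
  rownames(sites) <- NULL
  geno <- geno[o, , drop = FALSE]
  structure(list(sites = sites, geno = geno, samples = samples,
                 populations = populations[samples]),
            class = "genotype_panel")
}

#' @export
print.genotype_panel <- function(x, ...) {
  cat("genotype_panel:", nrow(x$sites), "sites x", length(x$samples),
      "samples\n")
  tab <- table(x$populations)
  cat("populations:", paste(names(tab), tab, sep = "=", collapse = ", "), "\n")
  invisible(x)
}

#' Construct pseudo-haploid (or diploid) calls for one ancient sample
#'
#' @param sites data.frame with `chrom`, `pos`, `ref`, `alt`.
#' @param allele observed allele per site (single base).
#' @param depth reads covering each site after quality filtering; must be >= 1.
#' @return An `ancient_calls` data.frame.
#' @export
ancient_calls <- function(sites, allele, depth) {
  validate_sites(sites)
  stopifnot(length(allele) == nrow(sites), length(depth) == nrow(sites))
  if (any(depth < 1)) stop("depth must be >= 1 at every retained site")
  out <- data.frame(chrom = sites$chrom, pos = sites$pos, ref = sites$ref,
                    alt = sites$alt, allele = allele,
                    depth = as.integer(depth), stringsAsFactors = FALSE)
  class(out) <- c("ancient_calls", "data.frame")
  out
}

#' Construct a labelled site set
#'
#' @param chrom,pos vectors of coordinates (1-based). Duplicates are removed.
#' @param label free-text label, e.g. `"MA_adaptive"`.
#' @return A `site_set` with elements `sites` (data.frame) and `label`.
#' @export
site_set <- function(chrom, pos, label = "") {
  n <- max(length(chrom), length(pos))
  chrom <- rep_len(chrom, n)
  pos <- rep_len(pos, n)
  keys <- site_key(chrom, pos)
  keep <- !duplicated(keys)
  structure(list(sites = data.frame(chrom = chrom[keep], pos = pos[keep],
                                    stringsAsFactors = FALSE),
                 label = label),
            class = "site_set")
}

#' @export
length.site_set <- function(x) nrow(x$sites)

site_set_keys <- function(x) site_key(x$sites$chrom, x$sites$pos)

resolve_populations <- function(populations, samples) {
  if (is.null(populations))
    return(setNames(rep("unknown", length(samples)), samples))
  if (is.character(populations) && length(populations) == 1L &&
      file.exists(populations)) {
    tab <- read.table(populations, header = FALSE, sep = "\t",
                      col.names = c("sample", "pop"),
                      stringsAsFactors = FALSE)
    populations <- setNames(tab$pop, tab$sample)
  }
  populations
}

gt_to_dosage <- function(gt) {
  gt <- sub(":.*", "", gt)
  gt <- gsub("|", "/", gt, fixed = TRUE)
  d <- rep(NA_integer_, length(gt))
  d[gt %in% c("0/0")] <- 0L
  d[gt %in% c("0/1", "1/0")] <- 1L
  d[gt %in% c("1/1")] <- 2L
  d
}

#' Read a VCF into a genotype panel
#'
#' Only the GT field is used. Multiallelic records are dropped by default or
#' split into one biallelic record per alternate allele.
#'
#' @param path VCF file (plain or bgzipped).
#' @param populations optional named character vector (sample -> population) or
#'   path to a two-column sample/population TSV.
#' @param multiallelic `"drop"` (default) or `"split"`.
#' @return A [genotype_panel()].
#' @export
read_vcf <- function(path, populations = NULL,
                     multiallelic = c("drop", "split")) {
  multiallelic <- match.arg(multiallelic)
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1,
                                       dimnames = list(NULL, names(fix)))
  if (ncol(v@gt) < 2L) stop("VCF contains no sample columns (empty panel)")
  gt <- vcfR::extract.gt(v, element = "GT")
  if (is.null(dim(gt))) gt <- matrix(gt, nrow = 1,
                                     dimnames = list(NULL, names(gt)))
  alt <- fix[, "ALT"]
  multi <- grepl(",", alt, fixed = TRUE)
  rows <- list()
  genos <- list()
  for (i in seq_len(nrow(fix))) {
    if (!multi[i]) {
      rows[[length(rows) + 1L]] <-
        data.frame(chrom = fix[i, "CHROM"], pos = as.integer(fix[i, "POS"]),
                   ref = fix[i, "REF"], alt = alt[i], stringsAsFactors = FALSE)
      genos[[length(genos) + 1L]] <- gt_to_dosage(gt[i, ])
    } else if (multiallelic == "split") {
      alts <- strsplit(alt[i], ",", fixed = TRUE)[[1]]
      g <- gsub("|", "/", sub(":.*", "", gt[i, ]), fixed = TRUE)
      for (k in seq_along(alts)) {
        al <- strsplit(g, "/", fixed = TRUE)
        d <- vapply(al, function(a) {
          if (length(a) != 2L || any(a == ".")) return(NA_integer_)
          sum(a == as.character(k))
        }, integer(1))
        rows[[length(rows) + 1L]] <-
          data.frame(chrom = fix[i, "CHROM"], pos = as.integer(fix[i, "POS"]),
                     ref = fix[i, "REF"], alt = alts[k],
                     stringsAsFactors = FALSE)
        genos[[length(genos) + 1L]] <- d
      }
    }
  }
  if (!length(rows)) stop("no biallelic records parsed from ", path)
  sites <- do.call(rbind, rows)
  geno <- do.call(rbind, genos)
  colnames(geno) <- colnames(gt)
  genotype_panel(sites, geno, resolve_populations(populations, colnames(gt)))
}

#' Write a genotype panel as VCF 4.2 (GT only)
#'
#' @param panel a [genotype_panel()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(panel, path) {
  gt_str <- matrix("./.", nrow(panel$geno), ncol(panel$geno))
  gt_str[panel$geno == 0L] <- "0/0"
  gt_str[panel$geno == 1L] <- "0/1"
  gt_str[panel$geno == 2L] <- "1/1"
  header <- c("##fileformat=VCFv4.2",
              "##source=paleomaize",
              '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
              paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                      "INFO", "FORMAT", panel$samples), collapse = "\t"))
  body <- paste(panel$sites$chrom, panel$sites$pos, ".", panel$sites$ref,
                panel$sites$alt, ".", "PASS", ".", "GT",
                apply(gt_str, 1, paste, collapse = "\t"), sep = "\t")
  writeLines(c(header, body), path)
  invisible(path)
}

#' Read a HapMap-like tab-separated genotype matrix
#'
#' One row per site; columns `chrom`, `pos`, `ref`, `alt`, then one column per
#' sample holding two-letter allele pairs (e.g. `CC`, `CT`; `NN` = missing).
#' SNP sites only.
#'
#' @inheritParams read_vcf
#' @return A [genotype_panel()].
#' @export
read_genotype_tsv <- function(path, populations = NULL) {
  lines <- readLines(path)
  if (!length(lines)) stop("empty genotype TSV: ", path)
  cells <- strsplit(lines, "\t", fixed = TRUE)
  widths <- lengths(cells)
  if (any(widths != widths[1]))
    stop("ragged genotype TSV: row ", which(widths != widths[1])[1],
         " has ", widths[widths != widths[1]][1], " fields, expected ",
         widths[1])
  header <- cells[[1]]
  if (length(header) < 5L || !identical(header[1:4],
                                        c("chrom", "pos", "ref", "alt")))
    stop("genotype TSV header must start with chrom, pos, ref, alt")
  samples <- header[-(1:4)]
  body <- do.call(rbind, cells[-1])
  sites <- data.frame(chrom = body[, 1], pos = as.integer(body[, 2]),
                      ref = body[, 3], alt = body[, 4],
                      stringsAsFactors = FALSE)
  cell <- body[, -(1:4), drop = FALSE]
  bad <- !grepl("^[ACGTN][ACGTN]$", cell)
  if (any(bad))
    stop("unknown allele code '", cell[bad][1], "' in genotype TSV")
  a1 <- substr(cell, 1, 1)
  a2 <- substr(cell, 2, 2)
  alt_m <- matrix(sites$alt, nrow(sites), ncol(cell))
  ref_m <- matrix(sites$ref, nrow(sites), ncol(cell))
  known <- (a1 == alt_m | a1 == ref_m) & (a2 == alt_m | a2 == ref_m)
  if (any(!known & a1 != "N" & a2 != "N")) {
    idx <- which(!known & a1 != "N" & a2 != "N")[1]
    stop("unknown allele code '", cell[idx], "' at site ",
         site_key(sites$chrom, sites$pos)[(idx - 1) %% nrow(sites) + 1])
  }
  d <- (a1 == alt_m) + (a2 == alt_m)
  d[a1 == "N" | a2 == "N"] <- NA_integer_
  geno <- matrix(as.integer(d), nrow(sites), length(samples),
                 dimnames = list(NULL, samples))
  genotype_panel(sites, geno, resolve_populations(populations, samples))
}

#' Write a genotype panel as a HapMap-like TSV
#'
#' @inheritParams write_vcf
#' @export
write_genotype_tsv <- function(panel, path) {
  ref <- matrix(panel$sites$ref, nrow(panel$geno), ncol(panel$geno))
  alt <- matrix(panel$sites$alt, nrow(panel$geno), ncol(panel$geno))
  cell <- matrix("NN", nrow(panel$geno), ncol(panel$geno))
  cell[panel$geno == 0L] <- paste0(ref, ref)[panel$geno == 0L]
  cell[panel$geno == 1L] <- paste0(ref, alt)[panel$geno == 1L]
  cell[panel$geno == 2L] <- paste0(alt, alt)[panel$geno == 2L]
  lines <- c(paste(c("chrom", "pos", "ref", "alt", panel$samples),
                   collapse = "\t"),
             paste(panel$sites$chrom, panel$sites$pos, panel$sites$ref,
                   panel$sites$alt, apply(cell, 1, paste, collapse = "\t"),
                   sep = "\t"))
  writeLines(lines, path)
  invisible(path)
}

#' Read a BED3 SNP list into a site set
#'
#' BED intervals are 0-based half-open; each single-base interval becomes one
#' 1-based position. Wider intervals trigger a warning and are collapsed to
#' their midpoint.
#'
#' @param path BED3 file (chrom, start, end).
#' @param label label for the returned [site_set()].
#' @return A [site_set()].
#' @export
read_site_list <- function(path, label = basename(path)) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) return(site_set(character(0), integer(0), label))
  cells <- strsplit(lines, "[ \t]+")
  if (any(lengths(cells) < 3L))
    stop("BED row ", which(lengths(cells) < 3L)[1], " has fewer than 3 fields")
  chrom <- vapply(cells, `[`, "", 1)
  start <- as.integer(vapply(cells, `[`, "", 2))
  end <- as.integer(vapply(cells, `[`, "", 3))
  wide <- end != start + 1L
  if (any(wide)) {
    warning(sum(wide), " BED interval(s) wider than one base; midpoint taken")
  }
  pos <- ifelse(wide, (start + 1L + end) %/% 2L, start + 1L)
  site_set(chrom, pos, label)
}

#' Intersect a genotype panel with ancient calls
#'
#' Returns the sites present in both inputs with the ancient allele reconciled
#' to the panel's ref/alt orientation. Sites whose ancient allele matches
#' neither panel allele (including complementary-strand ambiguities, which are
#' never flipped) are dropped and counted.
#'
#' @param panel a [genotype_panel()].
#' @param calls an [ancient_calls()] data.frame.
#' @return A list with `pairs` (data.frame: site columns, `allele`, `depth`,
#'   `is_alt`, `panel_row`) and `n_dropped`.
#' @export
intersect_calls <- function(panel, calls) {
  pk <- site_key(panel$sites$chrom, panel$sites$pos)
  ck <- site_key(calls$chrom, calls$pos)
  m <- match(ck, pk)
  shared <- !is.na(m)
  pr <- m[shared]
  al <- calls$allele[shared]
  ok <- al == panel$sites$ref[pr] | al == panel$sites$alt[pr]
  pairs <- data.frame(chrom = panel$sites$chrom[pr][ok],
                      pos = panel$sites$pos[pr][ok],
                      ref = panel$sites$ref[pr][ok],
                      alt = panel$sites$alt[pr][ok],
                      allele = al[ok],
                      depth = calls$depth[shared][ok],
                      is_alt = al[ok] == panel$sites$alt[pr][ok],
                      panel_row = pr[ok],
                      stringsAsFactors = FALSE)
  list(pairs = pairs, n_dropped = sum(!ok))
}

#' Samples belonging to a population
#' @param panel a [genotype_panel()].
#' @param pop population label.
#' @return Character vector of sample IDs.
#' @export
pop_samples <- function(panel, pop) {
  panel$samples[panel$populations == pop]
}

#' Per-site alternate-allele frequency of a population
#'
#' @param panel a [genotype_panel()].
#' @param pop population label (or vector of sample IDs via `samples`).
#' @param samples optional explicit sample IDs overriding `pop`.
#' @return List with `p` (alt-allele frequency per site, NA where all calls
#'   missing) and `n` (number of non-missing alleles per site).
#' @export
pop_freq <- function(panel, pop = NULL, samples = NULL) {
  if (is.null(samples)) samples <- pop_samples(panel, pop)
  if (!length(samples)) stop("no samples for population ", pop)
  g <- panel$geno[, samples, drop = FALSE]
  n <- 2L * rowSums(!is.na(g))
  p <- rowSums(g, na.rm = TRUE) / n
  p[n == 0L] <- NA_real_
  list(p = p, n = n)
}
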