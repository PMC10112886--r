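# Identity-by-state distances and neighbor joining: a qualitative placement
# of the ancient sample among panel populations. Pairwise distance is
# 1 - mean allele-sharing over jointly non-missing sites, with haploid calls
# compared to diploid genotypes by expected sharing.

#' Identity-by-state distance matrix
#'
#' Per-site sharing between two samples is `1 - |d1 - d2| / 2` on the dosage
#' scale (1 for identical homozygotes, 0.5 for hom vs het, 0 for opposite
#' homozygotes); pseudo-haploid ancient calls enter as dosage 0/2, which
#' makes the diploid-haploid comparison the expected sharing of a random
#' allele draw. Distance is 1 minus the mean sharing over jointly non-missing
#' sites.
#'
#' @param panel a [genotype_panel()].
#' @param ancient optional [ancient_calls()] appended as one more leaf.
#' @param ancient_label leaf label for the ancient sample.
#' @param min_shared pairs sharing fewer sites are flagged (distance still
#'   reported when computable).
#' @param mode `"ibs"`: per-site sharing `1 - |d1 - d2|/2` (identical
#'   duplicates at distance 0). `"expected"`: random-allele-draw sharing
#'   `(d1 d2 + (2-d1)(2-d2))/4`, the expected match of one allele drawn from
#'   each sample. When an ancient (pseudo-haploid) sample is included the
#'   expected mode is forced for every pair: mixing the two conventions puts
#'   haploid-diploid pairs on a different scale from diploid pairs, which
#'   deflates the ancient's apparent distance to near-monomorphic outgroups
#'   and drags its long branch toward the root.
#' @return An `ibs_dist` list: `labels`, `d` (symmetric matrix, `NA` where no
#'   shared sites), `n_shared`, `flagged` (logical matrix, below floor).
#' @export
ibs_distance <- function(panel, ancient = NULL, ancient_label = "ancient",
                         min_shared = 100, mode = c("ibs", "expected")) {
  mode <- match.arg(mode)
  g <- panel$geno
  if (!is.null(ancient)) {
    mode <- "expected"
    ix <- intersect_calls(panel, ancient)
    col <- rep(NA_real_, nrow(g))
    col[ix$pairs$panel_row] <- 2 * as.numeric(ix$pairs$is_alt)
    g <- cbind(g, col)
    colnames(g)[ncol(g)] <- ancient_label
  }
  labels <- colnames(g)
  ns <- length(labels)
  if (ns < 2L) stop("need at least 2 samples")
  d <- matrix(0, ns, ns, dimnames = list(labels, labels))
  n_shared <- matrix(0L, ns, ns, dimnames = list(labels, labels))
  for (i in seq_len(ns - 1L)) for (j in (i + 1L):ns) {
    ok <- !is.na(g[, i]) & !is.na(g[, j])
    n_shared[i, j] <- n_shared[j, i] <- sum(ok)
    if (any(ok)) {
      sharing <- if (mode == "ibs")
        1 - abs(g[ok, i] - g[ok, j]) / 2
      else
        (g[ok, i] * g[ok, j] + (2 - g[ok, i]) * (2 - g[ok, j])) / 4
      d[i, j] <- d[j, i] <- 1 - mean(sharing)
    } else {
      d[i, j] <- d[j, i] <- NA_real_
    }
  }
  flagged <- n_shared < min_shared
  diag(flagged) <- FALSE
  structure(list(labels = labels, d = d, n_shared = n_shared,
                 flagged = flagged),
            class = "ibs_dist")
}

#' Neighbor-joining tree from an IBS distance matrix
#'
#' Canonical Saitou-Nei neighbor joining; a negative branch length is clamped
#' to zero and its deficit transferred to the sibling branch(es), conserving
#' total tree length (Kuhner-Felsenstein convention). Any length still
#' negative after the transfer round is set to zero.
#'
#' @param dm an `ibs_dist` or a plain symmetric distance matrix.
#' @return An [ape::nj()]-style `phylo` tree.
#' @export
neighbor_joining <- function(dm) {
  d <- if (inherits(dm, "ibs_dist")) dm$d else as.matrix(dm)
  if (anyNA(d)) stop("incomplete distance matrix (pairs with no shared sites)")
  if (nrow(d) < 3L) stop("need at least 3 taxa")
  tr <- ape::nj(d)
  for (pass in 1:5) {
    neg <- which(tr$edge.length < 0)
    if (!length(neg)) break
    for (e in neg) {
      deficit <- tr$edge.length[e]
      tr$edge.length[e] <- 0
      sib <- setdiff(which(tr$edge[, 1] == tr$edge[e, 1]), e)
      if (length(sib))
        tr$edge.length[sib] <- tr$edge.length[sib] + deficit / length(sib)
    }
  }
  tr$edge.length <- pmax(tr$edge.length, 0)
  tr
}

#' Does a label set form a clade when rooted on an outgroup?
#'
#' @param tree a `phylo` tree.
#' @param group character vector of leaf labels (outgroup excluded).
#' @param outgroup leaf label used to root the tree.
#' @return Logical.
#' @export
check_monophyly <- function(tree, group, outgroup) {
  labs <- tree$tip.label
  if (!all(c(group, outgroup) %in% labs))
    stop("unknown leaf label: ",
         paste(setdiff(c(group, outgroup), labs), collapse = ", "))
  if (outgroup %in% group) stop("outgroup cannot be part of the group")
  if (length(group) <= 1L) return(TRUE)
  rooted <- ape::root(tree, outgroup = outgroup, resolve.root = TRUE)
  ape::is.monophyletic(rooted, group)
}

#' Concordance of ancient alleles with the panel
#'
#' Fraction of intersected sites at which the ancient allele is observed in
#' at least one panel genotype.
#'
#' @param calls an [ancient_calls()] data.frame.
#' @param panel a [genotype_panel()].
#' @return Fraction in `[0, 1]`; attribute `n_sites` gives the intersection
#'   size (allele-irreconcilable sites count as discordant).
#' @export
panel_concordance <- function(calls, panel) {
  ix <- intersect_calls(panel, calls)
  n_total <- nrow(ix$pairs) + ix$n_dropped
  if (n_total == 0L) stop("empty intersection between calls and panel")
  pr <- ix$pairs$panel_row
  g <- panel$geno[pr, , drop = FALSE]
  has_ref <- rowSums(g < 2L, na.rm = TRUE) > 0L
  has_alt <- rowSums(g > 0L, na.rm = TRUE) > 0L
  seen <- ifelse(ix$pairs$is_alt, has_alt, has_ref)
  out <- sum(seen) / n_total
  attr(out, "n_sites") <- n_total
  out
}
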