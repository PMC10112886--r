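# ABBA-BABA D-statistics. With the outgroup defining the ancestral (A) state,
# ABBA sites share the derived allele between P2 and P3 and BABA sites between
# P1 and P3; incomplete lineage sorting produces the two patterns at equal
# rates while gene flow between P3 and one of P1/P2 skews them. D =
# (x - y) / (x + y) with x = ABBA, y = BABA. Uncertainty comes from a
# delete-one block jackknife over contiguous genomic blocks.

#' Polarize quartet sites on an outgroup sample
#'
#' The outgroup's allele defines the ancestral state; the panel's other allele
#' is derived. Sites where the outgroup is heterozygous or missing are dropped
#' and counted.
#'
#' @param geno matrix (sites x samples) of dosage genotypes for the quartet
#'   samples.
#' @param outgroup dosage vector of the outgroup sample (0 = hom ref,
#'   2 = hom alt).
#' @return List with `derived` (matrix of derived-allele frequencies per
#'   sample, rows = retained sites), `kept` (logical index of retained sites)
#'   and `n_dropped`.
#' @export
polarize_sites <- function(geno, outgroup) {
  stopifnot(nrow(geno) == length(outgroup))
  kept <- !is.na(outgroup) & outgroup != 1L
  g <- geno[kept, , drop = FALSE] / 2
  flip <- outgroup[kept] == 2L
  g[flip, ] <- 1 - g[flip, , drop = FALSE]
  list(derived = g, kept = kept, n_dropped = sum(!kept))
}

#' Count ABBA and BABA site patterns
#'
#' In frequency mode each site contributes `(1-p1) p2 p3 (1-pO)` to ABBA and
#' `p1 (1-p2) p3 (1-pO)` to BABA, with `p` the derived-allele frequency; this
#' reduces to integer pattern counting when all frequencies are 0 or 1, which
#' is what count mode asserts and computes by direct pattern matching.
#'
#' @param p1,p2,p3 derived-allele frequencies (or 0/1 haploid codes) per site.
#' @param pO outgroup derived frequency per site; 0 after [polarize_sites()].
#' @param mode `"frequency"` (default) or `"count"` (requires 0/1 input).
#' @return A `pattern_counts` list: `x` (ABBA), `y` (BABA), `n_sites`
#'   (informative sites used), and per-site contributions `x_i`, `y_i` for
#'   jackknifing.
#' @export
count_abba_baba <- function(p1, p2, p3, pO = 0, mode = c("frequency",
                                                         "count")) {
  mode <- match.arg(mode)
  pO <- rep_len(pO, length(p1))
  keep <- complete.cases(p1, p2, p3, pO)
  p1 <- p1[keep]; p2 <- p2[keep]; p3 <- p3[keep]; pO <- pO[keep]
  if (mode == "count") {
    vals <- c(p1, p2, p3, pO)
    if (!all(vals %in% c(0, 1)))
      stop("count mode requires haploid 0/1 codings")
    x_i <- as.numeric(p1 == 0 & p2 == 1 & p3 == 1 & pO == 0)
    y_i <- as.numeric(p1 == 1 & p2 == 0 & p3 == 1 & pO == 0)
  } else {
    x_i <- (1 - p1) * p2 * p3 * (1 - pO)
    y_i <- p1 * (1 - p2) * p3 * (1 - pO)
  }
  structure(list(x = sum(x_i), y = sum(y_i), n_sites = length(x_i),
                 x_i = x_i, y_i = y_i),
            class = "pattern_counts")
}

#' The D statistic
#'
#' `D = (x - y) / (x + y)` from ABBA (`x`) and BABA (`y`) tallies.
#'
#' @param counts a `pattern_counts` from [count_abba_baba()], or a list with
#'   `x` and `y`.
#' @return Numeric D in `[-1, 1]`.
#' @export
compute_D <- function(counts) {
  if (counts$x + counts$y <= 0)
    stop("D undefined: no ABBA or BABA informative sites")
  (counts$x - counts$y) / (counts$x + counts$y)
}

#' Block-jackknife D with standard deviation
#'
#' Sites (already in genomic order) are partitioned into `n_blocks`
#' contiguous, near-equal blocks; a replicate D is computed deleting each
#' block in turn and the delete-one jackknife standard deviation
#' `sqrt((g-1)/g * sum((d_j - mean(d_j))^2))` is reported along with
#' `z = d / sd`.
#'
#' @param counts a `pattern_counts` carrying per-site contributions.
#' @param n_blocks number of jackknife blocks (reduced with a warning when
#'   there are fewer informative sites).
#' @param design,quartet optional metadata stored on the result.
#' @return A `d_result` list: `d`, `sd`, `z`, `n_sites`, `n_blocks`,
#'   `design`, `quartet`.
#' @export
jackknife_D <- function(counts, n_blocks = 100, design = NA_character_,
                        quartet = NULL) {
  n <- counts$n_sites
  if (n < 1L) stop("no informative sites")
  if (n_blocks > n) {
    warning("fewer informative sites (", n, ") than blocks (", n_blocks,
            "); reducing blocks")
    n_blocks <- n
  }
  block <- ceiling(seq_len(n) * n_blocks / n)
  xb <- rowsum(counts$x_i, block)[, 1]
  yb <- rowsum(counts$y_i, block)[, 1]
  X <- sum(xb); Y <- sum(yb)
  d <- compute_D(list(x = X, y = Y))
  d_j <- ((X - xb) - (Y - yb)) / ((X - xb) + (Y - yb))
  g <- length(d_j)
  sd_jk <- sqrt((g - 1) / g * sum((d_j - mean(d_j))^2))
  structure(list(d = d, sd = sd_jk, z = if (sd_jk > 0) d / sd_jk else NA_real_,
                 n_sites = n, n_blocks = n_blocks, design = design,
                 quartet = quartet),
            class = "d_result")
}

#' @export
print.d_result <- function(x, ...) {
  cat(sprintf("D = %.4f (jackknife sd %.4g, z = %.2f, %d sites, %d blocks)\n",
              x$d, x$sd, x$z, x$n_sites, x$n_blocks))
  if (!is.null(x$quartet))
    cat("quartet:", paste(x$quartet, collapse = ", "), "\n")
  invisible(x)
}

test_freqs <- function(panel, test, ancient = NULL) {
  if (!is.null(ancient)) {
    ix <- intersect_calls(panel, ancient)
    p <- rep(NA_real_, nrow(panel$sites))
    p[ix$pairs$panel_row] <- as.numeric(ix$pairs$is_alt)
    return(p)
  }
  if (!test %in% panel$samples) stop("unknown test sample ", test)
  panel$geno[, test] / 2
}

#' Distribution of D over accession pairs
#'
#' One D-statistic per (P1 accession x P2 accession) combination under the
#' chosen quartet design, restricted to sites covered in the test sample.
#' Design `"i"` is D(P1-pop accession, P2-pop accession, TEST, outgroup):
#' gene flow between the P2 population and TEST pushes D positive. Design
#' `"ii"` is D(TEST, P1-pop accession, P2-pop accession, outgroup): D below
#' zero indicates more gene flow between the P2 population and TEST than
#' between the P2 and P1 populations.
#'
#' @param panel a [genotype_panel()].
#' @param test test sample: a panel sample ID, or the name to report when
#'   `ancient` is supplied.
#' @param ancient optional [ancient_calls()] used as the test sample
#'   (pseudo-haploid, coded 0/1).
#' @param design `"i"` or `"ii"`.
#' @param p1_pop,p2_pop population labels whose accessions are crossed.
#' @param outgroup outgroup sample ID.
#' @param n_blocks jackknife blocks.
#' @return data.frame with one row per accession pair: `p1`, `p2`, `test`,
#'   `design`, `d`, `sd`, `z`, `n_sites`.
#' @export
d_distribution <- function(panel, test, ancient = NULL,
                           design = c("i", "ii"), p1_pop = "parviglumis",
                           p2_pop = "mexicana", outgroup = NULL,
                           n_blocks = 100) {
  design <- match.arg(design)
  s1 <- pop_samples(panel, p1_pop)
  s2 <- pop_samples(panel, p2_pop)
  if (!length(s1) || !length(s2))
    stop("empty role population (", p1_pop, ": ", length(s1), ", ",
         p2_pop, ": ", length(s2), ")")
  if (is.null(outgroup) || !outgroup %in% panel$samples)
    stop("outgroup sample must be in the panel")
  pt <- test_freqs(panel, test, ancient)
  og <- panel$geno[, outgroup]
  covered <- !is.na(pt)
  out <- vector("list", length(s1) * length(s2))
  k <- 0L
  for (a in s1) for (b in s2) {
    quartet_dosage <- cbind(panel$geno[, a], panel$geno[, b], pt * 2)
    pol <- polarize_sites(quartet_dosage[covered, , drop = FALSE],
                          og[covered])
    der <- pol$derived
    cnt <- if (design == "i")
      count_abba_baba(der[, 1], der[, 2], der[, 3])
    else
      count_abba_baba(der[, 3], der[, 1], der[, 2])
    r <- jackknife_D(cnt, n_blocks, design,
                     quartet = if (design == "i") c(a, b, test, outgroup)
                     else c(test, a, b, outgroup))
    k <- k + 1L
    out[[k]] <- data.frame(p1 = a, p2 = b, test = test, design = design,
                           d = r$d, sd = r$sd, z = r$z, n_sites = r$n_sites,
                           stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}

#' Two-sample Kolmogorov-Smirnov test on D distributions
#'
#' @param a,b numeric vectors (at least 2 values each).
#' @return List with `statistic` and `p.value` (two-sided, asymptotic).
#' @export
ks_two_sample <- function(a, b) {
  stopifnot(length(a) >= 2, length(b) >= 2)
  if (anyDuplicated(c(a, b)))
    warning("ties present; asymptotic K-S p-value is approximate")
  k <- suppressWarnings(ks.test(a, b))
  list(statistic = unname(k$statistic), p.value = k$p.value)
}

#' One-sample Wilcoxon signed-rank test of D against zero
#'
#' Zeros are dropped per the signed-rank convention; if every value is zero
#' the test is degenerate and p = 1.
#'
#' @param ds numeric vector of D values (at least 5).
#' @return Two-sided p-value.
#' @export
wilcoxon_sign_test <- function(ds) {
  stopifnot(length(ds) >= 5)
  ds <- ds[ds != 0]
  if (!length(ds)) return(1)
  suppressWarnings(wilcox.test(ds, mu = 0, alternative = "two.sided"))$p.value
}
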