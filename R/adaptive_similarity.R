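# Elevation-adaptive SNP identification by Hudson F_ST and the
# allelic-similarity statistic S: the mean frequency, in a test population,
# of the alleles carried by the ancient sample across intersected sites.
# Significance comes from resampling nulls (same draw size, background SNPs),
# a coverage-underrepresentation test, and a Fisher exact comparison of
# covered proportions between regions.

#' Hudson F_ST estimator with sample-size correction
#'
#' `((p1-p2)^2 - p1(1-p1)/(n1-1) - p2(1-p2)/(n2-1)) / (p1(1-p2) + p2(1-p1))`.
#' Pass `n = Inf` for the infinite-sample (parametric) value. Sites
#' monomorphic in both populations have an undefined F_ST and return `NA`.
#'
#' @param p1,p2 allele frequencies in the two populations (vectorised).
#' @param n1,n2 number of sampled alleles per population (>= 2).
#' @param clip clip the estimate into `[0, 1]` (default); `FALSE` returns the
#'   raw value, which can be slightly negative by sampling noise.
#' @return Numeric vector of F_ST values.
#' @export
#' @examples
#' hudson_fst(0.9, 0.1, Inf, Inf) # 0.64 / 0.82
hudson_fst <- function(p1, p2, n1, n2, clip = TRUE) {
  den <- p1 * (1 - p2) + p2 * (1 - p1)
  num <- (p1 - p2)^2 - p1 * (1 - p1) / (n1 - 1) - p2 * (1 - p2) / (n2 - 1)
  fst <- ifelse(den > 0, num / den, NA_real_)
  if (clip) fst <- pmin(pmax(fst, 0), 1)
  fst
}

#' Scan for elevation-adaptive SNPs by F_ST outliers
#'
#' Per-site Hudson F_ST between the highland and lowland populations of a
#' region; sites above an empirical outlier quantile (default 99.9th), or
#' with a label-permutation p-value below `alpha`, are flagged significant.
#' The adaptive allele is canonicalised on the non-reference allele: at a
#' biallelic site "allele A adaptive in lowland" and "allele B adaptive in
#' highland" describe the same site, so `adaptive_class` is reported as the
#' elevation class in which the alt allele is the high-frequency one.
#'
#' @param panel a [genotype_panel()].
#' @param region region label stored on the result (e.g. `"MA"`).
#' @param highland_pop,lowland_pop population labels.
#' @param sig significance rule: `"quantile"` (default) or `"permutation"`.
#' @param sig_quantile outlier quantile for the quantile rule.
#' @param n_perm,alpha permutation count and per-site threshold for the
#'   permutation rule.
#' @param seed integer seed (permutation rule only).
#' @return An `adaptive_snp_set` data.frame: site columns, `fst`,
#'   `adaptive_allele`, `adaptive_class`, `significant`; attribute `region`.
#' @export
identify_adaptive_snps <- function(panel, region, highland_pop, lowland_pop,
                                   sig = c("quantile", "permutation"),
                                   sig_quantile = 0.999, n_perm = 1000,
                                   alpha = 0.001, seed = 1L) {
  sig <- match.arg(sig)
  fh <- pop_freq(panel, highland_pop)
  fl <- pop_freq(panel, lowland_pop)
  fst <- hudson_fst(fh$p, fl$p, fh$n, fl$n)
  if (sig == "quantile") {
    thr <- quantile(fst, sig_quantile, na.rm = TRUE)
    significant <- !is.na(fst) & fst >= thr
  } else {
    set.seed(derive_seed(seed, "fst_perm"))
    cols <- c(pop_samples(panel, highland_pop),
              pop_samples(panel, lowland_pop))
    nh <- length(pop_samples(panel, highland_pop))
    exceed <- rep(0L, nrow(panel$sites))
    for (r in seq_len(n_perm)) {
      perm <- sample(cols)
      ph <- pop_freq(panel, samples = perm[seq_len(nh)])
      pl <- pop_freq(panel, samples = perm[-seq_len(nh)])
      f <- hudson_fst(ph$p, pl$p, ph$n, pl$n)
      exceed <- exceed + as.integer(!is.na(f) & !is.na(fst) & f >= fst)
    }
    significant <- !is.na(fst) & (exceed + 1) / (n_perm + 1) <= alpha
  }
  out <- data.frame(chrom = panel$sites$chrom, pos = panel$sites$pos,
                    ref = panel$sites$ref, alt = panel$sites$alt,
                    fst = fst,
                    adaptive_allele = panel$sites$alt,
                    adaptive_class = ifelse(fh$p >= fl$p, "highland",
                                            "lowland"),
                    significant = significant,
                    stringsAsFactors = FALSE)
  attr(out, "region") <- region
  class(out) <- c("adaptive_snp_set", "data.frame")
  out
}

#' Allelic similarity S between an ancient sample and a test population
#'
#' `S = (1/N) * sum_i f_i`, the mean over intersected sites of the test
#' population's frequency of the allele the ancient sample carries.
#' Pseudo-haploid calls contribute their single allele; diploid calls weight
#' both alleles by 0.5.
#'
#' @param calls an [ancient_calls()] data.frame.
#' @param panel a [genotype_panel()].
#' @param pop test population label.
#' @param sites optional [site_set()] restricting the intersected sites.
#' @return List: `s_obs`, `n_sites`, and the per-site frequencies `f`.
#' @export
allelic_similarity <- function(calls, panel, pop, sites = NULL) {
  ix <- intersect_calls(panel, calls)
  pairs <- ix$pairs
  if (!is.null(sites)) {
    keep <- site_key(pairs$chrom, pairs$pos) %in% site_set_keys(sites)
    pairs <- pairs[keep, , drop = FALSE]
  }
  if (!nrow(pairs)) stop("no intersected sites for similarity")
  pf <- pop_freq(panel, pop)
  p_alt <- pf$p[pairs$panel_row]
  f <- ifelse(pairs$is_alt, p_alt, 1 - p_alt)
  f <- f[!is.na(f)]
  if (!length(f)) stop("test population has no called genotypes at sites")
  list(s_obs = mean(f), n_sites = length(f), f = f)
}

#' Resampling null for the similarity statistic
#'
#' Each replicate draws `draw_size` background frequencies without
#' replacement and records their mean; `p_low` is the plain proportion of the
#' null at or below `s_obs` (the add-one convention is available). The null
#' mean is the genome-wide similarity expectation.
#'
#' @param f_background per-site frequencies of the ancient allele at
#'   background (non-adaptive) covered sites.
#' @param draw_size sites per draw (the number of covered adaptive SNPs).
#' @param s_obs observed similarity at the adaptive sites (optional; `p_low`
#'   is `NA` without it).
#' @param n_reps replicates (default 10000).
#' @param seed integer seed.
#' @param add_one use `(count + 1) / (n_reps + 1)` for `p_low`.
#' @return A `similarity_result` list: `s_obs`, `n_sites`, `null_mean`,
#'   `null_sd`, `null_quantiles`, `p_low`, `n_reps`, `seed`.
#' @export
similarity_null <- function(f_background, draw_size, s_obs = NULL,
                            n_reps = 10000, seed = 1L, add_one = FALSE) {
  if (length(f_background) < draw_size)
    stop("background smaller than draw size")
  set.seed(derive_seed(seed, "similarity_null"))
  null <- vapply(seq_len(n_reps), function(i)
    mean(f_background[sample.int(length(f_background), draw_size)]),
    numeric(1))
  p_low <- if (is.null(s_obs)) NA_real_
  else if (add_one) (sum(null <= s_obs) + 1) / (n_reps + 1)
  else mean(null <= s_obs)
  structure(list(s_obs = if (is.null(s_obs)) NA_real_ else s_obs,
                 n_sites = draw_size, null_mean = mean(null),
                 null_sd = sd(null),
                 null_quantiles = quantile(null, c(0.025, 0.5, 0.975)),
                 null = null, p_low = p_low, n_reps = n_reps, seed = seed),
            class = "similarity_result")
}

#' @export
print.similarity_result <- function(x, ...) {
  cat(sprintf(
    "S_obs = %.4f over %d sites; null %.4f +/- %.4f (%d reps); p_low = %s\n",
    x$s_obs, x$n_sites, x$null_mean, x$null_sd, x$n_reps,
    format.pval(x$p_low)))
  invisible(x)
}

#' Full similarity test of an ancient sample against a test population
#'
#' Computes the observed S at the covered adaptive sites and the resampling
#' null from covered background sites (draws of the same size), returning the
#' one-sided `p_low` for reduced similarity.
#'
#' @inheritParams allelic_similarity
#' @param adaptive a [site_set()] of adaptive sites.
#' @param background a [site_set()] of background (non-adaptive) sites; when
#'   `NULL`, all intersected sites not in `adaptive`.
#' @param n_reps,seed,add_one passed to [similarity_null()].
#' @return A `similarity_result`.
#' @export
similarity_test <- function(calls, panel, pop, adaptive, background = NULL,
                            n_reps = 10000, seed = 1L, add_one = FALSE) {
  obs <- allelic_similarity(calls, panel, pop, sites = adaptive)
  ix <- intersect_calls(panel, calls)
  pairs <- ix$pairs
  keys <- site_key(pairs$chrom, pairs$pos)
  bg_keep <- if (is.null(background)) !keys %in% site_set_keys(adaptive)
  else keys %in% site_set_keys(background)
  pairs <- pairs[bg_keep, , drop = FALSE]
  pf <- pop_freq(panel, pop)
  p_alt <- pf$p[pairs$panel_row]
  f_bg <- ifelse(pairs$is_alt, p_alt, 1 - p_alt)
  f_bg <- f_bg[!is.na(f_bg)]
  similarity_null(f_bg, draw_size = obs$n_sites, s_obs = obs$s_obs,
                  n_reps = n_reps, seed = seed, add_one = add_one)
}

#' Coverage-underrepresentation test for adaptive SNPs
#'
#' Observed = number of adaptive sites covered in the ancient sample. Each
#' replicate draws `|adaptive|` sites from the background and counts how many
#' are covered; `p_under` is the proportion of the null at or below the
#' observed count.
#'
#' @param adaptive,background,covered [site_set()] objects; `background` is
#'   the pool the null draws from, `covered` the ancient-covered sites.
#' @param n_reps replicates (default 10000).
#' @param seed integer seed.
#' @return A `coverage_test_result` list: `n_adaptive`, `n_covered_obs`,
#'   `null_mean`, `null_sd`, `p_under`, `n_reps`.
#' @export
coverage_test <- function(adaptive, background, covered, n_reps = 10000,
                          seed = 1L) {
  n_draw <- length(adaptive)
  if (length(background) < n_draw) stop("background smaller than draw size")
  obs <- sum(site_set_keys(adaptive) %in% site_set_keys(covered))
  set.seed(derive_seed(seed, "coverage_test"))
  bg_cov <- site_set_keys(background) %in% site_set_keys(covered)
  null <- vapply(seq_len(n_reps), function(i)
    sum(bg_cov[sample.int(length(bg_cov), n_draw)]), numeric(1))
  structure(list(n_adaptive = n_draw, n_covered_obs = obs,
                 null_mean = mean(null), null_sd = sd(null), null = null,
                 p_under = mean(null <= obs), n_reps = n_reps),
            class = "coverage_test_result")
}

#' Two-sided Fisher exact test on a 2x2 table
#'
#' Standard two-sided convention: the sum of hypergeometric point
#' probabilities no larger than that of the observed table, with margins
#' fixed. A zero margin makes the table degenerate and returns p = 1.
#'
#' @param a,b,c,d cell counts, table rows `(a, b)` and `(c, d)`.
#' @return Two-sided p-value.
#' @export
#' @examples
#' fisher_exact(32, 668, 20, 390)
fisher_exact <- function(a, b, c, d) {
  stopifnot(a >= 0, b >= 0, c >= 0, d >= 0)
  if (a + b == 0 || c + d == 0 || a + c == 0 || b + d == 0) return(1)
  fisher.test(matrix(c(a, c, b, d), 2))$p.value
}
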