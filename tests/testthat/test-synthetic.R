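two_pop_config <- function(f1, f2, n_sites = 20000, seed = 1,
                           n_per_pop = 10) {
  tree <- data.frame(parent = c("anc", "anc"), child = c("A", "B"),
                     drift = c(f1, f2), stringsAsFactors = FALSE)
  sim_config(n_sites = n_sites, pop_tree = tree,
             sample_sizes = c(A = n_per_pop, B = n_per_pop),
             ancient_pop = "A", outgroup = "A",
             outgroup_ancestral_frac = 0, seed = seed)
}

# genome-wide Hudson F_ST as a ratio of sums
fst_genomewide <- function(panel, pop1, pop2) {
  f1 <- pop_freq(panel, pop1); f2 <- pop_freq(panel, pop2)
  num <- (f1$p - f2$p)^2 - f1$p * (1 - f1$p) / (f1$n - 1) -
    f2$p * (1 - f2$p) / (f2$n - 1)
  den <- f1$p * (1 - f2$p) + f2$p * (1 - f1$p)
  sum(num, na.rm = TRUE) / sum(den, na.rm = TRUE)
}

test_that("panel genotypes conserve frequencies and dimensions", {
  sim <- small_sim()
  p <- sim$panel
  expect_equal(dim(p$geno), c(6000L, length(p$samples)))
  expect_true(all(p$geno %in% 0:2))
  expect_true(all(sim$truth$leaf_freqs >= 0 & sim$truth$leaf_freqs <= 1))
  # sites sorted and aligned with truth
  expect_false(is.unsorted(order(p$sites$chrom, p$sites$pos)))
  expect_equal(length(sim$truth$ancient_genotypes), nrow(p$sites))
})

test_that("zero drift and no admixture yields identical frequencies", {
  sim <- simulate_panel(two_pop_config(0, 0, n_sites = 5000))
  expect_equal(sim$truth$leaf_freqs[, "A"], sim$truth$leaf_freqs[, "B"])
  expect_lt(abs(fst_genomewide(sim$panel, "A", "B")), 0.01)
})

test_that("Balding-Nichols drift matches its closed-form Hudson F_ST", {
  # two populations split with branch values F1, F2: expected genome-wide
  # Hudson F_ST (ratio of sums) is (F1 + F2) / 2
  sim <- simulate_panel(two_pop_config(0.2, 0.2, n_sites = 20000, seed = 5))
  expect_lt(abs(fst_genomewide(sim$panel, "A", "B") - 0.2), 0.05)
  sim2 <- simulate_panel(two_pop_config(0.3, 0.1, n_sites = 20000, seed = 6))
  expect_lt(abs(fst_genomewide(sim2$panel, "A", "B") - 0.2), 0.05)
})

test_that("simulation is deterministic under a fixed seed", {
  a <- simulate_panel(sim_config(n_sites = 1000, seed = 42))
  b <- simulate_panel(sim_config(n_sites = 1000, seed = 42))
  expect_identical(a, b)
  c <- simulate_panel(sim_config(n_sites = 1000, seed = 43))
  expect_false(identical(a$panel$geno, c$panel$geno))
})

test_that("adaptive-site injection honors count, effect, and truth classes", {
  sim <- small_sim(seed = 9)
  out <- simulate_adaptive_sites(sim$panel, sim$truth, "MA", 40,
                                 effect = 0.4, seed = 2)
  tr <- out$truth$adaptive_sites
  expect_equal(nrow(tr), 40L)
  idx <- match(paste(tr$chrom, tr$pos), paste(out$panel$sites$chrom,
                                              out$panel$sites$pos))
  fh <- out$truth$leaf_freqs[idx, "MA_highland"]
  expect_true(all(abs(fh - 0.9) < 1e-9 | abs(fh - 0.1) < 1e-9))
  expect_equal(ifelse(fh > 0.5, "highland", "lowland"), tr$adaptive_class)
  # parametric Hudson F_ST at 0.9 vs 0.1 is 0.64/0.82
  expect_equal(hudson_fst(0.9, 0.1, Inf, Inf), 0.64 / 0.82, tolerance = 1e-12)
  expect_error(simulate_adaptive_sites(out$panel, out$truth, "MA", 1e6),
               "exceeds")
})

test_that("null-effect adaptive sites are indistinguishable from background", {
  sim <- small_sim(seed = 13)
  out <- simulate_adaptive_sites(sim$panel, sim$truth, "MA", 500,
                                 effect = 0, seed = 4)
  fh <- pop_freq(out$panel, "MA_highland")
  fl <- pop_freq(out$panel, "MA_lowland")
  fst <- hudson_fst(fh$p, fl$p, fh$n, fl$n)
  is_ad <- paste(out$panel$sites$chrom, out$panel$sites$pos, sep = ":") %in%
    paste(out$truth$adaptive_sites$chrom, out$truth$adaptive_sites$pos,
          sep = ":")
  ks <- suppressWarnings(stats::ks.test(fst[is_ad], fst[!is_ad]))
  expect_gt(ks$p.value, 0.01)
})

test_that("damage-free reads only show true alleles; depths are Poisson", {
  sim <- small_sim(seed = 21)
  clean <- damage_params(delta5 = 0, delta3 = 0, base_error = 0)
  rd <- simulate_ancient_reads(sim$truth$ancient_genotypes, sim$panel$sites,
                               clean, mean_depth = 1.2, seed = 8)
  g <- sim$truth$ancient_genotypes[rd$site]
  ok <- (rd$base == sim$panel$sites$ref[rd$site] & g < 2L) |
    (rd$base == sim$panel$sites$alt[rd$site] & g > 0L)
  expect_true(all(ok))
  # P(X = 1 | X >= 1) for Poisson(1.2) is 0.5172
  depth <- tabulate(rd$site, nbins = nrow(sim$panel$sites))
  analytic <- stats::dpois(1, 1.2) / (1 - stats::dpois(0, 1.2))
  expect_equal(mean(depth[depth >= 1] == 1), analytic, tolerance = 0.03)
})

test_that("terminal deamination rate matches the injected binomial rate", {
  sim <- simulate_panel(sim_config(n_sites = 25000, seed = 31))
  dmg <- damage_params(delta5 = 0.15, delta3 = 0.15, base_error = 0)
  rd <- simulate_ancient_reads(sim$truth$ancient_genotypes, sim$panel$sites,
                               dmg, mean_depth = 4, seed = 9)
  term <- rd$true_base == "C" & rd$offset5 == 1L
  rate <- mean(rd$base[term] == "T")
  se <- sqrt(0.15 * 0.85 / sum(term))
  expect_lt(abs(rate - 0.15), 3 * se)
})

test_that("pseudo-haploid calling applies thresholds and samples uniformly", {
  sites <- data.frame(chrom = "chr1", pos = 1:2, ref = "A", alt = "C",
                      stringsAsFactors = FALSE)
  one_read <- data.frame(site = 1L, chrom = "chr1", pos = 1L, base = "C",
                         true_base = "C", offset5 = 5L, offset3 = 26L,
                         len = 30L, qual = 30L, stringsAsFactors = FALSE)
  out <- pseudo_haploid_call(one_read, sites)
  expect_equal(nrow(out), 1L)
  expect_equal(out$allele, "C")
  expect_equal(out$depth, 1L)

  short <- one_read; short$len <- 29L
  expect_equal(nrow(pseudo_haploid_call(short, sites)), 0L)
  lowq <- one_read; lowq$qual <- 9L
  expect_equal(nrow(pseudo_haploid_call(lowq, sites)), 0L)

  # {T x3, C x1}: the call is T in ~75% of seeds
  reads <- data.frame(site = 1L, chrom = "chr1", pos = 1L,
                      base = c("T", "T", "T", "C"),
                      true_base = "T", offset5 = 10L, offset3 = 21L,
                      len = 30L, qual = 30L, stringsAsFactors = FALSE)
  picks <- vapply(1:300, function(s)
    pseudo_haploid_call(reads, sites, seed = s)$allele, "")
  expect_equal(mean(picks == "T"), 0.75, tolerance = 0.08)
  expect_equal(pseudo_haploid_call(reads, sites, seed = 1)$depth, 4L)
})
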