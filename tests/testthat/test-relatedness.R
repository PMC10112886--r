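panel_from_geno <- function(geno, pops = NULL) {
  n <- nrow(geno)
  sites <- data.frame(chrom = "chr1", pos = seq_len(n) * 10L, ref = "A",
                      alt = "G", stringsAsFactors = FALSE)
  if (is.null(pops)) pops <- setNames(rep("p", ncol(geno)), colnames(geno))
  genotype_panel(sites, geno, pops)
}

test_that("IBS distances hit their fixed points and a hand-computed fixture", {
  g <- cbind(a = c(0L, 2L, 1L, 0L), b = c(0L, 2L, 1L, 0L),
             c = c(2L, 0L, 1L, 2L), d = c(0L, 1L, 2L, 0L))
  p <- panel_from_geno(g)
  dm <- ibs_distance(p, min_shared = 1)
  expect_equal(unname(dm$d["a", "b"]), 0)        # duplicate sample
  expect_equal(unname(dm$d["a", "c"]), 0.75)     # opposite at 3 of 4
  # hand computation for a-d: per-site sharing 1, 0.5, 0.5, 1 -> d = 0.25
  expect_equal(unname(dm$d["a", "d"]), 0.25)
  expect_true(isSymmetric(dm$d))
  expect_equal(unname(diag(dm$d)), rep(0, 4))
  # fully opposite homozygotes
  g2 <- cbind(x = c(0L, 0L), y = c(2L, 2L))
  expect_equal(unname(ibs_distance(panel_from_geno(g2),
                                   min_shared = 1)$d["x", "y"]), 1)
})

test_that("pairs below the shared-site floor are flagged", {
  g <- cbind(a = c(0L, NA, NA, NA), b = c(0L, 2L, 1L, 0L),
             c = c(2L, 0L, 1L, 2L))
  dm <- ibs_distance(panel_from_geno(g), min_shared = 2)
  expect_true(dm$flagged["a", "b"])
  expect_false(dm$flagged["b", "c"])
  expect_equal(unname(dm$n_shared["a", "b"]), 1L)
})

test_that("neighbor joining recovers additive trees exactly", {
  set.seed(31)
  for (ntaxa in c(4, 6, 8)) {
    true <- ape::rtree(ntaxa, br = function(n) runif(n, 0.05, 0.5))
    dmat <- ape::cophenetic.phylo(true)
    rec <- neighbor_joining(dmat)
    expect_equal(ape::dist.topo(ape::unroot(true), ape::unroot(rec)), 0,
                 ignore_attr = TRUE)
    # branch lengths recovered on additive input
    expect_equal(ape::cophenetic.phylo(rec)[rownames(dmat), colnames(dmat)],
                 dmat, tolerance = 1e-8)
  }
})

test_that("neighbor joining handles 3 taxa, label order, and bad input", {
  d3 <- matrix(c(0, .2, .4, .2, 0, .5, .4, .5, 0), 3,
               dimnames = list(c("a", "b", "c"), c("a", "b", "c")))
  expect_equal(ape::Ntip(neighbor_joining(d3)), 3L)
  set.seed(5)
  true <- ape::rtree(6, br = function(n) runif(n, 0.05, 0.5))
  dmat <- ape::cophenetic.phylo(true)
  perm <- sample(rownames(dmat))
  t1 <- neighbor_joining(dmat)
  t2 <- neighbor_joining(dmat[perm, perm])
  expect_equal(ape::dist.topo(ape::unroot(t1), ape::unroot(t2)), 0,
               ignore_attr = TRUE)
  dmat[1, 2] <- dmat[2, 1] <- NA
  expect_error(neighbor_joining(dmat), "incomplete")
  expect_error(neighbor_joining(d3[1:2, 1:2]), "3 taxa")
})

test_that("negative NJ branches are clamped with excess moved to siblings", {
  # distances violating additivity produce a negative NJ branch
  d <- matrix(c(0, 0.500, 0.167, 0.696,
                0.500, 0, 0.449, 0.853,
                0.167, 0.449, 0, 0.235,
                0.696, 0.853, 0.235, 0), 4,
              dimnames = list(letters[1:4], letters[1:4]))
  raw <- ape::nj(d)
  tr <- neighbor_joining(d)
  expect_true(any(raw$edge.length < 0))
  expect_true(all(tr$edge.length >= 0))
  # the deficit is transferred to siblings, conserving total tree length
  expect_equal(sum(tr$edge.length), sum(raw$edge.length))
  expect_equal(ape::dist.topo(ape::unroot(raw), ape::unroot(tr)), 0,
               ignore_attr = TRUE)
})

test_that("monophyly checks respect the rooted topology", {
  tr <- ape::read.tree(text = "(((a:1,b:1):1,(c:1,d:1):1):1,o:3);")
  expect_true(check_monophyly(tr, c("a", "b"), "o"))
  expect_false(check_monophyly(tr, c("a", "c"), "o"))
  expect_true(check_monophyly(tr, c("a", "b", "c", "d"), "o"))
  expect_true(check_monophyly(tr, "a", "o"))
  expect_error(check_monophyly(tr, c("a", "zz"), "o"), "zz")
  expect_error(check_monophyly(tr, c("a", "o"), "o"), "outgroup")
})

test_that("panel concordance counts alleles observed in the panel", {
  g <- cbind(a = c(0L, 0L, 2L, 1L), b = c(0L, 0L, 2L, 0L))
  p <- panel_from_geno(g)
  # alt allele at site 1 is absent from the panel: 3 of 4 concordant
  calls <- ancient_calls(p$sites, c("G", "A", "G", "G"), rep(1L, 4))
  expect_equal(as.numeric(panel_concordance(calls, p)), 3 / 4)
  # allele matching neither ref nor alt counts as discordant
  calls2 <- ancient_calls(p$sites, c("T", "A", "G", "G"), rep(1L, 4))
  expect_equal(as.numeric(panel_concordance(calls2, p)), 3 / 4)
  # sampled straight from a panel member at zero error: fully concordant
  calls3 <- ancient_calls(p$sites, c("A", "A", "G", "G"), rep(1L, 4))
  expect_equal(as.numeric(panel_concordance(calls3, p)), 1)
})

test_that("ancient sample lands in the maize clade and filtering never hurts", {
  maize_pops <- c("MA_highland", "MA_lowland", "SA_highland", "SA_lowland")
  # undetectable miscalls: the called allele is a legitimate panel allele
  # (so looks concordant) yet the true diploid genotype does not carry it.
  # Deamination creates these only at C/T and G/A SNPs; at transversion
  # SNPs a damaged base matches neither allele and drops out at
  # intersection. The damage filter exists to remove this class.
  invisible_errors <- function(cc, sim) {
    key <- paste(sim$panel$sites$chrom, sim$panel$sites$pos)
    g <- sim$truth$ancient_genotypes[match(paste(cc$chrom, cc$pos), key)]
    valid <- cc$allele == cc$ref | cc$allele == cc$alt
    wrong <- (cc$allele == cc$ref & g == 2L) | (cc$allele == cc$alt & g == 0L)
    mean(valid & wrong)
  }
  res <- vapply(1:8, function(seed) {
    sim <- simulate_panel(sim_config(n_sites = 8000, seed = seed))
    rd <- simulate_ancient_reads(sim$truth$ancient_genotypes,
                                 sim$panel$sites, damage_params(),
                                 mean_depth = 1.2, seed = seed)
    calls_raw <- pseudo_haploid_call(rd, sim$panel$sites, seed = seed)
    calls <- apply_damage_filter(calls_raw)$filtered
    maize <- sim$panel$samples[sim$panel$populations %in% maize_pops]
    mono <- function(cc) {
      tr <- neighbor_joining(ibs_distance(sim$panel, cc))
      check_monophyly(tr, c(maize, "ancient"), "tripsacum_1")
    }
    c(mono(calls), mono(calls_raw), invisible_errors(calls, sim),
      invisible_errors(calls_raw, sim))
  }, numeric(4))
  expect_gte(mean(res[1, ]), 7 / 8)             # filtered placement
  expect_lt(mean(res[3, ]), mean(res[4, ]))     # filter removes miscalls
  expect_gte(mean(res[1, ]), mean(res[2, ]) - 1 / 8)  # placement not hurt
})
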