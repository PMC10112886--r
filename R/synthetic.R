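# Synthetic genotype panels with maize/teosinte-like structure, plus
# low-coverage terminally-deaminated observations of one ancient individual.
# Drift along each branch of the population tree follows the Balding-Nichols
# model: a child's allele frequency is Beta(p(1-F)/F, (1-p)(1-F)/F) around the
# parent's frequency p, so pairwise Hudson F_ST has a closed-form expectation
# (the sum of the two branch F values for a clean two-population split) that
# the test suite can check against.

#' Default population tree for the synthetic panel
#'
#' Edge list (parent, child, drift) of a rooted tree mirroring the structure of
#' a maize diversity panel: a *Tripsacum* outgroup, teosintes *parviglumis*
#' and *mexicana*, and domesticated landraces split by region (MA = Mesoamerica,
#' SA = South America) and elevation class. Drift values are Balding-Nichols
#' F per branch.
#'
#' @return data.frame with columns `parent`, `child`, `drift`.
#' @export
default_pop_tree <- function() {
  data.frame(
    parent = c("anc", "anc", "zea", "zea", "parviglumis", "maize", "maize",
               "MA", "MA", "SA", "SA"),
    child = c("tripsacum", "zea", "mexicana", "parviglumis", "maize",
              "MA", "SA", "MA_highland", "MA_lowland", "SA_highland",
              "SA_lowland"),
    drift = c(0.50, 0.05, 0.25, 0.10, 0.15, 0.03, 0.06, 0.03, 0.03,
              0.04, 0.04),
    stringsAsFactors = FALSE
  )
}

#' Simulation configuration
#'
#' @param n_sites number of biallelic SNPs to simulate.
#' @param pop_tree edge list (`parent`, `child`, `drift`) of the population
#'   tree; root must be named `"anc"`.
#' @param sample_sizes named integer vector, diploid individuals per leaf
#'   population. Defaults mirror a maize HapMap-style panel: 1 *Tripsacum*,
#'   15 *parviglumis*, 2 *mexicana*, and 22 landraces split by region and
#'   elevation.
#' @param admixture_edges list of `list(source=, dest=, m=)` frequency-mixing
#'   edges applied at the leaves: dest frequency becomes `(1-m)*dest +
#'   m*source`.
#' @param chrom_layout data.frame (`chrom`, `length`) of chromosome lengths in
#'   bp; sites are spread proportionally.
#' @param ancient_pop leaf population the ancient individual is drawn from.
#' @param outgroup leaf treated as the outgroup.
#' @param outgroup_ancestral_frac fraction of sites at which the outgroup is
#'   fixed for the ancestral allele.
#' @param ts_prob probability that a simulated SNP is a transition (C/T or
#'   A/G); the remainder are transversions.
#' @param sfs_range ancestral-frequency truncation bounds; frequencies are
#'   drawn with density proportional to 1/x on this interval.
#' @param seed master seed.
#' @return A `sim_config` list.
#' @export
sim_config <- function(n_sites = 20000,
                       pop_tree = default_pop_tree(),
                       sample_sizes = c(tripsacum = 1, parviglumis = 15,
                                        mexicana = 2, MA_highland = 4,
                                        MA_lowland = 6, SA_highland = 6,
                                        SA_lowland = 6),
                       admixture_edges = list(),
                       chrom_layout = data.frame(
                         chrom = paste0("chr", 1:10),
                         length = rep(1e8, 10)),
                       ancient_pop = "SA_lowland",
                       outgroup = "tripsacum",
                       outgroup_ancestral_frac = 0.95,
                       ts_prob = 2 / 3,
                       sfs_range = c(0.05, 0.95),
                       seed = 1L) {
  stopifnot(n_sites >= 1, all(pop_tree$drift >= 0))
  for (e in admixture_edges)
    stopifnot(e$m >= 0, e$m <= 1, e$source != e$dest)
  nodes <- unique(pop_tree$child)
  if (length(setdiff(nodes, pop_tree$parent)) < 2L)
    stop("degenerate population tree (single leaf)")
  # sampled populations may sit at internal nodes (e.g. parviglumis, within
  # which the domesticates nest)
  if (!all(names(sample_sizes) %in% nodes))
    stop("sample_sizes names must be tree nodes")
  if (!ancient_pop %in% nodes) stop("ancient_pop must be a tree node")
  structure(list(n_sites = as.integer(n_sites), pop_tree = pop_tree,
                 sample_sizes = sample_sizes,
                 admixture_edges = admixture_edges,
                 chrom_layout = chrom_layout, ancient_pop = ancient_pop,
                 outgroup = outgroup,
                 outgroup_ancestral_frac = outgroup_ancestral_frac,
                 ts_prob = ts_prob, sfs_range = sfs_range,
                 seed = as.integer(seed)),
            class = "sim_config")
}

#' Symmetric quartet configuration for D-statistic experiments
#'
#' A four-population tree (((P1, P2), P3), O) with exchangeable P1/P2 drift,
#' under which the expected D of the quartet (P1, P2, P3, O) is exactly zero
#' without gene flow; an optional admixture edge P2 -> P3 with proportion `m`
#' injects the asymmetry a positive design-(i) D detects. Populations are
#' named `parviglumis` (P1), `mexicana` (P2), `test` (P3) and `tripsacum`
#' (O) after the roles they play.
#'
#' @param n_sites number of SNPs.
#' @param drift Balding-Nichols F applied to the terminal branches. Under
#'   this model the pairwise Hudson F_ST of two populations split from a
#'   common ancestor with branch values F1, F2 is (F1 + F2) / 2, so the
#'   default 0.25 reproduces the ~0.25 differentiation observed between the
#'   two teosinte subspecies.
#' @param m admixture proportion mexicana -> test (0 = no gene flow).
#' @param sample_sizes named diploid counts for the four populations.
#' @param seed master seed.
#' @return A [sim_config()].
#' @export
quartet_config <- function(n_sites = 20000, drift = 0.25, m = 0,
                           sample_sizes = c(tripsacum = 1, parviglumis = 2,
                                            mexicana = 2, test = 2),
                           seed = 1L) {
  tree <- data.frame(
    parent = c("anc", "anc", "n1", "n1", "n12", "n12"),
    child = c("tripsacum", "n1", "test", "n12", "parviglumis", "mexicana"),
    drift = c(0.30, 0.05, drift, 0.05, drift, drift),
    stringsAsFactors = FALSE)
  edges <- if (m > 0)
    list(list(source = "mexicana", dest = "test", m = m))
  else list()
  sim_config(n_sites = n_sites, pop_tree = tree,
             sample_sizes = sample_sizes, admixture_edges = edges,
             ancient_pop = "test", outgroup = "tripsacum", seed = seed)
}

pop_tree_newick <- function(tree) {
  children <- split(seq_len(nrow(tree)), tree$parent)
  rec <- function(node) {
    idx <- children[[node]]
    if (is.null(idx)) return(node)
    paste0("(", paste(vapply(idx, function(i)
      paste0(rec(tree$child[i]), ":", tree$drift[i]), ""), collapse = ","),
      ")", node)
  }
  paste0(rec("anc"), ";")
}

bn_drift <- function(p, f) {
  if (f <= 0) return(p)
  q <- rbeta(length(p), p * (1 - f) / f, (1 - p) * (1 - f) / f)
  # rbeta returns NaN when both shapes are ~0 (p at the boundary); a fixed
  # frequency stays fixed under drift
  q[p <= 0] <- 0
  q[p >= 1] <- 1
  q
}

draw_snp_alleles <- function(n, ts_prob) {
  pair_ts <- matrix(c("C", "T", "A", "G"), 2)
  pair_tv <- matrix(c("A", "C", "A", "T", "C", "G", "G", "T"), 2)
  is_ts <- runif(n) < ts_prob
  pick_ts <- sample.int(2, n, replace = TRUE)
  pick_tv <- sample.int(4, n, replace = TRUE)
  a1 <- ifelse(is_ts, pair_ts[1, pick_ts], pair_tv[1, pick_tv])
  a2 <- ifelse(is_ts, pair_ts[2, pick_ts], pair_tv[2, pick_tv])
  flip <- runif(n) < 0.5
  data.frame(anc = ifelse(flip, a2, a1), der = ifelse(flip, a1, a2),
             stringsAsFactors = FALSE)
}

#' Simulate a structured genotype panel with ground truth
#'
#' Ancestral allele frequencies are drawn from a neutral-like 1/x density
#' truncated to `sfs_range`, evolved down the population tree by
#' Balding-Nichols drift, mixed along any admixture edges, and sampled
#' binomially into diploid genotypes. The ancestral allele is the reference
#' allele; frequencies refer to the derived (alt) allele. The outgroup is
#' fixed ancestral at a configurable fraction of sites.
#'
#' @param config a [sim_config()].
#' @return A list with `panel` (a [genotype_panel()]) and `truth`
#'   (a `truth_record`: `tree` in newick, `admixture_edges`, `leaf_freqs`
#'   matrix, `ancient_genotypes` dosage vector, `ancient_pop`,
#'   `adaptive_sites` accumulator).
#' @export
simulate_panel <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(derive_seed(config$seed, "panel"))
  n <- config$n_sites
  # coordinates are drawn and sorted first so that every per-site quantity
  # (frequencies, genotypes, truth) is aligned with the panel's site order
  layout <- config$chrom_layout
  n_per <- diff(round(cumsum(c(0, layout$length)) / sum(layout$length) * n))
  chrom <- rep(layout$chrom, n_per)
  pos <- unlist(lapply(seq_len(nrow(layout)), function(i) {
    if (n_per[i] == 0L) return(integer(0))
    sort(sample.int(layout$length[i], n_per[i]))
  }), use.names = FALSE)
  o <- order(chrom, pos)
  chrom <- chrom[o]; pos <- pos[o]

  lo <- config$sfs_range[1]; hi <- config$sfs_range[2]
  p0 <- lo * (hi / lo)^runif(n)

  tree <- config$pop_tree
  freqs <- list(anc = p0)
  todo <- seq_len(nrow(tree))
  while (length(todo)) {
    ready <- todo[tree$parent[todo] %in% names(freqs)]
    for (i in ready)
      freqs[[tree$child[i]]] <- bn_drift(freqs[[tree$parent[i]]],
                                         tree$drift[i])
    todo <- setdiff(todo, ready)
  }
  for (e in config$admixture_edges)
    freqs[[e$dest]] <- (1 - e$m) * freqs[[e$dest]] + e$m * freqs[[e$source]]
  og <- config$outgroup
  if (og %in% names(freqs)) {
    fixed <- runif(n) < config$outgroup_ancestral_frac
    freqs[[og]][fixed] <- 0
  }

  alleles <- draw_snp_alleles(n, config$ts_prob)
  sites <- data.frame(chrom = chrom, pos = pos, ref = alleles$anc,
                      alt = alleles$der, stringsAsFactors = FALSE)

  pops <- names(config$sample_sizes)
  geno_cols <- list()
  pop_of <- character(0)
  for (pp in pops) {
    k <- config$sample_sizes[[pp]]
    if (k == 0L) next
    g <- matrix(rbinom(n * k, 2L, freqs[[pp]]), nrow = n)
    colnames(g) <- paste0(pp, "_", seq_len(k))
    geno_cols[[pp]] <- g
    pop_of <- c(pop_of, setNames(rep(pp, k), colnames(g)))
  }
  geno <- do.call(cbind, geno_cols)
  panel <- genotype_panel(sites, geno, pop_of)

  leaf_freqs <- do.call(cbind, freqs[pops])
  ancient <- rbinom(n, 2L, freqs[[config$ancient_pop]])
  truth <- structure(list(tree = pop_tree_newick(tree),
                          admixture_edges = config$admixture_edges,
                          leaf_freqs = leaf_freqs,
                          ancient_genotypes = ancient,
                          ancient_pop = config$ancient_pop,
                          adaptive_sites = NULL,
                          seed = config$seed),
                     class = "truth_record")
  list(panel = panel, truth = truth)
}

#' Inject elevation-adaptive sites into a simulated panel
#'
#' At randomly chosen background sites the derived-allele frequency in the two
#' elevation populations of a region is displaced to `0.5 + effect` in one
#' class and `0.5 - effect` in the other; genotypes of those populations (and
#' the ancient individual, if it belongs to one of them) are re-drawn. Truth
#' records the canonical orientation: `adaptive_class` is the elevation class
#' in which the alt allele is the high-frequency one (the two descriptions
#' "allele A adaptive in lowland" and "allele B adaptive in highland" are
#' equivalent at a biallelic site, so both generator and scanner normalise on
#' the alt allele).
#'
#' @param panel a [genotype_panel()] from [simulate_panel()].
#' @param truth the matching `truth_record`.
#' @param region `"MA"` or `"SA"`; populations `<region>_highland` and
#'   `<region>_lowland` must exist.
#' @param n_adaptive number of adaptive sites to inject.
#' @param effect frequency displacement from 0.5 (default 0.4, i.e. 0.9 vs
#'   0.1).
#' @param ancient_mode how the ancient individual's genotypes are re-drawn at
#'   the injected sites: `"pop"` (default) samples them from its own
#'   population's shifted frequencies, making a locally adapted individual;
#'   `"deficit"` samples lowland-class sites from the population but draws
#'   highland-class sites at frequency 0.5 regardless, emulating a sample
#'   that carries lowland-adaptive alleles yet is unselected at
#'   highland-adaptive loci.
#' @param seed integer seed.
#' @return List with updated `panel` and `truth`; `truth$adaptive_sites` gains
#'   rows (`chrom`, `pos`, `region`, `adaptive_allele`, `adaptive_class`).
#' @export
simulate_adaptive_sites <- function(panel, truth, region = "MA",
                                    n_adaptive = 50, effect = 0.4,
                                    ancient_mode = c("pop", "deficit"),
                                    seed = 1L) {
  ancient_mode <- match.arg(ancient_mode)
  stopifnot(effect >= 0, effect <= 0.5)
  set.seed(derive_seed(seed, paste0("adaptive_", region)))
  hi_pop <- paste0(region, "_highland")
  lo_pop <- paste0(region, "_lowland")
  if (!all(c(hi_pop, lo_pop) %in% panel$populations))
    stop("panel lacks highland/lowland populations for region ", region)
  n <- nrow(panel$sites)
  taken <- if (is.null(truth$adaptive_sites)) integer(0) else
    match(site_key(truth$adaptive_sites$chrom, truth$adaptive_sites$pos),
          site_key(panel$sites$chrom, panel$sites$pos))
  avail <- setdiff(seq_len(n), taken)
  if (n_adaptive > length(avail))
    stop("n_adaptive exceeds available background sites")
  idx <- sort(sample(avail, n_adaptive))

  alt_high_in_highland <- runif(n_adaptive) < 0.5
  p_hi <- ifelse(alt_high_in_highland, 0.5 + effect, 0.5 - effect)
  p_lo <- 1 - p_hi
  for (pp in c(hi_pop, lo_pop)) {
    newp <- if (pp == hi_pop) p_hi else p_lo
    truth$leaf_freqs[idx, pp] <- newp
    cols <- pop_samples(panel, pp)
    panel$geno[idx, cols] <- matrix(
      rbinom(n_adaptive * length(cols), 2L, newp), nrow = n_adaptive)
    if (truth$ancient_pop == pp) {
      p_anc <- newp
      # alt_high_in_highland marks highland-class sites (alt-normalised);
      # an unselected ancient draws those at frequency 0.5
      if (ancient_mode == "deficit") p_anc[alt_high_in_highland] <- 0.5
      truth$ancient_genotypes[idx] <- rbinom(n_adaptive, 2L, p_anc)
    }
  }
  add <- data.frame(chrom = panel$sites$chrom[idx],
                    pos = panel$sites$pos[idx],
                    region = region,
                    adaptive_allele = panel$sites$alt[idx],
                    adaptive_class = ifelse(alt_high_in_highland,
                                            "highland", "lowland"),
                    stringsAsFactors = FALSE)
  truth$adaptive_sites <- rbind(truth$adaptive_sites, add)
  list(panel = panel, truth = truth)
}

#' Post-mortem damage and fragmentation parameters
#'
#' @param delta5 C-to-T deamination rate at the first 5' position.
#' @param delta3 G-to-A deamination rate at the first 3' position.
#' @param decay per-position geometric decay of the deamination rate moving
#'   into the read.
#' @param frag_median median fragment length in bp.
#' @param base_error uniform per-base sequencing error rate.
#' @param min_frag shortest possible fragment (bp); lengths are `min_frag`
#'   plus a geometric draw calibrated so the median equals `frag_median`.
#' @return A `damage_params` list.
#' @export
damage_params <- function(delta5 = 0.17, delta3 = 0.17, decay = 0.65,
                          frag_median = 36, base_error = 0.002,
                          min_frag = 20) {
  stopifnot(delta5 >= 0, delta5 <= 1, delta3 >= 0, delta3 <= 1,
            decay > 0, decay <= 1, frag_median >= 30, base_error >= 0,
            base_error <= 1, min_frag >= 1, min_frag < frag_median)
  structure(list(delta5 = delta5, delta3 = delta3, decay = decay,
                 frag_median = frag_median, base_error = base_error,
                 min_frag = min_frag),
            class = "damage_params")
}

OTHER_BASES <- list(A = c("C", "G", "T"), C = c("A", "G", "T"),
                    G = c("A", "C", "T"), T = c("A", "C", "G"))

#' Simulate low-coverage damaged reads over an ancient genome
#'
#' Per-site read counts are Poisson(`mean_depth`); each read carries one of the
#' two true alleles, lands at a uniform offset within a geometric-length
#' fragment, and is deaminated C-to-T near the 5' terminus or G-to-A near the
#' 3' terminus with probability `delta * decay^(offset-1)`; uniform sequencing
#' error is applied last. Base qualities are drawn around Phred 37.
#'
#' @param genotypes diploid dosage vector (0/1/2) of the ancient individual.
#' @param sites data.frame with `chrom`, `pos`, `ref`, `alt` (ref = ancestral).
#' @param damage a [damage_params()].
#' @param mean_depth mean per-site coverage.
#' @param seed integer seed.
#' @return A `read_set` data.frame: `site` (row index into `sites`), `chrom`,
#'   `pos`, `base`, `true_base` (simulation truth, used by profile-recovery
#'   oracles), `offset5`, `offset3`, `len`, `qual`.
#' @export
simulate_ancient_reads <- function(genotypes, sites, damage = damage_params(),
                                   mean_depth = 1.2, seed = 1L) {
  stopifnot(mean_depth > 0, length(genotypes) == nrow(sites))
  set.seed(derive_seed(seed, "reads"))
  depth <- rpois(nrow(sites), mean_depth)
  site <- rep(seq_len(nrow(sites)), depth)
  nr <- length(site)
  g <- genotypes[site]
  pick_alt <- runif(nr) < g / 2
  true_base <- ifelse(pick_alt, sites$alt[site], sites$ref[site])

  p_geom <- 1 - 0.5^(1 / (damage$frag_median - damage$min_frag))
  len <- damage$min_frag + rgeom(nr, p_geom)
  offset5 <- floor(runif(nr) * len) + 1L
  offset3 <- len - offset5 + 1L

  base <- true_base
  hit5 <- base == "C" &
    runif(nr) < damage$delta5 * damage$decay^(offset5 - 1)
  base[hit5] <- "T"
  hit3 <- base == "G" &
    runif(nr) < damage$delta3 * damage$decay^(offset3 - 1)
  base[hit3] <- "A"
  err <- runif(nr) < damage$base_error
  if (any(err)) {
    pick <- sample.int(3, sum(err), replace = TRUE)
    base[err] <- vapply(seq_along(pick), function(i)
      OTHER_BASES[[base[err][i]]][pick[i]], "")
  }
  qual <- pmax(2L, as.integer(round(rnorm(nr, 37, 3))))
  out <- data.frame(site = site, chrom = sites$chrom[site],
                    pos = sites$pos[site], base = base,
                    true_base = true_base, offset5 = offset5,
                    offset3 = offset3, len = len, qual = qual,
                    stringsAsFactors = FALSE)
  class(out) <- c("read_set", "data.frame")
  out
}

#' Pseudo-haploid calling from a read set
#'
#' Reads shorter than `min_len` or below `min_qual` are removed; at each site
#' still covered, one passing read drawn uniformly at random provides the
#' allele. Depth records the number of passing reads before sampling. Sites
#' with no passing reads are absent from the output.
#'
#' @param reads a `read_set` from [simulate_ancient_reads()].
#' @param sites the site table the read set was simulated over.
#' @param min_len minimum read length in bp.
#' @param min_qual minimum Phred base quality.
#' @param seed integer seed for the read draw.
#' @return An [ancient_calls()] data.frame.
#' @export
pseudo_haploid_call <- function(reads, sites, min_len = 30, min_qual = 10,
                                seed = 1L) {
  keep <- reads$len >= min_len & reads$qual >= min_qual
  r <- reads[keep, , drop = FALSE]
  if (!nrow(r)) {
    return(ancient_calls(sites[integer(0), , drop = FALSE],
                         character(0), integer(0)))
  }
  set.seed(derive_seed(seed, "pseudo_haploid"))
  depth <- tabulate(r$site, nbins = nrow(sites))
  o <- sample.int(nrow(r))
  r <- r[o, , drop = FALSE]
  first <- !duplicated(r$site)
  picked <- r[first, , drop = FALSE]
  picked <- picked[order(picked$site), , drop = FALSE]
  ancient_calls(sites[picked$site, , drop = FALSE], picked$base,
                depth[picked$site])
}
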