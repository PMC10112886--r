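# Small deterministic fixtures built in code.

# 3-site, 2-sample panel with known genotypes
toy_panel <- function() {
  sites <- data.frame(chrom = c("chr1", "chr1", "chr2"),
                      pos = c(100L, 200L, 50L),
                      ref = c("A", "C", "G"),
                      alt = c("C", "T", "T"),
                      stringsAsFactors = FALSE)
  geno <- matrix(c(0L, 1L, 2L, 2L, 0L, 1L), nrow = 3,
                 dimnames = list(NULL, c("s1", "s2")))
  genotype_panel(sites, geno, c(s1 = "popA", s2 = "popB"))
}

# write a VCF with arbitrary raw records
write_raw_vcf <- function(records, samples, path) {
  header <- c("##fileformat=VCFv4.2",
              '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
              paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                      "INFO", "FORMAT", samples), collapse = "\t"))
  writeLines(c(header, records), path)
  path
}

# sites data.frame with given counts of each substitution class
classified_sites <- function(n_ct = 0, n_ga = 0, n_indel = 0, n_tv = 0) {
  ref <- c(rep("C", n_ct), rep("G", n_ga), rep("AC", n_indel),
           rep("A", n_tv))
  alt <- c(rep("T", n_ct), rep("A", n_ga), rep("A", n_indel),
           rep("C", n_tv))
  n <- length(ref)
  data.frame(chrom = "chr1", pos = seq_len(n), ref = ref, alt = alt,
             stringsAsFactors = FALSE)
}

# ancient calls over classified sites (built directly: the filter needs the
# original alleles, including indels the SNP container would reject)
calls_over <- function(sites) {
  out <- data.frame(chrom = sites$chrom, pos = sites$pos, ref = sites$ref,
                    alt = sites$alt, allele = sites$ref,
                    depth = 1L, stringsAsFactors = FALSE)
  class(out) <- c("ancient_calls", "data.frame")
  out
}

# end-to-end small simulation shared by several tests
small_sim <- function(seed = 3, n_sites = 6000) {
  simulate_panel(sim_config(n_sites = n_sites, seed = seed))
}
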