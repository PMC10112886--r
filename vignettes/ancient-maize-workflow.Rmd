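---
title: "Methods: damage-aware population genomics for ancient maize"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: damage-aware population genomics for ancient maize}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(paleomaize)
```

## The problem

A low-coverage ancient maize genome — a few thousand to a few hundred
thousand SNPs, most covered by a single short, chemically damaged DNA
fragment — is to be interpreted against a modern diversity panel containing
an outgroup (*Tripsacum*), the two teosinte subspecies (*Zea mays* ssp.
*parviglumis*, the lowland progenitor, and ssp. *mexicana*, the highland
one), and domesticated landraces from Mesoamerica (MA) and South America
(SA), each split into highland and lowland populations. Four questions
recur:

1. Which of the observed SNPs can be trusted, given that post-mortem
   cytosine deamination masquerades as C→T and G→A substitutions?
2. Does the ancient genome carry *mexicana* introgression, as extant
   highland landraces do?
3. At SNPs known to differentiate highland from lowland landraces, which
   elevation class do the ancient alleles resemble?
4. Where does the sample fall among the panel populations?

`paleomaize` implements the statistics behind each question and bundles a
synthetic-data generator with the same statistical structure, so the whole
pipeline is testable end to end without any external download.

## Damage filtering

Sites are classified from the unordered ref/alt pair: `{C,T}` pairs are
deamination-compatible transitions, `{G,A}` pairs likewise, alleles longer
than one base are indels, and the remaining purine↔pyrimidine pairs are
transversions. The classification deliberately ignores read orientation:
the filter removes SNP *types*, not individual reads.

`apply_damage_filter()` removes both transition classes and all indels and
returns exact accounting (`retained = total − removed` per class, asserted
internally). A relaxed mode retains damage-pair SNPs supported by more than
one read and converts damage-compatible heterozygotes to the homozygote of
the undamaged allele (C at C/T sites, G at G/A sites); the strict default
reproduces published-style accounting tables.
`apply_transversion_filter()` keeps only transversions, the damage-immune
subset used to confirm that damage filtering does not bias a result.

One property of these filters is easy to get wrong. Deamination corrupts
reads at the same per-read rate in every SNP class, so the *raw accuracy* of
pseudo-haploid calls is essentially unchanged by filtering. What the filter
removes is the dangerous subclass: at a C/T or G/A SNP a damaged base is a
legitimate panel allele and the miscall is undetectable downstream, whereas
at a transversion SNP the damaged base matches neither allele and simply
drops out at intersection. The test suite asserts exactly that: the
undetectable-miscall rate strictly drops after filtering, while placement is
not degraded.

`estimate_damage_profile()` reports per-position terminal C→T (5′) and G→A
(3′) rates as mismatches over opportunities, with positions lacking
opportunities reported as `NA` rather than 0, plus a background mismatch
rate outside the two damage channels.

## D statistics

With the outgroup allele defining the ancestral state A and the other
allele derived (B), quartets (P1, P2, P3, O) are scored as
ABBA (derived shared by P2 and P3) or BABA (derived shared by P1 and P3),
and

\[ D = \frac{x - y}{x + y} \]

with \(x\) the ABBA and \(y\) the BABA tally. Incomplete lineage sorting
produces both patterns at equal rates; gene flow between P3 and one of
P1/P2 skews them. In frequency mode each site contributes
\((1-p_1)p_2p_3(1-p_O)\) and \(p_1(1-p_2)p_3(1-p_O)\), which reduces
exactly to pattern counting for 0/1 (pseudo-haploid) codings — the package
carries both code paths and the suite asserts their equality.

Two quartet designs are exposed. Design (i), D(*parviglumis*, *mexicana*,
TEST, outgroup), is pushed positive by *mexicana*→TEST gene flow. Design
(ii), D(TEST, *parviglumis*, *mexicana*, outgroup), is pushed negative when
*mexicana* shares more gene flow with TEST than with *parviglumis*.
`d_distribution()` crosses every P1 accession with every P2 accession,
restricting all computations to sites covered in the test sample, and
reports one jackknifed D per pair; K-S and Wilcoxon helpers compare the
resulting distributions.

Uncertainty comes from a delete-one block jackknife over 100 contiguous,
near-equal blocks of consecutive sites (`n_blocks` is a parameter; blocks
are reduced with a warning when informative sites are scarce). Contiguous
deletion respects genomic autocorrelation and has a closed form the tests
check on a two-block toy. Source material for this analysis sometimes
reports 100 and sometimes 1000 replicates; both are one flag away.

Heterozygous non-outgroup genotypes contribute allele frequency 0.5 rather
than being dropped; heterozygous or missing *outgroup* genotypes cannot be
polarized and are dropped with a counter.

## Adaptive alleles and allelic similarity

Elevation-adaptive SNPs are scanned with the Hudson F\_ST estimator with
sample-size correction,

\[ \hat F_{ST} =
   \frac{(p_1-p_2)^2 - \frac{p_1(1-p_1)}{n_1-1} - \frac{p_2(1-p_2)}{n_2-1}}
        {p_1(1-p_2) + p_2(1-p_1)}, \]

clipped to \([0,1]\) for reporting (the raw value is available). Hudson's
estimator is insensitive to unequal, modest sample sizes — the relevant
regime for a landrace panel. Significance is an empirical outlier quantile
(99.9th by default) or a label-permutation p-value; the permutation null
needs adequately sampled populations (tens of individuals per class) to
resolve small per-site p-values.

At a biallelic site "allele A is lowland-adaptive" and "allele B is
highland-adaptive" are the same statement, so both the scanner and the
generator canonicalise on the non-reference allele: `adaptive_class` is the
elevation class in which the alt allele is the high-frequency one. Without
such a convention, recovery against simulation truth would be ambiguous.

Allelic similarity of the ancient sample to a test population is

\[ S = \frac{1}{N}\sum_{i=1}^{N} f_i, \]

the mean frequency, in that population, of the allele the ancient sample
carries across the \(N\) intersected sites (diploid ancient calls weight
both alleles by 0.5). Significance of a *reduction* in similarity at
adaptive SNPs comes from a resampling null: 10,000 draws (default) of the
same number of background SNPs, without replacement within a draw,
independent across draws; `p_low` is the plain proportion of null draws at
or below the observed S (an add-one variant is available). The null's mean
is the genome-wide similarity expectation.

The coverage-underrepresentation test draws `|adaptive|` SNPs from a
background set 10,000 times and counts overlaps with the ancient-covered
set; `p_under` is the proportion of the null at or below the observed
coverage. The background is a parameter by design: drawing from SNPs
already intersected with the ancient sample would make every draw covered
and the null degenerate, so the package requires the caller to say which
background the expectation refers to. `fisher_exact()` compares covered
proportions between regions (two-sided, fixed margins, p = 1 on any zero
margin).

## Relatedness placement

Pairwise distances are 1 minus mean allele sharing over jointly non-missing
sites. For diploid-only panels, sharing is the IBS proportion
\(1 - |d_1 - d_2|/2\) on the dosage scale (duplicates at distance 0,
opposite homozygotes at 1). When a pseudo-haploid ancient sample is
included, *all* pairs switch to expected random-allele sharing
\((d_1 d_2 + (2-d_1)(2-d_2))/4\). The mixed convention — IBS for diploid
pairs, expected sharing for haploid-diploid pairs — looks natural but puts
the ancient on a different scale: its distance to a near-monomorphic
outgroup is deflated relative to its distances within diverse populations,
and neighbor joining then drags the ancient's long branch toward the root.
A single consistent scale removes the artifact; the ancient still shows a
long terminal branch (fewer sites, haploid calls), which NJ absorbs without
topological harm.

Trees come from canonical Saitou–Nei neighbor joining (via `ape`), with
negative branch lengths clamped to zero and the deficit transferred to the
sibling branch(es), conserving total tree length. Placement claims are
tested as monophyly of a labelled group after rooting on the outgroup.
`panel_concordance()` reports the fraction of ancient alleles observed
anywhere in the panel at intersected sites, with allele-irreconcilable
sites counted as discordant. Pairs sharing fewer than `min_shared` sites
(default 100) are flagged rather than silently trusted.

## The synthetic-data generator

`simulate_panel()` draws ancestral derived-allele frequencies with density
\(\propto 1/x\) truncated to \([0.05, 0.95]\) (polymorphism at usable
frequencies without conditioning machinery), evolves them down a population
tree by Balding–Nichols drift — each branch with parameter \(F\) replaces
frequency \(p\) by a \(\mathrm{Beta}\!\big(p\frac{1-F}{F},
(1-p)\frac{1-F}{F}\big)\) draw — applies optional admixture edges as
frequency mixtures \((1-m)\,\text{dest} + m\,\text{source}\), and samples
diploid genotypes binomially. The closed form that makes this model
test-friendly: two populations split from a common ancestor with branch
values \(F_1, F_2\) have expected genome-wide Hudson F\_ST (ratio of sums)
of \((F_1+F_2)/2\), which the suite verifies at 20,000 sites.

Defaults mirror the real panel's composition: 1 *Tripsacum*, 15
*parviglumis*, 2 *mexicana*, and 22 landraces split 4/6/6/6 by region and
elevation. Branch drift values were set once from published differentiation
scales — *parviglumis*–*mexicana* F\_ST ≈ 0.25 (hence terminal drift 0.25
in the D-statistic quartet and 0.25/0.10 in the panel tree), a domestication
bottleneck of 0.15, and within-region elevation splits of 0.03–0.04 — and
are configuration, not tuning knobs. The outgroup is fixed ancestral at 95%
of sites; SNP allele pairs are transitions with probability 2/3.

Adaptive sites are injected by displacing the derived-allele frequency to
\(0.5 \pm \text{effect}\) (default 0.4, i.e. 0.9 vs 0.1) in the two
elevation populations of a region and re-drawing the affected genotypes;
truth records the canonical (alt-normalised) class. The ancient individual
is by default a member of one leaf population (`SA_lowland`), re-drawn at
injected sites from its own population's shifted frequencies. That single
choice reproduces the qualitative published contrast — a significant
similarity deficit at highland-adaptive alleles, lowland similarity inside
genome-wide expectations — because the member carries the anti-highland
allele at ~0.9 at highland-class sites. An alternative `deficit` mode draws
highland-class sites at frequency 0.5 instead; note that such "random"
alleles are *not* neutral with respect to the null (genome-wide similarity
of a population member is ≈0.8, not 0.5), so that mode depresses similarity
to both classes.

Reads are simulated per site with Poisson depth (default mean 1.2×),
fragment lengths `min_frag` (20 bp) plus a geometric draw calibrated to a
36 bp median, uniform site offset within the fragment, terminal deamination
with probability \(\delta\,\mathrm{decay}^{\,\text{offset}-1}\)
(defaults \(\delta_5=\delta_3=0.17\), decay 0.65, matching the 13–20%
terminal deamination regime), and a uniform base error (0.002).
`pseudo_haploid_call()` drops reads shorter than 30 bp or below Phred 10,
then samples one passing read per site; depth records passing reads before
sampling, and sites with no passing reads are absent.

Everything is seeded through one master seed and named child streams
(`derive_seed()`), so identical configurations give byte-identical output.

## What the simulations do and do not show

The generator reproduces the *statistical* structure the analyses assume:
drift-structured allele frequencies, admixture as frequency mixing, extreme
frequency differentiation at adaptive sites, Poisson coverage, terminally
concentrated deamination, fragment-length filtering. It does not attempt
recombination maps, selection through time, inbreeding structure of real
inbred lines versus landraces, reference bias, contamination, or
sequence-level simulation. Green tests therefore certify the estimators and
their calibration under the assumed model — not robustness to every
property of real ancient data.

Problem sizes in the test and acceptance suites are desk-scale choices:
500 null simulations of 20,000 sites for D calibration, 50,000 sites for
admixture recovery (m = 0.2), 20,000-site panels with 390 injected adaptive
sites for the similarity contrast, 10,000-draw resampling nulls, and
placement checks at 8,000–10,000 sites.

## Numerical and degenerate-input choices

* `compute_D` refuses x + y = 0 (no informative sites) rather than return
  NaN; jackknife blocks reduce with a warning when sites are scarce.
* F\_ST is `NA` (not 0) when both populations are monomorphic; raw values
  may be slightly negative by sampling correction and are clipped only for
  reporting.
* Damage-profile positions with zero opportunities are `NA`, never 0.
* BED ingestion converts 0-based half-open coordinates exactly once;
  intervals wider than one base warn and collapse to their midpoint.
* Allele reconciliation at intersection never strand-flips; an ancient
  allele matching neither panel allele (including complementary-pair
  ambiguities) is dropped and counted.
* Multiallelic VCF records are dropped by default (biallelic analysis) or
  split on request.
* `rbeta` returns NaN when both shape parameters are ~0 (frequency at a
  boundary); drift keeps fixed frequencies fixed explicitly.

## Known limitations

* The ancient sample's long branch is handled, not modelled; no correction
  for isolation by time is attempted.
* The permutation F\_ST rule is granular below ~1/(n\_perm+1) and weak for
  very small populations; the default panel's 4–6 diploids per landrace
  population are enough for the outlier-quantile rule but not for per-site
  permutation p-values.
* The coverage-underrepresentation test is only as meaningful as the
  declared background set; the package computes the machinery but leaves
  the ascertainment decision to the caller.
* Frequency-mixing admixture captures mean introgression, not
  haplotype-block structure; D statistics behave correctly in expectation
  but linkage disequilibrium decay is not emulated beyond block
  jackknifing.
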