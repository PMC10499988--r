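---
title: "Discovering albumin-binding macrocycles from phage-display sequencing"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Discovering albumin-binding macrocycles from phage-display sequencing}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(macropan)
library(tibble)
library(dplyr)
```

## The problem

Genetically encoded libraries of short peptides displayed on phage, and
chemically cross-linked into macrocycles through a perfluoroaromatic
linchpin reacting with two fixed cysteines, can be panned against a protein
target and read out by short-read sequencing. The scaffold modelled here is
`SXCX(n)C`: a fixed serine, one variable residue, a fixed cysteine, `n`
variable residues (`n` = 3–5) and a closing cysteine. The `n = 3` library is
small enough (20^4 = 160,000 peptides at a full alphabet; 19^4 = 130,321
under the cysteine-free alphabet the trinucleotide codons actually encode)
to be covered exhaustively by one sequencing run, which makes a *single*
round of selection quantifiable: hits are not taken from the survivors of
many amplification rounds but called statistically, by comparing each
peptide's abundance in the target selection against control selections.

`macropan` implements that computational pipeline end to end — read
deconvolution, differential enrichment, motif analysis — plus the
quantitative binding models used to validate hits downstream
(fluorescence-polarization and ¹⁹F NMR titrations, alanine-scan ΔΔG), and a
synthetic-data generator so every stage is testable with known ground truth.

## The library model

A `library_design` records the peptide architecture and the DNA context each
clone is sequenced in. The shipped defaults are the construction template's
priming regions, with the variable region `TCT · X · TGT · XXX · TGT`
(Ser codon, variable codon, Cys codon, n variable codons, Cys codon)
between them:

```{r}
d <- library_design()
d
theoretical_diversity(d, 3, alphabet_size = 20)
```

The diversity count is deliberately parametric in the alphabet size: the
published 160,000 figure corresponds to 20 letters, while the design itself
excludes cysteine from variable positions (a stray cysteine would compete
for the linchpin), giving 19^4. Both conventions are exposed and neither is
asserted as the biologically correct one.

Observed peptides are classified against the fixed patterns: `n3`/`n4`/`n5`
when serine and the two cysteines sit at the fixed positions for that ring
size, `off_design` otherwise. Off-design reads are **kept and flagged**, not
discarded: ring sizes outside the designed architecture arise as rare
deletion variants in real libraries and have produced genuine hits, so
throwing them away would bias the screen.

```{r}
classify_architecture(c("SICRFFC", "STCHDITC", "AICRFFC"),
                      library_design(cycle_sizes = 3:5))
```

## Read deconvolution

`process_run()` composes the deconvolution rules the count tables are built
with, in a fixed order, each read landing in exactly one audit cell:

1. **Quality**: any base of either mate below `min_q` (default Phred 20,
   applied per base) fails the pair. The threshold and per-base semantics
   are declared package decisions: "low quality" is not defined more
   precisely by the protocol being modelled, and a per-base rule is the
   conservative reading.
2. **Barcode**: exact match of the leading bases of the forward read. No
   mismatch tolerance — the substitution allowance is documented only for
   priming regions, and barcodes separated by Hamming distance need exact
   matching to stay collision-free.
3. **Priming regions**: Hamming comparison at fixed offsets, at most one
   substitution each, on both mates; no indel search anywhere (the error
   model of the instrument and the matching rules are length-preserving).
4. **Forward–reverse agreement**: the variable-region windows of the two
   mates (reverse mate reverse-complemented) must agree at every base; a
   single disagreement discards the pair. With independent errors on the
   two mates this suppresses substitution errors quadratically.
5. **Translation and classification**: stop-codon inserts are discarded
   (`FAIL_STOP`); everything else is counted at the peptide level, DNA
   retained for audit, off-design flagged.

Counts are keyed by peptide, not DNA, because selection acts on the
displayed peptide; synonymous DNA is collapsed. The audit table conserves
the input read count exactly, which the test suite asserts across random
noisy simulations.

## The synthetic campaign generator

Real selections can't serve as unit-test fixtures, so the package generates
them. The generator's defaults are the simulated analogue of the modelled
campaign and are fixed once:

- **Naive abundances**: log-normal (`meanlog` 0, `sdlog` 1), a long-tailed
  shape typical of display libraries after amplification; uniform is
  available for degenerate tests.
- **Selection**: one round, modelled as frequency reweighting
  `f_i' = λ_i f_i / Σ λ_j f_j` followed by multinomial read sampling. The
  modelled campaign is single-round, so amplification kinetics between
  rounds never enter the count statistics.
- **Sequencing**: 1e5 read pairs per experiment, 75 nt mates (a 2×75 kit),
  substitution errors at 1e-3 per base, no indels (the matching rules
  presume length-preserving errors), Phred 37 everywhere with an optional
  low-quality injection mode to exercise the filter.

What the generator does **not** emulate: PCR bias, chimeras, indels,
per-cycle quality decay, and round-to-round amplification bias. Passing
tests therefore demonstrate the pipeline's correctness under the stated
error model, not robustness to every artefact of real sequencing.

```{r}
planted <- tibble(peptide = "SICRFFC", enrichment = 10,
                  naive_frequency = 1e-3)
cfg <- sim_config(n_variants = 500, planted = planted,
                  reads_per_experiment = 2e4, error_rate = 0, seed = 42)
naive <- generate_naive_population(d, cfg)
target <- simulate_selection_round(naive, planted, label = "target")
dir <- tempfile()
man <- render_fastq_run(list(naive = naive, target = target), d, cfg, dir)
ct <- process_run(file.path(dir, "R1.fastq"), file.path(dir, "R2.fastq"),
                  d, cfg$barcodes)
ct
```

## Differential enrichment

For each peptide the test experiment is compared against each control with
an **exact conditional binomial test**: conditional on the peptide being
seen `k = c_test + c_ctrl` times in total, under the null of equal
underlying frequency `c_test ~ Binomial(k, N_test/(N_test + N_ctrl))`, and
the two-sided p-value sums the probabilities of all outcomes no more likely
than the observed one. The choice is a package decision: the screen's
published rule states only raw `p < 0.05`, and an exact, replicate-free
test is the natural statistic for single-round count pairs (no replicates
exist from which to estimate overdispersion, so none is modelled). The fold
change is the ratio of pseudocounted frequencies
`((c_test + a)/N_test) / ((c_ctrl + a)/N_ctrl)` with `a = 1` by default —
the pseudocount keeps fold finite for zero control counts but is kept out
of the p-value, which stays exact on raw counts.

Hit nomination mirrors the published rule: raw `p < 0.05` **and** fold
`> 3`, strict inequalities, intersected across all control comparisons
(Benjamini–Hochberg adjustment is available but off by default, matching
the raw-p rule as printed). The final list is ranked by the *worst* raw p
across comparisons, ties broken by the smallest fold (descending), then
peptide — a deliberate most-conservative reading, since the rule does not
say which comparison's p orders the list.

```{r}
res <- compare_enrichment(ct, test = "target", controls = "naive")
nominate_hits(res, de_config())
```

## Motif analysis

Three views of a hit set, all exact tallies:

- `position_frequency_matrix()`: column-normalised residue frequencies per
  position (heat-map / logo input), requiring a single architecture.
- `dipeptide_enrichment()`: ordered adjacent residue pairs over the *full*
  displayed peptide, fixed serine and cysteines included — adjacency over
  the whole heptamer is a declared decision, since the pair-counting
  convention is not specified by the analysis being modelled. Expected
  counts come from a positional-independence background (outer product of
  the set's own residue frequencies) by default, or from naive-library
  frequencies; enrichment is `(obs + 1)/(exp + 1)`.
- `cluster_families()`: single-linkage connected components of the Hamming
  graph at radius 2 (the clustering method of the original analysis is
  unstated; single-linkage Hamming is the simplest method that recovers
  "families related by a few substitutions" and is what the consensus
  operation presumes). `consensus_from_family()` calls per-position modes,
  alphabetical on ties, with ties flagged.

## Binding models

Validation assays run at ligand concentrations (1–50 µM) comparable to the
dissociation constants being measured (single-digit µM), so the
excess-protein hyperbolic approximation is wrong by design. Everything is
built on the exact two-species depletion equilibrium,

$$f = \frac{(L + P + K_D) - \sqrt{(L + P + K_D)^2 - 4 L P}}{2L},$$

the physical root of the mass-action quadratic (`fraction_bound()`).

- **FP**: `r(P) = r_free + (r_bound − r_free)·f(L, P, K_D)`, least squares
  over the three parameters. Initialisation is a deterministic 7-start
  logarithmic grid for `K_D` over `[min(P)/10, max(P)·10]`; the reported
  fit is the lowest-RSS start, and the convergence flag is honest.
- **¹⁹F NMR suppression**: binding is modelled as complete loss of the
  observable signal for the bound fraction (slow-exchange broadening):
  `S(P) = S₀(1 − f)`. Under this model the half-suppression concentration
  is `AC50 = K_D + L/2` in closed form, so both are reported; when the
  model fit fails, a model-free AC50 by monotone interpolation at `S₀/2`
  is returned instead. Rising signal beyond 5% of the range triggers a
  complex-binding warning; flat signal is flagged as no binding. The
  ligand concentration is always an explicit argument, never defaulted:
  the assay has been run at 20 and 50 µM and the AC50 shifts with `L/2`.
- **Alanine scan**: `ΔΔG = RT ln(K_D,mut/K_D,wt)`, `R` = 1.987×10⁻³
  kcal/(mol·K), `T` = 298.15 K by default (the conversion temperature is
  not stated by the source analysis; 25 °C is the conventional choice).
  `correlate_ddg()` gives the Pearson r and OLS line of computed
  (e.g. free-energy-perturbation) against experimental ΔΔG.

```{r}
p <- 10^seq(-1, 2, length.out = 12)
curve <- tibble(protein_conc = p,
                signal = 0.05 + 0.2 * fraction_bound(1, p, 5))
fit <- fit_fp_curve(curve, l_tot = 1)
glance(fit)
ddg_from_kd(50, 5)   # a 10-fold affinity loss in kcal/mol
```

## Numerical and scale choices

- Exact-test ties use the customary `(1 + 1e-7)` relative slack when
  comparing outcome likelihoods, so results agree with the standard exact
  binomial test to machine precision.
- The simulator's determinism contract is byte-identical FASTQ for
  identical configuration and seed.
- The test suite and the acceptance script verify the pipeline at the
  campaign's stated operating points — 3 experiments × 1e5 read pairs for
  the error-free round trip, 200 null replicates of 500 variants at 1e4
  reads for the false-positive rate, 100 replicates at 1e4 variants × 1e5
  reads for planted-binder power, 50 noisy replicates per curve-fit study —
  sizes chosen so the whole battery reruns in a few minutes while keeping
  Monte-Carlo error well inside the asserted bounds.
- Coordinates are 1-based inclusive at the user surface (R convention);
  the reverse mate is reverse-complemented before any comparison.

## Known limitations

- The exact conditional binomial test is this package's choice; the
  original analysis script's statistic is not published in detail, so hit
  counts on the original deposited data may differ from the printed total
  without implying an implementation defect. Counting is at the peptide
  level with no synonymous-DNA clustering, which is the other place a
  reimplementation could diverge.
- No overdispersion: with true biological replicates the exact test will
  be anticonservative; it is designed for single-round, replicate-free
  screens.
- Binding models are strictly single-site. Multi-site or cooperative
  behaviour (seen for albumin by calorimetry) is out of scope, and partial
  NMR line broadening is not modelled.
- No indel-aware alignment: reads with indels fail the fixed-offset
  matches and are audited as primer failures, which is the intended
  behaviour under a substitution-only error model.
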