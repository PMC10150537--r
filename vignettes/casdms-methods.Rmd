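---
title: "Models and methods behind casdms"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind casdms}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(casdms)
library(dplyr)
```

casdms implements the computational side of a directed-evolution workflow
for CRISPR-Cas12a nucleases: scoring a one-codon-change saturation
mutagenesis library from multi-round bacterial survival selection,
inferring position-by-base mismatch energy matrices from Spec-seq
(bound/unbound) and SEAM-seq (cleaved/mock) count data, and classifying
editing outcomes of diploid T0 plants from amplicon allele frequencies.
This vignette explains the models, the parameters that matter, and the
design decisions taken where the analysis had genuine freedom. Every
empirical number quoted here is computed by the package's test suite or
the bundled acceptance script, not transcribed from elsewhere.

## The selection screen

### Library model

The library is built by NNK saturation mutagenesis: each clone carries
exactly one codon replaced by one of the 32 NNK codons (N = any base at
positions 1–2, K = G/T at position 3). The NNK set encodes all 20 amino
acids plus exactly one stop codon (TAG), so `enumerate_nnk_variants()`
emits, per codon position, the 32 NNK codons minus the wild-type codon
when it is itself NNK-encodable. Consequences (synonymous / missense /
nonsense) follow the standard genetic code via Biostrings.

### Selection dynamics

Cell survival under toxin induction is tied to nuclease activity, so we
summarize each variant by a survival weight $w \ge 0$: the per-round
multiplicative fitness relative to wild type ($w = 1$). One selection
round is the deterministic expectation update

$$ f'(v) = \frac{f(v)\,w(v)}{\sum_u f(u)\,w(u)}, $$

so after $t$ rounds a variant's abundance has grown by $w^t$ against the
library average. This is the simplest model consistent with iterative
plating: selection is deterministic in expectation, and stochasticity
enters only at sequencing, as one multinomial draw of the chosen depth
per sample. An optional per-round binomial bottleneck (transformation
efficiency) can be switched on; it adds variance without changing
expectations, and is off by default.

Ground-truth weights are assigned at the amino-acid-substitution level:
all synonymous codon encodings of the same missense substitution share
one weight, because selection acts on the protein, and the default
amino-acid-level scoring would otherwise have no well-defined truth per
scored record. Nonsense variants always get $w = 0$ (a truncated
nuclease cannot clear the toxin plasmid) and synonymous variants always
get $w = 1$. Missense substitutions fall into beneficial / neutral /
deleterious / null classes; the default class weights are the discrete
ladder $\{2, 1, 1/2, 0\}$ at proportions 10/70/15/5 %. A `continuous`
option draws beneficial and deleterious weights log-uniformly instead,
which is what the package's own rank-recovery property test uses (see
"Rank recovery and ties" below).

### Enrichment scoring

The phenotype score is the natural log of the pseudocounted frequency
ratio between the two sequenced rounds (3 and 4 by default):

$$ s_r(v) = \ln \frac{(c_{4,r}(v) + \alpha) / (N_{4,r} + \alpha V)}
                     {(c_{3,r}(v) + \alpha) / (N_{3,r} + \alpha V)} $$

per replicate $r$, with pseudocount $\alpha = 0.5$ and $V$ the number of
table rows. Design decisions, each exposed as an argument:

* **Round pair.** Scores default to the round-3 → round-4 ratio, the two
  sequenced rounds; any pair (including input → final) can be requested.
* **Count filter.** A variant is scorable in a replicate iff its summed
  counts across that replicate's sequenced rounds reach 50, boundary
  inclusive; the global filter requires all replicates. 50 counts bound
  the sampling standard deviation of $s$ at roughly
  $\sqrt{1/c_3 + 1/c_4} \lesssim 0.3$ natural-log units.
* **Centering.** Synonymous variants are biologically neutral, so each
  replicate's scores are centered by subtracting the median raw score of
  its passing synonymous variants. This makes the centered synonymous
  median exactly zero *by construction* — the "synonymous variants
  cluster around 0" behaviour is a calibration choice, not a finding —
  and makes scores invariant to uniform composition drift between
  rounds. With fewer than 10 passing anchors the replicate is left
  uncentered and flagged.
* **Resolution.** Scoring runs at amino-acid level by default
  (missense/nonsense counts pooled over codon encodings; synonymous
  rows kept at codon resolution as anchors), matching residue-style
  reporting such as G146R or R182V; codon-level scoring is a flag away.
* **Positivity.** A hit must have a strictly positive centered score in
  *every* replicate; the mean score is reported regardless. No p-values
  are attached: the screen calls hits by sign and rank, and shrinkage or
  significance machinery is deliberately out of scope.

`prioritize_interface()` then restricts the ranked hit list to residues
on a user-supplied interface annotation (for example, DNA/R-loop-contact
residues taken from a structure); the package does not derive such
annotations itself.

### Rank recovery and ties

A natural end-to-end check is the Spearman correlation between
$\ln w$ and the mean centered score. One subtlety deserves emphasis: with
*discrete* weight classes most variants are exactly tied in the ground
truth (70 % of missense substitutions at $w = 1$), and tie-averaged
Spearman correlation against a continuous score then has a hard ceiling
well below 1 even for a perfect scorer — about 0.78 when the three
nonzero classes all pass the filter, and about 0.58 when the $w = 0.5$
class is removed by the count filter (at the default 300-codon /
depth-$10^6$ scale its expected round-3+4 counts are ~13–40, below the
50-count threshold). The package therefore tests rank recovery with the
continuous effect map, where ties are absent and the observed Spearman
correlation exceeds 0.9; with the discrete ladder the observed value
sits at the tie ceiling, which is the expected behaviour of a correct
implementation, not a deficiency of the scorer.

## Specificity models (Spec-seq / SEAM-seq)

### Estimators

For a mismatch library (all sequences within Hamming distance $K$ of the
target, default $K \le 4$; exhaustive for small windows, per-distance
sampled otherwise), relative binding free energies come from the
bound/unbound double ratio

$$ \Delta\Delta G(s) = -\ln \frac{(b_s + \alpha)/(u_s + \alpha)}
                               {(b_{\mathrm{ref}} + \alpha)/(u_{\mathrm{ref}} + \alpha)} $$

in kT units, exactly 0 for the perfect match. All sequence-independent
constants — chemical potential, gel-partition efficiency, sequencing
depth — cancel in the double ratio, which is why this estimator is exact
in the infinite-depth limit. The SEAM-seq depletion score is the
analogous mock/cleaved log-ratio, anchored at the reference; higher $d$
means more efficiently cleaved, and sequences cut more poorly than the
perfect match score negative.

### The additive energy model

`fit_energy_model()` fits

$$ \mathrm{score}(s) \approx \sum_{i:\, s_i \ne t_i} \varepsilon[i, s_i] $$

by weighted least squares, with the target base pinned to exactly 0 at
every position, observation weights defaulting to the harmonic mean of
the two fraction counts (an inverse-variance proxy for a log-ratio of
counts), and parameters never observed in the library reported as
missing rather than zero. Additivity across positions is the key
modelling assumption; pairwise interaction terms are deliberately not
fitted.

The assays differ in how well the additive model can hold:

* **Binding** is simulated with a logistic (Fermi) occupancy
  $p_b = 1/(1 + e^{\Delta\Delta G - \mu})$, and the log-odds double
  ratio recovers $\Delta\Delta G$ exactly for any chemical potential
  $\mu$, so the fit is exactly identifiable: on analytic (noiseless)
  frequencies the round trip recovers the generating penalties to
  numerical precision (MAE below $10^{-6}$ kT; observed ~$10^{-16}$),
  and at depth $10^6$ per fraction over an exhaustive $K = 2$ library
  on a 24-nt site the MAE is a few hundredths of a kT.
* **Cleavage** is simulated with first-order kinetics,
  $\mathrm{surv}(s) = \exp(-k t\, e^{-\Delta\Delta G(s)})$, under which
  the depletion score is only *approximately* additive in the
  penalties. The cleavage fit is therefore treated as a descriptive
  summary — tests check sign and ordering, not exact recovery — and the
  nonlinearity of the assay lives entirely in this link function.

Position indexing is 1-based from the PAM-proximal end, so statements
about the seed region — for Cas12a, the PAM-proximal ~18 bp carry most
of the sequence specificity — map directly onto matrix rows. `energy_to_logo()` converts penalties to
per-position Boltzmann weights $p[i, b] \propto e^{-\varepsilon[i, b]}$
with information content $2 - H(p)$ bits, rendered by
`plot_energy_logo()` and exportable as a MEME minimal motif.

## Plant genotyping

Amplicon allele-frequency tables are classified per plant with explicit
frequency thresholds (all exposed via `genotype_thresholds()`): WT
fraction $\ge 0.95$ → `WT`; one mutant allele $\ge 0.90$ with WT
$< 0.05$ → `biallelic_homozygous`; two distinct major mutant alleles
(each $\ge 0.35$) with WT $< 0.05$ → `biallelic_heterozygous`; WT within
$[0.35, 0.65]$ plus exactly one major mutant allele → `monoallelic`;
everything else → `chimeric` (the residual mosaic class). Reported
genotyping studies do not publish numeric calling rules, so these
defaults are declared, not inferred: they encode the diploid
expectations (allele dosage ½ per chromosome) with generous margins for
sampling noise at the default minimum depth of 100 reads. Summaries
(`summarize_targets()`) compute the percentage edited, percentage
biallelic, homozygous rate with all called plants in the denominator
(so 10 of 12 homozygous plants is 83.33 %), and the deletion-size range
over mutant alleles.

The bundled read-level caller (`call_alleles_from_reads()`) is
intentionally minimal — global pairwise alignment via Biostrings with
+1/−1 match/mismatch and −4/−1 gap open/extend, alleles keyed by indel
pattern within ±20 bp of the cut site — and exists so that synthetic
fixtures can be processed end to end; production amplicon callers
interoperate through the same allele-table contract.

## What the synthetic data does and does not emulate

The generator provides ground truth for every stage: NNK libraries under
multi-round selection with multinomial sequencing noise, specificity
counts from a known additive energy model, and diploid allele mixtures
with optional chimeric noise. It deliberately omits PCR amplification
bias, position- or motif-dependent sequencing error (the optional FASTQ
emitter uses a uniform per-base substitution rate, default $10^{-3}$),
toxin-induction kinetics, plasmid copy-number effects, epistasis between
codons (impossible in a one-change library) and pairwise energy
couplings. Passing round-trip tests therefore demonstrates correctness
of the *analysis* under the stated generative assumptions — not that
real libraries satisfy those assumptions.

## Numerical and interface choices

* Pseudocount $\alpha = 0.5$ everywhere a log-ratio of counts is taken.
* Frequencies must sum to 1 within $10^{-9}$; TSV writers format
  doubles to 6 significant digits and stamp a version + configuration
  digest header, so identical configurations give byte-identical files.
* All stochastic operations take a single integer seed, forked
  deterministically per stage; the RNG state of the caller is restored.
* Default problem sizes — a 300-codon reference (a desk-scale stand-in
  for the 1228-residue protein), depth $10^6$ per sequenced sample,
  3 replicates, a 24-nt specificity target with exhaustive $K = 2$
  enumeration, 120 simulated plants — run the full pipeline and test
  suite in well under a minute on one CPU.
* The package is driven from R: `run_pipeline()` executes the
  screen / specseq / plants pipelines from a validated YAML or list
  configuration (unknown keys are rejected before anything runs) and
  writes TSV/JSON artifacts plus a structured run log, which is the
  package's batch interface.

## A worked micro-example

```{r screen-example}
scr <- simulate_screen(n_codons = 60, depth = 3e5, seed = 7)
rec <- score_enrichment(scr$counts, scr$variants)
summary_tbl <- rec |>
  filter(passes_count_filter) |>
  count(consequence, positive = is_positive)
summary_tbl
head(call_hits(rec), 3)
```

```{r specseq-example}
target <- "ACGTTGCA"
truth <- spec_truth(target, seed = 3)
lib <- enumerate_mismatch_library(target, K = 2)
cts <- simulate_specseq(truth, lib, analytic = TRUE)
fit <- fit_energy_model(
  cbind(binding_energy(cts, target, alpha = 0),
        cts[c("bound", "unbound")]),
  target
)
energy_mae(fit, truth)  # numerical-precision recovery in the analytic limit
```

## Known limitations

* The enrichment normalizer is the synonymous median; screens whose
  synonymous variants are *not* neutral (e.g. strong codon-usage
  effects) would need a different anchor.
* The additive energy model cannot represent epistatic mismatch
  interactions; residual RMSE is reported so such lack of fit is
  visible.
* The cleavage (SEAM-seq) penalties inherit the kinetic link's
  nonlinearity and should be read as relative depletion summaries, not
  calibrated activation energies.
* Genotype classes are threshold rules on allele frequencies; heavily
  chimeric tissue with alleles near the thresholds is assigned the
  residual class rather than resolved.
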