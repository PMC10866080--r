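---
title: "Methods: models, rules and the synthetic world behind nstrat"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: models, rules and the synthetic world behind nstrat}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

`nstrat` surveys ten microbial nitrogen (N) acquisition strategies in
protein sets: ammonium uptake (AmtB), biological nitrogen fixation
(nitrogenase, NifH+NifD+NifK), ferredoxin-dependent nitrite reduction
(NirA), NADH-dependent nitrite reduction (NirB+NirD), assimilatory
nitrate reduction (NasA co-occurring with a nitrite reductase), urea
(UreC), cyanate (CynS), chitin depolymerization (chitinase), HexNAc
assimilation (hexosaminidase), and amino-acid uptake (five transporter
families of the APC superfamily: APC, AGCS, BCCT, LIVCS, HAAAP). This
vignette records the models behind each stage, the parameters that
matter, and the design decisions taken where the design was genuinely
open.

## The energetic-cost frame

Strategy costs differ by orders of magnitude: GS–GOGAT ammonium
assimilation consumes 1 ATP per NH4+ and no reducing equivalents;
assimilatory nitrite and nitrate reduction consume 6 and 8 reducing
equivalents; nitrogenase consumes 16 ATP plus 8 reducing equivalents per
mole of N2. `cost_table()` returns these constants with a coarse
low/medium/high cost class. Amino-acid uptake is transport-coupled
(PMF/SMF secondary transport) with no assimilation electron cost; urea,
cyanate, chitin and HexNAc routes carry high *indirect* machinery costs
for which no single ATP stoichiometry is meaningful, so their `atp_cost`
is `NA` rather than an invented number.

## Profile models and scoring

A marker's reference alignment is compiled into a lightweight profile:
`M` match states (columns with gap fraction strictly below the
occupancy threshold, default 0.5 — the strict inequality makes the
boundary deterministic: a 4-row column with two gaps is *not* a match
state), position-specific match emissions with pseudocount smoothing
`(count + c·bg) / (n + c)` (default `c = 1`), one shared insert emission
distribution equal to the background, and per-position M/I/D transitions
estimated from gap patterns with Laplace (+1) smoothing. Wildcard
residues (B, Z, X, U, O, J) emit at background frequency both when
building and when scoring, so odd residues never disqualify a protein.

Scoring is a local forward algorithm in log2 space: free entry at any
match state with uniform mass `1/M`, free exit from any match state,
flanking residues emitted by the background so they cancel from the
log-odds. The score is the forward sum over *all* local alignment
paths, not the Viterbi best path. The exact path set is pinned by an
exhaustive enumeration oracle in the tests (all profiles with `M ≤ 3`
against all sequences of length ≤ 4 must agree to 1e-9 bits). Deliberate
non-goals: no per-position insert emissions, no glocal/multi-hit modes,
no domain envelopes, no tree-based hit curation.

### Threshold calibration

Per-marker acceptance thresholds default to *max decoy score + 2 bits*,
an empirical-maximum rule calibrated on background-sampled decoys.
Two calibration choices matter and are easy to get wrong:

* **Decoy length.** Local forward scores grow roughly logarithmically
  with query length (more entry points), so decoys must be at least as
  long as the queries being screened. We calibrate at the worst-case
  length (150 aa, the top of the synthetic decoy length span).
* **Sample size.** The empirical maximum sits in the tail; with only a
  few hundred decoys the +2-bit margin still admits roughly one false
  positive per thousand decoy–marker pairs. The default is 2000 decoys
  per marker, which pushes the expected false-positive count for a
  50-decoy × 17-marker screen to about 0.05. Because the rule is an
  empirical maximum, a small residual false-positive probability under
  re-seeding is irreducible; the shipped tests are fixed-seed.

`calibrate_null()` additionally fits a Gumbel to decoy scores by the
method of moments (`lambda = pi/(sd·sqrt(6))`,
`mu = mean − 0.5772/lambda`) and converts scores to E-values as
`N_targets · exp(−lambda·(score − mu))`. Note that by this formula the
E-value at `score = mu` is exactly 1. Degenerate calibrations (zero
score variance) are an error, not a silent NaN. Users reproducing an
external curation can bypass calibration entirely by supplying their own
thresholds to `marker_registry()` or the pipeline config.

## Rule set decisions

* **NirD is required** alongside NirB by default: the NADH-dependent
  nitrite reductase marker is the two-subunit NirBD complex, and
  requiring both subunits is the stricter reading of "functionally
  critical elements". A `require_nird = FALSE` flag relaxes this, since
  whether the original curation enforced the small subunit is not
  documented.
* **BNF requires all three** of NifH, NifD, NifK; there is no
  single-gene nitrogenase call.
* **UreC alone** counts as the urea strategy (the marker is the urease
  alpha subunit, not a transporter); this follows the marker definition
  even though "uptake" arguably also needs a urea transporter.
* **Cyanate is classed as organic** N for the inorganic-fraction
  statistic (the inorganic substrates are N2, ammonium, nitrite,
  nitrate); BNF is inorganic.
* **Transporter families are reported but not counted**: the five family
  flags decompose the single amino-acid-uptake strategy, so
  `strategy_count` ranges over 0–10, never 15.
* All rules are positive monotone (adding hits never removes a
  strategy), verified exhaustively against an independently coded
  brute-force evaluation over all 2^17 marker subsets.

QC follows MIMAG high-quality conventions with strict boundaries:
completeness must exceed 90 (exactly 90.0 fails), contamination must be
below 5, rRNA present, ≥ 18 tRNAs. Genomes with an all-false
10-strategy vector are dropped (`zero_pathways`) because absence of
every pathway is indistinguishable from assembly incompleteness, as are
genomes lacking domain-level taxonomy.

## Bootstrap prevalence

The resampling unit is the genome, and the summarized statistic is the
count of genomes carrying each strategy (proportions are reported
alongside). Intervals are plain percentile intervals (2.5/97.5, linear
interpolation between order statistics) around the replicate median —
not BCa — because the target quantity is the bootstrapped median count
with its percentile band. The taxon-balanced variant draws
`min(k, available)` genomes per taxon (default rank: phylum,
`k` = median per-taxon size) per replicate; it is one parameterized
scheme rather than a family of bespoke resampling designs, since the
exact variants used in published supplements are rarely specified.
Correctness is anchored at `n = 3`, where the 27 equally likely ordered
resamples can be enumerated exactly.

## Association models

* **Count scaling**: OLS of strategy count on log10 genome length. The
  generator links CDS count deterministically to length
  (`n_cds = length/1000`), so either axis can be used.
* **Group comparisons**: tie-corrected Kruskal–Wallis followed by all
  pairwise two-sided Wilcoxon rank-sum tests. The multiplicity
  correction is Holm — the conventional companion when no correction is
  named. Pairwise p-values agree with exhaustive permutation enumeration
  for group sizes ≤ 5.
* **Family-level taxonomic adjustment** is implemented as family
  indicator *fixed effects* by default, with a random-intercept option
  (`family_random = TRUE`, via lme4) behind a flag. The phrase
  "mixed models with fixed effects for taxonomic relatedness" is
  self-contradictory; the fixed-effect reading is literal,
  deterministic, and does not depend on optimizer convergence.
* **Reference categories**: respiration = anaerobic (so "aerobic
  effect" coefficients read directly), ecosystem = largest category.
* **Complete separation** in the logistic models is detected (huge
  coefficients/SEs) and reported via a `converged = FALSE` flag with a
  diagnostic, never silently.
* **Host contrast**: Welch two-sample t (unequal variances,
  Welch–Satterthwaite df). The Welch form is the only one that produces
  fractional degrees of freedom, which is how such results are reported.
* **Ordination**: column-centred PCA (constant columns retained; they
  contribute zero variance), and projection-form logistic PCA fit by
  majorization–minimization on the Bernoulli deviance with the
  saturated natural parameters scaled by `m = 4` — a concrete,
  reproducible choice where only the technique is named. The MM update
  solves the quadratic surrogate exactly by an eigendecomposition, so
  the deviance trace is provably non-increasing, and initialization from
  the linear PCA of the scaled natural parameters guarantees the final
  deviance never exceeds the k-truncated linear-PCA baseline passed
  through the logistic link. Constant columns are dropped (with a
  warning) for logistic PCA, where they carry no curvature information.

## The synthetic world

`simulate_community()` realizes each strategy independently per genome
with probability `logistic(baseline + beta_size·(log10len − 6.5) +
respiration offset + host offset + family effect)`, then plants the full
required marker complement for present strategies as sequences emitted
from the marker profiles (length = match states + Poisson(2) insertions,
per-residue substitution noise) plus background decoys. Defaults — the
generator's stated world, fixed once:

* baseline log-odds ordered amino-acid > ammonium > chitin > HexNAc >
  Fd-nitrite > urea > NADH-nitrite > nitrate > cyanate > BNF, with gaps
  wide enough that the implied marginal order is recoverable at a few
  hundred genomes;
* `beta_size = 1.5` per log10 bp shared across strategies; genome
  lengths uniform on 10^6–10^7 bp;
* respiration offsets (anaerobic = reference): aerobic +0.4 on all
  strategies except BNF (−1.5) and chitinase (+1.0); facultative +0.3
  with BNF −0.5; phototrophic +0.2 — encoding "aerobes carry more
  strategies, except BNF which is an anaerobe's strategy";
* host-associated offset −1.5 on the five inorganic strategies only;
* 20 families assigned round-robin sharing one N(0, 0.5) log-odds
  perturbation — the minimal structure needed to exercise family-level
  adjustment;
* uniform 1/20 residue background, making null calibrations
  analytically checkable.

Two consistency repairs keep sampled truth rule-consistent: a genome
drawn nitrate-positive without a nitrite route also gets the ferredoxin
route (co-planting, which slightly boosts the Fd-nitrite marginal — the
implied-order oracle in the tests accounts for this), and an
amino-acid-positive genome with no sampled family gets the most probable
family forced on.

Because published surveys report effect *directions* and significance
but almost never effect magnitudes, the default betas are chosen for
estimator testability, not to mimic any real catalogue. The generator
does **not** emulate nucleotide genomes, gene prediction, realistic
protein evolution (no indel phylogenies, no rate heterogeneity),
habitat-specific amino-acid composition, or correlated strategy
co-occurrence beyond the rule-consistency repairs. A green test
therefore establishes that the estimators recover planted structure from
data satisfying their assumptions — it says nothing about curation
quality or annotation error on real MAGs.

## Determinism and numerics

All randomness flows from one root seed through named substreams
(`covariates`, `planting`, `decoys`, `bootstrap`, per-stage pipeline
seeds) derived by stable string hashing, so identical (config, seed)
pairs regenerate byte-identical FASTA, TSV and JSON artifacts, and
re-running one stage never perturbs another. Ties in hit sorting break
on protein id; consensus ties break toward the alphabetically first
residue; TSV output is a pinned dialect (tab, UTF-8, '.' decimal, no
quoting, fixed numeric formats). Forward scoring runs in log2 space with
log-sum-exp (C++); empty sequences, illegal residues, ragged alignments,
degenerate profiles, zero-variance calibrations, constant outcomes and
zero-strategy profiles all raise typed errors rather than propagating
NaN.

## Known limitations

* The profile model is deliberately smaller than a full Plan7
  architecture; scores are comparable within this package, not to HMMER
  bit scores (the `tblout` reader exists for exact interop).
* The empirical-max threshold rule keeps a small, irreducible
  false-positive probability; users needing guarantees should supply
  curated thresholds.
* Presence of a pathway's genes does not imply its use; the package
  measures genomic potential only, and expression, regulation and
  peptidoglycan/peptidase routes are out of scope.
* Real-catalogue headline statistics (e.g. genome counts after MIMAG
  filtering of a public MAG set) require the external download and are
  not reproduced at desk scale.
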