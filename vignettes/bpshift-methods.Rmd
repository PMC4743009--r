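---
title: "Models and methods behind bpshift"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind bpshift}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bpshift)
```

# Scope and coordinate conventions

`bpshift` analyses the splicing signature of SF3B1 hotspot mutants:
cryptic 3′ splice sites (AG′) upstream of canonical acceptors (AG),
driven by alternative branchpoints (BP′). All genomic coordinates are
0-based half-open, matching the BED inputs. Transcript-relative acceptor
positions use the field's convention: −1 is the last intronic base (the G
of the AG dinucleotide), +1 the first exonic base, and position 0 does
not exist. Distances and windows are always transcript-oriented; minus
strands are handled only at I/O time (`extract_window` returns
reverse-complemented sequence), which keeps every downstream statistic
strand-agnostic.

# Differential junction usage

The test is a deliberately transparent negative-binomial analysis of
junction read counts rather than a wrapper around an existing
differential-expression engine, so that every step is inspectable:

* **Normalisation.** Median-of-ratios size factors over junctions with
  all-positive counts, rescaled to geometric mean 1. The rescaling is
  what makes normalisation idempotent (re-estimating factors on
  normalised counts returns exactly 1); without it the re-estimate is a
  common constant. If no junction is positive everywhere, total-count
  ratios are used with a warning.
* **Per-junction test.** Counts are modelled as NB with variance
  µ + αµ²; α is estimated per junction by method of moments on
  normalised counts with residuals taken around the group means, floored
  at 10⁻⁸. The Wald statistic compares log(mean + c) between groups
  (pseudocount c = 0.5, which also defines the reported log2 fold
  change) with delta-method standard errors, referred to the standard
  normal. A Monte-Carlo check at the cohort's design (16 vs 56 samples,
  µ = 100, α = 0.05) gives an empirical type-I error of ≈0.05–0.06 at
  nominal 0.05, so no finite-sample correction is applied.
* **Selection.** Benjamini–Hochberg adjustment over testable junctions
  (all-zero junctions are excluded from the denominator), with the study
  thresholds BH p ≤ 10⁻⁵ and |log2 FC| ≥ 1 as defaults. Junctions with a
  cohort-wide total below 10 are not tested; this stabilises the moment
  dispersion estimate and is configurable.

Exact replication of a shrinkage-based tool's output on real data is a
non-goal; on deep real cohorts the selected set will differ in the tail.

# Event classification

A differential junction is paired against annotated junctions sharing its
donor (alternative-3′ candidate) or its acceptor (alternative-5′
candidate). Exactly one side pairing fixes the class; both or neither is
`ambiguous_both` (the two ambiguous cases are never separated
numerically, so they are merged). The canonical partner is the annotated
junction with the highest mean normalised count, ties broken by smaller
absolute distance — the study does not state its canonical-selection
rule, so the most-expressed-partner convention was chosen as the one a
practitioner would assume. Novelty is defined against the supplied
annotation list, removing any dependence on a live transcript database.
The periodicity statistic is a one-sided exact binomial test of the
multiple-of-3 fraction against 1/3 over the −50..−1 window.

# Branchpoint scoring and assignment

The branch adenosine is bulged out of the U2/intron duplex, so a
heptamer with the branch A at position 6 pairs at positions 1–5 and 7
with the U2 branch-recognition region (partners A,U,G,A,U,G). A
Watson–Crick pair scores 1.0, a G·U wobble 0.5 (a tunable weight — no
weighting is published, and 0.5 is the conventional half-strength for
wobbles), anything else 0; the consensus UACUAAC scores 6.0. This
transparent scheme stands in for the SVM score used in the original
branchpoint predictions; published SVM values are not numerically
reproduced, only the ordering logic they support.

Candidates are every adenosine between 6 and 100 nt of the 3′ss (the
6-nt minimum mirrors the relaxed minimal distance the study configured in
its predictor). Assignment ranks candidates by pairing score, then
polypyrimidine score, then proximity to a distance prior (−25 for BP,
the BP′-window midpoint for BP′), then the more upstream position.

One refinement was required for coherence: candidates on the AG side
whose spacing from the AG′ falls inside the BP′ window are excluded from
the canonical-BP search. A branchpoint at working distance of the
upstream acceptor serves that acceptor; since the planted (and, by the
biology, the real) BP′ pairs more strongly than BP, omitting this
exclusion makes the BP′ win both assignments and no canonical
distribution centred near −25 can ever be observed.

# The AG/AG′ choice model

The mechanistic model turns the qualitative picture — mutant U2 snRNP has
a stricter branchpoint requirement and a lower U2AF dependence — into
usage fractions:

* Acceptor candidates are the reference AG plus every intronic AG
  dinucleotide in the search window; each carries a U2AF affinity
  `ppt × (1 + 0.5·[+1 = G])` (polypyrimidine fraction over −20..−3 and
  the U2AF1 AG-G preference).
* Each branchpoint candidate is **claimed by the first acceptor
  downstream of it at or beyond the regime's minimum spacing**
  (AG-scanning exclusivity), with the regime's maximum spacing still
  applying. The wild-type regime uses a wide window (default −44..−16),
  the mutant regime the short BP′ window (default −18..−9, the 11–14 nt
  spacing with margin). Exclusivity is essential: destroying the
  canonical BP must silence the AG (all flux moving to AG′), which is
  impossible if the strong BP′ can also serve the AG.
* An acceptor is usable in a regime if it owns a branchpoint with
  pairing score ≥ 3 (`s_floor`; needed so "abolished" states are
  representable). Wild-type usage softmax-weights usable acceptors by
  U2AF affinity, mutant usage by the owned branchpoint's pairing score,
  both at temperature τ; a sample with mutant transcript fraction f uses
  the linear mixture (1−f)·WT + f·MUT.
* τ defaults to 0.1. The minigene readouts this model must reproduce are
  nearly all-or-none, while the available score gaps are bounded
  (pairing ∈ [0,6], affinities ≲ 1.5): a soft temperature leaves tens of
  percent of residual usage in states described as completely abolished,
  so a sharp one — where a 0.5-point pairing advantage is near-decisive —
  is the smallest choice that makes the full mutagenesis table pass.
  With τ = 0.1 the wild-type AG′ leak of the TMEM14C-like construct is
  ≈0.4% and the AG′/AG index at f = 0.30 is ≈0.43, both in the range the
  capillary-electrophoresis measurements suggest.

The bundled `tmem14c_like_construct()` is a synthetic 70-mer built from
the described architecture (AG with +1 G inside a strong pyrimidine
tract; AG′ 16 nt upstream with +1 C; a suboptimal canonical BP, score
4.0, whose branch A lies unusually close to the AG at −6; a stronger BP′,
score 5.5, 13 nt upstream of the AG′ with a second adjacent adenosine).
The real minigene sequences are not embedded — positions and roles come
from the described mutagenesis, and the mutation series is named by role
(`bp_destroy`, `bpprime_destroy`, `agprime_destroy`, `neutral`,
`agprime_plus_one_G`, `bp_perfect`, `swap`). Because the construct's
canonical BP sits at −6, the truth table runs with construct-specific
windows (wild-type −44..−5, mutant −18..−5); the model honours whatever
windows it is given rather than taking a position on whether a −6
branchpoint implies relaxed spacing biology. Outcome labels compare
usage against the unmutated construct at both mutant fractions:
abolished (< 0.02 where the baseline was used), strengthened (increased
at both fractions), unchanged (within 5% at both), new_site (acceptor
absent from the baseline), else used.

```{r truth-table, eval = FALSE}
mutagenesis_truth_table()[, c("mutant", "acceptor_offset",
                              "usage_f_hi", "outcome")]
```

# The synthetic cohort generator

The generator is first-class, tested code: it plants the complete
signature and returns the ground truth needed for recovery tests.

* **Design.** 600-nt loci on one contig, alternating strands; a 300-nt
  intron with the canonical acceptor at a fixed position. Defaults: 16
  mutant vs 56 wild-type samples; 200 acceptors of which 30% are
  sensitive; ψ = 0.5 of a fully mutant transcriptome's reads redirected
  to AG′; mutant transcript fraction 0.5 per mutant sample (a
  heterozygous hotspot); wild-type AG′ leak 0.02 (the faint wild-type
  usage seen in minigene assays, whose exact transcriptome-wide value is
  not published); NB counts with µ = 200 and α = 0.05, the standard
  overdispersion magnitude for RNA-seq counts. In real tumour cohorts
  only ~0.5% of junctions are affected; the default sensitive fraction
  is deliberately far higher so that a 200-locus desk cohort yields
  enough planted events to measure sensitivity and recovery at all.
* **Sequence.** Uniform ACGT background with spurious AG dinucleotides
  left in place (classifiers must tolerate decoys); a pyrimidine-rich
  tract over −20..−3 (85% C/T); a canonical BP heptamer CACTAAC (score
  5.0) with its A at −25; for sensitive acceptors an AG′ at an offset
  drawn from weights concentrated on −24..−12 with multiples of 3
  enriched threefold, a +1 base that is G with probability 0.20 (0.50 at
  the AG), and a perfect BP′ heptamer TACTAAC 11–14 nt upstream of the
  AG′ — strictly stronger than the canonical BP, as the swap experiment
  implies. Draws whose geometry would overwrite a planted branch
  adenosine or AG dinucleotide (e.g. an AG′ at −24 putting its G on the
  BP A) are resampled with a bounded retry, so the realised offset
  distribution is the configured weights conditioned on feasibility;
  overlapping heptamers are otherwise allowed — the planted BP′ may
  legitimately sit inside, or coincide with, the canonical BP region,
  which is exactly the superimposition the real data show.
* **Counts.** Every (acceptor, sample) draw is keyed on
  (seed, acceptor, sample), so enlarging the cohort never perturbs
  existing draws and equal seeds give byte-identical outputs. The AG′
  read share is Binomial with probability
  `baseline + ψ · mutant_fraction`; conservation (AG + AG′ = the
  undivided draw) holds by construction and is asserted in tests.
* **What it does not emulate.** No read-level noise or mapping artefacts,
  no splice-graph complexity beyond two-acceptor events, no NMD-driven
  expression feedback, no inter-junction count correlation. Passing
  recovery tests on this cohort therefore demonstrates the correctness
  of the pipeline's logic under its stated model, not its robustness to
  alignment artefacts or annotation errors in real data.

# Problem sizes and numerical choices

The shipped tests and the acceptance script use desk-scale designs
chosen to estimate each property with comfortable margins: 2,000
junctions for the null calibration (type-I error to ±0.5%), the
200-acceptor default cohort for recovery, and 2,000 planted AG′ sites
for the +1 composition (binomial s.e. ≈0.9%). Probability matrices use no
pseudocount (frequencies are plotted as probabilities; a Laplace option
exists for logo rendering of small sets). Chi-square contrasts are
Pearson tests without continuity correction, with a warning attached
when more than 20% of expected cells fall below 5. The acceptor-context
window is 50 intronic + 50 exonic nt: the two published descriptions
(fifty-nucleotide and one-hundred-nucleotide windows) are consistent
only under this reading.

# Known limitations

* The NB test has no covariates beyond the two-group contrast and no
  independent-filtering optimisation.
* Multi-acceptor (>2) architectures are represented only through
  best-candidate selection; exon skipping and intron retention are out
  of scope.
* The choice model is a static competition; it does not model kinetics,
  thermodynamic free energies, or NMD consequences of frameshifted AG′
  products.
* Chromosome-name mismatches between inputs (e.g. `chr1` vs `1`) are an
  error by design, never silently harmonised.
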