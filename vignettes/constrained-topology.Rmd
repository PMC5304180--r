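---
title: "Constrained membrane-topology prediction from surface-labeled lysines"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Constrained membrane-topology prediction from surface-labeled lysines}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(topolabel)
```

## The experiment this package models

Sulfo-NHS-SS-biotin is a membrane-impermeable reagent that acylates primary
amines — lysine side chains and free N-termini — on the surface of intact
cells. Its disulfide linker is cleavable, so after enrichment on neutravidin
and reduction (or alkylative processing), labeled peptides carry one of a
small set of residual lysine modifications with characteristic monoisotopic
mass shifts. A confidently identified modified peptide therefore localizes
one lysine to the extracellular side of the membrane, and a collection of
such positions constitutes residue-level topology evidence that a predictor
can treat as constraints.

The package covers the computational half of this design: modification-mass
bookkeeping, in-silico digestion, peptide-to-position mapping with replicate
filtering, constrained HMM decoding with a reliability score, a
constraint-corruption benchmark simulation, sequence-context analyses, and a
synthetic-data generator that makes all of it testable without external data.

## The topology model

### States and durations

Topology is a per-residue labelling over inside loop (I), membrane helix
(M) and outside loop (O), with segments alternating I, M, O, M, I, ... The
model is a hidden Markov model over four macro states: the two loops and the
membrane helix split by traversal direction, M~io~ (entered from I, exiting
to O) and M~oi~. Splitting M by direction makes the I/O alternation a
structural property of the state graph rather than something to check after
decoding: every path through the graph corresponds to a valid topology.

Helix durations are bounded to 15–25 residues (configurable), realized by
chaining one sub-state per helix position: the first `min_len` sub-states
advance deterministically, sub-states `min_len..max_len - 1` either continue
(probability `helix_cont`) or exit to the opposite loop, and the last
sub-state must exit. Loops are geometric with self-continuation probability
`loop_cont` per side. Decoding additionally requires paths to *end* in a
loop state; otherwise a path could stop mid-helix and emit an M segment with
no flank, violating the alternation invariant.

The 15–25 band covers the canonical length range of membrane-spanning
α-helices; signal peptides and re-entrant loops are deliberately not
modelled.

### Training

`train_topology_hmm()` is supervised maximum likelihood on annotated
proteins. Emissions are additively smoothed residue frequencies per macro
state (`pseudocount`, default 1, also applied to the N-terminal start
distribution); a label absent from training falls back to the uniform row.
Loop continuation is the stay/(stay + exit) ratio of loop segment lengths,
clipped into [1e-4, 1 − 1e-4] and defaulting to 0.98 when a side never exits
in training (an all-loop training set says nothing about entry rates).
Helix continuation is estimated from helix lengths relative to the duration
bounds. `X` is a uniform-emission wildcard at prediction time and is
excluded from training counts; any other letter is rejected at parse time.

### Constraints, decoding, conflicts

A constraint pins one residue to I or O — never M, because the labeling
chemistry only reaches loop residues. Constraints are **hard**: at a
constrained position every state whose macro label differs is masked to
probability zero in the emission matrix. The simulation treats a labeled
lysine as ground truth, and averaging soft evidence would hide
contradictions rather than expose them. If the constraint set admits no
positive-probability path (e.g. I and O constraints closer together than a
minimum-length helix), the `conflict` flag is set and the unconstrained
prediction is returned, so the caller always gets a usable topology plus an
explicit signal that the evidence is inconsistent with the model.

All dynamic programming is in log space over a sparse edge list (each
sub-state has at most two successors), implemented in C++ for the benchmark
simulation's throughput. Viterbi ties are broken toward the lexicographically
smaller state index, and the graph is traversed in a fixed order, so decoding
is deterministic. Posteriors come from forward–backward under the same
masking and are renormalized per column to absorb rounding; an exhaustive
path-enumeration oracle in the test suite checks the constrained Viterbi
log-probability exactly on all short sequences over a reduced alphabet.

### Reliability and correctness

The per-prediction *reliability* is the mean over residues of the posterior
probability of the predicted macro label. The engines this stands in for do
not publish their confidence formula; the mean predicted-label posterior is
the simplest score that (a) lies in [0, 1], (b) cannot decrease when the
prediction is re-scored under constraints that agree with it, and (c)
empirically orders correct predictions above incorrect ones on synthetic
data — which is all the reliability–coverage analysis requires. Its
monotone relation to accuracy is only verified on synthetic data.

A predicted topology counts as *correct* against a reference iff the helix
counts match, the i-th predicted helix overlaps the i-th reference helix by
at least `min_overlap` residues, and the N-terminal side agrees. No
published overlap threshold exists for this comparison, so `min_overlap` is
an exposed parameter; the default of 5 residues tolerates boundary
fuzziness of a few residues in 15–25-residue helices while rejecting
register shifts that would pair the wrong helices. *Accuracy* of a set is
the percent of its proteins predicted correctly.

## Peptide mapping

Peptides are located by exact substring search against every database
protein; only when a peptide matches nowhere does an ungapped sliding window
accept the best location with ≥ 95 % identity (the conventional identity
filter; the alignment method behind the published filter is not specified,
so the simplest ungapped realization is used and the threshold is a
parameter). A peptide matching several proteins — homologous TMPs can
produce identical peptides — is propagated to *all* of them, with an
`ambiguous` flag so downstream analyses can exclude multi-mapped positions.
Observations at the same (protein, position) merge into one `MappedPosition`
accumulating the observation count and the replicate and cell-line sets.

The replicate filter keeps positions identified in at least three distinct
*biological replicates* (`min_replicates = 3`); cell lines do not collapse
replicates. Merging positions across cell lines before counting is the
default. Positions are 1-based throughout, matching UniProt residue
numbering. A protein is classified TMP iff its unconstrained prediction
contains at least one M segment.

## Mass and digestion bookkeeping

Monoisotopic masses are computed from elemental compositions with IUPAC
monoisotopic atomic masses hard-coded to ≥ 6 decimals, so rounded values are
bit-stable across platforms. The shipped modification table reproduces the
conventional mass shifts at 3 decimals (thioacyl 87.998, thioacyl-biotin
389.090, carbamidomethylthio-propanoyl 145.020, Thio(AE) 131.040,
aminoethyl 43.04, N-ethylmaleimide 125.048 Da). One discrepancy is kept
visible: Thio(NEM)'s composition C9H11NO3S sums to 213.046 Da while the
value usually quoted is 213.045; the table stores the computed value and
records the rounding in its note column rather than silently overriding
either.

Digestion follows the standard rules — trypsin C-terminal to K/R,
chymotrypsin C-terminal to F/W/Y/L, both with the no-cleavage-before-proline
exception of the common search engines; thermolysin N-terminal to
A/F/I/L/M/V (its exact specificity varies between preparations, so the
residue set is a parameter) — with 0..`max_missed` missed cleavages and an
optional semi-specific mode that enumerates peptides with one ragged end.

## The benchmark simulation

`run_simulation()` reproduces a constraint-corruption experiment: for each
coverage fraction *p* (default 0, 0.25, 0.5, 0.75, 1 — the zero anchor gives
the unconstrained baseline) and corruption fraction *f* (default 0, 0.04,
0.08, 0.12, 0.16), and each of `n_randomizations` (default 50)
randomizations, a fraction *p* of each protein's extracellular lysines is
sampled uniformly without replacement (sample sizes round half-up),
`round(f · n)` of the sampled constraints are *replaced* by intracellular
lysines still labelled O — replacement rather than addition keeps the
constraint count invariant in *f* — and the constrained predictions are
scored. Corruption is applied per protein; a pooled interpretation (corrupt
the concatenated lysine set) would let large proteins absorb most false
positives, and the per-protein reading matches replacing a fraction of the
selected lysines of each benchmark entry. Accuracy mean ± sd is reported per
(p, f) cell.

Reliability–coverage curves sort predictions by decreasing reliability (ties
by protein id) and report the accuracy among the top k for every coverage
level 100·k/N; the value at 100 % coverage equals the overall accuracy by
construction. Because it is ambiguous whether such curves are best shown for
one randomization or averaged, both are reported (`accuracy_last`,
`accuracy_mean`).

RNG sub-streams are derived from (seed, p-index, f-index, randomization,
protein-index) with a stepwise modular mix kept below 2^31, so results are
bit-reproducible and independent of evaluation order. Unconstrained
predictions are deterministic and computed once, which also makes every
p = 0 cell exactly constant (sd = 0).

## The synthetic generator

`generate_proteins()` draws a TM-helix count (default mixture: 10 % soluble
controls, 25 % single-pass, the rest 2–7 helices, weighted toward small
counts — the shape of a human TMP benchmark), alternates loops and helices,
and fills residues from per-label frequency tables: helices strongly
hydrophobic (L/I/V/F/A-rich), inside loops K/R-enriched (the positive-inside
rule), outside loops polar with a moderate lysine frequency. The inside/
outside contrast is deliberately moderate: orientation is then genuinely
uncertain for some proteins, which gives constraints something to fix — a
benchmark the unconstrained model already solves perfectly could not show
the coverage effect. Loop lengths are 5 + geometric (mean 30); helix lengths
uniform on [15, 25].

`simulate_labeling()` emulates the replicated experiment: per biological
replicate (default 4), each extracellular lysine is detected with
probability `detection_prob` and each intracellular lysine with `fp_rate`;
labeled proteins are digested (trypsin, ≤ 2 missed cleavages) and every
fully-specific peptide containing a labeled lysine within the observable
window of 6–40 residues yields one observation. The window stands in for
MS detectability — too-short peptides are ambiguous and unretained,
too-long ones fragment poorly; no published bounds exist, so round numbers
are used and exposed. The default `detection_prob = 0.42` is calibrated so
that, over 4 replicates with the ≥ 3-replicate filter, roughly 20 % of all
extracellular lysines are recovered — the pooled coverage a real labeling
experiment of this kind attains; this calibration is documented, not
asserted by tests. `fp_rate = 0.013` mirrors a 98.7 % position-level
labeling accuracy and is off by default.

What the generator does **not** emulate: homologous protein families (so
real multi-mapping ambiguity is underrepresented), glycosylation and other
PTMs that suppress identifications, abundance-dependent detection, signal
peptides, re-entrant loops, and search-engine score distributions. Passing
tests on synthetic data therefore demonstrate the pipeline's internal
correctness and the qualitative constraint/corruption behavior, not
field performance on real proteomes.

## The context analyses

Sequence logos use the surrounding ± 10 residues of each labeled lysine
(window 21, pads excluded from counts). Column heights follow the standard
information-content convention, log2(20) − H with H the plain-frequency
Shannon entropy; small-sample corrections are off by default because the
logos are compared between large position sets, not read as absolute bit
values.

The segment-length null asks whether labeling probability depends on
extracellular segment length: the observed statistic is the two-sample
Kolmogorov–Smirnov distance between the lengths of segments containing a
labeled lysine and the pooled lengths from resamples in which the same
number of lysines is drawn uniformly from all extracellular lysines; the
p-value is the fraction of resamples whose own KS distance from the pool is
at least the observed one. KS was chosen because the claim being tested is
"the distributions do not differ", with no named test to match; the
resampling calibration (rejection rate ≈ 5 % at α = 0.05 under uniform
labeling) is verified in the test suite. Each resample is included in the
pool it is compared against, which biases the test very slightly
conservative at O(1/R); with the default 199 resamples this is negligible
against the ± 3-point calibration band.

## Problem sizes used by the tests

The exhaustive decoding oracle covers all 510 sequences of length ≤ 8 over
a two-letter alphabet with a 2–3-residue-helix toy model. The benchmark
simulation runs 50 proteins × 50 randomizations over the full 5 × 5
(p, f) grid (~60 000 decodings). The end-to-end recovery checks use 12–15
proteins over 4 replicates, 20 seeded repetitions for the contaminated
setting. The null-test calibration uses 200 simulated datasets of 40
uniformly drawn labeled lysines over a 30-protein reference set with 199
resamples each. These sizes are the package's chosen trade-off between the
stability of stochastic assertions and a test suite that runs in minutes.

## Known limitations

* The HMM is a single bespoke model, not a consensus of established
  predictors; absolute accuracies on real proteomes are not comparable to
  published consensus figures, and no attempt is made to reproduce them.
* The reliability score is a stand-in with the right ordering properties,
  not a calibrated probability of correctness.
* The 95 %-identity fallback is ungapped; peptides spanning indels relative
  to the database will not map.
* Hard constraints make single wrong positions consequential by design;
  users with noisy evidence should corrupt-test their own settings with
  `run_simulation()` before trusting constrained predictions.
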