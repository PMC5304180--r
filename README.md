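# topolabel

Membrane-protein topology prediction constrained by surface-labeled lysines.

## The problem

The topology of a transmembrane protein (TMP) — which residues sit in the
cytosol (I), in the membrane (M), or outside the cell (O) — is usually
predicted from sequence alone, and predictions are wrong for a substantial
fraction of proteins. Cell-surface biotinylation with a membrane-impermeable,
cleavable reagent (sulfo-NHS-SS-biotin) covalently tags extracellular lysines;
after enrichment and LC/MS/MS, each confidently identified modified peptide
pins one lysine to the extracellular side. Such residue-level evidence can be
fed back into a topology predictor as a hard constraint.

`topolabel` implements that computational pipeline end to end for analysts
working with surface-labeling proteomics data:

* **Mass/digestion bookkeeping** — monoisotopic masses of the residual label
  chemistry from elemental compositions (thioacyl +87.998 Da, thioacyl-biotin
  +389.090 Da, carbamidomethylthio-propanoyl +145.020 Da, Thio(AE)
  +131.040 Da, ...), and in-silico trypsin/chymotrypsin/thermolysin digestion
  with missed cleavages and semi-specific peptides.
* **Peptide mapping** — modified peptides are located in a protein database
  (exact substring first, 95 %-identity ungapped window as fallback), merged
  into unique (protein, position) sites with biological-replicate provenance,
  and filtered to positions seen in ≥ 3 independent replicates.
* **Constrained prediction** — a duration-constrained HMM over macro states
  {I, O, M<sub>io</sub>, M<sub>oi</sub>} with helix durations of 15–25
  residues enforced by chained sub-states. A labeled lysine masks, at its
  position, every state whose macro label is not O; decoding is Viterbi, the
  per-residue confidence is the forward–backward posterior of the predicted
  label, and the prediction's *reliability* is the mean of that posterior.
* **Benchmark simulation** — sample a fraction *p* of the extracellular
  lysines as constraints, corrupt a fraction *f* of them into intracellular
  false positives, and measure accuracy (percent of proteins whose predicted
  topology is correct: same helix count, ≥ 5 residues of overlap per helix,
  matching N-terminal side) and reliability–coverage curves over repeated
  randomizations.
* **Context analysis** — entropy/information logos of the ±10 residues around
  labeled lysines, and a resampling test of whether labeling depends on
  extracellular segment length.
* **Synthetic data** — a generator of proteins with known topologies and
  replicated labeling experiments, so every stage is testable without
  external data.

## Worked example

```r
library(topolabel)

# synthetic benchmark: 40 training + 30 evaluation proteins
gen   <- generate_proteins(synthetic_config(n_proteins = 40, seed = 2024))
model <- train_topology_hmm(gen$proteins, gen$annotations)
evl   <- generate_proteins(synthetic_config(n_proteins = 30, seed = 515))

# simulated labeling experiment -> mapped, filtered constraints
cfg <- synthetic_config(n_proteins = 30, detection_prob = 0.85, seed = 515)
lab <- simulate_labeling(evl$proteins, evl$annotations, cfg)
pos <- filter_by_replicates(map_peptides(lab$observations, evl$proteins), 3)
cons <- positions_to_constraints(pos)

# constrained vs unconstrained prediction of one multi-spanning protein
p0 <- predict_topology(model, evl$proteins[3, ])
p1 <- predict_topology(model, evl$proteins[3, ], cons)
p0
#> topology prediction for SYN0003 | 5 TM helices | reliability 0.879
p1
#> topology prediction for SYN0003 | 5 TM helices | reliability 0.9452 | constrained
```

The reliability printed on the last lines is the mean posterior probability
of the predicted label: conditioning on constraints consistent with the
evidence raises it. Benchmark accuracy under increasing coverage and
corruption comes from `run_simulation()`:

```r
bench <- benchmark_entries(evl$proteins, evl$annotations)
res <- run_simulation(bench, model,
                      simulation_config(fractions = c(0, 0.5, 1),
                                        corruption_fractions = c(0, 0.08),
                                        n_randomizations = 5, seed = 3))
res$summary
#>     p    f accuracy_mean accuracy_sd
#> 1 0.0 0.00      76.66667    0.000000
#> 2 0.0 0.08      76.66667    0.000000
#> 3 0.5 0.00      92.66667    1.490712
#> 4 0.5 0.08      92.00000    1.825742
#> 5 1.0 0.00      93.33333    0.000000
#> 6 1.0 0.08      76.66667    0.000000
```

Accuracy rises with constraint coverage (77 % → 93 % at full coverage, f = 0)
and falls sharply when constraints are contaminated with intracellular false
positives — at full coverage, 8 % corruption gives back the whole gain.

A shell entry point with the same pipeline as subcommands
(`synth`, `map`, `filter`, `train`, `predict`, `validate`, `simulate`,
`context`) is installed at
`system.file("cli", "topolabel.R", package = "topolabel")`.

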