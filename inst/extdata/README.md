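# Packaged example data

* `published_outcome_tables.tsv` — published per-strain outcome-frequency
  rows (percent, SEM, bound flags) for three wild-type strains: a hybrid and
  a purebred diploid with a break in unique DNA, and a hybrid diploid with a
  break inside the Ty cluster.  Used as inputs to the derived-summary
  operations (`bdr_total`, `categorize_copy_number`) and as generating truth
  for recovery experiments.
* `worked_example_clone_counts.tsv`, `worked_example_plugs.tsv` — a
  SYNTHETIC RECONSTRUCTION of the purebred wild-type clone assay: clone and
  plug counts inferred from the published percentages (1062 cut clones,
  85.7% class I; 5 of 32 class-I plugs are internal deletions, 11 of 46
  class-II plugs are isochromosomes, ...).  The raw per-culture counts were
  not published; these are the unique integer counts consistent with the
  printed one-decimal percentages and plug totals.  Feeding them through the
  estimator reproduces the published 13.4 ± 5.5 internal-deletion cell.
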