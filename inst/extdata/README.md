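# Packaged data

* `mipner_genus_means.tsv` — published genus-level mean relative abundances
  (percent) per experimental condition for the ten most abundant partner-side
  genera of the original soil bait-capture experiment, bait genus masked.
  Used for the desk-scale enrichment checks and by `scripts/acceptance.R`.
  "Not present" in the Binder control is encoded as 0.

* `supplementary/` (not shipped) — drop-in location for the original
  experiment's per-sample count tables if you have them:
  `genus_counts.tsv` and `species_counts.tsv` in the combined count-table
  layout (`name  taxid  rank  domain  <sample...>`) plus `metadata.tsv`
  (`sample_id  condition  replicate`). With these present, the acceptance
  tests recompute the published tier counts and diversity statistics.
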