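# External data drop-in

The published character-taxon matrices exercised by the acceptance tests
are journal supplementary datasets and are not redistributable with this
package. To run the full published search protocol, place them here as:

- `analysis1_matrix.tnt` — 72 taxa × 785 characters (snake-wide analysis;
  expected optimum: length 1610, CI ≈ 0.386, RI ≈ 0.73)
- `analysis2_matrix.tnt` — 22 taxa × 656 characters (madtsoiid ingroup
  analysis; expected optimum: length 191, CI ≈ 0.634, RI ≈ 0.62)

Both files are TNT `xread` format as distributed. With the files in
place, `tests/testthat/test-acceptance.R` and `analysis/04_parsimony.R`
pick them up automatically.

No other fixtures live here: every other input is generated in code by
the `sim_*` functions (synthetic, with known ground truth).
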