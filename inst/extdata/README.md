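# Example data

Every file in this directory is **synthetic**: generated by
`andeandyn::make_fixture_set()` (seed 1) from the package's own scenario
presets, plus a made-up warfare period table
(`synthetic_warfare_periods.csv`) whose period boundaries and codes are
illustrative only.  No file here reproduces any real archaeological,
paleoclimatic or radiocarbon record.

- `fixture_<variant>.csv` — observed `N`, `W`, `C` series from a coupled
  scenario whose generating process features that model variant.
- `fixture_sdata_synthetic.csv` — a 36-row table in the nine-column
  exchange layout (`calBP`, `yearAD`, `SPDn`, `SPDnn`, `Rn`, `Rnn`,
  `LithPct`, `War`, `Rwar`).
- `fixtures.yml` — seed and scenario metadata for the files above.
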