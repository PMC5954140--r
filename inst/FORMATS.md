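# File formats

All artifacts are plain text. Time is in seconds, lengths in micrometres
(um), brightness and background in counts/s. Correlation values follow the
"+1" convention: an uncorrelated signal gives G = 1, and amplitudes are
G(0) - 1.

## Trace (`*.csv` + `*.csv.meta.yaml`)

CSV with header `bin_index,counts_green,counts_red` (tab-separated also
accepted on input). `bin_index` starts at 0; counts are non-negative
integers and both channels have equal length. A YAML sidecar named
`<trace>.meta.yaml` records `bin_time`, the RNG `seed`, the `optics`
block, the species ground truth and the realised particle counts. Traces
without a sidecar can be read by passing `bin_time` explicitly.

## Correlation curve (`*.csv`)

Comment header lines (`# kind: gg|rr|gr`, `# bin_time:`, `# estimator:`,
`# n_segments:`) followed by CSV `lag_s,value,stderr`. Lags are strictly
increasing, in seconds; `stderr` is `NA` when no error estimate exists.
Numbers are written with `%.17g`, so a write/read round trip is exact.

## Fit result (`*.json`)

JSON object with `estimates`, `stderr`, `fixed`, `free`, `components`,
`triplet`, `kind`, `reduced_chi_square`, `converged`, `info`, `message`,
`weighted`, `drop_first`, and the fitted `lags`, `values`, `residuals`.
Parameter names: `N`, `tau1..tau3` (s), `F1..F2`, `s`, `T`, `tauT` (s).

## Pipeline config (`*.yaml`)

Top-level keys: `seed`, `output`, `simulation` (`duration`, `bin_time`,
`time_step`, `box`), `optics` (`w0`, `z0`, crosstalk and background
rates), `correlate` (`estimator`, `n_segments`, `points_per_stage`),
`fit` (`components`, `s`, `triplet`), `rca` (`normalization`),
`conditions` (list of `name`, `n_cells`, `species`), `compare` (list of
condition-name pairs). Species entries use the `fccs_species()` fields.

## Pipeline outputs

`run_pipeline()` writes per-cell traces, curves and fits using the above
formats, `rca_table.csv` (`cell_id,condition,rca,nc_over_ng,
normalization`), one `compare_<a>_vs_<b>.json` per comparison (t, df,
p-value, stars), a `manifest.json` with per-stage status, outputs and MD5
checksums, and `pipeline.log`.
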