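# ecgkit

ECG denoising, heartbeat segmentation and 1-D CNN beat classification in R.

`ecgkit` implements a complete electrocardiogram analysis workflow:

1. **Signal I/O** — WFDB-style records (text header + format-212 packed
   12-bit binary signal), annotation CSVs, and plain CSV signals.
2. **Synthetic annotated ECG** — a generator that builds each beat from
   five Gaussian bumps (P, Q, R, S, T waves), jitters RR intervals, labels
   every beat (`N`/`V`), and injects additive noise at an *exactly*
   realized SNR. Everything in this README and the test suite runs on
   generated data, so the clean ground truth is always known.
3. **Six denoising filters** — median, Gaussian, moving-average,
   Savitzky–Golay (window 25, order 7), 4th-order 40 Hz Butterworth
   low-pass, and 4-level sym8 wavelet shrinkage with BayesShrink soft
   thresholds — plus a benchmark that ranks them by PSNR against the
   clean reference.
4. **Segmentation & normalization** — 2160-sample windows (6 s at 360 Hz)
   centered on each annotated beat, z-scored per window, stratified
   train/test split.
5. **Three 1-D CNN classifiers** — stacks of valid convolutions, ReLU,
   dropout and floor-halving max pooling ending in a single sigmoid unit,
   with **1,956,651**, **5,274,443** and **462,167** trainable parameters
   respectively. Counts are computed analytically and the embedded C++
   training engine (im2col + GEMM, Adam, binary cross-entropy) must
   allocate exactly that many parameters or training aborts.
6. **Metrics** — confusion counts, accuracy, sensitivity, specificity,
   precision, recall, F1, BCE loss, and a tie-aware trapezoidal ROC/AUC
   that provably equals pairwise concordance.
7. **Pipeline & CLI** — `run_pipeline()` chains every stage and writes a
   manifest with all seeds; two runs with the same config produce
   byte-identical artifacts. `inst/cli/ecgkit.R` exposes each stage as a
   subcommand with distinct per-stage exit codes.

## Worked example

Generate a 30-second annotated recording (30% abnormal beats), then noise
it at exactly 10 dB:

```r
library(ecgkit)

rec <- generate_clean_ecg(sim_config(duration = 30, fraction_abnormal = 0.3, seed = 1))
rec$annotations
#> # A tibble: 36 × 2
#>   sample_index symbol
#>          <int> <chr>
#> 1          150 N
#> 2          441 N
#> 3          743 N
#> 4         1031 N
#> # ℹ 32 more rows

clean <- record_channel(rec)
noisy <- add_noise(clean, noise_spec(snr_db = 10, seed = 2), 360)
10 * log10(mean(clean^2) / mean((noisy - clean)^2))
#> [1] 10
```

Benchmark all six filters on five independent records at 10 dB — the
`none` row is the unfiltered noisy baseline, and the table is sorted
ascending so the winner is last:

```r
records <- lapply(1:5, function(s) generate_clean_ecg(sim_config(duration = 10, seed = s)))
run_benchmark(records, noise_spec(snr_db = 10, seed = 100))
#> # A tibble: 7 × 5
#>   filter         mean_psnr_db sd_psnr_db n_records n_failed
#>   <chr>                 <dbl>      <dbl>     <int>    <int>
#> 1 none                   25.7     0.0345         5        0
#> 2 median                 30.8     0.0964         5        0
#> 3 moving_average         32.7     0.150          5        0
#> 4 butterworth            33.0     0.180          5        0
#> 5 savgol                 33.1     0.191          5        0
#> 6 gaussian               33.4     0.174          5        0
#> 7 wavelet                34.1     0.233          5        0
```

Every filter clears the baseline by 5–8 dB; under white Gaussian noise the
wavelet shrinkage leads. (The median filter's home turf is impulse
artifact, which this noise model does not contain — the benchmark is
parameterized by `noise_spec` for exactly that reason.)

Run the full pipeline — simulate, noise at 15 dB, median-filter, segment,
80/20 stratified split, train the 462k-parameter network for six epochs,
evaluate on held-out beats:

```r
cfg <- pipeline_config(seed = 1,
                       sim = sim_config(duration = 120, fraction_abnormal = 0.3, seed = 1),
                       noise = noise_spec(15, seed = 2))
res <- run_pipeline(cfg, out_dir = "artifacts")
res$fit$history
#>  epoch         loss  accuracy
#>      1 6.529544e-01 0.6788991
#>      2 3.660010e-01 0.8348624
#>      3 1.129868e-01 0.9633028
#>      4 6.437104e-03 1.0000000
#>      5 3.988624e-03 1.0000000
#>      6 1.454572e-07 1.0000000

res$report$metrics
#>  accuracy sensitivity specificity precision recall f1        loss auc
#>         1           1           1         1      1  1 0.001975442   1
```

On this separable synthetic task (109 training, 27 test beats) the network
converges within four epochs and classifies the held-out beats perfectly.
Everything above is seed-deterministic: rerunning any snippet reproduces
these numbers bit-for-bit, and `artifacts/manifest.json` records every
seed needed to do so.

## Command line

```sh
Rscript inst/cli/ecgkit.R simulate --seed 3 --duration 30 --snr-db 15 --out rec
Rscript inst/cli/ecgkit.R denoise  --record rec/sim3.hea --filter wavelet --out dn
Rscript inst/cli/ecgkit.R benchmark-filters --seed 2 --n-records 20 --out bench.csv
Rscript inst/cli/ecgkit.R run --seed 5 --duration 300 --out artifacts
```

Flags may also come from a JSON config file (`--config run.json`;
command-line flags win). Exit codes are 0 on success and a distinct
non-zero code per failing stage.

## Design notes

See the vignette (`vignettes/ecg-denoising-and-beat-classification.Rmd`)
for the science and the design decisions: why the wavelet transform is
periodized and orthonormal, how the Savitzky–Golay kernel is derived from
the least-squares projection, why parameter counts are verified
analytically against the engine, and what the synthetic generator does and
does not model.
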