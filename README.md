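# mcevent

Unsupervised characterization and detection of events in multichannel
signals — built for EEG artifact analysis (eye blinks, jaw clenches,
movements), but applicable to any set of cross-correlated channels whose
events change the local signal dynamics. No training data, no manual
thresholds: the method finds the events, their onsets, durations and
per-type frequencies, and the number of distinct signal regimes present in
any stretch (the number of independent components a downstream ICA would
need).

## Method

A window of `Lw` samples slides along the recording by `d` samples. Each
window of each of the Q channels is summarized by the two coefficients of
an AR(2) model `x_t = a1 x_(t-1) + a2 x_(t-2) + e_t` (Burg estimates;
scale- and location-invariant), concatenated into one feature row of
`S = 2Q` values per window. The rows are clustered by average-linkage
hierarchical clustering on Euclidean distances.

Two quality measures drive a joint optimization:

* the **cophenetic correlation coefficient** (CCC) — the correlation
  between original pairwise distances and dendrogram merge heights —
  gates the *minimum* window size (threshold `U = 0.85`);
* the **S_Dbw validity index** (intra-cluster scattering + inter-cluster
  density, lower is better), minimized over group counts `g = 2..NG+1`
  and then over window sizes `Lw0 + m*DL`, selects the optimal window
  `LwH` and group count `NoH`.

Maximal runs of consecutive same-group intervals `[Wi..Wj]` are localized
on the signal as `[(i-1)d + M*Lw - d/2, (j-1)d + M*Lw + d/2]` with
`M = 6/7`, so every interval contributes exactly `d` samples, adjacent runs
abut, and an event's duration is exactly `(j-i+1)*d/fs` seconds. The most
populous group is the event-free baseline; the rest are events. An
incremental mode classifies new interval batches against a reference
clustering and flags previously unseen event types.

## Worked example

Generate a 60 s, 4-channel recording at 256 Hz with three planted AR(2)
event regimes in an AR(2) background, then detect them:

```r
library(mcevent)
base   <- regimeSpec("background", c(0.5, -0.2))
events <- list(regimeSpec("A", c(-1.2, -0.6), duration = 1280),
               regimeSpec("B", c( 1.6, -0.8), duration = 1280),
               regimeSpec("C", c( 0.0,  0.8), duration = 1280))
g <- generateSignal(base, events, Q = 4, T = 60 * 256, fs = 256, seed = 11)
g$truth@events
#>   label start   end
#> 1     B  2876  4156
#> 2     C  6907  8187
#> 3     A 11097 12377

cfg <- searchConfig(d = 32, candidateSizes = c(64, 96, 128),
                    DL = 8, NL = 6, NG = 9, ipt = 512, maxExtend = 1)
res <- detectEvents(g$signal, cfg)
res$scan
#> ScanResult over 7 window size(s):
#>   Lw       CCC No         MIn
#>   64 0.9576614 14 0.012511807
#>   72 0.9560935 19 0.020886435
#>   80 0.9569114  9 0.027904517
#>   88 0.9604558 19 0.018409196
#>   96 0.9608441 19 0.012068403
#>  104 0.9546840 17 0.008642731
#>  112 0.9552700 19 0.010863340
#> optimum: Lw = 104 samples, No = 17 groups, MIn = 0.008643, CCC = 0.9547

ev <- eventTable(res$events)
ev[ev$dE > 1, c("label", "i", "j", "tE", "dE")]
#>    label   i   j       tE    dE
#> 4      5  91 128 11.53571 4.750
#> 9      8 216 254 27.16071 4.875
#> 15    14 348 384 43.66071 4.625
```

Reading the output: every candidate window clears the CCC gate (all
≥ 0.95), and each planted 5 s event is recovered as a long run of
same-group intervals at the planted position (onsets 11.5 s, 27.2 s,
43.7 s; durations 4.6–4.9 s). The group *count* is over-split (No = 17):
on cleanly separated synthetic regimes the S_Dbw curve decays past its
elbow, so single transition windows at event edges are reported as extra
one-interval groups — the scan warns about this and stores the per-`g`
curve in `res$scan@sdbwCurve` so the elbow (here at g = 4) can be read
directly. The methods vignette discusses this behavior and when it does
and does not occur.

A thin command-line front end covers the same pipeline:

```sh
Rscript inst/scripts/mcevent synth --seed 7 --out synth.csv --truth truth.csv
Rscript inst/scripts/mcevent run --input synth.csv --grid-start 64 \
    --grid-step 8 --grid-count 7 --ipt 512 --out events.csv --report report.json
Rscript inst/scripts/mcevent scan --input rec.edf --out table.csv
```

Input formats: EDF (header + int16 records) and CSV (samples as rows,
channel labels as header, `# fs=<Hz>` comment line). Output: events CSV
(label, sample span, onset, duration at full precision) plus a JSON run
report (`LwH`, `d`, `NoH`, `CCC`, `MIn`).

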