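# batchlens

Root-cause diagnosis of productivity differences in fed-batch cell culture
from inline sensor and offline assay data.

## The problem

Commercial fed-batch monoclonal-antibody cultures log two kinds of data:
high-frequency inline sensor series (pH, dissolved oxygen, temperature, gas
flows, broth volume — one sample every few seconds for ~12 days) and daily
offline assays (viable cell density, viability, cell diameter,
agglomeration, pH, glucose, lactate).  When some batches under-produce, the
engineering question is *which variables, in which part of the run,
distinguish the low-yield batches from the high-yield ones* — under two
obstacles: batches have unequal lengths, and nutrient feeds split every run
into distinct operating phases separated by short transitions.

`batchlens` answers this with a four-stage pipeline:

1. **Preprocessing** — impute missing runs by neighbouring means, repair
   out-of-range sensor spikes, discard batches with more than 30 % missing
   data, and filter uninformative variables by inner-/inter-batch variance.
2. **Phase division** — the moving-window kNN set distance
   `d(x_t) = (1/k) Σ_i d(x_t, x_{t,i})²` over the window `[t−L, t+L]`
   (defaults L = 1200 samples, k = 300 at 10-s sampling) spikes during feed
   transitions; thresholding it segments each batch into stable phases and
   discards transitions.
3. **Feature extraction and fusion** — each (variable, phase) trajectory is
   fitted by least squares with a shared basis (degree-3 B-splines on
   uniform knots for smooth curves, low-order polynomials for step/line/
   quadratic shapes; counts chosen by an MSE knee rule on a
   longest-and-roughest reference phase).  The coefficients form a
   fixed-width feature matrix regardless of batch length, to which the
   batch-wise unfolded offline table is appended.
4. **Cluster contrast (ccPCA)** — with the full feature matrix `E` and the
   low-productivity rows `R`, the first eigenvector `v*` of
   `C_E − α C_R` maximises overall variance while suppressing background
   variance; `|v*|` ranks every feature's contribution to what sets the
   high-productivity cluster apart.  A one-tailed Welch t-test compares the
   cluster productivities.

A synthetic fed-batch generator with known phase structure, known cluster
effects and injectable data defects (outage-style missing runs, sensor
spikes) makes the whole pipeline testable at desk scale.  See the methods
vignette (`vignettes/batch-root-cause-methods.Rmd`) for the model details
and design choices.

## Worked example

Simulate a 26-batch study (6 high-, 20 low-productivity) at 5-minute
resolution and run the full pipeline:

```r
library(batchlens)

cfg    <- syntheticConfig(nBatches = 26, sampleIntervalS = 300)
labels <- rep(c("high", "low"), c(6, 20))
params <- knnParams(L = 40, k = 10, minPhaseLength = 12)  # 200-min window at 5-min sampling

report <- runPipeline(cfg, labels, seed = 11, params = params)
report
```

```
RunReport
  batches analysed: 26 (discarded: 0)
  phases per batch: 5; delta=22.7
  features: 67 inline + 84 offline = 151
  productivity: target 1.054 vs background 0.959, one-tailed p=2.58e-10
  top contrast features:
          kind  variable phase coeff     family    loading contribution
1 inline_coeff    volume     5     1 polynomial  0.2925799    0.2925799
2      offline viability    10    10    offline  0.2783906    0.2783906
3      offline viability    12    12    offline  0.2422223    0.2422223
4      offline viability    11    11    offline  0.2324313    0.2324313
5      offline       VCD     4     4    offline -0.2252590    0.2252590
```

Reading the output: each batch segmented into the expected five stable
phases (four feeds); the extended feature matrix has 67 basis-coefficient
columns plus 7 × 12 unfolded offline values; the top-ranked contrast
features are exactly the two groups the generator shifts between clusters —
the volume level in phase 5 and viability on days 10–12 — and the high
cluster's productivity is significantly higher (p < 0.05).  On real data
this ranking is the candidate root-cause list handed to process experts.

Individual stages are available as plain functions
(`preprocessStudy()`, `distanceProfile()` / `segmentStudy()`,
`assignBasisSpec()` / `buildFeatureMatrix()` / `fuseOffline()`,
`ccpcaContributions()` / `selectAlpha()` / `compareProductivity()`), and a
thin command-line wrapper lives in `inst/scripts/batchlens.R`
(`Rscript batchlens.R simulate|run --out dir --seed N ...`).

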