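# SwallowQuant

Automatic detection and quantification of eating and drinking from two
wearable streams: a single-channel surface electromyogram (sEMG) recorded
over the sternocleidomastoid neck muscle and a wrist-mounted inertial unit
(WI) streaming X/Y/Z tilt angles, both at 1 kHz.  The package is aimed at
researchers in wearable biosignal processing and ingestive-behavior
monitoring who want a complete, testable re-implementation of this kind of
pipeline:

1. **Synchronization** — a deliberate interference gesture appears as a
   sudden broadband window in the sEMG and a simultaneous wrist-flick in the
   WI trace; a sliding-window high-frequency-energy-ratio change detector
   localizes it, the window is excised by interpolation, and the two streams
   are aligned by mapping the anchors onto each other.
2. **Demarcation and segmentation** — a decision tree calibrated on a free
   eat-and-drink pass labels wrist samples (drinking X ∈ [300, 350]°,
   Y ∈ [1, 60]°; eating X ∈ [200, 300]°, Y ∈ [90, 150]°); activity periods
   map onto the sEMG clock, and the rectified-smoothed envelope splits them
   into sip-swallow and bite-chew-swallow complexes, each classed as
   low or high muscle-activity magnitude (MAM).
3. **Features** — the forty time-frequency sEMG features (MAV, RMS, WL, ZC,
   SSC, WAMP, Willison amplitude, maximum fractal length, Yule-Walker AR
   coefficients, ...), each pinned to one canonical formula in a
   machine-readable registry and verified against brute-force references.
4. **Models** — solid-bolus material classification (KNN with K = 5, RBF-SVM
   with C = 1, entropy decision trees grown to pure leaves) and weight
   regression (extra trees, random forest, AdaBoost.R2, gradient boosting,
   XGBoost, SVR, Gaussian processes, feed-forward networks trained by
   Levenberg-Marquardt or Bayesian regularization) in both cascade
   orderings — classify-then-regress and regress-then-classify with volume
   groups < 4.5 g, [4.5, 7.5) g, ≥ 7.5 g; plus direct sip-volume regression
   and a raw-signal 1D CNN (5 conv blocks, kernel 5, channels
   32/32/32/64/64, batch norm + 1×2 max pooling, two dense layers, 4-way
   output) for sip volumes 10/20/30/40 ml.
5. **Evaluation** — fivefold among-subject (AS) and cross-subject (CS)
   validation with accuracy/sensitivity/specificity and RMSE/MAE/R².

Because no recordings ship with the package, a first-class synthetic cohort
generator reproduces the study protocol (55 subjects; per subject 40 water
sips over 4 volumes and 45 solid boluses over 3 materials × 3 weights) with
ground-truth labels, inter-subject gain/pace/spectral variability, talking
activity and the synchronization interference.  See the methods vignette
(`vignettes/swallowquant-methods.Rmd`) for the model details and design
rationale.

## Worked example

```r
library(SwallowQuant)

prof    <- sampleSubjectProfile("S01", seed = 11)
session <- generateSession(prof, IngestProtocol(), seed = 42)
session
#> SessionRecording S01: 600 s, 600000 sEMG samples @ 1000 Hz,
#>   600000 WI samples, 85 events (40 sips, 45 bites), interference injected

res <- segmentSession(session)     # sync + demarcate + split + MAM
res$alignment
#> StreamAlignment: offset -4.1450 s @ 1000 Hz   (true offset: -4.1350 s)

tab <- featurizeSegments(res$segments)
table(tab$label, tab$mam)
#>         high low
#>   A       15   0
#>   B       15   0
#>   C       15   0
#>   water    0  40
```

All 85 protocol events are recovered; the 10 ms alignment error is well
inside the 50 ms tolerance the pipeline is validated to, and every bite
lands in the high-MAM class and every sip in the low-MAM class.  From the
feature table, `runExperiment()` fits and cross-validates the bolus models;
`runSipCnnStudy()` trains the raw-signal CNN on synthetic sips.

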