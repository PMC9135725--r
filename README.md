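# sigwhistle

Identification of bottlenose dolphin **signature whistles** from recording
sessions, and analysis of the determinants of their acoustic variability.

Signature whistles are learned, individually distinctive
frequency-modulation contours that broadcast the identity of the emitter.
Because they are learned rather than genetically fixed, their structure
can differ between populations, reflecting geographic isolation, the
acoustic environment of the local sea bottom, and population demography.
`sigwhistle` implements the complete chain from (synthetic) recordings to
that inference, together with a fully seeded synthetic-repertoire
generator that provides exact ground truth for every stage.

## What the package computes

**Identification (SIGID bout criterion).** Whistle contours traced from
spectrograms are merged into single- or multi-loop units (inter-loop gaps
< 250 ms), grouped into contour types by shape matching, and classified:

* *REWT* (repeated element whistle type): the same contour occurs at
  least twice within 0.25–10 s in one recording session;
* *SW* (signature whistle): at least four stereotyped contours in a
  session, with ≥ 75 % of them within 1–10 s of at least one other —
  each SW receives an SW-ID shared by all matching contours study-wide;
* *OW*: variant whistles failing the repeated-element rule.

**Measurement.** The seven standard parameters per SW unit: minimum,
maximum, start and end frequency, frequency range, number of inflection
points, duration.

**Variability analysis.** Per-SW mean vectors → fourth-root transform →
Bray–Curtis dissimilarity → nMDS (Kruskal stress-1) and one-way ANOSIM

```
R = (r̄_between − r̄_within) / (M/2),   M = n(n−1)/2
```

per factor (region, site, sea bottom, demography); contour-level rows →
correlation-matrix PCA with Kaiser retention (eigenvalue ≥ 1) → Gaussian
mixed models `PC ~ factor + (1 | SW-ID)` fitted by REML, reporting the
usual table (Value, SE, containment DF, t, p; random-intercept and
residual SD). Sea-bottom (H1–H3) and demography (P1–P4) factors come from
Ward- and complete-linkage hierarchical clustering of the site metadata.

## A worked example

```r
library(sigwhistle)
cfg <- pipeline_config(sw_per_site = 2, sessions_per_site = 1, seed = 11)
report <- run_pipeline(cfg)
print(report)
```

```
Signature-whistle pipeline report
Per-site signature whistles:
 site n_sw_units n_sw_ids
   AL         10        2
   CL         10        2
   FI         10        2
   GC         10        2
   LA         13        2
   PC         10        2
nMDS stress: 0.097; PCA: 3 components (99% variance)
  ANOSIM site        R = -0.017  p = 0.538
  ANOSIM region      R = -0.103  p = 0.74
  ANOSIM sea_bottom  R = -0.134  p = 0.805
  ANOSIM demography  R = -0.003  p = 0.451
Manifest hash: 0fd7566441cbb06762672ecc89a80059
```

Two signature identities per site were simulated (plus repeated-element
and variant emitters); the classifier recovered exactly the 12 simulated
SW-IDs from their emissions. With zero configured site effects, all four
ANOSIM tests are correctly non-significant and R sits near zero. The
report also carries the full feature table, catalogue, model tables and a
reproducibility manifest; `write_report()` exports everything as
CSV/JSON. A thin command-line wrapper with `simulate / extract /
classify / features / stats / all` subcommands is installed at
`inst/scripts/whistle-pipeline.R`.

Audio in and out is supported end to end: `render_audio()` synthesizes
sessions at a stated in-band SNR, `spectrogram()` + `trace_contours()`
recover graded contours (grade-1 whistles are discarded), and
`write_wav()`/`read_wav()` handle PCM WAV files.

## The methods vignette

`vignettes/signature-whistle-analysis.Rmd` documents the classification
rules and their boundary conventions, the extraction and grading
thresholds, the statistical models and their assumptions, what the
synthetic generator does and does not emulate, and the package's
numerical choices and limitations.
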