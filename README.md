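# semgfusion

Feature-level fusion of multi-channel surface electromyography (sEMG) for
activity-of-daily-living (ADL) recognition.

Wearable sEMG reflects which muscles an activity recruits, but
concatenating per-channel feature vectors yields a high-dimensional,
redundant space whose quality varies with electrode placement. This
package builds a compact, discriminant fused space instead:

1. **Features** — per channel and whole trial: Wilson amplitude, fuzzy
   entropy, permutation entropy, AR(4) coefficients estimated from
   third-order cumulants, and 4-level wavelet-band energies (12 values per
   channel).
2. **Class-aware canonical fusion** — projection pairs maximise
   `u' S_bxy v / (u' S_Wx u · v' S_Wy v)`, the between-set covariance
   against the *within-class* scatters, so the projections are both
   correlated across channels and discriminant; more than two channels are
   fused by a block (sumcor) generalised eigenproblem.
3. **GA selection** — a binary genetic algorithm prunes fused components
   under a Fisher-criterion fitness `trace(S_W^-1 S_B)`, with crossover and
   mutation rates decayed by the cosine schedule
   `cos((gen/gen_max)·π/2)`.
4. **Dynamic channel weights** — each channel's block is scored by fuzzy
   c-means clustering accuracy `accu_i`; weights
   `W_i = accu_i − accu_min + W_min`, `r_i = W_i / ΣW_j` rescale the blocks
   so reliable electrode sites dominate.
5. **Evaluation** — Davies–Bouldin index over fuzzy c-means partitions
   (K = 2..10) and a one-vs-rest RBF-SVM (optionally PSO-tuned) under
   stratified six-fold cross-validation with sensitivity/specificity per
   class.

Because the motivating study's recordings were never deposited, the
package includes a seeded generator of band-limited (20–450 Hz),
activity-modulated, multi-channel sEMG-like trials (8 ADL classes,
1000 Hz, ~2 s) with class-dependent envelopes, cross-channel coupling and
heterogeneous channel quality, so the entire pipeline is reproducible
end-to-end. See the methods vignette
(`vignettes/semgfusion-methods.Rmd`) for the model, parameter meanings,
and what the synthetic data does and does not emulate.

## Worked example

```r
library(semgfusion)

scfg <- synth_config(n_trials_per_class = 12, n_channels = 4, seed = 42)
ds   <- generate_dataset(scfg)          # 96 labelled trials
fset <- extract_feature_set(ds)         # 4 channels x (96 x 12)

rep_wga  <- run_pipeline(fset, pipeline_config(method = "wga-gcca", seed = 1))
rep_none <- run_pipeline(fset, pipeline_config(method = "none",     seed = 1))
rep_wga
rep_none
```

```
<fusion_report> method=wga-gcca mode=type1
  mean CV accuracy: 0.9688
  DBI at K=8: 1.7725
  dimensions: raw 48 -> final 45
  channel weights: 0.320 0.196 0.149 0.335
<fusion_report> method=none mode=type1
  mean CV accuracy: 0.8646
  DBI at K=8: 1.5504
  dimensions: raw 48 -> final 48
```

Reading: on this dataset the weighted, GA-selected class-aware fusion
classifies held-out trials markedly better than plain concatenation
(0.97 vs 0.86), and the channel weights show how much each electrode
site contributes (channel 3 is the least reliable here). Across 20
seeded replicates the accuracy advantage holds in 16 of 19 non-tied
datasets (sign test p ≈ 0.002; asserted in the test suite).
`dimension_report(rep_wga)` breaks the dimensions down by stage, and
`report_json(rep_wga, "report.json")` serialises everything reproducibly
(same seed ⇒ byte-identical file).

A thin CLI over the same functions ships in `inst/exec/semgfusion`
(subcommands `simulate`, `extract`, `evaluate`, `monotonicity`).

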