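# neograde

Automated grading of background EEG abnormality in term neonates with
hypoxic-ischaemic encephalopathy (HIE).

Clinicians grade an hour of neonatal background EEG on a four-level scale
— 1 (normal/mild), 2 (moderate: discontinuous, interburst interval
IBI ≤ 10 s), 3 (major: IBI 10–60 s, attenuation < 30 µV), 4 (inactive:
< 10 µV) — a task requiring scarce neurophysiological expertise.
`neograde` automates it. The EEG is modelled multiplicatively,

    EEG(t) = a_m(t) · X(t),

with `X(t)` band-limited coloured noise (power-law amplitude response
`1/f^α`, α > 1) and `a_m(t)` a slowly varying non-negative
amplitude-modulation (AM) envelope. Both sub-signals are recovered from a
smoothed Wigner–Ville distribution ρ(t, f) of each 64 s analysis epoch:
the AM as `(∫ρ df)^½` and the instantaneous frequency (IF) as the first
frequency moment `∫f ρ df / ∫ρ df`. Sixteen per-epoch features (AM/IF
moments and covariance, relative delta power, EEG skewness/kurtosis, IBI,
inter-hemispheric symmetry and synchrony), median-combined over the
8-channel bipolar montage and Box-Cox normalised, feed a multi-class
linear discriminant: one Fisher discriminant `w ∝ Sw⁻¹(µᵢ − µⱼ)` per pair
of the six EEG states (1S1, 1S2, 2S1, 2S2, 3, 4 — sleep-state sub-grades
exist only in grades 1–2), combined by voting, merged to four grades, and
post-processed by a majority vote over the hour; a two-thirds majority
marks the decision *certain*. Agreement is scored with Cohen's
κ = (p_a − p_e)/(1 − p_e), and generalisation with leave-one-subject-out
(LOSO) cross-validation whose nested parameter/feature searches never see
the held-out subject.

Because clinical recordings cannot be redistributed, the package includes
a simulator that generates EEG from the same model with known grade,
EEG-state, envelope and spectral ground truth — every stage is testable
end to end.

## Worked example

```r
library(neograde)

corpus <- simulate_corpus(4, duration = 300, fs = 64, seed = 1)  # 16 subjects
model  <- train_ags(corpus, preprocess_params(64, 2.5), seed = 1)
model
#> <ags_model> 6-state pairwise Fisher LDA (15 pair models), 16 features
#>   epoch 64 s, HPF 2.5 Hz

unknown <- simulate_record(3, duration = 600, fs = 64, seed = 99,
                           state_cycle_period = 600)
dec <- grade_recording(unknown, model)
dec
#> <grade_decision> grade 3 (100% of 17 epochs, certain)
glance(dec)
#> # A tibble: 1 × 4
#>   final_grade vote_fraction certain n_epochs
#>         <int>         <dbl> <lgl>      <int>
#> 1           3             1 TRUE          17
```

The model was trained on sixteen 5-minute simulated recordings (four per
grade) at the default operating point (64 s epochs, 2.5 Hz high-pass); the
held-out burst-suppression recording is graded 3 with every epoch agreeing,
hence a certain decision.

Scoring a published-style rater-vs-system contingency table:

```r
cm <- matrix(c(20, 2, 0, 0,
                3, 10, 1, 0,
                0, 3, 9, 0,
                0, 0, 0, 6), nrow = 4, byrow = TRUE)
k <- cohens_kappa(cm)
sprintf("kappa %.3f accuracy %.1f%%", k$kappa, 100 * k$p_a)
#> [1] "kappa 0.762 accuracy 83.3%"
```

Other entry points: `loso()` (cross-validation with optional nested
`grid_search_preproc()` / `backward_elimination()`), `duration_curve()`,
`artefact_error_split()`, `read_edf()`/`write_edf()`, and `autoplot()`
methods for records, time-frequency maps, AM/IF pairs and confusion
matrices. A thin command-line wrapper with `simulate`, `train`, `grade`
and `evaluate` subcommands is installed at `inst/cli/neograde`. The
methods vignette (`vignettes/neograde-methods.Rmd`) documents the model,
parameters and design choices.

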