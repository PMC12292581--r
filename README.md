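# dscnl

Class-incremental learning for image classification when training
labels are noisy — the setting of evolving medical-imaging archives,
where new diagnostic classes arrive over time and a fraction of
annotations is simply wrong.

Rehearsal-based continual learners replay a small buffer of past
samples to fight catastrophic forgetting, but they silently assume
those stored labels are correct.  Under symmetric label noise (a
fraction ρ of labels replaced by a uniformly random other class) that
assumption fails twice over: noise corrupts the features learned for
the current task, and mislabelled samples that slip into the buffer are
rehearsed for the rest of the run, compounding the damage.

`dscnl` implements a dual-stage clean-sample selection framework around
a single-head incremental classifier:

1. **Clean-sample filtering.**  An auxiliary network accumulates each
   sample's *historical confidence* C\_i = Σ\_e p\_e(y = ỹ\_i | x\_i)
   over warm-up epochs.  Per class, the averages C\_i/E are modelled by
   a two-component Gaussian mixture (EM); samples with high posterior
   for the high-mean ("clean") component are kept.  A dynamic threshold
   amplifies or relaxes toward the expected clean count
   round((1 − ρ̂)·N\_t), with ρ̂ known or cross-validated, iterating
   {select → train aux net one epoch → update history → re-fit}.
2. **Uncertainty-aware replay sampling.**  Each clean candidate gets S
   stochastic augmentations; every copy votes for its argmax class, and
   U\_x = 1 − max\_c V\_c/S scores instability.  A fixed-capacity,
   class-balanced buffer (quota = ⌊N\_M / #classes seen⌋) is filled by
   interval sampling over the uncertainty-sorted list, always including
   the most representative and the most fragile sample of every class.
   Random and reservoir strategies ship as ablation baselines.
3. **Experience soft replay.**  Batches are drawn from the union of the
   clean subset and the buffer; mixup virtual samples
   x′ = λ′x\_i + (1−λ′)x\_j with λ ~ Beta(α, α), λ′ = max(λ, 1−λ)
   add a soft-label cross-entropy term, giving the objective
   L = L\_ce + β·L\_mix.  β = 0 recovers plain experience replay.

Evaluation uses the lower-triangular task-accuracy matrix and the
final average accuracy (FAA): the unweighted mean accuracy over all
tasks' test sets after the last task.  A synthetic stream generator
(separable parametric image classes, exact-count symmetric noise,
disjoint task splits, MedMNIST-dialect NPZ I/O) makes every claim
testable at desk scale, with true labels retained for purity
accounting.

## Worked example

```r
library(dscnl)

stream <- synthetic_stream(n_classes = 8, n_per_class = 200,
                           n_test_per_class = 50, image_size = 32,
                           noise_rate = 0.3, seed = 7)
cfg <- dscnl_config(filter = filter_config(noise_rate = 0.3))

fit <- dscnl(stream, mode = "dscnl", config = cfg, seed = 11)
summary(fit)
```

```
Class-incremental dscnl run (seed 11)

Task-accuracy matrix (%):
          on_task
after_task  t1  t2  t3  t4
        t1 100   -   -   -
        t2  99 100   -   -
        t3  99 100 100   -
        t4  98 100  99 100

Final average accuracy: 99.25%

Per-task purity:
 task n_task n_selected selection_purity buffer_purity noise_rate_estimate
    1    402        273            93.77         93.77                 0.3
    2    416        293            94.20         94.20                 0.3
    3    392        276            91.30         93.40                 0.3
    4    390        277            88.45         92.20                 0.3
```

Each row of the matrix is the model's test accuracy on every task
learned so far, after finishing the row's task; the FAA is the mean of
the last row.  The purity table shows that at ρ = 0.3 the filter keeps
~70% of each task's samples and 88–94% of what it keeps is correctly
labelled (the raw data is only 70% clean), and that the replay buffer
stays at or above that purity throughout.

The same stream under the finetuning baseline — no filter, no buffer,
no mixup — collapses to near chance:

```r
baseline <- dscnl(stream, mode = "finetune", config = cfg, seed = 11)
baseline$faa
#> [1] 20.75
```

`plot(fit)` draws the per-task accuracy trajectories;
`predict(fit, newdata)` classifies new images over the classes seen so
far.  See `vignette("dscnl-methods")` for the model, its assumptions,
and every tunable parameter.  A command-line wrapper with `simulate`,
`filter`, `run` and `evaluate` subcommands is installed under
`inst/scripts/dscnl.R`.

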