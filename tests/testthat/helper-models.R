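# The acceptance "world" and its trained models, built once per run.
# Scale: the default phantom (96 x 96 x 48 @ 1 x 1 x 2 mm) with two
# gland-like distractors; 20 training phantoms (40 cases after
# mirroring), 10 held-out. Reduced-width networks and a few hundred
# Adam steps keep the whole suite inside a CPU test budget; the
# configuration is fixed here, not tuned per test.

acceptance_phantom_config <- function() phantom_config(n_distractors = 2)

acceptance_train_phantoms <- function() {
  memo("acc_train", function()
    generate_cohort(20, acceptance_phantom_config(), seed = 11)$phantoms)
}

acceptance_eval_phantoms <- function() {
  memo("acc_eval", function()
    generate_cohort(10, acceptance_phantom_config(), seed = 99)$phantoms)
}

acceptance_model_3d <- function() {
  memo("acc_model3d", function() {
    cases <- cohort_training_cases(acceptance_train_phantoms())
    train_segmenter_3d(
      cases,
      arch = arch_spec(3, base_channels = 3),
      cfg = sampling_config(patch_extent = c(72L, 72L, 48L),
                            batch_size = 4L),
      steps = 320L,
      lr = function(step) if (step <= 220) 3e-3 else 1e-3,
      seed = 5L)$model
  })
}

acceptance_model_2d <- function() {
  memo("acc_model2d", function() {
    cases <- cohort_training_cases(acceptance_train_phantoms())
    train_segmenter_2d_roi(
      cases,
      arch = arch_spec(2, base_channels = 4),
      cfg = sampling_config(view = "axial", batch_size = 4L),
      steps = 250L,
      lr = function(step) if (step <= 180) 1e-2 else 3e-3,
      seed = 5L)$model
  })
}
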