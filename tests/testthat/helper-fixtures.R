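# Shared fixtures and a cached desk-scale model so expensive training runs
# once per session.

.cache <- new.env(parent = emptyenv())

# quadratic luminance bowl L = (x-cx)^2 + (y-cy)^2 on an n x n grid
quad_image <- function(n = 41, cx = (n + 1) / 2, cy = (n + 1) / 2) {
  outer(seq_len(n) - cy, seq_len(n) - cx, function(y, x) x^2 + y^2)
}

# study-condition training set: 60 schematic faces with pose variation and
# eyelid coverage up to 0.5
desk_training_specs <- function() {
  sample_face_specs(60, seed = 11, eyelid_coverage_range = c(0, 0.5))
}

desk_model <- function() {
  if (!is.null(.cache$model)) return(.cache$model)
  samples <- lapply(desk_training_specs(), function(sp) {
    f <- render_face(sp)
    list(image = f$image, true_shape = f$landmarks)
  })
  aug <- augment_training(samples, n_inits = 20L, seed = 2)
  # desk-scale hyperparameters; shrinkage scaled to the smaller training
  # set (bins hold ~40 members here, not the thousands of a full-scale run)
  .cache$model <- cascade_train(aug,
                                list(T = 5L, K = 50L, P = 100L, beta = 250),
                                seed = 3, scheme = ec_scheme_synth29())
  .cache$model
}

# planted-distractor condition: hooded strong brows with rounded heads plus
# partial eyelid occlusion (the regime where a plain MIC chases the brow)
distractor_specs <- function(n, seed = 123) {
  sample_face_specs(n, seed = seed, brow_strength = 2, brow_drop = 0.06,
                    brow_blob = 1.3, eyelid_coverage_range = c(0.2, 0.5))
}

eye_truth <- function(face, scheme = ec_scheme_synth29()) {
  list(left = face$landmarks[scheme$left$center, ],
       right = face$landmarks[scheme$right$center, ])
}
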