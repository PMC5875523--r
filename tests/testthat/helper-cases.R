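# Shared fixtures, built once per test run and memoised across files.

.fixture_env <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .fixture_env))
    assign(key, expr, envir = .fixture_env)
  get(key, envir = .fixture_env)
}

rec_case <- function() cached("rec_case",
  generate_phantom(phantom_spec("recoverable", seed = 1)))

rec_report <- function() cached("rec_report",
  run_case(rec_case(), keep_fields = TRUE))

# Small, fast phantoms for unit tests that only need plausible anatomy;
# the tumour is re-centred so it fits the reduced grid.
small48 <- function(scenario, seed, ...)
  generate_phantom(phantom_spec(scenario, seed = seed,
                                ct_dim = c(48L, 48L, 36L),
                                tumor_center = c(6, 5, 0),
                                tumor_radius = 12,
                                n_landmarks = 12L, n_near_tumor = 5L, ...))

small_case <- function() cached("small_case", small48("recoverable", 3))

# Noise-free-annotation variant used for exact-correspondence checks.
exact_case <- function() cached("exact_case",
  small48("recoverable", 7, landmark_noise_mm = 0))

# Volume whose intensity is affine in world coordinates: a + b . x
affine_volume <- function(dm = c(12L, 14L, 10L), spacing = c(1, 1.5, 3),
                          origin = c(-5, 2, -10), a = 7,
                          b = c(0.5, -1.2, 2)) {
  g <- expand.grid(x = origin[1] + (seq_len(dm[1]) - 1) * spacing[1],
                   y = origin[2] + (seq_len(dm[2]) - 1) * spacing[2],
                   z = origin[3] + (seq_len(dm[3]) - 1) * spacing[3])
  vals <- a + g$x * b[1] + g$y * b[2] + g$z * b[3]
  scalar_volume(array(vals, dm), spacing, origin)
}

# Uniform random world points strictly inside a volume's grid.
interior_points <- function(vol, n, margin = 1) {
  lo <- vol$origin + margin * vol$spacing
  hi <- vol$origin + (dim(vol$data) - 1 - margin) * vol$spacing
  cbind(runif(n, lo[1], hi[1]), runif(n, lo[2], hi[2]),
        runif(n, lo[3], hi[3]))
}
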