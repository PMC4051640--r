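# Shared fixtures: everything is generated in code. Expensive objects (the
# default-size phantom pipeline run) are computed once per session and
# cached.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(name, expr) {
  if (!exists(name, envir = .fixture_cache))
    assign(name, expr, envir = .fixture_cache)
  get(name, envir = .fixture_cache)
}

default_truth <- function() cached("truth", make_phantom(phantom_spec()))

# full end-to-end run on the default phantom (used by recovery tests)
default_case <- function() cached("case", {
  run_pipeline(pipeline_config(include_self_check = TRUE))
})

# a small random series for algebraic tests
toy_series <- function(dims = c(6, 6, 5), n_t = 60, tr = 2.0, seed = 1,
                       fill = NULL) {
  set.seed(seed)
  data <- if (is.null(fill))
    array(rnorm(prod(dims) * n_t), dim = c(dims, n_t))
  else array(fill, dim = c(dims, n_t))
  aff <- diag(c(2.5, 2.5, 2.5, 1))
  aff[1:3, 4] <- -2.5 * (dims - 1) / 2
  bold_series(data, aff, tr)
}

toy_affine <- function(voxel = 2.5, dims = c(6, 6, 5)) {
  aff <- diag(c(rep(voxel, 3), 1))
  aff[1:3, 4] <- -voxel * (dims - 1) / 2
  aff
}

# a quiet phantom spec (no noise/drift/global) for exactness tests
clean_spec <- function(...) {
  phantom_spec(noise_sd = 0, drift_coeffs = numeric(0), global_amp = 0, ...)
}

# independently coded double-gamma HRF (oracle for regressor tests)
oracle_hrf <- function(t) {
  h <- dgamma(t, shape = 7, rate = 1) - dgamma(t, shape = 17, rate = 1) / 6
  h / max(dgamma(0:32, shape = 7, rate = 1))
}
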