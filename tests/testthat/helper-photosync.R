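# Shared fixtures for the test suite: everything is generated in code.

# silence per-stage run-log messages inside tests
quietly <- function(expr) suppressMessages(expr)

# a small, fast default config for tests that don't need long sessions
test_config <- function(...) {
  sim_config(duration_s = 60, n_bouts = 3, seed = 42L, ...)
}

# independent normal-equations least-squares oracle (closed form via the
# Gram matrix), kept separate from the package's QR-based fit
normal_equations_fit <- function(refs, spectrum) {
  X <- t(refs$curves)
  as.numeric(solve(crossprod(X), crossprod(X, spectrum)))
}

# direct Pearson correlation of the stored ground-truth band components
truth_band_r <- function(truth) {
  stats::cor(truth$band_parts[, "region1"], truth$band_parts[, "region2"])
}
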