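# Independent oracles used across the suite.

# Exhaustive coarse-to-fine grid search for the angular SHG model, written
# directly from the trigonometric form (independent of the package's
# optimizer).  Amplitude is profiled by linear least squares; offset fixed
# at zero (the oracle is used on offset-free instances).  Final resolution
# ~0.001 in b and ~0.001 deg in phi.
grid_fit_oracle <- function(theta_deg, y) {
  sse_grid <- function(b_grid, phi_grid) {
    best <- c(Inf, NA, NA)
    th <- theta_deg * pi / 180
    for (b in b_grid) {
      for (phi in phi_grid) {
        u <- th - phi * pi / 180
        g <- sin(2 * u)^2 + (sin(u)^2 + b * cos(u)^2)^2
        A <- sum(g * y) / sum(g * g)
        sse <- sum((y - A * g)^2)
        if (sse < best[1]) best <- c(sse, b, phi)
      }
    }
    best
  }
  best <- sse_grid(seq(0.1, 6, by = 0.05), seq(0, 179.5, by = 0.5))
  for (res in c(0.01, 0.001)) {
    b0 <- best[2]; p0 <- best[3]
    # refine both 90-degree branches: near b = 1 the model is almost
    # 90-periodic and the coarse grid can land on the wrong branch
    best <- sse_grid(seq(max(0.05, b0 - 6 * res * 5), b0 + 6 * res * 5,
                         by = res),
                     c(seq(p0 - 0.6, p0 + 0.6, by = res),
                       seq(p0 + 89.4, p0 + 90.6, by = res)))
  }
  list(b = best[2], phi = best[3] %% 180, sse = best[1])
}

# Orientation difference modulo the model's 180-degree period.
phi_diff_mod180 <- function(a, b) {
  d <- abs(a - b) %% 180
  min(d, 180 - d)
}

# Difference allowing the additional 90-degree ambiguity that is exact at
# b = 1 (the bracketed model term is constant there).
phi_diff_mod90 <- function(a, b) {
  d <- abs(a - b) %% 90
  min(d, 90 - d)
}
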