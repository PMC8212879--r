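# Per-pixel fitting of the polarization-resolved SHG response.
#
# Model: I(theta) = A { sin^2[2(theta-phi)] + [sin^2(theta-phi)
#                      + b cos^2(theta-phi)]^2 } + c
# the cylindrically symmetric (C-inf-v) chi(2) form under Kleinman
# symmetry, with tensor ratio b = chi_ZZZ/chi_ZXX, in-plane orientation
# phi, amplitude A and offset c.  A and c enter linearly, so for a given
# (b, phi) they are profiled out by linear least squares and the nonlinear
# search runs over (b, phi) only, Levenberg-Marquardt with bounds,
# initialized from the Fourier cos/sin(2 theta) phase of the angular
# response and the max/min intensity ratio heuristic b ~ sqrt(Imax/Imin).

#' Fit the P-SHG model at every pixel of a polarization stack
#'
#' Performs a bounded nonlinear least-squares fit of the angular SHG
#' response at each pixel whose mean intensity over angles reaches
#' `min_mean_intensity`, returning per-pixel maps of the tensor ratio `b`,
#' fiber in-plane orientation `phi` (degrees in `[0, 180)`), amplitude,
#' offset, and the coefficient of determination `r2`, plus a validity mask.
#' Pixels below the intensity threshold, without angular modulation, or
#' with `r2 < r2_min` are masked invalid.
#'
#' Note the model is exactly 90-degree periodic when `b = 1` (the bracketed
#' term is constant), so at `b = 1` the orientations `phi` and `phi + 90`
#' are indistinguishable; the fitter returns one of the two.
#'
#' @param stack a [pol_stack()] with channel `"total"` and at least 5
#'   distinct angles.
#' @param min_mean_intensity validity threshold on the per-pixel mean
#'   intensity over angles; default 0 (all pixels with any signal are fit).
#' @param fit_offset if `FALSE`, the additive offset c is pinned to 0.
#' @param r2_min minimum coefficient of determination for a pixel to be
#'   considered valid (default 0.5).
#' @param b_bounds search bounds for the tensor ratio.
#' @return An object of class `"pshg_fit"` with elements `b_map`,
#'   `phi_map`, `amplitude_map`, `offset_map`, `r2_map`, `valid_mask`,
#'   `angles_deg`, `n_valid`.
#' @seealso [pitch_map()], [pshg_model()], [gen_pshg_stack()]
#' @export
fit_pshg <- function(stack, min_mean_intensity = 0, fit_offset = TRUE,
                     r2_min = 0.5, b_bounds = c(0.05, 10)) {
  stopifnot(inherits(stack, "pol_stack"))
  if (length(unique(stack$angles_deg)) < 5)
    stop("P-SHG fitting needs at least 5 distinct polarization angles")
  if (min_mean_intensity < 0) stop("min_mean_intensity must be >= 0")
  th <- stack$angles_deg
  d <- dim(stack$frames[[1]])
  npx <- prod(d)
  Y <- vapply(stack$frames, as.numeric, numeric(npx))  # npx x n_angles
  if (npx == 1) Y <- matrix(Y, nrow = 1)
  mean_i <- rowMeans(Y)
  b_map <- phi_map <- a_map <- c_map <- r2_map <- matrix(NA_real_, d[1], d[2])
  valid <- matrix(FALSE, d[1], d[2])
  candidate <- mean_i >= min_mean_intensity & mean_i > 0
  if (!any(candidate))
    warning("no pixel reaches min_mean_intensity; empty fit mask")
  for (p in which(candidate)) {
    y <- Y[p, ]
    fit <- fit_pshg_pixel(th, y, fit_offset, b_bounds)
    if (is.null(fit)) next
    b_map[p] <- fit$b; phi_map[p] <- fit$phi
    a_map[p] <- fit$A; c_map[p] <- fit$c; r2_map[p] <- fit$r2
    valid[p] <- is.finite(fit$r2) && fit$r2 >= r2_min
  }
  structure(
    list(b_map = b_map, phi_map = phi_map, amplitude_map = a_map,
         offset_map = c_map, r2_map = r2_map, valid_mask = valid,
         angles_deg = th, n_valid = sum(valid),
         min_mean_intensity = min_mean_intensity, r2_min = r2_min),
    class = "pshg_fit")
}

# Single-pixel fit; returns NULL for degenerate (unmodulated) responses.
fit_pshg_pixel <- function(theta_deg, y, fit_offset, b_bounds) {
  rng <- max(y) - min(y)
  if (rng <= max(1e-12, 1e-9 * max(abs(y))))
    return(NULL)  # no angular modulation: phi undefined
  # Fourier initialization of phi from the 2-theta component
  t2 <- 2 * theta_deg * pi / 180
  phase <- atan2(mean(y * sin(t2)), mean(y * cos(t2)))
  phi0 <- (phase / 2) * 180 / pi
  b0 <- sqrt(max(y) / max(min(y), 1e-6 * max(y)))
  b0 <- min(max(b0, b_bounds[1] * 1.5), b_bounds[2] / 1.5)
  starts <- expand.grid(phi = phi0 + c(0, 45, 90, 135),
                        b = unique(c(b0, 2)))
  # rank candidate starts by their profiled SSE; refine only the best few
  sse0 <- vapply(seq_len(nrow(starts)), function(s) {
    sum(profiled_residuals(c(b = starts$b[s],
                             phi = starts$phi[s] * pi / 180),
                           theta_deg, y, fit_offset)^2)
  }, numeric(1))
  starts <- starts[order(sse0), , drop = FALSE][seq_len(min(3, nrow(starts))), ]
  best <- NULL
  for (s in seq_len(nrow(starts))) {
    res <- try(minpack.lm::nls.lm(
      par = c(b = starts$b[s], phi = starts$phi[s] * pi / 180),
      lower = c(b_bounds[1], starts$phi[s] * pi / 180 - pi),
      upper = c(b_bounds[2], starts$phi[s] * pi / 180 + pi),
      fn = function(p) profiled_residuals(p, theta_deg, y, fit_offset),
      control = minpack.lm::nls.lm.control(maxiter = 200, ftol = 1e-15,
                                           ptol = 1e-15)),
      silent = TRUE)
    if (inherits(res, "try-error")) next
    sse <- sum(res$fvec^2)
    if (is.null(best) || sse < best$sse - 1e-12 * best$sse)
      best <- list(par = res$par, sse = sse)
  }
  if (is.null(best)) return(NULL)
  b <- best$par[["b"]]
  phi <- (best$par[["phi"]] * 180 / pi) %% 180
  lin <- profile_linear(b, phi, theta_deg, y, fit_offset)
  sst <- sum((y - mean(y))^2)
  r2 <- if (sst > 0) 1 - best$sse / sst else NA_real_
  list(b = b, phi = phi, A = lin$A, c = lin$c, r2 = r2)
}

# For fixed (b, phi) solve the linear amplitude/offset by least squares
# (amplitude clamped nonnegative).
profile_linear <- function(b, phi, theta_deg, y, fit_offset) {
  g <- pshg_model(theta_deg, b, phi, amplitude = 1, offset = 0)
  if (fit_offset) {
    X <- cbind(g, 1)
    beta <- tryCatch(qr.solve(X, y), error = function(e) c(0, mean(y)))
    A <- beta[1]; cc <- beta[2]
    if (A < 0 || cc < 0) {
      # refit on the boundary of the feasible quadrant
      A_only <- sum(g * y) / sum(g * g)
      sse_A <- sum((y - A_only * g)^2)
      c_only <- mean(y)
      sse_c <- sum((y - c_only)^2)
      if (A_only >= 0 && sse_A <= sse_c) { A <- A_only; cc <- 0 }
      else { A <- 0; cc <- c_only }
    }
  } else {
    A <- max(sum(g * y) / sum(g * g), 0)
    cc <- 0
  }
  list(A = A, c = cc, fitted = A * g + cc)
}

profiled_residuals <- function(p, theta_deg, y, fit_offset) {
  lin <- profile_linear(p[["b"]], (p[["phi"]] * 180 / pi) %% 180,
                        theta_deg, y, fit_offset)
  y - lin$fitted
}

#' Pitch angle from the chi(2) tensor ratio
#'
#' Converts the tensor ratio `b = chi_ZZZ/chi_ZXX` to the effective
#' alpha-helical pitch angle `theta_p = arctan(sqrt(2/b))`, in degrees.
#' The function is strictly decreasing in `b` and maps `(0, Inf)` onto
#' `(0, 90)` degrees; `b = 2` gives exactly 45 degrees.
#'
#' @param b tensor ratio(s), all > 0.
#' @return Pitch angle(s) in degrees, strictly inside (0, 90).
#' @export
pitch_angle_from_ratio <- function(b) {
  if (any(!is.finite(b) | b <= 0))
    stop("the tensor ratio b must be positive and finite")
  atan(sqrt(2 / b)) * 180 / pi
}

#' Per-pixel pitch-angle map from a P-SHG fit
#'
#' Applies [pitch_angle_from_ratio()] over the valid pixels of a
#' [fit_pshg()] result and summarizes the map as mean +/- standard error
#' over the validity mask.
#'
#' @param fit a `"pshg_fit"` object.
#' @return An object of class `"pitch_map"` with `theta_p_map` (degrees),
#'   `valid_mask`, and `summary` (`mean`, `sem`, `n`).  With an empty
#'   validity mask the summary is `NA` (with a warning).
#' @export
pitch_map <- function(fit) {
  stopifnot(inherits(fit, "pshg_fit"))
  tp <- matrix(NA_real_, nrow(fit$b_map), ncol(fit$b_map))
  v <- fit$valid_mask
  if (any(v)) tp[v] <- pitch_angle_from_ratio(fit$b_map[v])
  n <- sum(v)
  if (n == 0) {
    warning("empty validity mask: pitch summary is undefined")
    summ <- c(mean = NA_real_, sem = NA_real_, n = 0)
  } else {
    summ <- c(mean = mean(tp[v]),
              sem = if (n > 1) stats::sd(tp[v]) / sqrt(n) else NA_real_,
              n = n)
  }
  structure(list(theta_p_map = tp, valid_mask = v, summary = summ),
            class = "pitch_map")
}

#' Mean fitted polar response of a P-SHG fit
#'
#' Evaluates the fitted model curve at the requested angles for every valid
#' pixel, averages over pixels, and normalizes the mean curve to peak 1 —
#' the standard way a pixel-based P-SHG response is reconstructed for
#' display and group comparison.
#'
#' @param fit a `"pshg_fit"` object.
#' @param angles_deg angles at which to evaluate (default: a dense
#'   0..180-degree sweep).
#' @return A data.frame with columns `angle_deg` and `response` (peak 1).
#' @export
reconstruct_polar_response <- function(fit,
                                       angles_deg = seq(0, 180, by = 1)) {
  stopifnot(inherits(fit, "pshg_fit"))
  v <- fit$valid_mask
  if (!any(v)) {
    warning("empty validity mask: no response to reconstruct")
    return(data.frame(angle_deg = angles_deg,
                      response = rep(NA_real_, length(angles_deg))))
  }
  idx <- which(v)
  curve <- rowMeans(vapply(idx, function(p)
    pshg_model(angles_deg, fit$b_map[p], fit$phi_map[p],
               fit$amplitude_map[p], fit$offset_map[p]),
    numeric(length(angles_deg))))
  data.frame(angle_deg = angles_deg, response = curve / max(curve))
}

#' @export
print.pshg_fit <- function(x, ...) {
  cat("P-SHG pixel fit:", length(x$angles_deg), "angles,",
      x$n_valid, "of", length(x$b_map), "pixels valid\n")
  if (x$n_valid > 0) {
    v <- x$valid_mask
    cat("  b: median", format(stats::median(x$b_map[v]), digits = 4),
        " phi: median", format(stats::median(x$phi_map[v]), digits = 4),
        "deg  r2: median", format(stats::median(x$r2_map[v]), digits = 3),
        "\n")
  }
  invisible(x)
}

#' @export
summary.pshg_fit <- function(object, ...) {
  v <- object$valid_mask
  pm <- pitch_map(object)
  out <- list(
    n_valid = object$n_valid, n_pixels = length(object$b_map),
    b = if (any(v)) summary(object$b_map[v]) else NULL,
    theta_p = pm$summary,
    r2 = if (any(v)) summary(object$r2_map[v]) else NULL)
  class(out) <- "summary.pshg_fit"
  out
}

#' @export
print.summary.pshg_fit <- function(x, ...) {
  cat("P-SHG fit over", x$n_valid, "valid of", x$n_pixels, "pixels\n")
  if (!is.null(x$b)) { cat("tensor ratio b:\n"); print(x$b) }
  cat(sprintf("pitch angle: mean %.3f deg, SEM %.3g (n = %d)\n",
              x$theta_p[["mean"]], x$theta_p[["sem"]], x$theta_p[["n"]]))
  invisible(x)
}

#' @export
coef.pshg_fit <- function(object, ...) {
  v <- which(object$valid_mask)
  data.frame(pixel = v, b = object$b_map[v], phi_deg = object$phi_map[v],
             amplitude = object$amplitude_map[v],
             offset = object$offset_map[v], r2 = object$r2_map[v])
}

#' @export
predict.pshg_fit <- function(object, angles_deg = seq(0, 180, by = 1),
                             ...) {
  reconstruct_polar_response(object, angles_deg)
}

#' @export
fitted.pshg_fit <- function(object, ...) {
  lapply(seq_along(object$angles_deg), function(i) {
    m <- matrix(NA_real_, nrow(object$b_map), ncol(object$b_map))
    v <- which(object$valid_mask)
    m[v] <- pshg_model(object$angles_deg[i], object$b_map[v],
                       object$phi_map[v], object$amplitude_map[v],
                       object$offset_map[v])
    m
  })
}

#' @export
residuals.pshg_fit <- function(object, stack, ...) {
  if (missing(stack))
    stop("residuals.pshg_fit needs the original pol_stack")
  f <- fitted(object)
  Map(function(obs, fit) obs - fit, stack$frames, f)
}

#' @export
plot.pshg_fit <- function(x, ...) {
  r <- reconstruct_polar_response(x)
  graphics::plot(r$angle_deg, r$response, type = "l",
                 xlab = "excitation polarization angle (deg)",
                 ylab = "normalized SHG intensity",
                 main = "Reconstructed pixel-based polar response", ...)
  invisible(x)
}

#' @export
print.pitch_map <- function(x, ...) {
  s <- x$summary
  cat(sprintf(
    "Pitch-angle map: mean %.3f deg, SEM %.3g over %d valid pixels\n",
    s[["mean"]], s[["sem"]], s[["n"]]))
  invisible(x)
}
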