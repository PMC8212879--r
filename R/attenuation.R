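# Depth-dependent SHG attenuation: the rate at which the section-mean SHG
# intensity decays with depth is the relative conversion-efficiency readout
# for a z-series (flatter decay = brighter, more efficient sample).
#
# Each series is self-normalized: the per-section foreground means are
# divided by a robust peak estimate (the maximum of a 3-point running
# median of the section means, endpoints kept), so profiles from samples
# with different absolute brightness are directly comparable.  Both a
# linear slope of the normalized profile (the conventional attenuation
# slope) and a single-exponential coefficient mu (from a log-linear fit)
# are reported, over the window from the peak section to the last section.

#' Normalized intensity-versus-depth profile of a z-series
#'
#' Computes per-section foreground mean intensities, self-normalizes them
#' by the robust peak (max of a 3-point running median of section means),
#' and fits both a linear slope and an exponential attenuation coefficient
#' over the window from the peak section to the deepest section.
#'
#' The foreground mask keeps pixels above the background mean + `k_sigma`
#' SD (darkest-decile estimate) of the brightest section, and the same
#' mask is applied to every section, so empty regions do not dilute the
#' section means and per-section re-selection cannot bias the decay under
#' noise; when the rule would discard every pixel (e.g. a uniform
#' synthetic section) all pixels are used.
#'
#' @param series a [depth_series()].
#' @param k_sigma foreground threshold multiplier (default 3); `NULL`
#'   disables masking (all pixels averaged).
#' @return An object of class `"attenuation_profile"` with `depths_um`,
#'   `raw_means`, `normalized`, `slope_per_um`, `mu_per_um`,
#'   `fit_window_um`, `n_sections`.
#' @export
depth_profile <- function(series, k_sigma = 3) {
  stopifnot(inherits(series, "depth_series"))
  z <- depths_um(series)
  raw <- if (is.null(k_sigma)) {
    vapply(series$sections, mean, numeric(1))
  } else {
    bright <- series$sections[[
      which.max(vapply(series$sections, mean, numeric(1)))]]
    fg <- bright > background_threshold(bright, k_sigma)
    if (!any(fg)) fg[] <- TRUE
    vapply(series$sections, function(s) mean(s[fg]), numeric(1))
  }
  if (all(raw <= 0))
    stop("all sections are background: no attenuation profile")
  peak <- max(stats::runmed(raw, 3, endrule = "keep"))
  normalized <- raw / peak
  ipeak <- which.max(normalized)
  win <- ipeak:length(z)
  if (length(win) < 2)
    stop("attenuation window has fewer than 2 sections")
  lin <- stats::lm.fit(cbind(1, z[win]), normalized[win])
  slope <- lin$coefficients[2]
  pos <- win[normalized[win] > 0]
  mu <- if (length(pos) >= 2)
    -stats::lm.fit(cbind(1, z[pos]), log(normalized[pos]))$coefficients[2]
  else NA_real_
  structure(
    list(depths_um = z, raw_means = raw, normalized = normalized,
         slope_per_um = unname(slope), mu_per_um = unname(mu),
         fit_window_um = c(z[ipeak], z[length(z)]),
         n_sections = length(z)),
    class = "attenuation_profile")
}

#' Relative conversion efficiency of two attenuation profiles
#'
#' Ratio of the normalized intensities of two profiles at a query depth
#' (linear interpolation between bracketing sections).  Because both
#' profiles are self-normalized, the ratio isolates the difference in
#' attenuation, i.e. the relative SHG conversion efficiency of sample `a`
#' versus sample `b` at that depth.
#'
#' @param a,b `"attenuation_profile"` objects.
#' @param query_depth_um depth at which to compare; must lie inside both
#'   profiles' depth ranges.
#' @return The ratio `normalized_a(query)/normalized_b(query)`.
#' @export
relative_efficiency <- function(a, b, query_depth_um) {
  stopifnot(inherits(a, "attenuation_profile"),
            inherits(b, "attenuation_profile"))
  na <- interp_profile(a, query_depth_um)
  nb <- interp_profile(b, query_depth_um)
  if (nb == 0) stop("profile b is zero at the query depth")
  na / nb
}

interp_profile <- function(p, depth) {
  r <- range(p$depths_um)
  if (depth < r[1] || depth > r[2])
    stop("query depth ", depth, " um is outside the profile range [",
         r[1], ", ", r[2], "] um")
  stats::approx(p$depths_um, p$normalized, xout = depth)$y
}

#' @export
print.attenuation_profile <- function(x, ...) {
  cat(sprintf(
    "Attenuation profile: %d sections, z = %g..%g um\n",
    x$n_sections, min(x$depths_um), max(x$depths_um)))
  cat(sprintf("  slope = %.5g 1/um, mu = %.5g 1/um (window %g..%g um)\n",
              x$slope_per_um, x$mu_per_um, x$fit_window_um[1],
              x$fit_window_um[2]))
  invisible(x)
}

#' @export
as.data.frame.attenuation_profile <- function(x, ...) {
  data.frame(depth_um = x$depths_um, raw_mean = x$raw_means,
             normalized = x$normalized)
}

#' @export
plot.attenuation_profile <- function(x, ...) {
  graphics::plot(x$depths_um, x$normalized, type = "b",
                 xlab = "depth (um)", ylab = "normalized SHG intensity",
                 main = "Forward attenuation", ...)
  invisible(x)
}

#' @export
predict.attenuation_profile <- function(object, depth_um, ...) {
  vapply(depth_um, function(d) interp_profile(object, d), numeric(1))
}
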