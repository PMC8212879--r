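# SHG signal anisotropy from parallel/perpendicular analyzed channels.
#
# beta = (IPar - IPerp)/(IPar + 2 IPerp): 1 for perfectly aligned dipole
# moments, 0 for totally random, with analytic lower bound -0.5 (pure
# perpendicular emission).  Aggregation is the mask-mean of per-pixel beta,
# computed at each excitation angle independently; negative means are
# reported, not clipped, because low-count subtraction errors genuinely
# produce them near the orthogonal excitation angle.

#' Per-pixel SHG signal anisotropy
#'
#' `beta = (i_par - i_perp)/(i_par + 2 i_perp)`, vectorized.  Pixels with a
#' zero denominator are undefined and returned as `NA` (map-level code
#' masks them rather than erroring).
#'
#' @param i_par,i_perp nonnegative parallel/perpendicular intensities.
#' @return Anisotropy values in `[-0.5, 1]` (NA where undefined).
#' @export
beta_pixel <- function(i_par, i_perp) {
  if (any(i_par < 0, na.rm = TRUE) || any(i_perp < 0, na.rm = TRUE))
    stop("intensities must be nonnegative")
  den <- i_par + 2 * i_perp
  out <- (i_par - i_perp) / den
  out[den <= 0] <- NA_real_
  out
}

#' SHG anisotropy as a function of excitation angle
#'
#' Computes the per-pixel anisotropy at every excitation polarization angle
#' of a registered parallel/perpendicular stack pair and aggregates it as
#' mean +/- SEM over the per-angle validity mask.
#'
#' The mask at each angle keeps pixels whose denominator
#' `IPar + 2 IPerp` exceeds `threshold`.  The default `threshold = NULL`
#' keeps every pixel with a positive denominator; `threshold = "auto"`
#' estimates the noise background from the darkest decile of the
#' denominator image and masks below its mean + `k_sigma` standard
#' deviations (pixels with very low signal are what drive non-physical
#' negative means near 90 degrees).
#'
#' @param par,perp [pol_stack()]s with channels `"parallel"` and
#'   `"perpendicular"`, sharing angles and dimensions.
#' @param threshold `NULL`, a number, or `"auto"` (see Details).
#' @param k_sigma multiplier for the `"auto"` background rule.
#' @param keep_maps if `TRUE`, per-angle beta maps are retained.
#' @return An object of class `"anisotropy_curve"`: data.frame-like fields
#'   `angles_deg`, `beta_mean`, `beta_sem`, `n_valid`, plus `beta_maps`
#'   (list or NULL).
#' @export
anisotropy_curve <- function(par, perp, threshold = NULL, k_sigma = 3,
                             keep_maps = FALSE) {
  stopifnot(inherits(par, "pol_stack"), inherits(perp, "pol_stack"))
  if (!isTRUE(all.equal(par$angles_deg, perp$angles_deg)))
    stop("parallel and perpendicular stacks must share the same angles")
  if (!identical(dim(par$frames[[1]]), dim(perp$frames[[1]])))
    stop("channel stacks must share image dimensions")
  n <- length(par$angles_deg)
  bm <- bs <- nv <- numeric(n)
  maps <- if (keep_maps) vector("list", n) else NULL
  for (i in seq_len(n)) {
    p <- par$frames[[i]]; q <- perp$frames[[i]]
    den <- p + 2 * q
    thr <- if (is.null(threshold)) 0
           else if (identical(threshold, "auto"))
             background_threshold(den, k_sigma)
           else as.numeric(threshold)
    ok <- den > max(thr, 0)
    beta <- beta_pixel(p, q)
    vals <- beta[ok & !is.na(beta)]
    bm[i] <- if (length(vals)) mean(vals) else NA_real_
    bs[i] <- if (length(vals) > 1) stats::sd(vals) / sqrt(length(vals))
             else NA_real_
    nv[i] <- length(vals)
    if (keep_maps) {
      beta[!ok] <- NA_real_
      maps[[i]] <- beta
    }
  }
  structure(list(angles_deg = par$angles_deg, beta_mean = bm,
                 beta_sem = bs, n_valid = nv, beta_maps = maps),
            class = "anisotropy_curve")
}

# k-sigma noise background estimate from the darkest decile of an image.
background_threshold <- function(img, k_sigma = 3) {
  v <- sort(as.numeric(img))
  dark <- v[seq_len(max(1L, ceiling(length(v) / 10)))]
  mean(dark) + k_sigma * stats::sd(dark)
}

#' Anisotropy at a reference excitation angle
#'
#' Looks up the aggregated anisotropy at a requested angle (the 0- and
#' 90-degree excitations are the conventional reference points).
#'
#' @param curve an `"anisotropy_curve"`.
#' @param angle_deg requested angle.
#' @param tol lookup tolerance in degrees (default 1).
#' @return Named vector `c(beta_mean, beta_sem, n_valid)`.
#' @export
beta_at <- function(curve, angle_deg, tol = 1) {
  stopifnot(inherits(curve, "anisotropy_curve"))
  d <- abs(curve$angles_deg - angle_deg)
  i <- which.min(d)
  if (d[i] > tol)
    stop("no sampled excitation angle within ", tol, " deg of ",
         angle_deg, " deg")
  c(beta_mean = curve$beta_mean[i], beta_sem = curve$beta_sem[i],
    n_valid = curve$n_valid[i])
}

#' @export
print.anisotropy_curve <- function(x, ...) {
  cat("SHG anisotropy curve over", length(x$angles_deg), "angles\n")
  print(data.frame(angle_deg = x$angles_deg, beta_mean = x$beta_mean,
                   beta_sem = x$beta_sem, n_valid = x$n_valid),
        row.names = FALSE)
  invisible(x)
}

#' @export
as.data.frame.anisotropy_curve <- function(x, ...) {
  data.frame(angle_deg = x$angles_deg, beta_mean = x$beta_mean,
             beta_sem = x$beta_sem, n_valid = x$n_valid)
}

#' @export
plot.anisotropy_curve <- function(x, ...) {
  graphics::plot(x$angles_deg, x$beta_mean, type = "b",
                 xlab = "excitation polarization angle (deg)",
                 ylab = expression(beta),
                 main = "SHG signal anisotropy", ...)
  ok <- !is.na(x$beta_sem)
  graphics::arrows(x$angles_deg[ok], x$beta_mean[ok] - x$beta_sem[ok],
                   x$angles_deg[ok], x$beta_mean[ok] + x$beta_sem[ok],
                   angle = 90, code = 3, length = 0.03)
  invisible(x)
}
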