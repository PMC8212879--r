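# Fiber phantoms: constant-width curves with closed-form (segment, arc) or
# directly measured (smoothed random walk) centerline ground truth, rendered
# on a zero background, blurred, then passed through the scene noise model.

#' Generate a 2D fiber phantom with ground truth
#'
#' Renders each fiber in `scene$fiber_spec` as a constant-width curve
#' (straight segment, circular arc, or smoothed random walk with a target
#' straightness), applies a Gaussian blur of `sigma = width/4`, and the
#' scene's noise model.  The returned ground truth lists each fiber's true
#' arc length, width, and straightness (endpoint chord length divided by
#' arc length); for segments straightness is exactly 1 and for an arc of
#' angle `a` it is `2 sin(a/2)/a` (2/pi for a semicircle).
#'
#' @param scene a [synthetic_scene()] with nonempty `fiber_spec`.
#' @param shape image dimensions `c(rows, cols)`; default `scene$dim`.
#' @return A list with `image` (matrix), `fibers` (data.frame with columns
#'   `id`, `shape`, `length_um`, `width_um`, `straightness`),
#'   `centerlines` (list of n x 2 matrices, (row, col) in px) and
#'   `pixel_size_um`.
#' @export
gen_fiber_phantom <- function(scene, shape = scene$dim) {
  stopifnot(inherits(scene, "synthetic_scene"))
  if (length(scene$fiber_spec) == 0)
    stop("scene$fiber_spec is empty: nothing to render")
  px <- scene$pixel_size_um
  img <- matrix(0, shape[1], shape[2])
  truth <- list(); centers <- list()
  for (i in seq_along(scene$fiber_spec)) {
    fs <- scene$fiber_spec[[i]]
    pts <- fiber_centerline(fs, px, shape, scene$seed + 400L + i)
    w_px <- fs$width_um / px
    margin <- w_px / 2 + w_px / 4 * 3  # half width + 3 blur sigmas
    if (any(pts[, 1] < 1 + margin | pts[, 1] > shape[1] - margin |
            pts[, 2] < 1 + margin | pts[, 2] > shape[2] - margin))
      stop("fiber ", i, " extends outside the image (including its width ",
           "and blur margin); enlarge the image or shorten the fiber")
    img <- img | stamp_curve(shape, pts, w_px)
    arc_px <- polyline_length(pts)
    chord_px <- sqrt(sum((pts[nrow(pts), ] - pts[1, ])^2))
    truth[[i]] <- data.frame(
      id = i, shape = fs$shape, length_um = arc_px * px,
      width_um = fs$width_um, straightness = chord_px / arc_px)
    centers[[i]] <- pts
  }
  img <- img * scene$amplitude
  sigma <- max(vapply(scene$fiber_spec,
                      function(fs) fs$width_um / px / 4, numeric(1)))
  if (sigma > 0)
    img <- as.matrix(EBImage::gblur(img, sigma = sigma)) * 1
  img[img < 0] <- 0
  img <- apply_noise(list(img + scene$offset), scene, 401L)[[1]]
  list(image = img, fibers = do.call(rbind, truth),
       centerlines = centers, pixel_size_um = px)
}

# Sub-pixel centerline points (row, col), sampled every ~0.2 px.
fiber_centerline <- function(fs, px, shape, seed) {
  shape_kind <- match.arg(fs$shape, c("segment", "arc", "wiggle"))
  L <- fs$length_um / px
  alpha <- (if (is.null(fs$orientation_deg)) 0 else fs$orientation_deg) *
    pi / 180
  ctr <- if (is.null(fs$center_px)) (shape + 1) / 2 else fs$center_px
  step <- 0.2
  xy <- switch(shape_kind,
    segment = {
      t <- seq(-L / 2, L / 2, by = step)
      cbind(t, 0)
    },
    arc = {
      a <- (if (is.null(fs$arc_angle_deg)) 180 else fs$arc_angle_deg) *
        pi / 180
      r <- L / a
      t <- seq(-a / 2, a / 2, length.out = max(16, ceiling(L / step)))
      # chord along x, bulge along -y; recentered below
      cbind(r * sin(t), r * (1 - cos(t)))
    },
    wiggle = wiggle_polyline(L, fs$straightness, step, seed))
  xy[, 1] <- xy[, 1] - mean(range(xy[, 1]))
  xy[, 2] <- xy[, 2] - mean(range(xy[, 2]))
  # rotate by alpha (counterclockwise about x axis = columns), convert to
  # (row, col): row increases downward so row = -y
  xr <- xy[, 1] * cos(alpha) - xy[, 2] * sin(alpha)
  yr <- xy[, 1] * sin(alpha) + xy[, 2] * cos(alpha)
  cbind(ctr[1] - yr, ctr[2] + xr)
}

# Random-walk centerline whose heading noise is tuned by bisection so the
# realized straightness lands near the requested target.
wiggle_polyline <- function(L_px, target, step, seed) {
  if (is.null(target)) target <- 0.9
  n <- max(8, ceiling(L_px / step))
  make <- function(sd) {
    with_seed(seed, {
      dh <- stats::rnorm(n - 1, sd = sd)
      dh <- stats::filter(dh, rep(1 / 9, 9), circular = TRUE)
      heading <- cumsum(c(0, as.numeric(dh)))
      heading <- heading - mean(heading)
      cbind(cumsum(c(0, step * cos(heading[-1]))),
            cumsum(c(0, step * sin(heading[-1]))))
    })
  }
  meas <- function(xy) {
    sqrt(sum((xy[nrow(xy), ] - xy[1, ])^2)) / polyline_length(xy)
  }
  lo <- 0; hi <- 2
  for (it in 1:40) {
    mid <- (lo + hi) / 2
    if (meas(make(mid)) > target) lo <- mid else hi <- mid
  }
  make((lo + hi) / 2)
}

polyline_length <- function(pts) {
  sum(sqrt(rowSums(diff(pts)^2)))
}

# Binary stamp of a constant-width curve: pixel centers strictly closer
# than width/2 to the sampled centerline.  For even pixel widths the
# centerline is shifted by half a pixel so an axis-aligned fiber covers
# exactly `width` rows/columns.
stamp_curve <- function(shape, pts, w_px) {
  if (round(w_px) %% 2 == 0) pts <- pts + 0.5
  half <- w_px / 2
  rmin <- max(1L, floor(min(pts[, 1]) - half - 1))
  rmax <- min(shape[1], ceiling(max(pts[, 1]) + half + 1))
  cmin <- max(1L, floor(min(pts[, 2]) - half - 1))
  cmax <- min(shape[2], ceiling(max(pts[, 2]) + half + 1))
  rows <- rmin:rmax; cols <- cmin:cmax
  grid <- cbind(rep(rows, times = length(cols)),
                rep(cols, each = length(rows)))
  dmin <- rep(Inf, nrow(grid))
  chunk <- 500L
  for (j in seq(1, nrow(pts), by = chunk)) {
    jj <- j:min(j + chunk - 1L, nrow(pts))
    d2 <- outer(grid[, 1], pts[jj, 1], "-")^2 +
      outer(grid[, 2], pts[jj, 2], "-")^2
    dmin <- pmin(dmin, sqrt(do.call(pmin, as.data.frame(d2))))
  }
  mask <- matrix(FALSE, shape[1], shape[2])
  mask[grid[dmin < half, , drop = FALSE]] <- TRUE
  mask
}
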