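# Canonical in-memory containers for SHG acquisition geometries.
#
# Frames are numeric matrices (row 1 = top of image, columns = x axis).
# Polarization angle 0 deg is parallel to the image x axis, increasing
# counterclockwise.  Angles are stored in degrees; computation elsewhere
# converts to radians.

#' Polarization-resolved SHG image stack
#'
#' Bundles one frame per excitation linear-polarization angle together with
#' the acquisition metadata every downstream analysis needs.  This is the
#' input container for [fit_pshg()] (channel `"total"`) and, tagged with
#' channel `"parallel"`/`"perpendicular"`, for [anisotropy_curve()].
#'
#' @param frames list of numeric matrices, one per angle, all the same
#'   dimensions, all intensities nonnegative (photon-count scale).
#' @param angles_deg numeric vector of excitation polarization angles in
#'   degrees, strictly increasing, each in `[0, 180]` (the SHG response has
#'   180-degree periodicity; a sweep may or may not include both
#'   endpoints).
#' @param channel analyzer channel: `"total"`, `"parallel"` or
#'   `"perpendicular"`.
#' @param pixel_size_um pixel size in micrometres (> 0).
#' @param wavelength_nm excitation wavelength in nanometres (informational).
#' @return An object of class `"pol_stack"`.
#' @seealso [gen_pshg_stack()], [read_stack()], [fit_pshg()]
#' @export
pol_stack <- function(frames, angles_deg, channel = "total",
                      pixel_size_um = 0.332, wavelength_nm = 890) {
  frames <- check_frames(frames)
  angles_deg <- as.numeric(angles_deg)
  if (length(frames) != length(angles_deg))
    stop("number of frames (", length(frames),
         ") does not match number of angles (", length(angles_deg), ")")
  if (any(diff(angles_deg) <= 0))
    stop("angles_deg must be strictly increasing")
  if (any(angles_deg < 0 | angles_deg > 180))
    stop("angles_deg must lie in [0, 180] (the response is 180-periodic)")
  channel <- match.arg(channel, c("total", "parallel", "perpendicular"))
  if (!is.numeric(pixel_size_um) || length(pixel_size_um) != 1 ||
      pixel_size_um <= 0)
    stop("pixel_size_um must be a positive scalar")
  structure(
    list(frames = frames, angles_deg = angles_deg, channel = channel,
         pixel_size_um = pixel_size_um, wavelength_nm = wavelength_nm),
    class = "pol_stack")
}

#' LHCP/RHCP circular-polarization image pair
#'
#' Co-registered SHG images acquired under left- and right-handed circularly
#' polarized excitation; the input to [cd_field()].
#'
#' @param lhcp,rhcp numeric matrices of identical dimensions, nonnegative.
#' @param pixel_size_um pixel size in micrometres (> 0).
#' @return An object of class `"chiral_pair"`.
#' @export
chiral_pair <- function(lhcp, rhcp, pixel_size_um = 0.166) {
  lhcp <- check_frame(lhcp, "lhcp")
  rhcp <- check_frame(rhcp, "rhcp")
  if (!identical(dim(lhcp), dim(rhcp)))
    stop("lhcp and rhcp must have identical dimensions")
  if (!is.numeric(pixel_size_um) || pixel_size_um <= 0)
    stop("pixel_size_um must be a positive scalar")
  structure(list(lhcp = lhcp, rhcp = rhcp, pixel_size_um = pixel_size_um),
            class = "chiral_pair")
}

#' Depth (z) series of SHG optical sections
#'
#' Equally spaced optical sections through a sample, ordered by increasing
#' depth; the input to [depth_profile()].
#'
#' @param sections list of numeric matrices (>= 3), identical dimensions,
#'   nonnegative intensities, ordered from shallowest to deepest.
#' @param z_step_um section spacing in micrometres (> 0).
#' @param z0_um depth of the first section in micrometres.
#' @param pixel_size_um pixel size in micrometres (> 0).
#' @return An object of class `"depth_series"`.
#' @export
depth_series <- function(sections, z_step_um, z0_um = 0,
                         pixel_size_um = 0.332) {
  sections <- check_frames(sections)
  if (length(sections) < 3)
    stop("a depth series needs at least 3 sections")
  if (!is.numeric(z_step_um) || length(z_step_um) != 1 || z_step_um <= 0)
    stop("z_step_um must be a positive scalar")
  structure(
    list(sections = sections, z_step_um = as.numeric(z_step_um),
         z0_um = as.numeric(z0_um), pixel_size_um = pixel_size_um),
    class = "depth_series")
}

#' @export
depths_um <- function(series) {
  stopifnot(inherits(series, "depth_series"))
  series$z0_um + series$z_step_um * (seq_along(series$sections) - 1)
}

check_frame <- function(m, what = "frame") {
  if (is.null(dim(m)) || length(dim(m)) != 2)
    stop(what, " must be a 2D matrix")
  m <- as.matrix(m)
  storage.mode(m) <- "double"
  if (anyNA(m)) stop(what, " contains NA values")
  if (any(m < 0)) stop(what, " contains negative intensities")
  m
}

check_frames <- function(frames) {
  if (is.array(frames) && length(dim(frames)) == 3)
    frames <- lapply(seq_len(dim(frames)[3]), function(i) frames[, , i])
  if (!is.list(frames) || length(frames) == 0)
    stop("frames must be a nonempty list of matrices")
  frames <- lapply(frames, check_frame)
  d <- dim(frames[[1]])
  ok <- vapply(frames, function(f) identical(dim(f), d), logical(1))
  if (!all(ok)) stop("all frames must share the same dimensions")
  frames
}

#' @export
print.pol_stack <- function(x, ...) {
  d <- dim(x$frames[[1]])
  cat("Polarization-resolved SHG stack (", x$channel, " channel)\n", sep = "")
  cat("  ", length(x$frames), " frames of ", d[1], " x ", d[2], " px, ",
      x$pixel_size_um, " um/px\n", sep = "")
  cat("  angles [deg]: ", paste(x$angles_deg, collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' @export
print.chiral_pair <- function(x, ...) {
  d <- dim(x$lhcp)
  cat("SHG circular-polarization pair (LHCP/RHCP), ",
      d[1], " x ", d[2], " px, ", x$pixel_size_um, " um/px\n", sep = "")
  invisible(x)
}

#' @export
print.depth_series <- function(x, ...) {
  d <- dim(x$sections[[1]])
  z <- depths_um(x)
  cat("SHG depth series: ", length(x$sections), " sections of ",
      d[1], " x ", d[2], " px, z = ", z[1], " .. ", z[length(z)],
      " um (step ", x$z_step_um, " um)\n", sep = "")
  invisible(x)
}
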