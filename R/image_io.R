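# On-disk layout: multi-page grayscale TIFF + YAML sidecar.
#
# The tiff package stores samples in [0, 1]; intensities are therefore
# divided by `intensity_scale` (recorded in the sidecar) before writing.
# Integer-valued stacks with counts <= 65535 are written as 16-bit unsigned
# with scale 65535, which round-trips bit-exactly; anything else is written
# as 32-bit float scaled by the stack maximum (round-trips to single
# precision, ~1e-7 relative).

#' Read an image stack and its metadata sidecar
#'
#' Reads a multi-page grayscale TIFF together with a YAML sidecar describing
#' the acquisition geometry and returns the corresponding typed container:
#' a [pol_stack()] (`kind: pshg`), a [chiral_pair()] (`kind: chiral`) or a
#' [depth_series()] (`kind: depth`).
#'
#' The sidecar schema (one file covers all three kinds):
#' \preformatted{
#' kind: pshg | chiral | depth
#' intensity_scale: <number the stored samples are multiplied by>
#' pixel_size_um: <number>
#' angles_deg: [0, 10, ...]        # pshg only
#' channel: total|parallel|perpendicular   # pshg only
#' wavelength_nm: <number>         # pshg only, informational
#' z_step_um: <number>             # depth only
#' z0_um: <number>                 # depth only
#' }
#'
#' @param path path to a multi-page TIFF.
#' @param sidecar path to the YAML sidecar; defaults to `path` with the
#'   extension replaced by `.yml`.
#' @return A `pol_stack`, `chiral_pair` or `depth_series`, validated against
#'   the sidecar (frame count must match the declared angle list, a chiral
#'   pair must have exactly two pages, ...).
#' @export
read_stack <- function(path, sidecar = default_sidecar(path)) {
  if (!file.exists(path)) stop("no such file: ", path)
  if (!file.exists(sidecar)) stop("no such sidecar: ", sidecar)
  meta <- yaml::read_yaml(sidecar)
  if (is.null(meta$kind))
    stop("sidecar is missing the 'kind' field: ", sidecar)
  scale <- if (is.null(meta$intensity_scale)) 1 else
    as.numeric(meta$intensity_scale)
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  pages <- lapply(pages, function(p) {
    if (length(dim(p)) == 3) p <- p[, , 1]  # tolerate grayscale-as-RGB
    p * scale
  })
  px <- if (is.null(meta$pixel_size_um)) 1 else as.numeric(meta$pixel_size_um)
  switch(as.character(meta$kind),
    pshg = {
      ang <- as.numeric(meta$angles_deg)
      if (length(pages) != length(ang))
        stop("frame count (", length(pages),
             ") does not match sidecar angle list (", length(ang), ")")
      pol_stack(pages, ang,
                channel = if (is.null(meta$channel)) "total" else meta$channel,
                pixel_size_um = px,
                wavelength_nm = if (is.null(meta$wavelength_nm)) NA_real_
                                else as.numeric(meta$wavelength_nm))
    },
    chiral = {
      if (length(pages) != 2)
        stop("a chiral pair must have exactly 2 pages, found ", length(pages))
      chiral_pair(pages[[1]], pages[[2]], pixel_size_um = px)
    },
    depth = {
      if (is.null(meta$z_step_um)) stop("depth sidecar is missing z_step_um")
      depth_series(pages, z_step_um = as.numeric(meta$z_step_um),
                   z0_um = if (is.null(meta$z0_um)) 0
                           else as.numeric(meta$z0_um),
                   pixel_size_um = px)
    },
    stop("unknown stack kind in sidecar: ", meta$kind))
}

#' Write an image stack and its metadata sidecar
#'
#' Inverse of [read_stack()]: writes the frames as a multi-page grayscale
#' TIFF and the acquisition metadata as a YAML sidecar.  Integer-valued
#' stacks (counts <= 65535) round-trip bit-exactly through 16-bit storage;
#' other stacks round-trip to single-float precision.
#'
#' @param stack a `pol_stack`, `chiral_pair` or `depth_series`.
#' @param path output TIFF path.
#' @param sidecar output sidecar path; defaults to `path` with extension
#'   `.yml`.
#' @return Invisibly, `path`.
#' @export
write_stack <- function(stack, path, sidecar = default_sidecar(path)) {
  UseMethod("write_stack")
}

#' @export
write_stack.pol_stack <- function(stack, path,
                                  sidecar = default_sidecar(path)) {
  meta <- list(kind = "pshg", angles_deg = stack$angles_deg,
               channel = stack$channel, pixel_size_um = stack$pixel_size_um,
               wavelength_nm = stack$wavelength_nm)
  write_pages(stack$frames, path, sidecar, meta)
}

#' @export
write_stack.chiral_pair <- function(stack, path,
                                    sidecar = default_sidecar(path)) {
  meta <- list(kind = "chiral", pixel_size_um = stack$pixel_size_um)
  write_pages(list(stack$lhcp, stack$rhcp), path, sidecar, meta)
}

#' @export
write_stack.depth_series <- function(stack, path,
                                     sidecar = default_sidecar(path)) {
  meta <- list(kind = "depth", z_step_um = stack$z_step_um,
               z0_um = stack$z0_um, pixel_size_um = stack$pixel_size_um)
  write_pages(stack$sections, path, sidecar, meta)
}

default_sidecar <- function(path) sub("\\.[^.]+$", ".yml", path)

write_pages <- function(frames, path, sidecar, meta) {
  mx <- max(vapply(frames, max, numeric(1)), 0)
  integerish <- all(vapply(frames, function(f)
    all(f == round(f)), logical(1))) && mx <= 65535
  if (integerish) {
    scale <- 65535
    bits <- 16L
  } else {
    scale <- if (mx > 0) mx else 1
    bits <- 32L
  }
  ok <- try(tiff::writeTIFF(lapply(frames, function(f) f / scale), path,
                            bits.per.sample = bits, reduce = FALSE),
            silent = TRUE)
  if (inherits(ok, "try-error"))
    stop("could not write TIFF to ", path, ": ", attr(ok, "condition")$message)
  meta$intensity_scale <- scale
  yaml::write_yaml(meta, sidecar)
  invisible(path)
}
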