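# Per-fiber morphology from 2D SHG images: ridge enhancement, hysteresis
# binarization, skeletonization, branch decomposition, then per-branch
# length / width / straightness.
#
# Pipeline: large-kernel median background subtraction -> multiscale
# second-derivative ridge enhancement (magnitude of the most negative
# Hessian eigenvalue of the smoothed intensity surface, scale-normalized,
# max over scales) -> hysteresis binarization (8-connected growth from the
# high-threshold seeds) -> morphological thinning (Zhang-Suen) -> split at
# junction pixels (>= 3 skeleton neighbors) -> each remaining branch is one
# fiber candidate; branches shorter than min_length_um are pruned.
# Centerlines are smoothed with a short moving average before arc-length
# computation to avoid staircase length inflation on diagonal chains, and
# width comes from the distance transform of the hysteresis mask sampled
# along the middle 80% of the centerline.

#' Extract fibers from a 2D SHG intensity image
#'
#' @param image numeric matrix of nonnegative intensities.
#' @param pixel_size_um pixel size, um.
#' @param scales_px Gaussian smoothing scales (px) for the multiscale ridge
#'   filter; should bracket half the expected fiber widths.
#' @param high_frac,low_frac hysteresis thresholds as fractions of the
#'   maximum ridge response.
#' @param min_length_um minimum centerline arc length for a branch to be
#'   reported.
#' @param bg_radius_px radius of the median background filter;
#'   `NULL` disables background subtraction.
#' @return An object of class `"fiber_set"`: `fibers` (data.frame with
#'   `id`, `length_um`, `width_um`, `straightness`), `centerlines` (list
#'   of n x 2 (row, col) matrices, sub-pixel), `mask` (hysteresis mask)
#'   and `pixel_size_um`.  A blank image yields zero fibers (not an
#'   error).
#' @seealso [fiber_summary()], [gen_fiber_phantom()]
#' @export
extract_fibers <- function(image, pixel_size_um = 0.332,
                           scales_px = c(1, 2, 3), high_frac = 0.3,
                           low_frac = 0.1, min_length_um = 5,
                           bg_radius_px = 10) {
  image <- check_frame(image, "image")
  empty <- structure(
    list(fibers = data.frame(id = integer(), length_um = numeric(),
                             width_um = numeric(),
                             straightness = numeric()),
         centerlines = list(), mask = image > Inf,
         pixel_size_um = pixel_size_um),
    class = "fiber_set")
  if (max(image) <= 0) return(empty)
  img <- image / max(image)
  if (!is.null(bg_radius_px) && bg_radius_px >= 1 &&
      min(dim(img)) > 2 * bg_radius_px + 1) {
    bg <- as.matrix(EBImage::medianFilter(img, as.integer(bg_radius_px)))
    img <- pmax(img - bg, 0)
    if (max(img) <= 0) return(empty)
  }
  resp <- ridge_response(img, scales_px)
  if (max(resp) <= 0) return(empty)
  mask <- hysteresis_mask(resp, high_frac * max(resp),
                          low_frac * max(resp))
  if (!any(mask)) return(empty)
  skel <- thin_binary(mask)
  chains <- skeleton_branches(skel)
  if (length(chains) == 0) return(empty)
  # width is measured on a per-branch half-maximum intensity mask (the
  # FWHM of a blurred bar profile matches its true width, while the
  # hysteresis mask is deliberately permissive and runs wide)
  smw <- as.matrix(EBImage::gblur(img, sigma = 1))
  recs <- list(); lines <- list(); id <- 0L
  for (ch in chains) {
    if (nrow(ch) < 2) next
    sm <- smooth_chain(ch, window = 5)
    arc_px <- polyline_length(sm)
    len_um <- arc_px * pixel_size_um
    if (arc_px <= 0 || len_um < min_length_um) next
    chord_px <- sqrt(sum((sm[nrow(sm), ] - sm[1, ])^2))
    straight <- min(chord_px / arc_px, 1)
    n <- nrow(ch)
    mid <- unique(pmin(pmax(seq(ceiling(0.1 * n), floor(0.9 * n)), 1), n))
    if (length(mid) == 0) mid <- seq_len(n)
    half_max <- 0.5 * mean(smw[ch[mid, , drop = FALSE]])
    dmap <- as.matrix(EBImage::distmap((smw >= half_max) * 1))
    w_px <- 2 * mean(dmap[ch[mid, , drop = FALSE]]) - 0.5
    id <- id + 1L
    recs[[id]] <- data.frame(id = id, length_um = len_um,
                             width_um = max(w_px, 0.5) * pixel_size_um,
                             straightness = straight)
    lines[[id]] <- sm
  }
  if (id == 0L) return(empty)
  structure(list(fibers = do.call(rbind, recs), centerlines = lines,
                 mask = mask, pixel_size_um = pixel_size_um),
            class = "fiber_set")
}

#' Summary statistics over a set of extracted fibers
#'
#' Arithmetic mean and standard error of straightness, length and width
#' across fibers, the per-image quantities used for group comparison.
#'
#' @param x a `"fiber_set"` or a data.frame with columns `length_um`,
#'   `width_um`, `straightness`.
#' @return A data.frame with one row per metric: `metric`, `mean`, `sem`
#'   (`NA` for a single fiber), `n`.  Zero rows of input give a zero-`n`
#'   summary with `NA` means.
#' @export
fiber_summary <- function(x) {
  df <- if (inherits(x, "fiber_set")) x$fibers else as.data.frame(x)
  metrics <- c("straightness", "length_um", "width_um")
  n <- nrow(df)
  out <- lapply(metrics, function(m) {
    v <- df[[m]]
    data.frame(metric = m,
               mean = if (n > 0) mean(v) else NA_real_,
               sem = if (n > 1) stats::sd(v) / sqrt(n) else NA_real_,
               n = n)
  })
  do.call(rbind, out)
}

#' @export
print.fiber_set <- function(x, ...) {
  cat("Fiber set:", nrow(x$fibers), "fibers\n")
  if (nrow(x$fibers) > 0) print(fiber_summary(x), row.names = FALSE)
  invisible(x)
}

#' @export
plot.fiber_set <- function(x, image = NULL, ...) {
  d <- dim(x$mask)
  if (!is.null(image))
    graphics::image(t(image[d[1]:1, ]), col = grDevices::gray.colors(64),
                    axes = FALSE, useRaster = TRUE, ...)
  else
    graphics::image(t(x$mask[d[1]:1, ] * 1),
                    col = grDevices::gray.colors(2), axes = FALSE,
                    useRaster = TRUE, ...)
  for (ch in x$centerlines)
    graphics::lines((ch[, 2] - 0.5) / d[2], 1 - (ch[, 1] - 0.5) / d[1],
                    col = "red")
  invisible(x)
}

# --- internals -------------------------------------------------------------

# Shift a matrix by (dr, dc) with replicated borders.
shift_mat <- function(m, dr, dc) {
  nr <- nrow(m); nc <- ncol(m)
  ri <- pmin(pmax(seq_len(nr) - dr, 1), nr)
  ci <- pmin(pmax(seq_len(nc) - dc, 1), nc)
  m[ri, ci, drop = FALSE]
}

# Scale-normalized principal-curvature ridge response, max over scales.
ridge_response <- function(img, scales_px) {
  resp <- matrix(0, nrow(img), ncol(img))
  for (s in scales_px) {
    sm <- as.matrix(EBImage::gblur(img, sigma = s))
    ixx <- shift_mat(sm, 0, 1) + shift_mat(sm, 0, -1) - 2 * sm
    iyy <- shift_mat(sm, 1, 0) + shift_mat(sm, -1, 0) - 2 * sm
    ixy <- (shift_mat(sm, 1, 1) + shift_mat(sm, -1, -1) -
            shift_mat(sm, 1, -1) - shift_mat(sm, -1, 1)) / 4
    eigmin <- 0.5 * ((ixx + iyy) - sqrt((ixx - iyy)^2 + 4 * ixy^2))
    resp <- pmax(resp, pmax(-eigmin, 0) * s^2)
  }
  resp
}

# Hysteresis: 8-connected growth of the high-threshold seeds through the
# low-threshold mask.
hysteresis_mask <- function(resp, high, low) {
  lowm <- resp >= low
  mask <- resp >= high
  if (!any(mask)) return(mask)
  brush <- matrix(1, 3, 3)
  repeat {
    grown <- as.matrix(EBImage::dilate(mask * 1, brush)) > 0 & lowm
    if (sum(grown) == sum(mask)) break
    mask <- grown
  }
  mask
}

# Zhang-Suen morphological thinning to a 1-px-wide 8-connected skeleton.
thin_binary <- function(mask) {
  M <- mask
  neighbors <- function(M) {
    list(p2 = shift_mat(M, -1, 0), p3 = shift_mat(M, -1, 1),
         p4 = shift_mat(M, 0, 1),  p5 = shift_mat(M, 1, 1),
         p6 = shift_mat(M, 1, 0),  p7 = shift_mat(M, 1, -1),
         p8 = shift_mat(M, 0, -1), p9 = shift_mat(M, -1, -1))
  }
  # zero out the replicated border contribution by padding
  pad <- function(M) rbind(FALSE, cbind(FALSE, M, FALSE), FALSE)
  unpad <- function(M) M[2:(nrow(M) - 1), 2:(ncol(M) - 1), drop = FALSE]
  M <- pad(M)
  repeat {
    changed <- FALSE
    for (step in 1:2) {
      nb <- neighbors(M)
      B <- Reduce(`+`, nb)
      seqn <- with(nb, list(p2, p3, p4, p5, p6, p7, p8, p9, p2))
      A <- Reduce(`+`, lapply(1:8, function(i)
        (!seqn[[i]]) & seqn[[i + 1]]))
      cond <- M & B >= 2 & B <= 6 & A == 1
      cond <- cond & if (step == 1)
        with(nb, !(p2 & p4 & p6) & !(p4 & p6 & p8))
      else
        with(nb, !(p2 & p4 & p8) & !(p2 & p6 & p8))
      if (any(cond)) {
        M[cond] <- FALSE
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  unpad(M)
}

# Decompose a skeleton into simple branches.  Junction pixels are those
# whose crossing number (0->1 transitions around the 8-neighborhood) is
# >= 3 -- a plain neighbor count misclassifies diagonal staircase pixels,
# whose neighbors touch each other.  Junctions are removed and each
# remaining 8-connected chain is traced from an endpoint into an ordered
# pixel list.
skeleton_branches <- function(skel) {
  shifts <- list(c(-1, 0), c(-1, 1), c(0, 1), c(1, 1),
                 c(1, 0), c(1, -1), c(0, -1), c(-1, -1))
  nb <- lapply(shifts, function(d) shift_mat_zero(skel, d[1], d[2]))
  ring <- c(nb, nb[1])
  crossings <- Reduce(`+`, lapply(1:8, function(i)
    (!ring[[i]]) & ring[[i + 1]]))
  chains_mask <- skel & crossings < 3
  px <- which(chains_mask, arr.ind = TRUE)
  if (nrow(px) == 0) return(list())
  nr <- nrow(skel)
  key <- function(r, c) (c - 1L) * nr + r
  inchain <- logical(nr * ncol(skel))
  inchain[key(px[, 1], px[, 2])] <- TRUE
  visited <- logical(nr * ncol(skel))
  offs <- expand.grid(dr = -1:1, dc = -1:1)
  offs <- offs[!(offs$dr == 0 & offs$dc == 0), ]
  chain_nb <- function(r, c) {
    rr <- r + offs$dr; cc <- c + offs$dc
    ok <- rr >= 1 & rr <= nr & cc >= 1 & cc <= ncol(skel)
    rr <- rr[ok]; cc <- cc[ok]
    k <- key(rr, cc)
    sel <- inchain[k] & !visited[k]
    cbind(rr[sel], cc[sel])
  }
  degree <- function(r, c) {
    rr <- r + offs$dr; cc <- c + offs$dc
    ok <- rr >= 1 & rr <= nr & cc >= 1 & cc <= ncol(skel)
    sum(inchain[key(rr[ok], cc[ok])])
  }
  deg <- apply(px, 1, function(p) degree(p[1], p[2]))
  out <- list()
  trace_from <- function(r, c) {
    path <- matrix(NA_real_, 0, 2)
    repeat {
      visited[key(r, c)] <<- TRUE
      path <- rbind(path, c(r, c))
      nxt <- chain_nb(r, c)
      if (nrow(nxt) == 0) break
      # prefer 4-connected continuation to avoid skipping chain pixels
      d <- abs(nxt[, 1] - r) + abs(nxt[, 2] - c)
      i <- which.min(d)
      r <- nxt[i, 1]; c <- nxt[i, 2]
    }
    path
  }
  ends_first <- order(deg)  # endpoints (degree <= 1) traced first
  for (i in ends_first) {
    k <- key(px[i, 1], px[i, 2])
    if (visited[k]) next
    out[[length(out) + 1L]] <- trace_from(px[i, 1], px[i, 2])
  }
  out
}

# Zero-padded shift (no replication), for neighbor counting.
shift_mat_zero <- function(m, dr, dc) {
  nr <- nrow(m); nc <- ncol(m)
  out <- matrix(FALSE, nr, nc)
  rs <- max(1, 1 + dr):min(nr, nr + dr)
  cs <- max(1, 1 + dc):min(nc, nc + dc)
  out[rs, cs] <- m[rs - dr, cs - dc]
  out
}

# Centered moving average with truncated windows at the ends (keeps the
# chain endpoints close to their pixel positions).
smooth_chain <- function(ch, window = 5) {
  n <- nrow(ch)
  if (n <= 2 || window <= 1) return(ch)
  h <- floor(window / 2)
  sm <- ch
  for (j in 1:2) {
    cs <- cumsum(c(0, ch[, j]))
    lo <- pmax(seq_len(n) - h, 1)
    hi <- pmin(seq_len(n) + h, n)
    sm[, j] <- (cs[hi + 1] - cs[lo]) / (hi - lo + 1)
  }
  sm
}
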