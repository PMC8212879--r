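# Forward models with known ground truth for every acquisition geometry the
# analysis modules consume.  All generators are deterministic given
# scene$seed; noise is applied to the noise-free expectation as the last
# step (Poisson on expected counts emulates a photon-counting detector;
# additive Gaussian is available for read-noise studies).

#' Describe a synthetic SHG scene
#'
#' Collects the ground-truth parameters of a simulated acquisition.  The
#' defaults describe a typical cleared-collagen acquisition: tensor ratio
#' b = 2 (pitch angle 45 degrees), peak signal of 1000 counts (photon-count
#' scale) and Poisson noise.
#'
#' @param b_true chi(2) tensor ratio chi_ZZZ/chi_ZXX (> 0); scalar or a
#'   matrix (per-pixel map) matching `dim`.
#' @param phi_deg fiber in-plane orientation in `[0, 180)`; scalar or matrix.
#' @param amplitude peak signal scale A (> 0), counts.
#' @param offset additive background c (>= 0), counts.
#' @param noise `"none"`, `"poisson"` or `"gaussian"`.
#' @param noise_sd standard deviation of the Gaussian noise model, counts.
#' @param seed integer RNG seed; identical seed and parameters give
#'   bit-identical output.
#' @param beta_true SHG signal anisotropy used when splitting the total
#'   intensity into parallel/perpendicular channels, in `[-0.5, 1]`.
#' @param cd_epsilon fractional LHCP/RHCP asymmetry in `[0, 2)`.
#' @param mu_atten_per_um depth-attenuation coefficient (>= 0), 1/um.
#' @param dim image dimensions `c(rows, cols)`.
#' @param pixel_size_um pixel size, um.
#' @param fiber_spec list of fiber descriptions for [gen_fiber_phantom()];
#'   each element is a list with `shape` (`"segment"`, `"arc"` or
#'   `"wiggle"`), `length_um`, `width_um`, `orientation_deg` and optionally
#'   `arc_angle_deg` (arcs, default 180), `straightness` (wiggle target) and
#'   `center_px` (c(row, col)).
#' @return An object of class `"synthetic_scene"`.
#' @export
synthetic_scene <- function(b_true = 2, phi_deg = 30, amplitude = 1000,
                            offset = 0, noise = c("poisson", "none",
                                                  "gaussian"),
                            noise_sd = 10, seed = 1L, beta_true = 0.5,
                            cd_epsilon = 0.2, mu_atten_per_um = 0.01,
                            dim = c(64, 64), pixel_size_um = 0.332,
                            fiber_spec = list()) {
  noise <- match.arg(noise)
  if (any(b_true <= 0)) stop("b_true must be positive")
  if (any(phi_deg < 0 | phi_deg >= 180))
    stop("phi_deg must lie in [0, 180)")
  if (any(amplitude <= 0)) stop("amplitude must be positive")
  if (any(offset < 0)) stop("offset must be nonnegative")
  if (beta_true < -0.5 || beta_true > 1)
    stop("beta_true must lie in [-0.5, 1]")
  if (cd_epsilon < 0 || cd_epsilon >= 2)
    stop("cd_epsilon must lie in [0, 2): values >= 2 would force a ",
         "negative RHCP intensity")
  if (mu_atten_per_um < 0) stop("mu_atten_per_um must be nonnegative")
  structure(
    list(b_true = b_true, phi_deg = phi_deg, amplitude = amplitude,
         offset = offset, noise = noise, noise_sd = noise_sd,
         seed = as.integer(seed), beta_true = beta_true,
         cd_epsilon = cd_epsilon, mu_atten_per_um = mu_atten_per_um,
         dim = as.integer(dim), pixel_size_um = pixel_size_um,
         fiber_spec = fiber_spec),
    class = "synthetic_scene")
}

#' @export
print.synthetic_scene <- function(x, ...) {
  cat("Synthetic SHG scene: b =", format(mean(x$b_true)),
      " phi =", format(mean(x$phi_deg)), "deg  A =", x$amplitude,
      " noise =", x$noise, " seed =", x$seed, "\n")
  invisible(x)
}

# Evaluate code with a temporary RNG state seeded from `seed`, restoring the
# caller's stream afterwards.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (had) assign(".Random.seed", old, envir = globalenv())
          else if (exists(".Random.seed", envir = globalenv(),
                          inherits = FALSE))
            rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  force(code)
}

apply_noise <- function(frames, scene, substream = 0L) {
  if (scene$noise == "none") return(frames)
  with_seed(scene$seed + substream, {
    lapply(frames, function(f) {
      out <- switch(scene$noise,
        poisson = matrix(stats::rpois(length(f), lambda = f), nrow(f)),
        gaussian = f + matrix(stats::rnorm(length(f), sd = scene$noise_sd),
                              nrow(f)))
      out[out < 0] <- 0
      out
    })
  })
}

as_map <- function(x, dim) {
  if (is.matrix(x)) {
    if (!identical(base::dim(x), as.integer(dim)))
      stop("parameter map dimensions do not match scene dim")
    x
  } else matrix(x, dim[1], dim[2])
}

#' Angular intensity of the cylindrically symmetric P-SHG model
#'
#' The single-curve forward model fitted per pixel by [fit_pshg()]:
#' \deqn{I(\theta) = A\{\sin^2[2(\theta-\varphi)] +
#'   [\sin^2(\theta-\varphi) + b\cos^2(\theta-\varphi)]^2\} + c}
#' the C-infinity-v (single filament axis) form under Kleinman symmetry,
#' parameterized by the tensor ratio `b = chi_ZZZ/chi_ZXX`, the in-plane
#' fiber orientation `phi`, an amplitude `A` and an additive offset `c`.
#'
#' @param theta_deg excitation polarization angle(s), degrees.
#' @param b tensor ratio (> 0).
#' @param phi_deg fiber in-plane orientation, degrees.
#' @param amplitude amplitude A.
#' @param offset additive offset c.
#' @return Intensities, recycled over the longest argument.
#' @export
pshg_model <- function(theta_deg, b, phi_deg, amplitude = 1, offset = 0) {
  u <- (theta_deg - phi_deg) * pi / 180
  s <- sin(u)^2
  amplitude * (sin(2 * u)^2 + (s + b * (1 - s))^2) + offset
}

#' Generate a polarization-resolved SHG stack
#'
#' Evaluates the P-SHG forward model ([pshg_model()]) at each pixel and
#' angle, then applies the scene's noise model.
#'
#' @param scene a [synthetic_scene()].
#' @param angles_deg excitation angles, degrees (>= 5 distinct values);
#'   default 0 to 170 in 10-degree steps, emulating acquisition every
#'   10 degrees through the 180-degree period.
#' @return A [pol_stack()] with channel `"total"`.
#' @export
gen_pshg_stack <- function(scene, angles_deg = seq(0, 170, by = 10)) {
  stopifnot(inherits(scene, "synthetic_scene"))
  if (length(angles_deg) < 5) stop("need at least 5 angles")
  b <- as_map(scene$b_true, scene$dim)
  phi <- as_map(scene$phi_deg, scene$dim)
  A <- as_map(scene$amplitude, scene$dim)
  cc <- as_map(scene$offset, scene$dim)
  frames <- lapply(angles_deg, function(th) pshg_model(th, b, phi, A, cc))
  pol_stack(apply_noise(frames, scene, 101L), angles_deg,
            channel = "total", pixel_size_um = scene$pixel_size_um)
}

#' Generate parallel/perpendicular analyzed channels
#'
#' Splits the total-intensity forward model into analyzed channels so that
#' the noise-free anisotropy `(IPar - IPerp)/(IPar + 2 IPerp)` equals
#' `scene$beta_true` exactly at every pixel and angle:
#' `IPar = T (1 + 2 beta)/(2 + beta)` and `IPerp = T (1 - beta)/(2 + beta)`
#' with `T = IPar + IPerp` the total intensity.
#'
#' @inheritParams gen_pshg_stack
#' @return A list with elements `par` and `perp`, both [pol_stack()]s.
#' @export
gen_polarimetric_channels <- function(scene,
                                      angles_deg = seq(0, 170, by = 10)) {
  stopifnot(inherits(scene, "synthetic_scene"))
  beta <- scene$beta_true
  if (beta < -0.5 || beta > 1) stop("beta_true must lie in [-0.5, 1]")
  b <- as_map(scene$b_true, scene$dim)
  phi <- as_map(scene$phi_deg, scene$dim)
  A <- as_map(scene$amplitude, scene$dim)
  cc <- as_map(scene$offset, scene$dim)
  par_frames <- list(); perp_frames <- list()
  for (i in seq_along(angles_deg)) {
    total <- pshg_model(angles_deg[i], b, phi, A, cc)
    par_frames[[i]] <- total * (1 + 2 * beta) / (2 + beta)
    perp_frames[[i]] <- total * (1 - beta) / (2 + beta)
  }
  list(par = pol_stack(apply_noise(par_frames, scene, 201L), angles_deg,
                       channel = "parallel",
                       pixel_size_um = scene$pixel_size_um),
       perp = pol_stack(apply_noise(perp_frames, scene, 202L), angles_deg,
                        channel = "perpendicular",
                        pixel_size_um = scene$pixel_size_um))
}

# Smooth blob field used as the base intensity pattern for chiral pairs and
# depth series: a handful of Gaussian spots over a near-zero background, so
# that background-threshold masking is well posed.
base_intensity_image <- function(scene, n_blobs = 6) {
  d <- scene$dim
  with_seed(scene$seed + 301L, {
    rows <- matrix(seq_len(d[1]), d[1], d[2])
    cols <- matrix(seq_len(d[2]), d[1], d[2], byrow = TRUE)
    img <- matrix(0, d[1], d[2])
    for (i in seq_len(n_blobs)) {
      r0 <- stats::runif(1, 0.15, 0.85) * d[1]
      c0 <- stats::runif(1, 0.15, 0.85) * d[2]
      sg <- stats::runif(1, 0.05, 0.15) * min(d)
      img <- img + exp(-((rows - r0)^2 + (cols - c0)^2) / (2 * sg^2))
    }
    img * (scene$amplitude / max(img)) + scene$offset
  })
}

#' Generate an LHCP/RHCP circular-polarization pair
#'
#' The asymmetry is injected multiplicatively and symmetrically,
#' `LHCP = base (1 + eps/2)` and `RHCP = base (1 - eps/2)`, so the
#' normalized circular-dichroism statistic of [cd_pixel()] equals
#' `scene$cd_epsilon` exactly at every pixel in the noise-free case.
#'
#' @param scene a [synthetic_scene()].
#' @param base optional base intensity image (matrix); by default a smooth
#'   blob field with near-zero background generated from the scene seed.
#' @return A [chiral_pair()].
#' @export
gen_chiral_pair <- function(scene, base = NULL) {
  stopifnot(inherits(scene, "synthetic_scene"))
  eps <- scene$cd_epsilon
  if (eps < 0 || eps >= 2) stop("cd_epsilon must lie in [0, 2)")
  if (is.null(base)) base <- base_intensity_image(scene)
  base <- check_frame(base, "base")
  frames <- apply_noise(list(base * (1 + eps / 2), base * (1 - eps / 2)),
                        scene, 302L)
  chiral_pair(frames[[1]], frames[[2]],
              pixel_size_um = scene$pixel_size_um)
}

#' Generate a depth series with exponential attenuation
#'
#' Section means follow `I(z) = I(0) exp(-mu z)`; each section is the base
#' image scaled by the depth factor, with noise applied afterwards.
#'
#' @param scene a [synthetic_scene()]; `scene$mu_atten_per_um` is the
#'   attenuation coefficient.
#' @param n_sections number of sections (>= 3).
#' @param z_step_um section spacing, um.
#' @param base optional base intensity image; default as in
#'   [gen_chiral_pair()].
#' @return A [depth_series()].
#' @export
gen_depth_series <- function(scene, n_sections = 9, z_step_um = 10,
                             base = NULL) {
  stopifnot(inherits(scene, "synthetic_scene"))
  if (n_sections < 3) stop("n_sections must be at least 3")
  if (is.null(base)) base <- base_intensity_image(scene)
  base <- check_frame(base, "base")
  z <- z_step_um * (seq_len(n_sections) - 1)
  sections <- lapply(z, function(zz)
    base * exp(-scene$mu_atten_per_um * zz))
  depth_series(apply_noise(sections, scene, 303L), z_step_um = z_step_um,
               z0_um = 0, pixel_size_um = scene$pixel_size_um)
}
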