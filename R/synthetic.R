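#' Specify a synthetic membrane ensemble
#'
#' A `membrane_spec` fixes the ground-truth parameters of a surrogate NPT
#' membrane ensemble: the area expansion modulus K_A*, the tensionless mean
#' area A0*, the temperature, an optional lag-1 autocorrelation of the area
#' signal, and the geometry of the phosphorus head-group distribution
#' (peak-to-peak thickness d* and per-leaflet peak width). The defaults
#' describe a 400-lipid bilayer patch (200 phosphorus atoms per leaflet) at
#' 30 degrees C, the smallest of the 30/50/70 degrees C conditions the
#' pipeline is meant for.
#'
#' Because the fluctuation estimator of K_A depends only on the stationary
#' distribution of the area, the generator samples that distribution exactly
#' (Gaussian, optionally AR(1) with the same stationary variance) instead of
#' integrating any membrane dynamics.
#'
#' @param area_modulus Ground-truth K_A* in mN/m; positive.
#' @param area0 Ground-truth tensionless mean area A0* in nm2; positive.
#' @param temperature Absolute temperature in K; positive.
#' @param n_frames Number of frames to generate; positive integer.
#' @param rho Lag-1 autocorrelation of the area series, in `[0, 1)`.
#' @param thickness Ground-truth peak-to-peak bilayer thickness d* in nm.
#' @param peak_sigma Per-leaflet Gaussian width of the phosphorus z
#'   distribution in nm; `>= 0` and `< thickness` (0 gives exact point
#'   masses at the two leaflet positions).
#' @param n_phosphorus Number of phosphorus atoms per frame; at least 2.
#' @param seed Integer seed; the same spec and seed reproduce the output
#'   bit for bit.
#' @return An object of class `membrane_spec`.
#' @seealso [generate_area_series()], [generate_phosphorus_z()]
#' @export
#' @examples
#' spec <- membrane_spec(area_modulus = 240, area0 = 130,
#'                       temperature = 303.15, n_frames = 2000, seed = 7)
#' spec
membrane_spec <- function(area_modulus = 240, area0 = 130,
                          temperature = 303.15, n_frames = 20000L,
                          rho = 0, thickness = 3.8, peak_sigma = 0.35,
                          n_phosphorus = 400L, seed = 1L) {
  stopifnot(is.numeric(area_modulus), length(area_modulus) == 1L)
  if (!is.finite(area_modulus) || area_modulus <= 0) {
    stop("`area_modulus` must be a positive, finite K_A* (mN/m); ",
         "a zero modulus has no finite stationary variance", call. = FALSE)
  }
  if (!is.finite(area0) || area0 <= 0) {
    stop("`area0` must be positive (nm2)", call. = FALSE)
  }
  if (!is.finite(temperature) || temperature <= 0) {
    stop("`temperature` must be positive (K)", call. = FALSE)
  }
  if (n_frames < 1 || n_frames != floor(n_frames)) {
    stop("`n_frames` must be a positive integer", call. = FALSE)
  }
  if (!is.finite(rho) || rho < 0 || rho >= 1) {
    stop("`rho` must lie in [0, 1)", call. = FALSE)
  }
  if (!is.finite(thickness) || thickness <= 0) {
    stop("`thickness` must be positive (nm)", call. = FALSE)
  }
  if (!is.finite(peak_sigma) || peak_sigma < 0 || peak_sigma >= thickness) {
    stop("`peak_sigma` must satisfy 0 <= peak_sigma < thickness",
         call. = FALSE)
  }
  if (n_phosphorus < 2 || n_phosphorus != floor(n_phosphorus)) {
    stop("`n_phosphorus` must be an integer >= 2", call. = FALSE)
  }
  if (!is.numeric(seed) || length(seed) != 1L || seed != floor(seed)) {
    stop("`seed` must be a single integer", call. = FALSE)
  }
  structure(
    list(
      area_modulus = as.numeric(area_modulus),
      area0 = as.numeric(area0),
      temperature = as.numeric(temperature),
      n_frames = as.integer(n_frames),
      rho = as.numeric(rho),
      thickness = as.numeric(thickness),
      peak_sigma = as.numeric(peak_sigma),
      n_phosphorus = as.integer(n_phosphorus),
      seed = as.integer(seed)
    ),
    class = "membrane_spec"
  )
}

#' @export
print.membrane_spec <- function(x, ...) {
  cat(sprintf(
    paste0("membrane_spec: K_A* = %g mN/m, A0* = %g nm2, T = %g K, ",
           "d* = %g nm (sigma %g nm)\n  %d frames, rho = %g, %d P atoms, ",
           "seed %d\n"),
    x$area_modulus, x$area0, x$temperature, x$thickness, x$peak_sigma,
    x$n_frames, x$rho, x$n_phosphorus, x$seed
  ))
  invisible(x)
}

# Seed streams: the area series and the phosphorus coordinates use distinct
# seeds derived from spec$seed, so generating one never perturbs the other,
# and both are generated frame-sequentially so extending n_frames leaves the
# earlier frames bit-identical.
.area_seed <- function(seed) seed %% .Machine$integer.max
.coord_seed <- function(seed) (seed + 777767L) %% .Machine$integer.max

#' Generate a synthetic membrane area time series
#'
#' Draws the instantaneous projected area of a tensionless membrane from the
#' stationary distribution the fluctuation relation implies: Gaussian with
#' mean A0* and variance kB T A0* / K_A*. With `rho > 0` the series is a
#' stationary AR(1) process with that variance and lag-1 autocorrelation
#' `rho`, mimicking the frame-to-frame correlation of a real NPT trajectory.
#' Innovations are drawn frame by frame, so a spec that differs only in
#' `n_frames` reproduces the shorter series as a prefix.
#'
#' @param spec A [membrane_spec()].
#' @return An [area_series()] of `spec$n_frames` frames; times are frame
#'   indices starting at 1.
#' @export
#' @examples
#' s <- generate_area_series(membrane_spec(n_frames = 5000, seed = 1))
#' var(s$areas) # close to area_variance_nm4(240, 130, 303.15)
generate_area_series <- function(spec) {
  stopifnot(inherits(spec, "membrane_spec"))
  sd_st <- sqrt(area_variance_nm4(spec$area_modulus, spec$area0,
                                  spec$temperature))
  n <- spec$n_frames
  areas <- with_preserved_seed(.area_seed(spec$seed), {
    e <- stats::rnorm(n)
    if (spec$rho == 0) {
      spec$area0 + sd_st * e
    } else {
      x <- numeric(n)
      x[1] <- sd_st * e[1]
      if (n > 1) {
        innov_sd <- sd_st * sqrt(1 - spec$rho^2)
        x[-1] <- as.numeric(stats::filter(innov_sd * e[-1], spec$rho,
                                          method = "recursive",
                                          init = x[1]))
      }
      spec$area0 + x
    }
  })
  area_series(seq_len(n), areas, spec$temperature)
}

#' Generate synthetic per-frame phosphorus z coordinates
#'
#' Draws head-group phosphorus z positions from a symmetric two-component
#' Gaussian mixture with peaks at +/- d*/2 and width `peak_sigma`, the
#' bilayer midplane at z = 0. Each atom in each frame is assigned to a
#' leaflet with probability 1/2, so the expected leaflet occupancies are
#' equal. Frames are drawn sequentially (leaflet signs, then offsets), so
#' extending `n_frames` reproduces earlier frames exactly.
#'
#' @param spec A [membrane_spec()].
#' @param n_frames Number of frames to generate; defaults to `spec$n_frames`.
#' @return A data.frame with columns `frame`, `atom`, `z` (nm), ordered by
#'   frame then atom.
#' @export
#' @examples
#' z <- generate_phosphorus_z(membrane_spec(seed = 3), n_frames = 10)
#' range(z$z)
generate_phosphorus_z <- function(spec, n_frames = spec$n_frames) {
  stopifnot(inherits(spec, "membrane_spec"))
  if (n_frames < 1 || n_frames != floor(n_frames)) {
    stop("`n_frames` must be a positive integer", call. = FALSE)
  }
  nat <- spec$n_phosphorus
  half <- spec$thickness / 2
  z <- with_preserved_seed(.coord_seed(spec$seed), {
    out <- vector("list", n_frames)
    for (f in seq_len(n_frames)) {
      sgn <- ifelse(stats::runif(nat) < 0.5, -1, 1)
      out[[f]] <- sgn * half + stats::rnorm(nat, sd = spec$peak_sigma)
    }
    unlist(out, use.names = FALSE)
  })
  data.frame(
    frame = rep(seq_len(n_frames), each = nat),
    atom = rep(seq_len(nat), times = n_frames),
    z = z
  )
}
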