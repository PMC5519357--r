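#' Construct an area time series
#'
#' An `area_series` holds the instantaneous projected membrane area (the box
#' x*y area of an NPT simulation) per stored frame, together with the
#' simulation temperature and a record of how many leading equilibration
#' frames have already been discarded.
#'
#' @param times Numeric vector of frame times (frame index or ps); strictly
#'   increasing.
#' @param areas Numeric vector of instantaneous membrane areas in nm2; must
#'   be positive and finite, same length as `times`.
#' @param temperature Absolute simulation temperature in K.
#' @param equilibration_cut Number of leading frames already removed from the
#'   raw trajectory (metadata only).
#' @return An object of class `area_series`.
#' @seealso [apply_equilibration_cut()], [estimate_area_modulus()]
#' @export
#' @examples
#' s <- area_series(1:5, c(129, 131, 130, 132, 128), temperature = 303.15)
#' s
area_series <- function(times, areas, temperature, equilibration_cut = 0L) {
  times <- as.numeric(times)
  areas <- as.numeric(areas)
  if (length(times) != length(areas)) {
    stop("`times` and `areas` must have the same length", call. = FALSE)
  }
  if (length(areas) < 1L) stop("empty area series", call. = FALSE)
  if (!all(is.finite(areas)) || any(areas <= 0)) {
    stop("areas must be positive and finite", call. = FALSE)
  }
  if (!all(is.finite(times)) || any(diff(times) <= 0)) {
    stop("times must be finite and strictly increasing", call. = FALSE)
  }
  if (!is.numeric(temperature) || length(temperature) != 1L ||
      !is.finite(temperature) || temperature <= 0) {
    stop("temperature must be a single positive number (K)", call. = FALSE)
  }
  structure(
    list(
      times = times,
      areas = areas,
      temperature = as.numeric(temperature),
      equilibration_cut = as.integer(equilibration_cut)
    ),
    class = "area_series"
  )
}

#' @export
print.area_series <- function(x, ...) {
  cat(sprintf(
    "area_series: %d frames, T = %.2f K, <A> = %.3f nm2 (%d equilibration frames removed)\n",
    length(x$areas), x$temperature, mean(x$areas), x$equilibration_cut
  ))
  invisible(x)
}

#' @export
length.area_series <- function(x) length(x$areas)

#' Discard leading equilibration frames
#'
#' NPT membrane runs need an equilibration stretch before the area
#' fluctuations are stationary; production analysis drops the leading frames.
#' The default removes the first quarter of the series, the fraction that a
#' 50 ns equilibration represents of a 200 ns run (the shortest production
#' length the pipeline is parameterized for) when frames map 1:1 to ns.
#'
#' @param series An [area_series()].
#' @param cut Either an integer count of leading frames to drop (`cut >= 1`),
#'   or a fraction in (0, 1) of the series length; `cut = 0` is the identity.
#' @return The truncated `area_series`; `equilibration_cut` accumulates the
#'   number of frames removed.
#' @export
#' @examples
#' s <- area_series(1:600, rnorm(600, 130, 1.5), 303.15)
#' length(apply_equilibration_cut(s, 50))   # 550
#' length(apply_equilibration_cut(s, 0.25)) # 450
apply_equilibration_cut <- function(series, cut = 0.25) {
  stopifnot(inherits(series, "area_series"))
  n <- length(series$areas)
  if (!is.numeric(cut) || length(cut) != 1L || !is.finite(cut) || cut < 0) {
    stop("`cut` must be a non-negative count or a fraction in (0, 1)",
         call. = FALSE)
  }
  ncut <- if (cut == 0) 0L else if (cut < 1) as.integer(floor(cut * n)) else {
    if (cut != floor(cut)) stop("a frame count `cut` must be an integer",
                                call. = FALSE)
    as.integer(cut)
  }
  if (ncut >= n) {
    stop(sprintf("equilibration cut (%d) removes the whole %d-frame series",
                 ncut, n), call. = FALSE)
  }
  if (n - ncut < 100L) {
    stop(sprintf(
      "only %d frames would remain after the cut; at least 100 are required",
      n - ncut), call. = FALSE)
  }
  if (ncut == 0L) return(series)
  keep <- (ncut + 1L):n
  area_series(series$times[keep], series$areas[keep], series$temperature,
              equilibration_cut = series$equilibration_cut + ncut)
}

#' Thin an area series by a fixed stride
#'
#' Keeps every `stride`-th frame, starting from the first. Useful when stored
#' frames are much more finely spaced than the area decorrelation time.
#'
#' @param series An [area_series()].
#' @param stride Positive integer; `1` is the identity.
#' @return The thinned `area_series`.
#' @export
stride_series <- function(series, stride = 1L) {
  stopifnot(inherits(series, "area_series"))
  if (!is.numeric(stride) || length(stride) != 1L || stride < 1 ||
      stride != floor(stride)) {
    stop("`stride` must be a positive integer", call. = FALSE)
  }
  if (stride == 1) return(series)
  keep <- seq(1L, length(series$areas), by = as.integer(stride))
  area_series(series$times[keep], series$areas[keep], series$temperature,
              equilibration_cut = series$equilibration_cut)
}
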