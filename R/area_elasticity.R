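#' Estimate the area expansion modulus from area fluctuations
#'
#' For a tensionless membrane simulated at constant pressure, the area
#' expansion modulus follows from the equilibrium fluctuations of the
#' projected area:
#'
#'   K_A = kB T A0 / <dA^2>,
#'
#' where A0 is the mean (tensionless) area and `<dA^2> = <A^2> - <A>^2` the
#' variance of the instantaneous area. A0 is taken as the post-cut sample
#' mean of the same series unless overridden, and the variance is the
#' unbiased (n - 1) sample variance. The standard error of K_A is propagated
#' to first order from the block-average standard error of the variance
#' (see [block_average_se()]); a moving-block bootstrap is available as an
#' alternative.
#'
#' @param series An [area_series()], already equilibration-cut (see
#'   [apply_equilibration_cut()]); at least 100 frames.
#' @param a0 Optional externally supplied tensionless area A0 in nm2;
#'   defaults to the sample mean of `series`.
#' @param error `"block"` (default) for block-average propagation,
#'   `"bootstrap"` for a moving-block bootstrap of the whole estimator, or
#'   `"none"`.
#' @param n_boot Number of bootstrap replicates when `error = "bootstrap"`.
#' @return An object of class `ka_estimate`: `area_modulus` and `se` in
#'   mN/m, `area_modulus_kBT_nm2` in kBT/nm2, `area0` (nm2), `variance`
#'   (nm4), `temperature` (K), `n`, and the `block` error curve of the
#'   variance (when computed).
#' @export
#' @examples
#' spec <- membrane_spec(n_frames = 5000, seed = 42)
#' estimate_area_modulus(generate_area_series(spec))
estimate_area_modulus <- function(series, a0 = NULL,
                                  error = c("block", "bootstrap", "none"),
                                  n_boot = 200L) {
  stopifnot(inherits(series, "area_series"))
  error <- match.arg(error)
  x <- series$areas
  n <- length(x)
  if (n < 100L) {
    stop(sprintf(
      "need at least 100 frames after the equilibration cut (got %d)", n),
      call. = FALSE)
  }
  v <- stats::var(x)
  if (v == 0) {
    stop("zero area fluctuation: the series is constant, K_A is undefined",
         call. = FALSE)
  }
  mu <- if (is.null(a0)) mean(x) else {
    stopifnot(is.numeric(a0), length(a0) == 1L, a0 > 0)
    as.numeric(a0)
  }
  Tk <- series$temperature
  ka_mNm <- kBT_joules(Tk) * mu / v * 1e21

  block <- NULL
  se <- NA_real_
  if (error == "block") {
    block <- block_average_se(x, "variance")
    # K_A = c / v  =>  |dK_A/dv| = K_A / v
    se <- ka_mNm * block$plateau_se / v
  } else if (error == "bootstrap") {
    block <- block_average_se(x, "variance")
    b <- max(block$plateau_block, 1L)
    nblk <- n %/% b
    reps <- numeric(n_boot)
    starts_max <- n - b + 1L
    for (r in seq_len(n_boot)) {
      starts <- sample.int(starts_max, nblk, replace = TRUE)
      xb <- unlist(lapply(starts, function(s) x[s:(s + b - 1L)]),
                   use.names = FALSE)
      mub <- if (is.null(a0)) mean(xb) else mu
      reps[r] <- kBT_joules(Tk) * mub / stats::var(xb) * 1e21
    }
    se <- stats::sd(reps)
  }

  structure(
    list(
      area_modulus = ka_mNm,
      se = se,
      area_modulus_kBT_nm2 = ka_mNm_to_kBT_nm2(ka_mNm, Tk),
      area0 = mu,
      variance = v,
      temperature = Tk,
      n = n,
      error_method = error,
      block = block
    ),
    class = "ka_estimate"
  )
}

#' @export
print.ka_estimate <- function(x, ...) {
  se_txt <- if (is.finite(x$se)) sprintf(" +/- %.1f", x$se) else ""
  cat(sprintf(
    paste0("K_A = %.1f%s mN/m (%.3f kBT/nm2) at T = %.2f K\n",
           "  A0 = %.3f nm2, <dA^2> = %.4f nm4, n = %d frames\n"),
    x$area_modulus, se_txt, x$area_modulus_kBT_nm2, x$temperature,
    x$area0, x$variance, x$n
  ))
  if (!is.null(x$block) && !x$block$plateau_found) {
    cat("  warning: block-average SE did not plateau; largest block used\n")
  }
  invisible(x)
}
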