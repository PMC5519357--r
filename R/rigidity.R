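#' Bending rigidity from the area expansion modulus and thickness
#'
#' Combines the area expansion modulus K_A and the peak-to-peak bilayer
#' thickness d into the bending rigidity via the polymer-brush relation
#'
#'   kappa = K_A (d - d0)^2 / 24,
#'
#' where d - d0 is the mechanically active ("bending") thickness and the
#' offset d0 defaults to 1 nm. The result is reported both in joules and in
#' units of kBT at the given temperature, with a standard error propagated
#' to first order from the standard errors of K_A and d.
#'
#' @param area_modulus K_A in mN/m, or a [ka_estimate][estimate_area_modulus]
#'   (which also supplies its SE and temperature).
#' @param thickness Peak-to-peak bilayer thickness d in nm, or a
#'   [thickness_estimate][peak_to_peak_thickness] (which also supplies its
#'   uncertainty). Must satisfy `thickness >= d0`.
#' @param d0 Thickness offset in nm; default 1.
#' @param temperature Absolute temperature in K (required unless supplied by
#'   a `ka_estimate`), used for the kBT readout.
#' @param area_modulus_se,thickness_se Standard errors of K_A (mN/m) and d
#'   (nm); default 0 when the inputs are bare numbers.
#' @param label Optional lipid label (e.g. "DOPC") carried into reports.
#' @return An object of class `elasticity_result` with fields `label`,
#'   `temperature`, `area_modulus`, `area_modulus_se`, `thickness`,
#'   `thickness_se`, `d0`, `kappa_J`, `kappa_se_J`, `kappa_kBT`,
#'   `kappa_se_kBT`.
#' @export
#' @examples
#' r <- compute_bending_rigidity(240, 4.0, temperature = 303.15)
#' r$kappa_J   # 9e-20
#' r$kappa_kBT # about 21.5
compute_bending_rigidity <- function(area_modulus, thickness, d0 = 1.0,
                                     temperature = NULL,
                                     area_modulus_se = 0,
                                     thickness_se = 0,
                                     label = NA_character_) {
  if (inherits(area_modulus, "ka_estimate")) {
    ka <- area_modulus$area_modulus
    if (is.finite(area_modulus$se)) area_modulus_se <- area_modulus$se
    if (is.null(temperature)) temperature <- area_modulus$temperature
  } else {
    ka <- as.numeric(area_modulus)
  }
  if (inherits(thickness, "thickness_estimate")) {
    thickness_se <- thickness$uncertainty
    d <- thickness$thickness
  } else {
    d <- as.numeric(thickness)
  }
  if (is.null(temperature)) {
    stop("`temperature` (K) is required for the kBT readout", call. = FALSE)
  }
  stopifnot(is.numeric(temperature), length(temperature) == 1L,
            temperature > 0)
  if (!is.finite(ka) || ka <= 0) {
    stop("`area_modulus` must be positive (mN/m)", call. = FALSE)
  }
  if (!is.finite(d0) || d0 < 0) stop("`d0` must be non-negative (nm)",
                                     call. = FALSE)
  if (!is.finite(d) || d < d0) {
    stop(sprintf(
      "unphysical input: thickness (%.3f nm) is below the offset d0 (%.3f nm)",
      d, d0), call. = FALSE)
  }
  # mN/m -> J/m2 (1e-3), nm -> m (1e-9)
  kappa_J <- (ka * 1e-3) * ((d - d0) * 1e-9)^2 / 24
  rel_se2 <- if (kappa_J > 0) {
    (area_modulus_se / ka)^2 + (2 * thickness_se / (d - d0))^2
  } else 0
  kappa_se_J <- kappa_J * sqrt(rel_se2)
  structure(
    list(
      label = label,
      temperature = as.numeric(temperature),
      area_modulus = ka,
      area_modulus_se = as.numeric(area_modulus_se),
      thickness = d,
      thickness_se = as.numeric(thickness_se),
      d0 = as.numeric(d0),
      kappa_J = kappa_J,
      kappa_se_J = kappa_se_J,
      kappa_kBT = kappa_joules_to_kBT(kappa_J, temperature),
      kappa_se_kBT = kappa_joules_to_kBT(kappa_se_J, temperature)
    ),
    class = "elasticity_result"
  )
}

#' @export
print.elasticity_result <- function(x, ...) {
  lab <- if (is.na(x$label)) "" else paste0(x$label, ": ")
  cat(sprintf(
    paste0("%skappa = %.2f +/- %.2f kBT (%.3g +/- %.2g e-20 J) at %.2f K\n",
           "  K_A = %.1f +/- %.1f mN/m, d = %.3f +/- %.3f nm, d0 = %g nm\n"),
    lab, x$kappa_kBT, x$kappa_se_kBT, x$kappa_J * 1e20, x$kappa_se_J * 1e20,
    x$temperature, x$area_modulus, x$area_modulus_se, x$thickness,
    x$thickness_se, x$d0
  ))
  invisible(x)
}

#' Comparative bending-rigidity report across lipids and temperatures
#'
#' Orders a set of per-lipid rigidity results within each temperature and
#' issues a pairwise verdict for every pair of labels at the same
#' temperature: a lipid is "lower"/"higher" than another when the two kappa
#' values differ by more than one combined standard error
#' (`sqrt(se_a^2 + se_b^2)`), and "indistinguishable" otherwise. Across
#' temperatures, the spread of kappa between labels (max - min) summarizes
#' how strongly acyl-chain unsaturation differentiates the membranes — the
#' "double-bond effect" — at each temperature.
#'
#' @param results A list of [compute_bending_rigidity()] results; every
#'   temperature present must be shared by at least 2 results.
#' @param band Width of the indistinguishability band in combined SEs;
#'   default 1.
#' @return An object of class `comparative_report`: `table` (one row per
#'   result, sorted by temperature then kappa), `verdicts` (one row per
#'   ordered pair at each temperature, columns `temperature`, `label_a`,
#'   `label_b`, `delta_kBT`, `combined_se`, `verdict`) and `spread` (per
#'   temperature: min/max labels and kappa spread in kBT).
#' @export
comparative_report <- function(results, band = 1) {
  if (inherits(results, "elasticity_result")) results <- list(results)
  stopifnot(is.list(results), length(results) >= 2L,
            all(vapply(results, inherits, logical(1), "elasticity_result")),
            is.numeric(band), band >= 0)
  tab <- do.call(rbind, lapply(results, function(r) {
    data.frame(
      label = r$label, temperature = r$temperature,
      area_modulus_mNm = r$area_modulus, area_modulus_se_mNm = r$area_modulus_se,
      thickness_nm = r$thickness, thickness_se_nm = r$thickness_se,
      d0_nm = r$d0, kappa_kBT = r$kappa_kBT, kappa_se_kBT = r$kappa_se_kBT,
      kappa_1e20J = r$kappa_J * 1e20, kappa_se_1e20J = r$kappa_se_J * 1e20
    )
  }))
  temps <- unique(tab$temperature)
  counts <- table(tab$temperature)
  if (any(counts < 2)) {
    bad <- names(counts)[counts < 2]
    stop("comparison requires at least 2 results at each temperature; ",
         "unmatched temperature(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  if (anyDuplicated(paste(tab$label, tab$temperature))) {
    stop("duplicate label within a temperature group", call. = FALSE)
  }
  tab <- tab[order(tab$temperature, tab$kappa_kBT), ]
  rownames(tab) <- NULL

  verdicts <- do.call(rbind, lapply(temps, function(Tk) {
    g <- tab[tab$temperature == Tk, ]
    pairs <- expand.grid(a = seq_len(nrow(g)), b = seq_len(nrow(g)))
    pairs <- pairs[pairs$a != pairs$b, ]
    do.call(rbind, lapply(seq_len(nrow(pairs)), function(k) {
      a <- pairs$a[k]; b <- pairs$b[k]
      delta <- g$kappa_kBT[a] - g$kappa_kBT[b]
      cse <- sqrt(g$kappa_se_kBT[a]^2 + g$kappa_se_kBT[b]^2)
      verdict <- if (abs(delta) <= band * cse) "indistinguishable"
                 else if (delta < 0) "lower" else "higher"
      data.frame(temperature = Tk, label_a = g$label[a], label_b = g$label[b],
                 delta_kBT = delta, combined_se = cse, verdict = verdict)
    }))
  }))
  rownames(verdicts) <- NULL

  spread <- do.call(rbind, lapply(temps, function(Tk) {
    g <- tab[tab$temperature == Tk, ]
    i_min <- which.min(g$kappa_kBT); i_max <- which.max(g$kappa_kBT)
    data.frame(
      temperature = Tk,
      lowest_label = g$label[i_min], highest_label = g$label[i_max],
      kappa_min_kBT = g$kappa_kBT[i_min], kappa_max_kBT = g$kappa_kBT[i_max],
      spread_kBT = g$kappa_kBT[i_max] - g$kappa_kBT[i_min]
    )
  }))
  rownames(spread) <- NULL

  structure(list(table = tab, verdicts = verdicts, spread = spread,
                 band = band),
            class = "comparative_report")
}

#' @export
print.comparative_report <- function(x, ...) {
  cat("Bending-rigidity comparison (kappa in kBT)\n")
  for (Tk in unique(x$table$temperature)) {
    g <- x$table[x$table$temperature == Tk, ]
    cat(sprintf("  T = %.2f K:\n", Tk))
    for (i in seq_len(nrow(g))) {
      cat(sprintf("    %-8s kappa = %6.2f +/- %.2f\n",
                  g$label[i], g$kappa_kBT[i], g$kappa_se_kBT[i]))
    }
  }
  cat(sprintf("Spread between labels (double-bond effect), per temperature:\n"))
  for (i in seq_len(nrow(x$spread))) {
    cat(sprintf("    %.2f K: %.2f kBT (%s lowest, %s highest)\n",
                x$spread$temperature[i], x$spread$spread_kBT[i],
                x$spread$lowest_label[i], x$spread$highest_label[i]))
  }
  invisible(x)
}

#' Query a pairwise verdict from a comparative report
#'
#' @param report A [comparative_report()].
#' @param label_a,label_b Labels to compare (verdict is for a relative to b).
#' @param temperature Temperature (K) of the group; may be omitted when the
#'   report has a single temperature.
#' @return `"lower"`, `"higher"` or `"indistinguishable"`.
#' @export
pair_verdict <- function(report, label_a, label_b, temperature = NULL) {
  stopifnot(inherits(report, "comparative_report"))
  v <- report$verdicts
  if (is.null(temperature)) {
    if (length(unique(v$temperature)) > 1L) {
      stop("multiple temperatures present; specify `temperature`",
           call. = FALSE)
    }
  } else {
    v <- v[abs(v$temperature - temperature) < 1e-9, ]
  }
  if (label_a == label_b) return("indistinguishable")
  row <- v[v$label_a == label_a & v$label_b == label_b, ]
  if (nrow(row) != 1L) stop("pair not found in report", call. = FALSE)
  row$verdict
}
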