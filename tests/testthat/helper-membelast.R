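# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths: plain two-pass moment sums and brute-force
# histograms.

kB_ref <- 1.380649e-23

# brute-force two-pass evaluation of K_A = kB T A0 / var(A), in mN/m
oracle_ka_mNm <- function(areas, temperature) {
  n <- length(areas)
  mu <- sum(areas) / n
  v <- sum((areas - mu)^2) / (n - 1)
  # J * nm2 / nm4 -> mN/m carries a factor 1e21
  kB_ref * temperature * mu / v * 1e21
}

# brute-force histogram mode per side, no interpolation; returns the
# peak-to-peak distance between the two per-side argmax bin centers
oracle_thickness <- function(z, bin_width) {
  m <- ceiling(max(abs(z)) / bin_width + 1e-9)
  edges <- seq(-m, m) * bin_width
  mids <- (edges[-1] + edges[-length(edges)]) / 2
  counts <- tabulate(pmin(floor(z / bin_width) + m + 1, 2 * m), nbins = 2 * m)
  lo <- mids[mids < 0][which.max(counts[mids < 0])]
  hi <- mids[mids > 0][which.max(counts[mids > 0])]
  hi - lo
}

# closed-form SE of the mean of a stationary AR(1) series (large n)
oracle_ar1_se <- function(sd_stationary, rho, n) {
  sd_stationary * sqrt((1 + rho) / (1 - rho)) / sqrt(n)
}

# a small GRO file with the given atom-name/z pairs (z in nm), one frame
write_gro_fixture <- function(path, atoms, zs, box = "  10.0  10.0  10.0") {
  n <- length(atoms)
  lines <- c("synthetic bilayer fixture", sprintf("%5d", n))
  for (i in seq_len(n)) {
    lines <- c(lines, sprintf("%5d%-5s%5s%5d%8.3f%8.3f%8.3f",
                              1L, "POPC", atoms[i], i, 1.0, 2.0, zs[i]))
  }
  writeLines(c(lines, box), path)
  invisible(path)
}

# the same single frame as PDB (angstrom)
write_pdb_fixture <- function(path, atoms, zs_nm) {
  lines <- vapply(seq_along(atoms), function(i) {
    sprintf("ATOM  %5d %-4s%-4s A%4d    %8.3f%8.3f%8.3f  1.00  0.00",
            i, atoms[i], "POPC", 1L, 10.0, 20.0, zs_nm[i] * 10)
  }, "")
  writeLines(c(lines, "END"), path)
  invisible(path)
}
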