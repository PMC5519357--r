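#' Read a membrane area time series from xvg-style or CSV/TSV text
#'
#' Accepts the two-column time/area text that MD analysis toolchains export:
#' xvg dialect (lines starting with `#` or `@` are comments, whitespace
#' separated columns) or CSV/TSV with a header naming `time` and `area`
#' columns. Malformed numeric fields are reported with their file line
#' numbers. A comment line of the form `# temperature_K <value>` (as written
#' by [write_area_xvg()]) supplies the temperature when the `temperature`
#' argument is omitted.
#'
#' @param path Path to the file.
#' @param temperature Absolute temperature in K; overrides any value
#'   embedded in the file. Required if the file carries none.
#' @return An [area_series()].
#' @export
read_area_table <- function(path, temperature = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  is_comment <- grepl("^\\s*[#@]", lines) | grepl("^\\s*$", lines)

  if (is.null(temperature)) {
    tl <- grep("^\\s*#\\s*temperature_K\\s", lines, value = TRUE)
    if (length(tl)) {
      temperature <- suppressWarnings(
        as.numeric(sub("^\\s*#\\s*temperature_K\\s+", "", tl[1])))
    }
  }
  if (is.null(temperature) || !length(temperature) || is.na(temperature)) {
    stop("no temperature given and none embedded in ", path, call. = FALSE)
  }

  data_idx <- which(!is_comment)
  if (!length(data_idx)) stop("no data rows in ", path, call. = FALSE)
  toks <- strsplit(trimws(lines[data_idx]), "[,;\t ]+")

  col_t <- 1L
  col_a <- 2L
  first <- suppressWarnings(as.numeric(toks[[1]]))
  if (anyNA(first)) {
    # header line: locate time/area columns by name
    hdr <- tolower(toks[[1]])
    ct <- which(hdr %in% c("time", "t", "frame", "time_ps"))
    ca <- which(hdr %in% c("area", "a", "area_nm2"))
    if (length(ct)) col_t <- ct[1]
    if (length(ca)) col_a <- ca[1]
    if (!length(ca) && !length(ct) && length(hdr) < 2) {
      stop(sprintf("line %d of %s: expected two numeric columns or a header",
                   data_idx[1], path), call. = FALSE)
    }
    toks <- toks[-1]
    data_idx <- data_idx[-1]
    if (!length(toks)) stop("no data rows in ", path, call. = FALSE)
  }

  short <- lengths(toks) < max(col_t, col_a)
  if (any(short)) {
    stop(sprintf("line %d of %s: expected at least %d columns",
                 data_idx[which(short)[1]], path, max(col_t, col_a)),
         call. = FALSE)
  }
  times <- suppressWarnings(as.numeric(vapply(toks, `[`, "", col_t)))
  areas <- suppressWarnings(as.numeric(vapply(toks, `[`, "", col_a)))
  bad <- which(is.na(times) | is.na(areas))
  if (length(bad)) {
    stop(sprintf("line %d of %s: malformed numeric field",
                 data_idx[bad[1]], path), call. = FALSE)
  }
  if (any(diff(times) <= 0)) {
    stop("non-monotonic time column in ", path, call. = FALSE)
  }
  if (any(areas <= 0)) {
    stop(sprintf("line %d of %s: non-positive area",
                 data_idx[which(areas <= 0)[1]], path), call. = FALSE)
  }
  area_series(times, areas, temperature)
}

#' Write an area series as xvg-style text
#'
#' Emits `@` legend lines, a `# temperature_K` comment that
#' [read_area_table()] understands, and two whitespace-separated numeric
#' columns (time, area in nm2) at full double precision.
#'
#' @param series An [area_series()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_area_xvg <- function(series, path) {
  stopifnot(inherits(series, "area_series"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    "@    title \"Instantaneous membrane area\"",
    "@    xaxis  label \"Time (frame)\"",
    "@    yaxis  label \"Area (nm\\S2\\N)\"",
    sprintf("# temperature_K %.10g", series$temperature),
    sprintf("# equilibration_cut %d", series$equilibration_cut)
  ), con)
  writeLines(sprintf("%.17g %.17g", series$times, series$areas), con)
  invisible(path)
}

#' Read a per-frame phosphorus z table
#'
#' Reads the TSV layout `frame`, `atom` (or `atom_index`), `z` (or `z_nm`),
#' as written by [write_z_table()].
#'
#' @param path Path to the TSV file.
#' @return A data.frame with columns `frame`, `atom`, `z` (nm).
#' @export
read_z_table <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          comment.char = "#", stringsAsFactors = FALSE)
  nm <- tolower(names(df))
  names(df) <- nm
  if ("atom_index" %in% nm) names(df)[nm == "atom_index"] <- "atom"
  if ("z_nm" %in% nm) names(df)[names(df) == "z_nm"] <- "z"
  need <- c("frame", "atom", "z")
  if (!all(need %in% names(df))) {
    stop("z table must have columns frame, atom(_index), z(_nm): ", path,
         call. = FALSE)
  }
  if (!nrow(df)) stop("no data rows in ", path, call. = FALSE)
  if (!is.numeric(df$z) || anyNA(df$z)) {
    stop("malformed z column in ", path, call. = FALSE)
  }
  df[need]
}

#' Write a per-frame phosphorus z table as TSV
#'
#' @param z_table A data.frame with columns `frame`, `atom`, `z` (nm).
#' @param path Output path; columns are written as `frame`, `atom_index`,
#'   `z_nm`.
#' @return `path`, invisibly.
#' @export
write_z_table <- function(z_table, path) {
  stopifnot(all(c("frame", "atom", "z") %in% names(z_table)))
  out <- data.frame(frame = z_table$frame, atom_index = z_table$atom,
                    z_nm = sprintf("%.17g", z_table$z))
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

# ---- coordinate-file adapter (GRO / PDB) -----------------------------------

.read_gro_z <- function(lines, selection) {
  frames <- list()
  i <- 1L
  nline <- length(lines)
  f <- 0L
  while (i + 1L <= nline) {
    nat <- suppressWarnings(as.integer(trimws(lines[i + 1L])))
    if (is.na(nat)) stop("malformed GRO atom-count line ", i + 1L,
                         call. = FALSE)
    if (i + 1L + nat + 1L > nline) {
      stop("truncated GRO frame starting at line ", i, call. = FALSE)
    }
    at <- lines[(i + 2L):(i + 1L + nat)]
    names_at <- trimws(substr(at, 11L, 15L))
    keep <- names_at %in% selection
    z <- suppressWarnings(as.numeric(substr(at[keep], 37L, 44L)))
    if (anyNA(z)) stop("malformed GRO coordinate field", call. = FALSE)
    f <- f + 1L
    frames[[f]] <- z
    i <- i + 1L + nat + 2L  # title + count + atoms + box
  }
  frames
}

# PDB frames via bio3d; multi-model files give one frame per MODEL record.
# bio3d works in angstrom, converted to nm here.
.read_pdb_z <- function(path, selection) {
  pdb <- suppressWarnings(bio3d::read.pdb(path, multi = TRUE, verbose = FALSE))
  sel <- which(trimws(pdb$atom$elety) %in% selection)
  if (!length(sel)) return(list(numeric(0)))
  xyz <- pdb$xyz
  if (is.null(dim(xyz))) xyz <- matrix(xyz, nrow = 1)
  lapply(seq_len(nrow(xyz)), function(f) as.numeric(xyz[f, 3 * sel]) / 10)
}

#' Extract phosphorus z coordinates from GRO or PDB coordinate files
#'
#' Adapter from standard coordinate formats to the z-table the density
#' profiler consumes. Multi-frame files (concatenated GRO frames, PDB
#' MODEL/ENDMDL records) are supported; GRO coordinates are nm-native, PDB
#' files are parsed with \pkg{bio3d} and converted from angstrom to nm.
#' Coordinates are taken as given (already unwrapped).
#'
#' @param path Path to a `.gro` or `.pdb` file.
#' @param selection Character vector of atom names to keep; default `"P"`,
#'   the phosphorus atom name of common phospholipid force fields.
#' @param format `"auto"` (by extension), `"gro"` or `"pdb"`.
#' @return A data.frame with columns `frame`, `atom`, `z` (nm).
#' @export
read_coordinates_z <- function(path, selection = "P",
                               format = c("auto", "gro", "pdb")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- if (ext == "gro") "gro" else if (ext == "pdb") "pdb" else {
      stop("cannot infer coordinate format from extension: ", path,
           call. = FALSE)
    }
  }
  frames <- if (format == "gro") {
    .read_gro_z(readLines(path, warn = FALSE), selection)
  } else {
    .read_pdb_z(path, selection)
  }
  if (!length(frames)) stop("no frames found in ", path, call. = FALSE)
  nz <- lengths(frames)
  if (all(nz == 0)) {
    stop("atom selection (", paste(selection, collapse = ", "),
         ") matched no atoms in ", path, call. = FALSE)
  }
  if (length(unique(nz)) != 1L) {
    stop("inconsistent selected atom counts across frames in ", path, ": ",
         paste(unique(nz), collapse = ", "), call. = FALSE)
  }
  nat <- nz[1]
  data.frame(
    frame = rep(seq_along(frames), each = nat),
    atom = rep(seq_len(nat), times = length(frames)),
    z = unlist(frames, use.names = FALSE)
  )
}
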