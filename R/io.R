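#' Read and write SAXS profiles as 3-column text
#'
#' The conventional format: whitespace- or comma-separated columns
#' `q I [sigma]`, with `#`-prefixed comment/header lines. `q` is expected in
#' 1/Angstrom; files in 1/nm must be declared via `q_units = "nm^-1"` and
#' are converted on read. When the largest q is below 0.06 — too small for a
#' protein-scale measurement in 1/Angstrom — the units are ambiguous and an
#' explicit `q_units` is required instead of guessing.
#'
#' @param path file path.
#' @param q_units `"A^-1"` (default for unambiguous data) or `"nm^-1"`.
#' @return a [saxs_profile()].
#' @export
read_saxs <- function(path, q_units = NULL) {
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  lines <- readLines(path)
  keep <- !grepl("^\\s*(#|$)", lines)
  fields <- strsplit(trimws(lines[keep]), "[,[:space:]]+")
  nf <- lengths(fields)
  if (any(nf < 2 | nf > 3)) {
    abort(sprintf("malformed row %d: expected 2-3 numeric columns.",
                  which(keep)[which(nf < 2 | nf > 3)[1]]))
  }
  num <- suppressWarnings(lapply(fields, as.numeric))
  bad <- vapply(num, function(v) any(is.na(v)), logical(1))
  if (any(bad)) {
    abort(sprintf("malformed row %d: non-numeric value.", which(keep)[which(bad)[1]]))
  }
  q <- vapply(num, `[`, numeric(1), 1)
  I <- vapply(num, `[`, numeric(1), 2)
  s <- if (all(nf == 3)) vapply(num, `[`, numeric(1), 3) else NULL
  if (is.null(q_units)) {
    if (max(q) < 0.06) {
      abort("q units ambiguous (max q < 0.06): pass q_units = \"A^-1\" or \"nm^-1\" explicitly.")
    }
    q_units <- "A^-1"
  }
  q_units <- match.arg(q_units, c("A^-1", "nm^-1"))
  if (q_units == "nm^-1") q <- q / 10
  saxs_profile(q, I, s)
}

#' @rdname read_saxs
#' @param profile a [saxs_profile()].
#' @export
write_saxs <- function(profile, path) {
  stopifnot(inherits(profile, "data.frame"))
  header <- "# q[A^-1] I sigma"
  body <- sprintf("%.17g %.17g %.17g", profile$q, profile$I, profile$sigma)
  writeLines(c(header, body), path)
  invisible(path)
}

#' Read and write MALDI peak lists as CSV
#'
#' CSV/TSV with a header naming an `mz` column (an `intensity` column is
#' optional); headerless two-column numeric text is also accepted. Peaks
#' are sorted by m/z on load.
#'
#' @param path file path.
#' @return a tibble with `mz` (and `intensity` when present).
#' @export
read_peaks <- function(path) {
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  first <- readLines(path, n = 1)
  sep <- if (grepl("\t", first)) "\t" else if (grepl(",", first)) "," else ""
  has_header <- grepl("[A-Za-z]", first)
  df <- read.table(path, header = has_header, sep = sep, strip.white = TRUE,
                   colClasses = NA, comment.char = "#")
  if (!has_header) {
    names(df)[1] <- "mz"
    if (ncol(df) > 1) names(df)[2] <- "intensity"
  }
  if (!"mz" %in% names(df)) abort("peak file must have an `mz` column.")
  if (!is.numeric(df$mz)) {
    bad <- which(is.na(suppressWarnings(as.numeric(as.character(df$mz)))))[1]
    abort(sprintf("non-numeric mz in row %d.", bad))
  }
  dplyr::arrange(as_tibble(df), .data$mz)
}

#' @rdname read_peaks
#' @param peaks a data frame with at least `mz`.
#' @export
write_peaks <- function(peaks, path) {
  utils::write.csv(peaks[intersect(c("mz", "intensity"), names(peaks))],
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read and write AFM height maps as plain-text matrices
#'
#' The height map is a whitespace-separated numeric matrix in nm; the pixel
#' size travels in a YAML sidecar (`<path>.yaml` with key `pixel_size_nm`)
#' or is passed explicitly. A single-channel grayscale TIFF can be read via
#' `read_heightmap_tiff()` (requires the `tiff` package) with an explicit
#' nm-per-pixel and height scaling.
#'
#' @param path matrix file path.
#' @param pixel_size nm per pixel; overrides the sidecar when given.
#' @return an [afm_heightmap()].
#' @export
read_heightmap <- function(path, pixel_size = NULL) {
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  if (is.null(pixel_size)) {
    sidecar <- paste0(path, ".yaml")
    if (!file.exists(sidecar)) {
      abort("no pixel size: pass `pixel_size` or provide a <path>.yaml sidecar with pixel_size_nm.")
    }
    meta <- yaml::read_yaml(sidecar)
    pixel_size <- meta$pixel_size_nm %||% abort("sidecar lacks pixel_size_nm.")
  }
  m <- as.matrix(read.table(path, header = FALSE, comment.char = "#"))
  dimnames(m) <- NULL
  if (!is.numeric(m)) abort("height map contains non-numeric values.")
  afm_heightmap(m, pixel_size)
}

#' @rdname read_heightmap
#' @param map an [afm_heightmap()].
#' @export
write_heightmap <- function(map, path) {
  stopifnot(inherits(map, "afm_heightmap"))
  write.table(format(map$heights, digits = 15, trim = TRUE, scientific = TRUE),
              path, row.names = FALSE, col.names = FALSE, quote = FALSE)
  yaml::write_yaml(list(pixel_size_nm = map$pixel_size), paste0(path, ".yaml"))
  invisible(path)
}

#' @rdname read_heightmap
#' @param height_scale nm per TIFF intensity unit (default 1).
#' @export
read_heightmap_tiff <- function(path, pixel_size, height_scale = 1) {
  if (!requireNamespace("tiff", quietly = TRUE)) {
    abort("reading TIFF height maps requires the `tiff` package.")
  }
  img <- tiff::readTIFF(path)   # normalized [0, 1] sample values
  if (length(dim(img)) == 3L) img <- img[, , 1]
  afm_heightmap(t(img) * height_scale, pixel_size)
}

#' Read and write ITC traces as CSV
#'
#' The power trace is a CSV with columns `time_s`, `power_uW`; the
#' injection schedule is a second CSV with columns `injection`, `time_s`
#' (a `volume_uL` column is carried through when present).
#'
#' @param trace_path power-trace CSV.
#' @param injections_path injection-schedule CSV.
#' @param temperature cell temperature label (Celsius).
#' @return an [itc_thermogram()].
#' @export
read_itc <- function(trace_path, injections_path, temperature = 25) {
  for (p in c(trace_path, injections_path)) {
    if (!file.exists(p)) abort(sprintf("file not found: %s", p))
  }
  tr <- utils::read.csv(trace_path)
  if (!all(c("time_s", "power_uW") %in% names(tr))) {
    abort("trace CSV needs columns time_s, power_uW.")
  }
  inj <- utils::read.csv(injections_path)
  if (!"time_s" %in% names(inj)) abort("injection CSV needs a time_s column.")
  itc_thermogram(tr$time_s, tr$power_uW, inj$time_s, temperature = temperature)
}

#' @rdname read_itc
#' @param tg an [itc_thermogram()].
#' @export
write_itc <- function(tg, trace_path, injections_path) {
  stopifnot(inherits(tg, "itc_thermogram"))
  utils::write.csv(as.data.frame(tg)[c("time_s", "power_uW")], trace_path,
                   row.names = FALSE, quote = FALSE)
  utils::write.csv(attr(tg, "injections"), injections_path,
                   row.names = FALSE, quote = FALSE)
  invisible(trace_path)
}

# module parameter defaults; every threshold equals its documented default
default_config <- function() {
  list(
    saxs = list(qrg_limit = 1.3, qrc_limit = 1.0, n_r = 101,
                alpha_min = 1e-2, alpha_max = 1e8, n_alpha = 50,
                vbar = 0.73, q_units = "A^-1", frac_sd = 0.02),
    maldi = list(tol_ppm = 500, tol_ppm_high = 2000, n_high = 5,
                 n_max = 10, z_max = 3, proton_mass = 1.00728, protonated = TRUE),
    afm = list(threshold = 0.5, min_area_px = 4, min_count = 20,
               background_sd = 0.05, flatten_order = 1),
    itc = list(window = 290, baseline_frac = 0.2, tau = 15, noise_sd = 0.02,
               spacing = 300),
    report = list(helix_diameter = 12, helix_tol = 0.25, afm_saxs_tol = 0.35,
                  n_max = 10),
    seed = NULL
  )
}

#' Load a pipeline configuration file
#'
#' Reads a YAML configuration and merges it over the package defaults
#' (which reproduce every documented default threshold). Unknown keys are
#' rejected rather than silently ignored.
#'
#' @param path YAML file path; `NULL` returns the defaults.
#' @return nested named list of per-module parameter blocks.
#' @examples
#' cfg <- load_config(NULL)
#' cfg$afm$threshold
#' @export
load_config <- function(path = NULL) {
  base <- default_config()
  if (is.null(path)) return(base)
  if (!file.exists(path)) abort(sprintf("config not found: %s", path))
  user <- yaml::read_yaml(path)
  if (is.null(user)) return(base)
  bad_top <- setdiff(names(user), names(base))
  if (length(bad_top)) abort(sprintf("unknown config key(s): %s", paste(bad_top, collapse = ", ")))
  for (blk in names(user)) {
    if (blk == "seed") { base$seed <- user$seed; next }
    bad <- setdiff(names(user[[blk]]), names(base[[blk]]))
    if (length(bad)) {
      abort(sprintf("unknown config key(s) in %s: %s", blk, paste(bad, collapse = ", ")))
    }
    base[[blk]] <- modifyList(base[[blk]], user[[blk]])
  }
  base
}
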