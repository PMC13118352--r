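# Plain-text (CSV) interchange formats. All files are UTF-8 with "."
# decimal separators; dataset-level scalars travel as "# key: value"
# comment lines above the header.

#' Write spectra to a long-format CSV
#'
#' Columns: `wavelength_nm`, `intensity`, `series`, `temperature_c`,
#' `excitation_nm`, `kind`.
#'
#' @param spectra a `spectrum` or list of them.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_spectra_csv <- function(spectra, path) {
  if (inherits(spectra, "spectrum")) spectra <- list(spectra)
  rows <- lapply(spectra, function(s) {
    data.frame(wavelength_nm = s$wavelength, intensity = s$intensity,
               series = s$meta$series, temperature_c = s$meta$temperature,
               excitation_nm = s$meta$excitation, kind = s$meta$kind)
  })
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(path)
}

#' Read spectra from a long-format CSV
#'
#' @param path a CSV written by [write_spectra_csv()] (or matching its
#'   column contract).
#' @return A named list of `spectrum` objects, one per distinct
#'   `series`/`kind` combination.
#' @export
read_spectra_csv <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("wavelength_nm", "intensity", "series")
  .assert(all(need %in% names(d)),
          paste("spectra CSV must contain columns:",
                paste(need, collapse = ", ")), "fluorbind_io_error")
  if (is.null(d$kind)) d$kind <- "emission"
  if (is.null(d$temperature_c)) d$temperature_c <- NA_real_
  if (is.null(d$excitation_nm)) d$excitation_nm <- NA_real_
  key <- paste(d$series, d$kind, sep = "/")
  out <- lapply(split(d, key), function(g) {
    g <- g[order(g$wavelength_nm), ]
    spectrum(g$wavelength_nm, g$intensity,
             temperature = g$temperature_c[1],
             excitation = g$excitation_nm[1],
             series = g$series[1], kind = g$kind[1])
  })
  out
}

#' Write a titration dataset to CSV
#'
#' Per-point columns `Lt_M`, `F_obs`, `A_ex`, `A_em`, `temperature_c`;
#' dataset scalars (`Pt_M`, `d_ex_cm`, `d_em_cm`, `tau0_s`) as `# key:
#' value` header lines.
#'
#' @param ts a `titration_set`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_titration_csv <- function(ts, path) {
  con <- file(path, open = "w", encoding = "UTF-8")
  on.exit(close(con))
  hdr <- c(Pt_M = attr(ts, "Pt"), d_ex_cm = attr(ts, "d_ex"),
           d_em_cm = attr(ts, "d_em"), tau0_s = attr(ts, "tau0"))
  writeLines(sprintf("# %s: %.15g", names(hdr), hdr), con)
  d <- data.frame(Lt_M = ts$Lt_M, F_obs = ts$F_obs, A_ex = ts$A_ex,
                  A_em = ts$A_em, temperature_c = ts$temperature_K - 273.15)
  utils::write.csv(format(d, digits = 15, scientific = TRUE, trim = TRUE),
                   con, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a titration dataset from CSV
#'
#' @param path a CSV written by [write_titration_csv()].
#' @return A `titration_set` (temperatures converted back to kelvin).
#' @export
read_titration_csv <- function(path) {
  lines <- readLines(path, encoding = "UTF-8")
  hdr_lines <- grep("^#", lines, value = TRUE)
  kv <- regmatches(hdr_lines,
                   regexec("^#\\s*([A-Za-z0-9_]+)\\s*:\\s*(.+)$", hdr_lines))
  hdr <- stats::setNames(
    vapply(kv, function(m) as.numeric(m[3]), numeric(1)),
    vapply(kv, function(m) m[2], character(1)))
  d <- utils::read.csv(textConnection(grep("^#", lines, value = TRUE,
                                           invert = TRUE)))
  need <- c("Lt_M", "F_obs", "A_ex", "A_em", "temperature_c")
  .assert(all(need %in% names(d)),
          paste("titration CSV must contain columns:",
                paste(need, collapse = ", ")), "fluorbind_io_error")
  .assert(all(c("Pt_M") %in% names(hdr)),
          "titration CSV header must declare Pt_M", "fluorbind_io_error")
  out <- data.frame(temperature_K = d$temperature_c + 273.15,
                    Lt_M = d$Lt_M, F_obs = d$F_obs,
                    A_ex = d$A_ex, A_em = d$A_em)
  structure(out, Pt = unname(hdr[["Pt_M"]]),
            d_ex = unname(if ("d_ex_cm" %in% names(hdr)) hdr[["d_ex_cm"]] else 1),
            d_em = unname(if ("d_em_cm" %in% names(hdr)) hdr[["d_em_cm"]] else 1),
            tau0 = unname(if ("tau0_s" %in% names(hdr)) hdr[["tau0_s"]] else 5e-9),
            class = c("titration_set", "data.frame"))
}

#' Read a melt curve from CSV
#'
#' Columns: `temperature_c`, `ratio`, optional `label`.
#' @param path CSV path.
#' @return A `melt_curve` data frame.
#' @export
read_melt_csv <- function(path) {
  d <- utils::read.csv(path)
  .assert(all(c("temperature_c", "ratio") %in% names(d)),
          "melt CSV must contain temperature_c and ratio",
          "fluorbind_io_error")
  structure(d[order(d$temperature_c), c("temperature_c", "ratio")],
            label = if (!is.null(d$label)) d$label[1] else "",
            class = c("melt_curve", "data.frame"))
}

#' Read a kinetic trace from CSV
#'
#' Columns: `time_min`, `value`, optional `label`.
#' @param path CSV path.
#' @return A `kinetic_trace`.
#' @export
read_trace_csv <- function(path) {
  d <- utils::read.csv(path)
  .assert(all(c("time_min", "value") %in% names(d)),
          "trace CSV must contain time_min and value", "fluorbind_io_error")
  kinetic_trace(d$time_min, d$value, unit = "min",
                label = if (!is.null(d$label)) d$label[1] else "")
}
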