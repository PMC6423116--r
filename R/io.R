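# Reading and writing the package's interchange formats: TIFF/PNG
# micrographs and CSV attribute/curve tables.

#' Read a micrograph from TIFF or PNG
#'
#' @param file path to a `.tif`/`.tiff` or `.png` file.
#' @return Numeric matrix in `[0, 1]` (first channel of multi-channel
#'   images).
#' @export
read_micrograph <- function(file) {
  ext <- tolower(tools::file_ext(file))
  m <- switch(ext,
    tif = , tiff = tiff::readTIFF(file),
    png = png::readPNG(file),
    stop("unsupported image format: .", ext))
  if (length(dim(m)) == 3L) m <- m[, , 1L]
  m
}

#' Write a binary or grayscale micrograph
#'
#' @param image numeric matrix in `[0, 1]` or a `calibrated_image`.
#' @param file output path ending in `.tif`, `.tiff` or `.png`.
#' @return `file`, invisibly.
#' @export
write_micrograph <- function(image, file) {
  if (inherits(image, "calibrated_image")) image <- image$pixels
  m <- matrix(as.numeric(image), nrow(image), ncol(image))
  ext <- tolower(tools::file_ext(file))
  switch(ext,
    tif = , tiff = tiff::writeTIFF(m, file),
    png = png::writePNG(m, file),
    stop("unsupported image format: .", ext))
  invisible(file)
}

#' Write / read an attribute table
#'
#' Plain CSV with one row per sample and at least the five attribute
#' columns `pw`, `br`, `apl`, `ly`, `epr`.
#'
#' @param table data frame.
#' @param file CSV path.
#' @return The file path ([write_attribute_table()]) or the table
#'   ([read_attribute_table()]).
#' @export
write_attribute_table <- function(table, file) {
  write.csv(table, file, row.names = FALSE)
  invisible(file)
}

#' @rdname write_attribute_table
#' @export
read_attribute_table <- function(file) {
  tab <- read.csv(file)
  missing <- setdiff(MICRO_NAMES, names(tab))
  if (length(missing))
    stop("attribute table lacks column(s): ", paste(missing, collapse = ", "))
  tab
}

#' Write / read rheometer curves as CSV
#'
#' Frequency sweeps use columns `frequency_hz`, `g_prime_pa`,
#' `g_doubleprime_pa`; creep-recovery curves use `time_s`,
#' `compliance_per_pa`, `phase` (`"creep"`/`"recovery"`).
#'
#' @param sweep a [frequency_sweep()].
#' @param curve a [creep_recovery_curve()].
#' @param file CSV path.
#' @return The file path (writers) or the reconstructed object (readers).
#' @export
write_sweep_csv <- function(sweep, file) {
  stopifnot(inherits(sweep, "frequency_sweep"))
  write.csv(data.frame(frequency_hz = sweep$omega / (2 * pi),
                       g_prime_pa = sweep$g_prime,
                       g_doubleprime_pa = sweep$g_doubleprime),
            file, row.names = FALSE)
  invisible(file)
}

#' @rdname write_sweep_csv
#' @export
read_sweep_csv <- function(file) {
  d <- read.csv(file)
  frequency_sweep(frequency_hz = d$frequency_hz,
                  g_prime = d$g_prime_pa,
                  g_doubleprime = d$g_doubleprime_pa)
}

#' @rdname write_sweep_csv
#' @export
write_creep_csv <- function(curve, file) {
  stopifnot(inherits(curve, "creep_recovery_curve"))
  write.csv(data.frame(
    time_s = curve$t,
    compliance_per_pa = curve$j,
    phase = ifelse(curve$t <= curve$creep_end, "creep", "recovery")),
    file, row.names = FALSE)
  invisible(file)
}

#' @rdname write_sweep_csv
#' @param creep_end,recovery_end,stress protocol constants used when the
#'   CSV is read back.
#' @export
read_creep_csv <- function(file, creep_end = 180, recovery_end = 540,
                           stress = 250) {
  d <- read.csv(file)
  creep_recovery_curve(d$time_s, d$compliance_per_pa,
                       creep_end = creep_end, recovery_end = recovery_end,
                       stress = stress)
}
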