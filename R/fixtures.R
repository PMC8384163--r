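#' Packaged multisite reproducibility results
#'
#' The in-package transcription of the published multisite reproducibility
#' table: five travelling volunteers scanned at four US sites (eight
#' pancreas measures per scan), and the calibrated phantom imaged at five
#' sites (organ volume, four T1 vials, ADC, MTR, fat fraction, with
#' reference values where the phantom was calibrated).  Missing cells (a
#' site without the fat-fraction sequence, one failed MTR measurement)
#' are `NA`.
#'
#' Measures in the volunteer table: `volume` (ml), `pvi` (ml/kg), `adc`
#' (mm^2/s), `t1` (ms), `mtr`, `panc_fat_fraction`, `hep_fat_fraction`,
#' `surface_to_volume` (1/cm).
#'
#' @return `table2_volunteers()` returns a [measure_table()];
#'   `table2_phantom()` returns a data.frame with columns `site`,
#'   `measure`, `value`, `reference`.
#' @export
table2_volunteers <- function() {
  path <- system.file("extdata", "table2_volunteers.csv", package = "qpanc",
                      mustWork = TRUE)
  measure_table(utils::read.csv(path, stringsAsFactors = FALSE))
}

#' @rdname table2_volunteers
#' @export
table2_phantom <- function() {
  path <- system.file("extdata", "table2_phantom.csv", package = "qpanc",
                      mustWork = TRUE)
  utils::read.csv(path, stringsAsFactors = FALSE)
}
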