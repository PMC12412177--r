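#' Bundled SPLASH II cross-workflow CCS comparison table
#'
#' Published comparison of nitrogen CCS values (squared Angstroms) for six
#' deuterated SPLASH II Lipidomix standards: the vendor single-pass
#' calibration workflow versus single-pass and multipass refined
#' calibration on the same cyclic-IMS acquisitions, with percent
#' differences quoted against the vendor values. Useful for exercising
#' [percent_difference] and the consistency checks between single-pass
#' and multipass calibration.
#'
#' @return Data.frame with columns `standard`, `adduct`, `ccs_waters`,
#'   `ccs_singlepass`, `pctdiff_singlepass`, `ccs_multipass`,
#'   `pctdiff_multipass`.
#' @export
splash_table1 <- function() {
  utils::read.csv(system.file("extdata", "splash_table1.csv",
                              package = "cimscal", mustWork = TRUE),
                  check.names = TRUE, stringsAsFactors = FALSE)
}

#' Bundled SPLASH II calibrant list
#'
#' The six SPLASH II lipid standards of [splash_table1] formatted as a
#' calibrant list (vendor-workflow CCS as the reference value). The m/z
#' column holds nominal adduct masses supplied by this package, adequate
#' for reduced-mass scaling but not for mass assignment.
#'
#' @return Path to the bundled CSV, readable with [read_calibrant_list].
#' @export
splash_calibrants_path <- function() {
  system.file("extdata", "splash_calibrants.csv", package = "cimscal",
              mustWork = TRUE)
}
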