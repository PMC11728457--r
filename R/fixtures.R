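#' Bundled reference datasets
#'
#' Small CSV tables shipped with the package: the flat-sheet membrane
#' structural parameters, the lab-scale dialyzer configuration, commercial
#' dialyzer areas/fiber counts and fiber geometries, the standard feed
#' concentrations, and the tortuosity coefficients fitted to datasheet
#' clearances.
#'
#' @param name one of `"table2_flat_membranes"`, `"table3_lab_dialyzer"`,
#'   `"table4_commercial"`, `"table5_commercial_geometry"`,
#'   `"feed_concentrations"`, `"fitted_xi"`.
#' @return data.frame.
#' @examples
#' hd_fixture("table2_flat_membranes")
#' @export
hd_fixture <- function(name = c("table2_flat_membranes",
                                "table3_lab_dialyzer",
                                "table4_commercial",
                                "table5_commercial_geometry",
                                "feed_concentrations",
                                "fitted_xi")) {
  name <- match.arg(name)
  path <- system.file("extdata", paste0(name, ".csv"),
                      package = "hemoclear", mustWork = TRUE)
  read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
}

#' Lab-scale reference dialyzer
#'
#' Convenience constructor for the 90-fiber laboratory dialyzer
#' configuration bundled with the package (fiber inner diameter 190 um,
#' wall 140 um, length 15 cm, DBL 63 um).
#'
#' @return a [dialyzer_spec()].
#' @export
lab_dialyzer_spec <- function() {
  tab <- hd_fixture("table3_lab_dialyzer")
  val <- setNames(tab$value, tab$parameter)
  dialyzer_spec(dhf_um = val[["dhf"]], lhf_cm = val[["lhf"]],
                d_um = val[["d"]], Nhf = val[["Nhf"]],
                delta_um = val[["delta"]])
}

#' Lab-scale reference membrane structure
#'
#' @return a [membrane_structure()] with the bundled hollow-fiber
#'   parameters (fp 0.77, alpha 0.083).
#' @export
lab_membrane_structure <- function() {
  tab <- hd_fixture("table3_lab_dialyzer")
  val <- setNames(tab$value, tab$parameter)
  membrane_structure(fp = val[["fp"]], alpha = val[["alpha"]])
}
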