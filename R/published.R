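# Published aggregates bundled with the package.
#
# The Luohu Hospital Group (Shenzhen) case that motivated this toolkit
# reports only district-level aggregates: yearly input/output column
# totals and per-unit Malmquist index tables. Those published numbers are
# shipped as plain CSVs under extdata; the per-DMU microdata are not
# public, which is exactly why the calibrated synthetic fixtures exist.

.extdata <- function(name) {
  path <- system.file("extdata", name, package = "deapanel")
  if (!nzchar(path))
    path <- file.path("inst", "extdata", name)   # pre-install fallback
  if (!file.exists(path)) stop("bundled data file missing: ", name)
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Published yearly totals for the 20 Luohu community health centers
#'
#' Column totals (2015-2021) of the four inputs (health workers, floor
#' area, equipment over CNY 5000, home hospital beds) and five outputs
#' (outpatient visits, home-bed medical services, health education
#' sessions, preventive medical services, chronic-disease management)
#' summed over the group's 20 community health centers. Note the 2021
#' health-education total is an order of magnitude above every earlier
#' year; it is reproduced here as published.
#'
#' @return data frame: period, kind (input/output), variable, total.
#' @export
luohu_chc_totals <- function() .extdata("luohu_chc_totals.csv")

#' Published yearly totals for the Luohu Hospital Group
#'
#' Group-level totals (2015-2021) of two inputs (health workers, beds)
#' and two outputs (outpatient and emergency visits, discharges).
#' District-level totals for the other nine Shenzhen regions are not
#' published.
#'
#' @return data frame: period, kind, variable, total.
#' @export
luohu_group_totals <- function() .extdata("luohu_group_totals.csv")

#' Published Malmquist decomposition for ten Shenzhen regions, 2015-2021
#'
#' Per-region mean EFFCH, TECHCH, PECH, SECH and TFPCH as published for
#' the regional health-resource comparison.
#'
#' @return data frame: region plus the five index columns.
#' @export
shenzhen_region_mpi <- function() .extdata("shenzhen_region_mpi.csv")

#' Published Malmquist decomposition for the 20 Luohu CHCs, 2015-2021
#'
#' @return data frame: chc plus the five index columns.
#' @export
luohu_chc_mpi <- function() .extdata("luohu_chc_mpi.csv")
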