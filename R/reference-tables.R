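## Bundled reference tables: the published ion particle analysis (count /
## total area / average size per ion and treatment), the percentage of -OH
## area free of Li+, and the in-solution salt effects on enzyme activities.
## They serve as in-package inputs for consistency checks and as the planted
## parameter source of the synthetic suite.

ref_path <- function(file) system.file("extdata", file, package = "ionsurf",
                                       mustWork = TRUE)

#' Reference ion particle table (count, area, average size)
#'
#' One row per ion and treatment, as printed in the source particle-analysis
#' table of the study this package models.
#'
#' @return Data frame: `ion`, `treatment`, `count`, `area_um2`,
#'   `average_size_um2`.
#' @export
ion_particle_reference <- function() {
  read.csv(ref_path("ion_particle_reference.csv"))
}

#' Reference percentages of -OH area free of Li+
#'
#' @return Data frame: `treatment`, `li_free_oh_area_pct`.
#' @export
li_free_oh_reference <- function() {
  read.csv(ref_path("li_free_oh_reference.csv"))
}

#' Bundled ion-in-solution activity table
#'
#' @return An [load_ion_effects()] result for the bundled reference CSV.
#' @export
ion_solution_reference <- function() {
  load_ion_effects(ref_path("ion_solution_effects.csv"))
}

#' Check internal consistency of a particle table
#'
#' A (count, area, average size) triplet is self-consistent when
#' `area / count`, rounded to the table's printed precision, reproduces the
#' printed average size (zero-count rows are consistent iff area and size
#' are 0). Published particle tables are not always self-consistent; this
#' check flags each cell so that downstream arithmetic only relies on
#' consistent ones.
#'
#' @param tbl data frame with `count`, `area_um2`, `average_size_um2`
#'   columns (e.g. [ion_particle_reference()]).
#' @param digits printed precision of the size column (default 3).
#' @return `tbl` with added columns `recomputed_size_um2` and `consistent`.
#' @export
check_particle_table <- function(tbl, digits = 3) {
  stopifnot(all(c("count", "area_um2", "average_size_um2") %in% names(tbl)))
  rec <- ifelse(tbl$count > 0, tbl$area_um2 / tbl$count, 0)
  tbl$recomputed_size_um2 <- rec
  tbl$consistent <- round(rec, digits) == round(tbl$average_size_um2, digits)
  tbl
}

#' Coverage percentage from a free-area percentage
#'
#' The share of sites covered by an ion is the complement of the reported
#' free share: `coverage = 100 - free`.
#'
#' @param free_pct free-area percentage in `[0, 100]`.
#' @return Coverage percentage.
#' @export
coverage_from_free <- function(free_pct) {
  if (any(free_pct < 0 | free_pct > 100)) stop("percentages must lie in [0, 100]")
  100 - free_pct
}
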