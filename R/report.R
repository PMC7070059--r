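#' Significance marker in figure-legend style
#'
#' `***` for p < 0.001, `**` for p < 0.01, `*` for p < 0.05, `ns`
#' otherwise. Raw p values should always be reported alongside.
#'
#' @param p p value(s).
#' @return character vector of markers.
#' @export
significance_marker <- function(p) {
  vapply(p, function(pp) {
    if (!is.finite(pp)) return(NA_character_)
    if (pp < 0.001) "***" else if (pp < 0.01) "**" else if (pp < 0.05) "*"
    else "ns"
  }, character(1))
}

#' Group statistics table for a report
#'
#' Means with SEM per group plus the omnibus ANOVA row, formatted the
#' way figure legends summarise group comparisons.
#'
#' @param values numeric response.
#' @param groups group labels.
#' @return data frame with group, n, mean, sem and attributes
#'   `f_statistic`, `p_value`, `marker`.
#' @export
group_stats_table <- function(values, groups) {
  gc <- group_compare(values, groups)
  out <- gc$summary[, c("group", "n", "mean", "sem")]
  attr(out, "f_statistic") <- gc$f_statistic
  attr(out, "p_value") <- gc$p_value
  attr(out, "marker") <- significance_marker(gc$p_value)
  out
}

#' Write a provenance record for an analysis run
#'
#' Records the seed, parameters, package version and timestamp of a run
#' as JSON next to its outputs, so every results directory states how
#' it was produced.
#'
#' @param path output JSON path.
#' @param seed the seed the run used.
#' @param config named list of run parameters (echoed verbatim).
#' @export
write_provenance <- function(path, seed, config = list()) {
  jsonlite::write_json(
    list(
      seed = seed,
      config = config,
      package = "nirperm",
      version = as.character(utils::packageVersion("nirperm")),
      r_version = R.version.string,
      timestamp = format(Sys.time(), tz = "UTC", usetz = TRUE)
    ),
    path, auto_unbox = TRUE, digits = NA, pretty = TRUE
  )
  invisible(path)
}
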