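#' Read and write time-course tables
#'
#' CSV with columns `animal_id`, `group`, `time_h`, `conc_ng_ml`,
#' `censored` (0/1). Reading validates per animal (strictly increasing
#' times, non-negative concentrations).
#'
#' @param path file path.
#' @return [read_timecourse_csv()] returns a `timecourse` data frame.
#' @export
read_timecourse_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("animal_id", "group", "time_h", "conc_ng_ml", "censored")
  if (!all(need %in% names(df))) {
    stop("time-course CSV needs columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  parts <- lapply(split(df, df$animal_id), function(d) {
    d <- d[order(d$time_h), ]
    timecourse(d$animal_id[1], d$group[1], d$time_h, d$conc_ng_ml,
               as.logical(d$censored))
  })
  out <- do.call(rbind, unname(parts))
  class(out) <- c("timecourse", "data.frame")
  out
}

#' @rdname read_timecourse_csv
#' @param tc a `timecourse` data frame.
#' @export
write_timecourse_csv <- function(tc, path) {
  stopifnot(inherits(tc, "timecourse"))
  out <- as.data.frame(tc)
  out$censored <- as.integer(out$censored)
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' Read a plate-reader CSV and calibrate it
#'
#' Expects columns `well`, `type` (`standard`/`blank`/`sample`),
#' `known_conc_ng_ml`, `fluorescence`, `animal_id`, `group`. Fits the
#' standard curve from standard and blank wells and converts the sample
#' wells to blood concentrations.
#'
#' @param path plate CSV path (or a data frame in the same layout).
#' @param dilution blood dilution factor of sample wells.
#' @return list with `curve` (a `standard_curve`) and `samples` (data
#'   frame animal_id, group, conc_ng_ml, censored).
#' @export
read_plate_csv <- function(path, dilution = 3) {
  df <- if (is.data.frame(path)) path else {
    utils::read.csv(path, stringsAsFactors = FALSE)
  }
  need <- c("well", "type", "known_conc_ng_ml", "fluorescence")
  if (!all(need %in% names(df))) {
    stop("plate CSV needs columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  std <- df[df$type == "standard", ]
  blk <- df[df$type == "blank", ]
  smp <- df[df$type == "sample", ]
  curve <- fit_standard_curve(std$known_conc_ng_ml, std$fluorescence,
                              blk$fluorescence)
  samples <- NULL
  if (nrow(smp) > 0) {
    conv <- to_concentration(curve, smp$fluorescence, dilution = dilution)
    samples <- data.frame(animal_id = smp$animal_id, group = smp$group,
                          conc_ng_ml = conv$conc_ng_ml,
                          censored = conv$censored)
  }
  list(curve = curve, samples = samples)
}

#' Write kinetic parameters as JSON with the fixed/fitted split
#'
#' @param params a [pk_params()] object.
#' @param fitted character vector naming which fields were fitted
#'   (the rest are recorded as fixed).
#' @param path output path.
#' @export
write_pk_params_json <- function(params, path,
                                 fitted = c("ka", "kce")) {
  stopifnot(inherits(params, "pk_params"))
  vals <- unclass(params)
  fixed <- setdiff(c("ka", "kce", "k12", "k21", "k10", "Vc"), fitted)
  jsonlite::write_json(
    list(parameters = vals, fitted = fitted, fixed = fixed),
    path, auto_unbox = TRUE, digits = NA
  )
  invisible(path)
}

#' @rdname write_pk_params_json
#' @export
read_pk_params_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  do.call(pk_params, obj$parameters)
}
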