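#' Fit a plate-reader standard curve
#'
#' Ordinary least-squares line through known concentrations versus
#' fluorescence. The limit of detection is the concentration whose
#' expected signal equals the blank mean plus three blank standard
#' deviations (the usual analytical convention):
#' LOD = (mean(blanks) - intercept + 3 sd(blanks)) / slope.
#'
#' @param known_conc known standard concentrations (ng/ml), at least 4
#'   distinct levels.
#' @param fluorescence measured fluorescence for each standard (same
#'   length; replicates allowed by repeating concentrations).
#' @param blanks fluorescence readings of blank wells.
#' @return object of class `standard_curve`: `slope`, `intercept`,
#'   `lod` (ng/ml), `r_squared`, `residual_sd`.
#' @examples
#' sc <- fit_standard_curve(c(1, 5, 10, 50), 100 * c(1, 5, 10, 50) + 48,
#'                          blanks = c(50, 52, 48))
#' sc$lod
#' @export
fit_standard_curve <- function(known_conc, fluorescence, blanks) {
  if (length(known_conc) != length(fluorescence)) {
    stop("known_conc and fluorescence must have equal length", call. = FALSE)
  }
  if (length(unique(known_conc)) < 4) {
    stop("need at least 4 distinct concentration levels", call. = FALSE)
  }
  if (length(blanks) < 1) stop("need blank readings", call. = FALSE)
  fit <- stats::lm(fluorescence ~ known_conc)
  slope <- unname(stats::coef(fit)[2])
  intercept <- unname(stats::coef(fit)[1])
  if (!is.finite(slope) || slope <= 0) {
    stop("calibration is non-monotone (slope <= 0)", call. = FALSE)
  }
  blank_sd <- if (length(blanks) > 1) stats::sd(blanks) else 0
  lod <- max(0, (mean(blanks) - intercept + 3 * blank_sd) / slope)
  ss_res <- sum(stats::residuals(fit)^2)
  ss_tot <- sum((fluorescence - mean(fluorescence))^2)
  structure(
    list(slope = slope, intercept = intercept, lod = lod,
         r_squared = 1 - ss_res / ss_tot,
         residual_sd = sqrt(ss_res / fit$df.residual)),
    class = "standard_curve"
  )
}

#' Convert fluorescence to blood concentration
#'
#' Inverts the standard curve and multiplies by the dilution factor
#' (default 3: 10 uL whole blood into 20 uL EDTA/PBS). The in-well
#' concentration is compared against the curve's limit of detection;
#' readings below it are censored. Negative back-calculated
#' concentrations are floored at zero.
#'
#' @param curve a [fit_standard_curve()] object.
#' @param fluorescence sample fluorescence reading(s).
#' @param dilution dilution factor, >= 1.
#' @return data frame with `conc_ng_ml` (blood scale) and `censored`.
#' @export
to_concentration <- function(curve, fluorescence, dilution = 3) {
  stopifnot(inherits(curve, "standard_curve"))
  if (any(dilution < 1)) stop("dilution factor must be >= 1", call. = FALSE)
  well <- (fluorescence - curve$intercept) / curve$slope
  censored <- well < curve$lod
  conc <- pmax(well, 0) * dilution
  data.frame(conc_ng_ml = conc, censored = censored)
}

#' Percent reduction of a group mean relative to control
#'
#' (1 - treated/control) x 100, clipped at 0 (and flagged) when the
#' treated mean exceeds control. Invariant to rescaling both means.
#'
#' @param control control group mean (> 0).
#' @param treated treated group mean.
#' @return percent in \[0, 100\] with attribute `clipped`.
#' @examples
#' percent_reduction(2.6, 0.02)  # 99.2
#' @export
percent_reduction <- function(control, treated) {
  if (!is.finite(control) || control <= 0) {
    stop("control mean must be > 0", call. = FALSE)
  }
  raw <- (1 - treated / control) * 100
  out <- max(0, raw)
  attr(out, "clipped") <- raw < 0
  out
}

#' Fold change between two group means
#'
#' @param numerator numerator mean.
#' @param denominator denominator mean (> 0), or a censored value to be
#'   substituted.
#' @param denominator_censored if TRUE, `lod`/2 replaces the denominator
#'   and the result is flagged.
#' @param lod limit of detection used for the censored substitution.
#' @return ratio, with attribute `censored_denominator`.
#' @examples
#' fold_change(12.3, 3.4)  # 3.62
#' @export
fold_change <- function(numerator, denominator,
                        denominator_censored = FALSE, lod = NULL) {
  if (denominator_censored) {
    if (is.null(lod) || lod <= 0) {
      stop("censored denominator substitution needs a positive lod",
           call. = FALSE)
    }
    denominator <- lod / 2
  }
  if (!is.finite(denominator) || denominator <= 0) {
    stop("denominator must be > 0", call. = FALSE)
  }
  out <- numerator / denominator
  attr(out, "censored_denominator") <- denominator_censored
  out
}

#' One-way ANOVA with Tukey HSD pairwise comparisons
#'
#' Group means with SEM, the omnibus F test, and Tukey honestly
#' significant difference adjusted pairwise p values (Tukey-Kramer for
#' unequal n, as provided by [stats::TukeyHSD()]).
#'
#' @param values numeric response.
#' @param groups group labels, same length; at least 2 groups with
#'   n >= 2 each.
#' @param tukey compute pairwise Tukey comparisons (skippable in large
#'   simulation loops where only the omnibus test is needed).
#' @return object of class `group_comparison`: `summary` (data frame
#'   with group, n, mean, sd, sem), `f_statistic`, `p_value`,
#'   `tukey` (data frame with comparison, diff, p_adj) or NULL.
#' @export
group_compare <- function(values, groups, tukey = TRUE) {
  if (length(values) != length(groups)) {
    stop("values and groups must have equal length", call. = FALSE)
  }
  g <- factor(groups)
  if (nlevels(g) < 2) stop("need at least 2 groups", call. = FALSE)
  n_per <- table(g)
  if (any(n_per < 2)) stop("every group needs n >= 2", call. = FALSE)

  sm <- data.frame(
    group = levels(g),
    n = as.integer(n_per),
    mean = as.numeric(tapply(values, g, mean)),
    sd = as.numeric(tapply(values, g, stats::sd)),
    row.names = NULL
  )
  sm$sem <- sm$sd / sqrt(sm$n)

  grand <- mean(values)
  ss_between <- sum(n_per * (sm$mean - grand)^2)
  if (ss_between == 0) {
    # identical group means (e.g. all observations equal): no signal
    f <- 0
    p <- 1
    tk <- NULL
    if (tukey) {
      cmb <- utils::combn(levels(g), 2)
      tk <- data.frame(comparison = paste(cmb[2, ], cmb[1, ], sep = "-"),
                       diff = 0, p_adj = 1)
    }
  } else {
    fit <- stats::aov(values ~ g)
    an <- summary(fit)[[1]]
    f <- an[["F value"]][1]
    p <- an[["Pr(>F)"]][1]
    tk <- NULL
    if (tukey) {
      th <- stats::TukeyHSD(fit)$g
      tk <- data.frame(comparison = rownames(th),
                       diff = th[, "diff"],
                       p_adj = th[, "p adj"],
                       row.names = NULL)
    }
  }
  structure(
    list(summary = sm, f_statistic = f, p_value = p, tukey = tk),
    class = "group_comparison"
  )
}

#' @export
print.group_comparison <- function(x, ...) {
  cat("One-way ANOVA: F =", format(x$f_statistic, digits = 4),
      ", p =", format.pval(x$p_value, digits = 3),
      significance_marker(x$p_value), "\n")
  print(x$summary, row.names = FALSE)
  if (!is.null(x$tukey)) {
    cat("Tukey HSD:\n")
    print(x$tukey, row.names = FALSE)
  }
  invisible(x)
}
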