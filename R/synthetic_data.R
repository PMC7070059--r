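# run code under a given seed without disturbing the caller's RNG stream
.with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

# mean-preserving lognormal multiplier(s) with coefficient of variation cv
.lognorm_mult <- function(n, cv) {
  if (cv <= 0) return(rep(1, n))
  sigma <- sqrt(log(1 + cv^2))
  stats::rlnorm(n, meanlog = -sigma^2 / 2, sdlog = sigma)
}

#' Default disease-state kinetic parameters for the mouse tracer model
#'
#' Illustrative parameter sets for the synthetic cohorts. The disease
#' ("dss") set is calibrated so that a 2 mg/kg oral dose in a 20 g mouse
#' peaks near 8 h at about 13 ng/ml, with a very small bioavailable
#' fraction, as expected for a ~1 kDa polyanionic dye crossing the leak
#' pathway of an inflamed colon; the "naive" set absorbs essentially
#' nothing, leaving only the flat ~2 ng/ml blood background. The
#' disposition constants stand in for values that would come from
#' intravenously dosed animals.
#'
#' @param condition `"dss"` or `"naive"`.
#' @return a [pk_params()] object.
#' @export
default_pk_params <- function(condition = c("dss", "naive")) {
  condition <- match.arg(condition)
  switch(condition,
    dss = pk_params(ka = 2.38e-4, kce = 0.0873, k12 = 0.05, k21 = 0.08,
                    k10 = 0.15, Vc = 2),
    naive = pk_params(ka = 1.0e-6, kce = 0.0873, k12 = 0.05, k21 = 0.08,
                      k10 = 0.15, Vc = 2)
  )
}

#' Specification of a simulated pharmacokinetic cohort
#'
#' @param group group label.
#' @param n number of animals (>= 1).
#' @param params mean kinetic parameters ([pk_params()]).
#' @param dose the administered [pk_dose()].
#' @param times sampling times (h).
#' @param cv_ka inter-animal coefficient of variation of `ka`
#'   (lognormal, mean-preserving).
#' @param cv_noise multiplicative measurement noise CV (lognormal).
#' @param lod assay limit of detection (ng/ml); measurements below it
#'   are flagged censored.
#' @param baseline_ng_ml constant blood background added to the kinetic
#'   curve (the flat ~2 ng/ml signal of naive animals).
#' @param seed cohort seed (required; all randomness flows from it).
#' @return object of class `cohort_spec`.
#' @export
cohort_spec <- function(group, n, params, dose,
                        times = c(1, 2, 4, 6, 8, 10, 12, 16, 20, 24, 36, 48),
                        cv_ka = 0.3, cv_noise = 0.1, lod = 0.5,
                        baseline_ng_ml = 0, seed) {
  stopifnot(inherits(params, "pk_params"), inherits(dose, "pk_dose"))
  if (n < 1) stop("n must be >= 1", call. = FALSE)
  if (cv_ka < 0 || cv_noise < 0) stop("CVs must be >= 0", call. = FALSE)
  if (missing(seed)) stop("a seed is required for reproducibility", call. = FALSE)
  structure(
    list(group = group, n = n, params = params, dose = dose, times = times,
         cv_ka = cv_ka, cv_noise = cv_noise, lod = lod,
         baseline_ng_ml = baseline_ng_ml, seed = as.integer(seed)),
    class = "cohort_spec"
  )
}

#' Generate a synthetic pharmacokinetic cohort
#'
#' Draws per-animal absorption rates lognormally around the cohort mean,
#' simulates each animal's blood curve, adds the constant background,
#' applies multiplicative measurement noise, and censors values below
#' the limit of detection. A ground-truth table of the per-animal
#' parameters is returned alongside the data for recovery studies.
#'
#' @param spec a [cohort_spec()].
#' @return list with `data` (stacked [timecourse()] rows for all
#'   animals) and `truth` (data frame animal_id, group, ka, kce, ...).
#' @export
generate_pk_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  .with_seed(spec$seed, {
    p <- spec$params
    ka_i <- p$ka * .lognorm_mult(spec$n, spec$cv_ka)
    rows <- vector("list", spec$n)
    for (i in seq_len(spec$n)) {
      pi <- pk_params(ka = ka_i[i], kce = p$kce, k12 = p$k12, k21 = p$k21,
                      k10 = p$k10, Vc = p$Vc, ka2 = p$ka2, lag2 = p$lag2,
                      frac2 = p$frac2)
      id <- sprintf("%s_%02d", spec$group, i)
      tc <- simulate_pk(pi, spec$dose, spec$times, animal_id = id,
                        group = spec$group)
      conc <- (tc$conc_ng_ml + spec$baseline_ng_ml) *
        .lognorm_mult(length(spec$times), spec$cv_noise)
      rows[[i]] <- timecourse(id, spec$group, spec$times, conc,
                              censored = conc < spec$lod)
    }
    truth <- data.frame(
      animal_id = sprintf("%s_%02d", spec$group, seq_len(spec$n)),
      group = spec$group, ka = ka_i, kce = p$kce, k12 = p$k12, k21 = p$k21,
      k10 = p$k10, Vc = p$Vc, baseline_ng_ml = spec$baseline_ng_ml,
      stringsAsFactors = FALSE
    )
    list(data = do.call(rbind, rows), truth = truth)
  })
}

#' Generate a synthetic plate-reader table
#'
#' Standards, blanks and samples with multiplicative fluorescence noise,
#' in the layout consumed by [fit_standard_curve()] and
#' [to_concentration()]. Sample wells contain blood diluted by
#' `dilution`, so their in-well concentration is the blood concentration
#' divided by the dilution factor.
#'
#' @param slope,intercept true calibration line (fluorescence units per
#'   ng/ml; fluorescence units).
#' @param blank_sd standard deviation of blank wells.
#' @param standards concentration levels (ng/ml) of the standard series.
#' @param sample_conc named numeric vector of blood concentrations
#'   (names are animal ids).
#' @param groups group label per sample (recycled).
#' @param dilution blood dilution factor of the sample wells.
#' @param cv_noise multiplicative noise CV on non-blank wells.
#' @param n_blanks number of blank wells.
#' @param seed plate seed.
#' @return list with `plate` (data frame well, type, known_conc_ng_ml,
#'   fluorescence, animal_id, group) and `truth` (slope, intercept,
#'   blank_sd, sample concentrations).
#' @export
generate_plate <- function(slope, intercept, blank_sd = 0,
                           standards = c(0.5, 1, 2, 5, 10, 20),
                           sample_conc = numeric(0), groups = "sample",
                           dilution = 3, cv_noise = 0, n_blanks = 3, seed) {
  if (missing(seed)) stop("a seed is required", call. = FALSE)
  .with_seed(seed, {
    std_f <- (slope * standards + intercept) *
      .lognorm_mult(length(standards), cv_noise)
    blank_f <- intercept + stats::rnorm(n_blanks, 0, blank_sd)
    samp_f <- if (length(sample_conc)) {
      (slope * sample_conc / dilution + intercept) *
        .lognorm_mult(length(sample_conc), cv_noise)
    } else numeric(0)
    ids <- if (length(sample_conc)) {
      if (is.null(names(sample_conc))) {
        paste0("animal_", seq_along(sample_conc))
      } else names(sample_conc)
    } else character(0)
    plate <- rbind(
      data.frame(well = paste0("S", seq_along(standards)), type = "standard",
                 known_conc_ng_ml = standards, fluorescence = std_f,
                 animal_id = NA_character_, group = NA_character_),
      data.frame(well = paste0("B", seq_len(n_blanks)), type = "blank",
                 known_conc_ng_ml = NA_real_, fluorescence = blank_f,
                 animal_id = NA_character_, group = NA_character_),
      if (length(sample_conc)) {
        data.frame(well = paste0("W", seq_along(sample_conc)),
                   type = "sample", known_conc_ng_ml = NA_real_,
                   fluorescence = samp_f, animal_id = ids,
                   group = rep_len(groups, length(sample_conc)))
      }
    )
    list(plate = plate,
         truth = list(slope = slope, intercept = intercept,
                      blank_sd = blank_sd, dilution = dilution,
                      sample_conc = sample_conc))
  })
}

#' Defining frame annotation for each rubric grade
#'
#' The canonical annotation whose features match one grade of the CLE
#' severity rubric exactly (and no higher grade); used by the cohort
#' generator and as worked rubric examples.
#'
#' @param score integer 0-5.
#' @return a [frame_annotation()].
#' @export
rubric_exemplar <- function(score) {
  if (!(score %in% 0:5)) stop("score must be an integer in 0..5", call. = FALSE)
  switch(as.character(score),
    "0" = frame_annotation(),
    "1" = frame_annotation(ne680_lumen = "present"),
    "2" = frame_annotation(healthy_crypt_fraction = 0.8,
                           crypt_architecture_change = "present",
                           collapsed_crypts = "present",
                           ne680_lumen = "high"),
    "3" = frame_annotation(healthy_crypt_fraction = 0.4,
                           crypt_architecture_change = "present",
                           collapsed_crypts = "significant",
                           ne680_lumen = "high", ne680_area = "high"),
    "4" = frame_annotation(healthy_crypt_fraction = 0.2,
                           crypt_architecture_change = "present",
                           collapsed_crypts = "significant",
                           ne680_lumen = "high", ne680_area = "high",
                           acriflavine_unstained_fraction = 0.7,
                           ne680_cells_in_erosions = "present",
                           crypt_loss = "present"),
    "5" = frame_annotation(healthy_crypt_fraction = 0,
                           crypt_architecture_change = "present",
                           collapsed_crypts = "significant",
                           ne680_lumen = "high", ne680_area = "high",
                           acriflavine_unstained_fraction = 0.9,
                           ne680_cells_in_erosions = "exclusive",
                           crypt_loss = "significant")
  )
}

#' Specification of a simulated severity-scored cohort
#'
#' @param group group label.
#' @param target_score rubric score (0-5) the cohort should express.
#' @param n animals.
#' @param frames_per_animal CLE frames per animal (>= 1).
#' @param noise_rate probability that a frame is perturbed one severity
#'   step up or down.
#' @param seed cohort seed.
#' @return object of class `severity_cohort_spec`.
#' @export
severity_cohort_spec <- function(group, target_score, n,
                                 frames_per_animal = 3, noise_rate = 0,
                                 seed) {
  if (!(target_score %in% 0:5)) stop("target_score must be 0..5", call. = FALSE)
  if (missing(seed)) stop("a seed is required", call. = FALSE)
  if (noise_rate < 0 || noise_rate > 1) stop("noise_rate in [0,1]", call. = FALSE)
  structure(
    list(group = group, target_score = as.integer(target_score), n = n,
         frames_per_animal = frames_per_animal, noise_rate = noise_rate,
         seed = as.integer(seed)),
    class = "severity_cohort_spec"
  )
}

#' Generate CLE frame annotations for a severity cohort
#'
#' Each frame is the defining annotation of the cohort's target grade;
#' with noise rate epsilon a frame is instead drawn one severity step up
#' or down (clamped to 0-5). At zero noise the modal per-animal score
#' equals the target for every grade.
#'
#' @param spec a [severity_cohort_spec()].
#' @return list of animals; each animal is a list with `animal_id`,
#'   `group`, `frames` (list of [frame_annotation()]).
#' @export
generate_cle_cohort <- function(spec) {
  stopifnot(inherits(spec, "severity_cohort_spec"))
  .with_seed(spec$seed, {
    lapply(seq_len(spec$n), function(i) {
      frames <- lapply(seq_len(spec$frames_per_animal), function(j) {
        s <- spec$target_score
        if (spec$noise_rate > 0 && stats::runif(1) < spec$noise_rate) {
          s <- s + sample(c(-1L, 1L), 1)
          s <- max(0L, min(5L, s))
        }
        rubric_exemplar(s)
      })
      list(animal_id = sprintf("%s_%02d", spec$group, i),
           group = spec$group, frames = frames)
    })
  })
}

#' Generate synthetic organ-imaging and IHC tables
#'
#' Per-animal whole/distal/proximal ROI rows with lognormal mean
#' fluorescence intensities around the configured group means (the
#' proximal segment runs hotter than the distal one, as colon imaging
#' shows), and beta-distributed marker-positive area fractions for the
#' IHC table. Setting all group means equal makes the groups
#' exchangeable.
#'
#' @param group_mfi named numeric vector: mean whole-organ MFI per
#'   group.
#' @param group_pos_frac named numeric vector: mean marker-positive
#'   fraction (0-1) per group.
#' @param n animals per group.
#' @param mfi_cv inter-animal CV of MFI.
#' @param frac_kappa beta concentration parameter of the positive
#'   fractions (larger = tighter).
#' @param marker IHC marker name.
#' @param proximal_boost multiplicative elevation of the proximal over
#'   the distal segment.
#' @param seed seed.
#' @return list with `roi` (data frame animal_id, group, region,
#'   pixel_count, intensity_sum, mfi) and `ihc` (data frame animal_id,
#'   group, marker, marker_area, mucosal_area).
#' @export
generate_imaging_tables <- function(group_mfi, group_pos_frac = NULL,
                                    n = 10, mfi_cv = 0.25, frac_kappa = 50,
                                    marker = "NE", proximal_boost = 1.4,
                                    seed) {
  if (missing(seed)) stop("a seed is required", call. = FALSE)
  if (is.null(group_pos_frac)) {
    group_pos_frac <- stats::setNames(rep(0.05, length(group_mfi)),
                                      names(group_mfi))
  }
  .with_seed(seed, {
    roi <- list(); ihc <- list()
    for (g in names(group_mfi)) {
      for (i in seq_len(n)) {
        id <- sprintf("%s_%02d", g, i)
        base <- group_mfi[[g]] * .lognorm_mult(1, mfi_cv)
        n_dist <- 5000L
        n_prox <- 7000L
        mfi_prox <- base * proximal_boost * .lognorm_mult(1, 0.05)
        mfi_dist <- base * .lognorm_mult(1, 0.05)
        sum_dist <- mfi_dist * n_dist
        sum_prox <- mfi_prox * n_prox
        roi[[length(roi) + 1]] <- data.frame(
          animal_id = id, group = g,
          region = c("whole", "distal", "proximal"),
          pixel_count = c(n_dist + n_prox, n_dist, n_prox),
          intensity_sum = c(sum_dist + sum_prox, sum_dist, sum_prox)
        )
        mu <- group_pos_frac[[g]]
        frac <- stats::rbeta(1, mu * frac_kappa, (1 - mu) * frac_kappa)
        mucosa <- 1e6
        ihc[[length(ihc) + 1]] <- data.frame(
          animal_id = id, group = g, marker = marker,
          marker_area = round(frac * mucosa), mucosal_area = mucosa
        )
      }
    }
    roi <- do.call(rbind, roi)
    roi$mfi <- roi$intensity_sum / roi$pixel_count
    list(roi = roi, ihc = do.call(rbind, ihc))
  })
}
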