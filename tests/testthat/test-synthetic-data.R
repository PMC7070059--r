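test_that("zero-variability cohorts reproduce the mean curve exactly", {
  spec <- cohort_spec("DSS", n = 3, params = default_pk_params("dss"),
                      dose = pk_dose(mg_per_kg = 2), cv_ka = 0, cv_noise = 0,
                      baseline_ng_ml = 0, lod = 0.5, seed = 1)
  out <- generate_pk_cohort(spec)
  mean_curve <- simulate_pk(default_pk_params("dss"), pk_dose(mg_per_kg = 2),
                            spec$times)$conc_ng_ml
  for (id in unique(out$data$animal_id)) {
    expect_equal(out$data$conc_ng_ml[out$data$animal_id == id], mean_curve)
  }
})

test_that("cohort generation is seed-deterministic", {
  mk <- function(seed) generate_pk_cohort(
    cohort_spec("DSS", n = 4, params = default_pk_params("dss"),
                dose = pk_dose(mg_per_kg = 2), seed = seed))
  expect_identical(mk(11), mk(11))
  expect_false(identical(mk(11)$data$conc_ng_ml, mk(12)$data$conc_ng_ml))
})

test_that("generators leave the caller's RNG stream untouched", {
  set.seed(99)
  before <- .Random.seed
  invisible(generate_pk_cohort(
    cohort_spec("DSS", n = 2, params = default_pk_params("dss"),
                dose = pk_dose(mg_per_kg = 2), seed = 5)))
  invisible(generate_cle_cohort(
    severity_cohort_spec("g", 2, n = 2, seed = 5)))
  expect_identical(.Random.seed, before)
})

test_that("naive cohorts sit at the flat background and censor at the LOD", {
  spec <- cohort_spec("naive", n = 5, params = default_pk_params("naive"),
                      dose = pk_dose(mg_per_kg = 2), cv_ka = 0.3,
                      cv_noise = 0.1, baseline_ng_ml = 2, lod = 0.5, seed = 3)
  out <- generate_pk_cohort(spec)
  expect_lt(max(out$data$conc_ng_ml), 5)
  expect_identical(out$data$censored, out$data$conc_ng_ml < 0.5)
})

test_that("oral fitting recovers the per-animal ground truth", {
  spec <- cohort_spec("DSS", n = 3, params = default_pk_params("dss"),
                      dose = pk_dose(mg_per_kg = 2), cv_ka = 0.3,
                      cv_noise = 0, baseline_ng_ml = 0, lod = 0, seed = 17)
  out <- generate_pk_cohort(spec)
  for (i in seq_len(3)) {
    id <- out$truth$animal_id[i]
    d <- out$data[out$data$animal_id == id, ]
    tc <- timecourse(id, "DSS", d$time_h, d$conc_ng_ml)
    fit <- fit_oral(tc, list(k10 = 0.15, k12 = 0.05, k21 = 0.08, Vc = 2),
                    pk_dose(mg_per_kg = 2), lod = 0.5)
    expect_lt(abs(fit$estimate["ka"] - out$truth$ka[i]) / out$truth$ka[i],
              1e-3)
  }
})

test_that("zero-noise plates round-trip through calibration exactly", {
  conc <- c(a1 = 4, a2 = 9, a3 = 0.9)
  pl <- generate_plate(slope = 100, intercept = 50, blank_sd = 0,
                       sample_conc = conc, dilution = 3, cv_noise = 0,
                       seed = 2)
  res <- read_plate_csv(pl$plate, dilution = 3)
  expect_equal(res$curve$slope, 100)
  expect_equal(res$curve$intercept, 50)
  expect_equal(res$curve$lod, 0)
  expect_equal(res$samples$conc_ng_ml, unname(conc))
})

test_that("samples at zero concentration are censored on a noisy plate", {
  pl <- generate_plate(slope = 100, intercept = 50, blank_sd = 2,
                       sample_conc = c(x1 = 0, x2 = 0), cv_noise = 0,
                       seed = 8)
  res <- read_plate_csv(pl$plate)
  expect_true(all(res$samples$censored))
})

test_that("plate generation is seed-deterministic", {
  p1 <- generate_plate(100, 50, blank_sd = 2, cv_noise = 0.05,
                       sample_conc = c(a = 5), seed = 4)
  p2 <- generate_plate(100, 50, blank_sd = 2, cv_noise = 0.05,
                       sample_conc = c(a = 5), seed = 4)
  expect_identical(p1, p2)
})

test_that("severity cohorts hit their target score at zero noise", {
  for (s in 0:5) {
    cohort <- generate_cle_cohort(
      severity_cohort_spec("g", s, n = 4, frames_per_animal = 3, seed = 6))
    scores <- vapply(cohort, function(a) score_animal(a$frames)$score,
                     integer(1))
    expect_identical(scores, rep(as.integer(s), 4))
  }
})

test_that("annotation noise perturbs frames one severity step", {
  cohort <- generate_cle_cohort(
    severity_cohort_spec("g", 0, n = 10, frames_per_animal = 5,
                         noise_rate = 1, seed = 13))
  fr_scores <- unlist(lapply(cohort, function(a) {
    vapply(a$frames, score_frame, integer(1))
  }))
  expect_true(any(fr_scores > 0))
  expect_true(all(fr_scores <= 1))
})

test_that("imaging tables reproduce the configured group ordering", {
  tabs <- generate_imaging_tables(
    group_mfi = c(DSS = 2000, `DSS+IL22Fc` = 800, naive = 700),
    group_pos_frac = c(DSS = 0.2, `DSS+IL22Fc` = 0.06, naive = 0.05),
    n = 50, seed = 19)
  whole <- tabs$roi[tabs$roi$region == "whole", ]
  mfis <- tapply(whole$mfi, whole$group, mean)
  expect_gt(mfis[["DSS"]], mfis[["DSS+IL22Fc"]])
  expect_gt(mfis[["DSS+IL22Fc"]], 0.8 * mfis[["naive"]])
  pf <- with(tabs$ihc, tapply(positive_fraction(marker_area, mucosal_area),
                              group, mean))
  expect_gt(pf[["DSS"]], pf[["DSS+IL22Fc"]])
  # normalized group means preserve the ordering
  norm <- min_max_normalize(whole$mfi)
  nm <- tapply(norm, whole$group, mean)
  expect_gt(nm[["DSS"]], nm[["DSS+IL22Fc"]])
})

test_that("imaging whole-organ rows equal distal plus proximal", {
  tabs <- generate_imaging_tables(group_mfi = c(a = 1000, b = 1000),
                                  n = 5, seed = 23)
  for (id in unique(tabs$roi$animal_id)) {
    d <- tabs$roi[tabs$roi$animal_id == id, ]
    expect_equal(d$pixel_count[d$region == "whole"],
                 sum(d$pixel_count[d$region != "whole"]))
    expect_equal(d$intensity_sum[d$region == "whole"],
                 sum(d$intensity_sum[d$region != "whole"]))
  }
})
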