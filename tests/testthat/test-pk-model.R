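test_that("nothing is absorbed when ka = 0 after an oral dose", {
  p <- pk_params(ka = 0, kce = 0.1, k12 = 0.05, k21 = 0.08, k10 = 0.2, Vc = 2)
  tc <- simulate_pk(p, pk_dose(amount = 1e4, route = "oral"),
                    times = c(0, 1, 4, 8, 24, 48))
  expect_equal(tc$conc_ng_ml, rep(0, 6))
})

test_that("model reduces to the Bateman one-compartment form", {
  D <- 4e4; ka <- 0.4; k10 <- 0.1; Vc <- 2
  p <- pk_params(ka = ka, kce = 0, k12 = 0, k21 = 0, k10 = k10, Vc = Vc)
  tt <- c(0.5, 1, 2, 4, 8, 16, 32)
  got <- simulate_pk(p, pk_dose(amount = D, route = "oral"), tt)$conc_ng_ml
  want <- bateman_conc(D, ka, k10, Vc, tt)
  expect_lt(max(abs(got - want) / want), 1e-9)
})

test_that("oral concentration starts at zero and stays non-negative", {
  withr::with_seed(42, {
    for (i in 1:20) {
      p <- random_pk_params()
      d <- pk_dose(amount = 1e4, route = "oral")
      tc <- simulate_pk(p, d, times = c(0, 10^seq(-2, 2, length.out = 25)))
      expect_equal(tc$conc_ng_ml[1], 0)
      expect_true(all(tc$conc_ng_ml >= 0))
    }
  })
})

test_that("mass is conserved: compartments plus quadrature of both losses", {
  withr::with_seed(1, {
    D <- 5e4
    d <- pk_dose(amount = D, route = "oral")
    for (i in 1:10) {
      p <- random_pk_params()
      for (t_end in c(10, 60)) {
        lost_colon <- stats::integrate(
          function(t) p$kce * pk_solve(p, d, t)[, "G1"], 0, t_end,
          rel.tol = 1e-10, abs.tol = 1e-9 * D)$value
        lost_renal <- stats::integrate(
          function(t) p$k10 * pk_solve(p, d, t)[, "Ac"], 0, t_end,
          rel.tol = 1e-10, abs.tol = 1e-9 * D)$value
        st <- pk_solve(p, d, t_end)
        total <- sum(st[1, c("G1", "G2", "Ac", "Ap")]) +
          lost_colon + lost_renal
        expect_lt(abs(total - D), 1e-6 * D)
      }
    }
  })
})

test_that("solution is exactly linear in dose", {
  p <- pk_params(ka = 3e-4, kce = 0.09, k12 = 0.05, k21 = 0.08,
                 k10 = 0.15, Vc = 2)
  tt <- c(1, 4, 8, 16, 48)
  c1 <- simulate_pk(p, pk_dose(amount = 1e4, route = "oral"), tt)$conc_ng_ml
  c3 <- simulate_pk(p, pk_dose(amount = 3e4, route = "oral"), tt)$conc_ng_ml
  expect_equal(c3, 3 * c1, tolerance = 1e-12)
})

test_that("matrix-exponential solution matches an adaptive ODE integrator", {
  skip_if_not_installed("deSolve")
  withr::with_seed(7, {
    d <- pk_dose(amount = 4e4, route = "oral")
    tt <- c(0.5, 1, 2, 4, 8, 12, 24, 48)
    for (i in 1:10) {
      p <- random_pk_params()
      st <- pk_solve(p, d, tt)
      ref <- ode_solve_oracle(p, d, tt)
      expect_lt(max(abs(st - ref)) / d$amount, 1e-6)
    }
  })
})

test_that("IV dosing starts in the central compartment", {
  p <- pk_params(ka = 0, kce = 0, k12 = 0.2, k21 = 0.1, k10 = 0.3, Vc = 2)
  tc <- simulate_pk(p, pk_dose(amount = 1e4, route = "iv"), times = c(0, 1, 4))
  expect_equal(tc$conc_ng_ml[1], 1e4 / 2)
  expect_true(all(diff(tc$conc_ng_ml) < 0))
})

test_that("bimodal second site reproduces the unimodal model when off", {
  base <- list(ka = 2.4e-4, kce = 0.09, k12 = 0.05, k21 = 0.08,
               k10 = 0.15, Vc = 2)
  d <- pk_dose(amount = 4e4, route = "oral")
  tt <- seq(0.5, 48, by = 0.5)
  uni <- do.call(pk_params, base)
  off <- do.call(pk_params, c(base, list(ka2 = 0, lag2 = 12, frac2 = 0.4)))
  expect_identical(simulate_pk(off, d, tt)$conc_ng_ml,
                   simulate_pk(uni, d, tt)$conc_ng_ml)
})

test_that("bimodal second site can create a second concentration peak", {
  p <- pk_params(ka = 2.4e-4, kce = 0.09, k12 = 0.05, k21 = 0.08,
                 k10 = 0.15, Vc = 2, ka2 = 0.3, lag2 = 14, frac2 = 0.4)
  d <- pk_dose(amount = 4e4, route = "oral")
  tt <- seq(0.5, 48, by = 0.25)
  cc <- simulate_pk(p, d, tt)$conc_ng_ml
  n_peaks <- sum(diff(sign(diff(cc))) == -2)
  expect_gte(n_peaks, 2)
})

test_that("bimodal solution also matches the ODE oracle across the lag", {
  skip_if_not_installed("deSolve")
  p <- pk_params(ka = 2.4e-4, kce = 0.09, k12 = 0.05, k21 = 0.08,
                 k10 = 0.15, Vc = 2, ka2 = 0.3, lag2 = 14, frac2 = 0.4)
  d <- pk_dose(amount = 4e4, route = "oral")
  tt <- c(2, 8, 13.9, 14.1, 16, 24, 48)
  expect_lt(max(abs(pk_solve(p, d, tt) - ode_solve_oracle(p, d, tt))) /
              d$amount, 1e-6)
})

test_that("invalid parameters, doses and time courses are rejected", {
  expect_error(pk_params(ka = -1, kce = 0, k12 = 0, k21 = 0, k10 = 0.1,
                         Vc = 1), "rate")
  expect_error(pk_params(ka = 0.1, kce = 0, k12 = 0, k21 = 0, k10 = 0.1,
                         Vc = 0), "Vc")
  expect_error(pk_dose(amount = 0), "> 0")
  p <- pk_params(ka = 0.1, kce = 0, k12 = 0, k21 = 0, k10 = 0.1, Vc = 1)
  expect_error(pk_solve(p, pk_dose(amount = 1, time = 2), numeric(0)),
               "non-empty")
  expect_error(pk_solve(p, pk_dose(amount = 1, time = 2), times = 1),
               "after the dose")
  expect_error(timecourse("a", "g", c(1, 1, 2), c(0, 0, 0)), "increasing")
  expect_error(timecourse("a", "g", c(1, 2), c(-1, 0)), ">= 0")
})

test_that("dose conversion from mg/kg uses body mass", {
  expect_equal(pk_dose(mg_per_kg = 2, body_mass_g = 20)$amount, 4e4)
  expect_equal(pk_dose(mg_per_kg = 1, body_mass_g = 3000)$amount, 3e6)
})
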