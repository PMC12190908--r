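me_viability <- function(fit, d) 1 / (1 + (d / fit$dm)^fit$m)

test_that("DMSO normalization behaves at the edges", {
  expect_equal(normalize_viability(c(100, 0, 200), c(99, 101)), c(1, 0, 2))
  expect_error(normalize_viability(1, c(0, 0)), "positive")
})

test_that("logistic fits recover noise-free parameters and reject flat data", {
  d <- c(0.1, 0.5, 2, 5, 20, 100)
  truth <- list(top = 1, bottom = 0, hill = 1, ic50 = 5)
  v <- truth$bottom + (truth$top - truth$bottom) / (1 + (d / truth$ic50)^truth$hill)
  fit <- fit_logistic(data.frame(dose = d, viability = v))
  for (p in names(truth)) {
    expect_equal(fit[[p]], truth[[p]], tolerance = 1e-6)
  }
  expect_error(fit_logistic(data.frame(dose = d, viability = rep(1, 6))),
               "no inhibition")
  expect_error(fit_logistic(data.frame(dose = d[1:3], viability = v[1:3])),
               "4 distinct doses")
})

test_that("logistic IC50 is recovered within 15% under 5% CV noise", {
  set.seed(14)
  d <- rep(c(0.1, 0.5, 2, 5, 20, 100), each = 3)
  v_true <- 1 / (1 + d / 5)
  v <- v_true * rlnorm(length(d), 0, sqrt(log(1 + 0.05^2)))
  fit <- fit_logistic(data.frame(dose = d, viability = v))
  expect_lt(abs(fit$ic50 - 5) / 5, 0.15)
})

test_that("median-effect fits are exact on noise-free data", {
  d <- c(1, 2, 5, 10, 20)
  truth <- median_effect_fit(m = 2, dm = 5)
  fit <- fit_median_effect(data.frame(dose = d,
                                      viability = me_viability(truth, d)))
  expect_equal(fit$m, 2, tolerance = 1e-9)
  expect_equal(fit$dm, 5, tolerance = 1e-9)
  expect_equal(fit$r2, 1, tolerance = 1e-9)

  # a single usable point is not enough
  expect_error(
    fit_median_effect(data.frame(dose = c(1, 2), viability = c(0.5, 0.999))),
    "fewer than 2 usable")
})

test_that("median-effect regression equals the closed-form least squares", {
  set.seed(6)
  d <- c(0.5, 1, 3, 9, 27)
  v <- pmin(0.98, pmax(0.02, me_viability(median_effect_fit(1.3, 4), d) *
                         rlnorm(5, 0, 0.05)))
  fit <- fit_median_effect(data.frame(dose = d, viability = v))
  x <- log10(d)
  y <- log10((1 - v) / v)
  beta <- cov(x, y) / var(x)
  alpha <- mean(y) - beta * mean(x)
  expect_equal(fit$m, beta, tolerance = 1e-12)
  expect_equal(fit$dm, 10^(-alpha / beta), tolerance = 1e-10)
})

test_that("logistic and median-effect agree when the models coincide", {
  d <- 10 * 3^seq(-4, 2)
  v <- 1 / (1 + (d / 3)^1.7)  # logistic with top 1, bottom 0 == median effect
  lf <- fit_logistic(data.frame(dose = d, viability = v))
  mf <- fit_median_effect(data.frame(dose = d, viability = v))
  expect_lt(abs(lf$ic50 - mf$dm) / mf$dm, 0.05)
})

test_that("dose_for_effect inverts the median-effect equation", {
  fit <- median_effect_fit(m = 1, dm = 10)
  expect_equal(dose_for_effect(fit, 0.5), 10)          # fa = 0.5 -> Dm
  expect_equal(dose_for_effect(median_effect_fit(3.3, 10), 0.5), 10)
  expect_equal(dose_for_effect(fit, 0.9), 90)
  expect_equal(dose_for_effect(median_effect_fit(1, 1), 0.99), 99)
  expect_error(dose_for_effect(fit, 1), "strictly in")
})

test_that("combination index obeys the Loewe identities", {
  fa <- median_effect_fit(1.5, 2)
  fb <- median_effect_fit(1, 10)
  for (f in c(0.3, 0.5, 0.7)) {
    dxa <- dose_for_effect(fa, f)
    dxb <- dose_for_effect(fb, f)
    expect_equal(combination_index(dxa / 2, dxb / 2, f, fa, fb), 1)
    expect_equal(combination_index(dxa, dxb, f, fa, fb), 2)
    # sham: a drug combined with itself at its own Dx
    expect_equal(combination_index(dxa / 3, 2 * dxa / 3, f, fa, fa), 1)
  }
  expect_error(combination_index(1, 1, 1.2, fa, fb), "strictly in")
  expect_error(combination_index(0, 0, 0.5, fa, fb), "positive")
})

test_that("CI is invariant to rescaling one drug's dose axis", {
  fa <- median_effect_fit(2, 1)
  fb <- median_effect_fit(1, 5)
  ci0 <- combination_index(0.7, 3, 0.6, fa, fb)
  c_scale <- 37
  fa_scaled <- median_effect_fit(2, 1 * c_scale)
  expect_equal(combination_index(0.7 * c_scale, 3, 0.6, fa_scaled, fb), ci0)
})

test_that("checkerboard summaries recover the generated interaction level", {
  fa <- median_effect_fit(1.5, 2)
  fb <- median_effect_fit(1, 10)
  for (alpha in c(0.5, 1)) {
    sim <- simulate_checkerboard(fa, fb, alpha = alpha, noise_cv = 0,
                                 seed = 1)
    fit_a <- fit_median_effect(sim$curve_a)
    fit_b <- fit_median_effect(sim$curve_b)
    res <- summarize_checkerboard(sim$board, fit_a, fit_b)
    tol <- if (alpha == 1) 0.02 else 0.05
    expect_lt(abs(res$summary_ci - alpha), tol)
  }

  # all wells outside the effect window -> error
  weak <- checkerboard(doses_a = 0.09 / 3^(0:2), doses_b = 0.09 / 3^(0:2),
                       viability = matrix(0.95, 3, 3))
  expect_error(summarize_checkerboard(weak, fa, fb), "no wells in effect window")
})

test_that("synergy calls follow the CI < 1 boundary strictly", {
  fa <- median_effect_fit(1, 1)
  call_of <- function(board_ci) {
    if (board_ci < 1) "synergistic" else if (board_ci > 1) "antagonistic"
    else "additive"
  }
  expect_equal(call_of(0.999999), "synergistic")
  expect_equal(call_of(1), "additive")
  # and through the real path: a sham combination is exactly additive
  sham <- simulate_checkerboard(fa, fa, alpha = 1, noise_cv = 0, seed = 3)
  f1 <- fit_median_effect(sham$curve_a)
  res <- summarize_checkerboard(sham$board, f1, f1)
  expect_equal(res$summary_ci, 1, tolerance = 1e-6)
})

test_that("checkerboard TSVs round-trip through the long format", {
  fa <- median_effect_fit(1.5, 2)
  fb <- median_effect_fit(1, 10)
  sim <- simulate_checkerboard(fa, fb, alpha = 0.7, noise_cv = 0, seed = 5)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_checkerboard_tsv(sim, path)
  back <- read_checkerboard(path)
  expect_equal(back$board$viability, sim$board$viability, tolerance = 1e-9)
  expect_equal(back$board$doses_a, sim$board$doses_a, tolerance = 1e-12)
  # single-agent wells reproduce the generating curves
  f_a <- fit_median_effect(back$single_a)
  expect_equal(f_a$m, fa$m, tolerance = 1e-6)
  expect_equal(f_a$dm, fa$dm, tolerance = 1e-6)
})
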