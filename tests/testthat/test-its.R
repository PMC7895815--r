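years_full <- 1992:2016

england_panel <- function(rates, unit = "England")
  panel_from_rates(stats::setNames(list(rates), unit), years_full)

default_window <- function() analysis_window(1992, 1999, 2016)

test_that("single-unit design has the documented rows and columns", {
  p <- england_panel(pl_series(years_full))
  d <- build_design(p, its_spec(), default_window(), "England")
  expect_equal(nrow(d$X), 25L)
  expect_equal(colnames(d$X),
               c("intercept", "t", "corrector", "level", "trendchg"))
  expect_equal(d$X[, "t"], years_full - 1999)
  expect_equal(d$X[, "corrector"], as.numeric(years_full >= 1996))
  expect_equal(d$X[, "trendchg"], pmax(0, years_full - 1998))
})

test_that("a 2008 shock column is zero before 2008 and accumulates after", {
  p <- england_panel(pl_series(years_full))
  sp <- its_spec(common_shock_year = 2008)
  d <- build_design(p, sp, default_window(), "England")
  expect_true(all(d$X[d$year < 2008, "shock_trendchg"] == 0))
  expect_equal(d$X[d$year >= 2008, "shock_trendchg"],
               pmax(0, (2008:2016) - 2007))
})

test_that("design construction enforces its preconditions", {
  p <- england_panel(pl_series(years_full))
  expect_error(build_design(p, its_spec(intervention_year = 1994,
                                        corrector_year = 1993),
                            analysis_window(1992, 1994, 2016), "England"),
               "fewer than 3 pre-intervention years")
  expect_error(its_spec(corrector_year = 2000), "corrector_year must precede")
  expect_error(its_spec(common_shock_year = 1998),
               "common_shock_year must follow")
})

test_that("noiseless piecewise-linear series is recovered exactly", {
  y <- pl_series(years_full, a = 40, b = 0.7, c = 2, d = -0.5, g = -2.2)
  p <- england_panel(y)
  fit <- fit_segmented(build_design(p, its_spec(), default_window(),
                                    "England"))
  est <- stats::setNames(fit$coefficients$estimate, fit$coefficients$term)
  expect_equal(est[["t"]], 0.7, tolerance = 1e-9)
  expect_equal(est[["trendchg"]], -2.2, tolerance = 1e-9)
  expect_equal(est[["corrector"]], 2, tolerance = 1e-9)
  expect_equal(est[["level"]], -0.5, tolerance = 1e-9)
  expect_lt(max(abs(fit$residuals)), 1e-9)
})

test_that("with AR(1) correction off the fit equals the OLS normal-equations oracle", {
  set.seed(101)
  y <- pl_series(years_full) + rnorm(length(years_full))
  p <- england_panel(y)
  d <- build_design(p, its_spec(ar1_correction = FALSE), default_window(),
                    "England")
  fit <- fit_segmented(d)
  beta_oracle <- drop(solve(t(d$X) %*% d$X, t(d$X) %*% d$y))
  expect_equal(unname(fit$coefficients$estimate), unname(beta_oracle),
               tolerance = 1e-8)
  # and the t-based intervals use the OLS sigma
  e <- d$y - drop(d$X %*% beta_oracle)
  s2 <- sum(e^2) / (length(d$y) - ncol(d$X))
  se_oracle <- sqrt(diag(s2 * solve(t(d$X) %*% d$X)))
  expect_equal(unname(fit$coefficients$se), unname(se_oracle),
               tolerance = 1e-8)
})

test_that("durbin_watson matches its definition and limits", {
  e_alt <- rep(c(1, -1), 20)
  expect_gt(durbin_watson(e_alt), 3.8)
  expect_equal(durbin_watson(rep(1, 4)), 0)
  set.seed(11)
  expect_equal(durbin_watson(rnorm(1000)), 2, tolerance = 0.15)
  expect_error(durbin_watson(rep(0, 10)), "all-zero residuals")
  expect_error(durbin_watson(c(1, 2)), "at least 3 residuals")
})

test_that("durbin_watson agrees with the lmtest reference on a regression", {
  skip_if_not_installed("lmtest")
  set.seed(5)
  x <- 1:30; y <- 2 + 0.5 * x + rnorm(30)
  m <- lm(y ~ x)
  expect_equal(durbin_watson(residuals(m)),
               unname(lmtest::dwtest(m)$statistic), tolerance = 1e-10)
})

test_that("identical treated and control series give exactly zero differences", {
  y <- pl_series(years_full, a = 40, b = 0.5, g = -1.8)
  p <- panel_from_rates(list(England = y, Scotland = y), years_full)
  res <- controlled_comparison(p, "England", "Scotland",
                               its_spec(ar1_correction = FALSE),
                               default_window())
  expect_equal(res$level_diff$estimate, 0, tolerance = 1e-10)
  expect_equal(res$trend_diff$estimate, 0, tolerance = 1e-10)
  expect_equal(res$counterfactual$counterfactual,
               res$counterfactual$observed, tolerance = 1e-9)
})

test_that("controlled estimates are invariant to common shocks at the intervention", {
  set.seed(202)
  yE <- pl_series(years_full) + rnorm(25, 0, 0.5)
  yS <- pl_series(years_full, a = 38) + rnorm(25, 0, 0.5)
  p0 <- panel_from_rates(list(England = yE, Scotland = yS), years_full)
  bump <- function(y) y + 3 * (years_full >= 1999) -
    0.8 * pmax(0, years_full - 1998)
  p1 <- panel_from_rates(list(England = bump(yE), Scotland = bump(yS)),
                         years_full)
  r0 <- controlled_comparison(p0, "England", "Scotland", its_spec(),
                              default_window())
  r1 <- controlled_comparison(p1, "England", "Scotland", its_spec(),
                              default_window())
  expect_equal(r1$level_diff$estimate, r0$level_diff$estimate,
               tolerance = 1e-7)
  expect_equal(r1$trend_diff$estimate, r0$trend_diff$estimate,
               tolerance = 1e-7)
  expect_equal(r1$trend_diff$ci_lo, r0$trend_diff$ci_lo, tolerance = 1e-7)
})

test_that("the corrector dummy strictly reduces pre-period RSS when a 1996 shift exists", {
  set.seed(303)
  y <- pl_series(years_full, c = 2.5) + rnorm(25, 0, 0.3)
  p <- england_panel(y)
  w <- default_window()
  rss_pre <- function(spec) {
    fit <- fit_segmented(build_design(p, spec, w, "England"))
    sum(fit$residuals[fit$design$year < 1999]^2)
  }
  expect_lt(rss_pre(its_spec(ar1_correction = FALSE)),
            rss_pre(its_spec(corrector_year = NA, ar1_correction = FALSE)))
})

test_that("an injected treated-only trend effect is recovered on average", {
  reps <- 500
  est <- vapply(seq_len(reps), function(s) {
    p <- its_sim_panel(seed = 1000 + s, trend = -1.5, rho = 0.3,
                       noise_sd = 0.5, baseline = 80)
    controlled_comparison(p, "England", "Scotland", its_spec(),
                          default_window())$trend_diff$estimate
  }, numeric(1))
  expect_equal(mean(est), -1.5, tolerance = 0.1)
})

test_that("phase-in exclusion drops rows rather than dummying them", {
  p <- england_panel(pl_series(years_full))
  sp <- its_spec(phase_in_exclusion = c(1999L, 2000L))
  d <- build_design(p, sp, default_window(), "England")
  expect_equal(nrow(d$X), 23L)
  expect_false(any(d$year %in% c(1999, 2000)))
})

test_that("rank-deficient designs raise a singular-design error", {
  p <- england_panel(pl_series(years_full))
  sp <- its_spec(corrector_year = 1992)  # corrector column == intercept
  expect_error(fit_segmented(build_design(p, sp, default_window(),
                                          "England")),
               "rank deficient")
})

test_that("Newey-West mode keeps OLS point estimates with HAC intervals", {
  set.seed(404)
  y <- pl_series(years_full) + as.numeric(arima.sim(list(ar = 0.4), 25))
  p <- england_panel(y)
  w <- default_window()
  f_nw <- fit_segmented(build_design(p, its_spec(se = "newey-west"), w,
                                     "England"))
  f_ols <- fit_segmented(build_design(p, its_spec(ar1_correction = FALSE),
                                      w, "England"))
  expect_equal(f_nw$coefficients$estimate, f_ols$coefficients$estimate,
               tolerance = 1e-10)
  expect_false(isTRUE(all.equal(f_nw$coefficients$se,
                                f_ols$coefficients$se)))
  expect_true(all(f_nw$coefficients$ci_lo <= f_nw$coefficients$estimate &
                    f_nw$coefficients$estimate <= f_nw$coefficients$ci_hi))
})

test_that("Prais-Winsten correction tracks a strongly autocorrelated fit from nlme", {
  skip_if_not_installed("nlme")
  set.seed(505)
  y <- pl_series(years_full) + as.numeric(arima.sim(list(ar = 0.5), 25,
                                                    sd = 0.6))
  p <- england_panel(y)
  d <- build_design(p, its_spec(), default_window(), "England")
  fit <- fit_segmented(d)
  df <- data.frame(y = d$y, d$X[, -1], t_idx = seq_along(d$y))
  g <- nlme::gls(y ~ t + corrector + level + trendchg, data = df,
                 correlation = nlme::corAR1(form = ~ t_idx))
  # different estimation principles (iterative FGLS vs ML), so loose
  expect_equal(unname(fit$coefficients$estimate), unname(coef(g)),
               tolerance = 0.15)
  expect_lt(abs(fit$rho -
                  as.numeric(coef(g$modelStruct$corStruct,
                                  unconstrained = FALSE))), 0.35)
})

test_that("the REML rho profile matches the reference AR(1) GLS implementation", {
  skip_if_not_installed("nlme")
  p <- its_sim_panel(seed = 70001)
  d <- build_design(p, its_spec(common_shock_year = 2008,
                                rho_method = "reml"),
                    default_window(), c("England", "Scotland"))
  fit <- fit_segmented(d)
  df <- data.frame(y = d$y, d$X[, -1], unit = d$unit, yr = d$year)
  g <- nlme::gls(y ~ . - unit - yr, data = df,
                 correlation = nlme::corAR1(form = ~ yr | unit))
  expect_equal(fit$rho,
               as.numeric(coef(g$modelStruct$corStruct,
                               unconstrained = FALSE)), tolerance = 1e-4)
  expect_equal(unname(fit$coefficients$estimate), unname(coef(g)),
               tolerance = 1e-5)
  expect_equal(unname(fit$coefficients$se),
               unname(sqrt(diag(stats::vcov(g)))), tolerance = 1e-4)
})
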