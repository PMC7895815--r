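#' Interrupted time series model specification
#'
#' Controls the segmented-regression design: the intervention year, the
#' optional pre-intervention level corrector (by default the 1996 "pill
#' scare" dummy, accounting for the level jump after the 1995 oral
#' contraceptive safety warning in UK series), an optional common trend
#' shock (2008 in sensitivity analyses), the parallel pre-trend assumption
#' for controlled two-country models, phase-in year exclusion, and the
#' lag-1 autocorrelation correction.
#'
#' Time coding: `t = year - intervention_year`; the level dummy is
#' `1[year >= intervention_year]`; the trend-change regressor is
#' `max(0, year - (intervention_year - 1))` so its coefficient is the
#' per-year accumulating change in the outcome relative to the
#' pre-intervention trajectory.
#'
#' @param intervention_year first intervention year (default 1999).
#' @param corrector_year year a level corrector dummy switches on, or `NA`
#'   to omit (default 1996). Must precede the intervention.
#' @param common_shock_year year a shared post-intervention trend change
#'   starts, or `NA` to omit (default `NA`; 2008 in sensitivity mode).
#' @param parallel_pre_trends for controlled models, share one
#'   pre-intervention slope between treated and control (default `TRUE`).
#' @param shared_corrector for controlled models, share the corrector
#'   coefficient across units (default `TRUE`), as when the triggering
#'   event hit all units alike.
#' @param phase_in_exclusion integer years dropped as rows to allow a
#'   policy phase-in (default none).
#' @param ar1_correction apply AR(1) generalized least squares correction
#'   (default `TRUE`).
#' @param rho_method how the lag-1 parameter is estimated when
#'   `ar1_correction` is on: `"lag1"` (default) iterates the classical
#'   Cochrane-Orcutt/Prais-Winsten scheme with rho from the lag-1
#'   regression of the residuals; `"reml"` profiles the restricted
#'   likelihood over rho. The residual-regression estimator is the
#'   textbook choice but is biased toward zero in short series with many
#'   regressors; the REML profile restores near-nominal interval coverage
#'   there (see the package vignette).
#' @param se one of `"ar1"` (from the AR(1) generalized least squares fit,
#'   or plain OLS when `ar1_correction` is off) or `"newey-west"`
#'   (OLS point estimates with HAC standard errors).
#' @return An `its_spec` list.
#' @export
its_spec <- function(intervention_year = 1999L,
                     corrector_year = 1996L,
                     common_shock_year = NA_integer_,
                     parallel_pre_trends = TRUE,
                     shared_corrector = TRUE,
                     phase_in_exclusion = integer(0),
                     ar1_correction = TRUE,
                     rho_method = c("lag1", "reml"),
                     se = c("ar1", "newey-west")) {
  se <- match.arg(se)
  rho_method <- match.arg(rho_method)
  intervention_year <- as.integer(intervention_year)
  corrector_year <- as.integer(corrector_year)
  common_shock_year <- as.integer(common_shock_year)
  if (!is.na(corrector_year) && corrector_year >= intervention_year)
    stop("its spec error: corrector_year must precede intervention_year",
         call. = FALSE)
  if (!is.na(common_shock_year) && common_shock_year <= intervention_year)
    stop("its spec error: common_shock_year must follow intervention_year",
         call. = FALSE)
  structure(list(intervention_year = intervention_year,
                 corrector_year = corrector_year,
                 common_shock_year = common_shock_year,
                 parallel_pre_trends = isTRUE(parallel_pre_trends),
                 shared_corrector = isTRUE(shared_corrector),
                 phase_in_exclusion = as.integer(phase_in_exclusion),
                 ar1_correction = isTRUE(ar1_correction),
                 rho_method = rho_method,
                 se = se),
            class = "its_spec")
}

#' Build the segmented-regression design
#'
#' For a single unit the columns are an intercept, the linear time term
#' `t = year - intervention_year`, the corrector dummy, the level dummy
#' and the trend-change term (plus the common-shock trend term when
#' specified). For two units the rows are stacked and the treated unit
#' receives its own intercept and interactions on the level and
#' trend-change terms; the pre-intervention slope is shared unless
#' `parallel_pre_trends` is off, and the corrector is shared unless
#' `shared_corrector` is off. The common-shock term is never interacted:
#' it models a change hitting all units alike.
#'
#' @param panel a [rate_panel] holding the unit(s).
#' @param spec an [its_spec].
#' @param window an [analysis_window].
#' @param units one (uncontrolled) or two (controlled) country labels; for
#'   two, the first is treated and the second control.
#' @param age_group outcome age group (default `"U18"`).
#' @return A list with the model matrix `X`, outcome `y`, `year`, `unit`,
#'   and column bookkeeping; input to [fit_segmented()].
#' @export
build_design <- function(panel, spec, window, units, age_group = "U18") {
  stopifnot(inherits(spec, "its_spec"), inherits(window, "analysis_window"))
  if (spec$intervention_year != window$intervention_year)
    stop("its spec error: spec and window disagree on the intervention year",
         call. = FALSE)
  units <- as.character(units)
  if (!length(units) %in% 1:2)
    stop("its design error: need one or two units", call. = FALSE)
  if (length(pre_years(window)) < 3L)
    stop("its insufficient-data error: fewer than 3 pre-intervention years",
         call. = FALSE)

  series <- lapply(units, function(u) unit_series(panel, u, age_group, window))
  year <- unlist(lapply(series, `[[`, "year"), use.names = FALSE)
  y <- unlist(lapply(series, `[[`, "rate"), use.names = FALSE)
  unit <- rep(units, each = length(pre_years(window)) + length(post_years(window)))

  iy <- spec$intervention_year
  t_lin <- year - iy
  level <- as.numeric(year >= iy)
  trendchg <- pmax(0, year - (iy - 1L))

  X <- cbind(intercept = 1, t = t_lin)
  if (!is.na(spec$corrector_year))
    X <- cbind(X, corrector = as.numeric(year >= spec$corrector_year))
  X <- cbind(X, level = level, trendchg = trendchg)
  if (!is.na(spec$common_shock_year))
    X <- cbind(X, shock_trendchg = pmax(0, year - (spec$common_shock_year - 1L)))

  controlled <- length(units) == 2L
  if (controlled) {
    tr <- as.numeric(unit == units[1L])
    X <- cbind(X, treated = tr,
               `treated:level` = tr * level,
               `treated:trendchg` = tr * trendchg)
    if (!spec$parallel_pre_trends)
      X <- cbind(X, `treated:t` = tr * t_lin)
    if (!spec$shared_corrector && !is.na(spec$corrector_year))
      X <- cbind(X, `treated:corrector` = tr * X[, "corrector"])
  }

  keep <- !(year %in% spec$phase_in_exclusion)
  X <- X[keep, , drop = FALSE]
  list(X = X, y = y[keep], year = year[keep], unit = unit[keep],
       units = units, controlled = controlled, spec = spec, window = window,
       age_group = age_group)
}

#' Durbin-Watson statistic
#'
#' `sum(diff(e)^2) / sum(e^2)`, in `[0, 4]`; values near 2 indicate no
#' lag-1 autocorrelation, near 0 strong positive, near 4 strong negative.
#'
#' @param residuals numeric residual series (length >= 3).
#' @return The statistic.
#' @export
durbin_watson <- function(residuals) {
  residuals <- as.numeric(residuals)
  if (length(residuals) < 3L)
    stop("durbin-watson error: need at least 3 residuals", call. = FALSE)
  ss <- sum(residuals^2)
  if (ss < .Machine$double.eps)
    stop("durbin-watson error: statistic undefined for all-zero residuals",
         call. = FALSE)
  sum(diff(residuals)^2) / ss
}

# lag-1 residual autocorrelation estimated within unit blocks
lag1_rho <- function(e, unit) {
  num <- 0; den <- 0
  for (u in unique(unit)) {
    eu <- e[unit == u]
    n <- length(eu)
    num <- num + sum(eu[-1] * eu[-n])
    den <- den + sum(eu[-n]^2)
  }
  if (den < .Machine$double.eps) return(0)
  max(min(num / den, 0.99), -0.99)
}

# Prais-Winsten quasi-differencing within unit blocks, first row retained
# and scaled by sqrt(1 - rho^2).
pw_transform <- function(M, unit, rho) {
  M <- as.matrix(M)
  out <- M
  for (u in unique(unit)) {
    i <- which(unit == u)
    out[i[1], ] <- sqrt(1 - rho^2) * M[i[1], ]
    if (length(i) > 1L)
      out[i[-1], ] <- M[i[-1], ] - rho * M[i[-length(i)], ]
  }
  out
}

# Restricted-likelihood profile for the AR(1) parameter: for candidate
# rho, Prais-Winsten-transform the data (so the transformed errors are the
# white innovations), and evaluate the REML deviance
#   (n - k) log RSS* + sum_blocks -log(1 - rho^2) + log |X*'X*|.
reml_rho <- function(X, y, unit) {
  n <- length(y); k <- ncol(X)
  nblocks <- length(unique(unit))
  dev <- function(rho) {
    Xs <- pw_transform(X, unit, rho)
    ys <- drop(pw_transform(matrix(y), unit, rho))
    f <- stats::lm.fit(Xs, ys)
    rss <- sum(f$residuals^2)
    logdet_xx <- 2 * sum(log(abs(diag(qr.R(f$qr)))))
    (n - k) * log(rss) - nblocks * log(1 - rho^2) + logdet_xx
  }
  stats::optimize(dev, c(-0.98, 0.98))$minimum
}

#' Fit the segmented regression
#'
#' Ordinary least squares, or — when the spec's `ar1_correction` flag is on
#' — iterative feasible generalized least squares for AR(1) errors
#' (Cochrane-Orcutt iteration with Prais-Winsten retention of each unit's
#' first observation). The lag-1 coefficient `rho` is re-estimated from the
#' untransformed residuals until `|delta rho| < 1e-6` (at most 50
#' iterations). 95% confidence intervals use the t distribution with
#' residual degrees of freedom, appropriate for the short (about 25-year)
#' annual series these designs use. Lag-1 diagnostics (Durbin-Watson
#' statistic, ACF and PACF at lag 1, computed on the OLS residuals) are
#' reported regardless so that the user, not the package, judges whether
#' correction was warranted. With `se = "newey-west"` the point estimates
#' are OLS and the standard errors are Newey-West HAC (lag 1).
#'
#' @param design output of [build_design()].
#' @return An `its_fit` with elements `coefficients` (a data.frame of
#'   estimate, se, ci_lo, ci_hi per term), `rho`, `dw`, `acf1`, `pacf1`,
#'   `residuals`, `fitted`, `sigma`, `df`, and the design.
#' @export
fit_segmented <- function(design) {
  X <- design$X; y <- design$y
  n <- length(y); k <- ncol(X)
  if (n <= k + 1L)
    stop("its insufficient-data error: n must exceed columns + 1", call. = FALSE)
  if (qr(X)$rank < k)
    stop("its singular-design error: design matrix is rank deficient",
         call. = FALSE)
  spec <- design$spec

  ols <- stats::lm.fit(X, y)
  e_ols <- ols$residuals
  dw <- if (sum(e_ols^2) < .Machine$double.eps) NA_real_ else durbin_watson(e_ols)
  ac <- lag1_diagnostics(e_ols, design$unit)

  if (spec$se == "newey-west") {
    fit_lm <- stats::lm(y ~ X - 1)
    V <- sandwich::NeweyWest(fit_lm, lag = 1L, prewhite = FALSE, adjust = TRUE)
    beta <- ols$coefficients
    se <- sqrt(diag(V))
    rho <- lag1_rho(e_ols, design$unit)
    e <- e_ols; fitted <- drop(X %*% beta); df <- n - k
    sigma <- sqrt(sum(e^2) / df)
  } else if (spec$ar1_correction) {
    if (identical(spec$rho_method, "reml")) {
      rho <- if (sum(e_ols^2) < .Machine$double.eps) 0 else
        reml_rho(X, y, design$unit)
    } else {
      rho <- lag1_rho(e_ols, design$unit)
      beta <- ols$coefficients
      delta <- Inf
      for (it in seq_len(50L)) {
        Xs <- pw_transform(X, design$unit, rho)
        ys <- drop(pw_transform(matrix(y), design$unit, rho))
        g <- stats::lm.fit(Xs, ys)
        beta <- g$coefficients
        e <- y - drop(X %*% beta)
        rho_new <- lag1_rho(e, design$unit)
        delta <- abs(rho_new - rho)
        rho <- rho_new
        if (delta < 1e-6) break
      }
      if (delta >= 1e-6)
        stop("its convergence error: rho iteration did not converge ",
             sprintf("(last rho = %.4f, delta = %.2e)", rho, delta),
             call. = FALSE)
    }
    Xs <- pw_transform(X, design$unit, rho)
    ys <- drop(pw_transform(matrix(y), design$unit, rho))
    g <- stats::lm.fit(Xs, ys)
    beta <- g$coefficients
    df <- n - k
    sigma <- sqrt(sum(g$residuals^2) / df)
    XtXi <- chol2inv(qr.R(g$qr))
    se <- sigma * sqrt(diag(XtXi))
    fitted <- drop(X %*% beta)
    e <- y - fitted
  } else {
    beta <- ols$coefficients
    rho <- lag1_rho(e_ols, design$unit)
    df <- n - k
    sigma <- sqrt(sum(e_ols^2) / df)
    XtXi <- chol2inv(qr.R(ols$qr))
    se <- sigma * sqrt(diag(XtXi))
    fitted <- drop(X %*% beta)
    e <- e_ols
  }

  names(beta) <- names(se) <- colnames(X)
  tcrit <- stats::qt(0.975, df)
  coefs <- data.frame(term = colnames(X), estimate = unname(beta),
                      se = unname(se),
                      ci_lo = unname(beta - tcrit * se),
                      ci_hi = unname(beta + tcrit * se),
                      stringsAsFactors = FALSE)
  structure(list(coefficients = coefs, rho = rho, dw = dw,
                 acf1 = ac$acf1, pacf1 = ac$pacf1,
                 residuals = e, fitted = fitted, sigma = sigma, df = df,
                 design = design),
            class = "its_fit")
}

lag1_diagnostics <- function(e, unit) {
  # lag-1 ACF within the (first) unit block; PACF at lag 1 equals ACF at lag 1
  eu <- e[unit == unit[1L]]
  if (sum(eu^2) < .Machine$double.eps) return(list(acf1 = NA_real_, pacf1 = NA_real_))
  a <- stats::acf(eu, lag.max = 1L, plot = FALSE, demean = TRUE)$acf[2L]
  list(acf1 = a, pacf1 = a)
}

#' @export
print.its_fit <- function(x, ...) {
  cat("<its_fit> segmented regression",
      if (x$design$controlled) "(controlled, two-unit)" else "(single unit)",
      "\n")
  cf <- x$coefficients
  cf[, -1] <- lapply(cf[, -1], round, 3)
  print(cf, row.names = FALSE)
  cat(sprintf("rho = %.3f | DW = %s | ACF(1) = %s | sigma = %.3f | df = %d\n",
              x$rho, format(round(x$dw, 3)), format(round(x$acf1, 3)),
              x$sigma, x$df))
  invisible(x)
}

coef_row <- function(fit, term) {
  cf <- fit$coefficients
  cf[cf$term == term, c("estimate", "ci_lo", "ci_hi")]
}

#' Controlled two-country comparison
#'
#' Fits the stacked segmented regression with treated-unit interactions on
#' the intervention level and trend-change terms; the interaction
#' coefficients are the treated-over-control differences — the change in
#' level and the per-year accumulating change in trend beyond what the
#' control experienced — each with its 95% interval. Subtracting the
#' control's changes this way removes any shock common to both units at
#' the intervention date. A "no-intervention" counterfactual for the
#' treated unit is returned: its own pre-trend (and corrector) carried
#' forward with only the control's estimated level and trend changes
#' applied.
#'
#' @param panel a [rate_panel] with both units.
#' @param treated,control country labels.
#' @param spec an [its_spec].
#' @param window an [analysis_window].
#' @param age_group outcome age group (default `"U18"`).
#' @return A `controlled_its` list: `level_diff` and `trend_diff`
#'   (each `estimate`, `ci_lo`, `ci_hi`), `counterfactual` (data.frame of
#'   year, observed, counterfactual for the treated unit), and `fit`
#'   (the underlying [its_fit]).
#' @export
controlled_comparison <- function(panel, treated, control, spec = its_spec(),
                                  window, age_group = "U18") {
  design <- build_design(panel, spec, window, units = c(treated, control),
                         age_group = age_group)
  fit <- fit_segmented(design)

  X <- design$X
  beta <- fit$coefficients$estimate
  names(beta) <- fit$coefficients$term
  itr <- design$unit == treated
  Xcf <- X[itr, , drop = FALSE]
  Xcf[, c("treated:level", "treated:trendchg")] <- 0
  if ("treated:t" %in% colnames(Xcf)) {
    # without parallel pre-trends the treated unit keeps its own pre-slope
  }
  cf <- drop(Xcf %*% beta)

  structure(list(
    level_diff = coef_row(fit, "treated:level"),
    trend_diff = coef_row(fit, "treated:trendchg"),
    counterfactual = data.frame(year = design$year[itr],
                                observed = design$y[itr],
                                counterfactual = cf),
    treated = treated, control = control, fit = fit),
    class = "controlled_its")
}

#' @export
print.controlled_its <- function(x, ...) {
  fmt <- function(r) sprintf("%.2f (%.2f to %.2f)", r$estimate, r$ci_lo, r$ci_hi)
  cat(sprintf("<controlled_its> %s over %s at %d\n", x$treated, x$control,
              x$fit$design$spec$intervention_year))
  cat("  level change: ", fmt(x$level_diff), "\n", sep = "")
  cat("  trend change: ", fmt(x$trend_diff), " per 1000 women per year\n",
      sep = "")
  invisible(x)
}
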