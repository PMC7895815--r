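#' Configuration for the synthetic panel generator
#'
#' The generator emulates the statistical structure of teenage birth and
#' pregnancy rate panels in high-income countries over 1990-2016: a shared
#' secular trend that rises slowly through the 1990s and declines from
#' 1999, with a further common break in 2008; country-level offsets around
#' a baseline of about 45 events per 1000 women; an upward level shock
#' from 1996 confined to UK-like units (the "pill scare"); an optional
#' treated-unit intervention effect from 1999; and lag-1 autocorrelated
#' observation noise initialised at stationarity. In `mixture_mode` the
#' treated unit's latent mean is a stated convex combination of donor
#' latent means (each donor additionally carries idiosyncratic year
#' effects so the combination is identifiable), giving a ground truth for
#' weight-recovery tests.
#'
#' @param treated treated-unit label (default `"England"`).
#' @param donors donor labels (default the package's 15-country pool).
#' @param uk_like units sharing the 1996 level shock (default the treated
#'   unit and `"Scotland"`).
#' @param years year range (default `1990:2016`).
#' @param baseline_mean latent rate at the first year before offsets
#'   (default 45 per 1000).
#' @param offset_sd s.d. of the per-unit level offsets (default 3).
#' @param base_slope common slope before the first knot (default +0.5/yr).
#' @param trend_knots named numeric vector: names are years, values are
#'   slope changes taking effect from that year (default `-2.0` at 1999 —
#'   i.e. +0.5 to -1.5 — and a further `-1.0` at 2008).
#' @param pill_shock level bump for `uk_like` units from `pill_year`
#'   (default +2.0 from 1996).
#' @param pill_year first year of the shock (default 1996).
#' @param intervention_effect length-2 numeric `c(level, trend)` applied to
#'   the treated unit from `intervention_year` (default `c(0, 0)`: a null
#'   world).
#' @param intervention_year default 1999.
#' @param mixture_mode logical; see above (default `FALSE`).
#' @param mixture_weights named weights over a subset of donors (must sum
#'   to 1) defining the treated latent mean in `mixture_mode`.
#' @param unit_effect_sd s.d. of per-unit idiosyncratic year effects in
#'   `mixture_mode` (default 1.5).
#' @param rho,noise_sd AR(1) parameter and innovation s.d. of the
#'   observation noise (defaults 0.3 and 0.8).
#' @param seed integer seed; the same seed always yields the same panel.
#' @param age_group age-group label stamped on the rows (default `"U18"`).
#' @return A `sim_config` list.
#' @export
sim_config <- function(treated = "England",
                       donors = c("Denmark", "Finland", "France", "Germany",
                                  "Iceland", "Italy", "Netherlands", "Norway",
                                  "Portugal", "Scotland", "Spain", "Sweden",
                                  "Switzerland", "USA", "New Zealand"),
                       uk_like = c(treated, "Scotland"),
                       years = 1990:2016,
                       baseline_mean = 45, offset_sd = 3,
                       base_slope = 0.5,
                       trend_knots = c("1999" = -2.0, "2008" = -1.0),
                       pill_shock = 2.0, pill_year = 1996L,
                       intervention_effect = c(0, 0),
                       intervention_year = 1999L,
                       mixture_mode = FALSE, mixture_weights = NULL,
                       unit_effect_sd = 1.5,
                       rho = 0.3, noise_sd = 0.8,
                       seed = 1L, age_group = "U18") {
  if (abs(rho) >= 1)
    stop("sim config error: AR(1) |rho| must be < 1", call. = FALSE)
  if (length(trend_knots) > 0L) {
    ky <- as.integer(names(trend_knots))
    if (anyNA(ky) || is.unsorted(ky, strictly = TRUE))
      stop("sim config error: trend_knots must be named by strictly ",
           "increasing years", call. = FALSE)
  }
  if (mixture_mode) {
    if (is.null(mixture_weights))
      stop("sim config error: mixture_mode requires mixture_weights",
           call. = FALSE)
    if (!all(names(mixture_weights) %in% donors))
      stop("sim config error: mixture_weights name unknown donors",
           call. = FALSE)
    if (abs(sum(mixture_weights) - 1) > 1e-8 || any(mixture_weights < 0))
      stop("sim config error: mixture_weights must be a convex combination",
           call. = FALSE)
  }
  structure(list(treated = treated, donors = donors, uk_like = uk_like,
                 years = as.integer(years), baseline_mean = baseline_mean,
                 offset_sd = offset_sd, base_slope = base_slope,
                 trend_knots = trend_knots, pill_shock = pill_shock,
                 pill_year = as.integer(pill_year),
                 intervention_effect = intervention_effect,
                 intervention_year = as.integer(intervention_year),
                 mixture_mode = isTRUE(mixture_mode),
                 mixture_weights = mixture_weights,
                 unit_effect_sd = unit_effect_sd,
                 rho = rho, noise_sd = noise_sd,
                 seed = as.integer(seed), age_group = age_group),
            class = "sim_config")
}

# piecewise-linear common trend evaluated at `years`
common_trend <- function(config) {
  yrs <- config$years
  slope <- rep(config$base_slope, length(yrs))
  for (i in seq_along(config$trend_knots)) {
    ky <- as.integer(names(config$trend_knots)[i])
    slope[yrs >= ky] <- slope[yrs >= ky] + config$trend_knots[[i]]
  }
  config$baseline_mean + c(0, cumsum(slope[-length(slope)]))
}

ar1_noise <- function(n, rho, sd) {
  e <- numeric(n)
  e[1] <- stats::rnorm(1, 0, sd / sqrt(1 - rho^2))  # stationary start
  if (n > 1) for (t in 2:n) e[t] <- rho * e[t - 1] + stats::rnorm(1, 0, sd)
  e
}

#' Generate a synthetic country-year rate panel
#'
#' Deterministic in `config$seed`. Rates are truncated at 0 (with a
#' warning) should the configuration drive them negative; the default
#' parameters keep that probability negligible.
#'
#' @param config a [sim_config].
#' @param emit_counts also emit integer `births` and `population` columns
#'   by inverting the rate against a fixed population (default `FALSE`;
#'   `rate` is always emitted). Useful for exercising count-based I/O.
#' @param population population used when `emit_counts = TRUE`
#'   (default 100000).
#' @return A [rate_panel].
#' @export
generate_panel <- function(config, emit_counts = FALSE, population = 100000) {
  stopifnot(inherits(config, "sim_config"))
  units <- c(config$treated, config$donors)
  yrs <- config$years
  n <- length(yrs)
  base <- common_trend(config)

  withr::with_seed(config$seed, {
    offsets <- stats::setNames(stats::rnorm(length(units), 0,
                                            config$offset_sd), units)
    uefx <- if (config$mixture_mode) {
      m <- matrix(stats::rnorm(n * length(config$donors), 0,
                               config$unit_effect_sd),
                  nrow = n, dimnames = list(yrs, config$donors))
      m
    } else NULL

    latent <- sapply(units, function(u) {
      mu <- base + offsets[[u]]
      if (!is.null(uefx) && u %in% config$donors) mu <- mu + uefx[, u]
      if (u %in% config$uk_like)
        mu <- mu + config$pill_shock * (yrs >= config$pill_year)
      mu
    })
    if (config$mixture_mode) {
      w <- stats::setNames(rep(0, length(config$donors)), config$donors)
      w[names(config$mixture_weights)] <- config$mixture_weights
      latent[, config$treated] <- latent[, config$donors, drop = FALSE] %*% w
    }

    eff <- config$intervention_effect
    post <- yrs >= config$intervention_year
    latent[, config$treated] <- latent[, config$treated] +
      post * (eff[1] + eff[2] * (yrs - config$intervention_year + 1L))

    noise <- sapply(units, function(u)
      ar1_noise(n, config$rho, config$noise_sd))
    rates <- latent + noise
  })

  if (any(rates < 0)) {
    warning("generate_panel: ", sum(rates < 0),
            " rate value(s) truncated at 0")
    rates[rates < 0] <- 0
  }

  df <- data.frame(country = rep(units, each = n),
                   year = rep(yrs, times = length(units)),
                   age_group = config$age_group,
                   births = NA_real_, abortions = NA_real_,
                   population = NA_real_,
                   rate = as.vector(rates),
                   stringsAsFactors = FALSE)
  if (emit_counts) {
    df$population <- population
    df$births <- round(df$rate * population / 1000)
  }
  validate_rate_panel(df)
}

#' Inject an intervention effect into an existing panel
#'
#' Adds `level + trend * (year - from_year + 1)` to the treated unit's
#' rate for every `year >= from_year`, leaving all other rows untouched.
#' The effect-recovery harness for both engines.
#'
#' @param panel a [rate_panel].
#' @param treated unit label (must exist in the panel).
#' @param level level change (rate units).
#' @param trend per-year accumulating trend change (rate units / year).
#' @param from_year first affected year (default 1999).
#' @return The modified [rate_panel].
#' @export
inject_intervention <- function(panel, treated, level = 0, trend = 0,
                                from_year = 1999L) {
  panel <- validate_rate_panel(panel)
  if (!treated %in% panel$country)
    stop("panel integrity error: unknown unit '", treated, "'", call. = FALSE)
  i <- panel$country == treated & panel$year >= from_year
  panel$rate[i] <- panel$rate[i] +
    level + trend * (panel$year[i] - as.integer(from_year) + 1L)
  panel
}
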