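# Shared fixture builders. Everything is generated in code; no files.

# A small deterministic panel of explicit rates for I/O tests.
toy_panel <- function() {
  rate_panel(country = rep(c("England", "Scotland"), each = 4),
             year = rep(1996:1999, 2),
             age_group = "U18",
             rate = c(44.9, 45.3, 46.6, 44.8, 42.0, 42.5, 44.7, 43.0))
}

# Deterministic piecewise-linear series on the ITS design's own column
# space: intercept a, pre-slope b (per year, t = year - 1999), corrector
# jump c from 1996, level change d and trend change g from 1999.
pl_series <- function(years, a = 40, b = 0.7, c = 2, d = 0, g = -2.2,
                      intervention = 1999, corrector = 1996) {
  t <- years - intervention
  a + b * t + c * (years >= corrector) + d * (years >= intervention) +
    g * pmax(0, years - (intervention - 1))
}

panel_from_rates <- function(named_series, years, age_group = "U18") {
  do.call(rbind, lapply(names(named_series), function(u)
    data.frame(country = u, year = years, age_group = age_group,
               rate = named_series[[u]], stringsAsFactors = FALSE))) |>
    validate_rate_panel()
}

# Two-unit panel for controlled ITS simulations: common trend + pill for
# both, independent AR(1) noise; optional treated-only intervention effect.
its_sim_panel <- function(seed, level = 0, trend = 0, rho = 0.3,
                          noise_sd = 0.8, baseline = 45) {
  cfg <- sim_config(treated = "England", donors = "Scotland",
                    uk_like = c("England", "Scotland"),
                    intervention_effect = c(level, trend),
                    baseline_mean = baseline,
                    rho = rho, noise_sd = noise_sd, seed = seed)
  generate_panel(cfg)
}

# Mixture panel with planted donor weights for weight-recovery tests.
mixture_panel <- function(seed, weights = c(A = 0.6, B = 0.4),
                          donors = c("A", "B", "C", "D", "E"),
                          noise_sd = 0.1, rho = 0) {
  cfg <- sim_config(treated = "T", donors = donors, uk_like = character(0),
                    mixture_mode = TRUE, mixture_weights = weights,
                    noise_sd = noise_sd, rho = rho, seed = seed,
                    years = 1990:2013)
  generate_panel(cfg)
}

sc_window <- function() analysis_window(1990, 1999, 2013)

# Independent brute-force objective check: minimum V-weighted discrepancy
# over a dense simplex grid (compositions of `steps` among J donors).
grid_min_objective <- function(x1, X0, v, steps) {
  J <- ncol(X0)
  comp <- compositions(steps, J) / steps
  V <- v / sum(v)
  R <- sweep(comp %*% t(X0), 2, x1)   # rows: grid points, cols: predictors
  min(colSums(t(R^2) * V))
}

# All compositions of n into k non-negative parts (rows), iterative.
compositions <- function(n, k) {
  if (k == 1L) return(matrix(n, 1, 1))
  out <- vector("list", n + 1L)
  for (i in 0:n) {
    rest <- compositions(n - i, k - 1L)
    out[[i + 1L]] <- cbind(i, rest)
  }
  do.call(rbind, out)
}

# A placebo_set with stubbed fit metrics, for exercising the rank/p
# convention on exactly specified MSPE configurations.
stub_set <- function(pre, post, treated = names(pre)[1L]) {
  fits <- lapply(names(pre), function(u)
    structure(list(mspe_pre = pre[[u]], mspe_post = post[[u]]),
              class = "synth_fit"))
  names(fits) <- names(pre)
  structure(list(fits = fits, treated = treated,
                 donors = setdiff(names(pre), treated),
                 protocol = "fixed"),
            class = "placebo_set")
}

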