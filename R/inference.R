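#' Placebo-in-space analysis
#'
#' Re-runs the synthetic control procedure treating each donor in turn as
#' if it had been the intervened unit (its donor pool is the remaining
#' donors; the truly treated unit is excluded throughout, so no placebo
#' can borrow the real intervention signal). The treated unit's own fit
#' uses the full donor pool and is identical to the standalone
#' [fit_synth()] result. The resulting per-unit gap series and MSPEs form
#' the permutation null for [mspe_ratio_test()].
#'
#' @inheritParams fit_synth
#' @param protocol `"full"` re-runs the grouping search for every unit
#'   (the methodologically symmetric default); `"fixed"` reuses `spec` for
#'   all units (cheaper).
#' @param spec a [predictor_spec]; required for `protocol = "fixed"`, and
#'   used for the treated unit when supplied under `"full"` is `NULL`
#'   (otherwise the search chooses it).
#' @param tolerance,max_groups passed to [search_groupings()] under the
#'   full protocol.
#' @return A `placebo_set`: named list of [synth_fit] objects (treated
#'   first), plus bookkeeping.
#' @export
placebo_in_space <- function(panel, treated, donors, window, spec = NULL,
                             protocol = c("full", "fixed"),
                             age_group = "U18", v_seed = 20211L,
                             tolerance = 0.05, max_groups = Inf) {
  protocol <- match.arg(protocol)
  units <- c(treated, donors)
  if (length(units) < 3L)
    stop("inference error: need at least 3 units", call. = FALSE)
  if (protocol == "fixed" && is.null(spec))
    stop("inference error: protocol 'fixed' requires a predictor spec",
         call. = FALSE)

  fit_unit <- function(u, pool) {
    sp <- if (protocol == "fixed") spec else
      search_groupings(panel, u, pool, window, max_groups = max_groups,
                       tolerance = tolerance, age_group = age_group)$spec
    fit_synth(panel, u, pool, window, sp, age_group, v_seed)
  }

  fits <- vector("list", length(units))
  names(fits) <- units
  fits[[treated]] <- if (protocol == "full" && !is.null(spec))
    fit_synth(panel, treated, donors, window, spec, age_group, v_seed)
  else fit_unit(treated, donors)
  for (d in donors)
    fits[[d]] <- fit_unit(d, setdiff(donors, d))

  structure(list(fits = fits, treated = treated, donors = donors,
                 window = window, protocol = protocol,
                 age_group = age_group),
            class = "placebo_set")
}

#' @export
print.placebo_set <- function(x, ...) {
  cat(sprintf("<placebo_set> %d units (treated: %s), protocol '%s'\n",
              length(x$fits), x$treated, x$protocol))
  mp <- vapply(x$fits, `[[`, numeric(1), "mspe_pre")
  cat("  pre-period MSPE range:", format(signif(range(mp), 3)), "\n")
  invisible(x)
}

#' Exclude poorly fitting placebos
#'
#' Retains placebo units whose pre-intervention MSPE is at most `multiple`
#' times the treated unit's; the treated unit is always retained. Used
#' before plotting gap fans so that only placebos with fits comparable to
#' the treated unit frame the comparison. Idempotent.
#'
#' @param set a `placebo_set`.
#' @param multiple exclusion factor (default 5).
#' @return A filtered `placebo_set`.
#' @export
filter_placebos <- function(set, multiple = 5) {
  stopifnot(inherits(set, "placebo_set"))
  m0 <- set$fits[[set$treated]]$mspe_pre
  keep <- vapply(set$fits, function(f) f$mspe_pre <= multiple * m0,
                 logical(1))
  keep[set$treated] <- TRUE
  set$fits <- set$fits[keep]
  set$donors <- intersect(set$donors, names(set$fits))
  set
}

# rank/p convention shared by mspe_ratio_test and the acceptance surface:
# descending rank of the treated ratio counting itself, ties outrank
# (every tied unit counts), p = rank / n_units.
ratio_rank_p <- function(ratios, treated) {
  r0 <- ratios[[treated]]
  rank <- sum(ratios >= r0)
  list(rank = rank, p = rank / length(ratios))
}

#' Post/pre-MSPE ratio permutation test
#'
#' Computes each unit's ratio of post- to pre-intervention MSPE — large
#' values mean the unit diverged from its synthetic control after the
#' intervention by more than its fitting noise — and ranks the treated
#' unit among all units (itself included) by descending ratio, ties
#' counting as outranking. The permutation p-value is
#' `rank / n_units`: the probability, under random assignment of the
#' intervention among exchangeable units, of a ratio at least as extreme
#' as the treated unit's.
#'
#' @param set a `placebo_set` (typically unfiltered: the test uses all
#'   units).
#' @return A `ratio_test`: `ratios` (named, descending), `treated_rank`,
#'   `n_units`, `p` (full precision; the print method displays 2 dp).
#' @export
mspe_ratio_test <- function(set) {
  stopifnot(inherits(set, "placebo_set"))
  pre <- vapply(set$fits, `[[`, numeric(1), "mspe_pre")
  post <- vapply(set$fits, `[[`, numeric(1), "mspe_post")
  zero <- names(pre)[pre <= 0]
  if (length(zero) > 0L)
    stop("inference undefined-ratio error: zero pre-period MSPE for unit(s): ",
         paste(zero, collapse = ", "), call. = FALSE)
  ratios <- post / pre
  rp <- ratio_rank_p(ratios, set$treated)
  structure(list(ratios = sort(ratios, decreasing = TRUE),
                 treated = set$treated,
                 treated_rank = rp$rank, n_units = length(ratios),
                 p = rp$p),
            class = "ratio_test")
}

#' @export
print.ratio_test <- function(x, ...) {
  cat(sprintf("<ratio_test> %s post/pre-MSPE ratio %.2f; rank %d of %d; p = %.2f\n",
              x$treated, x$ratios[[x$treated]], x$treated_rank, x$n_units,
              x$p))
  invisible(x)
}

#' In-time placebo fits
#'
#' Re-runs the synthetic control protocol with fictitious intervention
#' dates: for each dummy year `d` the pre-period ends at `d - 1` and the
#' post-period starts at `d` (the window's end is unchanged). A model that
#' "finds" divergence at dates when nothing happened is over-fitting;
#' the fit at the true intervention year reproduces the main fit exactly.
#'
#' @inheritParams placebo_in_space
#' @param dummy_years fictitious intervention years (default 1995:1998).
#' @return Named list of [synth_fit] objects, one per dummy year.
#' @export
time_placebo <- function(panel, treated, donors, window,
                         dummy_years = 1995:1998, spec = NULL,
                         protocol = c("full", "fixed"),
                         age_group = "U18", v_seed = 20211L,
                         tolerance = 0.05, max_groups = Inf) {
  protocol <- match.arg(protocol)
  if (protocol == "fixed" && is.null(spec))
    stop("inference error: protocol 'fixed' requires a predictor spec",
         call. = FALSE)
  out <- list()
  for (d in as.integer(dummy_years)) {
    if (d - window$pre_start < 3L)
      stop("inference error: fewer than 3 pre-dummy years for dummy date ", d,
           call. = FALSE)
    wd <- analysis_window(window$pre_start, d, window$post_end)
    sp <- if (protocol == "fixed") {
      if (d == window$intervention_year) spec else
        stop("inference error: a fixed spec cannot be reused at dummy date ",
             d, " (its year groups cover a different pre-period); use ",
             "protocol 'full'", call. = FALSE)
    } else {
      search_groupings(panel, treated, donors, wd, max_groups = max_groups,
                       tolerance = tolerance, age_group = age_group)$spec
    }
    out[[as.character(d)]] <- fit_synth(panel, treated, donors, wd, sp,
                                        age_group, v_seed)
  }
  out
}

#' Iterative leave-one-out donor analysis
#'
#' Repeatedly removes the donor carrying the largest weight in the current
#' fit and refits, recording the dropped unit, the new weights and the new
#' pre-period MSPE — a robustness probe for over-reliance on one or two
#' donors. The originally selected predictor spec is held fixed across
#' iterations so that changes are attributable to donor removal alone.
#' Weight ties are broken by dropping the alphabetically first donor.
#'
#' @inheritParams fit_synth
#' @param max_iter maximum removals (default until 2 donors remain).
#' @return A list: `iterations` (data.frame of iteration, dropped,
#'   mspe_pre, top_weight) and `fits` (the refits, element 0 the full fit).
#' @export
leave_one_out <- function(panel, treated, donors, window, spec,
                          max_iter = Inf, age_group = "U18",
                          v_seed = 20211L) {
  if (length(donors) < 3L)
    stop("inference error: need at least 3 donors", call. = FALSE)
  pool <- donors
  fits <- list()
  rows <- list()
  fit <- fit_synth(panel, treated, pool, window, spec, age_group, v_seed)
  fits[["full"]] <- fit
  it <- 0L
  while (length(pool) > 2L && it < max_iter) {
    it <- it + 1L
    w <- fit$weights$w
    top <- sort(names(w)[w >= max(w) - 1e-12])[1L]
    pool <- setdiff(pool, top)
    fit <- fit_synth(panel, treated, pool, window, spec, age_group, v_seed)
    fits[[top]] <- fit
    rows[[it]] <- data.frame(iteration = it, dropped = top,
                             n_donors = length(pool),
                             mspe_pre = fit$mspe_pre,
                             top_weight = max(fit$weights$w),
                             stringsAsFactors = FALSE)
  }
  list(iterations = do.call(rbind, rows), fits = fits)
}
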