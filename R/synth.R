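#' Predictor specification for a synthetic control fit
#'
#' Predictors are the mean outcome rate within each block of a contiguous
#' partition of the pre-intervention years (one row per block), optionally
#' augmented with auxiliary covariate columns averaged over the pre-period
#' and z-scaled across units (covariates such as GDP sit on a very
#' different scale from rates per 1000).
#'
#' @param year_groups list of integer vectors partitioning the
#'   pre-intervention years into non-empty, contiguous, disjoint blocks that
#'   cover the pre-period exactly, e.g.
#'   `list(1990:1993, 1994, 1995, 1996:1998)`.
#' @param covariates character vector of covariate column names present in
#'   the panel object passed to the fit (default none).
#' @param v_mode `"optimized"` (predictor-importance weights chosen to
#'   minimise pre-period outcome MSPE) or `"equal"`.
#' @return A `predictor_spec` list.
#' @export
predictor_spec <- function(year_groups, covariates = character(0),
                           v_mode = c("optimized", "equal")) {
  v_mode <- match.arg(v_mode)
  year_groups <- lapply(year_groups, function(g) sort(as.integer(g)))
  for (g in year_groups) {
    if (length(g) == 0L)
      stop("predictor spec error: empty year group", call. = FALSE)
    if (length(g) > 1L && any(diff(g) != 1L))
      stop("predictor spec error: year group not contiguous: ",
           paste(g, collapse = ","), call. = FALSE)
  }
  all_years <- unlist(year_groups)
  if (anyDuplicated(all_years))
    stop("predictor spec error: overlapping year groups", call. = FALSE)
  structure(list(year_groups = year_groups,
                 covariates = as.character(covariates),
                 v_mode = v_mode),
            class = "predictor_spec")
}

check_groups_cover <- function(spec, window) {
  pre <- pre_years(window)
  got <- sort(unlist(spec$year_groups))
  if (!identical(as.integer(got), as.integer(pre)))
    stop("predictor spec error: year groups must cover the pre-period ",
         "exactly (", min(pre), "-", max(pre), ")", call. = FALSE)
}

group_label <- function(g)
  if (length(g) == 1L) as.character(g) else paste0(min(g), "-", max(g))

#' @export
print.predictor_spec <- function(x, ...) {
  cat("<predictor_spec> groups {",
      paste(vapply(x$year_groups, group_label, ""), collapse = ", "),
      "}, v_mode = ", x$v_mode, sep = "")
  if (length(x$covariates)) cat(", covariates: ",
                                paste(x$covariates, collapse = ", "), sep = "")
  cat("\n")
  invisible(x)
}

#' Build predictor matrices for treated unit and donors
#'
#' One row per year-group mean (and per covariate); one column per donor;
#' the treated unit's values form the aligned vector `x1`.
#'
#' @param panel a [rate_panel]; covariate columns, if declared in `spec`,
#'   must be present as extra columns.
#' @param spec a [predictor_spec].
#' @param treated treated-unit label.
#' @param donors character vector of donor labels.
#' @param window an [analysis_window].
#' @param age_group outcome age group (default `"U18"`).
#' @return List with `x1` (named numeric), `X0` (rows = predictors,
#'   columns = donors), and the pre-period outcome series `y1_pre`,
#'   `Y0_pre` used by the V optimisation.
#' @export
build_predictors <- function(panel, spec, treated, donors, window,
                             age_group = "U18") {
  check_groups_cover(spec, window)
  units <- c(treated, donors)
  series <- lapply(units, function(u) unit_series(panel, u, age_group, window))
  names(series) <- units
  pre <- pre_years(window)

  grp_means <- vapply(series, function(s) {
    vapply(spec$year_groups,
           function(g) mean(s$rate[match(g, s$year)]), numeric(1))
  }, numeric(length(spec$year_groups)))
  grp_means <- matrix(grp_means, nrow = length(spec$year_groups),
                      dimnames = list(vapply(spec$year_groups, group_label, ""),
                                      units))

  M <- grp_means
  if (length(spec$covariates) > 0L) {
    covm <- vapply(units, function(u) {
      sub <- panel[panel$country == u & panel$age_group == age_group &
                     panel$year %in% pre, , drop = FALSE]
      vapply(spec$covariates, function(cv) {
        if (!cv %in% names(panel))
          stop("predictor spec error: covariate column '", cv,
               "' not in panel", call. = FALSE)
        x <- sub[[cv]]
        if (anyNA(x))
          stop("panel integrity error: covariate '", cv,
               "' incomplete for unit '", u, "'", call. = FALSE)
        mean(x)
      }, numeric(1))
    }, numeric(length(spec$covariates)))
    covm <- matrix(covm, nrow = length(spec$covariates),
                   dimnames = list(spec$covariates, units))
    # z-scale each covariate row across units
    covm <- t(scale(t(covm)))
    covm[is.nan(covm)] <- 0  # constant covariate carries no information
    M <- rbind(M, covm)
  }

  Y_pre <- vapply(series, function(s) s$rate[match(pre, s$year)],
                  numeric(length(pre)))
  Y_pre <- matrix(Y_pre, nrow = length(pre),
                  dimnames = list(pre, units))

  list(x1 = M[, treated], X0 = M[, donors, drop = FALSE],
       y1_pre = Y_pre[, treated], Y0_pre = Y_pre[, donors, drop = FALSE],
       treated = treated, donors = donors)
}

# Euclidean projection onto the probability simplex (Duchi et al. style
# sort-and-threshold).
project_simplex <- function(v) {
  u <- sort(v, decreasing = TRUE)
  css <- cumsum(u)
  rho <- max(which(u - (css - 1) / seq_along(u) > 0))
  pmax(v - (css[rho] - 1) / rho, 0)
}

solve_w_pgd <- function(H, g, n, iter = 1000L) {
  # accelerated projected gradient on f(w) = w'Hw - 2 g'w over the simplex
  L <- 2 * max(eigen(H, symmetric = TRUE, only.values = TRUE)$values, 1e-12)
  w <- rep(1 / n, n); z <- w; tk <- 1
  for (i in seq_len(iter)) {
    grad <- 2 * (H %*% z - g)
    w_new <- project_simplex(drop(z - grad / L))
    t_new <- (1 + sqrt(1 + 4 * tk^2)) / 2
    z <- w_new + ((tk - 1) / t_new) * (w_new - w)
    w <- w_new; tk <- t_new
  }
  w
}

#' Solve for donor weights on the simplex
#'
#' Minimises the V-weighted predictor discrepancy
#' `sum_k v_k (x1_k - X0_k. w)^2` subject to `w >= 0`, `sum(w) = 1` — a
#' convex quadratic program over the probability simplex. The primary
#' solver is a dual active-set QP (`quadprog`) on the ridge-stabilised
#' cross-product matrix; `method = "pgd"` uses an accelerated projected
#' gradient scheme (1000 iterations) instead.
#'
#' @param x1 treated predictor vector (length K).
#' @param X0 donor predictor matrix (K x J, J >= 2).
#' @param v predictor importance weights (length K, non-negative; will be
#'   normalised to sum to 1).
#' @param method `"qp"` (default) or `"pgd"`.
#' @return Named weight vector summing to 1.
#' @export
solve_w <- function(x1, X0, v = rep(1, length(x1)), method = c("qp", "pgd")) {
  method <- match.arg(method)
  X0 <- as.matrix(X0)
  J <- ncol(X0)
  if (J < 2L) stop("synth error: need at least 2 donors", call. = FALSE)
  if (length(x1) != nrow(X0) || length(v) != length(x1))
    stop("synth error: predictor dimensions disagree", call. = FALSE)
  if (any(v < 0)) stop("synth error: negative importance weight", call. = FALSE)
  if (sum(v) <= 0) stop("synth error: importance weights sum to 0", call. = FALSE)
  v <- v / sum(v)

  H <- crossprod(X0, v * X0)
  g <- drop(crossprod(X0, v * x1))
  ridge <- 1e-8 * max(mean(diag(H)), 1e-8)
  Hr <- H + diag(ridge, J)

  w <- if (method == "qp") {
    sol <- tryCatch(
      quadprog::solve.QP(Dmat = 2 * Hr, dvec = 2 * g,
                         Amat = cbind(rep(1, J), diag(J)),
                         bvec = c(1, rep(0, J)), meq = 1),
      error = function(e) NULL)
    if (is.null(sol)) solve_w_pgd(Hr, g, J) else sol$solution
  } else {
    solve_w_pgd(Hr, g, J)
  }
  w <- pmax(w, 0)
  w <- w / sum(w)
  w <- polish_support(w, H, g)
  names(w) <- colnames(X0)
  w
}

# Re-solve the equality-constrained problem on the active support without
# the ridge, so vertex and edge optima come out exact; keep the polished
# solution only when it is feasible and no worse.
polish_support <- function(w, H, g) {
  S <- which(w > 1e-7)
  k <- length(S)
  KKT <- rbind(cbind(2 * H[S, S, drop = FALSE], rep(1, k)),
               c(rep(1, k), 0))
  sol <- tryCatch(solve(KKT, c(2 * g[S], 1)), error = function(e) NULL)
  if (is.null(sol)) return(w)
  wS <- sol[seq_len(k)]
  if (any(wS < -1e-10)) return(w)
  w2 <- numeric(length(w))
  w2[S] <- pmax(wS, 0)
  w2 <- w2 / sum(w2)
  obj <- function(x) drop(x %*% H %*% x - 2 * sum(g * x))
  if (obj(w2) <= obj(w) + 1e-12) w2 else w
}

# Weights for a predictor set with outcome-based tie-breaking: when the
# predictor match is (numerically) exact the weights are not identified by
# the predictors alone, so among predictor-optimal solutions we take the
# one minimising pre-period outcome MSPE (a second QP with the predictor
# match imposed as equality constraints).
solve_w_tiebreak <- function(x1, X0, v, y1_pre, Y0_pre) {
  w <- solve_w(x1, X0, v)
  loss <- synth_objective(w, x1, X0, v)
  if (loss > 1e-10 * (1 + sum((v / sum(v)) * x1^2))) return(w)
  J <- ncol(X0)
  H <- crossprod(Y0_pre)
  Hr <- H + diag(1e-8 * max(mean(diag(H)), 1e-8), J)
  sol <- tryCatch(
    quadprog::solve.QP(Dmat = 2 * Hr,
                       dvec = 2 * drop(crossprod(Y0_pre, y1_pre)),
                       Amat = cbind(rep(1, J), t(as.matrix(X0)), diag(J)),
                       bvec = c(1, x1, rep(0, J)), meq = 1L + length(x1)),
    error = function(e) NULL)
  if (is.null(sol)) return(w)
  w2 <- pmax(sol$solution, 0)
  w2 <- w2 / sum(w2)
  names(w2) <- colnames(X0)
  if (pre_mspe_of_w(w2, y1_pre, Y0_pre) <= pre_mspe_of_w(w, y1_pre, Y0_pre))
    w2 else w
}

synth_objective <- function(w, x1, X0, v) {
  v <- v / sum(v)
  r <- x1 - drop(as.matrix(X0) %*% w)
  sum(v * r^2)
}

pre_mspe_of_w <- function(w, y1_pre, Y0_pre)
  mean((y1_pre - drop(Y0_pre %*% w))^2)

#' Optimise predictor importance weights
#'
#' Nested optimisation: for candidate importance weights `v` on the
#' simplex, the induced donor weights `w*(v)` come from [solve_w()]; `v`
#' is chosen to minimise the pre-period outcome MSPE of `w*(v)`. The outer
#' search runs Nelder-Mead on a softmax parameterisation from an
#' equal-weights start plus `n_starts - 1` random starts drawn under a
#' fixed seed, returning the best of all starts.
#'
#' @param x1,X0 predictor vector/matrix as from [build_predictors()].
#' @param y1_pre,Y0_pre pre-period outcome series for treated and donors.
#' @param n_starts total number of starts (default 5).
#' @param seed seed for the random starts (default 20211).
#' @return A `synth_weights` list with `w`, `v`, and the achieved
#'   pre-period MSPE.
#' @export
optimize_v <- function(x1, X0, y1_pre, Y0_pre, n_starts = 5L, seed = 20211L) {
  K <- length(x1)
  if (K == 1L) {
    w <- solve_w_tiebreak(x1, X0, 1, y1_pre, Y0_pre)
    return(synth_weights(w, v = stats::setNames(1, names(x1)),
                         mspe_pre = pre_mspe_of_w(w, y1_pre, Y0_pre)))
  }
  obj <- function(theta) {
    v <- exp(c(0, theta) - max(c(0, theta)))
    v <- v / sum(v)
    w <- solve_w_tiebreak(x1, X0, v, y1_pre, Y0_pre)
    pre_mspe_of_w(w, y1_pre, Y0_pre)
  }
  starts <- c(list(rep(0, K - 1L)),
              withr::with_seed(seed, replicate(max(n_starts - 1L, 0L),
                                               stats::rnorm(K - 1L, 0, 2),
                                               simplify = FALSE)))
  best <- NULL
  for (th0 in starts) {
    op <- tryCatch(
      if (K == 2L)
        stats::optim(th0, obj, method = "Brent", lower = -30, upper = 30)
      else
        stats::optim(th0, obj, method = "Nelder-Mead",
                     control = list(maxit = 500L)),
      error = function(e) NULL)
    if (is.null(op)) next
    if (is.null(best) || op$value < best$value) best <- op
  }
  if (is.null(best))
    stop("synth optimization error: all V starts failed", call. = FALSE)
  v <- exp(c(0, best$par) - max(c(0, best$par)))
  v <- v / sum(v)
  names(v) <- names(x1)
  w <- solve_w_tiebreak(x1, X0, v, y1_pre, Y0_pre)
  mspe <- pre_mspe_of_w(w, y1_pre, Y0_pre)
  # equal weights may beat the search on rugged instances; keep dominance
  w_eq <- solve_w_tiebreak(x1, X0, rep(1, K), y1_pre, Y0_pre)
  mspe_eq <- pre_mspe_of_w(w_eq, y1_pre, Y0_pre)
  if (mspe_eq < mspe) {
    v <- stats::setNames(rep(1 / K, K), names(x1))
    w <- w_eq; mspe <- mspe_eq
  }
  synth_weights(w, v, mspe)
}

synth_weights <- function(w, v, mspe_pre) {
  stopifnot(all(w >= -1e-8), abs(sum(w) - 1) < 1e-8,
            all(v >= -1e-8), abs(sum(v) - 1) < 1e-8)
  structure(list(w = w, v = v, mspe_pre = mspe_pre), class = "synth_weights")
}

#' @export
print.synth_weights <- function(x, ...) {
  cat("<synth_weights>\n  donors (w > 0.1%):\n")
  w <- sort(x$w[x$w > 0.001], decreasing = TRUE)
  for (nm in names(w)) cat(sprintf("    %-20s %5.1f%%\n", nm, 100 * w[nm]))
  cat("  predictor importance v:",
      paste(sprintf("%s=%.2f", names(x$v), x$v), collapse = ", "), "\n")
  invisible(x)
}

#' Fit a synthetic control
#'
#' Builds predictors per `spec`, derives donor weights (with optimised or
#' equal predictor importance per `spec$v_mode`), and assembles the
#' synthetic series — the weighted donor outcome over the entire window —
#' together with the yearly gap series (treated minus synthetic) and the
#' pre- and post-period mean squared prediction errors.
#'
#' @inheritParams build_predictors
#' @param v_seed seed for the V-optimisation multistart (default 20211).
#' @return A `synth_fit`: `weights` ([synth_weights]), `series` (data.frame
#'   year, observed, synthetic, gap, period), `mspe_pre`, `mspe_post`,
#'   `rmse_pre` (`sqrt(mspe_pre)`, the prediction-error figure on the rate
#'   scale), plus the spec, window and unit labels.
#' @export
fit_synth <- function(panel, treated, donors, window, spec,
                      age_group = "U18", v_seed = 20211L) {
  stopifnot(inherits(spec, "predictor_spec"))
  P <- build_predictors(panel, spec, treated, donors, window, age_group)
  sw <- if (spec$v_mode == "optimized") {
    optimize_v(P$x1, P$X0, P$y1_pre, P$Y0_pre, seed = v_seed)
  } else {
    K <- length(P$x1)
    w <- solve_w_tiebreak(P$x1, P$X0, rep(1, K), P$y1_pre, P$Y0_pre)
    synth_weights(w, stats::setNames(rep(1 / K, K), names(P$x1)),
                  pre_mspe_of_w(w, P$y1_pre, P$Y0_pre))
  }

  yrs <- window$pre_start:window$post_end
  series <- lapply(c(treated, donors), function(u)
    unit_series(panel, u, age_group, window)$rate)
  obs <- series[[1L]]
  Y0 <- do.call(cbind, series[-1L])
  synth <- drop(Y0 %*% sw$w)
  gap <- obs - synth
  period <- ifelse(yrs < window$intervention_year, "pre", "post")
  mspe_pre <- mean(gap[period == "pre"]^2)
  mspe_post <- mean(gap[period == "post"]^2)

  structure(list(weights = sw,
                 series = data.frame(year = yrs, observed = obs,
                                     synthetic = synth, gap = gap,
                                     period = period),
                 mspe_pre = mspe_pre, mspe_post = mspe_post,
                 rmse_pre = sqrt(mspe_pre),
                 spec = spec, window = window,
                 treated = treated, donors = donors,
                 age_group = age_group, v_seed = v_seed),
            class = "synth_fit")
}

#' @export
print.synth_fit <- function(x, ...) {
  cat(sprintf("<synth_fit> %s vs synthetic of %d donors, %d-%d (intervention %d)\n",
              x$treated, length(x$donors), x$window$pre_start,
              x$window$post_end, x$window$intervention_year))
  cat(sprintf("  pre-period MSPE %.4g (prediction error %.3g per 1000), post-period MSPE %.4g\n",
              x$mspe_pre, x$rmse_pre, x$mspe_post))
  print(x$weights)
  invisible(x)
}

# all contiguous partitions of the integer vector `yrs` (2^(n-1) of them),
# optionally capped at max_groups blocks
contiguous_partitions <- function(yrs, max_groups = Inf) {
  n <- length(yrs)
  if (n == 1L) return(list(list(yrs)))
  out <- list()
  for (code in 0:(2^(n - 1L) - 1L)) {
    cuts <- which(bitwAnd(code, 2^(0:(n - 2L))) > 0)
    bounds <- c(0L, cuts, n)
    if (length(bounds) - 1L > max_groups) next
    grp <- lapply(seq_len(length(bounds) - 1L),
                  function(i) yrs[(bounds[i] + 1L):bounds[i + 1L]])
    out[[length(out) + 1L]] <- grp
  }
  out
}

#' Search for an optimal grouping of pre-intervention years
#'
#' Exhaustively enumerates every contiguous partition of the
#' pre-intervention years (2^(n-1) candidates for n years), fits a
#' synthetic control with the block means as predictors (equal importance
#' weights during the search), and applies a tolerance-band lexicographic
#' selection: among partitions whose pre-period MSPE is within
#' `(1 + tolerance)` of the global minimum, prefer the fewest groups,
#' then lower MSPE, then lexicographically earlier block boundaries. The
#' full enumeration table is returned for audit.
#'
#' @inheritParams build_predictors
#' @param max_groups cap on the number of blocks (default unlimited).
#' @param tolerance MSPE slack band as a fraction of the global minimum
#'   (default 0.05).
#' @param override allow pre-periods longer than 15 years (default `FALSE`;
#'   the enumeration is exponential in the pre-period length).
#' @return A list: `spec` (the selected [predictor_spec], `v_mode`
#'   `"optimized"`), `audit` (data.frame of partition, n_groups, mspe_pre,
#'   selected), `mspe_min`.
#' @export
search_groupings <- function(panel, treated, donors, window,
                             max_groups = Inf, tolerance = 0.05,
                             age_group = "U18", override = FALSE) {
  pre <- pre_years(window)
  n <- length(pre)
  if (n > 15L && !override)
    stop("combinatorial-limit error: ", n, " pre-intervention years imply 2^",
         n - 1L, " partitions; pass override = TRUE to force", call. = FALSE)
  parts <- contiguous_partitions(pre, max_groups)
  mspe <- numeric(length(parts))
  labs <- character(length(parts))
  ng <- integer(length(parts))
  for (i in seq_along(parts)) {
    sp <- predictor_spec(parts[[i]], v_mode = "equal")
    P <- build_predictors(panel, sp, treated, donors, window, age_group)
    w <- solve_w_tiebreak(P$x1, P$X0, rep(1, length(P$x1)), P$y1_pre,
                          P$Y0_pre)
    mspe[i] <- pre_mspe_of_w(w, P$y1_pre, P$Y0_pre)
    labs[i] <- paste(vapply(parts[[i]], group_label, ""), collapse = " | ")
    ng[i] <- length(parts[[i]])
  }
  m_star <- min(mspe)
  # absolute floor keeps the band meaningful when every fit is essentially
  # exact and solver noise alone separates partitions
  band <- mspe <= (1 + tolerance) * m_star + 1e-9
  cand <- which(band)
  # fewest groups, then lower MSPE, then lexicographic boundaries
  ord <- cand[order(ng[cand], mspe[cand], labs[cand])]
  sel <- ord[1L]
  audit <- data.frame(partition = labs, n_groups = ng, mspe_pre = mspe,
                      in_band = band, selected = seq_along(parts) == sel,
                      stringsAsFactors = FALSE)
  list(spec = predictor_spec(parts[[sel]], v_mode = "optimized"),
       audit = audit[order(audit$mspe_pre), ], mspe_min = m_star)
}
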