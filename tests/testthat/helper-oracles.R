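# Independent re-enumeration of the grouping search, sharing no code with
# the package: recursive partition generator, direct group means, and
# quadprog called directly for the weights.
oracle_partitions <- function(yrs) {
  if (length(yrs) == 1L) return(list(list(yrs)))
  first <- lapply(seq_along(yrs), function(k) yrs[1:k])
  out <- list()
  for (k in seq_along(yrs)) {
    head <- yrs[1:k]
    if (k == length(yrs)) out[[length(out) + 1L]] <- list(head)
    else for (rest in oracle_partitions(yrs[(k + 1L):length(yrs)]))
      out[[length(out) + 1L]] <- c(list(head), rest)
  }
  out
}

oracle_mspe <- function(part, Y1, Y0, pre_idx) {
  gm <- function(y) vapply(part, function(g) mean(y[pre_idx %in% g]),
                           numeric(1))
  x1 <- gm(Y1)
  X0 <- apply(Y0, 2, gm)
  if (length(part) == 1L) X0 <- matrix(X0, nrow = 1)
  J <- ncol(Y0); K <- length(x1)
  H <- crossprod(X0) + diag(1e-8 * max(mean(diag(crossprod(X0))), 1e-8), J)
  sol <- quadprog::solve.QP(2 * H, 2 * drop(crossprod(X0, x1)),
                            cbind(rep(1, J), diag(J)),
                            c(1, rep(0, J)), meq = 1)
  w <- pmax(sol$solution, 0); w <- w / sum(w)
  # same protocol as the package: an exact predictor match leaves w
  # under-identified, so re-solve for the best pre-period outcome fit
  # subject to the exact match
  if (sum((x1 - drop(X0 %*% w))^2) / K <= 1e-10 * (1 + mean(x1^2))) {
    Ho <- crossprod(Y0) + diag(1e-8 * max(mean(diag(crossprod(Y0))), 1e-8), J)
    s2 <- tryCatch(
      quadprog::solve.QP(2 * Ho, 2 * drop(crossprod(Y0, Y1)),
                         cbind(rep(1, J), t(X0), diag(J)),
                         c(1, x1, rep(0, J)), meq = 1L + K),
      error = function(e) NULL)
    if (!is.null(s2)) {
      w2 <- pmax(s2$solution, 0); w2 <- w2 / sum(w2)
      if (mean((Y1 - drop(Y0 %*% w2))^2) <= mean((Y1 - drop(Y0 %*% w))^2))
        w <- w2
    }
  }
  mean((Y1 - drop(Y0 %*% w))^2)
}
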