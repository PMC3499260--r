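#' Block-jackknife Wald test for a migration edge
#'
#' Tests an individual migration edge's weight against the null \eqn{w = 0}
#' for a fixed graph structure. For each left-out block the covariance is
#' recomputed from the remaining blocks and only the target edge's weight
#' is re-optimized (branch lengths are refit at every evaluation; the
#' topology and all other weights stay fixed). The delete-one jackknife
#' point estimate and standard error give a Wald Z, referred to a
#' two-sided normal.
#'
#' The weight is re-estimated over `bounds` (default \eqn{[-1, 1]}) rather
#' than the admixture range \eqn{[0, 1]}: under the null the constrained
#' estimator is pinned at the boundary, making every delete-one estimate
#' identical and the test degenerate, while the unconstrained estimator is
#' approximately normal around zero so the Wald p-value is calibrated.
#'
#' @param fit an `admix_fit` containing the edge.
#' @param edge migration-edge identifier (row index in `fit$graph$edges`
#'   or `c(from, to)` node ids).
#' @param cov a `cov_estimate` with at least 3 blocks (defaults to the one
#'   stored in `fit`).
#' @param weight_tol golden-section bracket tolerance.
#' @param bounds search interval for the re-estimated weight.
#' @return A `migration_test`: list with `from`, `to`, `weight_hat` (the
#'   graph's fitted weight), `weight_full` (full-data re-estimate over
#'   `bounds`), `jack_weight` (jackknife point estimate), `se`, `z`, `p`,
#'   `n_blocks`, `degenerate` (TRUE when all delete-one estimates
#'   coincide, in which case `p` is reported as 0).
#' @export
test_migration <- function(fit, edge, cov = fit$cov, weight_tol = 1e-4,
                           bounds = c(-1, 1)) {
  g <- fit$graph
  i <- resolve_migration_edge(g, edge)
  K <- cov$K
  if (K < 3) stop("need at least 3 blocks for the jackknife")
  w_hat <- g$edges$weight[i]
  w_full <- optimize_weight(g, i, cov, tol = weight_tol,
                            lo = bounds[1], hi = bounds[2],
                            drift_weighting = fit$drift_weighting)
  w_loo <- numeric(K)
  for (k in seq_len(K)) {
    cov_k <- drop_block(cov, k)
    w_loo[k] <- optimize_weight(g, i, cov_k, tol = weight_tol,
                                lo = bounds[1], hi = bounds[2],
                                drift_weighting = fit$drift_weighting)
  }
  jack <- K * w_full - (K - 1) * mean(w_loo)
  se <- sqrt((K - 1) / K * sum((w_loo - mean(w_loo))^2))
  degenerate <- se == 0
  z <- if (degenerate) Inf else jack / se
  p <- if (degenerate) 0 else 2 * stats::pnorm(-abs(z))
  structure(list(from = g$edges$from[i], to = g$edges$to[i],
                 weight_hat = w_hat, weight_full = w_full,
                 jack_weight = jack, se = se,
                 z = z, p = p, n_blocks = K, degenerate = degenerate),
            class = "migration_test")
}

#' @export
print.migration_test <- function(x, ...) {
  cat(sprintf(paste0("migration edge %d -> %d: w = %.4f ",
                     "(jackknife %.4f, se %.4g), Z = %.3f, p = %.3g%s\n"),
              x$from, x$to, x$weight_hat, x$jack_weight, x$se, x$z, x$p,
              if (x$degenerate) " [degenerate variance]" else ""))
  invisible(x)
}
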