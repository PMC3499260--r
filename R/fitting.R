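## upper-triangle (including diagonal) logical index for a P x P matrix;
## the composite likelihood takes each unordered pair of populations once,
## diagonal included (terminal-branch drift is informative).
ut_index <- function(P) upper.tri(matrix(0, P, P), diag = TRUE)

## U matrix (tip x node path weights); fast integer-indexed walk for trees
node_weight_matrix <- function(g, pops) {
  if (nrow(migration_edges(g)) == 0) {
    ids <- g$nodes$id
    n <- length(ids)
    te <- tree_edges(g)
    par_idx <- integer(n)                      # 0 for root
    par_idx[match(te$to, ids)] <- match(te$from, ids)
    tip_idx <- match(graph_tips(g)[pops], ids)
    U <- matrix(0, length(pops), n, dimnames = list(pops, ids))
    for (i in seq_along(tip_idx)) {
      node <- tip_idx[i]
      while (node != 0L) {
        U[i, node] <- 1
        node <- par_idx[node]
      }
    }
    U
  } else {
    path_node_weights(g, pops)
  }
}

## design matrix of the linear system W(G) = A %*% c: one row per unordered
## population pair (diagonal included), one column per tree edge (named by
## child node id); entries are centered path-pair overlap coefficients.
design_matrix <- function(g, pops, drift_weighting = "post") {
  U <- node_weight_matrix(g, pops)
  te <- tree_edges(g)
  cols <- match(te$to, g$nodes$id)
  Uc <- U[, cols, drop = FALSE]
  Uc <- sweep(Uc, 2, colMeans(Uc))
  P <- length(pops)
  idx <- which(ut_index(P), arr.ind = TRUE)
  A <- Uc[idx[, 1], , drop = FALSE] * Uc[idx[, 2], , drop = FALSE]
  if (drift_weighting != "post") {
    scl <- drift_scale(g, drift_weighting)
    A <- sweep(A, 2, scl[as.character(te$to)], `*`)
  }
  colnames(A) <- as.character(te$to)
  A
}

## non-negative least squares. Fast paths: unconstrained QR solution when
## already feasible, else an active-set iteration verified by the KKT
## conditions (sufficient for this convex problem); falls back to
## pracma::lsqnonneg (Lawson-Hanson) if the iteration stalls.
nnls_fit <- function(A, b) {
  qa <- qr(A)
  rank <- qa$rank
  x <- qr.coef(qa, b)
  x[is.na(x)] <- 0
  x <- drop(x)
  if (all(x >= -1e-10)) {
    return(list(x = pmax(x, 0), rank = rank))
  }
  m <- ncol(A)
  zeroed <- x < 0
  for (iter in seq_len(3 * m)) {
    x <- numeric(m)
    sup <- which(!zeroed)
    if (length(sup) > 0) {
      xs <- qr.coef(qr(A[, sup, drop = FALSE]), b)
      xs[is.na(xs)] <- 0
      x[sup] <- xs
    }
    if (any(x < -1e-10)) {
      zeroed[x < -1e-10] <- TRUE
      next
    }
    x <- pmax(x, 0)
    grad <- drop(crossprod(A, b - A %*% x))
    tol <- 1e-10 * max(1, max(abs(grad)))
    viol <- zeroed & grad > tol
    if (!any(viol)) {
      return(list(x = x, rank = rank))
    }
    zeroed[which(viol)[which.max(grad[viol])]] <- FALSE
  }
  out <- tryCatch(pracma::lsqnonneg(A, b)$x, error = function(e) pmax(x, 0))
  list(x = out, rank = rank)
}

## with a degree-2 root the two root-adjacent drift lengths enter the
## centered covariance only through their sum; split it evenly (unless a
## migration edge leaves the root, which breaks the symmetry)
even_root_split <- function(g) {
  root <- graph_root(g)
  kids <- tree_children(g, root)
  if (length(kids) != 2) return(g)
  if (any(g$edges$from == root & g$edges$type == "migration")) return(g)
  i <- which(g$edges$type == "tree" & g$edges$to %in% kids)
  g$edges$length[i] <- sum(g$edges$length[i]) / 2
  g
}

#' Fit tree-edge drift lengths by non-negative least squares
#'
#' With migration weights held fixed, the centered model covariance is
#' linear in the drift lengths, giving one equation per unordered
#' population pair (diagonal included). The overdetermined system is solved
#' under the constraint \eqn{c \ge 0} (plain, unweighted least squares).
#'
#' @param g a `popgraph` (weights fixed).
#' @param cov a `cov_estimate`; population order is taken from it.
#' @param drift_weighting see [predicted_covariance()].
#' @return the graph with fitted lengths. If the system is rank-deficient,
#'   attribute `"degenerate_edges"` lists child-node ids of edges whose
#'   lengths are not separately identifiable.
#' @export
fit_branch_lengths <- function(g, cov, drift_weighting = "post") {
  pops <- cov$populations
  A <- design_matrix(g, pops, drift_weighting)
  b <- cov$W_hat[ut_index(length(pops))]
  sol <- nnls_fit(A, b)
  lengths <- stats::setNames(sol$x, colnames(A))
  g <- set_lengths(g, lengths)
  g <- even_root_split(g)
  # with a degree-2 root, only the sum of the two root-adjacent lengths is
  # identified (their centered coefficients coincide); the sum is split
  # evenly, and this expected deficiency is not warned
  expected_rank <- ncol(A) -
    (length(tree_children(g, graph_root(g))) == 2)
  if (sol$rank < expected_rank) {
    # identify columns involved in the deficiency
    qrA <- qr(A)
    dep <- colnames(A)[-qrA$pivot[seq_len(qrA$rank)]]
    attr(g, "degenerate_edges") <- dep
    warning("rank-deficient branch-length system; unidentifiable edge(s): ",
            paste(dep, collapse = ","))
  }
  g
}

#' Composite log-likelihood of a model covariance
#'
#' Sum over unordered population pairs (diagonal included) of the log
#' Gaussian density of the observed covariance entry, with mean the model
#' entry and standard deviation the block-resampled standard error. A
#' pseudo-likelihood: entries of the covariance matrix are not independent,
#' but the product of their marginal densities is a practical objective.
#'
#' @param W_model model covariance matrix (centered), aligned with `cov`.
#' @param cov a `cov_estimate`.
#' @param se_floor standard errors below this are raised to it (with a
#'   warning); set to 0 to error on zero standard errors instead.
#' @return scalar log-likelihood.
#' @export
composite_log_likelihood <- function(W_model, cov, se_floor = 1e-12) {
  P <- length(cov$populations)
  ut <- ut_index(P)
  se <- cov$se[ut]
  if (any(se < se_floor)) {
    if (se_floor <= 0 || any(se <= 0 & se_floor <= 0)) {
      stop("zero standard error in covariance estimate; ",
           "increase the number of blocks or set a positive se_floor")
    }
    warning("flooring ", sum(se < se_floor), " standard error(s) at ", se_floor)
    se <- pmax(se, se_floor)
  }
  if (any(se == 0)) {
    stop("zero standard error in covariance estimate; ",
         "increase the number of blocks or set a positive se_floor")
  }
  sum(stats::dnorm(cov$W_hat[ut], mean = W_model[ut], sd = se, log = TRUE))
}

## loglik of a graph after refitting branch lengths; avoids building the
## full model covariance (W entries come straight from the linear system)
refit_loglik <- function(g, cov, drift_weighting = "post", se_floor = 1e-12) {
  pops <- cov$populations
  A <- design_matrix(g, pops, drift_weighting)
  b <- cov$W_hat[ut_index(length(pops))]
  sol <- nnls_fit(A, b)
  g <- set_lengths(g, stats::setNames(sol$x, colnames(A)))
  g <- even_root_split(g)
  se <- pmax(cov$se[ut_index(length(pops))], se_floor)
  if (any(se == 0)) {
    stop("zero standard error in covariance estimate; ",
         "increase the number of blocks or set a positive se_floor")
  }
  list(graph = g,
       loglik = sum(stats::dnorm(b, mean = drop(A %*% sol$x), sd = se,
                                 log = TRUE)))
}

## coordinate-ascent core shared by fit_graph and the topology search;
## returns a light list(graph, loglik, converged)
fit_core <- function(g, cov, tol = 1e-6, max_rounds = 50,
                     weight_tol = 1e-4, drift_weighting = "post",
                     se_floor = 1e-12) {
  me_idx <- which(g$edges$type == "migration")
  res <- refit_loglik(g, cov, drift_weighting, se_floor)
  g <- res$graph
  ll <- res$loglik
  converged <- TRUE
  if (length(me_idx) > 0) {
    converged <- FALSE
    for (round in seq_len(max_rounds)) {
      for (i in me_idx) {
        g$edges$weight[i] <- optimize_weight(g, i, cov, tol = weight_tol,
                                             drift_weighting = drift_weighting,
                                             se_floor = se_floor)
      }
      res <- refit_loglik(g, cov, drift_weighting, se_floor)
      g <- res$graph
      if (res$loglik - ll < tol) {
        ll <- max(ll, res$loglik)
        converged <- TRUE
        break
      }
      ll <- res$loglik
    }
  }
  list(graph = g, loglik = ll, converged = converged)
}

golden_section_max <- function(f, lo = 0, hi = 1, tol = 1e-4) {
  phi <- (sqrt(5) - 1) / 2
  x1 <- hi - phi * (hi - lo); x2 <- lo + phi * (hi - lo)
  f1 <- f(x1); f2 <- f(x2)
  while (hi - lo > tol) {
    if (f1 < f2) {
      lo <- x1; x1 <- x2; f1 <- f2
      x2 <- lo + phi * (hi - lo); f2 <- f(x2)
    } else {
      hi <- x2; x2 <- x1; f2 <- f1
      x1 <- hi - phi * (hi - lo); f1 <- f(x1)
    }
  }
  if (f1 > f2) x1 else x2
}

#' Optimize one migration-edge weight by golden-section search
#'
#' Maximizes the composite likelihood over \eqn{w \in [0,1]} for a single
#' migration edge, refitting all branch lengths at every evaluation.
#' Boundary optima are allowed.
#'
#' @param g a `popgraph`.
#' @param edge row index into `g$edges` of the migration edge, or a
#'   length-2 vector `c(from, to)` of node ids.
#' @param cov a `cov_estimate`.
#' @param tol golden-section bracket tolerance.
#' @param lo,hi search interval. The default \eqn{[0,1]} is the admixture
#'   range; significance testing widens it so the null estimator is not
#'   pinned at the boundary.
#' @param drift_weighting,se_floor see [fit_branch_lengths()],
#'   [composite_log_likelihood()].
#' @return the optimal weight.
#' @export
optimize_weight <- function(g, edge, cov, tol = 1e-4, lo = 0, hi = 1,
                            drift_weighting = "post", se_floor = 1e-12) {
  i <- resolve_migration_edge(g, edge)
  f <- function(w) {
    g$edges$weight[i] <- w
    refit_loglik(g, cov, drift_weighting, se_floor)$loglik
  }
  golden_section_max(f, lo, hi, tol)
}

resolve_migration_edge <- function(g, edge) {
  if (length(edge) == 2) {
    i <- which(g$edges$from == edge[1] & g$edges$to == edge[2] &
               g$edges$type == "migration")
  } else {
    i <- as.integer(edge)
  }
  if (length(i) != 1 || g$edges$type[i] != "migration") {
    stop("edge does not identify a migration edge")
  }
  i
}

#' Fit all branch lengths and migration weights of a graph
#'
#' Coordinate ascent: branch lengths are fit by non-negative least squares,
#' then each migration edge's weight is optimized in turn by golden-section
#' search (with nested branch refits), iterating until the composite
#' log-likelihood improves by less than `tol` or `max_rounds` is reached.
#'
#' @param g a `popgraph`.
#' @param cov a `cov_estimate`.
#' @param tol outer-loop convergence tolerance on the log-likelihood.
#' @param max_rounds maximum coordinate-ascent rounds.
#' @param weight_tol golden-section bracket tolerance.
#' @param drift_weighting,se_floor see [fit_branch_lengths()],
#'   [composite_log_likelihood()].
#' @return An `admix_fit`: list with `graph` (fitted), `model` (`V`, `W`),
#'   `loglik`, `residuals` (observed minus model), `scaled_residuals`
#'   (residuals over the average standard error), `variance_explained`,
#'   `converged`, `cov`.
#' @export
fit_graph <- function(g, cov, tol = 1e-6, max_rounds = 50,
                      weight_tol = 1e-4, drift_weighting = "post",
                      se_floor = 1e-12) {
  core <- fit_core(g, cov, tol, max_rounds, weight_tol, drift_weighting,
                   se_floor)
  if (!core$converged) {
    warning("fit_graph did not converge in ", max_rounds, " rounds")
  }
  model <- predicted_covariance(core$graph, cov$populations, drift_weighting)
  new_admix_fit(core$graph, model, core$loglik, cov, core$converged,
                drift_weighting)
}

new_admix_fit <- function(g, model, ll, cov, converged, drift_weighting) {
  R <- cov$W_hat - model$W
  structure(list(graph = g, model = model, loglik = ll,
                 residuals = R,
                 scaled_residuals = R / mean(cov$se[ut_index(nrow(R))]),
                 variance_explained = variance_explained_matrix(cov$W_hat, model$W),
                 converged = converged, drift_weighting = drift_weighting,
                 cov = cov),
            class = "admix_fit")
}

#' @export
print.admix_fit <- function(x, ...) {
  nm <- sum(x$graph$edges$type == "migration")
  cat(sprintf(paste0("admix_fit: %d populations, %d migration edge(s)\n",
                     "  composite log-likelihood: %.4f\n",
                     "  variance explained: %.4f%s\n"),
              length(x$cov$populations), nm, x$loglik,
              x$variance_explained,
              if (x$converged) "" else "  (NOT converged)"))
  invisible(x)
}
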