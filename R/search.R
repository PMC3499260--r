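#' Search configuration
#'
#' @param m_top_pairs number of worst-residual population pairs examined
#'   when proposing migration edges.
#' @param n_neighborhood tip neighborhood radius, in tree edges, around
#'   each member of a worst-residual pair.
#' @param n_migration number of migration edges to add.
#' @param seed integer seed driving the random starting triple and
#'   insertion order (NULL: use the current RNG state).
#' @param global_rearrangements attempt nearest-neighbor interchanges at
#'   all internal nodes after each migration edge is settled.
#' @param tol outer convergence tolerance on the composite log-likelihood.
#' @param weight_tol golden-section bracket tolerance for weights.
#' @param direction_tol flipping a migration edge's direction must improve
#'   the likelihood by more than this, else the current direction is kept
#'   (direction is a known error mode; near-ties are logged as ambiguous).
#' @param drift_weighting,se_floor see [predicted_covariance()],
#'   [composite_log_likelihood()].
#' @return a `search_config` list.
#' @export
search_config <- function(m_top_pairs = 10, n_neighborhood = 5,
                          n_migration = 0, seed = NULL,
                          global_rearrangements = TRUE,
                          tol = 1e-6, weight_tol = 1e-4,
                          direction_tol = 1e-6,
                          drift_weighting = "post", se_floor = 1e-12) {
  stopifnot(m_top_pairs >= 1, n_neighborhood >= 0, n_migration >= 0)
  structure(list(m_top_pairs = m_top_pairs,
                 n_neighborhood = n_neighborhood,
                 n_migration = n_migration, seed = seed,
                 global_rearrangements = global_rearrangements,
                 tol = tol, weight_tol = weight_tol,
                 direction_tol = direction_tol,
                 drift_weighting = drift_weighting, se_floor = se_floor),
            class = "search_config")
}

fit_with <- function(g, cov, config) {
  fit_graph(g, cov, tol = config$tol, weight_tol = config$weight_tol,
            drift_weighting = config$drift_weighting,
            se_floor = config$se_floor)
}

## light evaluation used inside the topology search: graph + loglik only
eval_light <- function(g, cov, config) {
  fit_core(g, cov, tol = config$tol, weight_tol = config$weight_tol,
           drift_weighting = config$drift_weighting,
           se_floor = config$se_floor)
}

## rooted triple ((x, y), z) over labels; z = trip[out]
triple_tree <- function(trip, out) {
  z <- trip[out]; xy <- trip[-out]
  nodes <- data.frame(id = 1:5,
                      label = c(NA, NA, xy[1], xy[2], z),
                      tip = c(FALSE, FALSE, TRUE, TRUE, TRUE))
  edges <- data.frame(from = c(1, 1, 2, 2), to = c(2, 5, 3, 4),
                      length = 0, weight = NA_real_, type = "tree")
  popgraph(nodes, edges)
}

## splice a new tip onto tree edge `edge_i` (row index in g$edges)
insert_tip <- function(g, edge_i, label) {
  u <- g$edges$from[edge_i]; v <- g$edges$to[edge_i]
  x <- max(g$nodes$id) + 1L
  t <- x + 1L
  g$nodes <- rbind(g$nodes,
                   data.frame(id = c(x, t), label = c(NA, label),
                              tip = c(FALSE, TRUE)))
  g$edges$to[edge_i] <- x   # u -> x
  g$edges <- rbind(g$edges,
                   data.frame(from = c(x, x), to = c(v, t),
                              length = 0, weight = NA_real_, type = "tree"))
  g
}

## tree children of a node
tree_children <- function(g, node) {
  te <- tree_edges(g)
  te$to[te$from == node]
}

## nearest-neighbor interchange alternatives across internal tree edge
## (u -> v): swap one child subtree of v with one sibling subtree under u.
nni_alternatives <- function(g, u, v) {
  kids <- tree_children(g, v)
  sibs <- setdiff(tree_children(g, u), v)
  out <- list()
  for (s in sibs) {
    for (a in kids) {
      g2 <- g
      g2$edges$from[g2$edges$to == a & g2$edges$type == "tree"] <- u
      g2$edges$from[g2$edges$to == s & g2$edges$type == "tree"] <- v
      out <- c(out, list(g2))
    }
  }
  out
}

## internal tree edges (u -> v with v internal), optionally restricted to
## edges incident to `nodes`
internal_tree_edges <- function(g, nodes = NULL) {
  te <- tree_edges(g)
  keep <- !g$nodes$tip[match(te$to, g$nodes$id)]
  if (!is.null(nodes)) keep <- keep & (te$from %in% nodes | te$to %in% nodes)
  te[keep, c("from", "to"), drop = FALSE]
}

## one pass of NNI moves on a light fit, accepting strict likelihood
## improvements; returns list(fit, improved). Validation is skipped for
## pure trees (NNI preserves tree-ness); with migration edges present a
## move can create a cycle or violate weights, so candidates are checked.
nni_pass <- function(fit, cov, config, around = NULL) {
  improved <- FALSE
  check <- nrow(migration_edges(fit$graph)) > 0
  repeat {
    edges <- internal_tree_edges(fit$graph, around)
    gained <- FALSE
    for (i in seq_len(nrow(edges))) {
      for (g2 in nni_alternatives(fit$graph, edges$from[i], edges$to[i])) {
        if (check && length(validate_popgraph(g2)) > 0) next
        f2 <- eval_light(g2, cov, config)
        if (f2$loglik > fit$loglik + 1e-9) {
          fit <- f2
          gained <- TRUE
          improved <- TRUE
          break
        }
      }
      if (gained) break
    }
    if (!gained) break
  }
  list(fit = fit, improved = improved)
}

#' Build the maximum-likelihood population tree
#'
#' Greedy stepwise addition: a random starting triple is fit under all
#' three rooted resolutions; remaining populations are added one by one in
#' random order, each tried on every branch and kept at the best position
#' by composite likelihood, followed by a round of nearest-neighbor
#' interchanges. The root is finally placed on the branch leading to the
#' declared outgroup (the likelihood itself is invariant to root placement
#' on a tree, so the root must come from prior information).
#'
#' @param cov a `cov_estimate` over at least 3 populations.
#' @param outgroup population name used to place the root.
#' @param config a [search_config()].
#' @return an `admix_fit` of the fitted tree.
#' @export
build_tree <- function(cov, outgroup, config = search_config()) {
  pops <- cov$populations
  if (length(pops) < 3) stop("need at least 3 populations")
  if (!outgroup %in% pops) stop("outgroup not among populations: ", outgroup)
  if (!is.null(config$seed)) set.seed(config$seed)
  ord <- sample(pops)
  sub <- subset_covariance(cov, pops[pops %in% ord[1:3]])
  best <- NULL
  for (out in 1:3) {
    g <- triple_tree(ord[1:3], out)
    f <- eval_light(g, sub, config)
    if (is.null(best) || f$loglik > best$loglik) best <- f
  }
  fit <- best
  for (t in ord[-(1:3)]) {
    tips_now <- names(graph_tips(fit$graph))
    sub <- subset_covariance(cov, pops[pops %in% c(tips_now, t)])
    te_idx <- which(fit$graph$edges$type == "tree")
    cand_best <- NULL
    for (e in te_idx) {
      g2 <- insert_tip(fit$graph, e, t)
      f2 <- eval_light(g2, sub, config)
      if (is.null(cand_best) || f2$loglik > cand_best$loglik) cand_best <- f2
    }
    fit <- nni_pass(cand_best, sub, config)$fit
  }
  g <- reroot_at_outgroup(fit$graph, outgroup)
  fit_with(g, cov, config)
}

## undirected tip neighborhood: tips within `n` tree edges of `tip_id`
tip_neighborhood <- function(g, tip_id, n) {
  te <- tree_edges(g)
  adj <- rbind(data.frame(a = te$from, b = te$to),
               data.frame(a = te$to, b = te$from))
  dist <- stats::setNames(rep(Inf, nrow(g$nodes)), g$nodes$id)
  dist[as.character(tip_id)] <- 0
  frontier <- tip_id
  d <- 0
  while (length(frontier) > 0 && d < n) {
    d <- d + 1
    nxt <- unique(adj$b[adj$a %in% frontier])
    nxt <- nxt[dist[as.character(nxt)] > d]
    dist[as.character(nxt)] <- d
    frontier <- nxt
  }
  tips <- graph_tips(g)
  tips[dist[as.character(tips)] <= n]
}

## node ids on the tree path from a tip to the root (tip first)
root_path_nodes <- function(g, tip_id) {
  par <- tree_parent(g)
  root <- graph_root(g)
  path <- tip_id
  node <- tip_id
  while (node != root) {
    node <- par[[as.character(node)]]
    path <- c(path, node)
  }
  path
}

#' Propose candidate migration edges from residuals
#'
#' Finds the `m_top_pairs` population pairs with the largest scaled
#' residuals, extends each member to its tip neighborhood (radius
#' `n_neighborhood` tree edges), and for each resulting pair enumerates
#' ordered node pairs, one from each tip's root path. A pair (source,
#' destination) is retained only if every residual between the tips
#' descending from the source and those descending from the destination is
#' positive, the destination is not the root, the descendant tip sets are
#' disjoint, and the edge would not create a cycle.
#'
#' @param fit an `admix_fit` (tree or graph).
#' @param config a [search_config()].
#' @return data.frame with columns `from`, `to` (node ids), possibly empty.
#' @export
propose_migration_edges <- function(fit, config = search_config()) {
  g <- fit$graph
  R <- fit$residuals
  pops <- rownames(R)
  P <- length(pops)
  ij <- which(upper.tri(R), arr.ind = TRUE)
  ord <- order(-R[ij], pops[ij[, 1]], pops[ij[, 2]])
  top <- ij[ord[seq_len(min(config$m_top_pairs, nrow(ij)))], , drop = FALSE]
  tips <- graph_tips(g)
  root <- graph_root(g)
  seen <- character(0)
  out <- data.frame(from = integer(), to = integer())
  for (r in seq_len(nrow(top))) {
    nb1 <- tip_neighborhood(g, tips[[pops[top[r, 1]]]], config$n_neighborhood)
    nb2 <- tip_neighborhood(g, tips[[pops[top[r, 2]]]], config$n_neighborhood)
    for (a in nb1) for (b in nb2) {
      if (a == b) next
      pa <- root_path_nodes(g, a)
      pb <- root_path_nodes(g, b)
      for (u in pa) for (v in pb) {
        if (u == v || v == root) next
        key <- paste(u, v)
        if (key %in% seen) next
        seen <- c(seen, key)
        du <- names(tips)[match(tips_below(g, u), tips)]
        dv <- names(tips)[match(tips_below(g, v), tips)]
        if (length(intersect(du, dv)) > 0) next
        if (any(R[du, dv] <= 0)) next
        if (has_directed_path(g, v, u)) next
        if (any(g$edges$from == u & g$edges$to == v)) next
        out <- rbind(out, data.frame(from = u, to = v))
      }
    }
  }
  unique(out)
}

## candidate endpoint moves and direction flips for migration edges
migration_moves <- function(g) {
  me_idx <- which(g$edges$type == "migration")
  moves <- list()
  for (i in me_idx) {
    u <- g$edges$from[i]; v <- g$edges$to[i]
    # move source / destination to a tree-adjacent node
    for (nu in c(tree_parent(g)[as.character(u)], tree_children(g, u))) {
      if (is.na(nu) || nu == v) next
      g2 <- g; g2$edges$from[i] <- as.integer(nu)
      moves <- c(moves, list(list(graph = g2, kind = "resource")))
    }
    for (nv in c(tree_parent(g)[as.character(v)], tree_children(g, v))) {
      if (is.na(nv) || nv == u) next
      g2 <- g; g2$edges$to[i] <- as.integer(nv)
      moves <- c(moves, list(list(graph = g2, kind = "redest")))
    }
    g2 <- g; g2$edges$from[i] <- v; g2$edges$to[i] <- u
    moves <- c(moves, list(list(graph = g2, kind = "flip", edge = i)))
  }
  moves
}

## valid graph and still a DAG with a unique root etc.
move_valid <- function(g) {
  length(validate_popgraph(g)) == 0
}

## enforce the convention that the tree edge into an admixed node carries
## the largest weight, swapping edge roles where a fitted migration weight
## exceeds one half
normalize_migration <- function(g) {
  me_idx <- which(g$edges$type == "migration")
  for (node in unique(g$edges$to[me_idx])) {
    inc <- which(g$edges$to == node & g$edges$type == "migration")
    if (length(inc) != 1) next
    w <- g$edges$weight[inc]
    if (is.na(w) || w <= 0.5) next
    ti <- which(g$edges$to == node & g$edges$type == "tree")
    g$edges$type[inc] <- "tree"
    g$edges$length[inc] <- g$edges$length[ti]
    g$edges$weight[inc] <- NA_real_
    g$edges$type[ti] <- "migration"
    g$edges$length[ti] <- 0
    g$edges$weight[ti] <- 1 - w
  }
  g
}

#' Add the best migration edge to a fitted graph
#'
#' Fits every candidate from [propose_migration_edges()], keeps the single
#' edge that most increases the composite likelihood, then greedily applies
#' local moves — nearest-neighbor interchanges at the new edge's source and
#' destination, moving the endpoints of every migration edge to adjacent
#' nodes, and flipping migration directions — accepting only likelihood
#' increases (direction flips must beat `direction_tol`). Finally attempts
#' interchanges at all internal nodes when `global_rearrangements` is set.
#'
#' @param fit an `admix_fit`.
#' @param config a [search_config()].
#' @return an `admix_fit`; unchanged (with attribute `"notice"`) when no
#'   candidate exists.
#' @export
add_best_migration <- function(fit, config = search_config()) {
  cov <- fit$cov
  cand <- propose_migration_edges(fit, config)
  if (nrow(cand) == 0) {
    attr(fit, "notice") <- "no admissible migration-edge candidates"
    return(fit)
  }
  best <- NULL
  for (r in seq_len(nrow(cand))) {
    g2 <- add_migration_edge(fit$graph, cand$from[r], cand$to[r], 0.05)
    f2 <- eval_light(g2, cov, config)
    if (is.null(best) || f2$loglik > best$loglik) best <- f2
  }
  fit <- best
  ambiguous <- integer(0)
  for (pass in 1:10) {
    gained <- FALSE
    me <- migration_edges(fit$graph)
    around <- unique(c(me$from, me$to))
    res <- nni_pass(fit, cov, config, around = around)
    if (res$improved) { fit <- res$fit; gained <- TRUE }
    for (mv in migration_moves(fit$graph)) {
      if (!move_valid(mv$graph)) next
      f2 <- eval_light(mv$graph, cov, config)
      gate <- if (mv$kind == "flip") config$direction_tol else 1e-9
      if (f2$loglik > fit$loglik + gate) {
        fit <- f2
        gained <- TRUE
      } else if (mv$kind == "flip" &&
                 abs(f2$loglik - fit$loglik) <= config$direction_tol) {
        ambiguous <- union(ambiguous, mv$edge)
      }
    }
    if (!gained) break
  }
  if (config$global_rearrangements) {
    fit <- nni_pass(fit, cov, config)$fit
  }
  g <- normalize_migration(fit$graph)
  out <- fit_with(g, cov, config)
  if (length(ambiguous) > 0) attr(out, "direction_ambiguous") <- ambiguous
  out
}

#' Infer an admixture graph from a covariance estimate
#'
#' The full search: build the maximum-likelihood tree, then add
#' `n_migration` migration edges one at a time, guided by residuals. A
#' per-round trace of the composite log-likelihood and variance explained
#' is attached as attribute `"trace"`.
#'
#' @param cov a `cov_estimate`.
#' @param outgroup population used to root the tree.
#' @param config a [search_config()].
#' @return the final `admix_fit`.
#' @export
infer_graph <- function(cov, outgroup, config = search_config()) {
  fit <- build_tree(cov, outgroup, config)
  trace <- data.frame(round = 0, loglik = fit$loglik,
                      variance_explained = fit$variance_explained)
  n_mig <- config$n_migration
  for (round in seq_len(n_mig)) {
    fit2 <- add_best_migration(fit, config)
    fit <- fit2
    trace <- rbind(trace, data.frame(round = round, loglik = fit$loglik,
                                     variance_explained = fit$variance_explained))
    if (!is.null(attr(fit, "notice"))) break
  }
  # the reported likelihood must equal a from-scratch refit of the graph
  fit <- fit_with(fit$graph, cov, config)
  attr(fit, "trace") <- trace
  fit
}
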