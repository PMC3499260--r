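# Independent oracles and fixture builders used across the test files.
# The oracles deliberately take different computational routes from the
# package implementation.

# Gaussian-recursion oracle for the model covariance: propagate the joint
# covariance of node frequencies in topological order. Post-mixture drift:
# x_k = sum_par w_par x_par + e_k with Var(e_k) = c_k (or c_k * sum w^2
# under the "squared" convention).
oracle_cov_recursion <- function(g, pops, drift_weighting = "post") {
  ids <- g$nodes$id
  n <- length(ids)
  ord <- admixgraph:::topo_order(g)
  te <- admixgraph:::tree_edges(g)
  me <- admixgraph:::migration_edges(g)
  S <- matrix(0, n, n, dimnames = list(ids, ids))
  root <- graph_root(g)
  for (node in ord) {
    if (node == root) next
    k <- as.character(node)
    ti <- which(te$to == node)
    mi <- which(me$to == node)
    par_ids <- c(te$from[ti], me$from[mi])
    ws <- c(1 - sum(me$weight[mi]), me$weight[mi])
    pk <- as.character(par_ids)
    for (j in ids) {
      if (j == node) next
      S[k, as.character(j)] <- sum(ws * S[pk, as.character(j)])
      S[as.character(j), k] <- S[k, as.character(j)]
    }
    own <- te$length[ti]
    if (drift_weighting == "squared" && length(mi) > 0) {
      own <- own * sum(ws^2)
    }
    S[k, k] <- drop(t(ws) %*% S[pk, pk, drop = FALSE] %*% ws) + own
  }
  tips <- graph_tips(g)[pops]
  V <- S[as.character(tips), as.character(tips)]
  dimnames(V) <- list(pops, pops)
  V
}

# scalar-loop oracle for the centered per-block covariance (no bias
# correction): explicit SNP-by-SNP cross products
oracle_centered_cov <- function(p_block) {
  P <- nrow(p_block)
  L <- ncol(p_block)
  W <- matrix(0, P, P)
  for (i in 1:P) for (j in 1:P) {
    acc <- 0
    for (l in 1:L) {
      pbar <- mean(p_block[, l])
      acc <- acc + (p_block[i, l] - pbar) * (p_block[j, l] - pbar)
    }
    W[i, j] <- acc / L
  }
  dimnames(W) <- list(rownames(p_block), rownames(p_block))
  W
}

# scalar-loop composite log-likelihood oracle
oracle_loglik <- function(W_hat, W_model, se) {
  P <- nrow(W_hat)
  acc <- 0
  for (i in 1:P) for (j in i:P) {
    acc <- acc + dnorm(W_hat[i, j], W_model[i, j], se[i, j], log = TRUE)
  }
  acc
}

# build a cov_estimate by hand (constant se, nominal blocks)
manual_cov <- function(W, se = 1e-4, K = 10, block_size = 100) {
  pops <- rownames(W)
  semat <- matrix(se, nrow(W), ncol(W), dimnames = dimnames(W))
  structure(list(W_hat = W, se = semat,
                 blocks = rep(list(W), K), K = K, block_size = block_size,
                 populations = pops),
            class = "cov_estimate")
}

# random rooted binary tree as a popgraph, small drift lengths
rand_tree <- function(ntips, max_c = 0.05) {
  phy <- ape::rtree(ntips, tip.label = paste0("p", seq_len(ntips)))
  phy$edge.length <- runif(nrow(phy$edge), 0, max_c)
  as_popgraph(phy)
}

# random admixture graph: random tree plus up to n_mig valid migration
# edges with weights below one half
rand_admix_graph <- function(ntips, n_mig = 2, max_c = 0.05) {
  g <- rand_tree(ntips, max_c)
  root <- graph_root(g)
  added <- 0
  guard <- 0
  while (added < n_mig && guard < 50) {
    guard <- guard + 1
    u <- sample(g$nodes$id, 1)
    v <- sample(setdiff(g$nodes$id, c(root, u)), 1)
    if (admixgraph:::has_directed_path(g, v, u)) next
    if (any(g$edges$from == u & g$edges$to == v)) next
    # keep total incoming weight below 1/2 at v
    cur <- sum(g$edges$weight[g$edges$to == v & g$edges$type == "migration"])
    w <- runif(1, 0.05, 0.45 - cur)
    if (w <= 0.05) next
    g <- add_migration_edge(g, u, v, w)
    added <- added + 1
  }
  g
}

# 4-tip example tree used in several places:
# ((p1,p2),(p3,p4)) with root->X=0.10, X->1=0.02, X->2=0.03,
#                        root->Y=0.05, Y->3=0.01, Y->4=0.04
example_tree4 <- function() {
  nodes <- data.frame(id = 1:7,
                      label = c("p1", "p2", "p3", "p4", NA, NA, NA),
                      tip = c(rep(TRUE, 4), rep(FALSE, 3)))
  edges <- data.frame(from = c(5, 5, 6, 6, 7, 7),
                      to = c(6, 7, 1, 2, 3, 4),
                      length = c(0.10, 0.05, 0.02, 0.03, 0.01, 0.04),
                      weight = NA_real_, type = "tree")
  popgraph(nodes, edges)
}

# admixed graph with an outgroup so the weight is identifiable:
# (o,((p1,p2),(p3,p4))); tip p3 draws ancestry w from the (p1,p2) ancestor
example_admixed_graph <- function(w = 0.25, c3 = 0.015, scale = 1) {
  nodes <- data.frame(id = 1:9,
                      label = c("p1", "p2", "p3", "p4", NA, NA, NA, NA, "o"),
                      tip = c(rep(TRUE, 4), rep(FALSE, 4), TRUE))
  edges <- data.frame(from = c(8, 8, 5, 5, 6, 6, 7, 7),
                      to = c(9, 5, 6, 7, 1, 2, 3, 4),
                      length = c(0.05, 0.02, 0.10, 0.05, 0.02, 0.03, c3,
                                 0.04) * scale,
                      weight = NA_real_, type = "tree")
  g <- popgraph(nodes, edges)
  add_migration_edge(g, 6L, 3L, w)
}
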