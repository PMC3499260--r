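#' Construct a population graph
#'
#' A population graph is a rooted directed acyclic graph in which nodes are
#' (ancestral or sampled) populations, tree edges carry a drift length
#' \eqn{c \ge 0}, and migration edges carry an admixture weight
#' \eqn{w \in (0,1)}. Every non-root node has exactly one incoming tree edge;
#' a node with additional incoming migration edges is admixed, and the tree
#' edge into it implicitly carries weight \eqn{1 - \sum w}. Migration edges
#' carry no drift of their own: all drift lives on tree edges, and the drift
#' on the tree edge into an admixed node is interpreted as post-mixture
#' drift.
#'
#' @param nodes data.frame with columns `id` (unique integer), `label`
#'   (population name for tips, `NA` for internal nodes), `tip` (logical).
#' @param edges data.frame with columns `from`, `to` (node ids), `length`
#'   (drift, tree edges; 0 for migration edges), `weight` (admixture weight,
#'   migration edges; `NA` for tree edges), `type` (`"tree"` or
#'   `"migration"`).
#' @param check validate the graph on construction.
#' @return An object of class `popgraph`.
#' @seealso [validate_popgraph()], [predicted_covariance()], [root_paths()]
#' @export
popgraph <- function(nodes, edges, check = TRUE) {
  nodes <- as.data.frame(nodes)
  edges <- as.data.frame(edges)
  stopifnot(all(c("id", "label", "tip") %in% names(nodes)))
  if (nrow(edges) == 0) {
    edges <- data.frame(from = integer(), to = integer(),
                        length = numeric(), weight = numeric(),
                        type = character())
  }
  stopifnot(all(c("from", "to", "length", "weight", "type") %in% names(edges)))
  nodes$id <- as.integer(nodes$id)
  edges$from <- as.integer(edges$from)
  edges$to <- as.integer(edges$to)
  rownames(nodes) <- NULL
  rownames(edges) <- NULL
  g <- structure(list(nodes = nodes, edges = edges), class = "popgraph")
  if (check) {
    v <- validate_popgraph(g)
    if (length(v) > 0) {
      stop("invalid popgraph: ", paste(vapply(v, `[[`, "", "message"),
                                       collapse = "; "))
    }
  }
  g
}

#' @export
print.popgraph <- function(x, ...) {
  nt <- sum(x$nodes$tip)
  nm <- sum(x$edges$type == "migration")
  cat(sprintf("popgraph: %d populations, %d nodes, %d migration edge(s)\n",
              nt, nrow(x$nodes), nm))
  cat("tips:", paste(sort(x$nodes$label[x$nodes$tip]), collapse = ", "), "\n")
  invisible(x)
}

tree_edges <- function(g) g$edges[g$edges$type == "tree", , drop = FALSE]
migration_edges <- function(g) g$edges[g$edges$type == "migration", , drop = FALSE]

#' Graph accessors
#'
#' `graph_root()` returns the id of the root node (no incoming tree edge);
#' `graph_tips()` returns tip node ids named by population label.
#'
#' @param g a `popgraph`.
#' @return node id(s).
#' @export
graph_root <- function(g) {
  te <- tree_edges(g)
  r <- setdiff(g$nodes$id, te$to)
  if (length(r) != 1) stop("graph does not have a unique root")
  r
}

#' @rdname graph_root
#' @export
graph_tips <- function(g) {
  ids <- g$nodes$id[g$nodes$tip]
  names(ids) <- g$nodes$label[g$nodes$tip]
  ids
}

## parent id by child id over tree edges (named integer vector)
tree_parent <- function(g) {
  te <- tree_edges(g)
  stats::setNames(te$from, te$to)
}

## incoming migration weight sum per node id
migration_in_weight <- function(g) {
  me <- migration_edges(g)
  w <- stats::setNames(rep(0, nrow(g$nodes)), g$nodes$id)
  if (nrow(me) > 0) {
    s <- tapply(me$weight, me$to, sum)
    w[names(s)] <- s
  }
  w
}

## Kahn topological order of node ids; NULL if cyclic
topo_order <- function(g) {
  ids <- g$nodes$id
  indeg <- stats::setNames(rep(0L, length(ids)), ids)
  tb <- table(factor(g$edges$to, levels = ids))
  indeg[names(tb)] <- as.integer(tb)
  out <- split(g$edges$to, factor(g$edges$from, levels = ids))
  queue <- ids[indeg == 0L]
  order <- integer(0)
  while (length(queue) > 0) {
    v <- queue[1]; queue <- queue[-1]
    order <- c(order, v)
    for (u in out[[as.character(v)]]) {
      key <- as.character(u)
      indeg[key] <- indeg[key] - 1L
      if (indeg[key] == 0L) queue <- c(queue, u)
    }
  }
  if (length(order) != length(ids)) return(NULL)
  order
}

#' Validate a population graph
#'
#' Checks the structural constraints of the model: unique root, one incoming
#' tree edge per non-root node, acyclicity (no population can contribute
#' genetic material to its own ancestor), reachability of every tip from the
#' root, migration weights in (0,1) summing to less than 1 at every node,
#' non-negative drift lengths, and the convention that the tree edge into an
#' admixed node carries the largest incoming weight.
#'
#' @param g a `popgraph`.
#' @return A list of violations (empty if the graph is valid); each element
#'   has fields `check` and `message`.
#' @export
validate_popgraph <- function(g) {
  v <- list()
  bad <- function(check, message) list(check = check, message = message)
  ids <- g$nodes$id
  if (anyDuplicated(ids)) {
    return(list(bad("ids", "duplicate node ids")))
  }
  if (!all(g$edges$from %in% ids) || !all(g$edges$to %in% ids)) {
    return(list(bad("ids", "edge endpoint not a node")))
  }
  labs <- g$nodes$label[g$nodes$tip]
  if (anyDuplicated(labs)) {
    v <- c(v, list(bad("labels", "duplicate tip labels")))
  }
  te <- tree_edges(g)
  if (anyDuplicated(te$to)) {
    v <- c(v, list(bad("tree", "node with more than one incoming tree edge")))
  }
  roots <- setdiff(ids, te$to)
  if (length(roots) != 1) {
    v <- c(v, list(bad("root", sprintf("%d root candidates", length(roots)))))
  }
  if (is.null(topo_order(g))) {
    v <- c(v, list(bad("acyclic",
      "graph contains a directed cycle (no population can contribute genetic material to its own ancestor)")))
    return(v)  # downstream checks assume a DAG
  }
  if (length(roots) == 1) {
    reach <- reachable_from(g, roots)
    un <- setdiff(graph_tips(g), reach)
    if (length(un) > 0) {
      v <- c(v, list(bad("reachable", paste("tips unreachable from root:",
        paste(g$nodes$label[match(un, g$nodes$id)], collapse = ",")))))
    }
  }
  if (any(te$length < 0, na.rm = TRUE)) {
    v <- c(v, list(bad("length", "negative drift length")))
  }
  me <- migration_edges(g)
  if (nrow(me) > 0) {
    if (any(me$weight <= 0 | me$weight >= 1)) {
      v <- c(v, list(bad("weight", "migration weight outside (0,1)")))
    }
    s <- tapply(me$weight, me$to, sum)
    over <- s[s >= 1]
    if (length(over) > 0) {
      v <- c(v, list(bad("weight-sum",
        sprintf("incoming migration weights sum to >= 1 at node(s) %s",
                paste(names(over), collapse = ",")))))
    }
    # tree edge must carry the largest incoming weight
    for (node in unique(me$to)) {
      ws <- me$weight[me$to == node]
      tree_w <- 1 - sum(ws)
      if (any(ws > tree_w + 1e-12)) {
        v <- c(v, list(bad("weight-order",
          sprintf("migration weight exceeds tree-edge weight at node %s", node))))
      }
    }
  }
  v
}

reachable_from <- function(g, start, tree_only = FALSE) {
  edges <- if (tree_only) tree_edges(g) else g$edges
  out <- split(edges$to, factor(edges$from, levels = g$nodes$id))
  seen <- start
  queue <- start
  while (length(queue) > 0) {
    v <- queue[1]; queue <- queue[-1]
    nb <- setdiff(out[[as.character(v)]], seen)
    seen <- c(seen, nb)
    queue <- c(queue, nb)
  }
  seen
}

## is there a directed path from a to b?
has_directed_path <- function(g, a, b) b %in% reachable_from(g, a)

## tip ids in the tree clade below node id (inclusive if tip); migration
## edges do not define clade membership
tips_below <- function(g, node) {
  r <- reachable_from(g, node, tree_only = TRUE)
  intersect(r, graph_tips(g))
}

#' Enumerate root-to-tip paths
#'
#' Every directed path from the root to `tip`, with its mixture weight: the
#' product over traversed edges of the edge's weight (migration edges carry
#' their weight \eqn{w}; the tree edge into an admixed node carries
#' \eqn{1-\sum w}; all other tree edges carry 1). Weights over all paths to a
#' tip sum to 1.
#'
#' @param g a `popgraph`.
#' @param tip a tip node id or population label.
#' @return A list with one element per path; each element has `nodes` (node
#'   id sequence from root to tip) and `weight`.
#' @export
root_paths <- function(g, tip) {
  if (is.character(tip)) {
    tip <- graph_tips(g)[tip]
    if (is.na(tip)) stop("unknown population label")
  }
  root <- graph_root(g)
  if (!has_directed_path(g, root, tip)) {
    stop("tip is not reachable from the root")
  }
  mig_w <- migration_in_weight(g)
  # walk backwards from tip
  walk <- function(node) {
    if (node == root) return(list(list(nodes = root, weight = 1)))
    inc <- g$edges[g$edges$to == node, , drop = FALSE]
    res <- list()
    for (i in seq_len(nrow(inc))) {
      ew <- if (inc$type[i] == "migration") inc$weight[i]
            else 1 - unname(mig_w[as.character(node)])
      for (p in walk(inc$from[i])) {
        res <- c(res, list(list(nodes = c(p$nodes, node),
                                weight = p$weight * ew)))
      }
    }
    res
  }
  walk(tip)
}

## P x N matrix: U[i, k] = total weight of root->tip_i paths through node k.
## Under the post-mixture drift convention the coefficient of the drift c_k
## (on the tree edge into node k) in V[i, j] is U[i,k] * U[j,k].
##
## Because mixture weights into every node sum to 1, the total weight of
## root->k segments is 1, so U[i,k] reduces to the total choice weight of
## descending k->tip_i paths: a single backward sweep per tip instead of
## exponential path enumeration.
path_node_weights <- function(g, pops = NULL) {
  tips <- graph_tips(g)
  if (!is.null(pops)) tips <- tips[pops]
  ids <- g$nodes$id
  n <- length(ids)
  mig_w <- migration_in_weight(g)
  ew <- ifelse(g$edges$type == "migration", g$edges$weight,
               1 - mig_w[as.character(g$edges$to)])
  efrom <- match(g$edges$from, ids)
  eto <- match(g$edges$to, ids)
  # process edges so that an edge's head is final before its tail is touched
  topo_pos <- match(ids, topo_order(g))
  eord <- order(topo_pos[eto], decreasing = TRUE)
  U <- matrix(0, nrow = length(tips), ncol = n,
              dimnames = list(names(tips), ids))
  tip_idx <- match(tips, ids)
  for (i in seq_along(tips)) {
    b <- numeric(n)
    b[tip_idx[i]] <- 1
    for (e in eord) {
      b[efrom[e]] <- b[efrom[e]] + ew[e] * b[eto[e]]
    }
    U[i, ] <- b
  }
  U
}

#' Model covariance implied by a population graph
#'
#' Computes the variance-covariance matrix \eqn{V} of tip allele frequencies
#' relative to the root, under the Gaussian drift model: \eqn{V_{ij}} is the
#' sum over pairs of root-to-tip paths (one to each tip) of the product of
#' the two path weights times the drift shared by the two paths. The drift
#' on the tree edge into an admixed node enters its descendants with
#' coefficient 1 (post-mixture drift); set `drift_weighting = "squared"` for
#' the alternative \eqn{\sum w^2} convention. The centered matrix is
#' \eqn{W = C V C'} with \eqn{C = I - \mathbf{1}\mathbf{1}'/P}, the model
#' analogue of the centered sample covariance.
#'
#' @param g a `popgraph`.
#' @param pops population order for the rows/columns (default: sorted tip
#'   labels).
#' @param drift_weighting weighting of the drift parameter on the tree edge
#'   into an admixed node: `"post"` (coefficient 1) or `"squared"`
#'   (coefficient \eqn{\sum_k w_k^2} over incoming weights).
#' @return list with elements `V`, `W` (P x P matrices) and `populations`.
#' @export
predicted_covariance <- function(g, pops = NULL,
                                 drift_weighting = c("post", "squared")) {
  drift_weighting <- match.arg(drift_weighting)
  if (is.null(pops)) pops <- sort(names(graph_tips(g)))
  U <- node_weight_matrix(g, pops)
  P <- length(pops)
  V <- matrix(0, P, P, dimnames = list(pops, pops))
  te <- tree_edges(g)
  scl <- drift_scale(g, drift_weighting)
  for (i in seq_len(nrow(te))) {
    k <- as.character(te$to[i])
    u <- U[, k]
    V <- V + te$length[i] * scl[k] * tcrossprod(u)
  }
  W <- center_matrix(V)
  list(V = V, W = W, populations = pops)
}

## per-node multiplier on the incoming drift length
drift_scale <- function(g, drift_weighting) {
  ids <- as.character(g$nodes$id)
  scl <- stats::setNames(rep(1, length(ids)), ids)
  if (drift_weighting == "squared") {
    me <- migration_edges(g)
    for (node in unique(me$to)) {
      ws <- me$weight[me$to == node]
      scl[as.character(node)] <- sum(ws^2) + (1 - sum(ws))^2
    }
  }
  scl
}

## W = C M C' with C = I - 11'/P
center_matrix <- function(M) {
  rm <- rowMeans(M)
  M - outer(rm, rep(1, ncol(M))) - outer(rep(1, nrow(M)), colMeans(M)) +
    mean(M)
}

#' Add a migration edge
#'
#' @param g a `popgraph`.
#' @param from,to node ids (or tip labels) for source and destination.
#' @param weight admixture weight in (0,1).
#' @return the modified graph.
#' @export
add_migration_edge <- function(g, from, to, weight) {
  from <- resolve_node(g, from)
  to <- resolve_node(g, to)
  if (to == graph_root(g)) stop("migration into the root is not allowed")
  if (from == to) stop("self migration")
  if (has_directed_path(g, to, from)) {
    stop("migration edge would create a cycle")
  }
  g$edges <- rbind(g$edges, data.frame(from = from, to = to, length = 0,
                                       weight = weight, type = "migration"))
  g
}

resolve_node <- function(g, x) {
  if (is.character(x)) {
    id <- graph_tips(g)[x]
    if (is.na(id)) stop("unknown population label: ", x)
    return(as.integer(id))
  }
  as.integer(x)
}

## set all tree-edge lengths from a vector named by child node id
set_lengths <- function(g, lengths) {
  i <- g$edges$type == "tree"
  g$edges$length[i] <- unname(lengths[as.character(g$edges$to[i])])
  g
}
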