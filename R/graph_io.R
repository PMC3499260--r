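#' Convert the tree backbone of a population graph to an ape "phylo"
#'
#' Migration edges are dropped; the spanning tree of tree edges is returned
#' with its drift lengths as branch lengths.
#'
#' @param g a `popgraph`.
#' @return an object of class `phylo`.
#' @export
as_phylo <- function(g) {
  te <- tree_edges(g)
  tips <- graph_tips(g)
  internal <- setdiff(g$nodes$id, tips)
  root <- graph_root(g)
  internal <- c(root, setdiff(internal, root))  # ape wants root first
  P <- length(tips)
  idx <- stats::setNames(seq_len(P + length(internal)), c(tips, internal))
  edge <- cbind(idx[as.character(te$from)], idx[as.character(te$to)])
  dimnames(edge) <- NULL
  phy <- list(edge = edge, tip.label = names(tips),
              edge.length = te$length, Nnode = length(internal))
  class(phy) <- "phylo"
  ape::reorder.phylo(phy, "cladewise")
}

#' Convert an ape "phylo" to a population graph
#'
#' @param phy a rooted `phylo` object with branch lengths (missing lengths
#'   become 0).
#' @return a `popgraph` with tree edges only.
#' @export
as_popgraph <- function(phy) {
  if (!ape::is.rooted(phy)) stop("tree must be rooted")
  P <- length(phy$tip.label)
  n <- P + phy$Nnode
  nodes <- data.frame(id = seq_len(n),
                      label = c(phy$tip.label, rep(NA, phy$Nnode)),
                      tip = c(rep(TRUE, P), rep(FALSE, phy$Nnode)))
  len <- if (is.null(phy$edge.length)) rep(0, nrow(phy$edge)) else phy$edge.length
  len[is.na(len)] <- 0
  len[len < 0] <- 0
  edges <- data.frame(from = phy$edge[, 1], to = phy$edge[, 2],
                      length = len, weight = NA_real_, type = "tree")
  popgraph(nodes, edges)
}

#' Re-root the tree backbone at an outgroup
#'
#' Places the root on the pendant branch leading to `outgroup`, the standard
#' practice of fixing the root with prior information about a known
#' outgroup. Only valid for graphs without migration edges; branch lengths
#' should be refit afterwards (the two root-adjacent lengths are not
#' separately identifiable).
#'
#' @param g a `popgraph` with tree edges only.
#' @param outgroup tip label.
#' @return the re-rooted `popgraph`.
#' @export
reroot_at_outgroup <- function(g, outgroup) {
  if (nrow(migration_edges(g)) > 0) {
    stop("re-rooting is only supported before migration edges are added")
  }
  if (!outgroup %in% names(graph_tips(g))) {
    stop("unknown outgroup: ", outgroup)
  }
  phy <- as_phylo(g)
  phy <- ape::root(ape::unroot(phy), outgroup = outgroup,
                   resolve.root = TRUE)
  as_popgraph(phy)
}

#' Are two graphs' tree backbones the same unrooted topology?
#'
#' @param g1,g2 `popgraph` or `phylo` objects over the same tip set.
#' @return logical.
#' @export
same_topology <- function(g1, g2) {
  p1 <- if (inherits(g1, "popgraph")) as_phylo(g1) else g1
  p2 <- if (inherits(g2, "popgraph")) as_phylo(g2) else g2
  if (!setequal(p1$tip.label, p2$tip.label)) return(FALSE)
  u1 <- ape::unroot(p1)
  u2 <- ape::unroot(p2)
  as.numeric(ape::dist.topo(u1, u2, method = "PH85")) == 0
}

#' Write and read a population graph as vertices/edges tables
#'
#' `write_popgraph()` writes `<stem>.vertices` (id, type, label) and
#' `<stem>.edges` (from, to, length, weight, type), tab-delimited.
#' `read_popgraph()` reads them back.
#'
#' @param g a `popgraph`.
#' @param stem output path stem.
#' @return `write_popgraph()` returns the two paths invisibly;
#'   `read_popgraph()` returns a `popgraph`.
#' @export
write_popgraph <- function(g, stem) {
  root <- graph_root(g)
  vt <- data.frame(id = g$nodes$id,
                   type = ifelse(g$nodes$id == root, "root",
                                 ifelse(g$nodes$tip, "tip", "internal")),
                   label = ifelse(is.na(g$nodes$label), "-", g$nodes$label))
  vf <- paste0(stem, ".vertices")
  ef <- paste0(stem, ".edges")
  utils::write.table(vt, vf, sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(g$edges, ef, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(c(vf, ef))
}

#' @rdname write_popgraph
#' @export
read_popgraph <- function(stem) {
  vt <- utils::read.table(paste0(stem, ".vertices"), sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE)
  ed <- utils::read.table(paste0(stem, ".edges"), sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE)
  nodes <- data.frame(id = vt$id,
                      label = ifelse(vt$label == "-", NA, vt$label),
                      tip = vt$type == "tip")
  popgraph(nodes, ed)
}

#' Extended Newick serialization of a population graph
#'
#' Writes the tree backbone in Newick format followed by one auxiliary line
#' per migration edge giving its weight and the tip sets descending from the
#' source and destination nodes.
#'
#' @param g a `popgraph`.
#' @return character vector of lines.
#' @export
graph_newick <- function(g) {
  lines <- ape::write.tree(as_phylo(g))
  me <- migration_edges(g)
  for (i in seq_len(nrow(me))) {
    src <- tips_below(g, me$from[i])
    dst <- tips_below(g, me$to[i])
    lab <- function(ids) paste(sort(g$nodes$label[match(ids, g$nodes$id)]),
                               collapse = ",")
    lines <- c(lines, sprintf("migration\t%.6g\t%s\t%s",
                              me$weight[i], lab(src), lab(dst)))
  }
  lines
}
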