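#' Serial-divergence (ladder) population graph
#'
#' Builds the caterpillar topology of a serial founding model: an ancestral
#' lineage from which populations bud off one at a time at equal drift
#' intervals, every tip equidistant from the root (total depth
#' \eqn{(P-1)\,c_{step}}). Tips are labeled `pop1` (first to split, the
#' natural outgroup) through `popP`. Optionally one admixture event is
#' added as a migration edge between two tips.
#'
#' @param P number of populations (>= 2).
#' @param c_step drift per inter-split interval. The default 0.005
#'   corresponds to roughly 100 generations between splits at effective
#'   size 10,000 (\eqn{c \approx t/2N}).
#' @param admixture optional `list(source =, dest =, w =)` with tip indices
#'   (or labels) and a weight in (0, 0.5].
#' @return a `popgraph`.
#' @export
serial_divergence_graph <- function(P, c_step = 0.005, admixture = NULL) {
  stopifnot(P >= 2, c_step >= 0)
  # ids: tips 1..P; trunk internals P+1 (root) .. 2P-1
  tips <- data.frame(id = seq_len(P), label = paste0("pop", seq_len(P)),
                     tip = TRUE)
  n_int <- P - 1
  ints <- data.frame(id = P + seq_len(n_int), label = NA, tip = FALSE)
  edges <- data.frame(from = integer(), to = integer(), length = numeric(),
                      weight = numeric(), type = character())
  for (i in seq_len(n_int)) {
    a <- P + i
    # tip i hangs off trunk node a with terminal length (P - i) * c_step
    edges <- rbind(edges, data.frame(from = a, to = i,
                                     length = (P - i) * c_step,
                                     weight = NA_real_, type = "tree"))
    if (i < n_int) {
      edges <- rbind(edges, data.frame(from = a, to = a + 1, length = c_step,
                                       weight = NA_real_, type = "tree"))
    } else {
      edges <- rbind(edges, data.frame(from = a, to = P, length = c_step,
                                       weight = NA_real_, type = "tree"))
    }
  }
  g <- popgraph(rbind(tips, ints), edges)
  if (!is.null(admixture)) {
    src <- admixture$source
    dst <- admixture$dest
    if (is.numeric(src)) src <- paste0("pop", src)
    if (is.numeric(dst)) dst <- paste0("pop", dst)
    g <- add_migration_edge(g, src, dst, admixture$w)
  }
  g
}

#' Simulate true population allele frequencies under Gaussian drift
#'
#' Per SNP: draws an ancestral frequency \eqn{p} from
#' `Uniform(ancestral[1], ancestral[2])`, then traverses the graph in
#' topological order; each node's frequency is the (weight-mixed, at
#' admixed nodes) parental frequency plus Gaussian drift
#' \eqn{N(0,\, c\, p(1-p))} for its incoming tree edge, truncated to
#' \eqn{[0,1]}. Scaling every branch's drift by the root-SNP
#' \eqn{p(1-p)} is the small-drift approximation the model itself rests
#' on. The fraction of truncated draws is reported as attribute
#' `"truncated"`.
#'
#' With `ld_factor = r > 1`, only every r-th SNP is simulated afresh; the
#' following r-1 SNPs copy its population frequencies with a small Gaussian
#' jitter (`ld_jitter`), emulating blocks of linked SNPs so that
#' block-resampling behavior under dependence can be exercised. Default is
#' independent SNPs.
#'
#' @param graph a `popgraph` with true drift lengths and weights.
#' @param n_snps number of SNPs L.
#' @param ancestral range of the uniform ancestral frequency distribution.
#' @param seed optional integer seed.
#' @param ld_factor SNPs per linked group (1 = independent).
#' @param ld_jitter frequency jitter between linked copies.
#' @return P x L matrix of true frequencies, rows named by population, with
#'   attribute `"truncated"` (fraction of drift draws truncated).
#' @export
simulate_frequencies <- function(graph, n_snps, ancestral = c(0.05, 0.95),
                                 seed = NULL, ld_factor = 1,
                                 ld_jitter = 0.01) {
  stopifnot(n_snps >= 1, ld_factor >= 1)
  if (!is.null(seed)) set.seed(seed)
  L0 <- ceiling(n_snps / ld_factor)
  p0 <- stats::runif(L0, ancestral[1], ancestral[2])
  ord <- topo_order(graph)
  root <- graph_root(graph)
  mig_w <- migration_in_weight(graph)
  te <- tree_edges(graph)
  me <- migration_edges(graph)
  x <- matrix(0, nrow(graph$nodes), L0,
              dimnames = list(graph$nodes$id, NULL))
  n_trunc <- 0; n_draw <- 0
  sp <- sqrt(p0 * (1 - p0))
  for (node in ord) {
    key <- as.character(node)
    if (node == root) {
      x[key, ] <- p0
      next
    }
    ti <- which(te$to == node)
    base <- (1 - mig_w[key]) * x[as.character(te$from[ti]), ]
    mi <- which(me$to == node)
    for (j in mi) {
      base <- base + me$weight[j] * x[as.character(me$from[j]), ]
    }
    if (mig_w[key] == 0) base <- x[as.character(te$from[ti]), ]
    drift <- stats::rnorm(L0, 0, sqrt(te$length[ti]) * sp)
    xi <- base + drift
    n_draw <- n_draw + L0
    n_trunc <- n_trunc + sum(xi < 0 | xi > 1)
    x[key, ] <- pmin(pmax(xi, 0), 1)
  }
  tips <- graph_tips(graph)
  out <- x[as.character(tips), , drop = FALSE]
  rownames(out) <- names(tips)
  if (ld_factor > 1) {
    idx <- rep(seq_len(L0), each = ld_factor)[seq_len(n_snps)]
    out <- out[, idx, drop = FALSE]
    jit <- matrix(stats::rnorm(length(out), 0, ld_jitter), nrow(out))
    # first copy of each group stays exact
    first <- !duplicated(idx)
    jit[, first] <- 0
    out <- pmin(pmax(out + jit, 0), 1)
  }
  attr(out, "truncated") <- n_trunc / max(n_draw, 1)
  out
}

#' Binomial sampling of allele counts from true frequencies
#'
#' Per SNP and population, the allele-A count is
#' \eqn{\mathrm{Binomial}(n, p)} over the sampled chromosomes.
#'
#' @param freqs P x L matrix of true frequencies (rows named by
#'   population), as from [simulate_frequencies()].
#' @param n chromosomes sampled per population (scalar or per-population
#'   named vector).
#' @param seed optional integer seed.
#' @return an `allele_panel`.
#' @export
sample_counts <- function(freqs, n, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  P <- nrow(freqs); L <- ncol(freqs)
  if (length(n) == 1) n <- stats::setNames(rep(n, P), rownames(freqs))
  n <- n[rownames(freqs)]
  stopifnot(all(n >= 1))
  a <- matrix(0L, L, P, dimnames = list(NULL, rownames(freqs)))
  for (i in seq_len(P)) {
    a[, i] <- stats::rbinom(L, n[i], freqs[i, ])
  }
  b <- sweep(-a, 2, n, `+`)
  allele_panel(rownames(freqs), a, b)
}

#' Simulate a complete allele-count panel from a graph
#'
#' Convenience wrapper: [simulate_frequencies()] then [sample_counts()].
#'
#' @inheritParams simulate_frequencies
#' @param n_chrom chromosomes per population.
#' @return an `allele_panel` with attribute `"truncated"`.
#' @export
simulate_panel <- function(graph, n_snps, n_chrom, seed = NULL,
                           ancestral = c(0.05, 0.95), ld_factor = 1,
                           ld_jitter = 0.01) {
  if (!is.null(seed)) set.seed(seed)
  fr <- simulate_frequencies(graph, n_snps, ancestral,
                             ld_factor = ld_factor, ld_jitter = ld_jitter)
  panel <- sample_counts(fr, n_chrom)
  attr(panel, "truncated") <- attr(fr, "truncated")
  panel
}

#' Ascertain SNPs polymorphic in a reference population
#'
#' Retains SNPs whose sample frequency in the reference population is
#' strictly between 0 and 1, emulating SNP discovery in a reference panel.
#'
#' @param panel an `allele_panel`.
#' @param reference_pop population name.
#' @return the filtered `allele_panel`.
#' @export
ascertain <- function(panel, reference_pop) {
  i <- match(reference_pop, panel$populations)
  if (is.na(i)) stop("unknown reference population: ", reference_pop)
  a <- panel$countA[, i]
  n <- a + panel$countB[, i]
  keep <- n > 0 & a > 0 & a < n
  if (!any(keep)) stop("no SNP is polymorphic in ", reference_pop)
  subset_panel(panel, keep)
}
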