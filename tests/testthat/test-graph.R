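test_that("root paths enumerate mixture routes with product weights", {
  g <- example_tree4()
  for (tip in c("p1", "p2", "p3", "p4")) {
    paths <- root_paths(g, tip)
    expect_length(paths, 1)
    expect_equal(paths[[1]]$weight, 1)
  }
  ga <- example_admixed_graph(w = 0.25)
  paths <- root_paths(ga, "p3")
  expect_length(paths, 2)
  expect_setequal(vapply(paths, `[[`, 0, "weight"), c(0.25, 0.75))
  expect_equal(sum(vapply(paths, `[[`, 0, "weight")), 1)
})

test_that("two stacked admixture events give four product-weight paths", {
  # lineage root -> A -> z passing two admixture events, (0.3, 0.7) into A
  # and (0.4, 0.6) into z, the second sourced below the first so every
  # path chooses at both events: products {0.12, 0.18, 0.28, 0.42}
  nodes <- data.frame(id = 1:5,
                      label = c("x", "z", "c", NA, NA),
                      tip = c(TRUE, TRUE, TRUE, FALSE, FALSE))
  edges <- data.frame(
    from = c(4, 4, 5, 5), to = c(1, 5, 2, 3),
    length = 0.01, weight = NA_real_, type = "tree")
  g <- popgraph(nodes, edges)   # root 4; A = 5; c hangs off A
  g <- add_migration_edge(g, 1L, 5L, 0.3)   # weights into A: 0.3 / 0.7
  g <- add_migration_edge(g, 3L, 2L, 0.4)   # weights into z: 0.4 / 0.6
  paths <- root_paths(g, "z")
  expect_length(paths, 4)
  expect_setequal(round(vapply(paths, `[[`, 0, "weight"), 10),
                  c(0.12, 0.18, 0.28, 0.42))
  expect_equal(sum(vapply(paths, `[[`, 0, "weight")), 1)
})

test_that("tree covariance equals shared root-path drift", {
  g <- example_tree4()
  V <- predicted_covariance(g, c("p1", "p2", "p3", "p4"))$V
  expected <- matrix(c(0.12, 0.10, 0, 0,
                       0.10, 0.13, 0, 0,
                       0, 0, 0.06, 0.05,
                       0, 0, 0.05, 0.09), 4, 4,
                     dimnames = list(paste0("p", 1:4), paste0("p", 1:4)))
  expect_equal(V, expected, tolerance = 1e-14)
  # all-zero drift gives the zero matrix
  g0 <- g; g0$edges$length <- 0
  expect_equal(max(abs(predicted_covariance(g0)$V)), 0)
})

test_that("admixed-tip variance follows the mixture expansion term by term", {
  w <- 0.25; c3 <- 0.015
  g <- example_admixed_graph(w, c3)
  pops <- c("o", "p1", "p2", "p3", "p4")
  V <- predicted_covariance(g, pops)$V
  Vfull <- oracle_cov_recursion(g, pops)
  # parents of p3: node 6 (weight w) and node 7 (weight 1-w)
  g1g1 <- 0.02 + 0.10   # V[node6, node6]
  g2g2 <- 0.02 + 0.05   # V[node7, node7]
  g1g2 <- 0.02          # shared root path of the two parents
  expect_equal(V["p3", "p3"],
               w^2 * g1g1 + (1 - w)^2 * g2g2 + 2 * w * (1 - w) * g1g2 + c3,
               tolerance = 1e-14)
  expect_equal(V, Vfull, tolerance = 1e-14)
  # cross terms: cov(p3, p1) mixes the parental covariances
  expect_equal(V["p3", "p1"], 0.02 + w * 0.10, tolerance = 1e-14)
})

test_that("path-weight covariance equals the Gaussian recursion oracle on random graphs", {
  set.seed(101)
  for (i in 1:60) {
    ntips <- sample(3:6, 1)
    g <- rand_admix_graph(ntips, n_mig = sample(0:2, 1))
    pops <- sort(names(graph_tips(g)))
    for (dw in c("post", "squared")) {
      V <- predicted_covariance(g, pops, drift_weighting = dw)$V
      Vo <- oracle_cov_recursion(g, pops, drift_weighting = dw)
      expect_lt(max(abs(V - Vo)), 1e-12)
    }
  }
})

test_that("centered model covariance rows sum to zero and V is PSD", {
  set.seed(102)
  for (i in 1:10) {
    g <- rand_admix_graph(5, n_mig = 1)
    mc <- predicted_covariance(g)
    expect_lt(max(abs(rowSums(mc$W))), 1e-12)
    expect_gt(min(eigen(mc$V, symmetric = TRUE)$values), -1e-12)
  }
})

test_that("simulated frequencies agree with the model covariance", {
  set.seed(103)
  g <- example_admixed_graph(w = 0.4)
  L <- 100000
  fr <- simulate_frequencies(g, L, ancestral = c(0.5, 0.5), seed = 104)
  emp <- cov(t(fr)) * (L - 1) / L
  # frequencies relative to the fixed root value 0.5: scale is p0(1-p0)
  V <- predicted_covariance(g, rownames(fr))$V * 0.25
  # Gaussian sampling error of a covariance entry
  se <- sqrt((outer(diag(V), diag(V)) + V^2) / L)
  expect_true(all(abs(emp - V) <= 4 * se + 1e-6))
})

test_that("validation reports cycles, weight violations and reachability", {
  g <- example_tree4()
  expect_length(validate_popgraph(g), 0)

  # directed cycle through migration
  gc <- g
  gc$edges <- rbind(gc$edges,
                    data.frame(from = 1, to = 6, length = 0,
                               weight = 0.2, type = "migration"),
                    data.frame(from = 6, to = 1, length = 0,
                               weight = 0.2, type = "migration"))
  v <- validate_popgraph(gc)
  expect_true("acyclic" %in% vapply(v, `[[`, "", "check"))

  # incoming weights 0.6 + 0.5 exceed 1
  gw <- g
  gw$edges <- rbind(gw$edges,
                    data.frame(from = c(2, 4), to = c(3, 3), length = 0,
                               weight = c(0.6, 0.5), type = "migration"))
  v <- validate_popgraph(gw)
  expect_true("weight-sum" %in% vapply(v, `[[`, "", "check"))

  # migration weight above the tree edge's implied weight
  gm <- g
  gm$edges <- rbind(gm$edges,
                    data.frame(from = 2, to = 3, length = 0,
                               weight = 0.7, type = "migration"))
  v <- validate_popgraph(gm)
  expect_true("weight-order" %in% vapply(v, `[[`, "", "check"))

  # unreachable tip: orphan node with its own tree edge from nowhere
  gu <- g
  gu$nodes <- rbind(gu$nodes, data.frame(id = 8:9, label = c(NA, "p5"),
                                         tip = c(FALSE, TRUE)))
  gu$edges <- rbind(gu$edges, data.frame(from = 8, to = 9, length = 0.1,
                                         weight = NA_real_, type = "tree"))
  v <- validate_popgraph(gu)
  expect_true(any(grepl("root", vapply(v, `[[`, "", "check")) |
                  grepl("reachable", vapply(v, `[[`, "", "check"))))

  expect_error(add_migration_edge(g, 1L, 6L, 0.2), "cycle")
})

test_that("graph serialization round-trips and Newick output parses", {
  set.seed(105)
  g <- example_admixed_graph(0.3)
  stem <- withr::local_tempfile()
  write_popgraph(g, stem)
  g2 <- read_popgraph(stem)
  expect_equal(g2$edges, g$edges)
  expect_setequal(names(graph_tips(g2)), names(graph_tips(g)))
  nwk <- graph_newick(g)
  phy <- ape::read.tree(text = nwk[1])
  expect_s3_class(phy, "phylo")
  expect_setequal(phy$tip.label, c("o", "p1", "p2", "p3", "p4"))
  expect_length(nwk, 2)              # one auxiliary migration line
  expect_match(nwk[2], "^migration\t0\\.3")
})

test_that("phylo conversion and re-rooting preserve unrooted topology", {
  set.seed(106)
  g <- rand_tree(6)
  phy <- as_phylo(g)
  expect_equal(sort(phy$tip.label), sort(names(graph_tips(g))))
  g2 <- as_popgraph(phy)
  expect_true(same_topology(g, g2))
  g3 <- reroot_at_outgroup(g, "p3")
  expect_true(same_topology(g, g3))
  # outgroup is now a child of the root
  root_kids <- admixgraph:::tree_children(g3, graph_root(g3))
  expect_true(graph_tips(g3)[["p3"]] %in% root_kids)
})
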