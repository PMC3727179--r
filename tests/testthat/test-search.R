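# z-scoring, activity, mutual information, greedy expansion, permutation
# filtering.

test_that("z-scoring standardizes every non-constant row exactly", {
  withr::local_seed(1)
  m <- matrix(rnorm(200, mean = 3, sd = 7), 20, 10,
              dimnames = list(paste0("g", 1:20), paste0("s", 1:10)))
  ds <- expression_dataset(m, rep(c("case", "control"), 5))
  z <- zscore_normalize(ds)
  expect_true(all(abs(rowMeans(z$values)) < 1e-12))
  expect_true(all(abs(apply(z$values, 1, sd) - 1) < 1e-12))

  vals <- rbind(g1 = c(1, 2, 3), gconst = c(5, 5, 5))
  colnames(vals) <- paste0("s", 1:3)
  ds2 <- expression_dataset(vals, c("case", "case", "control"))
  z2 <- zscore_normalize(ds2)
  expect_equal(mean(z2$values["g1", ]), 0)
  expect_equal(sd(z2$values["g1", ]), 1)
  expect_identical(unname(z2$values["gconst", ]), c(0, 0, 0))
  expect_identical(attr(z2, "constant_genes"), "gconst")
})

test_that("subnetwork activity is the member-mean of z-scores", {
  withr::local_seed(2)
  m <- matrix(rnorm(50), 5, 10,
              dimnames = list(paste0("g", 1:5), paste0("s", 1:10)))
  ds <- expression_dataset(m, rep(c("case", "control"), each = 5))
  z <- zscore_normalize(ds)

  expect_identical(subnetwork_activity(z, "g3"), z$values["g3", ])
  expect_equal(subnetwork_activity(z, paste0("g", 1:5)),
               colMeans(z$values))  # brute-force column mean

  opp <- expression_dataset(
    matrix(c(1, -1, -1, 1), 2, 2, dimnames = list(c("a", "b"), c("s1", "s2"))),
    c("case", "control"))
  expect_equal(unname(subnetwork_activity(opp, c("a", "b"))), c(0, 0))

  expect_error(subnetwork_activity(z, "nope"), "lookup error")
  expect_error(subnetwork_activity(z, character(0)), "non-empty")

  expect_equal(subnetwork_activity(z, c("g1", "g2"), scaling = "sqrt_sum"),
               colSums(z$values[c("g1", "g2"), ]) / sqrt(2))
})

test_that("mutual information matches the plug-in formula", {
  # perfect association, balanced 4/4 -> exactly 1 bit
  act <- c(1, 1, 1, 1, 0, 0, 0, 0)
  labs <- rep(c("case", "control"), each = 4)
  expect_equal(mutual_information(act, labs, 2), 1.0)

  # constant activity -> 0 bits
  expect_identical(mutual_information(rep(2, 8), labs, 2), 0)

  # hand-evaluated joint table {(b0,case)=3,(b0,ctrl)=1,(b1,case)=1,(b1,ctrl)=3}
  act2 <- c(0, 0, 0, 1, 0, 1, 1, 1)
  expected <- mi_oracle_table(matrix(c(3, 1, 1, 3), 2, byrow = TRUE))
  expect_equal(mutual_information(act2, labs, 2), expected, tolerance = 1e-12)

  expect_error(mutual_information(act, rep("case", 8), 2), "two classes")
})

test_that("MI is non-negative, label-entropy-bounded, and matches the oracle", {
  withr::local_seed(3)
  for (rep_i in 1:40) {
    n <- sample(6:40, 1)
    act <- rnorm(n)
    cls <- sample(0:1, n, replace = TRUE)
    if (length(unique(cls)) < 2) cls[1:2] <- 0:1
    nbins <- sample(2:6, 1)
    labs <- c("control", "case")[cls + 1]
    mi <- mutual_information(act, labs, nbins)
    expect_gte(mi, 0)
    p1 <- mean(cls)
    H <- -p1 * log2(p1) - (1 - p1) * log2(1 - p1)
    expect_lte(mi, H + 1e-12)
    expect_equal(mi, mi_oracle(act, cls, nbins), tolerance = 1e-12)
  }
})

test_that("greedy search solves a constructed two-gene-signal instance", {
  inst <- make_path_dataset()
  cfg <- search_config(n_bins = 2)
  sub <- greedy_search("A", zscore_normalize(inst$ds), inst$net, cfg)
  expect_identical(sub$members, c("A", "B"))
  expect_equal(sub$score, 1.0)

  # exhaustive over all connected subgraphs containing A agrees
  z <- zscore_normalize(inst$ds)$values
  adj <- list(2L, c(1L, 3L), 2L)  # A-B-C path, 1-based indices
  cls <- c(rep(1, 4), rep(0, 4))
  expect_equal(exhaustive_best_score(z, cls, adj, 1L, 2), 1.0)
})

test_that("isolated seeds return singletons scored by their own z-profile", {
  inst <- make_path_dataset()
  lone <- igraph::add_vertices(inst$net, 1, name = "D")
  vals <- rbind(inst$ds$values, D = c(3, -1, 2, -2, 1, -3, 0.5, 0))
  ds <- expression_dataset(vals, as.character(inst$ds$labels))
  z <- zscore_normalize(ds)
  cfg <- search_config(n_bins = 2)
  sub <- greedy_search("D", z, lone, cfg)
  expect_identical(sub$members, "D")
  expect_equal(sub$score,
               mutual_information(z$values["D", ], z$labels, 2))
})

test_that("greedy stays connected, capped, and below the exhaustive optimum", {
  withr::local_seed(4)
  for (rep_i in 1:25) {
    n <- sample(6:10, 1)
    edges <- random_graph_edges(n, 0.4)
    if (nrow(edges) < 2) next
    ids <- sprintf("v%02d", 1:n)
    net <- igraph::graph_from_data_frame(
      data.frame(from = ids[edges[, 1]], to = ids[edges[, 2]]),
      directed = FALSE, vertices = data.frame(name = ids))
    ns <- 16
    vals <- matrix(rnorm(n * ns), n, ns, dimnames = list(ids, paste0("s", 1:ns)))
    ds <- expression_dataset(vals, rep(c("case", "control"), each = ns / 2))
    z <- zscore_normalize(ds)
    cfg <- search_config(max_distance_from_seed = n, n_bins = 3,
                         max_subnetwork_size = 4)
    seed_id <- ids[sample(n, 1)]
    sub <- greedy_search(seed_id, z, net, cfg)

    expect_lte(length(sub$members), 4)
    el <- igraph::as_edgelist(net)
    expect_true(is_connected_set(sub$members, el))

    adj <- lapply(igraph::as_adj_list(net), as.integer)
    best <- exhaustive_best_score(z$values, class_vector(ds), adj,
                                  match(seed_id, ids), 3, maxsize = 4)
    expect_lte(sub$score, best + 1e-9)
  }
})

test_that("search_all_seeds yields one candidate per shared gene", {
  withr::local_seed(5)
  sim <- simulate_dataset(synthetic_config(n_genes = 40, n_case = 15,
                                           n_control = 15, seed = 6))
  cands <- search_all_seeds(sim$dataset, sim$network)
  expect_length(cands, 40)  # all network proteins are measured
  expect_identical(sort(vapply(cands$subnetworks, `[[`, "", "seed")),
                   sort(gene_ids(sim$dataset)))

  # partial overlap: only the shared genes are eligible seeds
  ds_sub <- sim$dataset
  ds_sub$values <- ds_sub$values[1:25, ]
  ds_part <- expression_dataset(ds_sub$values, as.character(ds_sub$labels))
  expect_length(search_all_seeds(ds_part, sim$network), 25)

  # disjoint gene universes cannot be integrated
  rownames(ds_sub$values) <- paste0("x", 1:25)
  ds_disj <- expression_dataset(ds_sub$values, as.character(ds_sub$labels))
  expect_error(search_all_seeds(ds_disj, sim$network), "integration error")
})

test_that("search results are bit-identical across repeated runs", {
  sim <- simulate_dataset(synthetic_config(n_genes = 60, n_case = 20,
                                           n_control = 20, seed = 13))
  cfg <- search_config(n_permutations = 30, rng_seed = 99)
  r1 <- search_all_seeds(sim$dataset, sim$network, cfg)
  r2 <- search_all_seeds(sim$dataset, sim$network, cfg)
  expect_identical(r1$subnetworks, r2$subnetworks)
  f1 <- permutation_filter(r1, sim$dataset, sim$network, cfg)
  f2 <- permutation_filter(r2, sim$dataset, sim$network, cfg)
  expect_identical(f1$subnetworks, f2$subnetworks)
})

test_that("permutation filter keeps a strongly planted module", {
  cfg_syn <- synthetic_config(n_genes = 100, n_case = 50, n_control = 50,
                              module_size = 5, connector_fraction = 0.2,
                              effect_size = 3, seed = 17)
  sim <- simulate_dataset(cfg_syn)
  cfg <- search_config(n_permutations = 100, rng_seed = 7)
  cands <- search_all_seeds(sim$dataset, sim$network, cfg)
  filt <- permutation_filter(cands, sim$dataset, sim$network, cfg)
  expect_gt(length(filt), 0)
  module <- sim$truth$modules[[1]]
  hit <- vapply(filt$subnetworks, function(x)
    length(intersect(x$members, module)) > 0, TRUE)
  expect_true(any(hit))
  # every retained candidate clears all three nulls
  for (x in filt$subnetworks) {
    expect_lte(x$p_gene_null, cfg$alpha)
    expect_lte(x$p_label_null, cfg$alpha)
    expect_lte(x$p_random_null, cfg$alpha)
  }
  # add-one estimator lower bound: no p can undercut 1/(1+n_permutations)
  pmin_all <- vapply(filt$subnetworks, function(x)
    min(x$p_gene_null, x$p_label_null, x$p_random_null), 0)
  expect_true(all(pmin_all >= 1 / (1 + cfg$n_permutations) - 1e-12))

  expect_error(
    permutation_filter(cands, sim$dataset, sim$network,
                       search_config(n_permutations = 10, alpha = 0.05)),
    "config error")
})
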