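# Patient-half resampling design and frequency-based consensus: cases are
# split in half R times, every half is merged with the full control set
# (controls are reused to balance class sizes), the search runs K times per
# half, and member sets recurring across the 2*R*K runs are ranked.

#' Build the patient-half resampling plan
#'
#' `R` independent random bipartitions of the case samples into halves of
#' sizes `ceiling(n/2)` and `floor(n/2)`; each half is merged with all
#' controls, and `K` seeded runs are scheduled per half, giving `2 * R * K`
#' plans in total.
#'
#' @param ds An `ExpressionDataset`.
#' @param R Number of resamples (case re-partitions).
#' @param K Runs per half-dataset.
#' @param master_seed Seed from which each half's partition and each run's
#'   seed are derived (counter-based, so plans are reproducible and adding
#'   runs never perturbs earlier ones).
#' @return List of `split_plan` records: `resample_index`, `half_index`,
#'   `run_index`, `case_ids`, `control_ids`, `run_seed`.
#' @export
make_split_plans <- function(ds, R = 5, K = 4, master_seed = 1) {
  if (R < 1 || K < 1) stop("config error: R and K must be >= 1")
  cases <- sample_ids(ds)[ds$labels == "case"]
  controls <- sample_ids(ds)[ds$labels == "control"]
  if (length(cases) < 2) stop("need >= 2 case samples to split")
  plans <- list()
  counter <- 0
  for (r in seq_len(R)) {
    perm <- with_seed(derive_seed(master_seed, 1000 + r), sample(cases))
    n1 <- ceiling(length(cases) / 2)
    halves <- list(perm[seq_len(n1)], perm[-seq_len(n1)])
    for (h in 1:2) {
      for (k in seq_len(K)) {
        counter <- counter + 1
        plans[[counter]] <- structure(
          list(resample_index = r, half_index = h, run_index = k,
               case_ids = halves[[h]], control_ids = controls,
               run_seed = derive_seed(master_seed, 2000 + counter)),
          class = "split_plan")
      }
    }
  }
  plans
}

#' Execute the search + filter on every planned run
#'
#' Each plan's samples are subset from `ds`, z-scored within the run, searched
#' from every seed, and permutation-filtered with the plan's `run_seed`.
#'
#' @param plans Plans from [make_split_plans()].
#' @param ds The full `ExpressionDataset`.
#' @param net Interaction network.
#' @param cfg A [search_config()]; its `rng_seed` is replaced per run.
#' @return List of filtered `subnetwork_set`s, one per plan (possibly empty
#'   sets), each tagged with its plan in `meta$plan`.
#' @export
run_all <- function(plans, ds, net, cfg = search_config()) {
  lapply(plans, function(plan) {
    run_ds <- subset_samples(ds, c(plan$case_ids, plan$control_ids))
    run_cfg <- cfg
    run_cfg$rng_seed <- plan$run_seed
    cands <- search_all_seeds(run_ds, net, run_cfg)
    filt <- permutation_filter(cands, run_ds, net, run_cfg)
    filt$meta$all_candidates <- NULL  # keep per-run results lean
    filt$meta$plan <- unclass(plan)
    filt
  })
}

#' Group recurring subnetworks across runs and rank them
#'
#' Candidates are grouped by exact member-set equality; a group's frequency is
#' the number of runs whose filtered set contains that member set (at most one
#' count per run). Groups are ranked by frequency (desc), mean score (desc),
#' then lexicographic member list, and either the `top_k` first groups or all
#' groups with `frequency >= min_frequency` are selected.
#'
#' With `identity = "jaccard"` (the default), member sets that are slight
#' variants of one another are first clustered: exact groups are visited in
#' (frequency, mean score) order and absorbed into an earlier cluster when
#' their Jaccard index with its representative set reaches
#' `jaccard_threshold`; a cluster's frequency is the number of runs containing
#' any of its variants, and its member set is the best-scoring variant's.
#' `identity = "exact"` keeps strict member-set equality, under which a
#' recurrent module whose recovered boundary wobbles by one gene across
#' resamples splinters into several low-frequency groups.
#'
#' @param results List of filtered `subnetwork_set`s from [run_all()].
#' @param top_k Select this many top groups (exclusive with `min_frequency`).
#' @param min_frequency Select all groups at or above this frequency
#'   (exclusive with `top_k`).
#' @param identity `"jaccard"` (cluster near-identical member sets, default)
#'   or `"exact"` (strict member-set equality).
#' @param jaccard_threshold Similarity at or above which two member sets count
#'   as the same subnetwork (used by `identity = "jaccard"`).
#' @return A `consensus_result`: `groups` (ranked list with `members`,
#'   `frequency`, `mean_score`, `representative`), `selected`,
#'   `total_candidates` (distinct groups after identity resolution), `n_runs`.
#' @export
group_and_rank <- function(results, top_k = NULL, min_frequency = NULL,
                           identity = c("jaccard", "exact"),
                           jaccard_threshold = 0.8) {
  identity <- match.arg(identity)
  if (is.null(top_k) == is.null(min_frequency))
    stop("config error: give exactly one of top_k or min_frequency")
  if (!length(results)) stop("need >= 1 result set")
  keys <- list()   # key -> list(members, scores, runs, best)
  for (run_i in seq_along(results)) {
    subs <- results[[run_i]]$subnetworks
    seen <- character(0)
    for (x in subs) {
      key <- paste(x$members, collapse = "|")
      if (is.null(keys[[key]]))
        keys[[key]] <- list(members = x$members, scores = numeric(0),
                            runs = integer(0), best = x)
      g <- keys[[key]]
      g$scores <- c(g$scores, x$score)
      if (!(key %in% seen)) g$runs <- c(g$runs, run_i)
      if (x$score > g$best$score) g$best <- x
      keys[[key]] <- g
      seen <- c(seen, key)
    }
  }
  groups <- lapply(names(keys), function(key) {
    g <- keys[[key]]
    list(members = g$members, frequency = length(g$runs), runs = g$runs,
         scores = g$scores, mean_score = mean(g$scores),
         representative = g$best, key = key)
  })
  if (identity == "jaccard" && length(groups) > 1) {
    ord <- lex_order(-vapply(groups, `[[`, 0L, "frequency"),
                     -vapply(groups, `[[`, 0, "mean_score"),
                     vapply(groups, `[[`, "", "key"))
    clusters <- list()
    for (g in groups[ord]) {
      placed <- FALSE
      for (ci in seq_along(clusters)) {
        if (jaccard(g$members, clusters[[ci]]$members) >= jaccard_threshold) {
          cl <- clusters[[ci]]
          cl$runs <- union(cl$runs, g$runs)
          cl$frequency <- length(cl$runs)
          cl$scores <- c(cl$scores, g$scores)
          cl$mean_score <- mean(cl$scores)
          if (g$representative$score > cl$representative$score) {
            cl$representative <- g$representative
            cl$members <- g$members
            cl$key <- g$key
          }
          clusters[[ci]] <- cl
          placed <- TRUE
          break
        }
      }
      if (!placed) clusters[[length(clusters) + 1]] <- g
    }
    groups <- clusters
  }
  groups <- lapply(groups, function(g) {
    g$representative$frequency <- g$frequency
    g$runs <- NULL
    g$scores <- NULL
    g
  })
  if (length(groups)) {
    ord <- lex_order(-vapply(groups, `[[`, 0L, "frequency"),
                     -vapply(groups, `[[`, 0, "mean_score"),
                     vapply(groups, `[[`, "", "key"))
    groups <- groups[ord]
  }
  selected <- if (!is.null(top_k)) {
    head(groups, top_k)
  } else {
    Filter(function(g) g$frequency >= min_frequency, groups)
  }
  structure(list(groups = groups, selected = selected,
                 total_candidates = length(groups),
                 n_runs = length(results)),
            class = "consensus_result")
}

#' @export
print.consensus_result <- function(x, ...) {
  cat(sprintf("consensus_result: %d distinct group(s) over %d run(s); %d selected\n",
              x$total_candidates, x$n_runs, length(x$selected)))
  invisible(x)
}

#' Consensus table as a data.frame
#'
#' @param x A `consensus_result`.
#' @param row.names,optional,... Ignored (data.frame method signature).
#' @param selected_only If `TRUE` (default) only the selected groups.
#' @return One row per group: members, size, frequency, mean score and the
#'   representative's p-values.
#' @export
as.data.frame.consensus_result <- function(x, row.names = NULL,
                                           optional = FALSE, ...,
                                           selected_only = TRUE) {
  gs <- if (selected_only) x$selected else x$groups
  data.frame(
    members = vapply(gs, function(g) paste(g$members, collapse = "|"), ""),
    size = vapply(gs, function(g) length(g$members), 0L),
    frequency = vapply(gs, `[[`, 0L, "frequency"),
    mean_score = vapply(gs, `[[`, 0, "mean_score"),
    p_gene_null = vapply(gs, function(g) g$representative$p_gene_null, 0),
    p_label_null = vapply(gs, function(g) g$representative$p_label_null, 0),
    p_random_null = vapply(gs, function(g) g$representative$p_random_null, 0),
    stringsAsFactors = FALSE)
}
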