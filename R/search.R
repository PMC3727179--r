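# The integration algorithm: per-gene z-scores, subnetwork activity, binned
# mutual information against the phenotype, greedy seed expansion over the
# interaction network, and the three permutation-test significance filters.

#' Search configuration
#'
#' Knobs of the greedy subnetwork search and its permutation filters. The
#' defaults cap subnetworks at 10 members (the size range the marker modules
#' are expected to span), restrict members to within 2 interactions of the
#' seed, and require a 5% relative mutual-information gain per added gene.
#'
#' @param max_distance_from_seed Maximum graph distance of any member from the
#'   seed (>= 1).
#' @param min_improvement_rate Minimum relative MI gain to accept an
#'   expansion, as a fraction of the current score (>= 0).
#' @param max_subnetwork_size Maximum member count.
#' @param n_bins Histogram bins for the activity, or `"auto"` for Sturges'
#'   rule `floor(log2(n_samples)) + 1`.
#' @param n_permutations Draws per permutation null.
#' @param alpha Significance level each of the three p-values must reach.
#' @param rng_seed Seed for all permutation randomness.
#' @param research_nulls If `TRUE` (default) the gene-null and label-null
#'   re-run the greedy search from the candidate's seed under the permuted
#'   data, so the null distribution reflects the same greedy optimization the
#'   observed score went through. `FALSE` recomputes the score on the fixed
#'   member set only (cheaper, but anti-conservative for an optimized score).
#' @param activity_scaling `"mean"` (arithmetic mean of member z-scores) or
#'   `"sqrt_sum"` (sum divided by sqrt of member count).
#' @return A `search_config` list.
#' @export
search_config <- function(max_distance_from_seed = 2, min_improvement_rate = 0.05,
                          max_subnetwork_size = 10, n_bins = "auto",
                          n_permutations = 100, alpha = 0.05, rng_seed = 1,
                          research_nulls = TRUE,
                          activity_scaling = c("mean", "sqrt_sum")) {
  cfg <- list(max_distance_from_seed = as.integer(max_distance_from_seed),
              min_improvement_rate = min_improvement_rate,
              max_subnetwork_size = as.integer(max_subnetwork_size),
              n_bins = n_bins, n_permutations = as.integer(n_permutations),
              alpha = alpha, rng_seed = as.integer(rng_seed),
              research_nulls = isTRUE(research_nulls),
              activity_scaling = match.arg(activity_scaling))
  if (cfg$max_distance_from_seed < 1)
    stop("config error: max_distance_from_seed must be >= 1")
  if (cfg$min_improvement_rate < 0)
    stop("config error: min_improvement_rate must be >= 0")
  if (cfg$max_subnetwork_size < 1)
    stop("config error: max_subnetwork_size must be >= 1")
  if (!identical(cfg$n_bins, "auto") &&
      (!is.numeric(cfg$n_bins) || cfg$n_bins < 2))
    stop("config error: n_bins must be 'auto' or an integer >= 2")
  if (cfg$alpha <= 0 || cfg$alpha >= 1)
    stop("config error: alpha must lie in (0, 1)")
  structure(cfg, class = "search_config")
}

resolve_bins <- function(cfg, n_samples) {
  b <- if (identical(cfg$n_bins, "auto"))
    floor(log2(n_samples)) + 1 else cfg$n_bins
  b <- as.integer(b)
  if (b < 2) stop("config error: resolved bin count must be >= 2")
  b
}

#' Z-score each gene across all samples
#'
#' Each row is centred and scaled to unit standard deviation. Constant rows
#' (zero variance) carry no signal: they are set to all zeros and listed in
#' the `"constant_genes"` attribute.
#'
#' @param ds An `ExpressionDataset`.
#' @return A z-scored `ExpressionDataset`.
#' @export
zscore_normalize <- function(ds) {
  v <- ds$values
  mu <- rowMeans(v)
  sdv <- apply(v, 1, sd)
  const <- !is.finite(sdv) | sdv == 0
  sdv[const] <- 1
  z <- (v - mu) / sdv
  z[const, ] <- 0
  out <- expression_dataset(z, as.character(ds$labels))
  attr(out, "constant_genes") <- rownames(v)[const]
  attr(out, "zscored") <- TRUE
  out
}

#' Subnetwork activity
#'
#' The per-sample summary of a member set: the arithmetic mean of the members'
#' z-scores (or their sum scaled by `1/sqrt(size)` if configured so).
#'
#' @param ds_z A z-scored `ExpressionDataset` (see [zscore_normalize()]).
#' @param members Non-empty character vector of member gene ids.
#' @param scaling `"mean"` or `"sqrt_sum"`.
#' @return Numeric vector over samples, named by sample id.
#' @export
subnetwork_activity <- function(ds_z, members, scaling = c("mean", "sqrt_sum")) {
  scaling <- match.arg(scaling)
  if (!length(members)) stop("members must be non-empty")
  missing <- setdiff(members, gene_ids(ds_z))
  if (length(missing))
    stop("lookup error: unknown gene id(s): ",
         paste(head(missing, 5), collapse = ", "))
  s <- colSums(ds_z$values[members, , drop = FALSE])
  if (scaling == "mean") s / length(members) else s / sqrt(length(members))
}

#' Mutual information between binned activity and the phenotype
#'
#' Plug-in estimate in bits: the activity is discretized into `n_bins`
#' equal-width bins over its observed range and
#' `MI = sum p(b,c) log2[p(b,c) / (p(b) p(c))]` is evaluated on the joint
#' histogram with the two-class label. Constant activity returns 0.
#'
#' @param act Numeric activity vector.
#' @param labels Class labels (two classes required), factor or character.
#' @param n_bins Integer >= 2 or `"auto"` (Sturges on the sample count).
#' @return MI in bits (non-negative, bounded by the label entropy).
#' @export
mutual_information <- function(act, labels, n_bins = "auto") {
  labels <- as.factor(labels)
  if (length(act) != length(labels) || length(act) < 2)
    stop("activity and labels must have equal length >= 2")
  if (nlevels(droplevels(labels)) != 2)
    stop("contract error: exactly two classes are required")
  if (!all(is.finite(act))) stop("activity must be finite")
  b <- if (identical(n_bins, "auto"))
    as.integer(floor(log2(length(act))) + 1) else as.integer(n_bins)
  if (b < 2) stop("n_bins must resolve to >= 2")
  cls <- as.integer(droplevels(labels)) - 1L
  cpp_mi(as.numeric(act), cls, b)
}

# Shared-gene search space: canonical (byte-lexicographic) gene order, the
# transposed z-matrix, and a 0-based adjacency list over that order.
search_space <- function(ds_z, net) {
  shared <- intersect(gene_ids(ds_z), igraph::V(net)$name)
  if (!length(shared))
    stop("integration error: dataset and network share no genes")
  genes <- lex_sort(shared)
  sub <- igraph::induced_subgraph(net, genes)
  sub_names <- igraph::V(sub)$name
  idx <- setNames(seq_along(genes), genes)
  al <- igraph::as_adj_list(sub)
  adj <- lapply(seq_along(al), function(i)
    unname(idx[sub_names[as.integer(al[[i]])]]) - 1L)
  adj_ord <- vector("list", length(genes))
  adj_ord[idx[sub_names]] <- adj
  list(genes = genes,
       zt = t(ds_z$values[genes, , drop = FALSE]),
       cls = class_vector(ds_z),
       adj = adj_ord,
       lexrank = seq_along(genes))
}

.as_zscored <- function(ds) {
  if (isTRUE(attr(ds, "zscored"))) ds else zscore_normalize(ds)
}

#' Greedy seed-expansion search from one seed
#'
#' Starting from `{seed}`, each step evaluates every gene adjacent to the
#' current member set and within `max_distance_from_seed` interactions of the
#' seed, and adds the one with the largest MI gain (ties broken by
#' lexicographically smallest gene id). Expansion stops when the best relative
#' gain falls below `min_improvement_rate`, the size cap is hit, or no
#' candidates remain. Fully deterministic.
#'
#' @param seed Seed gene id (must be in both the network and the dataset).
#' @param ds_z A z-scored `ExpressionDataset`.
#' @param net Interaction network (igraph).
#' @param cfg A [search_config()].
#' @return A subnetwork record: list with `seed`, `members` (lexicographically
#'   sorted, inducing a connected subgraph), `score` (final MI in bits), the
#'   three p-value slots (`NA` until filtered), and `frequency` (`NA` until
#'   consensus).
#' @export
greedy_search <- function(seed, ds_z, net, cfg = search_config()) {
  sp <- search_space(.as_zscored(ds_z), net)
  if (!seed %in% sp$genes)
    stop("contract error: seed '", seed,
         "' is not in both the network and the dataset")
  res <- cpp_search_seeds(sp$zt, sp$cls, sp$adj,
                          match(seed, sp$genes) - 1L, sp$lexrank,
                          cfg$max_distance_from_seed, cfg$min_improvement_rate,
                          cfg$max_subnetwork_size,
                          resolve_bins(cfg, length(sp$cls)))
  new_subnetwork(seed, sp$genes[res$members[[1]]], res$score[1])
}

new_subnetwork <- function(seed, members, score,
                           p_gene = NA_real_, p_label = NA_real_,
                           p_random = NA_real_, frequency = NA_integer_) {
  list(seed = seed, members = lex_sort(members), score = score,
       p_gene_null = p_gene, p_label_null = p_label, p_random_null = p_random,
       frequency = frequency)
}

#' Container for a set of candidate or significant subnetworks
#'
#' @param subnetworks List of subnetwork records (see [greedy_search()]).
#' @param meta Provenance list (run id, config digest, counts).
#' @return A `subnetwork_set`.
#' @export
subnetwork_set <- function(subnetworks, meta = list()) {
  structure(list(subnetworks = subnetworks, meta = meta),
            class = "subnetwork_set")
}

#' @export
print.subnetwork_set <- function(x, ...) {
  cat(sprintf("subnetwork_set: %d subnetwork(s)\n", length(x$subnetworks)))
  invisible(x)
}

#' @export
length.subnetwork_set <- function(x) length(x$subnetworks)

#' Turn a subnetwork set into a data.frame
#'
#' @param x A `subnetwork_set`.
#' @param row.names,optional,... Ignored (data.frame method signature).
#' @return One row per subnetwork: seed, size, members (`|`-joined), score,
#'   the three p-values, frequency.
#' @export
as.data.frame.subnetwork_set <- function(x, row.names = NULL, optional = FALSE, ...) {
  subs <- x$subnetworks
  data.frame(
    seed = vapply(subs, `[[`, "", "seed"),
    size = vapply(subs, function(s) length(s$members), 0L),
    members = vapply(subs, function(s) paste(s$members, collapse = "|"), ""),
    score = vapply(subs, `[[`, 0, "score"),
    p_gene_null = vapply(subs, `[[`, 0, "p_gene_null"),
    p_label_null = vapply(subs, `[[`, 0, "p_label_null"),
    p_random_null = vapply(subs, `[[`, 0, "p_random_null"),
    frequency = vapply(subs, function(s) as.integer(s$frequency), 0L),
    stringsAsFactors = FALSE)
}

#' Run the greedy search from every eligible seed
#'
#' One candidate subnetwork per gene present in both the dataset and the
#' network (the search space; unmeasured network genes are excluded).
#' De-duplication of identical member sets is deferred to the consensus
#' stage.
#'
#' @param ds An `ExpressionDataset` (z-scored internally if not already).
#' @param net Interaction network (igraph).
#' @param cfg A [search_config()].
#' @return A `subnetwork_set` with exactly one record per eligible seed.
#' @export
search_all_seeds <- function(ds, net, cfg = search_config()) {
  ds_z <- .as_zscored(ds)
  sp <- search_space(ds_z, net)
  res <- cpp_search_seeds(sp$zt, sp$cls, sp$adj,
                          seq_along(sp$genes) - 1L, sp$lexrank,
                          cfg$max_distance_from_seed, cfg$min_improvement_rate,
                          cfg$max_subnetwork_size,
                          resolve_bins(cfg, length(sp$cls)))
  subs <- lapply(seq_along(sp$genes), function(i)
    new_subnetwork(sp$genes[i], sp$genes[res$members[[i]]], res$score[i]))
  subnetwork_set(subs, meta = list(n_seeds = length(sp$genes),
                                   n_samples = length(sp$cls),
                                   config = unclass(cfg)))
}

#' Three-way permutation significance filter
#'
#' For every candidate, three one-sided permutation p-values with
#' `n_permutations` draws each (add-one estimator
#' `p = (1 + #null >= observed) / (1 + n_permutations)`):
#' \describe{
#'   \item{gene-null}{the assignment of z-score rows to gene ids is permuted
#'     and (by default) the greedy search is re-run from the same seed;}
#'   \item{label-null}{class labels are permuted and (by default) the search
#'     is re-run from the same seed;}
#'   \item{random-subnetwork-null}{random connected subgraphs of the same size
#'     are scored on the unpermuted data.}
#' }
#' A candidate is retained iff all three p-values are `<= alpha`. Seeded by
#' `cfg$rng_seed` and fully reproducible.
#'
#' @param s Candidate `subnetwork_set` from [search_all_seeds()] on the same
#'   data and network.
#' @param ds The `ExpressionDataset` the candidates were found on.
#' @param net The interaction network they were found in.
#' @param cfg A [search_config()].
#' @return A `subnetwork_set` of the retained candidates, p-value slots
#'   filled; `meta$n_candidates` records the pre-filter count and
#'   `meta$all_candidates` keeps the full annotated list.
#' @export
permutation_filter <- function(s, ds, net, cfg = search_config()) {
  stopifnot(inherits(s, "subnetwork_set"))
  if (cfg$n_permutations < ceiling(1 / cfg$alpha) - 1)
    stop("config error: n_permutations = ", cfg$n_permutations,
         " cannot reach alpha = ", cfg$alpha)
  ds_z <- .as_zscored(ds)
  sp <- search_space(ds_z, net)
  subs <- s$subnetworks
  if (!length(subs)) return(subnetwork_set(list(), meta = s$meta))
  midx <- lapply(subs, function(x) {
    i <- match(x$members, sp$genes)
    if (anyNA(i)) stop("candidate members missing from the search space")
    i
  })
  seeds0 <- match(vapply(subs, `[[`, "", "seed"), sp$genes) - 1L
  if (anyNA(seeds0)) stop("candidate seed missing from the search space")
  pv <- with_seed(cfg$rng_seed,
    cpp_permutation_pvalues(sp$zt, sp$cls, sp$adj, midx, seeds0,
                            vapply(subs, `[[`, 0, "score"), sp$lexrank,
                            cfg$max_distance_from_seed,
                            cfg$min_improvement_rate,
                            cfg$max_subnetwork_size,
                            resolve_bins(cfg, length(sp$cls)),
                            cfg$n_permutations,
                            cfg$research_nulls, cfg$research_nulls))
  annotated <- lapply(seq_along(subs), function(i) {
    x <- subs[[i]]
    x$p_gene_null <- pv[i, 1]
    x$p_label_null <- pv[i, 2]
    x$p_random_null <- pv[i, 3]
    x
  })
  keep <- vapply(annotated, function(x)
    x$p_gene_null <= cfg$alpha && x$p_label_null <= cfg$alpha &&
      x$p_random_null <= cfg$alpha, TRUE)
  meta <- s$meta
  meta$n_candidates <- length(subs)
  meta$n_retained <- sum(keep)
  meta$all_candidates <- annotated
  subnetwork_set(annotated[keep], meta = meta)
}
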