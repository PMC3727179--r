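# The expression-based comparator: per-gene Welch t-tests, top-k DE gene
# selection, two-way complete-linkage hierarchical clustering on
# 1 - Pearson correlation, misclassification counting from a two-cluster cut,
# and subnetwork / DE-gene overlap.

#' Per-gene two-sample t-tests, ranked
#'
#' Welch (unequal-variance) two-tailed t-test for every gene; `de_flag` marks
#' raw `p < 0.05` (no multiple-testing correction, deliberately, as the
#' comparator works on raw per-gene significance). Genes are ranked by
#' ascending p, ties by descending `|t|`, then gene id. A gene that is
#' constant within both classes provides no evidence and is assigned
#' `t = 0, p = 1`.
#'
#' @param ds An `ExpressionDataset` with >= 2 samples per class.
#' @param var_equal Use the pooled-variance (Student) test instead of Welch.
#' @return A `de_table` data.frame: `gene_id`, `t`, `p`, `mean_diff`
#'   (case minus control), `de_flag`, `rank`.
#' @export
t_test_rank <- function(ds, var_equal = FALSE) {
  case <- ds$labels == "case"
  if (sum(case) < 2 || sum(!case) < 2)
    stop("contract error: each class needs >= 2 samples")
  x <- ds$values[, case, drop = FALSE]
  y <- ds$values[, !case, drop = FALSE]
  res <- t(vapply(seq_len(nrow(ds$values)), function(i) {
    out <- tryCatch({
      tt <- stats::t.test(x[i, ], y[i, ], var.equal = var_equal)
      c(unname(tt$statistic), tt$p.value)
    }, error = function(e) c(0, 1))  # constant gene: no evidence
    out
  }, numeric(2)))
  de <- data.frame(gene_id = gene_ids(ds),
                   t = res[, 1], p = res[, 2],
                   mean_diff = rowMeans(x) - rowMeans(y),
                   stringsAsFactors = FALSE)
  de$de_flag <- de$p < 0.05
  ord <- lex_order(de$p, -abs(de$t), de$gene_id)
  de$rank <- integer(nrow(de))
  de$rank[ord] <- seq_len(nrow(de))
  class(de) <- c("de_table", "data.frame")
  de
}

#' Top-k most differential genes
#'
#' @param de A `de_table` from [t_test_rank()].
#' @param k How many genes (0 allowed; must not exceed the gene count).
#' @return Character vector of `k` gene ids in rank order.
#' @export
top_k_genes <- function(de, k) {
  if (k > nrow(de)) stop("contract error: k = ", k, " exceeds ", nrow(de), " genes")
  if (k == 0) return(character(0))
  de$gene_id[order(de$rank)][seq_len(k)]
}

#' Two-way complete-linkage hierarchical clustering
#'
#' Genes and samples are clustered with complete linkage on the distance
#' `1 - Pearson correlation`: gene-gene correlations are taken across all
#' samples, sample-sample correlations across the selected genes only. Rows
#' and columns are pre-sorted by id so leaf order is deterministic.
#'
#' @param ds An `ExpressionDataset`.
#' @param genes Gene ids to cluster on (>= 2).
#' @return An `expression_dendrograms` list: `genes` and `samples`, both
#'   [stats::hclust] objects.
#' @export
hcluster_expression <- function(ds, genes) {
  missing <- setdiff(genes, gene_ids(ds))
  if (length(missing))
    stop("unknown gene id(s): ", paste(head(missing, 5), collapse = ", "))
  if (length(genes) < 2 || n_samples(ds) < 2)
    stop("need >= 2 genes and >= 2 samples")
  X <- ds$values[lex_sort(genes), lex_sort(sample_ids(ds)), drop = FALSE]
  gene_sd <- apply(X, 1, sd)
  if (any(gene_sd == 0))
    stop("contract error: zero-variance gene '",
         rownames(X)[gene_sd == 0][1], "' has undefined correlation")
  samp_sd <- apply(X, 2, sd)
  if (any(samp_sd == 0))
    stop("contract error: zero-variance sample '",
         colnames(X)[samp_sd == 0][1], "' has undefined correlation")
  gene_h <- hclust(as.dist(1 - cor(t(X))), method = "complete")
  samp_h <- hclust(as.dist(1 - cor(X)), method = "complete")
  structure(list(genes = gene_h, samples = samp_h),
            class = "expression_dendrograms")
}

#' Count misclassified samples from a two-cluster cut
#'
#' The sample dendrogram is cut into exactly two clusters at its highest
#' merge; each cluster is assigned its majority label (a within-cluster tie
#' goes to "case" for the cluster holding more cases). Samples whose label
#' disagrees with their cluster's label are counted per class.
#'
#' @param sample_dend A sample [stats::hclust] (e.g.
#'   `hcluster_expression(...)$samples`).
#' @param labels Class labels named by sample id (or an `ExpressionDataset`).
#' @return Named integer vector `c(case_errors, control_errors)`.
#' @export
count_misclassified <- function(sample_dend, labels) {
  if (inherits(labels, "ExpressionDataset")) labels <- labels$labels
  labels <- setNames(as.character(labels), names(labels))
  cl <- cutree(sample_dend, k = 2)
  lab <- labels[names(cl)]
  if (anyNA(lab)) stop("labels missing for clustered samples")
  n_case <- vapply(1:2, function(k) sum(lab[cl == k] == "case"), 0L)
  n_ctrl <- vapply(1:2, function(k) sum(lab[cl == k] == "control"), 0L)
  cluster_label <- character(2)
  for (k in 1:2) {
    if (n_case[k] > n_ctrl[k]) cluster_label[k] <- "case"
    else if (n_case[k] < n_ctrl[k]) cluster_label[k] <- "control"
    else cluster_label[k] <- if (n_case[k] >= n_case[3 - k]) "case" else "control"
  }
  case_err <- sum(n_case[cluster_label == "control"])
  ctrl_err <- sum(n_ctrl[cluster_label == "case"])
  c(case_errors = case_err, control_errors = ctrl_err)
}

#' Overlap between a subnetwork gene set and a DE gene list
#'
#' @param subnet_genes Character vector (e.g. the union of all selected
#'   subnetwork members).
#' @param top_genes Character vector (e.g. from [top_k_genes()]).
#' @return A `gene_overlap` list: `genes` (the intersection), `size`,
#'   `size_subnet`, `size_top`.
#' @export
overlap_genes <- function(subnet_genes, top_genes) {
  common <- intersect(subnet_genes, top_genes)
  structure(list(genes = lex_sort(common), size = length(common),
                 size_subnet = length(unique(subnet_genes)),
                 size_top = length(unique(top_genes))),
            class = "gene_overlap")
}

#' @export
print.gene_overlap <- function(x, ...) {
  cat(sprintf("gene_overlap: %d common of %d subnetwork and %d DE genes\n",
              x$size, x$size_subnet, x$size_top))
  invisible(x)
}

#' Serialize a dendrogram as Newick
#'
#' @param hc A [stats::hclust] object.
#' @return A single Newick string (requires the `ape` package).
#' @export
dendrogram_newick <- function(hc) {
  if (!requireNamespace("ape", quietly = TRUE))
    stop("dendrogram_newick() needs the 'ape' package")
  ape::write.tree(ape::as.phylo(hc))
}
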