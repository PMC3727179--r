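# End-to-end orchestration: simulate (or load) -> search -> filter ->
# consensus -> classify -> baseline -> machine-readable report. One master
# seed fans out to every stage by counter-based derivation, so a config
# reproduces its report byte for byte.

REPORT_SCHEMA_VERSION <- "1.0"

#' Pipeline configuration
#'
#' Either a `synthetic` block (the bundled generator) or the three input
#' paths (`expr_path`, `label_path`, `net_path`) must be provided.
#'
#' @param synthetic A [synthetic_config()], or `NULL` when reading files.
#' @param expr_path,label_path,net_path Input files (see [read_expression()],
#'   [read_network()]); ignored when `synthetic` is given.
#' @param search A [search_config()].
#' @param R,K Resampling design: `R` case re-partitions, `K` runs per half
#'   (`2 * R * K` runs in total).
#' @param top_k Consensus groups to select.
#' @param classifiers Subset of `c("tree", "rbf")`.
#' @param top_de Size of the top-DE-gene comparator set.
#' @param cv_folds Folds for cross-validation.
#' @param master_seed Mandatory master seed; all stage seeds derive from it.
#' @param out_dir Optional output directory (report JSON, subnetworks
#'   GMT/JSON, consensus TSV).
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(synthetic = synthetic_config(),
                            expr_path = NULL, label_path = NULL,
                            net_path = NULL,
                            search = search_config(),
                            R = 2, K = 2, top_k = 5,
                            classifiers = c("tree", "rbf"),
                            top_de = 100, cv_folds = 10,
                            master_seed = 1, out_dir = NULL) {
  if (is.null(master_seed)) stop("config error: master_seed is mandatory")
  if (is.null(synthetic) &&
      (is.null(expr_path) || is.null(label_path) || is.null(net_path)))
    stop("config error: give a synthetic block or all three input paths")
  classifiers <- match.arg(classifiers, several.ok = TRUE)
  structure(list(synthetic = synthetic, expr_path = expr_path,
                 label_path = label_path, net_path = net_path,
                 search = search, R = as.integer(R), K = as.integer(K),
                 top_k = as.integer(top_k), classifiers = classifiers,
                 top_de = as.integer(top_de), cv_folds = as.integer(cv_folds),
                 master_seed = as.integer(master_seed), out_dir = out_dir),
            class = "pipeline_config")
}

#' Load a pipeline configuration from YAML
#'
#' @param path YAML file; top-level keys mirror the [pipeline_config()]
#'   arguments, with `synthetic` and `search` as nested blocks.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  if (!requireNamespace("yaml", quietly = TRUE))
    stop("read_pipeline_config() needs the 'yaml' package")
  raw <- yaml::read_yaml(path)
  syn <- if (!is.null(raw$synthetic)) do.call(synthetic_config, raw$synthetic)
  srch <- if (!is.null(raw$search)) do.call(search_config, raw$search)
    else search_config()
  args <- raw[setdiff(names(raw), c("synthetic", "search"))]
  do.call(pipeline_config, c(list(synthetic = syn, search = srch), args))
}

#' Run the full marker-discovery pipeline
#'
#' Executes: data acquisition (synthetic generation or file loading),
#' patient-half resampling search runs, permutation filtering, consensus
#' grouping, cross-validated classification of the selected subnetworks'
#' activity, half-to-half cross-testing, and the DE-gene clustering baseline.
#' Re-running with an identical config reproduces the report exactly.
#'
#' @param cfg A [pipeline_config()].
#' @return The run report (list, schema-validated); written to
#'   `out_dir/report.json` when `out_dir` is set, along with the selected
#'   subnetworks (GMT + JSON) and the consensus table (TSV).
#' @export
run_pipeline <- function(cfg = pipeline_config()) {
  stopifnot(inherits(cfg, "pipeline_config"))
  # --- data ---------------------------------------------------------------
  if (!is.null(cfg$synthetic)) {
    sim <- simulate_dataset(cfg$synthetic)
    ds <- sim$dataset; net <- sim$network; truth <- sim$truth
  } else {
    ds <- read_expression(cfg$expr_path, cfg$label_path)
    net <- read_network(cfg$net_path)
    truth <- NULL
  }
  # --- resampled search runs ---------------------------------------------
  plans <- make_split_plans(ds, R = cfg$R, K = cfg$K,
                            master_seed = derive_seed(cfg$master_seed, 1))
  results <- run_all(plans, ds, net, cfg$search)
  cons <- group_and_rank(results, top_k = cfg$top_k)
  selected_sets <- lapply(cons$selected, `[[`, "members")
  subnet_genes <- unique(unlist(selected_sets))

  # --- classification of subnetwork activity ------------------------------
  cv <- list(); xtest <- list()
  if (length(cons$selected)) {
    fm <- build_features(ds, cons)
    for (cl in cfg$classifiers) {
      r <- kfold_cv(fm, cl, k = cfg$cv_folds,
                    seed = derive_seed(cfg$master_seed, 2))
      cv[[cl]] <- list(mean_accuracy_pct = r$mean_accuracy_pct,
                       pooled_accuracy_pct = r$pooled_accuracy_pct,
                       fold_accuracies = r$fold_accuracies)
    }
    # half-to-half cross-test on the first resample (controls shared)
    h1 <- plans[[1]]; h2 <- plans[[cfg$K + 1]]
    train_ds <- subset_samples(ds, c(h1$case_ids, h1$control_ids))
    test_ds <- subset_samples(ds, c(h2$case_ids, h2$control_ids))
    for (cl in cfg$classifiers)
      xtest[[cl]] <- cross_test(train_ds, test_ds, cons, cl,
                                seed = derive_seed(cfg$master_seed, 3))
  }

  # --- DE baseline --------------------------------------------------------
  de <- t_test_rank(ds)
  k_de <- min(cfg$top_de, nrow(de))
  top_genes <- top_k_genes(de, k_de)
  base_cv <- list()
  fm_de <- build_features(ds, top_genes)
  for (cl in cfg$classifiers) {
    r <- kfold_cv(fm_de, cl, k = cfg$cv_folds,
                  seed = derive_seed(cfg$master_seed, 4))
    base_cv[[cl]] <- r$mean_accuracy_pct
  }
  dend <- hcluster_expression(ds, top_genes)
  miscls <- count_misclassified(dend$samples, ds$labels)
  ovl <- overlap_genes(subnet_genes, top_genes)

  # --- report -------------------------------------------------------------
  report <- list(
    schema_version = REPORT_SCHEMA_VERSION,
    config_digest = string_digest(
      deparse(unclass(cfg)[setdiff(names(cfg), "out_dir")])),
    master_seed = cfg$master_seed,
    n_genes = n_genes(ds), n_samples = n_samples(ds),
    n_runs = length(results),
    run_seeds = vapply(plans, `[[`, 0L, "run_seed"),
    candidates_per_run = vapply(results, function(r)
      r$meta$n_candidates %||% NA_integer_, 0L),
    significant_per_run = vapply(results, length, 0L),
    consensus = as.data.frame(cons, selected_only = FALSE),
    n_groups = cons$total_candidates,
    n_selected = length(cons$selected),
    selected_members = selected_sets,
    subnetwork_cv = cv,
    subnetwork_cross_test = xtest,
    baseline_cv = base_cv,
    baseline_misclassified = as.list(miscls),
    overlap = list(size = ovl$size, genes = ovl$genes,
                   size_subnet = ovl$size_subnet, size_top = ovl$size_top),
    truth_recovery = if (!is.null(truth) && length(truth$modules) &&
                         length(selected_sets)) {
      list(top1_jaccard = max(vapply(truth$modules, function(m)
        jaccard(selected_sets[[1]], m), 0)))
    })
  validate_report(report)
  if (!is.null(cfg$out_dir)) {
    dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
    jsonlite::write_json(report, file.path(cfg$out_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA, null = "null",
                         pretty = TRUE, dataframe = "rows")
    sel <- subnetwork_set(lapply(cons$selected, `[[`, "representative"),
                          meta = list(config_digest = report$config_digest))
    write_subnetworks(sel, file.path(cfg$out_dir, "subnetworks.gmt"),
                      file.path(cfg$out_dir, "subnetworks.json"))
    write.table(report$consensus, file.path(cfg$out_dir, "consensus.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
  }
  report
}

#' Validate a pipeline report against the schema
#'
#' @param report A report list (from [run_pipeline()] or [read_report()]).
#' @return `TRUE`, invisibly; errors describe the first violation.
#' @export
validate_report <- function(report) {
  required <- c("schema_version", "config_digest", "master_seed", "n_genes",
                "n_samples", "n_runs", "candidates_per_run",
                "significant_per_run", "n_groups", "n_selected",
                "subnetwork_cv", "baseline_cv", "baseline_misclassified",
                "overlap")
  missing <- setdiff(required, names(report))
  if (length(missing))
    stop("invalid report: missing field(s) ", paste(missing, collapse = ", "))
  if (!identical(as.character(report$schema_version), REPORT_SCHEMA_VERSION))
    stop("invalid report: schema version '", report$schema_version, "'")
  if (length(report$candidates_per_run) != report$n_runs)
    stop("invalid report: candidates_per_run length != n_runs")
  invisible(TRUE)
}

#' @rdname validate_report
#' @param path Path to a `report.json`.
#' @export
read_report <- function(path) {
  report <- jsonlite::read_json(path, simplifyVector = TRUE)
  validate_report(report)
  report
}

#' Jaccard index of two gene sets
#'
#' @param a,b Character vectors.
#' @return `|intersection| / |union|` (1 if both empty).
#' @export
jaccard <- function(a, b) {
  u <- length(union(a, b))
  if (u == 0) return(1)
  length(intersect(a, b)) / u
}
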