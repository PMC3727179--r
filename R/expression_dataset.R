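#' Two-class expression dataset
#'
#' The substrate of every pipeline stage: a genes x samples matrix of
#' (pre-normalized) expression values plus a case/control label per sample.
#'
#' @param values Numeric matrix, rows = genes (rownames required), columns =
#'   samples (colnames required). All values must be finite.
#' @param labels Character or factor of class labels, one per sample, values
#'   `"case"` or `"control"`. May be named by sample id; unnamed vectors are
#'   matched by column order.
#'
#' @return An object of class `ExpressionDataset`: a list with elements
#'   `values` (the matrix) and `labels` (a factor with levels
#'   `c("control", "case")`, named by sample id).
#' @export
#' @examples
#' m <- matrix(rnorm(12), 3, 4,
#'             dimnames = list(paste0("g", 1:3), paste0("s", 1:4)))
#' ds <- expression_dataset(m, c("case", "case", "control", "control"))
#' n_samples(ds)
expression_dataset <- function(values, labels) {
  if (!is.matrix(values) || !is.numeric(values))
    stop("`values` must be a numeric matrix")
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("`values` must have gene rownames and sample colnames")
  if (anyDuplicated(rownames(values)))
    stop("duplicate gene ids: ",
         paste(head(unique(rownames(values)[duplicated(rownames(values))]), 3),
               collapse = ", "))
  if (anyDuplicated(colnames(values)))
    stop("duplicate sample ids: ",
         paste(head(unique(colnames(values)[duplicated(colnames(values))]), 3),
               collapse = ", "))
  if (!all(is.finite(values)))
    stop("expression values must all be finite (no NA/NaN/Inf)")

  labels <- .normalize_labels(labels, colnames(values))
  structure(list(values = values, labels = labels),
            class = "ExpressionDataset")
}

.normalize_labels <- function(labels, sample_ids) {
  nm <- names(labels)
  labels <- as.character(labels)
  names(labels) <- nm
  if (!is.null(names(labels)) && !all(names(labels) == "")) {
    missing <- setdiff(sample_ids, names(labels))
    if (length(missing))
      stop("labeled-data error: no class label for sample(s) ",
           paste(head(missing, 5), collapse = ", "))
    labels <- labels[sample_ids]
  } else {
    if (length(labels) != length(sample_ids))
      stop("labeled-data error: ", length(labels), " labels for ",
           length(sample_ids), " samples")
    names(labels) <- sample_ids
  }
  bad <- setdiff(unique(labels), c("case", "control"))
  if (length(bad))
    stop("class labels must be 'case' or 'control'; found: ",
         paste(head(bad, 5), collapse = ", "))
  labels <- factor(labels, levels = c("control", "case"))
  if (any(table(labels) == 0))
    stop("labeled-data error: both classes must be non-empty")
  labels
}

#' @export
print.ExpressionDataset <- function(x, ...) {
  tab <- table(x$labels)
  cat(sprintf("ExpressionDataset: %d genes x %d samples (%d case, %d control)\n",
              nrow(x$values), ncol(x$values), tab[["case"]], tab[["control"]]))
  invisible(x)
}

#' @rdname expression_dataset
#' @param ds An `ExpressionDataset`.
#' @export
n_genes <- function(ds) nrow(ds$values)

#' @rdname expression_dataset
#' @export
n_samples <- function(ds) ncol(ds$values)

#' @rdname expression_dataset
#' @export
gene_ids <- function(ds) rownames(ds$values)

#' @rdname expression_dataset
#' @export
sample_ids <- function(ds) colnames(ds$values)

#' Subset an expression dataset by sample ids
#'
#' @param ds An `ExpressionDataset`.
#' @param ids Sample ids to keep (order preserved as given).
#' @return An `ExpressionDataset` restricted to `ids`.
#' @export
subset_samples <- function(ds, ids) {
  missing <- setdiff(ids, sample_ids(ds))
  if (length(missing))
    stop("unknown sample id(s): ", paste(head(missing, 5), collapse = ", "))
  expression_dataset(ds$values[, ids, drop = FALSE],
                     as.character(ds$labels[ids]))
}

# integer 0/1 class vector (case = 1) in sample order
class_vector <- function(ds) as.integer(ds$labels == "case")
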