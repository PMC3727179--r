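# Readers and writers for the plain-text formats the pipeline speaks:
# expression TSV (+ labels TSV), probe annotation TSV, network edge-list/SIF,
# and subnetwork sets as GMT + JSON. All files are UTF-8, tab-delimited, LF.

#' Read a two-class expression matrix with sample labels
#'
#' The expression file is a TSV with one header row of sample ids and gene (or
#' probe) ids in the first column. GEO series-matrix style banner lines
#' starting with `!` are skipped. The label file is a TSV of
#' `(sample_id, class)` rows, `class` being `case` or `control`; a header row
#' is detected and skipped.
#'
#' @param path Path to the expression TSV.
#' @param label_path Path to the sample-label TSV.
#' @return An [expression_dataset()] with file row/column order preserved.
#' @export
read_expression <- function(path, label_path) {
  lines <- readLines(path, encoding = "UTF-8")
  lines <- lines[!startsWith(lines, "!")]
  lines <- lines[nzchar(lines)]
  if (length(lines) < 2) stop("format error: ", path, " has no data rows")
  tab <- read.delim(text = paste(lines, collapse = "\n"), sep = "\t",
                    header = TRUE, check.names = FALSE, quote = "",
                    colClasses = "character")
  ids <- tab[[1]]
  if (anyDuplicated(ids))
    stop("format error: duplicate row id '", ids[duplicated(ids)][1], "'")
  samples <- colnames(tab)[-1]
  if (anyDuplicated(samples))
    stop("format error: duplicate sample id '",
         samples[duplicated(samples)][1], "'")
  vals <- matrix(NA_real_, nrow(tab), length(samples),
                 dimnames = list(ids, samples))
  for (j in seq_along(samples)) {
    col <- tab[[j + 1]]
    num <- suppressWarnings(as.numeric(col))
    bad <- which(is.na(num) | !is.finite(num))
    if (length(bad))
      stop(sprintf("parse error: non-numeric or non-finite value '%s' at row %d (gene %s), column %d (sample %s)",
                   col[bad[1]], bad[1], ids[bad[1]], j, samples[j]))
    vals[, j] <- num
  }
  expression_dataset(vals, read_labels(label_path))
}

#' @rdname read_expression
#' @export
read_labels <- function(label_path) {
  tab <- read.delim(label_path, sep = "\t", header = FALSE, quote = "",
                    colClasses = "character")
  if (ncol(tab) < 2) stop("format error: label file needs two columns")
  if (nrow(tab) && tolower(tab[[2]][1]) %in% c("class", "label"))
    tab <- tab[-1, , drop = FALSE]
  setNames(tab[[2]], tab[[1]])
}

#' Write an expression dataset (and its labels) to TSV
#'
#' @param ds An `ExpressionDataset`.
#' @param path Output path for the expression TSV.
#' @param label_path Optional output path for the label TSV.
#' @return `path`, invisibly.
#' @export
write_expression <- function(ds, path, label_path = NULL) {
  df <- data.frame(gene_id = gene_ids(ds), ds$values, check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(label_path))
    write.table(data.frame(sample_id = sample_ids(ds),
                           class = as.character(ds$labels)),
                label_path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a probe-to-gene annotation table
#'
#' TSV with two columns `(probe_id, gene_id)`; a header row is detected and
#' skipped. Rows with an empty gene id are dropped.
#'
#' @param path Path to the annotation TSV.
#' @return A data.frame with columns `probe_id`, `gene_id`.
#' @export
read_annotation <- function(path) {
  tab <- read.delim(path, sep = "\t", header = FALSE, quote = "",
                    colClasses = "character")
  if (ncol(tab) < 2) stop("format error: annotation file needs two columns")
  if (nrow(tab) && tolower(tab[[1]][1]) %in% c("probe_id", "probe", "probeset_id"))
    tab <- tab[-1, , drop = FALSE]
  ann <- data.frame(probe_id = tab[[1]], gene_id = tab[[2]])
  ann <- ann[nzchar(ann$gene_id), , drop = FALSE]
  if (anyDuplicated(ann$probe_id))
    stop("format error: duplicate probe id '",
         ann$probe_id[duplicated(ann$probe_id)][1], "'")
  ann
}

#' Collapse probe rows to one row per gene
#'
#' Rows whose probes map to the same gene id are replaced by their arithmetic
#' column-wise mean, on the provided (already normalized) scale. Probes absent
#' from the annotation are dropped and counted.
#'
#' @param ds An `ExpressionDataset` whose rows are probe ids.
#' @param ann Annotation data.frame from [read_annotation()].
#' @return An `ExpressionDataset` with one row per mapped gene, gene order by
#'   first appearance of each gene among the probe rows. The attribute
#'   `"collapse_report"` records probe/gene counts.
#' @export
collapse_probes <- function(ds, ann) {
  map <- setNames(ann$gene_id, ann$probe_id)
  probes <- gene_ids(ds)
  mapped <- probes[probes %in% names(map)]
  if (!length(mapped))
    stop("empty-result error: no probe in the dataset is annotated")
  n_unmapped <- length(probes) - length(mapped)
  if (n_unmapped)
    message("collapse_probes: dropping ", n_unmapped, " unmapped probe(s)")
  genes <- map[mapped]
  gene_order <- unique(unname(genes))
  sums <- rowsum(ds$values[mapped, , drop = FALSE], group = unname(genes))
  counts <- as.vector(table(factor(unname(genes), levels = rownames(sums))))
  means <- sums / counts
  means <- means[gene_order, , drop = FALSE]
  out <- expression_dataset(means, as.character(ds$labels))
  attr(out, "collapse_report") <- list(n_probes_in = length(probes),
                                       n_unmapped = n_unmapped,
                                       n_genes_out = length(gene_order))
  out
}

#' Read an undirected protein-interaction network
#'
#' Accepts a two-column edge-list TSV or SIF (`id relation id [id ...]`).
#' Duplicate edges (in either orientation) are collapsed and self-loops
#' dropped, with counts reported via `message()`.
#'
#' @param path Path to the network file.
#' @return An undirected simple [igraph::igraph] with named vertices.
#' @export
read_network <- function(path) {
  lines <- readLines(path, encoding = "UTF-8")
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) stop("format error: network file is empty")
  from <- character(0); to <- character(0)
  for (i in seq_along(lines)) {
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(f) == 1) f <- strsplit(trimws(lines[i]), "[ \t]+")[[1]]
    f <- f[nzchar(f)]
    if (length(f) == 2) {            # edge list
      from <- c(from, f[1]); to <- c(to, f[2])
    } else if (length(f) >= 3) {     # SIF: source relation target [target...]
      from <- c(from, rep(f[1], length(f) - 2)); to <- c(to, f[-(1:2)])
    } else {
      stop("parse error: malformed network line ", i, ": '", lines[i], "'")
    }
  }
  n_loops <- sum(from == to)
  pair_key <- ifelse(from < to, paste(from, to, sep = "\t"),
                     paste(to, from, sep = "\t"))
  keep <- from != to & !duplicated(pair_key)
  n_dup <- sum(from != to) - sum(keep)
  if (n_loops) message("read_network: dropped ", n_loops, " self-loop(s)")
  if (n_dup) message("read_network: collapsed ", n_dup, " duplicate edge(s)")
  if (!any(keep)) stop("format error: network has no usable edges")
  igraph::graph_from_data_frame(data.frame(from = from[keep], to = to[keep]),
                                directed = FALSE)
}

#' @rdname read_network
#' @param net An undirected igraph network.
#' @param path Output path (two-column edge-list TSV).
#' @export
write_network <- function(net, path) {
  el <- igraph::as_edgelist(net)
  write.table(el, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Write / read a subnetwork set (GMT + JSON)
#'
#' The GMT file carries one line per subnetwork (name, score as description,
#' member genes); the JSON file carries the full records (seed, members,
#' score, the three permutation p-values, consensus frequency) and metadata,
#' and round-trips losslessly through [read_subnetworks()].
#'
#' @param s A `subnetwork_set`.
#' @param path_gmt Output path for the GMT file.
#' @param path_json Output path for the JSON file.
#' @return `path_json`, invisibly.
#' @export
write_subnetworks <- function(s, path_gmt, path_json) {
  stopifnot(inherits(s, "subnetwork_set"))
  subs <- s$subnetworks
  if (!length(subs)) warning("writing an empty subnetwork set")
  gmt <- vapply(seq_along(subs), function(i) {
    x <- subs[[i]]
    paste(c(sprintf("subnetwork_%03d_%s", i, x$seed),
            format(x$score, digits = 15), x$members), collapse = "\t")
  }, "")
  writeLines(gmt, path_gmt)
  jsonlite::write_json(list(meta = s$meta, subnetworks = subs), path_json,
                       auto_unbox = TRUE, digits = NA, null = "null",
                       pretty = TRUE)
  invisible(path_json)
}

#' @rdname write_subnetworks
#' @export
read_subnetworks <- function(path_json) {
  raw <- jsonlite::read_json(path_json)
  subs <- lapply(raw$subnetworks, function(x) {
    list(seed = x$seed,
         members = vapply(x$members, identity, ""),
         score = as.numeric(x$score),
         p_gene_null = if (is.null(x$p_gene_null)) NA_real_ else as.numeric(x$p_gene_null),
         p_label_null = if (is.null(x$p_label_null)) NA_real_ else as.numeric(x$p_label_null),
         p_random_null = if (is.null(x$p_random_null)) NA_real_ else as.numeric(x$p_random_null),
         frequency = if (is.null(x$frequency)) NA_integer_ else as.integer(x$frequency))
  })
  subnetwork_set(subs, meta = raw$meta)
}

#' Quantile-normalize an expression matrix
#'
#' Classical sort/average-rank quantile normalization (tied values receive the
#' mean of their tied quantiles), delegated to
#' \code{limma::normalizeQuantiles}. Provided as an optional utility: pipeline
#' inputs are assumed already normalized, so nothing calls this by default.
#'
#' @param values Numeric matrix (genes x samples).
#' @return The normalized matrix, same dimnames.
#' @export
quantile_normalize <- function(values) {
  if (!requireNamespace("limma", quietly = TRUE))
    stop("quantile_normalize() needs the 'limma' package")
  out <- limma::normalizeQuantiles(values, ties = TRUE)
  dimnames(out) <- dimnames(values)
  out
}
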