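# Readers, writers, and probe collapsing.

write_tsv_lines <- function(lines, path) writeLines(lines, path)

make_expr_files <- function(dir, banner = FALSE) {
  expr <- file.path(dir, "expr.tsv")
  labs <- file.path(dir, "labels.tsv")
  lines <- c("gene_id\ts1\ts2\ts3\ts4",
             "gA\t1.5\t2\t3\t4",
             "gB\t0\t-1\t0.5\t2.25",
             "gC\t10\t11\t12\t13")
  if (banner) lines <- c("!Series_title\tdemo", "!platform\tx", lines)
  write_tsv_lines(lines, expr)
  write_tsv_lines(c("sample_id\tclass", "s1\tcase", "s2\tcase",
                    "s3\tcontrol", "s4\tcontrol"), labs)
  list(expr = expr, labels = labs)
}

test_that("expression reading preserves shape, order and labels", {
  d <- withr::local_tempdir()
  f <- make_expr_files(d)
  ds <- read_expression(f$expr, f$labels)
  expect_identical(dim(ds$values), c(3L, 4L))
  expect_identical(gene_ids(ds), c("gA", "gB", "gC"))
  expect_identical(sample_ids(ds), c("s1", "s2", "s3", "s4"))
  expect_identical(as.character(ds$labels), c("case", "case", "control", "control"))
  expect_identical(ds$values["gB", "s4"], 2.25)

  # GEO-style banner lines are skipped transparently
  f2 <- make_expr_files(d, banner = TRUE)
  ds2 <- read_expression(f2$expr, f2$labels)
  expect_identical(ds2$values, ds$values)
})

test_that("expression reading rejects bad files with located errors", {
  d <- withr::local_tempdir()
  f <- make_expr_files(d)

  short <- file.path(d, "short.tsv")
  write_tsv_lines(c("sample_id\tclass", "s1\tcase", "s2\tcase", "s3\tcontrol"),
                  short)
  expect_error(read_expression(f$expr, short), "labeled-data")

  bad <- file.path(d, "bad.tsv")
  write_tsv_lines(c("gene_id\ts1\ts2", "gA\t1\ttwo", "gB\t3\t4"), bad)
  lab2 <- file.path(d, "lab2.tsv")
  write_tsv_lines(c("s1\tcase", "s2\tcontrol"), lab2)
  expect_error(read_expression(bad, lab2), "row 1.*column 2|column 2.*row 1")

  dup <- file.path(d, "dup.tsv")
  write_tsv_lines(c("gene_id\ts1\ts1", "gA\t1\t2"), dup)
  expect_error(read_expression(dup, lab2), "duplicate sample")

  naninf <- file.path(d, "nan.tsv")
  write_tsv_lines(c("gene_id\ts1\ts2", "gA\t1\tNaN", "gB\tInf\t4"), naninf)
  expect_error(read_expression(naninf, lab2), "non-numeric or non-finite")
})

test_that("expression write/read round-trips exactly", {
  d <- withr::local_tempdir()
  vals <- matrix(round(rnorm(20), 6), 5, 4,
                 dimnames = list(paste0("g", 1:5), paste0("s", 1:4)))
  ds <- expression_dataset(vals, c("case", "control", "case", "control"))
  write_expression(ds, file.path(d, "e.tsv"), file.path(d, "l.tsv"))
  back <- read_expression(file.path(d, "e.tsv"), file.path(d, "l.tsv"))
  expect_identical(gene_ids(back), gene_ids(ds))
  expect_identical(sample_ids(back), sample_ids(ds))
  expect_identical(back$labels, ds$labels)
  expect_equal(back$values, ds$values, tolerance = 1e-12)
})

test_that("collapse_probes averages probe rows per gene", {
  vals <- matrix(c(2, 4, 6,   # p1 -> G1
                   4, 8, 10,  # p2 -> G1
                   1, 1, 1,   # p3 -> G2
                   3, 5, 7,   # p4 -> G2
                   5, 9, 4),  # p5 -> G2
                 nrow = 5, byrow = TRUE,
                 dimnames = list(paste0("p", 1:5), paste0("s", 1:3)))
  ds <- expression_dataset(cbind(vals, s4 = 0), c("case", "case", "control", "control"))
  ann <- data.frame(probe_id = paste0("p", 1:5),
                    gene_id = c("G1", "G1", "G2", "G2", "G2"))

  out <- collapse_probes(ds, ann)
  expect_identical(gene_ids(out), c("G1", "G2"))
  # brute-force column-wise means of each gene's probe rows
  expect_equal(out$values["G1", ], colMeans(ds$values[c("p1", "p2"), ]))
  expect_equal(out$values["G2", ], colMeans(ds$values[c("p3", "p4", "p5"), ]))
  expect_identical(out$values["G1", "s1"], 3)  # (2 + 4) / 2

  # column-sum conservation against per-gene probe means
  expect_equal(colSums(out$values),
               colMeans(ds$values[c("p1", "p2"), ]) +
                 colMeans(ds$values[c("p3", "p4", "p5"), ]))
})

test_that("collapse_probes handles identity maps, unmapped probes and misses", {
  vals <- matrix(1:8, 4, 2, dimnames = list(paste0("p", 1:4), c("s1", "s2")))
  ds <- expression_dataset(vals + 0, c("case", "control"))

  ann_id <- data.frame(probe_id = paste0("p", 1:4), gene_id = paste0("G", 1:4))
  out <- collapse_probes(ds, ann_id)
  expect_identical(unname(out$values), unname(ds$values))
  expect_identical(gene_ids(out), paste0("G", 1:4))

  ann_partial <- data.frame(probe_id = c("p1", "p2"), gene_id = c("G", "G"))
  expect_message(out2 <- collapse_probes(ds, ann_partial), "2 unmapped")
  expect_identical(attr(out2, "collapse_report")$n_unmapped, 2L)
  expect_identical(nrow(out2$values), 1L)

  ann_none <- data.frame(probe_id = "q9", gene_id = "G")
  expect_error(collapse_probes(ds, ann_none), "empty-result")
})

test_that("network reading dedups edges, drops self-loops, reads SIF", {
  d <- withr::local_tempdir()
  f <- file.path(d, "net.tsv")
  write_tsv_lines(c("A\tB", "B\tA", "A\tA"), f)
  suppressMessages(net <- read_network(f))
  expect_equal(igraph::vcount(net), 2)
  expect_equal(igraph::ecount(net), 1)

  path4 <- file.path(d, "path.tsv")
  write_tsv_lines(c("a\tb", "b\tc", "c\td"), path4)
  net2 <- read_network(path4)
  degs <- igraph::degree(net2)[c("a", "b", "c", "d")]
  expect_identical(unname(degs), c(1, 2, 2, 1))

  sif <- file.path(d, "net.sif")
  write_tsv_lines(c("a pp b", "b pp c d"), sif)
  net3 <- read_network(sif)
  expect_equal(igraph::ecount(net3), 3)
  expect_true(igraph::are_adjacent(net3, "b", "d"))

  suppressWarnings(expect_error(read_network(file.path(d, "missing-edges.tsv"))))
  empty <- file.path(d, "empty.tsv")
  writeLines(character(0), empty)
  expect_error(read_network(empty), "empty")
  bad <- file.path(d, "bad.tsv")
  write_tsv_lines(c("a\tb", "lonely"), bad)
  expect_error(read_network(bad), "line 2")
})

test_that("duplicate-heavy edge files collapse to the frozen-pair set", {
  withr::local_seed(42)
  d <- withr::local_tempdir()
  n <- 20
  from <- sprintf("n%02d", sample(n, 50, replace = TRUE))
  to <- sprintf("n%02d", sample(n, 50, replace = TRUE))
  # inject 10 explicit duplicates (reversed orientation)
  from <- c(from, to[1:10]); to <- c(to, from[1:10])
  f <- file.path(d, "rand.tsv")
  writeLines(paste(from, to, sep = "\t"), f)
  suppressMessages(net <- read_network(f))
  keep <- from != to
  pairs <- unique(ifelse(from[keep] < to[keep],
                         paste(from[keep], to[keep]),
                         paste(to[keep], from[keep])))
  expect_equal(igraph::ecount(net), length(pairs))

  # idempotence under re-serialization: same node and edge sets
  f2 <- file.path(d, "roundtrip.tsv")
  write_network(net, f2)
  net2 <- read_network(f2)
  expect_setequal(igraph::V(net)$name, igraph::V(net2)$name)
  canon <- function(g) {
    el <- igraph::as_edgelist(g)
    sort(paste(pmin(el[, 1], el[, 2]), pmax(el[, 1], el[, 2])))
  }
  expect_identical(canon(net), canon(net2))
})

test_that("subnetwork sets round-trip through GMT + JSON", {
  d <- withr::local_tempdir()
  subs <- lapply(1:19, function(i)
    list(seed = sprintf("g%03d", i),
         members = sort(sprintf("g%03d", c(i, i + 100, i + 200))),
         score = round(runif(1), 6), p_gene_null = 0.01, p_label_null = 0.02,
         p_random_null = 0.03, frequency = i))
  s <- subnetwork_set(subs, meta = list(run_id = "demo"))
  gmt <- file.path(d, "s.gmt"); js <- file.path(d, "s.json")
  write_subnetworks(s, gmt, js)

  lines <- readLines(gmt)
  expect_length(lines, 19)
  expect_length(strsplit(lines[1], "\t")[[1]], 2 + 3)  # name, score, 3 members

  back <- read_subnetworks(js)
  expect_length(back, 19)
  for (i in seq_along(subs)) expect_equal(back$subnetworks[[i]], subs[[i]])

  empty <- subnetwork_set(list())
  expect_warning(write_subnetworks(empty, gmt, js), "empty")
  expect_length(read_subnetworks(js), 0)
})

test_that("quantile normalization equalizes column distributions", {
  skip_if_not_installed("limma")
  withr::local_seed(7)
  m <- matrix(rexp(300, c(1, 2, 5)), 100, 3,
              dimnames = list(paste0("g", 1:100), paste0("s", 1:3)))
  q <- quantile_normalize(m)
  expect_equal(sort(q[, 1]), sort(q[, 2]), ignore_attr = TRUE)
  expect_equal(sort(q[, 2]), sort(q[, 3]), ignore_attr = TRUE)
  expect_identical(dimnames(q), dimnames(m))
})
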