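# Independent oracles: small, direct implementations kept deliberately
# separate from the package's code paths.

# Plug-in MI (bits) evaluated straight off a joint count table
# (rows = bins, cols = classes).
mi_oracle_table <- function(tab) {
  n <- sum(tab)
  mi <- 0
  for (b in seq_len(nrow(tab))) {
    for (c in seq_len(ncol(tab))) {
      nbc <- tab[b, c]
      if (nbc == 0) next
      pbc <- nbc / n
      mi <- mi + pbc * log2(pbc / ((sum(tab[b, ]) / n) * (sum(tab[, c]) / n)))
    }
  }
  mi
}

# Equal-width binning + table MI, mirroring the stated discretization rule
# but via an independent code path (findInterval).
mi_oracle <- function(act, cls, nbins) {
  lo <- min(act); hi <- max(act)
  if (hi <= lo) return(0)
  edges <- seq(lo, hi, length.out = nbins + 1)
  b <- findInterval(act, edges, rightmost.closed = TRUE, all.inside = TRUE)
  tab <- table(factor(b, levels = seq_len(nbins)), factor(cls, levels = 0:1))
  mi_oracle_table(unclass(tab))
}

# All connected subgraphs containing `seed` (indices into adj), by recursive
# frontier expansion; returns the best mean-z-score MI among them.
exhaustive_best_score <- function(z, cls, adj, seed, nbins, maxsize = nrow(z)) {
  best <- -Inf
  n <- nrow(z)
  score_set <- function(set) {
    act <- colMeans(z[set, , drop = FALSE])
    mi_oracle(act, cls, nbins)
  }
  recurse <- function(set, candidates, banned) {
    s <- score_set(set)
    if (s > best) best <<- s
    if (length(set) >= maxsize) return()
    cand <- setdiff(candidates, banned)
    for (i in seq_along(cand)) {
      v <- cand[i]
      new_cand <- union(candidates, adj[[v]])
      new_cand <- setdiff(new_cand, c(set, v))
      # ban earlier candidates to enumerate each subgraph exactly once
      recurse(c(set, v), new_cand, union(banned, cand[seq_len(i)]))
    }
  }
  recurse(seed, setdiff(adj[[seed]], seed), integer(0))
  best
}

# Naive O(n^3) complete-linkage clustering: returns sorted merge heights.
naive_complete_linkage_heights <- function(d) {
  d <- as.matrix(d)
  n <- nrow(d)
  clusters <- as.list(seq_len(n))
  heights <- numeric(0)
  while (length(clusters) > 1) {
    best <- c(NA, NA); best_h <- Inf
    for (i in seq_len(length(clusters) - 1)) {
      for (j in (i + 1):length(clusters)) {
        h <- max(d[clusters[[i]], clusters[[j]]])
        if (h < best_h) { best_h <- h; best <- c(i, j) }
      }
    }
    heights <- c(heights, best_h)
    merged <- c(clusters[[best[1]]], clusters[[best[2]]])
    clusters <- clusters[-best]
    clusters[[length(clusters) + 1]] <- merged
  }
  sort(heights)
}

# Connectivity check by plain BFS on an edge list (no igraph).
is_connected_set <- function(members, edges) {
  if (length(members) <= 1) return(TRUE)
  nbrs <- function(v) unique(c(edges[edges[, 1] == v, 2], edges[edges[, 2] == v, 1]))
  seen <- members[1]
  frontier <- members[1]
  while (length(frontier)) {
    nxt <- setdiff(intersect(unlist(lapply(frontier, nbrs)), members), seen)
    seen <- c(seen, nxt)
    frontier <- nxt
  }
  setequal(seen, members)
}

# Welch t statistic and two-tailed p computed directly from the formulas.
welch_oracle <- function(x, y) {
  m <- mean(x) - mean(y)
  vx <- var(x) / length(x); vy <- var(y) / length(y)
  t <- m / sqrt(vx + vy)
  df <- (vx + vy)^2 / (vx^2 / (length(x) - 1) + vy^2 / (length(y) - 1))
  c(t = t, p = 2 * pt(-abs(t), df))
}

# A tiny labelled dataset with a perfectly separating pair {A, B} and a noise
# gene C on a path A - B - C; used for constructed greedy instances.
make_path_dataset <- function() {
  # 8 samples, 4 case + 4 control; A and B are each partially informative but
  # their mean activity separates the classes perfectly (MI = 1 bit at 2 bins).
  zA <- c(2, 2, 0, 0, -2, -2, 0, 0)
  zB <- c(0, 0, 2, 2, 0, 0, -2, -2)
  zC <- c(0.10, -0.20, 0.30, -0.40, 0.15, -0.25, 0.35, -0.05)
  vals <- rbind(A = zA, B = zB, C = zC)
  colnames(vals) <- paste0("s", 1:8)
  labels <- rep(c("case", "control"), each = 4)
  ds <- expression_dataset(vals, labels)
  net <- igraph::graph_from_data_frame(
    data.frame(from = c("A", "B"), to = c("B", "C")), directed = FALSE)
  list(ds = ds, net = net)
}

# Random G(n, p) graph as an edge data.frame with letter-free node ids.
random_graph_edges <- function(n, p) {
  pairs <- t(combn(n, 2))
  keep <- runif(nrow(pairs)) < p
  pairs[keep, , drop = FALSE]
}
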