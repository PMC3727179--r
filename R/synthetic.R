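# Synthetic interactome + two-class expression generator with planted,
# partially non-differential modules and a ground-truth record. Emulates the
# statistical structure the search assumes: a sparse PPI-like graph, a subset
# of genes mean-shifted between classes, and "connector" module members whose
# expression carries no class signal at all.

#' Configuration for the synthetic-data generator
#'
#' Defaults are the toy-scale analogue of the study conditions used throughout
#' the package's validation: a 300-gene scale-free interactome, 50 cases vs 50
#' controls, one planted 5-gene module containing one zero-effect connector,
#' a 2-SD mean shift on the remaining members, and unit Gaussian noise.
#'
#' @param n_genes Number of genes (network nodes).
#' @param n_case,n_control Samples per class.
#' @param network_model `"scale_free"` (preferential attachment) or
#'   `"erdos_renyi"`.
#' @param mean_degree Target mean degree of the network.
#' @param n_modules Number of planted, vertex-disjoint modules (0 allowed).
#' @param module_size Genes per module.
#' @param effect_size Class mean shift, in within-class SD units, for
#'   non-connector module members.
#' @param connector_fraction Fraction of each module planted with effect
#'   exactly 0 (rounded up to a member count).
#' @param sign_scheme `"per_module"` (default): all differential members of a
#'   module shift in one random common direction, so the module's mean
#'   activity is an identifiable target for recovery. `"per_gene"`: each
#'   member draws its own sign, producing mixed up/down modules; note that a
#'   module whose directions cancel is invisible to mean-activity scoring by
#'   construction, so recovery benchmarks use the coherent scheme.
#' @param noise_sd Within-class standard deviation of the Gaussian noise.
#' @param seed Integer seed; every generator output is bit-identical under an
#'   identical config.
#' @return A `synthetic_config` list.
#' @export
synthetic_config <- function(n_genes = 300, n_case = 50, n_control = 50,
                             network_model = c("scale_free", "erdos_renyi"),
                             mean_degree = 4, n_modules = 1, module_size = 5,
                             effect_size = 2, connector_fraction = 0.2,
                             sign_scheme = c("per_module", "per_gene"),
                             noise_sd = 1, seed = 1) {
  network_model <- match.arg(network_model)
  sign_scheme <- match.arg(sign_scheme)
  cfg <- list(n_genes = as.integer(n_genes), n_case = as.integer(n_case),
              n_control = as.integer(n_control),
              network_model = network_model, mean_degree = mean_degree,
              n_modules = as.integer(n_modules),
              module_size = as.integer(module_size),
              effect_size = effect_size,
              connector_fraction = connector_fraction,
              sign_scheme = sign_scheme,
              noise_sd = noise_sd, seed = as.integer(seed))
  if (cfg$n_genes < 2) stop("config error: n_genes must be >= 2")
  if (cfg$n_case < 1 || cfg$n_control < 1)
    stop("config error: both classes need >= 1 sample")
  if (cfg$n_modules > 0 && cfg$module_size < 1)
    stop("config error: module_size must be >= 1")
  if (cfg$n_modules * cfg$module_size > cfg$n_genes)
    stop("config error: n_modules * module_size exceeds n_genes")
  if (cfg$effect_size < 0) stop("config error: effect_size must be >= 0")
  if (cfg$connector_fraction < 0 || cfg$connector_fraction > 1)
    stop("config error: connector_fraction must lie in [0, 1]")
  if (cfg$noise_sd <= 0) stop("config error: noise_sd must be > 0")
  if (cfg$mean_degree >= cfg$n_genes)
    stop("config error: mean_degree infeasible for n_genes")
  structure(cfg, class = "synthetic_config")
}

#' Generate a synthetic interactome
#'
#' Scale-free graphs come from undirected preferential attachment with
#' `m = round(mean_degree / 2)` edges per arriving node; Erdos-Renyi graphs
#' from G(n, p) with `p = mean_degree / (n - 1)`. If the largest connected
#' component covers < 90% of nodes the draw is retried; as a last resort the
#' remaining components are bridged to the largest one so downstream module
#' planting always has room.
#'
#' @param cfg A [synthetic_config()].
#' @return An undirected simple igraph with vertices named `g0001`, ...
#' @export
generate_network <- function(cfg) {
  stopifnot(inherits(cfg, "synthetic_config"))
  n <- cfg$n_genes
  with_seed(derive_seed(cfg$seed, 101), {
    net <- NULL
    for (attempt in 1:20) {
      g <- if (cfg$network_model == "scale_free") {
        igraph::sample_pa(n, m = max(1L, as.integer(round(cfg$mean_degree / 2))),
                          directed = FALSE)
      } else {
        igraph::sample_gnp(n, p = min(1, cfg$mean_degree / (n - 1)))
      }
      g <- igraph::simplify(g)
      comp <- igraph::components(g)
      if (max(comp$csize) >= 0.9 * n) { net <- g; break }
      net <- g
    }
    comp <- igraph::components(net)
    if (max(comp$csize) < 0.9 * n) {
      # bridge every smaller component into the largest
      main <- which.max(comp$csize)
      main_nodes <- which(comp$membership == main)
      for (k in seq_len(comp$no)) {
        if (k == main) next
        u <- which(comp$membership == k)[1]
        v <- main_nodes[runif_int(length(main_nodes))]
        net <- igraph::add_edges(net, c(u, v))
      }
    }
    igraph::V(net)$name <- sprintf("g%04d", seq_len(n))
    net
  })
}

runif_int <- function(n) max(1L, min(n, as.integer(ceiling(stats::runif(1) * n))))

#' Plant vertex-disjoint discriminative modules
#'
#' Each module is a connected induced subgraph of exactly `module_size` nodes,
#' grown by seeded random frontier expansion over vertices not yet used by
#' another module. `ceiling(connector_fraction * module_size)` members per
#' module receive effect exactly 0 (the connectors); the rest receive a mean
#' shift of `effect_size` with a per-gene random sign.
#'
#' @param net Network from [generate_network()].
#' @param cfg A [synthetic_config()].
#' @return A `synthetic_truth` list: `modules` (list of member vectors),
#'   `effect` (named signed effect per gene, 0 off-module and for connectors),
#'   and `de_flag` (`effect != 0`).
#' @export
plant_modules <- function(net, cfg) {
  stopifnot(inherits(cfg, "synthetic_config"))
  genes <- igraph::V(net)$name
  effect <- setNames(numeric(length(genes)), genes)
  modules <- list()
  if (cfg$n_modules > 0) {
    adj <- lapply(igraph::as_adj_list(net), as.integer)
    with_seed(derive_seed(cfg$seed, 202), {
      used <- logical(length(genes))
      for (m in seq_len(cfg$n_modules)) {
        placed <- NULL
        for (attempt in 1:200) {
          avail <- which(!used)
          if (length(avail) < cfg$module_size) break
          start <- avail[runif_int(length(avail))]
          members <- start
          frontier <- setdiff(adj[[start]], which(used))
          while (length(members) < cfg$module_size && length(frontier)) {
            pick <- frontier[runif_int(length(frontier))]
            members <- c(members, pick)
            frontier <- setdiff(unique(c(frontier, adj[[pick]])),
                                c(members, which(used)))
          }
          if (length(members) == cfg$module_size) { placed <- members; break }
        }
        if (is.null(placed))
          stop("placement error: could not place ", cfg$n_modules,
               " disjoint connected module(s) of size ", cfg$module_size)
        used[placed] <- TRUE
        member_ids <- lex_sort(genes[placed])
        n_conn <- ceiling(cfg$connector_fraction * cfg$module_size)
        conn <- if (n_conn > 0) sample(member_ids, n_conn) else character(0)
        de <- setdiff(member_ids, conn)
        signs <- if (cfg$sign_scheme == "per_module") {
          rep(sample(c(-1, 1), 1), length(de))
        } else {
          sample(c(-1, 1), length(de), replace = TRUE)
        }
        effect[de] <- cfg$effect_size * signs
        modules[[m]] <- member_ids
      }
    })
  }
  structure(list(modules = modules, effect = effect, de_flag = effect != 0),
            class = "synthetic_truth")
}

#' Generate a two-class expression dataset from a planted truth
#'
#' `value(g, s) = mu_g + effect(g) * 1[s is case] + eps` with
#' `mu_g ~ N(0, 1)` and `eps ~ N(0, noise_sd)`.
#'
#' @param net Network whose genes are measured.
#' @param truth A `synthetic_truth` from [plant_modules()].
#' @param cfg A [synthetic_config()].
#' @return An [expression_dataset()] with `n_case + n_control` samples.
#' @export
generate_expression <- function(net, truth, cfg) {
  stopifnot(inherits(cfg, "synthetic_config"), inherits(truth, "synthetic_truth"))
  genes <- igraph::V(net)$name
  if (!all(names(truth$effect) %in% genes))
    stop("truth genes must be a subset of network nodes")
  n_s <- cfg$n_case + cfg$n_control
  samples <- c(sprintf("case_%03d", seq_len(cfg$n_case)),
               sprintf("control_%03d", seq_len(cfg$n_control)))
  labels <- rep(c("case", "control"), c(cfg$n_case, cfg$n_control))
  with_seed(derive_seed(cfg$seed, 303), {
    mu <- rnorm(length(genes))
    eff <- truth$effect[genes]
    eff[is.na(eff)] <- 0
    case_ind <- rep(c(1, 0), c(cfg$n_case, cfg$n_control))
    vals <- matrix(rnorm(length(genes) * n_s, sd = cfg$noise_sd),
                   length(genes), n_s,
                   dimnames = list(genes, samples))
    vals <- vals + mu + outer(eff, case_ind)
    expression_dataset(vals, setNames(labels, samples))
  })
}

#' One-call synthetic study: network, truth, expression
#'
#' @param cfg A [synthetic_config()].
#' @return A list with elements `network`, `truth`, `dataset`.
#' @export
simulate_dataset <- function(cfg = synthetic_config()) {
  net <- generate_network(cfg)
  truth <- plant_modules(net, cfg)
  ds <- generate_expression(net, truth, cfg)
  list(network = net, truth = truth, dataset = ds)
}
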