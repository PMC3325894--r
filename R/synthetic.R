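# Synthetic fixture generator. Emulates the statistical structure PeC
# exploits in real interactomes: dense protein-complex-like clusters whose
# members share correlated expression and are enriched for essentiality,
# embedded in a sparse background, plus decoy hubs whose neighbors are
# mutually unconnected and uncorrelated (the pattern behind high-degree,
# low-PeC false positives).

#' Parameters of a synthetic interactome fixture
#'
#' Defaults define the package's reference study conditions: a 500-protein
#' network with ten 12-member clusters wired at density 0.8 over a 0.01
#' background, ten degree-15 decoy hubs, 36 expression samples (the sample
#' count of the yeast compendium the method was designed around), a
#' within-cluster expression correlation of 0.8, and essentiality rates of
#' 0.8 inside clusters versus 0.1 outside.
#'
#' @param n_nodes Total number of proteins.
#' @param n_clusters,cluster_size Number and size of planted clusters.
#' @param p_in,p_out Within-cluster and background edge probabilities
#'   (`0 <= p_out < p_in <= 1`).
#' @param n_hub_decoys,hub_degree Number of decoy hubs and the degree given
#'   to each.
#' @param s_samples Number of expression samples per protein (>= 2).
#' @param rho_in Target pairwise expression correlation within a cluster, in
#'   `[0, 1)`.
#' @param essential_prob_cluster,essential_prob_background Probability that a
#'   cluster member / any other protein is essential.
#' @param seed Integer RNG seed; generation is fully reproducible from it.
#' @return A validated list of class `"synthetic_spec"`.
#' @export
synthetic_spec <- function(n_nodes = 500L, n_clusters = 10L,
                           cluster_size = 12L, p_in = 0.8, p_out = 0.01,
                           n_hub_decoys = 10L, hub_degree = 15L,
                           s_samples = 36L, rho_in = 0.8,
                           essential_prob_cluster = 0.8,
                           essential_prob_background = 0.1,
                           seed = 42L) {
  spec <- list(n_nodes = as.integer(n_nodes), n_clusters = as.integer(n_clusters),
               cluster_size = as.integer(cluster_size), p_in = p_in,
               p_out = p_out, n_hub_decoys = as.integer(n_hub_decoys),
               hub_degree = as.integer(hub_degree),
               s_samples = as.integer(s_samples), rho_in = rho_in,
               essential_prob_cluster = essential_prob_cluster,
               essential_prob_background = essential_prob_background,
               seed = as.integer(seed))
  n_cluster_nodes <- spec$n_clusters * spec$cluster_size
  n_background <- spec$n_nodes - n_cluster_nodes - spec$n_hub_decoys
  if (n_cluster_nodes > spec$n_nodes) {
    stop("n_clusters * cluster_size exceeds n_nodes")
  }
  if (n_background < spec$hub_degree && spec$n_hub_decoys > 0L) {
    stop("not enough background nodes to attach hub_degree neighbors")
  }
  if (!(spec$p_out >= 0 && spec$p_out < spec$p_in && spec$p_in <= 1)) {
    stop("edge probabilities must satisfy 0 <= p_out < p_in <= 1")
  }
  if (spec$rho_in < 0 || spec$rho_in >= 1) stop("rho_in must be in [0, 1)")
  probs <- c(spec$essential_prob_cluster, spec$essential_prob_background)
  if (any(probs < 0 | probs > 1)) stop("essentiality probabilities must be in [0, 1]")
  if (spec$s_samples < 2L) stop("s_samples must be at least 2")
  structure(spec, class = "synthetic_spec")
}

#' Generate a synthetic network, expression matrix and annotation
#'
#' Builds a planted-partition graph (same-cluster pairs wired with `p_in`,
#' all other non-hub pairs with `p_out`), attaches each decoy hub to
#' `hub_degree` sampled background proteins and removes any edges among that
#' neighbor set, draws expression profiles as
#' `sqrt(rho_in) * cluster latent + sqrt(1 - rho_in) * noise` (i.i.d.
#' standard-normal samples; pure noise for hubs and background), and labels
#' essentiality Bernoulli per role. Identical spec and seed give identical
#' output.
#'
#' @param spec A [synthetic_spec()].
#' @return A list with elements `network` (igraph), `expression` (matrix),
#'   `annotation` (named status vector), `membership` (`data.frame` with
#'   `protein`, `role` in cluster/hub/background, `cluster` id or `NA`), and
#'   the `spec`.
#' @export
generate_fixture <- function(spec = synthetic_spec()) {
  stopifnot(inherits(spec, "synthetic_spec"))
  set.seed(spec$seed)
  n <- spec$n_nodes
  ids <- sprintf("P%04d", seq_len(n))
  n_cl <- spec$n_clusters * spec$cluster_size
  cluster_of <- rep(NA_integer_, n)
  if (n_cl > 0L) cluster_of[seq_len(n_cl)] <- rep(seq_len(spec$n_clusters),
                                                  each = spec$cluster_size)
  hub_idx <- if (spec$n_hub_decoys > 0L) n_cl + seq_len(spec$n_hub_decoys) else integer(0L)
  role <- rep("background", n)
  role[seq_len(n_cl)] <- "cluster"
  role[hub_idx] <- "hub"
  bg_idx <- which(role == "background")

  # planted-partition wiring over all non-hub nodes
  nonhub <- which(role != "hub")
  edges <- matrix(integer(0L), ncol = 2L)
  if (length(nonhub) >= 2L) {
    pr <- utils::combn(nonhub, 2L)
    same <- !is.na(cluster_of[pr[1L, ]]) & !is.na(cluster_of[pr[2L, ]]) &
      cluster_of[pr[1L, ]] == cluster_of[pr[2L, ]]
    p <- ifelse(same, spec$p_in, spec$p_out)
    keep <- stats::runif(ncol(pr)) < p
    edges <- t(pr[, keep, drop = FALSE])
  }

  # decoy hubs: attach to sampled background nodes, then disconnect those
  # neighbors from one another so each hub's neighborhood is edge-free
  for (h in hub_idx) {
    nbrs <- sample(bg_idx, spec$hub_degree)
    edges <- rbind(edges, cbind(h, nbrs))
    lo <- pmin(edges[, 1L], edges[, 2L])
    hi <- pmax(edges[, 1L], edges[, 2L])
    forbidden <- lo %in% nbrs & hi %in% nbrs
    edges <- edges[!forbidden, , drop = FALSE]
  }

  net <- ppi_network(data.frame(u = ids[edges[, 1L]], v = ids[edges[, 2L]],
                                stringsAsFactors = FALSE),
                     nodes = ids)

  # expression: shared latent per cluster plus independent noise
  s <- spec$s_samples
  latent <- matrix(stats::rnorm(spec$n_clusters * s), nrow = spec$n_clusters)
  noise <- matrix(stats::rnorm(n * s), nrow = n)
  expr <- noise
  in_cl <- !is.na(cluster_of)
  if (any(in_cl)) {
    expr[in_cl, ] <- sqrt(spec$rho_in) * latent[cluster_of[in_cl], , drop = FALSE] +
      sqrt(1 - spec$rho_in) * noise[in_cl, , drop = FALSE]
  }
  dimnames(expr) <- list(ids, sprintf("S%02d", seq_len(s)))

  p_ess <- ifelse(role == "cluster", spec$essential_prob_cluster,
                  spec$essential_prob_background)
  ann <- stats::setNames(
    ifelse(stats::runif(n) < p_ess, "essential", "nonessential"), ids)

  list(network = net,
       expression = expr,
       annotation = ann,
       membership = data.frame(protein = ids, role = role,
                               cluster = cluster_of,
                               stringsAsFactors = FALSE),
       spec = spec)
}

#' Hub-versus-clique contrast fixture
#'
#' Two disjoint components of equal degree k: a star hub whose k leaves carry
#' independent noise profiles, and a (k+1)-clique whose members share one
#' profile. Degree cannot tell the hub and a clique member apart; PeC can,
#' because every clique edge has ECC = 1 and PCC = 1 while the hub's pendant
#' edges have near-zero correlation.
#'
#' @param k Hub degree (and clique member degree); the clique has k + 1
#'   members.
#' @param s Number of expression samples.
#' @param seed Optional integer seed.
#' @return List with `network`, `expression`, and the identifiers `hub` and
#'   `clique_member` to compare.
#' @export
generate_decoy_contrast <- function(k = 10L, s = 36L, seed = NULL) {
  stopifnot(k >= 1L, s >= 2L)
  if (!is.null(seed)) set.seed(seed)
  hub <- "HUB000"
  leaves <- sprintf("LEAF%03d", seq_len(k))
  clique <- sprintf("CLQ%03d", seq_len(k + 1L))
  star_edges <- data.frame(u = hub, v = leaves, stringsAsFactors = FALSE)
  cl_pairs <- utils::combn(clique, 2L)
  edges <- rbind(star_edges,
                 data.frame(u = cl_pairs[1L, ], v = cl_pairs[2L, ],
                            stringsAsFactors = FALSE))
  net <- ppi_network(edges)
  shared <- stats::rnorm(s)
  expr <- rbind(
    matrix(stats::rnorm((k + 1L) * s), nrow = k + 1L,
           dimnames = list(c(hub, leaves), NULL)),
    matrix(rep(shared, each = k + 1L), nrow = k + 1L,
           dimnames = list(clique, NULL))
  )
  colnames(expr) <- sprintf("S%02d", seq_len(s))
  list(network = net, expression = expr, hub = hub,
       clique_member = clique[1L])
}
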