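# PeC centrality: edge clustering coefficient (ECC), edge co-clustering
# probability pc = ECC x PCC, and the per-protein sums PeC, SoECC, SoPCC.

#' Score vector constructor
#'
#' A score vector is a named numeric vector covering every network node, with
#' a `measure` attribute naming the centrality it came from.
#'
#' @param values Named numeric vector (names = protein identifiers).
#' @param measure Label of the measure.
#' @return The validated score vector.
#' @export
score_vector <- function(values, measure) {
  stopifnot(is.numeric(values), !is.null(names(values)))
  if (any(!is.finite(values))) stop("scores must be finite")
  attr(values, "measure") <- measure
  values
}

#' Edge clustering coefficient of one interaction
#'
#' For an edge (u, v) the ECC is the common-neighbor form
#' \deqn{ECC(u,v) = \frac{|N_u \cap N_v| + 1}{\min\{d_u, d_v\}}}
#' which stays informative in networks with few triangles: a pendant edge
#' scores 1 instead of the 0 a triangle-count form would give. The value is
#' always in (0, 1] and is largest when the sparser endpoint's neighborhood
#' is nested in the other's, i.e. when the two proteins are likely members of
#' one dense cluster.
#'
#' @param net An `igraph` network.
#' @param u,v Protein identifiers joined by an edge.
#' @return The ECC, a single value in (0, 1].
#' @export
ecc <- function(net, u, v) {
  .check_protein(net, u)
  .check_protein(net, v)
  if (!igraph::are_adjacent(net, u, v)) {
    stop("ECC is defined for edges only: no interaction between ",
         u, " and ", v)
  }
  nu <- ppi_neighbors(net, u)
  nv <- ppi_neighbors(net, v)
  (length(intersect(nu, nv)) + 1) / min(length(nu), length(nv))
}

#' Edge clustering coefficient for every edge
#'
#' Vectorized whole-network computation (common-neighbor counts via one
#' sparse matrix product); evaluation layers compute this table once per
#' frozen graph and reuse it.
#'
#' @param net An `igraph` network.
#' @return A `data.frame` with columns `u`, `v`, `ecc` (canonical edge order
#'   as in [ppi_edges()]).
#' @export
edge_ecc <- function(net) {
  ed <- ppi_edges(net)
  if (nrow(ed) == 0L) {
    ed$ecc <- numeric(0L)
    return(ed)
  }
  a <- igraph::as_adjacency_matrix(net, sparse = TRUE)
  common <- Matrix::crossprod(a)[cbind(match(ed$u, rownames(a)),
                                       match(ed$v, rownames(a)))]
  deg <- igraph::degree(net)
  ed$ecc <- (as.numeric(common) + 1) / pmin(deg[ed$u], deg[ed$v])
  ed
}

#' Co-clustering probability of one interaction
#'
#' The probability that two interacting proteins sit in the same cluster,
#' read jointly from topology and expression:
#' \deqn{p_c(u,v) = ECC(u,v) \times PCC(u,v)}
#' Missing or degenerate expression on either endpoint gives 0.
#'
#' @inheritParams ecc
#' @param expr Numeric expression matrix with protein rownames.
#' @return A single value in \eqn{[-1, 1]}.
#' @export
pc_edge <- function(net, expr, u, v) {
  e <- ecc(net, u, v)
  r <- 0
  if (u %in% rownames(expr) && v %in% rownames(expr)) {
    r <- tryCatch(pcc(expr[u, ], expr[v, ]),
                  pecnet_degenerate_profile = function(cond) 0)
  }
  e * r
}

#' Per-edge ECC, PCC and co-clustering probability
#'
#' @param net An `igraph` network.
#' @param expr Numeric expression matrix with protein rownames.
#' @return A `data.frame` with columns `u`, `v`, `ecc`, `pcc`,
#'   `pc = ecc * pcc`, one row per edge in canonical order.
#' @export
edge_scores <- function(net, expr) {
  ed <- edge_ecc(net)
  ed$pcc <- edge_pcc(net, expr)$pcc
  ed$pc <- ed$ecc * ed$pcc
  ed
}

# Sum per-edge values into per-node scores over the full node set.
.sum_incident <- function(net, u, v, w, measure) {
  scores <- stats::setNames(numeric(igraph::vcount(net)),
                            igraph::V(net)$name)
  if (length(w) > 0L) {
    agg <- rowsum(c(w, w), group = c(u, v))
    scores[rownames(agg)] <- agg[, 1L]
  }
  score_vector(scores, measure)
}

#' PeC centrality
#'
#' Scores each protein by the summed probability that it and its neighbors
#' belong to one cluster:
#' \deqn{PeC(v) = \sum_{u \in N_v} p_c(u, v)
#'             = \sum_{u \in N_v} ECC(u,v)\, PCC(u,v)}
#' A highly connected protein scores high only when its neighborhood is both
#' densely interconnected and co-expressed; hubs with mutually unconnected or
#' uncorrelated neighbors score near 0, which is what distinguishes PeC from
#' pure-topology centralities. Negative correlations propagate, so PeC can be
#' negative. Isolated proteins and proteins without expression data score 0.
#'
#' @param net An `igraph` network.
#' @param expr Numeric expression matrix with protein rownames.
#' @return A [score_vector()] over all nodes, measure `"PeC"`.
#' @export
pec_scores <- function(net, expr) {
  es <- edge_scores(net, expr)
  .sum_incident(net, es$u, es$v, es$pc, "PeC")
}

#' Sum of edge clustering coefficients
#'
#' The pure-topology reduction of PeC: \eqn{SoECC(v) = \sum_{u \in N_v}
#' ECC(u,v)}. Equals PeC when every profile is a positive affine copy of one
#' profile (PCC identically 1).
#'
#' @param net An `igraph` network.
#' @return A [score_vector()], measure `"SoECC"`.
#' @export
soecc_scores <- function(net) {
  es <- edge_ecc(net)
  .sum_incident(net, es$u, es$v, es$ecc, "SoECC")
}

#' Sum of neighbor expression correlations
#'
#' Diagnostic aggregate \eqn{SoPCC(v) = \sum_{u \in N_v} PCC(u,v)}; bounded
#' by the degree.
#'
#' @inheritParams pec_scores
#' @return A [score_vector()], measure `"SoPCC"`.
#' @export
sopcc_scores <- function(net, expr) {
  es <- edge_pcc(net, expr)
  .sum_incident(net, es$u, es$v, es$pcc, "SoPCC")
}

#' Average co-clustering and co-expression of a neighborhood
#'
#' Returns `SoECC(v)/d_v` and `SoPCC(v)/d_v`: how strongly protein `v` is
#' co-clustered, respectively co-expressed, with its neighbors on average.
#' Used to diagnose high-degree proteins whose PeC is nevertheless low.
#'
#' @inheritParams pec_scores
#' @param v A protein identifier with degree >= 1.
#' @return Named numeric vector `c(avg_ecc = , avg_pcc = )`.
#' @export
neighborhood_averages <- function(net, expr, v) {
  .check_protein(net, v)
  d <- ppi_degree(net, v)
  if (d == 0L) stop("average undefined for degree 0: ", v)
  nb <- ppi_neighbors(net, v)
  e <- vapply(nb, function(u) ecc(net, u, v), numeric(1L))
  z <- .standardized_profiles(expr)
  r <- vapply(nb, function(u) {
    if (u %in% rownames(z) && v %in% rownames(z)) {
      min(1, max(-1, sum(z[u, ] * z[v, ]) / (ncol(z) - 1L)))
    } else 0
  }, numeric(1L))
  c(avg_ecc = mean(e), avg_pcc = mean(r))
}
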