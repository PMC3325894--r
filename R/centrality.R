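# Comparison centralities benchmarked against PeC. Degree, betweenness and
# closeness delegate to igraph; the remaining measures (subgraph, eigenvector,
# information, bottleneck, DMNC, LAC, lobby index, LeaderRank, normalized
# alpha-centrality) are implemented here.

.node_names <- function(net) igraph::V(net)$name

.dense_adjacency <- function(net) {
  as.matrix(igraph::as_adjacency_matrix(net, sparse = TRUE))
}

#' Degree centrality
#' @param net An `igraph` network.
#' @return A [score_vector()], measure `"DC"`.
#' @export
dc_scores <- function(net) {
  score_vector(igraph::degree(net), "DC")
}

#' Shortest-path betweenness centrality
#'
#' Brandes accumulation over geodesics; each unordered pair is counted once
#' and pairs in other components contribute 0.
#' @param net An `igraph` network.
#' @return A [score_vector()], measure `"BC"`.
#' @export
bc_scores <- function(net) {
  score_vector(igraph::betweenness(net, directed = FALSE), "BC")
}

#' Closeness centrality (per connected component)
#'
#' For node v in a component of size n_c, closeness is
#' (n_c - 1) / sum of distances to the other members; isolated nodes score 0.
#' @param net An `igraph` network.
#' @return A [score_vector()], measure `"CC"`.
#' @export
cc_scores <- function(net) {
  cl <- suppressWarnings(igraph::closeness(net, normalized = TRUE))
  cl[!is.finite(cl)] <- 0
  score_vector(cl, "CC")
}

#' Subgraph centrality
#'
#' Weighted count of closed walks through each node,
#' \eqn{SC(v) = \sum_k (A^k)_{vv}/k! = \sum_j \phi_j(v)^2 e^{\lambda_j}},
#' computed by eigendecomposition of the adjacency matrix. An isolated node
#' scores 1 (the k = 0 term).
#' @param net An `igraph` network.
#' @return A [score_vector()], measure `"SC"`.
#' @export
sc_scores <- function(net) {
  a <- .dense_adjacency(net)
  e <- eigen(a, symmetric = TRUE)
  sc <- as.numeric((e$vectors^2) %*% exp(e$values))
  score_vector(stats::setNames(sc, rownames(a)), "SC")
}

#' Eigenvector centrality
#'
#' Principal eigenvector of the adjacency matrix, non-negative and scaled to
#' unit Euclidean norm.
#' @param net An `igraph` network.
#' @return A [score_vector()], measure `"EC"`.
#' @export
ec_scores <- function(net) {
  a <- .dense_adjacency(net)
  if (nrow(a) == 0L) return(score_vector(stats::setNames(numeric(0L), character(0L)), "EC"))
  e <- eigen(a, symmetric = TRUE)
  v1 <- abs(e$vectors[, 1L])
  nrm <- sqrt(sum(v1^2))
  if (nrm > 0) v1 <- v1 / nrm
  score_vector(stats::setNames(v1, rownames(a)), "EC")
}

#' Information centrality (Stephenson-Zelen)
#'
#' Per connected component of size n_c, with B = (L + J)^{-1} (Laplacian plus
#' all-ones), the harmonic form
#' \eqn{I_v = [ (1/n_c) \sum_u (B_{vv} + B_{uu} - 2 B_{uv}) ]^{-1}}.
#' Computing per component avoids the singular whole-graph Laplacian;
#' isolated nodes score 0.
#' @param net An `igraph` network.
#' @return A [score_vector()], measure `"IC"`.
#' @export
ic_scores <- function(net) {
  nms <- .node_names(net)
  out <- stats::setNames(numeric(length(nms)), nms)
  comp <- igraph::components(net)
  for (ci in seq_len(comp$no)) {
    members <- nms[comp$membership == ci]
    nc <- length(members)
    if (nc < 2L) next
    sub <- igraph::induced_subgraph(net, members)
    a <- .dense_adjacency(sub)
    l <- diag(rowSums(a)) - a
    b <- solve(l + 1)
    d <- diag(b)
    out[rownames(a)] <- nc / (nc * d + sum(d) - 2 * rowSums(b))
  }
  score_vector(out, "IC")
}

# Sorted adjacency lists keyed by name; BFS tie-breaking is lexicographic.
.sorted_adjacency_list <- function(net) {
  nms <- .node_names(net)
  al <- igraph::as_adj_list(net)
  out <- lapply(al, function(x) sort(x$name))
  names(out) <- nms
  out
}

#' Bottleneck centrality
#'
#' For each root, one BFS shortest-path tree is grown (neighbors explored in
#' lexicographic identifier order, so the tree is deterministic); a node is a
#' bottleneck of that tree when its subtree, itself included, holds strictly
#' more than a quarter of the root's component. BN(v) counts the roots for
#' which v is a bottleneck.
#' @param net An `igraph` network.
#' @return A [score_vector()], measure `"BN"`.
#' @export
bn_scores <- function(net) {
  nms <- .node_names(net)
  adj <- .sorted_adjacency_list(net)
  comp <- igraph::components(net)
  csize <- comp$csize[comp$membership]
  names(csize) <- nms
  score <- stats::setNames(numeric(length(nms)), nms)
  for (root in nms) {
    nc <- csize[[root]]
    order_ <- character(nc)
    parent_of <- stats::setNames(rep(NA_character_, nc), character(nc))
    seen <- stats::setNames(logical(length(nms)), nms)
    order_[1L] <- root
    seen[root] <- TRUE
    head <- 1L
    tail <- 1L
    while (head <= tail) {
      x <- order_[head]
      for (nb in adj[[x]]) {
        if (!seen[[nb]]) {
          seen[nb] <- TRUE
          tail <- tail + 1L
          order_[tail] <- nb
          parent_of[tail] <- x
        }
      }
      head <- head + 1L
    }
    names(parent_of) <- order_
    ndesc <- stats::setNames(rep(1L, tail), order_)
    for (i in rev(seq_len(tail))) {
      p <- parent_of[[i]]
      if (!is.na(p)) ndesc[p] <- ndesc[[p]] + ndesc[[i]]
    }
    hit <- names(ndesc)[ndesc > nc / 4]
    score[hit] <- score[hit] + 1
  }
  score_vector(score, "BN")
}

#' Density of maximum neighborhood component
#'
#' Take the largest connected component of the subgraph induced by a node's
#' neighbors (the MNC; ties broken by edge count); the score is
#' \eqn{E_{MNC} / N_{MNC}^{1.7}} with the published exponent 1.7. Nodes whose
#' MNC has at most one member score 0.
#' @param net An `igraph` network.
#' @return A [score_vector()], measure `"DMNC"`.
#' @export
dmnc_scores <- function(net) {
  nms <- .node_names(net)
  score <- stats::setNames(numeric(length(nms)), nms)
  for (v in nms) {
    nb <- igraph::neighbors(net, v)$name
    if (length(nb) < 2L) next
    sub <- igraph::induced_subgraph(net, nb)
    comp <- igraph::components(sub)
    sizes <- comp$csize
    cand <- which(sizes == max(sizes))
    best_e <- -1L
    best_n <- 0L
    for (ci in cand) {
      mem <- which(comp$membership == ci)
      ecnt <- igraph::ecount(igraph::induced_subgraph(sub, mem))
      if (ecnt > best_e) {
        best_e <- ecnt
        best_n <- sizes[ci]
      }
    }
    if (best_n > 1L) score[v] <- best_e / best_n^1.7
  }
  score_vector(score, "DMNC")
}

#' Local average connectivity
#'
#' Mean degree of a node's neighbors inside the subgraph they induce:
#' \eqn{LAC(v) = (1/d_v) \sum_{u \in N_v} deg_{G[N_v]}(u)}. Degree-0 nodes
#' score 0.
#' @param net An `igraph` network.
#' @return A [score_vector()], measure `"LAC"`.
#' @export
lac_scores <- function(net) {
  nms <- .node_names(net)
  score <- stats::setNames(numeric(length(nms)), nms)
  for (v in nms) {
    nb <- igraph::neighbors(net, v)$name
    if (length(nb) == 0L) next
    sub <- igraph::induced_subgraph(net, nb)
    score[v] <- mean(igraph::degree(sub))
  }
  score_vector(score, "LAC")
}

#' Lobby index (L-index)
#'
#' The largest l such that the node has at least l neighbors each of degree
#' at least l; an h-index over neighbor degrees.
#' @param net An `igraph` network.
#' @return A [score_vector()], measure `"LI"`.
#' @export
li_scores <- function(net) {
  nms <- .node_names(net)
  deg <- igraph::degree(net)
  score <- stats::setNames(numeric(length(nms)), nms)
  for (v in nms) {
    nd <- sort(deg[igraph::neighbors(net, v)$name], decreasing = TRUE)
    if (length(nd) > 0L) score[v] <- sum(nd >= seq_along(nd))
  }
  score_vector(score, "LI")
}

#' LeaderRank
#'
#' Parameter-free random-walk ranking: a ground node linked to every protein
#' is added, unit score is placed on each protein (0 on the ground), and the
#' degree-normalized walk is iterated to stationarity; the ground node's
#' final score is then shared equally among the proteins. Scores sum to the
#' number of proteins.
#'
#' @param net An `igraph` network.
#' @param tol Convergence tolerance on the max absolute score change.
#' @param max_iter Iteration cap.
#' @return A [score_vector()], measure `"LR"`.
#' @export
lr_scores <- function(net, tol = 1e-10, max_iter = 1e5) {
  nms <- .node_names(net)
  n <- length(nms)
  if (n == 0L) return(score_vector(stats::setNames(numeric(0L), character(0L)), "LR"))
  a <- igraph::as_adjacency_matrix(net, sparse = TRUE)
  deg <- igraph::degree(net)
  s <- rep(1, n)          # protein scores
  sg <- 0                 # ground-node score
  outdeg <- deg + 1       # every protein also links to the ground node
  for (it in seq_len(max_iter)) {
    w <- s / outdeg
    s_new <- as.numeric(a %*% w) + sg / n
    sg_new <- sum(w)
    delta <- max(abs(s_new - s), abs(sg_new - sg))
    s <- s_new
    sg <- sg_new
    if (delta < tol) break
  }
  score_vector(stats::setNames(s + sg / n, nms), "LR")
}

#' Normalized alpha-centrality
#'
#' Solves \eqn{c = \alpha A c + e} with e the all-ones exogenous vector and
#' returns c normalized to unit sum. The default
#' \eqn{\alpha = 0.9 / \lambda_{max}} sits strictly inside the convergence
#' radius of the Katz series the fixed point represents.
#'
#' @param net An `igraph` network.
#' @param alpha Attenuation factor; `NULL` (default) for `0.9 / lambda_max`.
#' @return A [score_vector()], measure `"NC"`.
#' @export
nc_scores <- function(net, alpha = NULL) {
  a <- .dense_adjacency(net)
  n <- nrow(a)
  if (n == 0L) return(score_vector(stats::setNames(numeric(0L), character(0L)), "NC"))
  lam <- max(eigen(a, symmetric = TRUE, only.values = TRUE)$values, 0)
  if (is.null(alpha)) alpha <- if (lam > 0) 0.9 / lam else 0
  if (lam > 0 && abs(alpha) * lam >= 1) {
    stop("alpha must satisfy |alpha| * lambda_max < 1")
  }
  cvec <- solve(diag(n) - alpha * a, rep(1, n))
  cvec <- cvec / sum(cvec)
  score_vector(stats::setNames(cvec, rownames(a)), "NC")
}

# Measures needing only topology, and those that also need expression;
# resolved to <name>_scores functions at call time.
.topology_measures <- c("DC", "BC", "CC", "SC", "EC", "IC", "BN", "DMNC",
                        "LAC", "SoECC", "LI", "LR", "NC")
.expression_measures <- c("PeC", "SoPCC")

.measure_fun <- function(m) {
  get(paste0(tolower(m), "_scores"), envir = asNamespace("pecnet"))
}

#' Available centrality measure names
#' @return Character vector of the measure labels accepted by
#'   [centrality_suite()].
#' @export
centrality_measures <- function() {
  c(.expression_measures, .topology_measures)
}

#' Compute a set of centrality measures
#'
#' @param net An `igraph` network.
#' @param measures Character vector of measure names (see
#'   [centrality_measures()]). Default: all of them when `expr` is given,
#'   otherwise all topology-only measures.
#' @param expr Expression matrix; required for `PeC` and `SoPCC`.
#' @param nc_alpha Attenuation factor passed to [nc_scores()].
#' @return A wide `data.frame`: column `protein` plus one numeric column per
#'   measure, rows sorted by protein identifier.
#' @export
centrality_suite <- function(net, measures = NULL, expr = NULL,
                             nc_alpha = NULL) {
  if (is.null(measures)) {
    measures <- if (is.null(expr)) .topology_measures
                else centrality_measures()
  }
  bad <- setdiff(measures, centrality_measures())
  if (length(bad) > 0L) {
    stop("unknown measure(s) ", paste(bad, collapse = ", "),
         "; valid names are: ", paste(centrality_measures(), collapse = ", "))
  }
  nms <- sort(.node_names(net))
  out <- data.frame(protein = nms, stringsAsFactors = FALSE)
  for (m in measures) {
    sv <- if (m %in% .expression_measures) {
      if (is.null(expr)) stop("measure ", m, " needs an expression matrix")
      .measure_fun(m)(net, expr)
    } else if (m == "NC") {
      nc_scores(net, alpha = nc_alpha)
    } else {
      .measure_fun(m)(net)
    }
    out[[m]] <- unname(sv[nms])
  }
  out
}
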