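# Small in-code fixtures used across tests.

quiet_net <- function(edges, nodes = NULL) {
  suppressMessages(ppi_network(edges, nodes = nodes))
}

edge_df <- function(u, v) data.frame(u = u, v = v, stringsAsFactors = FALSE)

# Erdos-Renyi graph built directly from Bernoulli pair draws (independent of
# igraph's own generators).
er_net <- function(n, p, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  nms <- sprintf("n%02d", seq_len(n))
  pr <- utils::combn(nms, 2L)
  keep <- stats::runif(ncol(pr)) < p
  quiet_net(edge_df(pr[1L, keep], pr[2L, keep]), nodes = nms)
}

# complete graph on the given identifiers
complete_net <- function(nms) {
  pr <- utils::combn(nms, 2L)
  quiet_net(edge_df(pr[1L, ], pr[2L, ]))
}

path_net <- function(nms) {
  quiet_net(edge_df(nms[-length(nms)], nms[-1L]))
}

star_net <- function(center, leaves) {
  quiet_net(edge_df(rep(center, length(leaves)), leaves))
}

cycle_net <- function(nms) {
  quiet_net(edge_df(nms, c(nms[-1L], nms[1L])))
}

# igraph net from a 0/1 adjacency matrix with names (fast path for the
# exhaustive enumeration tests)
net_from_adjacency <- function(a, nms = sprintf("v%02d", seq_len(nrow(a)))) {
  dimnames(a) <- list(nms, nms)
  igraph::graph_from_adjacency_matrix(a, mode = "undirected")
}

# random labelled tree via Pruefer-like attachment
random_tree_net <- function(n, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  nms <- sprintf("t%02d", seq_len(n))
  u <- nms[1L]
  v <- character(0L)
  for (i in 2:n) {
    v <- c(v, sample(nms[seq_len(i - 1L)], 1L))
  }
  quiet_net(edge_df(nms[2:n], v))
}
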