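# Protein-protein interaction network: reading, filtering, querying.
# The network container is an undirected, simple igraph object whose vertex
# names are the protein identifiers (e.g. systematic yeast ORF names).

#' Build a protein-protein interaction network from an edge table
#'
#' Constructs a simple undirected network from a two-column table of
#' interacting protein identifiers. Self-interactions and repeated
#' interactions (in either node order) are removed, and the number of records
#' dropped by each filter is reported via [message()].
#'
#' @param edges A two-column `data.frame`, matrix, or list whose first two
#'   columns hold the interacting protein identifiers. Extra columns
#'   (confidence scores, interaction types) are ignored.
#' @param nodes Optional character vector of additional protein identifiers
#'   to include as (possibly isolated) nodes. Scoring must cover every
#'   protein in the study even when it has no surviving interaction, so
#'   isolated nodes are first-class.
#'
#' @return An undirected simple `igraph` graph with vertex `name`
#'   attributes.
#' @export
#' @examples
#' net <- ppi_network(data.frame(u = c("A", "B", "C"), v = c("B", "A", "C")))
#' igraph::ecount(net) # the B-A duplicate and the C-C self-loop are dropped
ppi_network <- function(edges, nodes = NULL) {
  edges <- as.data.frame(edges, stringsAsFactors = FALSE)
  if (ncol(edges) < 2L) {
    stop("edge table must have at least two identifier columns")
  }
  u <- as.character(edges[[1L]])
  v <- as.character(edges[[2L]])
  if (any(!nzchar(u)) || any(!nzchar(v)) ||
      any(grepl("\\s", u)) || any(grepl("\\s", v))) {
    stop("protein identifiers must be non-empty and contain no whitespace")
  }
  self <- u == v
  n_self <- sum(self)
  u2 <- pmin(u[!self], v[!self])
  v2 <- pmax(u[!self], v[!self])
  dup <- duplicated(paste(u2, v2, sep = "\r"))
  n_dup <- sum(dup)
  if (n_self > 0L || n_dup > 0L) {
    message(sprintf("filtered %d self-interaction(s) and %d repeated interaction(s)",
                    n_self, n_dup))
  }
  all_nodes <- sort(unique(c(u, v, as.character(nodes))))
  igraph::graph_from_data_frame(
    data.frame(u = u2[!dup], v = v2[!dup], stringsAsFactors = FALSE),
    directed = FALSE,
    vertices = all_nodes
  )
}

#' Read a protein-protein interaction network from a file
#'
#' Supports plain edge lists (tab- or whitespace-separated; first two columns
#' are the interacting proteins, further columns ignored) and SIF
#' (`node relation target [target ...]`). Lines starting with `#` are
#' comments. Self-interactions and duplicate interactions are filtered as in
#' [ppi_network()].
#'
#' @param path Path to the network file.
#' @param format `"edgelist"` (default) or `"sif"`.
#' @param nodes Optional: a character vector of extra node identifiers, or
#'   the path to a one-identifier-per-line node file, to include as isolated
#'   nodes when they carry no edge.
#'
#' @return An undirected simple `igraph` graph.
#' @export
read_ppi <- function(path, format = c("edgelist", "sif"), nodes = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("network file not found: ", path)
  raw <- readLines(path, warn = FALSE)
  keep <- nzchar(trimws(raw)) & !grepl("^\\s*#", raw)
  lines <- trimws(raw[keep])
  lineno <- which(keep)
  if (length(lines) == 0L) stop("empty network file: ", path)
  fields <- strsplit(lines, "[ \t]+")
  nf <- lengths(fields)
  min_cols <- if (format == "edgelist") 2L else 3L
  bad <- which(nf < min_cols)
  if (length(bad) > 0L) {
    stop(sprintf("malformed %s line %d in %s: expected at least %d fields",
                 format, lineno[bad[1L]], path, min_cols))
  }
  if (format == "edgelist") {
    edges <- data.frame(
      u = vapply(fields, `[[`, character(1L), 1L),
      v = vapply(fields, `[[`, character(1L), 2L),
      stringsAsFactors = FALSE
    )
  } else {
    # SIF: source, relation, one or more targets
    edges <- do.call(rbind, lapply(fields, function(f) {
      data.frame(u = f[1L], v = f[-(1:2)], stringsAsFactors = FALSE)
    }))
  }
  if (is.character(nodes) && length(nodes) == 1L && file.exists(nodes)) {
    nodes <- trimws(readLines(nodes, warn = FALSE))
    nodes <- nodes[nzchar(nodes) & !grepl("^#", nodes)]
  }
  ppi_network(edges, nodes = nodes)
}

#' Canonical edge table of a network
#'
#' @param net An `igraph` network as built by [ppi_network()].
#' @return A `data.frame` with character columns `u`, `v`, each row an
#'   unordered edge written with `u < v` lexicographically, rows sorted.
#' @export
ppi_edges <- function(net) {
  stopifnot(igraph::is_igraph(net))
  el <- igraph::as_edgelist(net, names = TRUE)
  if (nrow(el) == 0L) {
    return(data.frame(u = character(0L), v = character(0L),
                      stringsAsFactors = FALSE))
  }
  u <- pmin(el[, 1L], el[, 2L])
  v <- pmax(el[, 1L], el[, 2L])
  ord <- order(u, v)
  data.frame(u = u[ord], v = v[ord], stringsAsFactors = FALSE)
}

#' Write a network as a canonical edge list
#'
#' Each edge is written once as `u TAB v` with `u < v` lexicographically and
#' lines sorted, so that equal networks serialize to byte-identical files.
#'
#' @param net An `igraph` network.
#' @param path Output path for the edge list.
#' @param nodes_path Optional path for a one-per-line node list; writing it
#'   preserves isolated nodes across a round trip.
#' @return `path`, invisibly.
#' @export
write_ppi <- function(net, path, nodes_path = NULL) {
  ed <- ppi_edges(net)
  writeLines(paste(ed$u, ed$v, sep = "\t"), path)
  if (!is.null(nodes_path)) {
    writeLines(sort(igraph::V(net)$name), nodes_path)
  }
  invisible(path)
}

.check_protein <- function(net, v) {
  if (length(v) != 1L || !is.character(v)) {
    stop("expected a single protein identifier")
  }
  if (!v %in% igraph::V(net)$name) stop("unknown protein: ", v)
  invisible(v)
}

#' Neighbors of a protein
#'
#' @param net An `igraph` network.
#' @param v A protein identifier present in the network.
#' @return Sorted character vector of the neighbors of `v` (never includes
#'   `v` itself; empty for isolated nodes).
#' @export
ppi_neighbors <- function(net, v) {
  .check_protein(net, v)
  sort(igraph::neighbors(net, v)$name)
}

#' Degree of one protein, or of all proteins
#'
#' @param net An `igraph` network.
#' @param v A protein identifier, or `NULL` (default) for a named vector of
#'   all degrees.
#' @return Integer degree(s).
#' @export
ppi_degree <- function(net, v = NULL) {
  if (is.null(v)) {
    return(igraph::degree(net))
  }
  .check_protein(net, v)
  unname(igraph::degree(net, v))
}
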