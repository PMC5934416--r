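#' Read a protein-interaction edge list
#'
#' TSV with columns `node_a`, `node_b`, `combined_score` (extra columns,
#' e.g. per-evidence-channel scores, are kept). Both the 0-1 and the
#' 0-1000 score dialects are accepted; the latter is auto-detected (max
#' score > 1) and rescaled to 0-1. Self-loops are dropped and symmetric
#' duplicates collapsed (the higher score wins).
#'
#' @param path TSV file.
#' @return edge tibble with normalized scores.
#' @export
read_edge_list <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- readr::read_tsv(path, col_types = readr::cols(), progress = FALSE)
  need <- c("node_a", "node_b", "combined_score")
  if (!all(need %in% names(raw))) {
    stop("edge list is missing column(s): ",
         paste(setdiff(need, names(raw)), collapse = ", "), call. = FALSE)
  }
  score <- suppressWarnings(as.numeric(raw$combined_score))
  if (anyNA(score)) {
    stop("malformed combined_score at line ", which(is.na(score))[1] + 1L,
         call. = FALSE)
  }
  raw$combined_score <- score
  normalize_edges(raw)
}

normalize_edges <- function(edges) {
  edges <- tibble::as_tibble(edges)
  if (nrow(edges) && max(edges$combined_score) > 1) {
    edges$combined_score <- edges$combined_score / 1000
  }
  if (nrow(edges) && (min(edges$combined_score) < 0 || max(edges$combined_score) > 1)) {
    stop("combined scores must lie in [0, 1] after rescaling", call. = FALSE)
  }
  edges <- edges[edges$node_a != edges$node_b, ]
  a <- pmin(edges$node_a, edges$node_b)
  b <- pmax(edges$node_a, edges$node_b)
  edges$node_a <- a
  edges$node_b <- b
  edges <- edges[order(edges$node_a, edges$node_b, -edges$combined_score), ]
  edges[!duplicated(edges[, c("node_a", "node_b")]), ]
}

#' Filter edges by confidence score
#'
#' Retains edges at or above the confidence cutoff (medium confidence is
#' 0.4 in the STRING convention) after normalizing orientation and score
#' dialect.
#'
#' @param edges edge tibble (columns `node_a`, `node_b`, `combined_score`).
#' @param min_score minimum combined score.
#' @return filtered edge tibble.
#' @export
filter_edges <- function(edges, min_score = 0.4) {
  edges <- normalize_edges(edges)
  edges[edges$combined_score >= min_score, ]
}

#' Connectivity of a gene set in an interaction network
#'
#' Partitions the gene set into members with at least one interaction
#' inside the induced subgraph and isolated members, with per-node degrees.
#'
#' @param nodes character vector of gene symbols.
#' @param edges edge tibble.
#' @return list with `n_connected`, `n_isolated`, `connected`, `isolated`,
#'   `degrees` (named vector) and `n_edges` in the induced subgraph.
#' @export
connectivity_summary <- function(nodes, edges) {
  nodes <- unique(as.character(nodes))
  edges <- normalize_edges(edges)
  sub <- edges[edges$node_a %in% nodes & edges$node_b %in% nodes, ]
  g <- igraph::graph_from_data_frame(sub[, c("node_a", "node_b")],
                                     directed = FALSE,
                                     vertices = data.frame(name = nodes))
  deg <- igraph::degree(g)
  list(
    n_connected = sum(deg > 0),
    n_isolated = sum(deg == 0),
    connected = names(deg)[deg > 0],
    isolated = names(deg)[deg == 0],
    degrees = deg,
    n_edges = igraph::ecount(g)
  )
}

count_induced_edges <- function(node_sets, edge_a, edge_b) {
  vapply(node_sets, function(nodes) {
    sum(edge_a %in% nodes & edge_b %in% nodes)
  }, numeric(1))
}

#' Permutation test for edge enrichment of a gene set
#'
#' Tests whether a gene set carries more interactions among its members
#' than random sets of the same size drawn uniformly from a background
#' universe: observed = edges in the induced subgraph, expected = mean over
#' permutations, p = (1 + #[perm >= observed]) / (1 + n_perm).
#'
#' @param nodes gene set (must be a subset of `background`).
#' @param edges edge tibble (filter first with [filter_edges()] if a
#'   confidence cutoff applies).
#' @param background character vector: the node universe to resample from.
#' @param n_perm number of permutations (>= 100).
#' @param seed RNG seed.
#' @return list with `observed`, `expected`, `p_value`, `n_perm`,
#'   `perm_counts`.
#' @export
edge_enrichment <- function(nodes, edges, background, n_perm = 1000, seed = NULL) {
  nodes <- unique(as.character(nodes))
  background <- unique(as.character(background))
  if (!all(nodes %in% background)) {
    stop("gene set contains nodes outside the background universe: ",
         paste(setdiff(nodes, background), collapse = ", "), call. = FALSE)
  }
  if (length(nodes) > length(background)) {
    stop("gene set larger than the background universe", call. = FALSE)
  }
  if (n_perm < 100) stop("n_perm must be at least 100", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  edges <- normalize_edges(edges)
  k <- length(nodes)
  observed <- unname(count_induced_edges(list(nodes), edges$node_a, edges$node_b))
  if (k == 0L) {
    return(list(observed = 0, expected = 0, p_value = 1, n_perm = n_perm,
                perm_counts = rep(0, n_perm)))
  }
  draws <- lapply(seq_len(n_perm), function(i) sample(background, k))
  perm_counts <- count_induced_edges(draws, edges$node_a, edges$node_b)
  list(
    observed = observed,
    expected = mean(perm_counts),
    p_value = (1 + sum(perm_counts >= observed)) / (1 + n_perm),
    n_perm = n_perm,
    perm_counts = perm_counts
  )
}
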