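#' Protein-protein interaction networks
#'
#' A `ppi_network` wraps an undirected, unweighted simple [igraph] graph over
#' gene symbols: no self-loops, no multi-edges, symmetric edges. It is the
#' background network on which inter-set shortest-path proximity is measured.
#'
#' @param edges A two-column data frame (or matrix) of interacting symbol
#'   pairs, or a character matrix with two columns.
#' @param nodes Optional character vector of extra isolated nodes.
#' @return A `ppi_network` object.
#' @export
ppi_network <- function(edges, nodes = NULL) {
  edges <- as.data.frame(edges, stringsAsFactors = FALSE)
  stopifnot(ncol(edges) >= 2)
  a <- toupper(trimws(as.character(edges[[1]])))
  b <- toupper(trimws(as.character(edges[[2]])))
  keep <- nzchar(a) & nzchar(b)
  a <- a[keep]; b <- b[keep]
  n_loops <- sum(a == b)
  ok <- a != b
  # canonical order so duplicate edges collapse irrespective of direction
  lo <- pmin(a[ok], b[ok]); hi <- pmax(a[ok], b[ok])
  key <- paste(lo, hi, sep = "\r")
  dup <- duplicated(key)
  n_dup <- sum(dup)
  lo <- lo[!dup]; hi <- hi[!dup]
  verts <- sort(unique(c(lo, hi, toupper(nodes %||% character()))))
  g <- igraph::graph_from_data_frame(
    data.frame(from = lo, to = hi, stringsAsFactors = FALSE),
    directed = FALSE,
    vertices = data.frame(name = verts, stringsAsFactors = FALSE)
  )
  structure(
    list(graph = g, n_self_loops_dropped = n_loops, n_duplicates_dropped = n_dup),
    class = "ppi_network"
  )
}

#' @export
print.ppi_network <- function(x, ...) {
  cat(sprintf("<ppi_network> %d nodes, %d edges\n",
              igraph::vcount(x$graph), igraph::ecount(x$graph)))
  invisible(x)
}

#' Nodes and edges of a PPI network
#' @param x A `ppi_network`.
#' @return `network_nodes()`: character vector of gene symbols.
#' @export
network_nodes <- function(x) {
  stopifnot(inherits(x, "ppi_network"))
  igraph::V(x$graph)$name
}

#' @rdname network_nodes
#' @return `network_edges()`: tibble with columns `from`, `to`.
#' @export
network_edges <- function(x) {
  stopifnot(inherits(x, "ppi_network"))
  el <- igraph::as_edgelist(x$graph)
  tibble(from = pmin(el[, 1], el[, 2]), to = pmax(el[, 1], el[, 2])) |>
    arrange(.data$from, .data$to)
}

#' Read a PPI network from an edge-list file
#'
#' Two dialects are supported: `tsv2col` (each row names two interactors,
#' tab- or whitespace-separated) and `sif` (Simple Interaction Format:
#' `node relation node [node ...]`, fanning out one edge per trailing node;
#' the relation token is ignored). Self-loops and duplicate edges are
#' dropped, with counts recorded on the returned object. Lines starting
#' with `#` are comments.
#'
#' @param path Path to the file.
#' @param dialect `"tsv2col"` or `"sif"`.
#' @return A [ppi_network].
#' @export
read_ppi_edgelist <- function(path, dialect = c("tsv2col", "sif")) {
  dialect <- match.arg(dialect)
  lines <- read_clean_lines(path)
  keep <- nzchar(trimws(lines)) & !startsWith(trimws(lines), "#")
  rows <- which(keep)
  pairs_from <- character(0)
  pairs_to <- character(0)
  for (i in rows) {
    fields <- strsplit(trimws(lines[i]), "[\t ]+")[[1]]
    if (dialect == "tsv2col") {
      if (length(fields) < 2) {
        abort(sprintf("read_ppi_edgelist: line %d has fewer than 2 fields", i))
      }
      pairs_from <- c(pairs_from, fields[1])
      pairs_to <- c(pairs_to, fields[2])
    } else {
      if (length(fields) < 2) {
        abort(sprintf("read_ppi_edgelist: line %d has fewer than 2 fields", i))
      }
      if (length(fields) == 2) {
        # SIF permits a bare node row (an isolated node); here a 2-field row
        # is ambiguous, treat as node + relation with no partners: skip edge
        next
      }
      src <- fields[1]
      partners <- fields[-(1:2)]
      pairs_from <- c(pairs_from, rep(src, length(partners)))
      pairs_to <- c(pairs_to, partners)
    }
  }
  net <- ppi_network(data.frame(from = pairs_from, to = pairs_to,
                                stringsAsFactors = FALSE))
  if (net$n_self_loops_dropped > 0 || net$n_duplicates_dropped > 0) {
    inform(sprintf(
      "read_ppi_edgelist: dropped %d self-loop(s) and %d duplicate edge(s)",
      net$n_self_loops_dropped, net$n_duplicates_dropped))
  }
  net
}

#' Write a PPI network as a two-column TSV edge list
#'
#' @param x A [ppi_network].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_ppi_edgelist <- function(x, path) {
  ed <- network_edges(x)
  readr::write_tsv(ed, path, col_names = FALSE)
  invisible(path)
}

#' @export
tidy.ppi_network <- function(x, ...) network_edges(x)

#' @export
glance.ppi_network <- function(x, ...) {
  g <- x$graph
  tibble(
    n_nodes = igraph::vcount(g),
    n_edges = igraph::ecount(g),
    n_components = igraph::count_components(g),
    median_degree = stats::median(igraph::degree(g)),
    max_degree = if (igraph::vcount(g) > 0) max(igraph::degree(g)) else NA_real_
  )
}
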