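#' Load an interaction network from a tab-separated edge list
#'
#' Reads a BioGRID/TRRUST-style two-or-more-column TSV (extra columns
#' ignored, lines starting with `#` skipped). Identifiers are
#' whitespace-trimmed but case-preserving. In undirected mode duplicate and
#' reversed-duplicate edges are collapsed; self-loops are dropped with a
#' message reporting how many.
#'
#' @param path file path.
#' @param directed logical; `FALSE` for PPI, `TRUE` for regulator-target.
#' @return an [igraph::igraph] simple graph.
#' @export
load_edge_list <- function(path, directed = FALSE) {
  lines <- readLines(path, warn = FALSE)
  keep <- !grepl("^\\s*#", lines) & nzchar(trimws(lines))
  lines <- lines[keep]
  lineno <- which(keep)
  if (length(lines) == 0) stop_invalid("empty edge-list file: %s", path)
  parts <- strsplit(lines, "\t|\\s+")
  bad <- which(vapply(parts, length, 1L) < 2L)
  if (length(bad) > 0)
    stop_invalid("malformed edge-list line %d in %s (need >= 2 columns)",
                 lineno[bad[1]], path)
  el <- t(vapply(parts, function(x) trimws(x[1:2]), character(2)))
  as_network(data.frame(from = el[, 1], to = el[, 2],
                        stringsAsFactors = FALSE), directed = directed)
}

#' Build a simple graph from a two-column edge data.frame
#'
#' @param edges data.frame whose first two columns are endpoints.
#' @param directed logical.
#' @return an [igraph::igraph] with self-loops and duplicate (in undirected
#'   mode: also reversed-duplicate) edges removed.
#' @export
as_network <- function(edges, directed = FALSE) {
  if (igraph::is_igraph(edges)) return(edges)
  stopifnot(is.data.frame(edges), ncol(edges) >= 2)
  g <- igraph::graph_from_data_frame(edges[, 1:2], directed = directed)
  n_loop <- sum(igraph::which_loop(g))
  if (n_loop > 0)
    message(sprintf("dropped %d self-loop edge(s)", n_loop))
  igraph::simplify(g, remove.multiple = TRUE, remove.loops = TRUE)
}

#' Reconstruct the seed-centred first-neighbor subnetwork
#'
#' Node set = (seeds found in the network) plus their direct neighbors;
#' edge set = every network edge with both endpoints in that node set
#' (induced subgraph, so neighbor-neighbor edges are retained). Seeds absent
#' from the network are reported via a message, not an error; seeds left
#' without any incident edge are excluded.
#'
#' @param seeds character vector of seed identifiers (e.g. common DEGs), or
#'   a `CommonDEGSet`.
#' @param ppi an [igraph::igraph] or edge data.frame.
#' @return the induced subgraph as an [igraph::igraph].
#' @export
reconstruct_subnetwork <- function(seeds, ppi) {
  if (inherits(seeds, "CommonDEGSet")) seeds <- seeds$genes
  g <- as_network(ppi, directed = FALSE)
  present <- intersect(trimws(seeds), igraph::V(g)$name)
  if (length(present) < length(seeds))
    message(sprintf("%d of %d seeds not found in the network",
                    length(seeds) - length(present), length(seeds)))
  if (length(present) == 0) stop_invalid("empty subnetwork: no seed maps into the network")
  nbr <- unique(unlist(lapply(
    igraph::adjacent_vertices(g, present), function(v) v$name)))
  sub <- igraph::induced_subgraph(g, union(present, nbr))
  isolated <- igraph::V(sub)$name[igraph::degree(sub) == 0]
  if (length(isolated) > 0)
    sub <- igraph::delete_vertices(sub, isolated)
  if (igraph::vcount(sub) == 0) stop_invalid("empty subnetwork: seeds are isolated")
  sub
}

#' Degree and betweenness centrality of every node
#'
#' Degree is the local metric, betweenness the global one: for node `v`, the
#' sum over node pairs of the fraction of shortest paths through `v`
#' (unnormalized, endpoints excluded; disconnected graphs are handled per
#' component).
#'
#' @param net an [igraph::igraph] or edge data.frame (treated undirected).
#' @return data.frame `node`, `degree`, `betweenness`, sorted by node id.
#' @export
centralities <- function(net) {
  g <- as_network(net, directed = FALSE)
  if (igraph::vcount(g) == 0) stop_invalid("empty graph")
  out <- data.frame(
    node = igraph::V(g)$name,
    degree = as.integer(igraph::degree(g)),
    betweenness = igraph::betweenness(g, directed = FALSE, normalized = FALSE),
    stringsAsFactors = FALSE
  )
  out <- out[order(out$node), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Select hub nodes by the dual degree/betweenness criterion
#'
#' Hubs are the union of the top-`k` nodes by degree and the top-`k` by
#' betweenness, so between `k` and `2k` hubs emerge. Ties at the k-th rank
#' are broken by the other metric, then lexicographically by node id, making
#' the selection deterministic.
#'
#' @param table data.frame from [centralities()].
#' @param k rank cutoff per metric (default 10).
#' @return `table` with added columns `hub_flag` (logical) and
#'   `selection_reason` (`"degree"`, `"betweenness"`, `"both"` or `""`),
#'   sorted by decreasing degree.
#' @export
select_hubs <- function(table, k = 10) {
  stopifnot(is.data.frame(table),
            all(c("node", "degree", "betweenness") %in% names(table)))
  if (nrow(table) == 0) stop_invalid("centrality table is empty")
  if (k <= 0) stop_invalid("k must be positive")
  k <- min(k, nrow(table))
  top_by <- function(primary, secondary) {
    ord <- order(-table[[primary]], -table[[secondary]], table$node)
    table$node[ord[seq_len(k)]]
  }
  top_deg <- top_by("degree", "betweenness")
  top_btw <- top_by("betweenness", "degree")
  hubs <- union(top_deg, top_btw)
  table$hub_flag <- table$node %in% hubs
  table$selection_reason <- ""
  table$selection_reason[table$node %in% top_deg] <- "degree"
  table$selection_reason[table$node %in% top_btw] <- "betweenness"
  table$selection_reason[table$node %in% intersect(top_deg, top_btw)] <- "both"
  table <- table[order(-table$degree, -table$betweenness, table$node), ,
                 drop = FALSE]
  rownames(table) <- NULL
  table
}

#' Export an undirected network as a SIF file
#'
#' Simple interaction format (`A pp B`), one edge per line, for downstream
#' visualization tools.
#'
#' @param net an [igraph::igraph] or edge data.frame.
#' @param path output path.
#' @param interaction interaction label (default `"pp"`).
#' @return `path`, invisibly.
#' @export
write_sif <- function(net, path, interaction = "pp") {
  g <- as_network(net, directed = FALSE)
  el <- igraph::as_edgelist(g)
  writeLines(paste(el[, 1], interaction, el[, 2], sep = "\t"), path)
  invisible(path)
}
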