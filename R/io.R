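#' Read a signed edge list
#'
#' Parses the package's tab-separated edge-list dialect: optional comment
#' lines starting `#`; an optional `#nodes:` header (tab- or
#' comma-separated names after the colon) fixing the canonical node order
#' and admitting isolated nodes; data rows
#' `source<TAB>target<TAB>weight` with weight literally `+1`, `1` or `-1`.
#' Without a `#nodes:` header, nodes are ordered by first appearance.
#'
#' @param path Path to the edge-list file.
#' @return A `threshold_network`.
#' @seealso [write_edge_list()] which inverts this exactly.
#' @export
read_edge_list <- function(path) {
  lines <- readLines(path)
  nodes <- NULL
  node_hdr <- grep("^#nodes:", lines)
  if (length(node_hdr) > 0) {
    spec <- sub("^#nodes:[ \t]*", "", lines[node_hdr[1]])
    nodes <- trimws(strsplit(spec, "[\t,]")[[1]])
    nodes <- nodes[nzchar(nodes)]
  }
  keep <- !grepl("^#", lines) & nzchar(trimws(lines))
  data_lines <- lines[keep]
  line_no <- seq_along(lines)[keep]
  if (length(data_lines) == 0) {
    return(as_threshold_network(
      tibble::tibble(source = character(), target = character(),
                     weight = numeric()),
      nodes = if (is.null(nodes)) character(0) else nodes
    ))
  }
  parts <- strsplit(data_lines, "\t", fixed = TRUE)
  bad <- which(lengths(parts) != 3L)
  if (length(bad) > 0) {
    stop("malformed edge-list line ", line_no[bad[1]], ": expected ",
         "source<TAB>target<TAB>weight", call. = FALSE)
  }
  m <- do.call(rbind, parts)
  w_txt <- trimws(m[, 3])
  ok <- w_txt %in% c("+1", "1", "-1")
  if (!all(ok)) {
    stop("invalid weight '", w_txt[!ok][1], "' on line ",
         line_no[which(!ok)[1]], ": must be +1 or -1", call. = FALSE)
  }
  as_threshold_network(
    tibble::tibble(source = trimws(m[, 1]), target = trimws(m[, 2]),
                   weight = as.numeric(sub("^\\+", "", w_txt))),
    nodes = nodes
  )
}

#' Write a signed edge list
#'
#' Emits the TSV dialect read by [read_edge_list()], including a `#nodes:`
#' header preserving the canonical node order, so the round trip is the
#' identity on the weight matrix.
#'
#' @param net A `threshold_network`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_edge_list <- function(net, path) {
  stopifnot(inherits(net, "threshold_network"))
  e <- network_edges(net)
  w <- ifelse(e$weight > 0, "+1", "-1")
  lines <- c(
    paste0("#nodes:\t", paste(net$nodes, collapse = "\t")),
    if (nrow(e) > 0) paste(e$source, e$target, w, sep = "\t")
  )
  writeLines(lines, path)
  invisible(path)
}

#' Export a network as SIF
#'
#' Writes a Cytoscape-loadable simple-interaction-format file: one line
#' `source activates target` or `source represses target` per interaction,
#' and a bare node line for every isolated node.
#'
#' @param net A `threshold_network`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
export_sif <- function(net, path) {
  stopifnot(inherits(net, "threshold_network"))
  e <- network_edges(net)
  rel <- ifelse(e$weight > 0, "activates", "represses")
  isolated <- setdiff(net$nodes, unique(c(e$source, e$target)))
  lines <- c(
    if (nrow(e) > 0) paste(e$source, rel, e$target),
    isolated
  )
  writeLines(lines, path)
  invisible(path)
}

as_igraph <- function(net) {
  e <- network_edges(net)
  g <- igraph::graph_from_data_frame(
    d = data.frame(from = e$source, to = e$target),
    directed = TRUE,
    vertices = data.frame(name = net$nodes, label = unname(net$labels))
  )
  igraph::E(g)$weight <- e$weight
  igraph::E(g)$sign <- ifelse(e$weight > 0, "activates", "represses")
  g
}

#' Export a network as GraphML
#'
#' Writes the network as a directed GraphML graph with a signed `weight`
#' attribute per edge and the display `label` per node, suitable for
#' Cytoscape or any GraphML consumer.
#'
#' @param net A `threshold_network`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
export_graphml <- function(net, path) {
  igraph::write_graph(as_igraph(net), path, format = "graphml")
  invisible(path)
}

#' Export the state-transition graph
#'
#' Writes the full synchronous state-transition graph: one node per network
#' state (all `2^N` of them, named by their bit-string) and exactly one
#' out-edge per state, to its successor. Node attributes mark attractor
#' membership (`is_attractor`), the basin each state belongs to
#' (`basin_id`, the attractor id of [enumerate_attractors()]), and the
#' largest attractor (`is_largest_attractor`), so the flow toward the main
#' stationary state can be inspected in Cytoscape or Graphviz.
#'
#' @param net A `threshold_network`.
#' @param path Output file path.
#' @param format `"graphml"` or `"dot"`.
#' @param max_nodes Passed to [enumerate_attractors()].
#' @return `path`, invisibly.
#' @export
export_state_transition_graph <- function(net, path,
                                          format = c("graphml", "dot"),
                                          max_nodes = 20L) {
  format <- match.arg(format)
  rep <- enumerate_attractors(net, max_nodes = max_nodes)
  n <- n_nodes(net)
  M <- rep$total_states
  succ <- all_successors(net)
  names_v <- vapply(0:(M - 1L), function(i) format_state(state_from_index(i, n)),
                    character(1))
  on_attractor <- logical(M)
  for (ix in rep$states) on_attractor[ix + 1L] <- TRUE
  largest_id <- rep$attractors$attractor_id[which.max(rep$attractors$basin_size)]
  g <- igraph::graph_from_data_frame(
    d = data.frame(from = names_v, to = names_v[succ]),
    directed = TRUE,
    vertices = data.frame(
      name = names_v,
      is_attractor = as.integer(on_attractor),
      basin_id = rep$assignment,
      is_largest_attractor = as.integer(on_attractor &
                                          rep$assignment == largest_id)
    )
  )
  igraph::write_graph(g, path, format = format)
  invisible(path)
}
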