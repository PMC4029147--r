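#' Signed threshold Boolean networks
#'
#' A `threshold_network` holds an ordered set of named regulator nodes, a
#' signed integer weight matrix `W` (`W[source, target]` is +1 for activation,
#' -1 for repression/degradation, 0 for no interaction) and a per-node
#' activation threshold (0 by default). It is the object every dynamics,
#' ensemble and perturbation function operates on.
#'
#' @param edges A data frame with columns `source`, `target` and `weight`
#'   (each weight +1 or -1), one row per directed interaction. At most one
#'   interaction per ordered (source, target) pair.
#' @param nodes Optional character vector fixing the canonical node order
#'   (and admitting isolated nodes). Defaults to first-appearance order in
#'   `edges`.
#' @param labels Optional character vector of display labels, same length as
#'   the node set; defaults to the node names themselves.
#' @param thresholds Per-node activation threshold; a single value is
#'   recycled. Default 0.
#'
#' @return A `threshold_network` object.
#' @examples
#' toy <- as_threshold_network(
#'   data.frame(source = c("A", "B"), target = c("B", "B"), weight = c(1, -1))
#' )
#' toy
#' @export
as_threshold_network <- function(edges, nodes = NULL, labels = NULL,
                                 thresholds = 0) {
  if (!is.data.frame(edges)) {
    stop("`edges` must be a data frame with columns source, target, weight",
         call. = FALSE)
  }
  required <- c("source", "target", "weight")
  missing_cols <- setdiff(required, names(edges))
  if (length(missing_cols) > 0) {
    stop("`edges` is missing column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  edges <- tibble::as_tibble(edges)[required]
  edges$source <- as.character(edges$source)
  edges$target <- as.character(edges$target)
  edges$weight <- as.numeric(edges$weight)
  if (nrow(edges) > 0 && !all(edges$weight %in% c(-1, 1))) {
    bad <- which(!(edges$weight %in% c(-1, 1)))
    stop("interaction weights must be +1 or -1 (offending row ", bad[1], ")",
         call. = FALSE)
  }
  key <- paste(edges$source, edges$target, sep = "\r")
  if (anyDuplicated(key)) {
    dup <- key[duplicated(key)][1]
    stop("duplicate interaction for ordered pair: ",
         gsub("\r", " -> ", dup), call. = FALSE)
  }
  if (is.null(nodes)) {
    nodes <- unique(c(rbind(edges$source, edges$target)))
    if (length(nodes) == 0) nodes <- character(0)
  } else {
    nodes <- as.character(nodes)
    if (anyDuplicated(nodes)) stop("node names must be unique", call. = FALSE)
    unknown <- setdiff(unique(c(edges$source, edges$target)), nodes)
    if (length(unknown) > 0) {
      stop("interaction endpoint(s) not in node set: ",
           paste(unknown, collapse = ", "), call. = FALSE)
    }
  }
  n <- length(nodes)
  if (is.null(labels)) labels <- nodes
  if (length(labels) != n) {
    stop("`labels` must have one entry per node", call. = FALSE)
  }
  thresholds <- rep_len(as.numeric(thresholds), n)
  W <- matrix(0, n, n, dimnames = list(nodes, nodes))
  if (nrow(edges) > 0) {
    W[cbind(match(edges$source, nodes), match(edges$target, nodes))] <-
      edges$weight
  }
  new_threshold_network(nodes, labels, W, thresholds)
}

# clamped: names of nodes held inactive (update function = constant 0), the
# in-silico knockdown state. Empty for ordinary networks.
new_threshold_network <- function(nodes, labels, W, thresholds,
                                  clamped = character(0)) {
  structure(
    list(
      nodes = nodes,
      labels = stats::setNames(labels, nodes),
      W = W,
      thresholds = stats::setNames(thresholds, nodes),
      clamped = clamped
    ),
    class = "threshold_network"
  )
}

#' @export
print.threshold_network <- function(x, ...) {
  e <- network_edges(x)
  cat("<threshold_network> ", n_nodes(x), " nodes, ", nrow(e),
      " interactions (", sum(e$weight > 0), " activating, ",
      sum(e$weight < 0), " repressing)\n", sep = "")
  cat("nodes:", paste(x$nodes, collapse = ", "), "\n")
  if (length(x$clamped) > 0) {
    cat("clamped inactive (knocked down):",
        paste(x$clamped, collapse = ", "), "\n")
  }
  invisible(x)
}

n_nodes <- function(net) length(net$nodes)

#' Interactions of a network as a tibble
#'
#' Returns one row per signed interaction, in row-major (source-major) order
#' of the weight matrix. `tidy()` on a `threshold_network` is an alias.
#'
#' @param net A `threshold_network`.
#' @return A tibble with columns `source`, `target`, `weight`.
#' @export
network_edges <- function(net) {
  stopifnot(inherits(net, "threshold_network"))
  idx <- which(t(net$W) != 0, arr.ind = TRUE)  # transpose -> source-major
  tibble::tibble(
    source = net$nodes[idx[, "col"]],
    target = net$nodes[idx[, "row"]],
    weight = net$W[cbind(idx[, "col"], idx[, "row"])]
  )
}

#' @rdname network_edges
#' @param x A `threshold_network`.
#' @param ... Unused.
#' @export
tidy.threshold_network <- function(x, ...) network_edges(x)

#' One-row summary of a network
#'
#' @param x A `threshold_network`.
#' @param ... Unused.
#' @return A tibble with node/edge/sign/self-loop counts.
#' @export
glance.threshold_network <- function(x, ...) {
  e <- network_edges(x)
  tibble::tibble(
    n_nodes = n_nodes(x),
    n_edges = nrow(e),
    n_activating = sum(e$weight > 0),
    n_repressing = sum(e$weight < 0),
    n_self_loops = sum(e$source == e$target),
    n_states = 2L^n_nodes(x)
  )
}

#' Weight matrix of a network
#'
#' @param net A `threshold_network`.
#' @return The signed weight matrix, rows = source, columns = target.
#' @export
weight_matrix <- function(net) {
  stopifnot(inherits(net, "threshold_network"))
  net$W
}

# Canonical order and labels of the built-in cell-cycle network. The order is
# the column order used throughout reports and bit-strings (most significant
# bit first).
celegans_node_table <- function() {
  tibble::tibble(
    name = c("cdk2_cyclinE", "cdc25_1", "cul1_lin23", "lin35_efl1_dpl1",
             "cdk1_cyclinB", "fzr1", "cdc14_fzy1", "cki1"),
    label = c("cdk-2/cyclinE", "cdc-25.1", "cul-1/lin-23",
              "lin-35/efl-1/dpl-1", "cdk-1/cyclinB", "fzr-1",
              "cdc-14/fzy-1", "cki-1")
  )
}

#' The C. elegans early embryonic cell-cycle network
#'
#' Builds the bundled eight-regulator signed network controlling S/M
#' oscillations in the early C. elegans embryo: 21 interactions (9 activating,
#' 12 repressing), including -1 self-degradation loops on cul-1/lin-23, fzr-1
#' and cki-1 (regulators with no other repressor). All thresholds are 0.
#'
#' Node order (most significant bit first in all bit-strings and reports):
#' cdk-2/cyclinE, cdc-25.1, cul-1/lin-23, lin-35/efl-1/dpl-1, cdk-1/cyclinB,
#' fzr-1, cdc-14/fzy-1, cki-1. Node names are file-safe slugs
#' (e.g. `cdk2_cyclinE`); display labels keep the conventional gene names.
#'
#' @return A `threshold_network` with 8 nodes and 21 interactions.
#' @examples
#' net <- celegans_cell_cycle()
#' glance(net)
#' @export
celegans_cell_cycle <- function() {
  nd <- celegans_node_table()
  e <- function(source, target, weight) c(source, target, weight)
  edges <- rbind(
    e("cdc14_fzy1",      "cdk1_cyclinB",    -1),  # APC-mediated cyclin B degradation
    e("cdc14_fzy1",      "fzr1",            +1),
    e("cdc14_fzy1",      "cki1",            +1),
    e("cdc25_1",         "cdk2_cyclinE",    +1),  # activating dephosphorylation
    e("cdc25_1",         "cdk1_cyclinB",    +1),
    e("cdk1_cyclinB",    "cdc14_fzy1",      +1),
    e("cdk2_cyclinE",    "cul1_lin23",      +1),  # SCF triggered for cyclin E degradation
    e("cdk2_cyclinE",    "lin35_efl1_dpl1", -1),
    e("cdk2_cyclinE",    "cdc14_fzy1",      -1),
    e("cki1",            "cdk2_cyclinE",    -1),  # CKI blocks S-phase entry
    e("cki1",            "cdk1_cyclinB",    -1),
    e("cki1",            "cki1",            -1),  # self-degradation
    e("cul1_lin23",      "cdk2_cyclinE",    -1),
    e("cul1_lin23",      "cdc25_1",         -1),
    e("cul1_lin23",      "cul1_lin23",      -1),  # self-degradation
    e("cul1_lin23",      "lin35_efl1_dpl1", +1),
    e("fzr1",            "cdk1_cyclinB",    -1),
    e("fzr1",            "fzr1",            -1),  # self-degradation
    e("fzr1",            "cki1",            +1),
    e("lin35_efl1_dpl1", "cdk2_cyclinE",    -1),  # Rb/E2F repression of cyclin E
    e("lin35_efl1_dpl1", "cdk1_cyclinB",    +1)
  )
  as_threshold_network(
    data.frame(source = edges[, 1], target = edges[, 2],
               weight = as.numeric(edges[, 3])),
    nodes = nd$name, labels = nd$label
  )
}
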