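#' In-silico gene knockdown
#'
#' Mimics an RNAi knockdown: the knocked gene is silenced, so (i) every
#' *outgoing* weight of each knocked node — including its self-degradation
#' loop — is set to 0, and (ii) the node's update function becomes the
#' constant 0: it is held inactive throughout the simulation and no longer
#' affects any interacting node. The node stays in the network (state
#' space unchanged at `2^N`); incoming interactions are left in place but
#' can no longer switch it on. Holding the node inactive is what collapses
#' near-duplicate attractors differing only in the knocked gene's bit, and
#' is the rule under which the published knockdown attractor counts arise.
#'
#' @param net A `threshold_network`.
#' @param nodes Character vector of node names to knock down (may be
#'   empty, returning the network unchanged).
#' @return A new `threshold_network`; the input is not modified.
#' @examples
#' kd <- knockdown_network(celegans_cell_cycle(), "cki1")
#' sum(weight_matrix(kd)["cki1", ] != 0)
#' @export
knockdown_network <- function(net, nodes) {
  stopifnot(inherits(net, "threshold_network"))
  nodes <- as.character(nodes)
  unknown <- setdiff(nodes, net$nodes)
  if (length(unknown) > 0) {
    stop("unknown node(s): ", paste(unknown, collapse = ", "), call. = FALSE)
  }
  W2 <- net$W
  W2[nodes, ] <- 0
  new_threshold_network(net$nodes, unname(net$labels), W2,
                        unname(net$thresholds),
                        clamped = union(net$clamped, nodes))
}

#' Full knockdown analysis of one gene
#'
#' Knocks down one node, re-enumerates the attractors of the knocked
#' network, and simulates the biological pathway — the trajectory of one
#' cell cycle — from the S-entry state: the knocked network's largest
#' attractor with cdk-2/cyclinE forced on (S-phase entry signal) and the
#' knocked node set inactive, matching the start used for knockdown
#' pathway tables. The pathway length counts time points from the start
#' state through the first fixed-point state, inclusive.
#'
#' @param net A `threshold_network` containing a `cdk2_cyclinE` node.
#' @param node Name of the node to knock down.
#' @param max_steps Trajectory budget.
#' @return A list: `node`, `network` (the knocked network), `report`
#'   (its `attractor_report`), `trajectory`, `pathway_length`,
#'   `n_fixed_points`.
#' @examples
#' ka <- knockdown_analysis(celegans_cell_cycle(), "cdc14_fzy1")
#' ka$n_fixed_points
#' @export
knockdown_analysis <- function(net, node, max_steps = 1000L) {
  stopifnot(inherits(net, "threshold_network"), length(node) == 1)
  kd <- knockdown_network(net, node)
  report <- enumerate_attractors(kd)
  a <- report$attractors
  fp <- a[a$type == "fixed_point", ]
  if (nrow(fp) == 0) {
    stop("knocked network has no fixed point; no pathway start defined",
         call. = FALSE)
  }
  i_s <- match("cdk2_cyclinE", kd$nodes)
  if (is.na(i_s)) stop("network lacks a cdk2_cyclinE node", call. = FALSE)
  start <- parse_state(fp$state[which.max(fp$basin_size)])
  start[i_s] <- 1L
  start[match(node, kd$nodes)] <- 0L
  traj <- simulate_trajectory(kd, start, max_steps = max_steps)
  list(
    node = node,
    network = kd,
    report = report,
    trajectory = traj,
    pathway_length = nrow(traj),
    n_fixed_points = nrow(fp)
  )
}
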