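#' Synchronous threshold update
#'
#' Advances a state by one time step under the threshold rule: each node i
#' receives the weighted input sum `h_i = sum_j W[j, i] * S_j(t)` and takes
#' value 1 if `h_i` exceeds its threshold, 0 if below, and keeps its current
#' value at equality (the tie holds the state; self-degradation acts purely
#' through the -1 self-loop summand). All nodes update simultaneously.
#'
#' @param net A `threshold_network`.
#' @param state A bit-string or 0/1 vector of length `n_nodes(net)`.
#' @return Integer 0/1 vector: the successor state.
#' @examples
#' net <- celegans_cell_cycle()
#' format_state(successor_state(net, "10010111"))
#' @export
successor_state <- function(net, state) {
  stopifnot(inherits(net, "threshold_network"))
  s <- parse_state(state, n = n_nodes(net))
  h <- as.vector(s %*% net$W)
  th <- unname(net$thresholds)
  nxt <- ifelse(h > th, 1L, ifelse(h < th, 0L, s))
  if (length(net$clamped) > 0) nxt[match(net$clamped, net$nodes)] <- 0L
  nxt
}

# Successor index (1-based) for every state, in state-index order 0..2^N-1.
# Vectorised over the whole state space; the workhorse behind enumeration.
all_successors <- function(net) {
  n <- n_nodes(net)
  S <- state_space_matrix(n)
  H <- S %*% net$W
  Th <- matrix(net$thresholds, nrow(S), n, byrow = TRUE)
  Nxt <- (H > Th) + (H == Th) * S
  if (length(net$clamped) > 0) Nxt[, match(net$clamped, net$nodes)] <- 0
  pow <- 2^(n:1 - 1L)
  as.integer(Nxt %*% pow) + 1L
}

#' Simulate a trajectory to absorption
#'
#' Iterates the synchronous update from a start state until a state repeats
#' or `max_steps` states have been produced. If the repeat is the immediate
#' successor (a fixed point) the trajectory is absorbed and the fixed point
#' appears exactly once, as the final state; a revisit of an earlier state
#' (a limit cycle) stops the walk unabsorbed.
#'
#' Each state is labelled with a cell-cycle phase via [label_phase()].
#'
#' @param net A `threshold_network`.
#' @param start Start state (bit-string or 0/1 vector).
#' @param max_steps Maximum number of states to generate (>= 1).
#' @return A `trajectory`: a tibble with columns `time`, `state`
#'   (bit-string), one 0/1 column per node, and `phase`; attribute
#'   `absorbed` says whether the final state is a fixed point.
#' @examples
#' traj <- simulate_trajectory(celegans_cell_cycle(), "10010111")
#' traj
#' attr(traj, "absorbed")
#' @export
simulate_trajectory <- function(net, start, max_steps = 1000L) {
  stopifnot(inherits(net, "threshold_network"), max_steps >= 1)
  s <- parse_state(start, n = n_nodes(net))
  states <- list(s)
  seen <- stats::setNames(1L, format_state(s))
  absorbed <- FALSE
  while (length(states) < max_steps) {
    nxt <- successor_state(net, states[[length(states)]])
    key <- format_state(nxt)
    if (!is.na(seen[key])) {
      absorbed <- seen[[key]] == length(states)  # repeat of current = fixed point
      break
    }
    states[[length(states) + 1L]] <- nxt
    seen[key] <- length(states)
  }
  if (!absorbed && length(states) == max_steps) {
    # ran out of budget: check whether we happened to stop on a fixed point
    absorbed <- identical(successor_state(net, states[[length(states)]]),
                          states[[length(states)]])
  }
  build_trajectory(net, states, absorbed)
}

build_trajectory <- function(net, states, absorbed) {
  M <- do.call(rbind, states)
  colnames(M) <- net$nodes
  out <- tibble::tibble(
    time = seq_along(states),
    state = vapply(states, format_state, character(1))
  )
  out <- dplyr::bind_cols(out, tibble::as_tibble(M))
  fixed_last <- c(rep(FALSE, length(states) - 1L), absorbed)
  out$phase <- vapply(seq_along(states), function(i) {
    label_phase(net, states[[i]], is_fixed = fixed_last[i])
  }, character(1))
  structure(out, absorbed = absorbed,
            class = c("trajectory", class(out)))
}

#' Cell-cycle phase of a state
#'
#' Phase is read off the two CDK/cyclin complexes: S while cdk-2/cyclinE is
#' active (DNA synthesis), else M while cdk-1/cyclinB is active (mitosis),
#' else M/S for the stationary state (a fixed point, the cell resting at the
#' M-to-S transition awaiting the next cycle) and S/M for a transient state
#' between S exit and M entry. Networks lacking either CDK node get
#' `"unlabeled"`.
#'
#' @param net A `threshold_network`.
#' @param state Bit-string or 0/1 vector.
#' @param is_fixed Is this state a fixed point?
#' @return One of `"S"`, `"S/M"`, `"M"`, `"M/S"`, `"unlabeled"`.
#' @export
label_phase <- function(net, state, is_fixed = FALSE) {
  s <- parse_state(state, n = n_nodes(net))
  i_s <- match("cdk2_cyclinE", net$nodes)
  i_m <- match("cdk1_cyclinB", net$nodes)
  if (is.na(i_s) || is.na(i_m)) return("unlabeled")
  if (s[i_s] == 1L) "S"
  else if (s[i_m] == 1L) "M"
  else if (is_fixed) "M/S"
  else "S/M"
}

#' Exhaustive attractor and basin enumeration
#'
#' Visits all `2^N` states of the synchronous state-transition graph and
#' decomposes it into its attractors — fixed points (states equal to their
#' own successor) and limit cycles — together with their basins of
#' attraction. The basin of an attractor is the number of initial states
#' whose forward orbit is absorbed by it; states on a cycle count toward
#' their own cycle's basin, so basin sizes always sum to `2^N`.
#'
#' Attractors are ordered by descending basin size, ties broken by ascending
#' smallest state index.
#'
#' @param net A `threshold_network`.
#' @param max_nodes Hard cap on exhaustive enumeration (default 20 nodes,
#'   i.e. about a million states); larger networks raise an error telling
#'   the user to lift the cap deliberately.
#' @return An `attractor_report`: list with `attractors` (tibble:
#'   `attractor_id`, `type`, `period`, `state` of the fixed point or cycle
#'   entry state, `basin_size`), `states` (list of integer state-index
#'   vectors per attractor), `assignment` (attractor id per state, in state
#'   index order), `total_states`, and the network.
#' @examples
#' rep <- enumerate_attractors(celegans_cell_cycle())
#' glance(rep)
#' tidy(rep)
#' @export
enumerate_attractors <- function(net, max_nodes = 20L) {
  stopifnot(inherits(net, "threshold_network"))
  n <- n_nodes(net)
  if (n > max_nodes) {
    stop("network has ", n, " nodes; exhaustive enumeration is capped at ",
         max_nodes, " (raise `max_nodes` to override)", call. = FALSE)
  }
  succ <- all_successors(net)
  dec <- decompose_functional_graph(succ)
  basin <- tabulate(dec$assignment, nbins = length(dec$attractors))
  # canonical order: descending basin, ties by ascending min state index
  min_idx <- vapply(dec$attractors, min, integer(1))
  ord <- order(-basin, min_idx)
  remap <- match(seq_along(ord), ord)
  attractors <- tibble::tibble(
    attractor_id = seq_along(ord),
    type = ifelse(lengths(dec$attractors)[ord] == 1L, "fixed_point", "cycle"),
    period = lengths(dec$attractors)[ord],
    state = vapply(dec$attractors[ord], function(ix) {
      format_state(state_from_index(min(ix) - 1L, n))
    }, character(1)),
    basin_size = basin[ord]
  )
  structure(
    list(
      attractors = attractors,
      states = lapply(dec$attractors[ord], function(ix) ix - 1L),
      assignment = remap[dec$assignment],
      total_states = 2L^n,
      net = net
    ),
    class = "attractor_report"
  )
}

# Decompose a functional graph succ (1-based successor per node) into
# terminal components (attractors) and a per-node component assignment.
# Iterative path-following with memoisation: amortised O(M).
decompose_functional_graph <- function(succ) {
  M <- length(succ)
  comp <- integer(M)      # 0 = unassigned
  pos <- integer(M)       # position on the current path, 0 otherwise
  attractors <- list()
  path <- integer(0)
  for (s0 in seq_len(M)) {
    if (comp[s0] > 0L) next
    plen <- 0L
    cur <- s0
    while (comp[cur] == 0L && pos[cur] == 0L) {
      plen <- plen + 1L
      path[plen] <- cur
      pos[cur] <- plen
      cur <- succ[cur]
    }
    if (comp[cur] > 0L) {
      aid <- comp[cur]
    } else {
      aid <- length(attractors) + 1L
      attractors[[aid]] <- path[pos[cur]:plen]
    }
    ix <- path[seq_len(plen)]
    comp[ix] <- aid
    pos[ix] <- 0L
  }
  list(assignment = comp, attractors = attractors)
}

#' @export
print.attractor_report <- function(x, ...) {
  cat("<attractor_report> ", nrow(x$attractors), " attractor(s) over ",
      x$total_states, " states\n", sep = "")
  print(x$attractors)
  invisible(x)
}

#' Attractor table in report layout
#'
#' One row per attractor state (fixed points contribute one row, limit
#' cycles one row per cycle state), with the basin size followed by the 0/1
#' value of every node — the layout of the published fixed-point table.
#'
#' @param x An `attractor_report`.
#' @param ... Unused.
#' @return A tibble: `attractor_id`, `type`, `basin_size`, `state`, then one
#'   0/1 column per node.
#' @export
tidy.attractor_report <- function(x, ...) {
  n <- n_nodes(x$net)
  rows <- purrr::map2_dfr(
    x$attractors$attractor_id, x$states,
    function(id, ix) {
      M <- do.call(rbind, lapply(ix, state_from_index, n = n))
      colnames(M) <- x$net$nodes
      dplyr::bind_cols(
        tibble::tibble(
          attractor_id = id,
          type = x$attractors$type[id],
          basin_size = x$attractors$basin_size[id],
          state = vapply(ix, function(i) format_state(state_from_index(i, n)),
                         character(1))
        ),
        tibble::as_tibble(M)
      )
    }
  )
  rows
}

#' @rdname tidy.attractor_report
#' @export
glance.attractor_report <- function(x, ...) {
  a <- x$attractors
  tibble::tibble(
    n_attractors = nrow(a),
    n_fixed_points = sum(a$type == "fixed_point"),
    n_cycles = sum(a$type == "cycle"),
    largest_basin = if (nrow(a)) max(a$basin_size) else 0L,
    largest_fixed_point_basin =
      if (any(a$type == "fixed_point")) {
        max(a$basin_size[a$type == "fixed_point"])
      } else 0L,
    total_states = x$total_states
  )
}

#' Largest fixed-point basin of a network
#'
#' Convenience wrapper: enumerates attractors and returns the basin size of
#' the largest fixed point (0 if the network has no fixed point).
#'
#' @param net A `threshold_network`.
#' @return Integer basin size.
#' @export
largest_basin <- function(net) {
  glance(enumerate_attractors(net))$largest_fixed_point_basin
}
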