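#' Specification of a matched random-network ensemble
#'
#' Describes an ensemble of random signed threshold networks matched to a
#' reference network in node count and in the number of activating and
#' repressing edges — the null model against which the cell-cycle network's
#' stability is judged. Defaults are the reference conditions: 1000 networks
#' of 8 nodes with 9 activating and 12 repressing edges, self-loops allowed
#' (the reference network itself has three), thresholds 0.
#'
#' @param n_networks Number of networks in the ensemble.
#' @param n_nodes Nodes per network.
#' @param n_activating Number of +1 edges.
#' @param n_repressing Number of -1 edges.
#' @param allow_self_loops May edges join a node to itself?
#' @param seed Integer seed; together with a draw index it pins down every
#'   network, so ensembles are bit-reproducible.
#' @return An `ensemble_spec`.
#' @examples
#' ensemble_spec(n_networks = 10, seed = 42)
#' @export
ensemble_spec <- function(n_networks = 1000L, n_nodes = 8L,
                          n_activating = 9L, n_repressing = 12L,
                          allow_self_loops = TRUE, seed = 1L) {
  stopifnot(n_networks >= 1, n_nodes >= 1,
            n_activating >= 0, n_repressing >= 0)
  n_pairs <- if (allow_self_loops) n_nodes^2 else n_nodes * (n_nodes - 1L)
  if (n_activating + n_repressing > n_pairs) {
    stop("infeasible spec: ", n_activating + n_repressing,
         " edges requested but only ", n_pairs,
         " ordered pairs are available", call. = FALSE)
  }
  structure(
    list(n_networks = as.integer(n_networks),
         n_nodes = as.integer(n_nodes),
         n_activating = as.integer(n_activating),
         n_repressing = as.integer(n_repressing),
         allow_self_loops = isTRUE(allow_self_loops),
         seed = as.integer(seed)),
    class = "ensemble_spec"
  )
}

#' @export
print.ensemble_spec <- function(x, ...) {
  cat("<ensemble_spec> ", x$n_networks, " networks of ", x$n_nodes,
      " nodes; ", x$n_activating, " activating + ", x$n_repressing,
      " repressing edges; self-loops ",
      if (x$allow_self_loops) "allowed" else "forbidden",
      "; seed ", x$seed, "\n", sep = "")
  invisible(x)
}

# Deterministic per-draw seed, kept inside 32-bit signed range.
draw_seed <- function(seed, draw_index) {
  as.integer((as.numeric(seed) * 69069 + as.numeric(draw_index)) %% 2147483647)
}

#' Draw one matched random network
#'
#' Samples `n_activating + n_repressing` distinct ordered node pairs
#' uniformly from the allowed pair set and partitions them uniformly at
#' random into the two sign classes. The draw is fully determined by
#' `(spec$seed, draw_index)` and leaves the caller's RNG state untouched.
#'
#' @param spec An [ensemble_spec()].
#' @param draw_index Which network of the ensemble (1-based).
#' @return A `threshold_network` with nodes `n1..nK` and thresholds 0.
#' @export
generate_random_network <- function(spec, draw_index = 1L) {
  stopifnot(inherits(spec, "ensemble_spec"), draw_index >= 1)
  n <- spec$n_nodes
  nodes <- paste0("n", seq_len(n))
  pairs <- expand.grid(source = seq_len(n), target = seq_len(n))
  if (!spec$allow_self_loops) pairs <- pairs[pairs$source != pairs$target, ]
  n_edges <- spec$n_activating + spec$n_repressing
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(draw_seed(spec$seed, draw_index))
  chosen <- sample(nrow(pairs), n_edges)
  signs <- rep(-1, n_edges)
  signs[sample(n_edges, spec$n_activating)] <- 1
  as_threshold_network(
    tibble::tibble(source = nodes[pairs$source[chosen]],
                   target = nodes[pairs$target[chosen]],
                   weight = signs),
    nodes = nodes
  )
}

#' Attractor statistics over a random ensemble
#'
#' Generates every network of the ensemble, enumerates its attractors
#' exhaustively, and records per network the number of fixed points, the
#' number of limit cycles (tallied separately, never mixed into fixed-point
#' counts) and the largest fixed-point basin (0 if the network has no fixed
#' point). Summaries follow: mean fixed-point count, mean largest basin,
#' the pooled basin-size histogram over all fixed points, and the fraction
#' of basins strictly exceeding `reference_basin` — computed both over all
#' pooled fixed points and over per-network largest basins (the reference
#' statistic is reported under both denominators because either reading is
#' defensible).
#'
#' @param spec An [ensemble_spec()].
#' @param reference_basin Basin size of the reference network's largest
#'   attractor (219 for the built-in cell-cycle network).
#' @return An `ensemble_stats` object; see [tidy.ensemble_stats()] and
#'   [glance.ensemble_stats()].
#' @examples
#' st <- run_ensemble(ensemble_spec(n_networks = 20, seed = 7))
#' glance(st)
#' @export
run_ensemble <- function(spec, reference_basin = 219L) {
  stopifnot(inherits(spec, "ensemble_spec"))
  per <- vector("list", spec$n_networks)
  pooled <- vector("list", spec$n_networks)
  for (k in seq_len(spec$n_networks)) {
    net <- generate_random_network(spec, k)
    rep <- enumerate_attractors(net)
    a <- rep$attractors
    fp <- a[a$type == "fixed_point", ]
    per[[k]] <- tibble::tibble(
      network_id = k,
      n_fixed_points = nrow(fp),
      n_cycles = sum(a$type == "cycle"),
      largest_basin = if (nrow(fp)) max(fp$basin_size) else 0L
    )
    pooled[[k]] <- fp$basin_size
  }
  per_network <- dplyr::bind_rows(per)
  basins <- unlist(pooled)
  hist <- tibble::as_tibble(as.data.frame(table(basin_size = basins),
                                          stringsAsFactors = FALSE))
  names(hist) <- c("basin_size", "count")
  hist$basin_size <- as.integer(hist$basin_size)
  hist$probability <- hist$count / sum(hist$count)
  structure(
    list(
      spec = spec,
      reference_basin = as.integer(reference_basin),
      per_network = per_network,
      pooled_basins = basins,
      basin_histogram = hist
    ),
    class = "ensemble_stats"
  )
}

#' @export
print.ensemble_stats <- function(x, ...) {
  g <- glance(x)
  cat("<ensemble_stats> ", nrow(x$per_network), " networks; mean fixed points ",
      round(g$mean_attractors, 2), "; mean largest basin ",
      round(g$mean_largest_basin, 2), "; P(basin > ", x$reference_basin,
      ") = ", signif(g$exceedance_pooled, 3), " (pooled)\n", sep = "")
  invisible(x)
}

#' Per-network and summary tables of an ensemble
#'
#' `tidy()` returns the per-network record (one row per random network);
#' `glance()` the one-row summary: means with standard errors and normal
#' 95% confidence intervals, and the exceedance fraction versus the
#' reference basin under both denominators (`exceedance_pooled`: share of
#' all pooled fixed points with basin > reference; `exceedance_largest`:
#' share of networks whose largest basin exceeds it).
#'
#' @param x An `ensemble_stats` object.
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.ensemble_stats <- function(x, ...) x$per_network
#' @rdname tidy.ensemble_stats
#' @export
glance.ensemble_stats <- function(x, ...) {
  p <- x$per_network
  nn <- nrow(p)
  se <- function(v) stats::sd(v) / sqrt(length(v))
  se_a <- se(p$n_fixed_points)
  se_b <- se(p$largest_basin)
  tibble::tibble(
    n_networks = nn,
    mean_attractors = mean(p$n_fixed_points),
    se_attractors = se_a,
    ci_attractors_lo = mean(p$n_fixed_points) - 1.96 * se_a,
    ci_attractors_hi = mean(p$n_fixed_points) + 1.96 * se_a,
    mean_largest_basin = mean(p$largest_basin),
    se_largest_basin = se_b,
    ci_largest_basin_lo = mean(p$largest_basin) - 1.96 * se_b,
    ci_largest_basin_hi = mean(p$largest_basin) + 1.96 * se_b,
    total_fixed_points = length(x$pooled_basins),
    exceedance_pooled = mean(x$pooled_basins > x$reference_basin),
    exceedance_largest = mean(p$largest_basin > x$reference_basin),
    reference_basin = x$reference_basin
  )
}

#' Pooled basin-size distribution
#'
#' The empirical probability of each fixed-point basin size pooled across
#' the ensemble — the distribution whose heavy tail distinguishes random
#' networks from the biological one. Optionally written as a two-column
#' TSV (`basin_size`, `probability`) ready for log-log plotting.
#'
#' @param stats An `ensemble_stats` object.
#' @param path Optional output TSV path.
#' @return A tibble with `basin_size`, `count`, `probability`
#'   (probabilities sum to 1).
#' @export
basin_size_distribution <- function(stats, path = NULL) {
  stopifnot(inherits(stats, "ensemble_stats"))
  if (length(stats$pooled_basins) == 0) {
    stop("ensemble contains no fixed points; nothing to tabulate",
         call. = FALSE)
  }
  h <- stats$basin_histogram
  if (!is.null(path)) {
    readr::write_tsv(h[c("basin_size", "probability")], path)
  }
  h
}
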