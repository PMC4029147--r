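# Shared fixtures and the naive enumeration oracle.

# 2-node toy: A activates B, B degrades itself. Hand-evaluated truth table:
# (0,0)->(0,0)  (0,1)->(0,0)  (1,0)->(1,1)  (1,1)->(1,1)
toy_ab <- function() {
  as_threshold_network(
    data.frame(source = c("A", "B"), target = c("B", "B"),
               weight = c(1, -1)),
    nodes = c("A", "B")
  )
}

edgeless_net <- function(n) {
  as_threshold_network(
    data.frame(source = character(), target = character(),
               weight = numeric()),
    nodes = paste0("n", seq_len(n))
  )
}

# Independent oracle: follow the orbit of every state individually, with
# per-orbit cycle detection and no memoisation, and tally basins. Returns
# attractors as a list of sorted state-index vectors plus basin counts,
# both ordered like enumerate_attractors (descending basin, then ascending
# min state index).
oracle_attractors <- function(net) {
  n <- length(net$nodes)
  m <- 2^n
  att_keys <- character(0)
  att_states <- list()
  basin <- integer(0)
  for (idx in 0:(m - 1)) {
    s <- state_from_index(idx, n)
    seen <- character(0)
    repeat {
      key <- format_state(s)
      hit <- match(key, seen)
      if (!is.na(hit)) {
        cyc_keys <- seen[hit:length(seen)]
        cyc_idx <- sort(vapply(cyc_keys,
                               function(k) state_index(parse_state(k)),
                               numeric(1)))
        akey <- paste(cyc_idx, collapse = ",")
        j <- match(akey, att_keys)
        if (is.na(j)) {
          att_keys <- c(att_keys, akey)
          att_states <- c(att_states, list(unname(cyc_idx)))
          basin <- c(basin, 0L)
          j <- length(att_keys)
        }
        basin[j] <- basin[j] + 1L
        break
      }
      seen <- c(seen, key)
      s <- successor_state(net, s)
    }
  }
  ord <- order(-basin, vapply(att_states, min, numeric(1)))
  list(states = att_states[ord], basin = basin[ord])
}

# Small random signed network for property tests (may contain cycles).
random_small_net <- function(n_nodes, n_edges, seed) {
  set.seed(seed)
  nodes <- paste0("g", seq_len(n_nodes))
  pairs <- expand.grid(s = seq_len(n_nodes), t = seq_len(n_nodes))
  pick <- sample(nrow(pairs), min(n_edges, nrow(pairs)))
  as_threshold_network(
    data.frame(source = nodes[pairs$s[pick]], target = nodes[pairs$t[pick]],
               weight = sample(c(-1, 1), length(pick), replace = TRUE)),
    nodes = nodes
  )
}

# Published golden tables for the built-in network.
golden_attractor_table <- data.frame(
  basin_size = c(219L, 16L, 12L, 5L, 4L),
  state = c("00010111", "01010111", "00000111", "01000111", "00000000")
)

golden_wildtype_pathway <- data.frame(
  time = 1:8,
  state = c("10010111", "00100101", "00010001", "00010000",
            "00011000", "00011010", "00011111", "00010111"),
  phase = c("S", "S/M", "S/M", "S/M", "M", "M", "M", "M/S")
)

# cki-1 knockdown pathway; the knocked node's own column is excluded from
# comparison (the published column is inconsistent with the update rule).
golden_cki_kd_pathway <- data.frame(
  time = 1:7,
  state7 = c("1001011", "0010010", "0001000", "0001100",
             "0001101", "0001111", "0001011"),
  phase = c("S", "S/M", "S/M", "M", "M", "M", "M/S")
)
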