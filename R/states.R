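#' Network states as bit-vectors
#'
#' A network state is an ordered 0/1 vector, one bit per node in the
#' canonical node order. The integer encoding treats the first node as the
#' most significant bit, so for an N-node network the state index lies in
#' `[0, 2^N)` and `"10010111"` on the built-in network means cdk-2/cyclinE
#' on, cdc-25.1 off, and so on left to right.
#'
#' @param state A bit-string such as `"10010111"`, or a 0/1 vector.
#' @param n Number of nodes.
#' @param index Non-negative integer state index.
#' @return `parse_state()` an integer 0/1 vector; `format_state()` a
#'   bit-string; `state_index()` the integer encoding;
#'   `state_from_index()` the bit-vector for an index.
#' @examples
#' state_index(parse_state("00010111"))
#' format_state(state_from_index(23, 8))
#' @name network-state
NULL

#' @rdname network-state
#' @export
parse_state <- function(state, n = NULL) {
  if (is.character(state)) {
    stopifnot(length(state) == 1)
    bits <- suppressWarnings(as.integer(strsplit(state, "")[[1]]))
  } else {
    bits <- suppressWarnings(as.integer(state))
  }
  if (anyNA(bits) || !all(bits %in% c(0L, 1L))) {
    stop("state must consist of 0s and 1s only", call. = FALSE)
  }
  if (!is.null(n) && length(bits) != n) {
    stop("state has ", length(bits), " bits but the network has ", n,
         " nodes", call. = FALSE)
  }
  bits
}

#' @rdname network-state
#' @export
format_state <- function(state) paste(as.integer(state), collapse = "")

#' @rdname network-state
#' @export
state_index <- function(state) {
  bits <- as.integer(state)
  sum(bits * 2L^(rev(seq_along(bits)) - 1L))
}

#' @rdname network-state
#' @export
state_from_index <- function(index, n) {
  stopifnot(index >= 0, index < 2^n)
  as.integer(intToBits(index)[n:1] != 0)
}

# All 2^n states as a (2^n x n) 0/1 matrix, row r = state index r-1.
state_space_matrix <- function(n) {
  m <- as.integer(2^n)
  idx <- 0:(m - 1L)
  vapply(seq_len(n), function(j) (idx %/% as.integer(2^(n - j))) %% 2L,
         integer(m))
}
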