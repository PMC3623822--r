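# Suffix Tarray: a frequency-truncated trie over the reversed reference whose
# nodes cache SA intervals on the forward FM-index, with FM backward search as
# the fallback below the trie.  A root-to-node path (edge labels in
# backward-search consumption order) is a substring of the reversed reference;
# the node's cached interval is the SA interval of the reversed path on the
# forward index, and its frequency is that interval's width.

#' Occurrence count of a substring in the reversed reference
#'
#' The frequency value a trie node would carry: the number of occurrences of
#' `s` in the reversed reference `xbar`.
#'
#' @param xbar The reversed reference, as a character scalar or an `fm_index`
#'   built from it.
#' @param s Nonempty query string.
#' @return Integer occurrence count.
#' @examples
#' node_frequency("AGAACTTCTA", "CT")  # 2
#' @export
node_frequency <- function(xbar, s) {
  if (!inherits(xbar, "fm_index")) xbar <- build_fm_index(xbar)
  count_occurrences(xbar, s)
}

#' Build the frequency-truncated trie
#'
#' Contains exactly the paths (up to `max_depth`) whose frequency in the
#' reversed reference is at least `epsilon`; truncation is automatically
#' prefix-closed because frequency is non-increasing along a path. Each node
#' caches the SA interval of its reversed path string on `fm`. If the non-root
#' node count would exceed `node_budget` the construction aborts and returns
#' with `exceeded = TRUE` (a size signal consumed by [select_epsilon()], not a
#' user-facing failure).
#'
#' @param fm `fm_index` of the forward reference.
#' @param epsilon Frequency threshold (>= 1).
#' @param node_budget Maximum number of non-root nodes (default unbounded).
#' @param max_depth Maximum trie depth (default 12).
#' @return A list with `children` (node x 4 matrix of 1-based child ids, 0 =
#'   absent), `k`, `l`, `depth`, `parent`, `edge`, and `exceeded`. Node 1 is
#'   the root with the empty-query interval.
#' @export
build_truncated_trie <- function(fm, epsilon, node_budget = Inf, max_depth = 12L) {
  stopifnot(inherits(fm, "fm_index"))
  epsilon <- as.integer(epsilon)
  if (is.na(epsilon) || epsilon < 1L) stop("epsilon must be >= 1")
  if (node_budget < 0) stop("node_budget must be >= 0")
  build_trie_cpp(fm$bwt, fm$C, fm$occ_buckets, fm$bucket_size,
                 epsilon, as.numeric(node_budget), as.integer(max_depth))
}

#' Select the frequency threshold for a node budget
#'
#' Trie size is non-increasing in the threshold, so the smallest admissible
#' epsilon (whose trie fits `node_budget`) is found by binary search over
#' `[1, n]`; it yields the largest trie within the budget.
#'
#' @param fm `fm_index` of the forward reference.
#' @param node_budget Maximum non-root node count (>= 1).
#' @param max_depth Maximum trie depth.
#' @return List with `epsilon` and the corresponding `trie`.
#' @export
select_epsilon <- function(fm, node_budget, max_depth = 12L) {
  stopifnot(inherits(fm, "fm_index"), node_budget >= 1)
  lo <- 1L; hi <- fm$n
  while (lo < hi) {
    mid <- lo + (hi - lo) %/% 2L
    t <- build_truncated_trie(fm, mid, node_budget, max_depth)
    if (t$exceeded) lo <- mid + 1L else hi <- mid
  }
  trie <- build_truncated_trie(fm, lo, node_budget, max_depth)
  if (trie$exceeded) stop("internal error: no admissible epsilon for budget ", node_budget)
  list(epsilon = lo, trie = trie)
}

#' Build a Suffix Tarray
#'
#' Wraps an FM-index with the largest frequency-truncated trie that fits the
#' node budget (threshold chosen by [select_epsilon()]).
#'
#' @param fm `fm_index` of the forward reference.
#' @param node_budget Maximum non-root trie nodes; the `index` CLI derives it
#'   from a byte budget at 36 bytes per node.
#' @param max_depth Maximum trie depth (default 12).
#' @param epsilon Optional explicit threshold (skips selection).
#' @return An object of class `suffix_tarray`.
#' @export
build_suffix_tarray <- function(fm, node_budget = 8192L, max_depth = 12L,
                                epsilon = NULL) {
  stopifnot(inherits(fm, "fm_index"))
  if (is.null(epsilon)) {
    sel <- select_epsilon(fm, node_budget, max_depth)
    epsilon <- sel$epsilon
    trie <- sel$trie
  } else {
    trie <- build_truncated_trie(fm, epsilon, node_budget, max_depth)
    if (trie$exceeded) stop("trie exceeds node_budget at epsilon = ", epsilon)
  }
  structure(
    list(fm = fm, children = trie$children, k = trie$k, l = trie$l,
         depth = trie$depth, parent = trie$parent, edge = trie$edge,
         epsilon = as.integer(epsilon), node_budget = node_budget,
         max_depth = as.integer(max_depth)),
    class = "suffix_tarray")
}

#' @export
print.suffix_tarray <- function(x, ...) {
  cat("Suffix Tarray: n =", x$fm$n, "| nodes =", nrow(x$children) - 1L,
      "(non-root) | epsilon =", x$epsilon, "| max_depth =", x$max_depth, "\n")
  invisible(x)
}

#' Number of non-root trie nodes
#' @param sta A `suffix_tarray` or a trie list from [build_truncated_trie()].
#' @return Integer count.
#' @export
trie_node_count <- function(sta) {
  nrow(sta$children) - 1L
}

#' Look up a trie node by its path string
#'
#' Descends the trie along the characters of `s` (a substring of the reversed
#' reference). Returns `NULL` when the path left the trie.
#'
#' @param sta A `suffix_tarray`.
#' @param s Path string.
#' @return List with `node` (1-based id), `interval` and `frequency`, or `NULL`.
#' @export
trie_lookup <- function(sta, s) {
  codes <- .as_codes_read(s)
  node <- 1L
  for (code in codes) {
    if (code < 1L || code > 4L) return(NULL)
    child <- sta$children[node, code]
    if (child == 0L) return(NULL)
    node <- child
  }
  list(node = node, interval = c(sta$k[node], sta$l[node]),
       frequency = sta$l[node] - sta$k[node] + 1L)
}

#' Initial state for stepped backward search through a Suffix Tarray
#' @param sta A `suffix_tarray`.
#' @return State list: trie root plus the empty-query interval.
#' @export
sta_state_init <- function(sta) {
  stopifnot(inherits(sta, "suffix_tarray"))
  list(node = 1L, interval = fm_interval_init(sta$fm))
}

#' One backward-search step through a Suffix Tarray
#'
#' While the query prefix is resolved in the trie, descends the child edge and
#' returns its cached interval without any Occ computation; on a missing child
#' the state transitions permanently to FM mode, seeded with the current
#' interval, and further steps delegate to [backward_extend()]. The interval
#' sequence is identical to FM-only backward search at every step.
#'
#' @param sta A `suffix_tarray`.
#' @param state A state from [sta_state_init()] or a previous step.
#' @param c Single character.
#' @return Updated state (`node` is `NULL` in FM mode).
#' @export
sta_backward_step <- function(sta, state, c) {
  code <- .as_code1(c)
  if (code < 1L || code > 4L) {
    return(list(node = NULL, interval = c(1L, 0L)))
  }
  if (!is.null(state$node)) {
    child <- sta$children[state$node, code]
    if (child > 0L) {
      return(list(node = child, interval = c(sta$k[child], sta$l[child])))
    }
  }
  iv <- state$interval
  if (iv[1L] > iv[2L]) return(list(node = NULL, interval = c(1L, 0L)))
  list(node = NULL, interval = as.integer(.bw_ext(sta$fm, iv[1L], iv[2L], code)))
}
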