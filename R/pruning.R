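# Lower bounds on edit cost used to prune the inexact search.  The D-metric
# charges every column (substitution = 1, gap open = 1, gap extension = 1),
# unlike the search metric where extensions are free; both D-arrays below are
# true lower bounds under the D-metric only.

#' Minimal edit cost of aligning a string onto a reference
#'
#' The minimum, over all substrings of `X`, of the cost of transforming `w`
#' into that substring. Under `model = "full_edit"` substitutions, insertions
#' and deletions all cost 1 (semi-global dynamic programme, free ends in `X`);
#' under `model = "substitution_only"` only mismatches over equal-length
#' windows are counted (the model under which mined two-edit patterns are
#' verified by default).
#'
#' @param w Nonempty query string.
#' @param X Reference string (or `fm_index`-sized character).
#' @param model `"full_edit"` or `"substitution_only"`.
#' @return Integer minimal cost `e(w)`.
#' @examples
#' edit_distance_to_reference("AACT", "AACGTATCGACG")   # 1
#' edit_distance_to_reference("AACTG", "AACGTATCGACG")  # 1 (delete T)
#' edit_distance_to_reference("AACTG", "AACGTATCGACG", "substitution_only")  # 2
#' @export
edit_distance_to_reference <- function(w, X,
                                       model = c("full_edit", "substitution_only")) {
  model <- match.arg(model)
  wc <- .as_codes_read(w)
  xc <- .as_codes_ref(X)
  m <- length(wc)
  n <- length(xc)
  if (m == 0L) stop("w must be nonempty")
  if (model == "substitution_only") {
    if (m > n) return(m - n + if (n > 0L) min_hamming(wc[seq_len(n)], xc) else 0L)
    return(min_hamming(wc, xc))
  }
  rm <- .semiglobal_rowmins(wc, xc)
  rm[length(rm)]
}

# Minimum Hamming distance of wc over all equal-length windows of xc.
min_hamming <- function(wc, xc) {
  m <- length(wc); n <- length(xc)
  best <- m
  for (j in 0:(n - m)) {
    d <- sum(wc != xc[(j + 1L):(j + m)])
    if (d < best) best <- d
    if (best == 0L) break
  }
  as.integer(best)
}

# Semi-global DP: row i holds, for each end column j in X, the minimal cost of
# aligning w[1..i] to some substring of X ending at j (free start).  Returns
# the per-row minima: the true D-metric lower bound for every prefix of w.
.semiglobal_rowmins <- function(wc, xc) {
  m <- length(wc); n <- length(xc)
  prev <- integer(n + 1L)  # dp[0, ] = 0: free start anywhere
  rowmin <- integer(m)
  for (i in seq_len(m)) {
    sub <- prev[seq_len(n)] + as.integer(wc[i] != xc)
    ins <- prev[2L:(n + 1L)] + 1L
    cand <- pmin(sub, ins)
    cur <- integer(n + 1L)
    cur[1L] <- i
    for (j in seq_len(n)) cur[j + 1L] <- min(cand[j], cur[j] + 1L)
    rowmin[i] <- min(cur)
    prev <- cur
  }
  rowmin
}

#' Single-mismatch segmentation lower bound (basic D-array)
#'
#' Forward scan of `W` maintaining a window that must remain a substring of
#' the reference (checked by backward extension on the index of the reversed
#' reference). Whenever appending `W[i]` breaks the window, the running bound
#' is incremented and the window restarts empty at the next position;
#' `D[i]` is the running bound after position `i` (1-based positions, bound on
#' the prefix `W[1..i]`).
#'
#' @param W Nonempty read string.
#' @param rev_ref_index `fm_index` of the reversed reference.
#' @return Integer vector of per-prefix lower bounds (non-negative,
#'   non-decreasing).
#' @examples
#' rev_fm <- build_fm_index(revstring("AACGTATCGACG"))
#' calculate_d_basic("AACTGA", rev_fm)  # 0 0 0 1 1 1
#' @export
calculate_d_basic <- function(W, rev_ref_index) {
  stopifnot(inherits(rev_ref_index, "fm_index"))
  codes <- .as_codes_read(W)
  m <- length(codes)
  if (m == 0L) stop("W must be nonempty")
  n <- rev_ref_index$n
  D <- integer(m)
  z <- 0L; k <- 0L; l <- n
  for (i in seq_len(m)) {
    code <- codes[i]
    iv <- if (code >= 1L && code <= 4L) .bw_ext(rev_ref_index, k, l, code) else c(1L, 0L)
    if (iv[1L] > iv[2L]) {
      z <- z + 1L
      k <- 0L; l <- n   # window restarts empty after the breaking position
    } else {
      k <- iv[1L]; l <- iv[2L]
    }
    D[i] <- z
  }
  D
}

#' Reverse a DNA string (no complementation)
#' @param x Character scalar.
#' @return The reversed string.
#' @export
revstring <- function(x) {
  paste(rev(strsplit(x, "", fixed = TRUE)[[1L]]), collapse = "")
}

#' Mine frequent two-edit patterns from training reads
#'
#' Enumerates substrings of the training reads by depth-first traversal of an
#' FM-index built over their concatenation (reads isolated by separator
#' symbols), keeping strings that occur at least `min_freq` times. Candidates
#' are then filtered to those with minimal edit value `e(f) = 2` against the
#' reference under `model`, ordered by frequency (descending, ties broken
#' lexicographically), and accepted greedily until the Aho-Corasick automaton
#' byte budget (`bytes_per_state` per state, root included) is filled.
#'
#' @param training_reads Nonempty character vector of reads.
#' @param ref Reference string.
#' @param byte_budget Automaton byte budget.
#' @param model Edit model for verifying `e(f) = 2`; default `"full_edit"`
#'   (indels count); `"substitution_only"` verifies over equal-length windows
#'   and is the model under which one-deletion strings do not qualify.
#' @param min_freq Frequency floor applied before edit filtering (default 10).
#' @param max_pattern_length Longest candidate considered (default 16).
#' @param bytes_per_state Byte cost per automaton state (default 64).
#' @return `data.frame` with `pattern`, `e_value` (always 2) and `frequency`.
#' @export
mine_frequent_patterns <- function(training_reads, ref, byte_budget,
                                   model = c("full_edit", "substitution_only"),
                                   min_freq = 10L, max_pattern_length = 16L,
                                   bytes_per_state = 64L) {
  model <- match.arg(model)
  if (length(training_reads) == 0L) stop("training read set must be nonempty")
  min_freq <- max(1L, as.integer(min_freq))

  # concatenate reads with separators so no substring spans two reads
  parts <- lapply(training_reads, .as_codes_read)
  codes <- integer(sum(lengths(parts)) + length(parts) - 1L)
  at <- 1L
  for (i in seq_along(parts)) {
    p <- parts[[i]]
    if (length(p)) codes[at:(at + length(p) - 1L)] <- p
    at <- at + length(p)
    if (i < length(parts)) { codes[at] <- 5L; at <- at + 1L }
  }
  tfm <- build_fm_index(codes)

  # DFS over backward extensions: a stack entry is (interval, string); the
  # child on c represents the string c<parent> (prepending), so every
  # substring of the concatenation over ACGT is enumerated exactly once.
  pats <- character(0)
  freqs <- integer(0)
  stack <- list(list(k = 0L, l = tfm$n, s = "", d = 0L))
  while (length(stack)) {
    top <- stack[[length(stack)]]
    stack[[length(stack)]] <- NULL
    if (top$d >= max_pattern_length) next
    for (code in 1:4) {
      iv <- .bw_ext(tfm, top$k, top$l, code)
      w <- iv[2L] - iv[1L] + 1L
      if (w < min_freq) next
      s <- paste0(.ALPHABET[code], top$s)
      pats <- c(pats, s)
      freqs <- c(freqs, w)
      stack[[length(stack) + 1L]] <- list(k = iv[1L], l = iv[2L], s = s,
                                          d = top$d + 1L)
    }
  }
  if (length(pats) == 0L) {
    return(data.frame(pattern = character(0), e_value = integer(0),
                      frequency = integer(0), stringsAsFactors = FALSE))
  }

  ev <- vapply(pats, function(p) edit_distance_to_reference(p, ref, model),
               integer(1L), USE.NAMES = FALSE)
  keep <- ev == 2L
  pats <- pats[keep]
  freqs <- freqs[keep]
  o <- order(-freqs, pats, method = "radix")
  pats <- pats[o]
  freqs <- freqs[o]

  # greedy fill of the byte budget: count new automaton states (= new pattern
  # prefixes) each accepted pattern contributes; root state always present
  seen_prefix <- new.env(parent = emptyenv())
  states <- 1L
  sel <- logical(length(pats))
  for (i in seq_along(pats)) {
    p <- pats[i]
    new_states <- 0L
    for (d in seq_len(nchar(p))) {
      pre <- substr(p, 1L, d)
      if (is.null(seen_prefix[[pre]])) new_states <- new_states + 1L
    }
    if ((states + new_states) * bytes_per_state > byte_budget) next
    for (d in seq_len(nchar(p))) {
      pre <- substr(p, 1L, d)
      if (is.null(seen_prefix[[pre]])) seen_prefix[[pre]] <- TRUE
    }
    states <- states + new_states
    sel[i] <- TRUE
  }
  data.frame(pattern = pats[sel], e_value = rep(2L, sum(sel)),
             frequency = freqs[sel], stringsAsFactors = FALSE)
}

#' Build an Aho-Corasick automaton over frequent patterns
#'
#' Trie of the patterns with breadth-first failure links and totalized goto
#' transitions. Leaf states mark complete patterns; each state also carries an
#' output link to the nearest leaf on its failure chain, so a match is
#' detected whenever the scanned window has any pattern as a suffix (the
#' longest such pattern is reported). Duplicate patterns collapse to one leaf.
#'
#' @param patterns Character vector of patterns, or a `data.frame` with a
#'   `pattern` column (as returned by [mine_frequent_patterns()]); an
#'   `e_value` column is carried along (default 2).
#' @return Object of class `ac_automaton`: totalized `goto` (state x 4),
#'   `fail`, `leaf_pat` (pattern id or 0), `outleaf` (nearest leaf state or 0),
#'   `state_str`, and the `patterns` data frame.
#' @export
build_ac_automaton <- function(patterns) {
  if (is.data.frame(patterns)) {
    pat_df <- patterns
    pats <- as.character(pat_df$pattern)
    evs <- if ("e_value" %in% names(pat_df)) as.integer(pat_df$e_value) else rep(2L, length(pats))
  } else {
    pats <- as.character(patterns)
    evs <- rep(2L, length(pats))
  }
  dup <- duplicated(pats)
  pats <- pats[!dup]
  evs <- evs[!dup]

  children <- matrix(0L, nrow = 1L, ncol = 4L)
  state_str <- ""
  leaf_pat <- 0L
  for (pi in seq_along(pats)) {
    codes <- .as_codes_read(pats[pi])
    if (any(codes < 1L | codes > 4L)) stop("pattern outside {A,C,G,T}: ", pats[pi])
    st <- 1L
    for (code in codes) {
      child <- children[st, code]
      if (child == 0L) {
        children <- rbind(children, rep(0L, 4L))
        state_str <- c(state_str, paste0(state_str[st], .ALPHABET[code]))
        leaf_pat <- c(leaf_pat, 0L)
        child <- nrow(children)
        children[st, code] <- child
      }
      st <- child
    }
    leaf_pat[st] <- pi
  }

  ns <- nrow(children)
  goto <- children
  fail <- rep(1L, ns)
  outleaf <- integer(ns)
  queue <- integer(0)
  for (code in 1:4) {
    v <- children[1L, code]
    if (v > 0L) {
      fail[v] <- 1L
      outleaf[v] <- if (leaf_pat[v] > 0L) v else 0L
      queue <- c(queue, v)
    } else {
      goto[1L, code] <- 1L
    }
  }
  qi <- 1L
  while (qi <= length(queue)) {
    u <- queue[qi]; qi <- qi + 1L
    for (code in 1:4) {
      v <- children[u, code]
      if (v > 0L) {
        fail[v] <- goto[fail[u], code]
        outleaf[v] <- if (leaf_pat[v] > 0L) v else outleaf[fail[v]]
        queue <- c(queue, v)
      } else {
        goto[u, code] <- goto[fail[u], code]
      }
    }
  }

  structure(
    list(goto = goto, fail = fail, leaf_pat = leaf_pat, outleaf = outleaf,
         state_str = state_str,
         patterns = data.frame(pattern = pats, e_value = evs,
                               stringsAsFactors = FALSE)),
    class = "ac_automaton")
}

#' @export
print.ac_automaton <- function(x, ...) {
  cat("Aho-Corasick automaton:", nrow(x$patterns), "patterns,",
      length(x$fail), "states\n")
  invisible(x)
}

#' Greedy non-overlapping pattern scan
#'
#' Single left-to-right pass of `W` through the automaton; whenever a leaf
#' state is reached (directly or through the output link) the match is
#' recorded, the automaton resets to the root, and scanning resumes at the
#' next character, so matches are non-overlapping and greedy-first.
#'
#' @param automaton An `ac_automaton`.
#' @param W String to scan.
#' @return `data.frame` with `end` (0-based end position) and `pattern`.
#' @examples
#' a <- build_ac_automaton(c("AA", "AC", "AG", "C", "G", "T"))
#' scan_patterns(a, "CAT")  # C ending at 0, T ending at 2
#' @export
scan_patterns <- function(automaton, W) {
  stopifnot(inherits(automaton, "ac_automaton"))
  codes <- .as_codes_read(W)
  ends <- integer(0)
  found <- character(0)
  st <- 1L
  for (i in seq_along(codes)) {
    code <- codes[i]
    st <- if (code >= 1L && code <= 4L) automaton$goto[st, code] else 1L
    lf <- automaton$outleaf[st]
    if (lf > 0L) {
      ends <- c(ends, i - 1L)
      found <- c(found, automaton$patterns$pattern[automaton$leaf_pat[lf]])
      st <- 1L
    }
  }
  data.frame(end = ends, pattern = found, stringsAsFactors = FALSE)
}

#' Pattern-tightened lower bound (DCDC D-array)
#'
#' Runs the single-mismatch fallback recurrence of [calculate_d_basic()] and
#' an Aho-Corasick scan concurrently from the current segment start. Positions
#' before a pattern completes carry the fallback bound; when a pattern with
#' edit value 2 completes at position `i`, `D[i]` becomes the bound at the
#' segment start plus 2, the segment restarts at `i + 1` with the automaton
#' reset and an empty fallback window. The array is finalized as a running
#' maximum to preserve monotonicity.
#'
#' @param W Nonempty read string.
#' @param rev_ref_index `fm_index` of the reversed reference.
#' @param automaton An `ac_automaton` of mined patterns (possibly empty, in
#'   which case the result equals [calculate_d_basic()]).
#' @return Integer vector of per-prefix lower bounds.
#' @examples
#' rev_fm <- build_fm_index(revstring("AACGTATCGACG"))
#' aut <- build_ac_automaton("AACTG")
#' calculate_d_dcdc("AACTGA", rev_fm, aut)  # 0 0 0 1 2 2
#' @export
calculate_d_dcdc <- function(W, rev_ref_index, automaton) {
  stopifnot(inherits(rev_ref_index, "fm_index"), inherits(automaton, "ac_automaton"))
  codes <- .as_codes_read(W)
  m <- length(codes)
  if (m == 0L) stop("W must be nonempty")
  n <- rev_ref_index$n
  D <- integer(m)
  base <- 0L   # committed bound at the current segment start
  fz <- 0L     # fallback increments inside the current segment
  k <- 0L; l <- n
  st <- 1L
  for (i in seq_len(m)) {
    code <- codes[i]
    iv <- if (code >= 1L && code <= 4L) .bw_ext(rev_ref_index, k, l, code) else c(1L, 0L)
    if (iv[1L] > iv[2L]) {
      fz <- fz + 1L
      k <- 0L; l <- n
    } else {
      k <- iv[1L]; l <- iv[2L]
    }
    st <- if (code >= 1L && code <= 4L) automaton$goto[st, code] else 1L
    if (automaton$outleaf[st] > 0L) {
      base <- base + 2L
      D[i] <- base
      fz <- 0L; k <- 0L; l <- n
      st <- 1L
    } else {
      D[i] <- base + fz
    }
  }
  as.integer(cummax(D))
}
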