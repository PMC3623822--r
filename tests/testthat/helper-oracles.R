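# Independent oracles used across the suite.  Everything here is written
# against definitions (brute force, enumeration, naive DP), not against the
# package's own code paths.

rand_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n, replace = TRUE),
                              collapse = "")

# Brute-force suffix array: sort sentinel-terminated suffixes byte-wise.
# "$" (0x24) sorts below "A" in the C locale used by radix order.
brute_suffix_array <- function(text) {
  t0 <- paste0(text, "$")
  sufs <- substring(t0, seq_len(nchar(t0)), nchar(t0))
  order(sufs, method = "radix") - 1L
}

brute_bwt <- function(text) {
  sa <- brute_suffix_array(text)
  t0 <- strsplit(paste0(text, "$"), "")[[1L]]
  n1 <- length(t0)
  vapply(sa, function(p) t0[((p - 1L) %% n1) + 1L], character(1L))
}

# Sliding-window occurrence count of w in text.
brute_count <- function(text, w) {
  m <- nchar(w); n <- nchar(text)
  if (m > n) return(0L)
  sum(vapply(0:(n - m), function(j) substr(text, j + 1L, j + m) == w,
             logical(1L)))
}

brute_positions <- function(text, w) {
  m <- nchar(w); n <- nchar(text)
  if (m > n) return(integer(0))
  which(vapply(0:(n - m), function(j) substr(text, j + 1L, j + m) == w,
               logical(1L))) - 1L
}

# Naive minimal edit distance of w to any substring of X (full edit model),
# via base adist over every substring.  Tiny inputs only.
brute_edit_to_ref <- function(w, X) {
  n <- nchar(X)
  best <- nchar(w)  # empty substring: delete everything
  for (i in 0:(n - 1L)) {
    for (j in (i + 1L):n) {
      d <- utils::adist(w, substr(X, i + 1L, j))[1L, 1L]
      if (d < best) best <- d
    }
  }
  as.integer(best)
}

# Full-DP prefix lower bounds: for every prefix w[1..i], the minimal D-metric
# cost (every column charged 1) against any substring of X.  Used to certify
# that the D-arrays are true lower bounds.
dp_prefix_bounds <- function(w, X) {
  wc <- strsplit(w, "")[[1L]]
  xc <- strsplit(X, "")[[1L]]
  m <- length(wc); n <- length(xc)
  prev <- rep(0L, n + 1L)
  out <- integer(m)
  for (i in seq_len(m)) {
    cur <- integer(n + 1L)
    cur[1L] <- i
    for (j in seq_len(n)) {
      cur[j + 1L] <- min(prev[j] + (wc[i] != xc[j]),
                         prev[j + 1L] + 1L,
                         cur[j] + 1L)
    }
    out[i] <- min(cur)
    prev <- cur
  }
  out
}

# Independent re-implementation of the single-mismatch segmentation
# recurrence, using sliding-window substring tests instead of the FM-index.
brute_d_basic <- function(W, X) {
  m <- nchar(W)
  D <- integer(m)
  z <- 0L; j <- 1L
  for (i in seq_len(m)) {
    win <- substr(W, j, i)
    if (j > i || brute_count(X, win) > 0L) {
      # window still a substring
    } else {
      z <- z + 1L
      j <- i + 1L
    }
    D[i] <- z
  }
  D
}

# Longest proper suffix of s that is a prefix of any pattern (for checking
# failure links by definition).
brute_fail_target <- function(s, prefixes) {
  for (start in 2:(nchar(s) + 1L)) {
    suf <- substr(s, start, nchar(s))
    if (suf %in% prefixes) return(suf)
  }
  ""
}

# Greedy non-overlapping scan by definition: from the current start, find the
# smallest end such that some pattern is a suffix of the window; report the
# longest such pattern, resume at end + 1.
brute_greedy_scan <- function(patterns, W) {
  m <- nchar(W)
  ends <- integer(0); found <- character(0)
  start <- 1L
  i <- start
  while (i <= m) {
    win <- substr(W, start, i)
    cand <- patterns[vapply(patterns, function(p) {
      nchar(p) <= nchar(win) &&
        substr(win, nchar(win) - nchar(p) + 1L, nchar(win)) == p
    }, logical(1L))]
    if (length(cand)) {
      best <- cand[which.max(nchar(cand))]
      ends <- c(ends, i - 1L)
      found <- c(found, best)
      start <- i + 1L
    }
    i <- i + 1L
  }
  data.frame(end = ends, pattern = found, stringsAsFactors = FALSE)
}

# All reads at Hamming distance <= z from w (substitution enumeration).
enumerate_sub_variants <- function(w, z) {
  bases <- c("A", "C", "G", "T")
  out <- w
  if (z >= 1L) {
    m <- nchar(w)
    for (i in seq_len(m)) {
      for (b in setdiff(bases, substr(w, i, i))) {
        v <- w
        substr(v, i, i) <- b
        out <- c(out, v)
        if (z >= 2L) {
          for (i2 in seq_len(m)) {
            if (i2 <= i) next
            for (b2 in setdiff(bases, substr(v, i2, i2))) {
              v2 <- v
              substr(v2, i2, i2) <- b2
              out <- c(out, v2)
            }
          }
        }
      }
    }
  }
  unique(out)
}

# Replay an edit script (left-to-right M/X/I/D columns) against the read to
# reconstruct the reference window it claims to match.
replay_script <- function(read, script) {
  ops <- strsplit(script, "")[[1L]]
  rc <- strsplit(read, "")[[1L]]
  ri <- 1L
  ref <- character(0)
  for (op in ops) {
    if (op == "M") { ref <- c(ref, rc[ri]); ri <- ri + 1L }
    else if (op == "X") { ref <- c(ref, NA); ri <- ri + 1L }   # some other base
    else if (op == "I") { ri <- ri + 1L }                      # read-only column
    else if (op == "D") { ref <- c(ref, NA) }                  # ref-only column
    else stop("bad op: ", op)
  }
  stopifnot(ri == length(rc) + 1L)
  ref  # NA = unconstrained-by-read reference column
}

make_bundle <- function(ref, ...) build_index_bundle(ref, ...)

# Deterministic two-gap / two-mismatch divergence case.  The reference avoids
# the dinucleotide TT; the read carries a 3-base insertion (gap open + 2 free
# extensions), a 1-base deletion and two substitutions: search-metric cost 4.
# Under the D-metric every gap column costs 1, so the pattern-tightened bound
# reaches 3 at the critical read position (0-based 15) while the basic bound
# stays at 2.
make_divergence_case <- function() {
  rand_no_tt <- function(n) {
    out <- character(n); prev <- ""
    for (i in seq_len(n)) {
      pool <- if (prev == "T") c("A", "C", "G") else c("A", "C", "G", "T")
      out[i] <- sample(pool, 1L)
      prev <- out[i]
    }
    paste(out, collapse = "")
  }
  set.seed(11)
  A1 <- rand_no_tt(6)
  A2 <- paste0("T", rand_no_tt(6))
  C1 <- rand_no_tt(5)
  C2 <- rand_no_tt(8)
  locus <- paste0(A1, A2, "A", "G", C1, "A", C2)
  X <- paste0(rand_no_tt(40), locus, rand_no_tt(40))
  W <- paste0(A1, "C", "G", "T", A2, "C", C1, "G", C2)
  P <- paste0(substr(A1, 3L, 6L), "CG")
  list(X = X, W = W, P = P, origin = 40L, critical = 16L)
}
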