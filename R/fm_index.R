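# FM-index over a sentinel-terminated text: suffix array, BWT, cumulative
# character counts C, bucketed Occ table, and a position-sampled suffix array
# for locate queries.  Rows are 0-based over n+1 suffixes; row 0 is always the
# sentinel suffix.  The empty-string query interval is [0, n].

# Prefix-doubling suffix array over integer codes (sentinel already appended).
# Returns 0-based suffix start positions in lexicographic order.
.sa_prefix_doubling <- function(codes0) {
  n <- length(codes0)
  if (n == 1L) return(0L)
  rk <- codes0 + 1L
  k <- 1L
  repeat {
    kk <- min(k, n)
    key2 <- c(rk[-seq_len(kk)], integer(kk))
    o <- order(rk, key2, method = "radix")
    r1 <- rk[o]
    r2 <- key2[o]
    new_rk <- cumsum(c(1L, as.integer(r1[-1L] != r1[-n] | r2[-1L] != r2[-n])))
    rk[o] <- new_rk
    if (new_rk[n] == n) break
    k <- k * 2L
  }
  sa <- integer(n)
  sa[rk] <- seq_len(n) - 1L
  sa
}

#' Suffix array of a sentinel-terminated text
#'
#' A sentinel smaller than every alphabet character is appended internally, so
#' the result is a permutation of `0..n` (0-based suffix start positions) with
#' the sentinel suffix in row 0.
#'
#' @param text A character scalar over `{A,C,G,T,N}` (reference N policy is
#'   applied) or an integer code vector.
#' @return Integer vector of length `n + 1`: suffix start positions in strict
#'   lexicographic order.
#' @examples
#' build_suffix_array("AAA")  # 3 2 1 0
#' @export
build_suffix_array <- function(text) {
  codes <- .as_codes_ref(text)
  if (length(codes) == 0L) stop("text must be nonempty")
  .sa_prefix_doubling(c(codes, 0L))
}

#' Build an FM-index
#'
#' Indexes a sentinel-terminated text: Burrows-Wheeler transform, cumulative
#' smaller-character counts `C`, an Occ table precomputed at fixed bucket
#' boundaries, and suffix-array values sampled at text positions divisible by
#' `sample_rate` (so every locate walk-back takes at most `sample_rate - 1`
#' LF steps).
#'
#' @param text Character scalar (reference N policy applied) or integer codes.
#' @param bucket_size Occ bucket width in BWT rows (>= 1). Affects speed only,
#'   never results.
#' @param sample_rate Suffix-array sampling rate (>= 1); 1 stores the full SA.
#' @return An object of class `fm_index`.
#' @examples
#' fm <- build_fm_index("ATCTTCAAGA")
#' count_occurrences(fm, "CT")
#' @export
build_fm_index <- function(text, bucket_size = 128L, sample_rate = 4L) {
  codes <- .as_codes_ref(text)
  if (length(codes) == 0L) stop("text must be nonempty")
  bucket_size <- as.integer(bucket_size)
  sample_rate <- as.integer(sample_rate)
  if (is.na(bucket_size) || bucket_size < 1L) stop("bucket_size must be >= 1")
  if (is.na(sample_rate) || sample_rate < 1L) stop("sample_rate must be >= 1")

  n <- length(codes)
  codes0 <- c(codes, 0L)
  sa <- .sa_prefix_doubling(codes0)
  bwt <- codes0[ifelse(sa == 0L, n + 1L, sa)]

  counts <- tabulate(bwt + 1L, nbins = 7L)        # counts[code + 1]
  C <- as.integer(cumsum(c(0L, counts[-7L])))     # C[code + 1] = # chars < code

  nb <- (n + 1L) %/% bucket_size
  occ_buckets <- matrix(0L, nrow = 7L, ncol = nb + 1L)
  if (nb > 0L) {
    bpos <- seq_len(nb) * bucket_size
    for (code in 0:6) {
      if (counts[code + 1L] == 0L) next
      occ_buckets[code + 1L, -1L] <- cumsum(bwt == code)[bpos]
    }
  }

  sa_sample <- rep(NA_integer_, n + 1L)
  keep <- sa %% sample_rate == 0L
  sa_sample[keep] <- sa[keep]

  structure(
    list(n = n, bwt = bwt, counts = counts, C = C,
         bucket_size = bucket_size, occ_buckets = occ_buckets,
         sample_rate = sample_rate, sa_sample = sa_sample),
    class = "fm_index")
}

#' @export
print.fm_index <- function(x, ...) {
  cat("FM-index: n =", x$n, "| bucket_size =", x$bucket_size,
      "| sample_rate =", x$sample_rate, "\n")
  invisible(x)
}

.as_code1 <- function(c) {
  if (is.character(c)) {
    v <- .ENC[utf8ToInt(c)]
    if (length(v) != 1L || is.na(v)) stop("not a single alphabet character: '", c, "'")
    v
  } else {
    as.integer(c)
  }
}

#' Occ query: occurrences of a character in a BWT prefix
#'
#' Counts occurrences of `c` among BWT rows `0..y` (0-based, inclusive);
#' `y = -1` denotes the empty prefix. The value is assembled from the nearest
#' precomputed bucket boundary plus an in-bucket scan, and is independent of
#' the bucket size.
#'
#' @param index An `fm_index`.
#' @param c A single character (or internal code).
#' @param y Row index in `-1..n`.
#' @return Integer count.
#' @export
occ <- function(index, c, y) {
  stopifnot(inherits(index, "fm_index"))
  y <- as.integer(y)
  if (is.na(y) || y < -1L || y > index$n) {
    stop("row index y out of range [-1, ", index$n, "]: ", y)
  }
  code <- .as_code1(c)
  if (y < 0L) return(0L)
  j <- (y + 1L) %/% index$bucket_size
  cnt <- index$occ_buckets[code + 1L, j + 1L]
  from <- j * index$bucket_size
  if (from <= y) cnt <- cnt + sum(index$bwt[(from + 1L):(y + 1L)] == code)
  as.integer(cnt)
}

# Internal fast path: no validation, code already integer.
.bw_ext <- function(index, k, l, code) {
  c(index$C[code + 1L] + .occ_raw(index, code, k - 1L),
    index$C[code + 1L] + .occ_raw(index, code, l) - 1L)
}

.occ_raw <- function(index, code, y) {
  if (y < 0L) return(0L)
  j <- (y + 1L) %/% index$bucket_size
  cnt <- index$occ_buckets[code + 1L, j + 1L]
  from <- j * index$bucket_size
  if (from <= y) cnt <- cnt + sum(index$bwt[(from + 1L):(y + 1L)] == code)
  cnt
}

#' The SA interval of the empty query
#'
#' All `n + 1` rows, including the sentinel row: `[0, n]`. Backward extension
#' from this interval by `c` yields the interval of the single-character query
#' `c`.
#'
#' @param index An `fm_index`.
#' @return Integer vector `c(k, l)`.
#' @export
fm_interval_init <- function(index) {
  stopifnot(inherits(index, "fm_index"))
  c(0L, index$n)
}

#' Backward extension of an SA interval
#'
#' Maps the SA interval of a query `W` to the interval of `cW` using the
#' Ferragina-Manzini update `k' = C(c) + Occ(c, k-1)`,
#' `l' = C(c) + Occ(c, l) - 1`. The result is empty (`k > l`) iff `cW` does
#' not occur in the text. A character outside `{A,C,G,T}` yields an empty
#' interval (documented behaviour, not an error).
#'
#' @param index An `fm_index`.
#' @param interval Integer `c(k, l)`; empty intervals propagate.
#' @param c Single character (or code).
#' @return Integer `c(k, l)` for `cW`.
#' @export
backward_extend <- function(index, interval, c) {
  stopifnot(inherits(index, "fm_index"), length(interval) == 2L)
  k <- as.integer(interval[1L]); l <- as.integer(interval[2L])
  if (k > l) return(c(1L, 0L))
  code <- if (is.character(c)) {
    v <- .ENC[utf8ToInt(c)]
    if (length(v) != 1L) stop("c must be a single character")
    v
  } else as.integer(c)
  if (is.na(code) || code < 1L || code > 4L) return(c(1L, 0L))
  iv <- as.integer(.bw_ext(index, k, l, code))
  if (iv[1L] > iv[2L]) c(1L, 0L) else iv
}

#' Count occurrences of a query string
#'
#' `|W|` backward extensions from the empty-query interval; the count is the
#' final interval width (0 when the interval empties).
#'
#' @param index An `fm_index`.
#' @param W Query string (N never matches) or integer codes.
#' @return Integer occurrence count of `W` in the indexed text.
#' @export
count_occurrences <- function(index, W) {
  stopifnot(inherits(index, "fm_index"))
  iv <- fm_query_interval(index, W)
  max(0L, iv[2L] - iv[1L] + 1L)
}

#' SA interval of a query string (full backward search)
#'
#' @param index An `fm_index`.
#' @param W Query string or integer codes.
#' @return Integer `c(k, l)`; empty (`k > l`) when `W` is absent.
#' @export
fm_query_interval <- function(index, W) {
  codes <- .as_codes_read(W)
  if (length(codes) == 0L) stop("query must be nonempty")
  k <- 0L; l <- index$n
  for (i in rev(seq_along(codes))) {
    code <- codes[i]
    if (code < 1L || code > 4L) return(c(1L, 0L))
    iv <- .bw_ext(index, k, l, code)
    if (iv[1L] > iv[2L]) return(c(1L, 0L))
    k <- iv[1L]; l <- iv[2L]
  }
  as.integer(c(k, l))
}

#' Locate: text positions of an SA interval
#'
#' Resolves each row of the interval to a 0-based text position by LF-mapping
#' walk-back to the nearest sampled suffix-array value.
#'
#' @param index An `fm_index`.
#' @param interval Integer `c(k, l)`; an empty interval yields `integer(0)`.
#' @return Sorted integer vector of 0-based start positions.
#' @export
locate <- function(index, interval) {
  stopifnot(inherits(index, "fm_index"), length(interval) == 2L)
  k <- as.integer(interval[1L]); l <- as.integer(interval[2L])
  if (k > l) return(integer(0))
  if (k < 0L || l > index$n) stop("interval out of range")
  pos <- vapply(k:l, function(row) {
    t <- 0L
    while (is.na(index$sa_sample[row + 1L])) {
      code <- index$bwt[row + 1L]
      row <- index$C[code + 1L] + .occ_raw(index, code, row) - 1L
      t <- t + 1L
    }
    index$sa_sample[row + 1L] + t
  }, integer(1L))
  sort(pos)
}
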