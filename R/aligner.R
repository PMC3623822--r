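# Bounded inexact search over the Suffix Tarray (or a raw FM-index) with
# D-array pruning, strand handling, hit selection and mapping quality.

#' Search parameter set
#'
#' @param z Maximum charged differences; `NULL` chooses a read-length default
#'   (`round(0.04 * length)` clamped to `[2, 5]`, i.e. 4 for 100 bp reads).
#' @param max_gap_opens Gap opens allowed per alignment (default 1, the field
#'   convention: without this cap bounded search at `z = 5` is combinatorially
#'   intractable because an insertion branch is always available).
#' @param max_gap_extensions Free gap-extension columns allowed after each gap
#'   open (default 3, the "loose" `-e 3` analogue). Extensions beyond the cap
#'   would need a new gap open.
#' @param seed_length When positive, at most `seed_max_diff` differences are
#'   permitted within the last `seed_length` read bases (the portion searched
#'   first); 0 disables seeding.
#' @param seed_max_diff Differences allowed inside the seed (default 2).
#' @param use_dcdc Use the pattern-tightened D-array when the index bundle
#'   carries an automaton.
#' @param use_sta Drive the search with the Suffix Tarray when present
#'   (results are identical either way; only speed changes).
#' @param max_steps Safety cap on search-tree nodes (error if exceeded).
#' @return Object of class `search_params`.
#' @export
search_params <- function(z = NULL, max_gap_opens = 1L, max_gap_extensions = 3L,
                          seed_length = 0L, seed_max_diff = 2L,
                          use_dcdc = FALSE, use_sta = TRUE, max_steps = 2e7) {
  if (!is.null(z)) {
    z <- as.integer(z)
    stopifnot(z >= 0L)
  }
  stopifnot(max_gap_opens >= 0L, max_gap_extensions >= 0L, seed_length >= 0L,
            seed_max_diff >= 0L)
  structure(list(z = z, max_gap_opens = as.integer(max_gap_opens),
                 max_gap_extensions = as.integer(max_gap_extensions),
                 seed_length = as.integer(seed_length),
                 seed_max_diff = as.integer(seed_max_diff),
                 use_dcdc = isTRUE(use_dcdc), use_sta = isTRUE(use_sta),
                 max_steps = as.numeric(max_steps)),
            class = "search_params")
}

.default_z <- function(m) max(2L, min(5L, as.integer(round(0.04 * m))))

#' Bounded inexact search
#'
#' Depth-first search from the read end toward the start over backward-search
#' intervals, allowing matches, substitutions (cost 1), read insertions and
#' deletions (gap open cost 1, up to `max_gap_extensions` consecutive
#' extensions cost 0). A branch is pruned whenever the remaining difference
#' budget falls below `D[i]`, the lower bound for the unprocessed prefix.
#' Branch order is match > substitution > deletion > insertion; the hit set
#' (not its order) is the contract.
#'
#' @param W Read string or integer codes.
#' @param index A `suffix_tarray` or `fm_index` of the forward reference.
#' @param D Integer lower-bound array for `W` against the same reference (all
#'   zeros disables pruning).
#' @param params A [search_params()] object.
#' @return `data.frame` with interval `k`, `l`, charged `ndiff`, and a
#'   per-column edit `script` (left-to-right over `M`/`X`/`I`/`D`).
#' @export
inexact_search <- function(W, index, D, params = search_params(z = 0L)) {
  codes <- .as_codes_read(W)
  m <- length(codes)
  if (m == 0L) stop("W must be nonempty")
  if (inherits(index, "suffix_tarray")) {
    fm <- index$fm
    trie_children <- index$children
    trie_k <- index$k
    trie_l <- index$l
    use_trie <- isTRUE(params$use_sta)
  } else if (inherits(index, "fm_index")) {
    fm <- index
    trie_children <- matrix(integer(0), 0L, 4L)
    trie_k <- integer(0)
    trie_l <- integer(0)
    use_trie <- FALSE
  } else stop("index must be a suffix_tarray or fm_index")
  D <- as.integer(D)
  if (length(D) != m) stop("D must have one bound per read position")
  z <- params$z %||% .default_z(m)
  res <- inexact_search_cpp(fm$bwt, fm$C, fm$occ_buckets, fm$bucket_size,
                            codes, D, z, params$max_gap_opens,
                            params$max_gap_extensions,
                            params$seed_length, params$seed_max_diff,
                            trie_children, trie_k, trie_l, use_trie,
                            params$max_steps)
  data.frame(k = res$k, l = res$l, ndiff = res$ndiff,
             script = as.character(res$script), stringsAsFactors = FALSE)
}

#' Mapping quality from hit-stratum counts
#'
#' Documented monotone scheme (the upstream tool's exact formula is out of
#' scope): multiple co-optimal placements give 0; a unique best placement with
#' an empty next stratum gives 37; a unique best with `s` next-stratum
#' placements gives `max(3, 25 - 3 * s)`. Values always lie in `[0, 60]`;
#' qualities at or above the evaluator's threshold (10) are "confident".
#'
#' @param n_best Number of co-optimal (best-stratum) placements.
#' @param n_second Number of placements in the next difference stratum.
#' @return Integer mapping quality.
#' @export
mapping_quality <- function(n_best, n_second = 0L) {
  if (n_best < 1L) return(0L)
  if (n_best > 1L) return(0L)
  if (n_second == 0L) return(37L)
  as.integer(max(3L, 25L - 3L * n_second))
}

.cigar_from_script <- function(script) {
  ops <- strsplit(script, "", fixed = TRUE)[[1L]]
  ops[ops == "X"] <- "M"
  r <- rle(ops)
  paste0(r$lengths, r$values, collapse = "")
}

.nm_from_script <- function(script) {
  ops <- strsplit(script, "", fixed = TRUE)[[1L]]
  sum(ops != "M")
}

.ref_span_from_script <- function(script) {
  ops <- strsplit(script, "", fixed = TRUE)[[1L]]
  sum(ops %in% c("M", "X", "D"))
}

# Map a concatenated-reference coordinate to (record, local position).
.translate_pos <- function(offsets, pos, span) {
  idx <- findInterval(pos, offsets$start)
  if (idx < 1L || pos + span > offsets$start[idx] + offsets$length[idx]) {
    return(NULL)  # overlaps a separator / record boundary: not a real hit
  }
  list(rname = offsets$name[idx], local = pos - offsets$start[idx])
}

#' Align one read against an index bundle
#'
#' Searches the read and its reverse complement, computing the D-array (basic
#' or pattern-tightened, per `params$use_dcdc`) on the reversed-reference
#' index for each orientation, locates the best-stratum intervals, counts
#' co-optimal and next-stratum placements for the mapping quality, and returns
#' the primary hit (lowest reference coordinate among co-optimal placements,
#' forward strand first on ties).
#'
#' @param read Read string (length >= 2) — shorter reads yield an unmapped
#'   record.
#' @param bundle An `index_bundle` from [build_index_bundle()].
#' @param params A [search_params()] object.
#' @param name Read name for the SAM record.
#' @param qual Base-quality string (defaults to `"I"` run).
#' @return One-row `data.frame`: `qname`, `mapped`, `rname`, `pos` (1-based),
#'   `strand`, `mapq`, `cigar`, `nm`, `ndiff`, `n_best`, `n_second`, `seq`,
#'   `qual`.
#' @export
align_read <- function(read, bundle, params = search_params(), name = "read",
                       qual = NULL) {
  stopifnot(inherits(bundle, "index_bundle"))
  read <- toupper(read)
  m <- nchar(read)
  qual <- qual %||% strrep("I", m)
  unmapped <- data.frame(qname = name, mapped = FALSE, rname = "*", pos = 0L,
                         strand = "*", mapq = 0L, cigar = "*", nm = NA_integer_,
                         ndiff = NA_integer_, n_best = 0L, n_second = 0L,
                         seq = read, qual = qual, stringsAsFactors = FALSE)
  if (m < 2L) return(unmapped)

  idx <- if (isTRUE(params$use_sta) && !is.null(bundle$sta)) bundle$sta else bundle$fm
  all_hits <- list()
  for (strand in c("+", "-")) {
    W <- if (strand == "+") read else revcomp(read)
    D <- if (isTRUE(params$use_dcdc) && !is.null(bundle$automaton)) {
      calculate_d_dcdc(W, bundle$rev_fm, bundle$automaton)
    } else {
      calculate_d_basic(W, bundle$rev_fm)
    }
    h <- inexact_search(W, idx, D, params)
    if (nrow(h)) {
      h$strand <- strand
      all_hits[[strand]] <- h
    }
  }
  if (length(all_hits) == 0L) return(unmapped)
  hits <- do.call(rbind, all_hits)

  best <- min(hits$ndiff)
  .placements <- function(stratum, cap = 10000L) {
    hs <- hits[hits$ndiff == stratum, , drop = FALSE]
    out <- list()
    total <- 0L
    for (r in seq_len(nrow(hs))) {
      if (total >= cap) break
      pos <- locate(bundle$fm, c(hs$k[r], hs$l[r]))
      span <- .ref_span_from_script(hs$script[r])
      for (p in pos) {
        tr <- .translate_pos(bundle$offsets, p, span)
        if (is.null(tr)) next
        out[[length(out) + 1L]] <- data.frame(
          pos = p, rname = tr$rname, local = tr$local,
          strand = hs$strand[r], script = hs$script[r],
          stringsAsFactors = FALSE)
        total <- total + 1L
      }
    }
    if (length(out) == 0L) return(NULL)
    pl <- do.call(rbind, out)
    pl[!duplicated(pl[, c("pos", "strand")]), , drop = FALSE]
  }

  pl_best <- .placements(best)
  if (is.null(pl_best)) return(unmapped)
  pl_second <- .placements(best + 1L)

  # Stratum counts are per locus: placements within 5 bp on the same strand
  # are one locus (re-parses of the same alignment shifted by a gap), and
  # next-stratum placements at a best locus are the same alignment with one
  # superfluous edit, not a competing one.
  .n_loci <- function(pl) {
    total <- 0L
    for (s in unique(pl$strand)) {
      p <- sort(pl$pos[pl$strand == s])
      total <- total + 1L + sum(diff(p) > 5L)
    }
    total
  }
  n_best <- .n_loci(pl_best)
  n_second <- 0L
  if (!is.null(pl_second)) {
    away <- vapply(seq_len(nrow(pl_second)), function(r) {
      same <- pl_best$strand == pl_second$strand[r]
      !any(same & abs(pl_best$pos - pl_second$pos[r]) <= 5L)
    }, logical(1L))
    if (any(away)) n_second <- .n_loci(pl_second[away, , drop = FALSE])
  }
  mapq <- mapping_quality(n_best, n_second)

  o <- order(pl_best$pos, pl_best$strand)
  prim <- pl_best[o[1L], ]
  out_seq <- if (prim$strand == "+") read else revcomp(read)
  out_qual <- if (prim$strand == "+") qual else paste(rev(strsplit(qual, "")[[1L]]), collapse = "")
  data.frame(qname = name, mapped = TRUE, rname = prim$rname,
             pos = prim$local + 1L, strand = prim$strand, mapq = mapq,
             cigar = .cigar_from_script(prim$script),
             nm = .nm_from_script(prim$script), ndiff = best,
             n_best = n_best, n_second = n_second,
             seq = out_seq, qual = out_qual, stringsAsFactors = FALSE)
}

#' Align a set of reads
#'
#' @param reads Named character vector of reads (names become SAM QNAMEs), or
#'   a `data.frame` with `name`, `seq` and optional `qual` columns (as
#'   returned by [simulate_reads()]).
#' @param bundle An `index_bundle`.
#' @param params A [search_params()] object.
#' @return `data.frame` of per-read hit records (see [align_read()]).
#' @export
align_reads <- function(reads, bundle, params = search_params()) {
  if (is.data.frame(reads)) {
    nms <- reads$name
    seqs <- reads$seq
    quals <- if ("qual" %in% names(reads)) reads$qual else rep(NA_character_, nrow(reads))
  } else {
    nms <- names(reads) %||% paste0("read", seq_along(reads))
    seqs <- as.character(reads)
    quals <- rep(NA_character_, length(seqs))
  }
  rows <- lapply(seq_along(seqs), function(i) {
    q <- if (is.na(quals[i])) NULL else quals[i]
    align_read(seqs[i], bundle, params, name = nms[i], qual = q)
  })
  do.call(rbind, rows)
}
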