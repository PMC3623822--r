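# The index bundle: forward FM-index, reversed-reference FM-index (for
# D-array calculation), optional Suffix Tarray and pattern automaton, plus the
# record offset table used for SAM coordinate translation.  Multi-record
# references are concatenated with separator symbols the search cannot cross.

# Paper-derived byte cost of one trie node; the --trie-size byte budget is
# converted to a node budget with this constant.
.BYTES_PER_TRIE_NODE <- 36L

#' Build an alignment index bundle
#'
#' @param ref Named character vector of reference records (a single unnamed
#'   string is named `"ref"`). N bases are replaced by the deterministic
#'   reference policy.
#' @param bucket_size,sample_rate FM-index parameters (speed/memory only).
#' @param build_sta Build the Suffix Tarray accelerator (`FALSE` leaves a
#'   plain FM-index bundle that the aligner reads identically).
#' @param trie_size Trie byte budget; the node budget is
#'   `floor(trie_size / 36)` (36 bytes per node).
#' @param max_depth Trie depth cap (default 12).
#' @param automaton Optional `ac_automaton` used by the pattern-tightened
#'   D-array (attach later with [attach_automaton()]).
#' @return Object of class `index_bundle`.
#' @export
build_index_bundle <- function(ref, bucket_size = 128L, sample_rate = 4L,
                               build_sta = TRUE, trie_size = 262144L,
                               max_depth = 12L, automaton = NULL) {
  if (is.null(names(ref))) {
    if (length(ref) != 1L) stop("multi-record references must be named")
    names(ref) <- "ref"
  }
  parts <- lapply(ref, .as_codes_ref)
  if (any(lengths(parts) == 0L)) stop("empty reference record")
  starts <- integer(length(parts))
  codes <- integer(sum(lengths(parts)) + length(parts) - 1L)
  at <- 1L
  for (i in seq_along(parts)) {
    starts[i] <- at - 1L
    p <- parts[[i]]
    codes[at:(at + length(p) - 1L)] <- p
    at <- at + length(p)
    if (i < length(parts)) { codes[at] <- 5L; at <- at + 1L }
  }
  offsets <- data.frame(name = names(ref), start = starts,
                        length = lengths(parts), stringsAsFactors = FALSE)

  fm <- build_fm_index(codes, bucket_size = bucket_size, sample_rate = sample_rate)
  rev_fm <- build_fm_index(rev(codes), bucket_size = bucket_size,
                           sample_rate = sample_rate)
  sta <- NULL
  if (isTRUE(build_sta)) {
    node_budget <- max(1L, as.integer(trie_size %/% .BYTES_PER_TRIE_NODE))
    sta <- build_suffix_tarray(fm, node_budget = node_budget,
                               max_depth = max_depth)
  }
  structure(list(version = 1L, fm = fm, rev_fm = rev_fm, sta = sta,
                 automaton = automaton, offsets = offsets,
                 params = list(bucket_size = as.integer(bucket_size),
                               sample_rate = as.integer(sample_rate),
                               trie_size = as.integer(trie_size),
                               max_depth = as.integer(max_depth))),
            class = "index_bundle")
}

#' Attach a mined-pattern automaton to a bundle
#' @param bundle An `index_bundle`.
#' @param automaton An `ac_automaton`.
#' @return The updated bundle.
#' @export
attach_automaton <- function(bundle, automaton) {
  stopifnot(inherits(bundle, "index_bundle"), inherits(automaton, "ac_automaton"))
  bundle$automaton <- automaton
  bundle
}

#' @export
print.index_bundle <- function(x, ...) {
  cat("Index bundle: ", nrow(x$offsets), " record(s), ",
      sum(x$offsets$length), " bases; STA: ",
      if (is.null(x$sta)) "no" else paste0(trie_node_count(x$sta), " nodes"),
      "; automaton: ",
      if (is.null(x$automaton)) "no" else nrow(x$automaton$patterns),
      " patterns\n", sep = "")
  invisible(x)
}

#' Serialize an index bundle
#'
#' Versioned RDS container; [load_index()] restores an object `identical()`
#' to the saved one (bit-exact round trip).
#'
#' @param bundle An `index_bundle`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
save_index <- function(bundle, path) {
  stopifnot(inherits(bundle, "index_bundle"))
  saveRDS(bundle, path)
  invisible(path)
}

#' Load a serialized index bundle
#' @param path File written by [save_index()].
#' @return The `index_bundle`.
#' @export
load_index <- function(path) {
  b <- readRDS(path)
  if (!inherits(b, "index_bundle")) stop("not an index bundle: ", path)
  if (!identical(b$version, 1L)) stop("unsupported index version: ", b$version)
  b
}
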