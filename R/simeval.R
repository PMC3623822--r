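# Read simulation with truth-encoded names (wgsim-style convention) and
# TPR/PPV scoring of alignments against the simulation truth.

#' Simulate shotgun reads with controlled error
#'
#' Uniform start positions over the reference records (weighted by length),
#' each strand with probability 1/2, independent per-base substitution errors
#' at `error_rate`, and optional short (1-3 bp) indels at `indel_rate` per
#' read. Fully reproducible from `seed`. The truth is encoded in the read name
#' as `<contig>_<start0>_<strand>_<serial>` (start is the 0-based leftmost
#' coordinate of the source window on the forward strand).
#'
#' @param ref Named character vector of reference records (single unnamed
#'   string allowed).
#' @param n_reads Number of reads.
#' @param read_length Read length in bases (must not exceed the shortest
#'   record).
#' @param error_rate Per-base substitution error rate in `[0, 1)` (default
#'   0.02).
#' @param indel_rate Per-read probability of planting one short indel
#'   (default 0, i.e. substitution errors only).
#' @param seed Integer RNG seed.
#' @return `data.frame` with `name`, `seq`, `qual`, `contig`, `pos` (0-based),
#'   `strand`, `n_sub`, `n_ins`, `n_del`.
#' @export
simulate_reads <- function(ref, n_reads, read_length = 100L, error_rate = 0.02,
                           indel_rate = 0, seed = 1L) {
  if (is.null(names(ref))) {
    if (length(ref) != 1L) stop("multi-record references must be named")
    names(ref) <- "ref"
  }
  stopifnot(error_rate >= 0, error_rate < 1, indel_rate >= 0, indel_rate < 1)
  read_length <- as.integer(read_length)
  if (any(nchar(ref) < read_length)) {
    stop("read_length exceeds a reference record length")
  }
  set.seed(as.integer(seed))
  codes <- lapply(ref, .as_codes_ref)
  lens <- nchar(ref)
  slack <- 4L  # extra reference bases available to deletion planting

  recs <- vector("list", n_reads)
  for (i in seq_len(n_reads)) {
    ci <- if (length(ref) == 1L) 1L else
      sample.int(length(ref), 1L, prob = lens - read_length + 1L)
    maxstart <- lens[ci] - read_length
    start <- sample.int(maxstart + 1L, 1L) - 1L
    strand <- if (stats::runif(1L) < 0.5) "+" else "-"

    window <- codes[[ci]][(start + 1L):min(lens[ci], start + read_length + slack)]
    n_ins <- 0L; n_del <- 0L
    if (indel_rate > 0 && stats::runif(1L) < indel_rate &&
        start + read_length + slack <= lens[ci]) {
      ilen <- sample.int(3L, 1L)
      at <- sample.int(read_length - ilen - 1L, 1L) + 1L
      if (stats::runif(1L) < 0.5) {  # insertion in the read
        ins <- sample.int(4L, ilen, replace = TRUE)
        window <- c(window[seq_len(at)], ins, window[(at + 1L):length(window)])
        n_ins <- ilen
      } else {                       # deletion from the read
        window <- window[-((at + 1L):(at + ilen))]
        n_del <- ilen
      }
    }
    bases <- window[seq_len(read_length)]
    nerr <- stats::rbinom(1L, read_length, error_rate)
    n_sub <- 0L
    if (nerr > 0L) {
      at <- sample.int(read_length, nerr)
      shift <- sample.int(3L, nerr, replace = TRUE)
      bases[at] <- ((bases[at] - 1L + shift) %% 4L) + 1L
      n_sub <- nerr
    }
    if (strand == "-") bases <- .revcomp_codes(bases)
    recs[[i]] <- data.frame(
      name = sprintf("%s_%d_%s_%06d", names(ref)[ci], start, strand, i),
      seq = dna_decode(bases), qual = strrep("I", read_length),
      contig = names(ref)[ci], pos = start, strand = strand,
      n_sub = n_sub, n_ins = n_ins, n_del = n_del, stringsAsFactors = FALSE)
  }
  do.call(rbind, recs)
}

#' Parse a truth-encoded read name
#' @param name Read name `<contig>_<start0>_<strand>_<serial>` (contig may
#'   itself contain underscores; fields are taken from the right).
#' @return List with `contig`, `pos`, `strand`.
#' @export
parse_truth_name <- function(name) {
  parts <- strsplit(name, "_", fixed = TRUE)[[1L]]
  np <- length(parts)
  if (np < 4L) stop("not a truth-encoded read name: ", name)
  list(contig = paste(parts[seq_len(np - 3L)], collapse = "_"),
       pos = as.integer(parts[np - 2L]), strand = parts[np - 1L])
}

#' Write the simulation truth sidecar
#' @param sim `data.frame` from [simulate_reads()].
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_truth <- function(sim, path) {
  utils::write.table(sim[, c("name", "contig", "pos", "strand",
                             "n_sub", "n_ins", "n_del")],
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a simulation truth sidecar
#' @param path TSV written by [write_truth()].
#' @return `data.frame` of truth records.
#' @export
read_truth <- function(path) {
  utils::read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE,
                    colClasses = c(name = "character", contig = "character",
                                   strand = "character"))
}

#' Score alignments against simulation truth
#'
#' A read counts as correct iff it is mapped with quality at or above
#' `confidence_threshold`, on the true contig and strand, and its reported
#' leftmost position is within `tolerance` bases of the true one.
#' TPR = correct / input reads; PPV = correct / confidently mapped reads
#' (0 when none are confidently mapped).
#'
#' @param alignments SAM path, SAM lines, or a record table from [read_sam()]
#'   / [align_reads()].
#' @param truth `data.frame` from [simulate_reads()] or [read_truth()].
#' @param tolerance Position tolerance in bases (default 5, the wgsim-style
#'   evaluation convention).
#' @param confidence_threshold Minimum mapping quality for a confident
#'   mapping (default 10).
#' @return Object of class `eval_report`: `n_input`, `n_mapped_confident`,
#'   `n_correct`, `tpr`, `ppv`, `conf_rate`.
#' @export
evaluate_alignments <- function(alignments, truth, tolerance = 5L,
                                confidence_threshold = 10L) {
  aln <- if (is.data.frame(alignments)) alignments else read_sam(alignments)
  if ("qname" %in% names(aln)) {
    # normalise column names between read_sam() and align_reads() output
    aln$pos1 <- aln$pos
  } else stop("alignments must be SAM records or an alignment table")
  if (!all(aln$qname %in% truth$name)) {
    stop("alignment/truth name mismatch: ",
         aln$qname[!(aln$qname %in% truth$name)][1L])
  }
  n_input <- nrow(truth)
  ix <- match(aln$qname, truth$name)
  conf <- aln$mapped & aln$mapq >= confidence_threshold
  correct <- conf &
    aln$rname == truth$contig[ix] &
    aln$strand == truth$strand[ix] &
    abs((aln$pos1 - 1L) - truth$pos[ix]) <= tolerance
  n_conf <- sum(conf)
  n_correct <- sum(correct)
  structure(list(n_input = n_input, n_mapped_confident = n_conf,
                 n_correct = n_correct,
                 tpr = n_correct / n_input,
                 ppv = if (n_conf > 0L) n_correct / n_conf else 0,
                 conf_rate = n_conf / n_input),
            class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf("reads: %d  confident: %d  correct: %d\nTPR: %.2f%%  PPV: %.2f%%  Conf: %.2f%%\n",
              x$n_input, x$n_mapped_confident, x$n_correct,
              100 * x$tpr, 100 * x$ppv, 100 * x$conf_rate))
  invisible(x)
}
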