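# Sequence file IO.  FASTA/FASTQ parsing is delegated to Biostrings; writers
# are plain-text and byte-deterministic.  SAM output is written directly
# (header + 11 mandatory columns + NM tag).

#' Read a FASTA file
#'
#' Wrapped lines are joined, case is folded to upper, record order preserved;
#' names are truncated at the first whitespace (SAM convention).
#'
#' @param path FASTA file path.
#' @return Named character vector of sequences.
#' @export
read_fasta <- function(path) {
  x <- tryCatch(Biostrings::readBStringSet(path, format = "fasta"),
                error = function(e) stop("FASTA parse error in '", path, "': ",
                                         conditionMessage(e), call. = FALSE))
  if (length(x) == 0L) stop("no FASTA records in '", path, "'")
  s <- toupper(as.character(x))
  names(s) <- sub("\\s.*$", "", names(x))
  s
}

#' Read a FASTQ file
#'
#' @param path FASTQ file path (4-line records; sequence/quality length
#'   equality is enforced by the parser).
#' @return List with `seq` (named character) and `qual` (named character).
#' @export
read_fastq <- function(path) {
  # structural pre-check: Biostrings does not validate record shape and will
  # read past a short quality line
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines) | seq_along(lines) < length(lines)]
  if (length(lines) %% 4L != 0L) {
    stop("FASTQ parse error in '", path, "': record count not a multiple of 4 lines")
  }
  if (length(lines)) {
    hd <- seq(1L, length(lines), by = 4L)
    if (!all(startsWith(lines[hd], "@")) ||
        !all(startsWith(lines[hd + 2L], "+"))) {
      stop("FASTQ parse error in '", path, "': malformed record markers")
    }
    if (!all(nchar(lines[hd + 1L]) == nchar(lines[hd + 3L]))) {
      stop("FASTQ parse error in '", path,
           "': sequence/quality length mismatch at record ",
           which(nchar(lines[hd + 1L]) != nchar(lines[hd + 3L]))[1L])
    }
  }
  parsed <- tryCatch({
    x <- Biostrings::readDNAStringSet(path, format = "fastq",
                                      with.qualities = TRUE)
    s <- toupper(as.character(x))
    q <- as.character(S4Vectors::mcols(x)$qualities)
    has_nul <- vapply(q, function(v) any(charToRaw(v) == as.raw(0L)),
                      logical(1L), USE.NAMES = FALSE)
    if (any(nchar(s, type = "bytes") != nchar(q, type = "bytes")) ||
        any(has_nul)) {
      stop("sequence/quality length mismatch")
    }
    list(s = s, q = q, n = names(x))
  }, error = function(e) stop("FASTQ parse error in '", path, "': ",
                              conditionMessage(e), call. = FALSE))
  if (length(parsed$s) == 0L) stop("no FASTQ records in '", path, "'")
  s <- parsed$s
  q <- parsed$q
  nms <- sub("\\s.*$", "", parsed$n)
  names(s) <- nms
  names(q) <- nms
  list(seq = s, qual = q)
}

#' Write a FASTA file
#' @param seqs Named character vector.
#' @param path Output path.
#' @param width Line-wrap column (default 60).
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path, width = 60L) {
  con <- file(path, "wb")
  on.exit(close(con))
  for (i in seq_along(seqs)) {
    writeLines(paste0(">", names(seqs)[i]), con, sep = "\n")
    s <- seqs[[i]]
    for (at in seq(1L, nchar(s), by = width)) {
      writeLines(substr(s, at, min(nchar(s), at + width - 1L)), con, sep = "\n")
    }
  }
  invisible(path)
}

#' Write a FASTQ file
#' @param seqs Named character vector of reads.
#' @param quals Character vector of quality strings (recycled `"I"` run when
#'   `NULL`).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fastq <- function(seqs, quals = NULL, path) {
  if (is.null(quals)) quals <- strrep("I", nchar(seqs))
  stopifnot(length(quals) == length(seqs), all(nchar(quals) == nchar(seqs)))
  con <- file(path, "wb")
  on.exit(close(con))
  for (i in seq_along(seqs)) {
    writeLines(c(paste0("@", names(seqs)[i]), seqs[[i]], "+", quals[[i]]),
               con, sep = "\n")
  }
  invisible(path)
}

#' Write alignment hits as SAM
#'
#' Header: `@HD`, one `@SQ` per reference record, `@PG`. FLAG is 0/16/4 for
#' forward/reverse/unmapped, POS is 1-based, CIGAR uses `M`/`I`/`D`, and the
#' `NM` tag counts every non-match column (charged differences plus free gap
#' extensions).
#'
#' @param hits Hit records from [align_reads()].
#' @param bundle The `index_bundle` the hits were produced against.
#' @param path Output SAM path.
#' @return `path`, invisibly.
#' @export
write_sam <- function(hits, bundle, path) {
  stopifnot(inherits(bundle, "index_bundle"))
  header <- c("@HD\tVN:1.6\tSO:unknown",
              sprintf("@SQ\tSN:%s\tLN:%d", bundle$offsets$name,
                      bundle$offsets$length),
              paste0("@PG\tID:staligner\tPN:staligner\tVN:",
                     as.character(utils::packageVersion("staligner"))))
  body <- vapply(seq_len(nrow(hits)), function(i) {
    h <- hits[i, ]
    if (!h$mapped) {
      flag <- 4L
      paste(h$qname, flag, "*", 0L, 0L, "*", "*", 0L, 0L, h$seq, h$qual,
            sep = "\t")
    } else {
      if (h$pos < 1L || h$pos > bundle$offsets$length[
            match(h$rname, bundle$offsets$name)]) {
        stop("internal error: hit coordinate outside reference record")
      }
      flag <- if (h$strand == "-") 16L else 0L
      paste(h$qname, flag, h$rname, h$pos, h$mapq, h$cigar, "*", 0L, 0L,
            h$seq, h$qual, paste0("NM:i:", h$nm), sep = "\t")
    }
  }, character(1L))
  con <- file(path, "wb")
  on.exit(close(con))
  writeLines(c(header, body), con, sep = "\n")
  invisible(path)
}

#' Parse a SAM file into a minimal record table
#'
#' Only the fields the evaluator needs: QNAME, FLAG, RNAME, POS, MAPQ.
#'
#' @param path SAM file path, or a character vector of SAM lines.
#' @return `data.frame` with `qname`, `flag`, `rname`, `pos`, `mapq`,
#'   `mapped`, `strand`.
#' @export
read_sam <- function(path) {
  lines <- if (length(path) == 1L && file.exists(path)) readLines(path) else path
  lines <- lines[!startsWith(lines, "@")]
  if (length(lines) == 0L) {
    return(data.frame(qname = character(0), flag = integer(0),
                      rname = character(0), pos = integer(0),
                      mapq = integer(0), mapped = logical(0),
                      strand = character(0), stringsAsFactors = FALSE))
  }
  f <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(f) < 11L)
  if (length(bad)) stop("malformed SAM record at line ", bad[1L])
  flag <- as.integer(vapply(f, `[[`, "", 2L))
  data.frame(qname = vapply(f, `[[`, "", 1L), flag = flag,
             rname = vapply(f, `[[`, "", 3L),
             pos = as.integer(vapply(f, `[[`, "", 4L)),
             mapq = as.integer(vapply(f, `[[`, "", 5L)),
             mapped = bitwAnd(flag, 4L) == 0L,
             strand = ifelse(bitwAnd(flag, 16L) == 16L, "-", "+"),
             stringsAsFactors = FALSE)
}
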