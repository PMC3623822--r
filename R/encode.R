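# Internal nucleotide coding shared by the whole package:
#   0 = sentinel terminator (lexicographically smallest, appended at build time)
#   1..4 = A, C, G, T
#   5 = record separator inserted between concatenated reference records /
#       training reads; the search never extends through it
#   6 = ambiguous base (N) in a *read*: matches nothing, i.e. a guaranteed
#       mismatch

.ALPHABET <- c("A", "C", "G", "T")
.CODE_CHARS <- c("$", "A", "C", "G", "T", "#", "N")

.ENC <- local({
  t <- rep(NA_integer_, 256L)
  for (i in 1:4) {
    t[utf8ToInt(.ALPHABET[i])] <- i
    t[utf8ToInt(tolower(.ALPHABET[i]))] <- i
  }
  t[utf8ToInt("N")] <- 6L
  t[utf8ToInt("n")] <- 6L
  t
})

# Encode one DNA string to integer codes.  Characters outside {A,C,G,T,N}
# (either case) are an error.
dna_encode <- function(x) {
  stopifnot(is.character(x), length(x) == 1L, !is.na(x))
  if (nchar(x) == 0L) return(integer(0))
  v <- .ENC[utf8ToInt(x)]
  if (anyNA(v)) {
    bad <- substr(x, which(is.na(v))[1L], which(is.na(v))[1L])
    stop("sequence contains character outside {A,C,G,T,N}: '", bad, "'")
  }
  v
}

dna_decode <- function(codes) {
  if (length(codes) == 0L) return("")
  paste(.CODE_CHARS[codes + 1L], collapse = "")
}

# Reference N policy: ambiguous bases are replaced by a base derived from a
# deterministic integer hash of the position (no RNG state is consumed), so
# the same reference always yields the same index.
resolve_ambiguous_reference <- function(codes, salt = 101L) {
  idx <- which(codes == 6L)
  if (length(idx)) {
    codes[idx] <- ((idx * 2654435761 + salt) %% 4) + 1L
  }
  as.integer(codes)
}

# Codes for a reference sequence (N replaced deterministically).
.as_codes_ref <- function(x) {
  if (is.integer(x)) return(x)
  resolve_ambiguous_reference(dna_encode(x))
}

# Codes for a read (N kept as never-matching code 6).
.as_codes_read <- function(x) {
  if (is.integer(x)) return(x)
  dna_encode(x)
}

.COMP <- c(0L, 4L, 3L, 2L, 1L, 5L, 6L)  # indexed by code + 1

#' Reverse complement of a DNA string
#'
#' `N` complements to `N`; case is folded to upper.
#'
#' @param x A character scalar over `{A,C,G,T,N}`.
#' @return The reverse-complemented string.
#' @examples
#' revcomp("ACGTN")
#' @export
revcomp <- function(x) {
  dna_decode(rev(.COMP[dna_encode(x) + 1L]))
}

.revcomp_codes <- function(codes) rev(.COMP[codes + 1L])

`%||%` <- function(a, b) if (is.null(a)) b else a
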