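# IUPAC nucleotide degeneracy primitives.
#
# Degenerate primers are written with IUPAC ambiguity codes, each standing
# for a pool of 2-4 concrete bases.  Every matching rule in the package is
# defined in terms of the expansion sets below, so they live in one place.

.IUPAC_EXPANSION <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"),
  H = c("A", "C", "T"), V = c("A", "C", "G"),
  N = c("A", "C", "G", "T")
)

# Bitmask encoding (A=1, C=2, G=4, T=8); the OR of a symbol's base bits.
# Subset tests between expansions reduce to bitwAnd(x, bitwNot(y)) == 0.
.IUPAC_BITS <- vapply(.IUPAC_EXPANSION, function(b) {
  sum(c(A = 1L, C = 2L, G = 4L, T = 8L)[b])
}, integer(1))

# Reverse lookup: bitmask -> symbol, for re-encoding base sets (consensus).
.BITS_TO_SYMBOL <- local({
  out <- character(15)
  out[.IUPAC_BITS] <- names(.IUPAC_BITS)
  out
})

.IUPAC_COMPLEMENT <- c(
  A = "T", C = "G", G = "C", T = "A",
  R = "Y", Y = "R", S = "S", W = "W", K = "M", M = "K",
  B = "V", D = "H", H = "D", V = "B", N = "N"
)

#' Expand an IUPAC ambiguity code to its base set
#'
#' @param symbol A single character from the 15-letter IUPAC nucleotide
#'   alphabet (`A C G T R Y S W K M B D H V N`).
#' @return Character vector of the concrete bases the symbol stands for
#'   (length 1 to 4).
#' @examples
#' expand_iupac("R")  # A G
#' expand_iupac("N")  # A C G T
#' @export
expand_iupac <- function(symbol) {
  if (!is.character(symbol) || length(symbol) != 1L || nchar(symbol) != 1L) {
    stop("`symbol` must be a single character", call. = FALSE)
  }
  symbol <- toupper(symbol)
  out <- .IUPAC_EXPANSION[[symbol]]
  if (is.null(out)) {
    stop(sprintf("not an IUPAC nucleotide symbol: '%s'", symbol),
         call. = FALSE)
  }
  out
}

# Encode an IUPAC string as an integer bitmask vector; errors name the
# offending character and its position.
iupac_bits <- function(seq, what = "sequence") {
  chars <- strsplit(toupper(seq), "", fixed = TRUE)[[1]]
  bits <- unname(.IUPAC_BITS[chars])
  bad <- which(is.na(bits))
  if (length(bad) > 0L) {
    stop(sprintf("non-IUPAC character '%s' at position %d of %s",
                 chars[bad[1]], bad[1], what), call. = FALSE)
  }
  bits
}

is_iupac_string <- function(seq) {
  nchar(seq) > 0L &
    !grepl(sprintf("[^%s]", paste(names(.IUPAC_BITS), collapse = "")),
           toupper(seq))
}

#' Reverse complement of an IUPAC string
#'
#' Ambiguity codes are complemented set-wise, e.g. `R` (\{A,G\}) becomes
#' `Y` (\{C,T\}).  Needed to place reverse primers on sense-strand
#' templates.
#'
#' @param seq An IUPAC nucleotide string.
#' @return The reverse complement, same length.
#' @examples
#' reverse_complement("ACGT")   # "ACGT"
#' reverse_complement("AAGGN")  # "NCCTT"
#' @export
reverse_complement <- function(seq) {
  stopifnot(is.character(seq), length(seq) == 1L)
  chars <- strsplit(toupper(seq), "", fixed = TRUE)[[1]]
  comp <- unname(.IUPAC_COMPLEMENT[chars])
  bad <- which(is.na(comp))
  if (length(bad) > 0L) {
    stop(sprintf("non-IUPAC character '%s' at position %d",
                 chars[bad[1]], bad[1]), call. = FALSE)
  }
  paste(rev(comp), collapse = "")
}
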