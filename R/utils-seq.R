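#' @importFrom rlang .data abort warn %||%
#' @importFrom tibble tibble as_tibble
NULL

# IUPAC classes used by the MRS patterns (plus the four bases and N).
IUPAC_CLASS <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), W = c("A", "T"),
  N = c("A", "C", "G", "T")
)

DNA_BASES <- c("A", "C", "G", "T", "N")

#' Reverse complement of a DNA string
#'
#' Thin wrapper over [Biostrings::reverseComplement()] accepting and returning
#' plain character strings (the package's working representation).
#'
#' @param x Character vector of DNA strings over A/C/G/T/N.
#' @return Character vector of reverse complements.
#' @export
#' @examples
#' revcomp("ACGTN")
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

# Normalise to uppercase and validate the alphabet; reports the first
# offending character and its position. U is rejected (DNA only).
normalise_dna <- function(x, id = "sequence") {
  x <- toupper(x)
  chars <- strsplit(x, "", fixed = TRUE)[[1]]
  bad <- which(!chars %in% DNA_BASES)
  if (length(bad) > 0) {
    abort(sprintf(
      "Non-IUPAC-DNA character '%s' at position %d in %s (alphabet is A/C/G/T/N).",
      chars[bad[1]], bad[1], id
    ))
  }
  x
}

# Integer encoding (A=1,C=2,G=3,T=4,N=5) for the vectorised scanner.
encode_dna <- function(x) {
  match(strsplit(x, "", fixed = TRUE)[[1]], DNA_BASES)
}

# substr() shorthand used throughout; 1-based inclusive, like all package
# coordinates.
subseq_chr <- function(x, start, end) substr(x, start, end)

`subseq_chr<-` <- function(x, start, end, value) {
  substr(x, start, end) <- value
  x
}
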