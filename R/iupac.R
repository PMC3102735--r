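# IUPAC nucleotide code table and low-level sequence helpers shared by the
# readers, the scanner and the generators.

IUPAC_TABLE <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"),
  H = c("A", "C", "T"), V = c("A", "C", "G"),
  N = c("A", "C", "G", "T")
)

IUPAC_CODES <- names(IUPAC_TABLE)

# complement of each IUPAC code (code whose allowed set is the complement set)
IUPAC_COMPLEMENT <- c(
  A = "T", C = "G", G = "C", T = "A",
  R = "Y", Y = "R", S = "S", W = "W", K = "M", M = "K",
  B = "V", D = "H", H = "D", V = "B", N = "N"
)

#' Reverse-complement a DNA string
#'
#' Accepts the full IUPAC alphabet, so it can be applied to degenerate
#' consensus patterns as well as plain sequence.
#'
#' @param x character vector of DNA strings (IUPAC alphabet).
#' @return character vector of reverse complements, upper-case.
#' @examples
#' reverse_complement("CAGGTAG")
#' reverse_complement("TTCNNNGAA")  # palindromic STAT consensus
#' @export
reverse_complement <- function(x) {
  vapply(toupper(x), function(s) {
    ch <- strsplit(s, "", fixed = TRUE)[[1]]
    comp <- IUPAC_COMPLEMENT[ch]
    if (anyNA(comp)) {
      bad <- ch[is.na(comp)][1]
      stop("non-IUPAC character '", bad, "' in sequence", call. = FALSE)
    }
    paste(rev(comp), collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

# map a sequence string to integer codes A=1, C=2, G=3, T=4; any other IUPAC
# character (including N) becomes 5L, which the scanner treats as ambiguous.
seq_to_codes <- function(s) {
  code <- c(A = 1L, C = 2L, G = 3L, T = 4L)
  ch <- strsplit(toupper(s), "", fixed = TRUE)[[1]]
  out <- unname(code[ch])
  out[is.na(out)] <- 5L
  out
}

validate_sequences <- function(seqs, where = "sequence set") {
  if (length(seqs) == 0) stop("empty ", where, call. = FALSE)
  if (is.null(names(seqs)) || any(names(seqs) == ""))
    stop("all sequences in ", where, " must be named", call. = FALSE)
  if (anyDuplicated(names(seqs)))
    stop("duplicate sequence ids in ", where, ": ",
         paste(unique(names(seqs)[duplicated(names(seqs))]), collapse = ", "),
         call. = FALSE)
  if (any(nchar(seqs) == 0))
    stop("empty sequence in ", where, call. = FALSE)
  invisible(seqs)
}
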