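# IUPAC DNA alphabet semantics shared by every downstream stage.

IUPAC_LETTERS <- c("A", "C", "G", "T", "R", "Y", "S", "W", "K", "M",
                   "B", "D", "H", "V", "N")

CONCRETE_BASES <- c("A", "C", "G", "T")

# complement table over the full degenerate alphabet
IUPAC_COMPLEMENT <- c(
  A = "T", C = "G", G = "C", T = "A",
  R = "Y", Y = "R", S = "S", W = "W", K = "M", M = "K",
  B = "V", D = "H", H = "D", V = "B", N = "N"
)

#' Degeneracy set of an IUPAC nucleotide code
#'
#' @param code single IUPAC DNA letter (case-insensitive).
#' @return Character vector of the concrete bases the code stands for,
#'   e.g. `"R"` gives `c("A", "G")`.
#' @export
iupac_set <- function(code) {
  code <- toupper(code)
  if (!code %in% IUPAC_LETTERS) {
    stop("invalid IUPAC code: '", code, "'", call. = FALSE)
  }
  strsplit(Biostrings::IUPAC_CODE_MAP[[code]], "", fixed = TRUE)[[1L]]
}

#' Does a concrete base satisfy an IUPAC pattern code?
#'
#' Degenerate codes are allowed on the pattern side only; the sequence
#' side must be a concrete base (A, C, G or T).
#'
#' @param pattern_char single IUPAC letter from a recognition site.
#' @param base single concrete base from a substrate sequence.
#' @return `TRUE` iff `base` belongs to the degeneracy set of
#'   `pattern_char`.
#' @export
iupac_match <- function(pattern_char, base) {
  base <- toupper(base)
  if (!base %in% CONCRETE_BASES) {
    stop("sequence-side base must be concrete (A/C/G/T), got '",
         base, "'", call. = FALSE)
  }
  base %in% iupac_set(pattern_char)
}

#' Validate a string against the 15-letter IUPAC DNA alphabet
#'
#' @param x character string.
#' @param what label used in error messages (a record id, typically).
#' @return The uppercased string, invisibly usable downstream.
#' @export
validate_iupac <- function(x, what = "sequence") {
  if (length(x) != 1L || is.na(x) || !nzchar(x)) {
    stop("alphabet error in ", what, ": residues must be a nonempty string",
         call. = FALSE)
  }
  x <- toupper(x)
  chars <- strsplit(x, "", fixed = TRUE)[[1L]]
  bad <- which(!chars %in% IUPAC_LETTERS)
  if (length(bad)) {
    stop("alphabet error in ", what, ": illegal character '",
         chars[bad[1L]], "' at offset ", bad[1L] - 1L, call. = FALSE)
  }
  x
}

#' Reverse complement of an IUPAC DNA string
#'
#' Standard IUPAC complementation (R<->Y, K<->M, B<->V, D<->H; S, W and
#' N are self-complementary) followed by reversal. Applying the
#' function twice returns the input.
#'
#' @param s IUPAC DNA string (case-insensitive; returned uppercase).
#' @return The reverse complement as an uppercase string.
#' @export
reverse_complement <- function(s) {
  s <- validate_iupac(s, "reverse_complement input")
  chars <- strsplit(s, "", fixed = TRUE)[[1L]]
  paste(rev(unname(IUPAC_COMPLEMENT[chars])), collapse = "")
}

# TRUE iff the string contains only concrete bases.
is_concrete <- function(s) {
  !grepl("[^ACGT]", toupper(s))
}

# Digestion-engine policy: substrates must be concrete.
assert_concrete <- function(s, what = "sequence") {
  s <- validate_iupac(s, what)
  if (!is_concrete(s)) {
    stop("degenerate base in ", what,
         ": the digestion engine requires a concrete A/C/G/T substrate",
         call. = FALSE)
  }
  s
}
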