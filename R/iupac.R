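# IUPAC nucleotide ambiguity handling used by the primer toolkit.

IUPAC_SETS <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("G", "C"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
  V = c("A", "C", "G"), N = c("A", "C", "G", "T")
)

# 15 x 5 logical lookup: does IUPAC code (row) match template base (col)?
# Template 'N' (unknown base) never matches any primer code.
.iupac_match_matrix <- local({
  codes <- names(IUPAC_SETS)
  bases <- c("A", "C", "G", "T", "N")
  m <- matrix(FALSE, length(codes), length(bases),
              dimnames = list(codes, bases))
  for (cd in codes) m[cd, IUPAC_SETS[[cd]]] <- TRUE
  m
})

#' Match an IUPAC primer code against a template base
#'
#' Standard IUPAC semantics: a degenerate code matches a template base when
#' the base belongs to the code's expansion set (e.g. `R` matches `A` or `G`,
#' `N` matches every base). An `N` in the *template* represents an unknown
#' base and never matches.
#'
#' @param primer_code Character vector of single IUPAC nucleotide codes.
#' @param template_base Character vector of template bases (`A`, `C`, `G`,
#'   `T`, or `N`). Recycled against `primer_code`.
#' @return Logical vector.
#' @examples
#' iupac_match("N", "A")
#' iupac_match("R", c("G", "C"))
#' @export
iupac_match <- function(primer_code, template_base) {
  primer_code <- toupper(primer_code)
  template_base <- toupper(template_base)
  bad_p <- setdiff(unique(primer_code), rownames(.iupac_match_matrix))
  if (length(bad_p) > 0) {
    abort(paste0("not an IUPAC nucleotide code: ", paste(bad_p, collapse = ", ")))
  }
  bad_b <- setdiff(unique(template_base), colnames(.iupac_match_matrix))
  if (length(bad_b) > 0) {
    abort(paste0("not a template base (A/C/G/T/N): ", paste(bad_b, collapse = ", ")))
  }
  .iupac_match_matrix[cbind(primer_code, template_base)]
}

#' Expand an IUPAC code to its base set
#' @param code Single IUPAC nucleotide code.
#' @return Character vector of plain bases.
#' @export
iupac_expand <- function(code) {
  code <- toupper(code)
  if (!code %in% names(IUPAC_SETS)) {
    abort(paste0("not an IUPAC nucleotide code: ", code))
  }
  IUPAC_SETS[[code]]
}

# Reverse lookup: a set of plain bases -> the unique IUPAC code.
iupac_from_bases <- function(bases) {
  key <- paste(sort(unique(bases)), collapse = "")
  keys <- vapply(IUPAC_SETS, function(b) paste(sort(b), collapse = ""), "")
  code <- names(keys)[match(key, keys)]
  if (is.na(code)) abort(paste0("no IUPAC code for base set: ", key))
  code
}

#' Reverse-complement DNA strings (IUPAC-aware)
#' @param x Character vector of DNA strings.
#' @return Character vector of reverse complements.
#' @export
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

.is_iupac_dna <- function(x) {
  !grepl(paste0("[^", paste(names(IUPAC_SETS), collapse = ""), "]"),
         toupper(x))
}

AA_ALPHABET20 <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I", "L",
                   "K", "M", "F", "P", "S", "T", "W", "Y", "V")
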