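#' Amino-acid alphabets
#'
#' `amino_acids()` returns the 20 canonical one-letter codes;
#' `alignment_alphabet()` appends the gap symbol `"-"`, giving the 21-symbol
#' alphabet over which column frequencies and sequence entropies are
#' computed.
#'
#' @return A character vector of one-letter symbols.
#' @export
#' @examples
#' amino_acids()
#' alignment_alphabet()
amino_acids <- function() {
  c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
    "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")
}

#' @rdname amino_acids
#' @export
alignment_alphabet <- function() {
  c(amino_acids(), "-")
}

# Condition labels for the two effector states of a repression assay.
assay_conditions <- function() c("minus_effector", "plus_effector")

other_condition <- function(condition) {
  ifelse(condition == "minus_effector", "plus_effector", "minus_effector")
}

check_amino_acids <- function(aa, what = "amino acid") {
  bad <- !is.na(aa) & !(aa %in% amino_acids())
  if (any(bad)) {
    abort(sprintf(
      "Unknown %s letter(s): %s (expected one of the 20 canonical codes)",
      what, paste(unique(aa[bad]), collapse = ", ")
    ))
  }
  invisible(aa)
}

# round-half-up at integer precision; base round() is round-half-even
round_half_up <- function(x) floor(x + 0.5)
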