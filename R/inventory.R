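#' Phoneme inventory
#'
#' A phoneme inventory is the closed set of phoneme labels a lexicon's
#' transcriptions may use, with every label classified as a vowel or a
#' consonant. The vowel/consonant partition is what the phonemic clustering
#' criteria (vowel-only mismatch, rhyme from the final vowel) rely on; the
#' labels themselves are arbitrary as long as they are used consistently.
#'
#' @param symbols Character vector of phoneme labels (unique, non-empty).
#' @param vowels Character vector, the subset of `symbols` that are vowels.
#' @return An object of class `phoneme_inventory`: a list with elements
#'   `symbols` (character) and `is_vowel` (named logical over `symbols`).
#' @examples
#' inv <- phoneme_inventory(c("D", "AO", "G"), vowels = "AO")
#' inv$is_vowel[["AO"]]
#' @export
phoneme_inventory <- function(symbols, vowels) {
  symbols <- as.character(symbols)
  vowels <- as.character(vowels)
  if (length(symbols) == 0L) stop("phoneme inventory is empty")
  if (anyDuplicated(symbols)) {
    stop("duplicate phoneme symbols: ",
         paste(unique(symbols[duplicated(symbols)]), collapse = ", "))
  }
  bad <- setdiff(vowels, symbols)
  if (length(bad)) {
    stop("vowel labels not in inventory: ", paste(bad, collapse = ", "))
  }
  is_vowel <- stats::setNames(symbols %in% vowels, symbols)
  structure(list(symbols = symbols, is_vowel = is_vowel),
            class = "phoneme_inventory")
}

#' @export
print.phoneme_inventory <- function(x, ...) {
  cat("Phoneme inventory:", length(x$symbols), "symbols (",
      sum(x$is_vowel), "vowels,", sum(!x$is_vowel), "consonants )\n")
  invisible(x)
}

# Validate a list of phoneme sequences against an inventory; returns a
# character vector of offending labels (empty when all valid).
unknown_phonemes <- function(phoneme_list, inventory) {
  setdiff(unique(unlist(phoneme_list, use.names = FALSE)), inventory$symbols)
}
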