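# Orthographic normalization used throughout: unicode NFC, lowercase,
# diacritics preserved (Spanish minimal pairs such as "papa"/"papá" depend
# on them). A transcript cell is one response verbatim; multi-word responses
# ("polar bear") are single forms containing spaces.

#' Normalize an orthographic form
#'
#' Unicode NFC normalization plus lowercasing; diacritics are preserved.
#' All lexicon keys and transcript tokens pass through this before lookup.
#'
#' @param x Character vector.
#' @return Normalized character vector.
#' @export
normalize_form <- function(x) {
  stringi::stri_trans_tolower(stringi::stri_trans_nfc(trimws(as.character(x))))
}

lexicon_key <- function(form, language) paste(form, language, sep = "\r")

new_lexicon <- function(entries, inventory) {
  entries$form <- normalize_form(entries$form)
  entries$language <- as.character(entries$language)
  entries$concept_id <- as.character(entries$concept_id)
  entries$category <- ifelse(is.na(entries$category) | entries$category == "",
                             NA_character_, as.character(entries$category))
  entries$initial_letter <- substr(entries$form, 1L, 1L)
  rownames(entries) <- NULL

  key <- lexicon_key(entries$form, entries$language)
  if (anyDuplicated(key)) {
    dup <- entries[duplicated(key), c("form", "language")]
    stop("duplicate (form, language) entries: ",
         paste(paste0(dup$form, "/", dup$language), collapse = ", "))
  }
  subcats <- strsplit(ifelse(is.na(entries$subcategories), "",
                             entries$subcategories), ";", fixed = TRUE)
  subcats <- lapply(subcats, function(s) trimws(s[nzchar(trimws(s))]))
  bad_sub <- which(!is.na(entries$category) & lengths(subcats) == 0L)
  if (length(bad_sub)) {
    stop("category-bearing entries without subcategory tags at rows: ",
         paste(bad_sub, collapse = ", "))
  }
  phons <- strsplit(trimws(entries$phonemes), "\\s+")
  if (any(lengths(phons) == 0L)) {
    stop("entries with empty phoneme sequence at rows: ",
         paste(which(lengths(phons) == 0L), collapse = ", "))
  }
  bad_ph <- unknown_phonemes(phons, inventory)
  if (length(bad_ph)) {
    stop("phoneme labels absent from inventory: ",
         paste(bad_ph, collapse = ", "))
  }
  # translation equivalents must agree on category and subcategory tags
  by_concept <- split(seq_len(nrow(entries)), entries$concept_id)
  for (idx in by_concept) {
    if (length(idx) > 1L) {
      cats <- unique(entries$category[idx])
      tags <- unique(vapply(subcats[idx],
                            function(s) paste(sort(s), collapse = ";"), ""))
      if (length(cats) > 1L || length(tags) > 1L) {
        stop("translation equivalents disagree on category/subcategories: ",
             entries$concept_id[idx[1L]])
      }
    }
  }
  structure(list(
    entries = entries,
    inventory = inventory,
    index = stats::setNames(seq_len(nrow(entries)), key),
    subcats = subcats,
    phons = phons,
    concept_index = by_concept
  ), class = "bifluency_lexicon")
}

#' Construct a lexicon from a data frame
#'
#' @param entries Data frame with columns `form`, `language`, `concept_id`,
#'   `category` (`NA` or `""` for letter-task words), `subcategories`
#'   (semicolon-separated tags; required when `category` is present) and
#'   `phonemes` (space-separated labels from `inventory`).
#' @param inventory A [phoneme_inventory()].
#' @return A `bifluency_lexicon` object.
#' @export
lexicon <- function(entries, inventory) {
  required <- c("form", "language", "concept_id", "category",
                "subcategories", "phonemes")
  miss <- setdiff(required, names(entries))
  if (length(miss)) stop("missing lexicon columns: ", paste(miss, collapse = ", "))
  new_lexicon(as.data.frame(entries, stringsAsFactors = FALSE), inventory)
}

#' @export
print.bifluency_lexicon <- function(x, ...) {
  cat("Bilingual fluency lexicon:", nrow(x$entries), "entries;",
      length(unique(x$entries$language)), "languages;",
      length(stats::na.omit(unique(x$entries$category))), "categories\n")
  invisible(x)
}

#' Read a lexicon file
#'
#' The TSV dialect has `#`-prefixed header lines declaring the phoneme
#' inventory and vowel subset, then a header row
#' `form language concept_id category subcategories phonemes`:
#' subcategories are semicolon-separated, phonemes space-separated. A JSON
#' mirror (`.json`) with fields `phonemes`, `vowels` and `entries` is also
#' accepted.
#'
#' @param path Path to the lexicon file.
#' @param inventory Optional [phoneme_inventory()]; when `NULL` it is read
#'   from the file header (`# phonemes:` / `# vowels:` lines).
#' @return A `bifluency_lexicon`.
#' @export
read_lexicon <- function(path, inventory = NULL) {
  if (!file.exists(path)) stop("lexicon file not found: ", path)
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    obj <- jsonlite::read_json(path, simplifyVector = TRUE)
    if (is.null(inventory)) {
      inventory <- phoneme_inventory(obj$phonemes, obj$vowels)
    }
    entries <- as.data.frame(obj$entries, stringsAsFactors = FALSE)
    if (nrow(entries) == 0L) stop("no entries in lexicon file: ", path)
    return(lexicon(entries, inventory))
  }
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  hdr <- lines[startsWith(lines, "#")]
  body <- lines[!startsWith(lines, "#") & nzchar(trimws(lines))]
  if (is.null(inventory)) {
    get_decl <- function(tag) {
      ln <- grep(paste0("^#\\s*", tag, "\\s*:"), hdr, value = TRUE)
      if (!length(ln)) stop("lexicon header missing '# ", tag, ":' line")
      strsplit(trimws(sub(paste0("^#\\s*", tag, "\\s*:"), "", ln[1L])),
               "\\s+")[[1L]]
    }
    inventory <- phoneme_inventory(get_decl("phonemes"), get_decl("vowels"))
  }
  if (length(body) < 2L) stop("no entries in lexicon file: ", path)
  con <- textConnection(body)
  on.exit(close(con))
  entries <- utils::read.delim(con, stringsAsFactors = FALSE,
                               na.strings = character())
  tryCatch(lexicon(entries, inventory),
           error = function(e) stop("invalid lexicon ", path, ": ",
                                    conditionMessage(e), call. = FALSE))
}

#' Write a lexicon file
#'
#' Emits the TSV dialect read by [read_lexicon()], including the inventory
#' header lines; `read_lexicon(write_lexicon(...))` round-trips every entry.
#'
#' @param lex A `bifluency_lexicon`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_lexicon <- function(lex, path) {
  inv <- lex$inventory
  hdr <- c(paste("# phonemes:", paste(inv$symbols, collapse = " ")),
           paste("# vowels:", paste(inv$symbols[inv$is_vowel], collapse = " ")))
  out <- lex$entries[, c("form", "language", "concept_id", "category",
                         "subcategories", "phonemes")]
  out$category[is.na(out$category)] <- ""
  out$subcategories[is.na(out$subcategories)] <- ""
  con <- file(path, open = "w", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(hdr, con)
  writeLines(paste(names(out), collapse = "\t"), con)
  writeLines(do.call(paste, c(lapply(out, as.character), sep = "\t")), con)
  invisible(path)
}

#' Look up a lexicon entry
#'
#' Exact-match retrieval keyed by normalized form and language:
#' case-insensitive, diacritic-sensitive. Absence is a value, not an error.
#'
#' @param lex A `bifluency_lexicon`.
#' @param token Orthographic string.
#' @param language Language tag as used in the lexicon (e.g. `"English"`).
#' @return A one-row data frame (the entry) or `NULL` when absent.
#' @export
lexicon_lookup <- function(lex, token, language) {
  i <- lexicon_row(lex, token, language)
  if (is.na(i)) NULL else lex$entries[i, , drop = FALSE]
}

# Integer row index (NA when absent); the fast path used by the scorer.
lexicon_row <- function(lex, token, language) {
  i <- lex$index[lexicon_key(normalize_form(token), language)]
  if (is.na(i)) NA_integer_ else unname(i)
}

# Vectorized row lookup for a whole trial.
lexicon_rows <- function(lex, tokens, languages) {
  i <- lex$index[lexicon_key(normalize_form(tokens), languages)]
  unname(i)
}

#' Do two entries share a semantic subcategory?
#'
#' Linkage is at concept level and ignores the entries' languages: two
#' category-bearing entries are linked when their subcategory tag sets
#' intersect. Entries from different categories (or entries without a
#' category) are never linked; no error is raised.
#'
#' @param lex A `bifluency_lexicon`.
#' @param a,b Entry identifiers: either integer row indices into
#'   `lex$entries`, or character forms, in which case `language_a` /
#'   `language_b` select the entry.
#' @param language_a,language_b Languages for character `a` / `b`.
#' @return Logical scalar.
#' @export
shared_subcategory <- function(lex, a, b, language_a = NULL, language_b = NULL) {
  ia <- if (is.character(a)) lexicon_row(lex, a, language_a) else as.integer(a)
  ib <- if (is.character(b)) lexicon_row(lex, b, language_b) else as.integer(b)
  if (is.na(ia) || is.na(ib)) return(FALSE)
  ca <- lex$entries$category[ia]; cb <- lex$entries$category[ib]
  if (is.na(ca) || is.na(cb) || ca != cb) return(FALSE)
  length(intersect(lex$subcats[[ia]], lex$subcats[[ib]])) > 0L
}
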