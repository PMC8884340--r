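# Small in-code fixtures used across the suite.

mini_inventory <- function() {
  phoneme_inventory(
    symbols = c("AA", "AE", "AH", "AO", "EH", "IH", "UH", "IY",
                "B", "D", "F", "G", "HH", "K", "M", "N", "P", "R", "S",
                "SH", "T", "W",
                "a", "e", "o", "g", "k", "p", "rr", "t", "b"),
    vowels = c("AA", "AE", "AH", "AO", "EH", "IH", "UH", "IY",
               "a", "e", "o"))
}

# Five-entry animal fixture (pets / farm) in two languages, plus the
# phonemic-criterion example words and a couple of letter-task fillers.
mini_entries <- function() {
  data.frame(
    form = c("dog", "cat", "horse", "pig", "cow", "dolphin", "table",
             "perro", "gato", "vaca",
             "art", "arm", "fat", "fit", "foot", "sand", "stand",
             "sum", "some", "fish"),
    language = c(rep("English", 7), rep("Spanish", 3), rep("English", 10)),
    concept_id = c("an_dog", "an_cat", "an_horse", "an_pig", "an_cow",
                   "an_dolphin", "ob_table",
                   "an_dog", "an_cat", "an_cow",
                   "lw_art", "lw_arm", "lw_fat", "lw_fit", "lw_foot",
                   "lw_sand", "lw_stand", "lw_sum", "lw_some", "an_fish"),
    category = c(rep("animals", 6), "furniture", rep("animals", 3),
                 rep(NA, 9), "animals"),
    subcategories = c("pets", "pets", "farm", "farm", "farm", "water",
                      "household", "pets", "pets", "farm",
                      rep(NA, 9), "water"),
    phonemes = c("D AO G", "K AE T", "HH AO R S", "P IH G", "K AW",
                 "D AA L F IH N", "T EY B AH L",
                 "p e rr o", "g a t o", "b a k a",
                 "AA R T", "AA R M", "F AE T", "F IH T", "F UH T",
                 "S AE N D", "S T AE N D", "S AH M", "S AH M", "F IH SH"),
    stringsAsFactors = FALSE)
}

mini_lexicon <- function() {
  e <- mini_entries()
  # mini inventory lacks a few labels used above; build a wider one
  ph <- unique(unlist(strsplit(e$phonemes, " ")))
  vowels <- intersect(ph, c("AA", "AE", "AH", "AO", "AW", "EH", "EY", "IH",
                            "IY", "UH", "a", "e", "i", "o", "u"))
  lexicon(e, phoneme_inventory(ph, vowels))
}

# Build a one-trial transcript data frame from a token vector.
make_trial <- function(tokens, language = "English", condition = "NS-L1",
                       target = "animals", task = "category",
                       administration = 1L, l1 = language,
                       participant = "p1", phonemes = NULL) {
  d <- data.frame(participant_id = participant, group = "HB", task = task,
                  condition = condition, target = target,
                  administration = administration,
                  position = seq_along(tokens), token = tokens,
                  produced_language = rep_len(language, length(tokens)),
                  l1_language = l1, stringsAsFactors = FALSE)
  if (!is.null(phonemes)) d$phonemes <- phonemes
  d
}

# Brute-force reference edit distance (naive recursion, exponential):
# independent of the DP implementation under test.
ref_edit_distance <- function(a, b) {
  if (!length(a)) return(length(b))
  if (!length(b)) return(length(a))
  min(ref_edit_distance(a[-1], b) + 1L,
      ref_edit_distance(a, b[-1]) + 1L,
      ref_edit_distance(a[-1], b[-1]) + (a[1] != b[1]))
}

random_phoneme_seq <- function(symbols, min_len = 0L, max_len = 6L) {
  n <- sample(min_len:max_len, 1L)
  if (n == 0L) character(0) else sample(symbols, n, replace = TRUE)
}

# Definitional BH: sorted p * m / rank with a running minimum, capped at 1.
ref_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- p[o] * m / seq_len(m)
  for (i in (m - 1):1) if (m > 1) adj[i] <- min(adj[i], adj[i + 1])
  pmin(adj, 1)[order(o)]
}

scored_cols <- function(n, matched = rep(NA_integer_, n),
                        status = rep("correct", n)) {
  data.frame(position = seq_len(n), token = sprintf("t%d", seq_len(n)),
             produced_language = rep_len("English", n), status = status,
             matched_row = matched, stringsAsFactors = FALSE)
}
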