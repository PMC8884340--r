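CATEGORY_CONDITIONS <- c("NS-L1", "NS-L2", "SS", "FS")
LETTER_CONDITIONS <- c("LF-L1", "LF-L2")

#' Scoring configuration
#'
#' Policy knobs for the scorer and downstream metrics.
#'
#' @param concept_repetition Treat translation equivalents (same concept in
#'   the other language) as repetitions? Default `FALSE`: the repetition
#'   rule is word-form-level, so "perro" after "dog" is creditable in
#'   dual-language conditions.
#' @param cluster_rule `"adjacent"` (each consecutive pair must share a
#'   subcategory / satisfy a phonemic criterion; default) or `"common_tag"`
#'   (all members of a semantic cluster must share one tag).
#' @param lf_aggregate How per-letter correct counts combine into a letter
#'   fluency condition score: `"mean"` (default, comparable in scale to a
#'   single category trial) or `"sum"`.
#' @return A list of class `scoring_config`.
#' @export
scoring_config <- function(concept_repetition = FALSE,
                           cluster_rule = c("adjacent", "common_tag"),
                           lf_aggregate = c("mean", "sum")) {
  structure(list(concept_repetition = isTRUE(concept_repetition),
                 cluster_rule = match.arg(cluster_rule),
                 lf_aggregate = match.arg(lf_aggregate)),
            class = "scoring_config")
}

#' Language required at a given response position
#'
#' Encodes the condition semantics: the no-switch conditions require one
#' language exclusively, the self-switch condition permits either, and the
#' forced-switch condition requires strict alternation from the starting
#' language.
#'
#' @param condition One of `"NS-L1"`, `"NS-L2"`, `"SS"`, `"FS"`, `"LF-L1"`,
#'   `"LF-L2"`.
#' @param position 1-based response position within the trial.
#' @param start_language For `"FS"`: the language of the first response.
#' @param languages Length-2 vector naming (L1, L2); defaults to the
#'   abstract tags `c("L1", "L2")`, pass actual language names to work in
#'   transcript space.
#' @return A language tag, or `"any"` for the self-switch condition.
#' @examples
#' required_language("FS", 2, "L1")   # "L2"
#' required_language("SS", 7)         # "any"
#' @export
required_language <- function(condition, position, start_language = NULL,
                              languages = c("L1", "L2")) {
  stopifnot(position >= 1L, length(languages) == 2L)
  switch(condition,
    "NS-L1" = , "LF-L1" = languages[1L],
    "NS-L2" = , "LF-L2" = languages[2L],
    "SS" = "any",
    "FS" = {
      if (is.null(start_language)) stop("FS requires start_language")
      if (!start_language %in% languages)
        stop("start_language not among languages")
      if (position %% 2L == 1L) start_language
      else setdiff(languages, start_language)
    },
    stop("unknown condition: ", condition)
  )
}

# Candidate lexicon rows for a target within one language.
target_candidates <- function(lex, task, target, language) {
  e <- lex$entries
  if (task == "letter") {
    which(e$language == language &
            e$initial_letter == normalize_form(target))
  } else {
    which(e$language == language & !is.na(e$category) & e$category == target)
  }
}

#' Match a token against the lexicon with phonemic tolerance
#'
#' Exact orthographic match (distance 0) is preferred; otherwise the
#' in-target entry of the same language whose phoneme sequence is within
#' one edit of the token's phonemes. Tokens absent from the lexicon must
#' supply their own phoneme sequence to be resolvable. Ambiguity at the
#' minimal distance is broken deterministically by lexicographic
#' `concept_id`.
#'
#' @param lex A `bifluency_lexicon`.
#' @param token Orthographic string.
#' @param language Language tag.
#' @param target Category name (task `"category"`) or letter (task
#'   `"letter"`).
#' @param task `"category"` or `"letter"`.
#' @param phonemes Optional character vector (or space-separated string) of
#'   the token's phonemes, used when the token has no exact lexicon entry.
#' @return List with `row` (lexicon row index or `NA`), `distance`
#'   (integer; `NA` when unresolved) and `resolvable` (logical: phonemes
#'   were available and in-target candidates existed).
#' @export
match_with_tolerance <- function(lex, token, language, target, task,
                                 phonemes = NULL) {
  i <- lexicon_row(lex, token, language)
  if (!is.na(i)) return(list(row = i, distance = 0L, resolvable = TRUE))
  if (!is.null(phonemes)) phonemes <- phonemes[!is.na(phonemes)]
  if (is.character(phonemes) && length(phonemes) == 1L && grepl(" ", phonemes))
    phonemes <- strsplit(trimws(phonemes), "\\s+")[[1L]]
  if (is.null(phonemes) || !length(phonemes) || !any(nzchar(phonemes)))
    return(list(row = NA_integer_, distance = NA_integer_, resolvable = FALSE))
  cand <- target_candidates(lex, task, target, language)
  if (!length(cand))
    return(list(row = NA_integer_, distance = NA_integer_, resolvable = FALSE))
  hit <- integer(0)
  exact <- cand[vapply(lex$phons[cand], identical, TRUE, y = phonemes)]
  if (length(exact)) {
    hit <- exact; d <- 0L
  } else {
    near <- cand[vapply(lex$phons[cand], within_one_edit, TRUE, b = phonemes)]
    if (length(near)) { hit <- near; d <- 1L }
  }
  if (length(hit)) {
    # deterministic tie-break at the minimal distance
    hit <- hit[order(lex$entries$concept_id[hit], lex$entries$form[hit])][1L]
    return(list(row = hit, distance = d, resolvable = TRUE))
  }
  dmin <- min(vapply(lex$phons[cand], phoneme_edit_distance, 0L, b = phonemes))
  list(row = NA_integer_, distance = as.integer(dmin), resolvable = TRUE)
}

#' Score one fluency trial
#'
#' Assigns each response exactly one status under the active condition's
#' rules. A response is correct when it resolves to a unique in-target word
#' within one phonemic edit, in the required language, and is not a
#' repetition of a previously produced response in this administration.
#' Error and repetition responses are retained in the output (they
#' participate in the clustering and switching analyses).
#'
#' Status precedence: `unknown` (unresolvable even at distance 1) >
#' `category_error`/`letter_error` (resolved entry violates the target) >
#' `language_error` (violates [required_language()]) > `repetition` >
#' `form_error` (resolvable only at distance > 1) > `correct`.
#'
#' @param responses Data frame, one trial: columns `participant_id`,
#'   `task`, `condition`, `target`, `administration`, `position`, `token`,
#'   `produced_language`, `l1_language` (participant's L1) and optionally
#'   `phonemes` (space-separated, for out-of-lexicon tokens).
#' @param lex A `bifluency_lexicon`.
#' @param config A [scoring_config()].
#' @return Object of class `trial_score`: list with `responses` (the input
#'   plus `status`, `matched_row`, `matched_concept`, `edit_distance`),
#'   `correct_count`, and the trial identifiers.
#' @export
score_trial <- function(responses, lex, config = scoring_config()) {
  responses <- as.data.frame(responses, stringsAsFactors = FALSE)
  key_cols <- c("participant_id", "task", "condition", "target",
                "administration")
  for (k in key_cols) {
    if (length(unique(responses[[k]])) != 1L)
      stop("score_trial expects responses from a single trial; column '",
           k, "' is mixed")
  }
  n <- nrow(responses)
  responses <- responses[order(responses$position), , drop = FALSE]
  if (!identical(as.integer(responses$position), seq_len(n)))
    stop("positions must be consecutive from 1")
  task <- responses$task[1L]
  condition <- responses$condition[1L]
  if ((task == "category") != (condition %in% CATEGORY_CONDITIONS))
    stop("task inconsistent with condition: ", task, "/", condition)
  target <- responses$target[1L]
  l1 <- responses$l1_language[1L]
  langs_present <- unique(c(l1, responses$produced_language))
  l2 <- setdiff(langs_present, l1)
  l2 <- if (length(l2)) l2[1L] else NA_character_

  tok <- normalize_form(responses$token)
  lang <- as.character(responses$produced_language)
  phon_col <- if ("phonemes" %in% names(responses))
    as.character(responses$phonemes) else rep(NA_character_, n)

  matched <- rep(NA_integer_, n)
  dist <- rep(NA_integer_, n)
  resolvable <- rep(FALSE, n)
  exact <- lexicon_rows(lex, tok, lang)
  for (i in seq_len(n)) {
    if (!is.na(exact[i])) {
      matched[i] <- exact[i]; dist[i] <- 0L; resolvable[i] <- TRUE
    } else {
      m <- match_with_tolerance(lex, tok[i], lang[i], target, task,
                                phonemes = phon_col[i])
      matched[i] <- m$row; dist[i] <- m$distance; resolvable[i] <- m$resolvable
    }
  }

  # target violation, for resolved entries
  viol_target <- rep(FALSE, n)
  has_row <- !is.na(matched)
  if (any(has_row)) {
    if (task == "letter") {
      viol_target[has_row] <-
        lex$entries$initial_letter[matched[has_row]] != normalize_form(target)
    } else {
      ecat <- lex$entries$category[matched[has_row]]
      viol_target[has_row] <- is.na(ecat) | ecat != target
    }
  }

  # required language per position (FS start taken from the first response)
  langs <- c(l1, l2)
  req <- vapply(seq_len(n), function(i) {
    if (condition == "FS" && is.na(l2)) return("any")  # degenerate transcript
    required_language(condition, i, start_language = lang[1L],
                      languages = langs)
  }, "")
  viol_lang <- req != "any" & lang != req

  # repetitions: previously produced response within this administration
  rep_id <- if (config$concept_repetition && any(has_row)) {
    ifelse(has_row, lex$entries$concept_id[ifelse(is.na(matched), 1L, matched)],
           paste0("\r", tok, "\r", lang))
  } else {
    paste0(tok, "\r", lang)
  }
  is_rep <- duplicated(rep_id)

  status <- rep("correct", n)
  status[resolvable & !has_row] <- "form_error"
  status[is_rep] <- "repetition"
  status[viol_lang] <- "language_error"
  status[viol_target] <- if (task == "letter") "letter_error" else "category_error"
  status[!resolvable & !has_row] <- "unknown"

  responses$status <- status
  responses$matched_row <- matched
  responses$matched_concept <- ifelse(has_row, lex$entries$concept_id[matched],
                                      NA_character_)
  responses$edit_distance <- dist
  structure(list(responses = responses,
                 participant_id = responses$participant_id[1L],
                 task = task, condition = condition, target = target,
                 administration = responses$administration[1L],
                 correct_count = sum(status == "correct")),
            class = "trial_score")
}

#' @export
print.trial_score <- function(x, ...) {
  cat(sprintf("Trial %s / %s / %s (adm %s): %d responses, %d correct\n",
              x$participant_id, x$condition, x$target, x$administration,
              nrow(x$responses), x$correct_count))
  invisible(x)
}

#' Score a full transcript table
#'
#' Splits the transcript into trials and applies [score_trial()] to each.
#'
#' @param transcripts Data frame of raw responses (see [score_trial()] for
#'   required columns; `group` is carried through when present).
#' @param lex A `bifluency_lexicon`.
#' @param config A [scoring_config()].
#' @return Data frame of scored responses, one row per response.
#' @export
score_transcripts <- function(transcripts, lex, config = scoring_config()) {
  if (nrow(transcripts) == 0L) stop("empty transcript table")
  f <- interaction(transcripts$participant_id, transcripts$condition,
                   transcripts$target, transcripts$administration,
                   drop = TRUE)
  parts <- lapply(split(transcripts, f), function(tr)
    score_trial(tr, lex, config)$responses)
  out <- do.call(rbind, parts)
  rownames(out) <- NULL
  out
}

#' Average correct counts across two administrations
#'
#' @param t1,t2 `trial_score` objects (or plain correct counts); `t2` may
#'   be `NULL`/`NA` when the second administration is missing, in which
#'   case the single available count is used and flagged.
#' @return List with `mean_correct` and `incomplete`.
#' @export
average_administrations <- function(t1, t2 = NULL) {
  cc <- function(x) if (inherits(x, "trial_score")) x$correct_count else x
  c1 <- cc(t1); c2 <- if (is.null(t2)) NA_real_ else cc(t2)
  if (is.na(c1) && is.na(c2)) stop("both administrations missing")
  vals <- c(c1, c2)
  list(mean_correct = mean(vals, na.rm = TRUE),
       incomplete = anyNA(vals))
}

#' Per-participant condition scores
#'
#' Category conditions: the mean correct count across the two
#' administrations (single available administration flagged incomplete).
#' Letter conditions: per-letter correct counts aggregated by
#' `config$lf_aggregate`.
#'
#' @param scored Scored responses from [score_transcripts()].
#' @param config A [scoring_config()].
#' @return Data frame: `participant_id`, `group`, `condition`,
#'   `mean_correct`, `n_trials`, `incomplete`.
#' @export
condition_scores <- function(scored, config = scoring_config()) {
  has_group <- "group" %in% names(scored)
  per_trial <- stats::aggregate(
    cbind(correct = scored$status == "correct"),
    by = list(participant_id = scored$participant_id,
              group = if (has_group) scored$group else "all",
              task = scored$task,
              condition = scored$condition,
              target = scored$target,
              administration = scored$administration),
    FUN = sum)
  agg_one <- function(d) {
    task <- d$task[1L]
    if (task == "category") {
      n_expected <- 2L
      val <- mean(d$correct)
      inc <- nrow(d) < n_expected
    } else {
      val <- if (config$lf_aggregate == "sum") sum(d$correct)
             else mean(d$correct)
      inc <- FALSE
    }
    data.frame(participant_id = d$participant_id[1L], group = d$group[1L],
               condition = d$condition[1L], mean_correct = val,
               n_trials = nrow(d), incomplete = inc,
               stringsAsFactors = FALSE)
  }
  f <- interaction(per_trial$participant_id, per_trial$condition, drop = TRUE)
  out <- do.call(rbind, lapply(split(per_trial, f), agg_one))
  rownames(out) <- NULL
  out[order(out$participant_id, out$condition), ]
}
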