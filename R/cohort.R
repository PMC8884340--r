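FLUENCY_CATEGORIES <- c("animals", "clothing", "food", "transportation")
TASK_LETTERS <- list(English = c("f", "a", "s"), Spanish = c("p", "m", "r"))

#' Cohort specification
#'
#' Generative parameters for the synthetic bilingual fluency study. The
#' packaged default calibration targets published group-by-condition mean
#' correct counts; per-condition switch-success probabilities are derived
#' analytically from those targets: with continuation probability `p_c`,
#' switch success `p_s` and per-emission error proportion `eps`, the
#' expected correct count is `lambda * (p_c + (1 - p_c) * p_s) * (1 - eps)`,
#' so `p_s = (target / (lambda * (1 - eps)) - p_c) / (1 - p_c)`.
#' Condition effects are carried only by switch success and
#' language-error rates; `p_continue` is constant across conditions
#' (switching, not clustering, carries the control demand).
#'
#' @param n_bpwa,n_hb Group sizes (defaults 35 and 22).
#' @param seed Integer seed; fixed seed gives byte-identical cohorts.
#' @param calibration Parsed calibration list (see
#'   `system.file("extdata", "cohort_calibration.json", package =
#'   "bifluency")`); the default loads that file.
#' @return Object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_bpwa = 35, n_hb = 22, seed = 1,
                        calibration = NULL) {
  if (is.null(calibration)) {
    calibration <- jsonlite::read_json(
      system.file("extdata", "cohort_calibration.json",
                  package = "bifluency"),
      simplifyVector = TRUE)
  }
  problems <- character(0)
  chk <- function(ok, msg) if (!ok) problems <<- c(problems, msg)
  chk(n_bpwa >= 0 && n_hb >= 0 && n_bpwa + n_hb > 0,
      "group sizes must be non-negative and total > 0")
  chk(is.numeric(seed) && length(seed) == 1L, "seed must be a scalar")
  groups <- list()
  for (g in c("BPWA", "HB")) {
    st <- calibration$structural[[g]]
    tg <- calibration$targets[[g]]
    chk(st$p_continue >= 0 && st$p_continue <= 1,
        paste(g, "p_continue outside [0,1]"))
    chk(st$lambda_category > 0 && st$lambda_letter > 0,
        paste(g, "lambda must be positive"))
    r <- st$rates
    chk(all(unlist(r[c("intrusion", "repetition", "paraphasia")]) >= 0) &&
          all(unlist(r$language_error) >= 0) &&
          sum(unlist(r[c("intrusion", "repetition", "paraphasia")])) +
            max(unlist(r$language_error)) < 1,
        paste(g, "error rates invalid"))
    p_switch <- sapply(names(tg), function(cond) {
      lam <- if (cond %in% LETTER_CONDITIONS) st$lambda_letter
             else st$lambda_category
      eps <- r$intrusion + r$repetition + r$paraphasia / 2 +
        r$language_error[[cond]]
      e_tgt <- tg[[cond]] / (lam * (1 - eps))
      (e_tgt - st$p_continue) / (1 - st$p_continue)
    })
    bad <- p_switch <= 0 | p_switch >= 1
    chk(!any(bad), paste0(g, " derived switch-success outside (0,1) for: ",
                          paste(names(tg)[bad], collapse = ", ")))
    groups[[g]] <- list(
      p_continue = st$p_continue,
      lambda_category = st$lambda_category,
      lambda_letter = st$lambda_letter,
      rates = r,
      p_switch = p_switch,
      ability_sd = st$ability_sd,
      lambda_coupling = st$lambda_coupling,
      switch_coupling = st$switch_coupling)
  }
  if (length(problems))
    stop("invalid cohort spec:\n  - ", paste(problems, collapse = "\n  - "))
  structure(list(n_bpwa = as.integer(n_bpwa), n_hb = as.integer(n_hb),
                 seed = as.integer(seed), groups = groups,
                 l1_spanish_prop = calibration$l1_spanish_prop,
                 dominance_l1 = calibration$dominance_l1,
                 assessment_loading = calibration$assessment_ability_loading,
                 targets = calibration$targets),
            class = "cohort_spec")
}

#' @export
print.cohort_spec <- function(x, ...) {
  cat(sprintf("Cohort spec: %d BPWA + %d HB, seed %d\n",
              x$n_bpwa, x$n_hb, x$seed))
  for (g in names(x$groups))
    cat(sprintf("  %s: switch success %s\n", g,
                paste(sprintf("%s=%.2f", names(x$groups[[g]]$p_switch),
                              x$groups[[g]]$p_switch), collapse = " ")))
  invisible(x)
}

# Retrieval pool for one category x language(s): concepts with their
# primary subcategory and the lexicon row per language.
category_pool <- function(lex, target) {
  idx <- which(!is.na(lex$entries$category) & lex$entries$category == target)
  cid <- lex$entries$concept_id[idx]
  concepts <- unique(cid)
  first <- idx[match(concepts, cid)]
  subcat <- vapply(lex$subcats[first], `[`, "", 1L)
  rows <- lapply(split(idx, cid)[concepts], function(ii)
    stats::setNames(ii, lex$entries$language[ii]))
  list(concepts = concepts, subcat = stats::setNames(subcat, concepts),
       rows = rows)
}

# Letter pool: entries of one language starting with the letter; retrieval
# units ("subcategories") are first-two-phoneme neighbourhoods, so the
# generator produces emergent phonemic clusters.
letter_pool <- function(lex, letter, language) {
  idx <- which(lex$entries$language == language &
                 lex$entries$initial_letter == normalize_form(letter))
  unit <- vapply(lex$phons[idx], function(p)
    paste(utils::head(p, 2L), collapse = " "), "")
  concepts <- as.character(idx)  # row index doubles as the unit of use
  rows <- lapply(idx, function(i) stats::setNames(i, language))
  names(rows) <- concepts
  list(concepts = concepts, subcat = stats::setNames(unit, concepts),
       rows = rows)
}

perturb_phonemes <- function(ph, inventory, n_edits) {
  syms <- inventory$symbols
  iv <- inventory$is_vowel
  pos <- sample(seq_along(ph), min(n_edits, length(ph)))
  for (p in pos) {
    same_class <- syms[iv[syms] == iv[[ph[p]]] & syms != ph[p]]
    if (length(same_class)) ph[p] <- sample(same_class, 1L)
  }
  ph
}

#' Generate one synthetic fluency trial
#'
#' Two-level Markov retrieval process: the number of retrieval attempts is
#' Poisson(`lambda`); a current subcategory is maintained, and each
#' attempt either continues within it (probability `p_continue`, emitting
#' an unused word) or attempts a subcategory switch, which succeeds with
#' probability `p_switch` (failure emits nothing). An exhausted
#' subcategory forces a switch attempt; an exhausted pool ends the trial.
#' Intrusions, repetitions, paraphasias (half one-edit, half two-edit) and
#' language errors are injected per emission at the configured rates.
#'
#' @param lex A `bifluency_lexicon`.
#' @param condition Condition tag (`"NS-L1"`, ..., `"LF-L2"`).
#' @param target Category name, or letter for letter-fluency conditions.
#' @param params List: `lambda`, `p_continue`, `p_switch`, `rates` (list
#'   with `intrusion`, `repetition`, `paraphasia`, `language_error`
#'   scalars), `l1`, `l2` (language names), `dominance_l1`.
#' @return Data frame of emitted responses: `position`, `token`,
#'   `produced_language`, `phonemes` (`NA` except for paraphasic forms).
#' @export
generate_trial <- function(lex, condition, target, params) {
  task <- if (condition %in% LETTER_CONDITIONS) "letter" else "category"
  l1 <- params$l1; l2 <- params$l2
  trial_lang <- switch(condition,
                       "NS-L1" = , "LF-L1" = l1,
                       "NS-L2" = , "LF-L2" = l2,
                       NA_character_)
  pool <- if (task == "letter") letter_pool(lex, target, trial_lang)
          else category_pool(lex, target)
  if (!length(pool$concepts))
    stop("lexicon does not cover target '", target, "'")
  n_attempts <- rpois(1L, params$lambda)
  used <- character(0)
  out_tok <- character(0); out_lang <- character(0); out_ph <- character(0)
  cur <- NA_character_   # current subcategory
  cur_lang <- if (condition == "SS") {
    if (runif(1) < params$dominance_l1) l1 else l2
  } else trial_lang
  emitted <- 0L
  prev_forms <- character(0)
  r <- params$rates

  unused_in <- function(sub) {
    cc <- pool$concepts[pool$subcat == sub]
    setdiff(cc, used)
  }
  pick_lang_row <- function(concept, language) {
    rr <- pool$rows[[concept]]
    if (language %in% names(rr)) unname(rr[[language]]) else NA_integer_
  }

  for (a in seq_len(n_attempts)) {
    avail_all <- setdiff(pool$concepts, used)
    if (!length(avail_all)) break
    avail_cur <- if (!is.na(cur)) unused_in(cur) else character(0)
    if (length(avail_cur) && runif(1) < params$p_continue) {
      concept <- if (length(avail_cur) == 1L) avail_cur else
        sample(avail_cur, 1L)
    } else {
      # switch attempt (forced when the current subcategory is exhausted)
      if (runif(1) >= params$p_switch) next
      subs <- unique(pool$subcat[match(avail_all, pool$concepts)])
      subs <- setdiff(subs, cur)
      if (!length(subs)) subs <- unique(pool$subcat[match(avail_all,
                                                          pool$concepts)])
      w <- vapply(subs, function(s) length(unused_in(s)), 0L)
      cur <- if (length(subs) == 1L) subs else sample(subs, 1L, prob = w)
      if (condition == "SS")
        cur_lang <- if (runif(1) < params$dominance_l1) l1 else l2
      cands <- unused_in(cur)
      concept <- if (length(cands) == 1L) cands else sample(cands, 1L)
    }
    emitted <- emitted + 1L
    # intended language of this emission
    lang <- if (condition == "FS") {
      if (emitted %% 2L == 1L) l1 else l2
    } else cur_lang
    # error injection
    u <- runif(1)
    status_plan <- "normal"
    if (u < r$intrusion) status_plan <- "intrusion"
    else if (u < r$intrusion + r$repetition && length(prev_forms))
      status_plan <- "repeat"
    else if (u < r$intrusion + r$repetition + r$paraphasia)
      status_plan <- "paraphasia"
    else if (condition != "SS" &&
             u < r$intrusion + r$repetition + r$paraphasia + r$language_error)
      status_plan <- "language"

    tok <- NA_character_; ph <- NA_character_; out_language <- lang
    if (status_plan == "repeat") {
      j <- sample.int(length(prev_forms), 1L)
      tok <- prev_forms[j]
      out_language <- attr(prev_forms, "langs")[j]
    } else if (status_plan == "intrusion") {
      if (task == "category") {
        other <- which(!is.na(lex$entries$category) &
                         lex$entries$category != target &
                         lex$entries$language == lang)
      } else {
        other <- which(lex$entries$language == lang &
                         lex$entries$initial_letter !=
                           normalize_form(target))
      }
      if (length(other)) {
        i <- other[sample.int(length(other), 1L)]
        tok <- lex$entries$form[i]
      }
    } else if (status_plan == "language") {
      other_lang <- if (lang == l1) l2 else l1
      if (task == "category") {
        i <- pick_lang_row(concept, other_lang)
        if (!is.na(i)) {
          tok <- lex$entries$form[i]; out_language <- other_lang
          used <- c(used, concept)
        }
      } else {
        alt <- which(lex$entries$language == other_lang &
                       lex$entries$initial_letter == normalize_form(target))
        if (length(alt)) {
          i <- alt[sample.int(length(alt), 1L)]
          tok <- lex$entries$form[i]; out_language <- other_lang
        }
      }
    }
    if (is.na(tok)) {   # normal emission or fallback from a failed error
      i <- pick_lang_row(concept, lang)
      if (is.na(i)) { used <- c(used, concept); next }
      used <- c(used, concept)
      if (status_plan == "paraphasia") {
        n_edits <- if (runif(1) < 0.5) 1L else 2L
        php <- perturb_phonemes(lex$phons[[i]], lex$inventory, n_edits)
        tok <- paste0(lex$entries$form[i], "'")
        ph <- paste(php, collapse = " ")
      } else {
        tok <- lex$entries$form[i]
      }
    }
    out_tok <- c(out_tok, tok); out_lang <- c(out_lang, out_language)
    out_ph <- c(out_ph, ph)
    prev_forms <- c(prev_forms, tok)
    attr(prev_forms, "langs") <- out_lang
  }
  data.frame(position = seq_along(out_tok), token = out_tok,
             produced_language = out_lang, phonemes = out_ph,
             stringsAsFactors = FALSE)
}

#' Generate a full synthetic cohort
#'
#' Produces participants (covariates: latent ability, L1/L2 identity, LUQ
#' metrics for both languages, standardized assessment scores) and raw
#' response transcripts covering the full design: four category-generation
#' conditions administered twice with counterbalanced categories, plus one
#' letter-fluency condition per language with three letters each. Fully
#' deterministic given `spec$seed`.
#'
#' @param spec A [cohort_spec()].
#' @param lex A `bifluency_lexicon`; defaults to the packaged fixture.
#' @return Object of class `fluency_cohort`: list with `participants`,
#'   `transcripts` (valid [score_transcripts()] input) and `spec`.
#' @export
generate_cohort <- function(spec, lex = NULL) {
  stopifnot(inherits(spec, "cohort_spec"))
  if (is.null(lex)) lex <- bifluency_lexicon()
  set.seed(spec$seed)
  groups <- c(rep("BPWA", spec$n_bpwa), rep("HB", spec$n_hb))
  n <- length(groups)
  ids <- sprintf("%s%02d", groups, c(seq_len(spec$n_bpwa),
                                     seq_len(spec$n_hb)))
  l1 <- ifelse(runif(n) < spec$l1_spanish_prop, "Spanish", "English")
  l2 <- ifelse(l1 == "Spanish", "English", "Spanish")

  participants <- data.frame(participant_id = ids, group = groups,
                             l1_language = l1, l2_language = l2,
                             stringsAsFactors = FALSE)
  participants$ability <- NA_real_
  luq_cols <- list()
  assess <- list()
  for (g in unique(groups)) {
    gi <- which(groups == g)
    z <- rnorm(length(gi), 0, spec$groups[[g]]$ability_sd)
    participants$ability[gi] <- z
    for (lg in c("L1", "L2")) {
      st <- luq_structure(g, lg)
      X <- generate_luq(length(gi), st)
      colnames(X) <- paste0(tolower(lg), "_", colnames(X))
      for (cn in colnames(X)) {
        if (is.null(luq_cols[[cn]])) luq_cols[[cn]] <- rep(NA_real_, n)
        luq_cols[[cn]][gi] <- X[, cn]
      }
    }
    A <- generate_assessments(z, g, spec$assessment_loading)
    for (cn in colnames(A)) {
      if (is.null(assess[[cn]])) assess[[cn]] <- rep(NA_real_, n)
      assess[[cn]][gi] <- A[, cn]
    }
  }
  participants <- cbind(participants,
                        as.data.frame(luq_cols), as.data.frame(assess))

  cats <- FLUENCY_CATEGORIES
  trs <- vector("list", n * 16L)
  ti <- 0L
  for (i in seq_len(n)) {
    g <- groups[i]
    gp <- spec$groups[[g]]
    z <- participants$ability[i]
    lam_mult <- exp(gp$lambda_coupling * z - gp$lambda_coupling^2 / 2)
    one_trial <- function(cond, target, adm) {
      task <- if (cond %in% LETTER_CONDITIONS) "letter" else "category"
      lam <- if (task == "letter") gp$lambda_letter else gp$lambda_category
      ps <- plogis(qlogis(gp$p_switch[[cond]]) + gp$switch_coupling * z)
      params <- list(lambda = lam * lam_mult, p_continue = gp$p_continue,
                     p_switch = ps,
                     rates = list(
                       intrusion = gp$rates$intrusion,
                       repetition = gp$rates$repetition,
                       paraphasia = gp$rates$paraphasia,
                       language_error = gp$rates$language_error[[cond]]),
                     l1 = l1[i], l2 = l2[i],
                     dominance_l1 = spec$dominance_l1)
      tr <- generate_trial(lex, cond, target, params)
      if (!nrow(tr)) return(NULL)
      cbind(data.frame(participant_id = ids[i], group = g, task = task,
                       condition = cond, target = target,
                       administration = adm, l1_language = l1[i],
                       stringsAsFactors = FALSE),
            tr)
    }
    for (adm in 1:2) {
      for (j in seq_along(CATEGORY_CONDITIONS)) {
        target <- cats[((i + adm + j) %% 4L) + 1L]
        ti <- ti + 1L
        trs[[ti]] <- one_trial(CATEGORY_CONDITIONS[j], target, adm)
      }
    }
    for (cond in LETTER_CONDITIONS) {
      lg <- if (cond == "LF-L1") l1[i] else l2[i]
      for (letter in TASK_LETTERS[[lg]]) {
        ti <- ti + 1L
        trs[[ti]] <- one_trial(cond, letter, 1L)
      }
    }
  }
  transcripts <- do.call(rbind, trs[!vapply(trs, is.null, TRUE)])
  rownames(transcripts) <- NULL
  structure(list(participants = participants, transcripts = transcripts,
                 spec = spec),
            class = "fluency_cohort")
}

#' @export
print.fluency_cohort <- function(x, ...) {
  cat(sprintf("Synthetic fluency cohort: %d participants, %d responses\n",
              nrow(x$participants), nrow(x$transcripts)))
  invisible(x)
}

#' Write a cohort to disk
#'
#' Writes `transcripts.tsv`, `participants.tsv` and a spec echo
#' (`spec.json`) into a directory.
#'
#' @param cohort A `fluency_cohort`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.table(cohort$transcripts, file.path(dir, "transcripts.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE, na = "")
  utils::write.table(cohort$participants, file.path(dir, "participants.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE, na = "")
  jsonlite::write_json(unclass(cohort$spec), file.path(dir, "spec.json"),
                       auto_unbox = TRUE, pretty = TRUE, force = TRUE)
  invisible(dir)
}

#' The packaged synthetic bilingual lexicon
#'
#' Loads the fixture lexicon shipped with the package (four semantic
#' categories and the six task letters, English and Spanish).
#'
#' @return A `bifluency_lexicon`.
#' @export
bifluency_lexicon <- function() {
  read_lexicon(system.file("extdata", "bilingual_lexicon_synthetic.tsv",
                           package = "bifluency"))
}
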