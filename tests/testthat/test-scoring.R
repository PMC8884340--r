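test_that("phoneme_edit_distance matches printed examples and brute force", {
  expect_identical(phoneme_edit_distance(c("D", "AO", "G"), c("D", "AO", "G")), 0L)
  expect_identical(phoneme_edit_distance(c("D", "AO", "G"), c("D", "AO", "T")), 1L)
  expect_identical(phoneme_edit_distance(c("D", "AO", "G"), c("T", "AA", "K")), 3L)
  withr::local_seed(11)
  syms <- c("A", "B", "C", "D")
  for (k in 1:200) {
    a <- random_phoneme_seq(syms)
    b <- random_phoneme_seq(syms)
    expect_identical(phoneme_edit_distance(a, b), ref_edit_distance(a, b))
  }
})

test_that("phoneme_edit_distance is a metric", {
  withr::local_seed(12)
  syms <- c("A", "B", "C")
  for (k in 1:150) {
    a <- random_phoneme_seq(syms, 1, 5)
    b <- random_phoneme_seq(syms, 1, 5)
    cc <- random_phoneme_seq(syms, 1, 5)
    dab <- phoneme_edit_distance(a, b)
    expect_gte(dab, 0L)
    expect_identical(dab, phoneme_edit_distance(b, a))
    expect_identical(phoneme_edit_distance(a, a), 0L)
    if (dab == 0L) expect_identical(a, b)
    expect_lte(phoneme_edit_distance(a, cc),
               dab + phoneme_edit_distance(b, cc))
  }
})

test_that("within_one_edit agrees with the full distance", {
  withr::local_seed(13)
  syms <- c("A", "B", "C")
  for (k in 1:300) {
    a <- random_phoneme_seq(syms, 0, 5)
    b <- random_phoneme_seq(syms, 0, 5)
    expect_identical(bifluency:::within_one_edit(a, b),
                     phoneme_edit_distance(a, b) <= 1L)
  }
})

test_that("required_language implements the condition semantics", {
  expect_identical(required_language("FS", 1, "L1"), "L1")
  expect_identical(required_language("FS", 2, "L1"), "L2")
  expect_identical(required_language("FS", 3, "L2"), "L2")
  expect_identical(required_language("FS", 4, "L2"), "L1")
  expect_identical(required_language("SS", 7), "any")
  expect_identical(required_language("NS-L2", 3), "L2")
  expect_identical(required_language("NS-L1", 1), "L1")
  expect_identical(required_language("LF-L2", 5), "L2")
  # actual language names
  expect_identical(
    required_language("FS", 2, "Spanish", c("Spanish", "English")),
    "English")
  expect_error(required_language("FS", 1), "start_language")
})

test_that("match_with_tolerance prefers exact and resolves distance 1", {
  lex <- bifluency_lexicon()
  m <- match_with_tolerance(lex, "dog", "English", "animals", "category")
  expect_identical(m$distance, 0L)
  expect_identical(lex$entries$concept_id[m$row], "an_dog")
  # /D AO T/ is one edit from dog and nothing else in the category
  m1 <- match_with_tolerance(lex, "dot", "English", "animals", "category",
                             phonemes = "D AO T")
  expect_identical(m1$distance, 1L)
  expect_identical(lex$entries$concept_id[m1$row], "an_dog")
  # out-of-category word resolves exactly but the trial rules flag it later
  m2 <- match_with_tolerance(lex, "table", "English", "animals", "category")
  expect_true(is.na(m2$row))
  expect_false(m2$resolvable)
})

test_that("score_trial applies the correctness rules in order", {
  lex <- bifluency_lexicon()
  ts <- score_trial(make_trial(c("dog", "cat", "dog")), lex)
  expect_identical(ts$responses$status, c("correct", "correct", "repetition"))
  expect_identical(ts$correct_count, 2L)

  # letter task: initial-letter rule
  tf <- score_trial(make_trial(c("fox", "apple"), condition = "LF-L1",
                               target = "f", task = "letter"), lex)
  expect_identical(tf$responses$status, c("correct", "letter_error"))

  # out-of-category exact word resolves lexicon-wide, then violates target
  tc <- score_trial(make_trial(c("dog", "apple")), lex)
  expect_identical(tc$responses$status[2], "category_error")

  # language violation in NS-L1
  tr <- make_trial(c("dog", "perro"))
  tr$produced_language[2] <- "Spanish"
  tl <- score_trial(tr, lex)
  expect_identical(tl$responses$status[2], "language_error")

  # unknown: no lexicon entry, no phonemes
  tu <- score_trial(make_trial(c("dog", "blorp")), lex)
  expect_identical(tu$responses$status[2], "unknown")

  # form_error: phonemes two edits away from anything in target
  tfm <- make_trial(c("dog", "dord"), phonemes = c(NA, "D ER D ER"))
  expect_identical(score_trial(tfm, lex)$responses$status[2], "form_error")
})

test_that("FS alternation and translation-equivalent policy", {
  lex <- bifluency_lexicon()
  # perro after dog in FS (start English): alternation satisfied, both correct
  tr <- make_trial(c("dog", "perro"), condition = "FS", l1 = "English")
  tr$produced_language <- c("English", "Spanish")
  ts <- score_trial(tr, lex)
  expect_identical(ts$responses$status, c("correct", "correct"))

  # same tokens but concept-level repetition policy
  cfg <- scoring_config(concept_repetition = TRUE)
  ts2 <- score_trial(tr, lex, cfg)
  expect_identical(ts2$responses$status, c("correct", "repetition"))

  # alternation failure is a language error but stays in the sequence;
  # the schedule is anchored at the first response, so after a failure the
  # following on-schedule position is judged against the original parity
  tr3 <- make_trial(c("dog", "cat", "perro"), condition = "FS",
                    l1 = "English")
  tr3$produced_language <- c("English", "English", "Spanish")
  ts3 <- score_trial(tr3, lex)
  expect_identical(ts3$responses$status,
                   c("correct", "language_error", "language_error"))
  tr4 <- make_trial(c("dog", "gato", "pig", "vaca"), condition = "FS",
                    l1 = "English")
  tr4$produced_language <- c("English", "Spanish", "English", "Spanish")
  expect_identical(score_trial(tr4, lex)$responses$status, rep("correct", 4))
  expect_identical(nrow(ts3$responses), 3L)
})

test_that("scoring is deterministic and rejects mixed trials", {
  lex <- bifluency_lexicon()
  tr <- make_trial(c("dog", "cat", "horse"))
  expect_identical(score_trial(tr, lex)$responses,
                   score_trial(tr, lex)$responses)
  mixed <- rbind(tr, within(make_trial("cow"), condition <- "SS"))
  expect_error(score_trial(mixed, lex), "single trial")
  gap <- tr
  gap$position <- c(1L, 3L, 4L)
  expect_error(score_trial(gap, lex), "consecutive")
})

test_that("L1/L2 relabelling leaves correct counts invariant", {
  lex <- bifluency_lexicon()
  tr <- make_trial(c("dog", "cat", "perro", "horse"), condition = "SS",
                   l1 = "English")
  tr$produced_language <- c("English", "English", "Spanish", "English")
  base <- score_trial(tr, lex)$correct_count
  # relabel: L1 becomes Spanish; SS semantics do not depend on the mapping
  tr2 <- tr
  tr2$l1_language <- "Spanish"
  expect_identical(score_trial(tr2, lex)$correct_count, base)
  # NS-L1 with English L1 == NS-L2 with Spanish L1 on the same stream
  a <- score_trial(make_trial(c("dog", "cat"), condition = "NS-L1",
                              l1 = "English"), lex)$correct_count
  b <- score_trial(make_trial(c("dog", "cat"), condition = "NS-L2",
                              l1 = "Spanish"), lex)$correct_count
  expect_identical(a, b)
})

test_that("every response gets exactly one status; correct <= total", {
  lex <- bifluency_lexicon()
  spec <- cohort_spec(n_bpwa = 4, n_hb = 3, seed = 99)
  coh <- generate_cohort(spec, lex)
  scored <- score_transcripts(coh$transcripts, lex)
  expect_false(anyNA(scored$status))
  expect_true(all(scored$status %in%
    c("correct", "repetition", "category_error", "letter_error",
      "language_error", "form_error", "unknown")))
  cc <- tapply(scored$status == "correct",
               paste(scored$participant_id, scored$condition,
                     scored$target, scored$administration), sum)
  nn <- tapply(scored$status,
               paste(scored$participant_id, scored$condition,
                     scored$target, scored$administration), length)
  expect_true(all(cc <= nn))
  # correct implies a matched entry at distance <= 1
  ok <- scored$status == "correct"
  expect_false(anyNA(scored$matched_row[ok]))
  expect_true(all(scored$edit_distance[ok] <= 1L))
})

test_that("average_administrations averages and flags missing", {
  expect_identical(average_administrations(8, 6)$mean_correct, 7)
  expect_identical(average_administrations(0, 0)$mean_correct, 0)
  a5 <- average_administrations(5, NULL)
  expect_identical(a5$mean_correct, 5)
  expect_true(a5$incomplete)
  expect_false(average_administrations(8, 6)$incomplete)
})

test_that("condition_scores averages administrations and aggregates letters", {
  lex <- bifluency_lexicon()
  tr <- rbind(make_trial(c("dog", "cat", "horse")),
              make_trial(c("dog", "cat"), administration = 2L,
                         target = "food") |>
                transform(token = c("apple", "milk")))
  scored <- score_transcripts(tr, lex)
  cs <- condition_scores(scored)
  expect_equal(cs$mean_correct[cs$condition == "NS-L1"], 2.5)
  # letter conditions: mean vs sum over letters
  trl <- rbind(make_trial(c("fox", "fat"), condition = "LF-L1",
                          target = "f", task = "letter"),
               make_trial(c("sand", "sun", "sea"), condition = "LF-L1",
                          target = "s", task = "letter"))
  sl <- score_transcripts(trl, lex)
  expect_equal(condition_scores(sl)$mean_correct, 2.5)
  expect_equal(condition_scores(
    sl, scoring_config(lf_aggregate = "sum"))$mean_correct, 5)
})
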