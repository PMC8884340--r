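#' Phonemic linkage between two words
#'
#' Two words are phonemically linked when ANY of the four criteria holds:
#' (i) their first two phonemes are identical; (ii) the sequences have
#' equal length and differ only at vowel positions (vowel-vs-vowel
#' mismatches, at least one); (iii) they rhyme: the phoneme suffixes from
#' the final vowel onward are identical; (iv) they are homonyms: identical
#' phoneme sequences but different orthographic forms. Sequences shorter
#' than two phonemes simply fail criterion (i); the others still apply.
#'
#' @param a_phon,b_phon Character vectors of phoneme labels.
#' @param inventory A [phoneme_inventory()] (supplies the vowel flags).
#' @param a_form,b_form Orthographic forms, used only for the homonym
#'   criterion; when missing, criterion (iv) requires distinct forms and
#'   evaluates false.
#' @return Logical scalar.
#' @export
phonemic_link <- function(a_phon, b_phon, inventory,
                          a_form = NULL, b_form = NULL) {
  any(phonemic_link_criteria(a_phon, b_phon, inventory, a_form, b_form))
}

#' Which phonemic criteria link two words?
#'
#' @return Named logical vector over `first_two`, `vowel_only`, `rhyme`,
#'   `homonym` (the four criteria of [phonemic_link()]).
#' @rdname phonemic_link
#' @export
phonemic_link_criteria <- function(a_phon, b_phon, inventory,
                                   a_form = NULL, b_form = NULL) {
  a <- as.character(a_phon); b <- as.character(b_phon)
  out <- c(first_two = FALSE, vowel_only = FALSE,
           rhyme = FALSE, homonym = FALSE)
  if (!length(a) || !length(b)) return(out)
  iv <- inventory$is_vowel
  # (i) same first two sounds (fails for sequences shorter than 2)
  out["first_two"] <- length(a) >= 2L && length(b) >= 2L && all(a[1:2] == b[1:2])
  if (length(a) == length(b)) {
    mis <- which(a != b)
    if (length(mis) == 0L) {
      # (iv) homonyms: identical sounds, different spellings
      out["homonym"] <- !is.null(a_form) && !is.null(b_form) &&
        normalize_form(a_form) != normalize_form(b_form)
    } else {
      # (ii) differ only by vowel sounds, regardless of spelling
      out["vowel_only"] <- all(iv[a[mis]] & iv[b[mis]])
    }
  }
  # (iii) rhyme: identical from the final vowel onward
  va <- which(iv[a]); vb <- which(iv[b])
  if (length(va) && length(vb)) {
    sa <- a[max(va):length(a)]; sb <- b[max(vb):length(b)]
    out["rhyme"] <- length(sa) == length(sb) && all(sa == sb)
  }
  out
}

#' Semantic linkage between two scored responses
#'
#' Concept-level shared-subcategory test, ignoring language (translation
#' equivalents carry identical tags by lexicon invariant). Unresolved
#' responses never link.
#'
#' @param lex A `bifluency_lexicon`.
#' @param row_a,row_b Lexicon row indices (`NA` = unresolved).
#' @return Logical scalar.
#' @export
semantic_link <- function(lex, row_a, row_b) {
  if (is.na(row_a) || is.na(row_b)) return(FALSE)
  shared_subcategory(lex, row_a, row_b)
}

#' Partition a response sequence into clusters
#'
#' Greedy left-to-right chaining: a cluster extends while each consecutive
#' pair satisfies the link predicate; otherwise a new cluster starts.
#' Singletons are clusters of span 1. Errors and repetitions are included;
#' unresolved (`unknown`) responses participate as always-unlinked items.
#' Because linkage is pairwise-adjacent, this greedy partition is the
#' unique partition into maximal runs of pairwise-linked neighbours.
#'
#' @param scored A `trial_score`, or a data frame of scored responses from
#'   one trial (needs `matched_row`, `status`, `produced_language`,
#'   `token`; `phonemes` used for unmatched tokens in phonemic mode).
#' @param lex A `bifluency_lexicon`.
#' @param mode `"semantic"` or `"phonemic"`. In dual-language sequences,
#'   semantic linkage ignores language; phonemic linkage is evaluated only
#'   between words sharing a language (cross-language rhyme is ill-defined
#'   across inventories), otherwise false.
#' @param link Optional custom predicate `function(i, j)` over response
#'   indices, overriding `mode` (used by property tests).
#' @return Object of class `cluster_partition`: list with `clusters` (list
#'   of integer index vectors), `mode`, `n` (number of responses).
#' @export
partition_responses <- function(scored, lex = NULL,
                                mode = c("semantic", "phonemic"),
                                link = NULL) {
  if (inherits(scored, "trial_score")) scored <- scored$responses
  mode <- if (is.null(link)) match.arg(mode) else "custom"
  n <- nrow(scored)
  if (is.null(n)) n <- length(scored$status)
  if (n == 0L)
    return(structure(list(clusters = list(), mode = mode, n = 0L),
                     class = "cluster_partition"))
  if (is.null(link)) {
    rows <- scored$matched_row
    lang <- scored$produced_language
    phon <- function(i) {
      if (!is.na(rows[i])) return(lex$phons[[rows[i]]])
      p <- scored$phonemes[i]
      if (is.null(p) || is.na(p) || !nzchar(p)) return(character(0))
      strsplit(trimws(p), "\\s+")[[1L]]
    }
    form <- function(i) {
      if (!is.na(rows[i])) lex$entries$form[rows[i]]
      else normalize_form(scored$token[i])
    }
    link <- if (mode == "semantic") {
      function(i, j) semantic_link(lex, rows[i], rows[j])
    } else {
      function(i, j) {
        if (lang[i] != lang[j]) return(FALSE)
        phonemic_link(phon(i), phon(j), lex$inventory, form(i), form(j))
      }
    }
  }
  linked <- if (n > 1L)
    vapply(seq_len(n - 1L), function(i) isTRUE(link(i, i + 1L)), TRUE)
  else logical(0)
  cuts <- c(0L, which(!linked), n)
  clusters <- lapply(seq_len(length(cuts) - 1L),
                     function(k) seq.int(cuts[k] + 1L, cuts[k + 1L]))
  structure(list(clusters = clusters, mode = mode, n = n),
            class = "cluster_partition")
}

#' @export
print.cluster_partition <- function(x, ...) {
  cat(sprintf("%s partition: %d responses in %d clusters\n",
              x$mode, x$n, length(x$clusters)))
  invisible(x)
}

#' Cluster metrics: mean cluster size and number of switches
#'
#' Cluster size counts from the second word of each cluster, so a single
#' word has size 0 and a two-word cluster size 1. Mean cluster size is the
#' total of the sizes divided by the number of clusters (singletons count
#' in the denominator). Switches tally the transitions between clusters,
#' single words included, so `n_switches = n_clusters - 1`.
#'
#' @param partition A `cluster_partition`.
#' @return List of class `cluster_metrics`: `mean_cluster_size`,
#'   `n_switches`, `n_clusters`. An empty partition yields an
#'   undefined-marker (`NA`) metrics object, never zeros.
#' @examples
#' # dog, cat | horse, pig, cow -> sizes 1 and 2, mean 1.5, one switch
#' @export
cluster_metrics <- function(partition) {
  stopifnot(inherits(partition, "cluster_partition"))
  k <- length(partition$clusters)
  if (k == 0L)
    return(structure(list(mean_cluster_size = NA_real_,
                          n_switches = NA_integer_, n_clusters = 0L),
                     class = "cluster_metrics"))
  sizes <- lengths(partition$clusters) - 1L
  structure(list(mean_cluster_size = mean(sizes),
                 n_switches = k - 1L,
                 n_clusters = k),
            class = "cluster_metrics")
}

#' @export
print.cluster_metrics <- function(x, ...) {
  cat(sprintf("clusters: %d; mean cluster size: %.3f; switches: %d\n",
              x$n_clusters, x$mean_cluster_size, x$n_switches))
  invisible(x)
}

#' Per-condition clustering and switching table
#'
#' Runs the partition and metrics over every trial in a scored transcript
#' and averages the per-trial metrics across the two administrations of
#' each condition (the same averaging applied to correct counts).
#' Category-generation trials are partitioned semantically, letter-fluency
#' trials phonemically; letter trials are aggregated over letters with the
#' same rule as correct counts.
#'
#' @param scored Scored responses from [score_transcripts()].
#' @param lex A `bifluency_lexicon`.
#' @param config A [scoring_config()].
#' @return Data frame: `participant_id`, `group`, `condition`, `mode`,
#'   `mean_cluster_size`, `n_switches` (administration means).
#' @export
cluster_switch_table <- function(scored, lex, config = scoring_config()) {
  has_group <- "group" %in% names(scored)
  f <- interaction(scored$participant_id, scored$condition, scored$target,
                   scored$administration, drop = TRUE)
  per_trial <- lapply(split(scored, f), function(tr) {
    mode <- if (tr$task[1L] == "category") "semantic" else "phonemic"
    m <- cluster_metrics(partition_responses(tr, lex, mode))
    data.frame(participant_id = tr$participant_id[1L],
               group = if (has_group) tr$group[1L] else "all",
               condition = tr$condition[1L], mode = mode,
               mean_cluster_size = m$mean_cluster_size,
               n_switches = as.numeric(m$n_switches),
               stringsAsFactors = FALSE)
  })
  per_trial <- do.call(rbind, per_trial)
  agg <- stats::aggregate(
    per_trial[, c("mean_cluster_size", "n_switches")],
    by = per_trial[, c("participant_id", "group", "condition", "mode")],
    FUN = mean, na.rm = TRUE)
  agg[order(agg$participant_id, agg$condition), ]
}
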