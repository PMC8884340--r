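#' End-to-end analysis table for a cohort
#'
#' Convenience pipeline: scores the transcripts, computes condition
#' scores, clustering/switching metrics and fluency difference scores,
#' and joins participant covariates into one analysis table.
#'
#' @param cohort A `fluency_cohort` (or a list with `transcripts` and
#'   `participants` data frames).
#' @param lex A `bifluency_lexicon`; defaults to the packaged fixture.
#' @param config A [scoring_config()].
#' @return An `analysis_table` (see [build_analysis_table()]).
#' @export
cohort_analysis_table <- function(cohort, lex = NULL,
                                  config = scoring_config()) {
  if (is.null(lex)) lex <- bifluency_lexicon()
  scored <- score_transcripts(cohort$transcripts, lex, config)
  cs <- condition_scores(scored, config)
  ct <- cluster_switch_table(scored, lex, config)
  fds <- fds_table(cs)
  build_analysis_table(cs, ct, fds, cohort$participants)
}
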