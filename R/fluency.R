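#' Fluency difference score
#'
#' The difference in correct responses between category generation and
#' letter fluency as a proportion of category-generation correct:
#' `(ns_correct - lf_correct) / ns_correct`, computed per language.
#' Negative values (letter fluency exceeding category generation) are
#' permitted; a zero category-generation count yields an undefined marker
#' (`NA`), never a division error. Arithmetically, a smaller FDS means
#' letter-fluency performance closer to category-generation performance.
#'
#' @param ns_correct Correct count in the no-switch category condition
#'   (administration-averaged), `>= 0`.
#' @param lf_correct Correct count in the letter fluency condition of the
#'   same language (aggregated over letters), `>= 0`.
#' @return Numeric (vectorized); `NA` where `ns_correct == 0`.
#' @examples
#' compute_fds(16.68, 13.11)  # 0.2140...
#' @export
compute_fds <- function(ns_correct, lf_correct) {
  stopifnot(all(ns_correct >= 0, na.rm = TRUE),
            all(lf_correct >= 0, na.rm = TRUE))
  out <- ifelse(ns_correct > 0, (ns_correct - lf_correct) / ns_correct,
                NA_real_)
  as.numeric(out)
}

#' Per-participant, per-language fluency difference scores
#'
#' Pairs each language's no-switch condition score with its letter-fluency
#' condition score: NS-L1 with LF-L1 and NS-L2 with LF-L2.
#'
#' @param cond_scores Condition scores from [condition_scores()].
#' @return Data frame: `participant_id`, `group`, `language` (`"L1"` /
#'   `"L2"`), `ns_correct`, `lf_correct`, `fds`.
#' @export
fds_table <- function(cond_scores) {
  get1 <- function(pid, cond) {
    v <- cond_scores$mean_correct[cond_scores$participant_id == pid &
                                    cond_scores$condition == cond]
    if (length(v)) v[1L] else NA_real_
  }
  pids <- unique(cond_scores$participant_id)
  rows <- lapply(pids, function(pid) {
    grp <- cond_scores$group[cond_scores$participant_id == pid][1L]
    do.call(rbind, lapply(c("L1", "L2"), function(lg) {
      ns <- get1(pid, paste0("NS-", lg))
      lf <- get1(pid, paste0("LF-", lg))
      data.frame(participant_id = pid, group = grp, language = lg,
                 ns_correct = ns, lf_correct = lf,
                 fds = if (is.na(ns) || is.na(lf)) NA_real_
                       else compute_fds(ns, lf),
                 stringsAsFactors = FALSE)
    }))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Assemble the participant-by-condition analysis table
#'
#' Full outer join of condition scores, clustering/switching metrics,
#' fluency difference scores and participant covariates, with explicit
#' missing codes (`NA`). One row per participant x condition; FDS columns
#' (per language) and covariates repeat within participant.
#'
#' @param cond_scores From [condition_scores()].
#' @param cluster_tab From [cluster_switch_table()].
#' @param fds From [fds_table()] (optional).
#' @param covariates Data frame keyed by `participant_id` (optional).
#' @return Data frame of class `analysis_table`.
#' @export
build_analysis_table <- function(cond_scores, cluster_tab, fds = NULL,
                                 covariates = NULL) {
  key <- c("participant_id", "group", "condition")
  dup <- function(d, what) {
    k <- do.call(paste, d[intersect(key, names(d))])
    if (anyDuplicated(k))
      stop("conflicting duplicate keys in ", what, ": ",
           paste(unique(k[duplicated(k)]), collapse = ", "))
  }
  dup(cond_scores, "condition scores"); dup(cluster_tab, "cluster metrics")
  tab <- merge(cond_scores, cluster_tab, by = key, all = TRUE)
  if (!is.null(fds) && nrow(fds)) {
    wide <- stats::reshape(
      fds[, c("participant_id", "language", "fds")],
      idvar = "participant_id", timevar = "language", direction = "wide")
    names(wide) <- sub("^fds\\.", "fds_", names(wide))
    tab <- merge(tab, wide, by = "participant_id", all = TRUE)
  }
  if (!is.null(covariates) && nrow(covariates)) {
    if (anyDuplicated(covariates$participant_id))
      stop("conflicting duplicate keys in covariates")
    tab <- merge(tab, covariates,
                 by = "participant_id", all = TRUE,
                 suffixes = c("", ".cov"))
  }
  tab <- tab[order(tab$participant_id, tab$condition), ]
  rownames(tab) <- NULL
  class(tab) <- c("analysis_table", "data.frame")
  tab
}

#' Write an analysis table with its column dictionary
#'
#' Writes the table as CSV and a machine-readable JSON sidecar
#' (`<path>.dict.json`) describing each column.
#'
#' @param tab An `analysis_table`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_analysis_table <- function(tab, path) {
  utils::write.csv(tab, path, row.names = FALSE, na = "")
  base_dict <- c(
    participant_id = "participant identifier",
    group = "participant group (BPWA / HB)",
    condition = "task condition (NS-L1, NS-L2, SS, FS, LF-L1, LF-L2)",
    mean_correct = "correct responses, averaged across administrations",
    n_trials = "trials contributing to this row",
    incomplete = "TRUE when an administration was missing",
    mode = "clustering mode (semantic / phonemic)",
    mean_cluster_size = "mean cluster size (cluster size = span - 1)",
    n_switches = "number of between-cluster transitions",
    fds_L1 = "fluency difference score, L1",
    fds_L2 = "fluency difference score, L2")
  dict <- lapply(names(tab), function(nm) {
    list(column = nm,
         description = if (nm %in% names(base_dict)) base_dict[[nm]]
                       else "participant covariate")
  })
  jsonlite::write_json(dict, paste0(path, ".dict.json"), auto_unbox = TRUE,
                       pretty = TRUE)
  invisible(path)
}
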