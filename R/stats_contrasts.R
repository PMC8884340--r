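#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up false discovery rate adjustment: sorted `p * m / rank`, running
#' minimum from the largest p downward, capped at 1.
#'
#' @param p Numeric vector of raw p-values.
#' @return Adjusted p-values in the original order; `adjusted >= raw`
#'   elementwise.
#' @export
bh_adjust <- function(p) {
  p <- as.numeric(p)
  ok <- !is.na(p)
  m <- sum(ok)
  out <- rep(NA_real_, length(p))
  if (m == 0L) return(out)
  o <- order(p[ok], decreasing = TRUE)
  ro <- order(o)
  adj <- pmin(1, cummin(m / (m:1) * p[ok][o]))[ro]
  out[ok] <- adj
  out
}

#' Cohen's d
#'
#' Independent samples: mean difference over the pooled standard deviation.
#' Paired samples: mean difference over the standard deviation of the
#' differences.
#'
#' @param x,y Numeric vectors.
#' @param paired Logical.
#' @return Numeric scalar.
#' @export
cohens_d <- function(x, y, paired = FALSE) {
  if (paired) {
    d <- x - y
    mean(d) / sd(d)
  } else {
    nx <- length(x); ny <- length(y)
    sp <- sqrt(((nx - 1) * var(x) + (ny - 1) * var(y)) / (nx + ny - 2))
    (mean(x) - mean(y)) / sp
  }
}

#' Planned contrasts with FDR correction
#'
#' Runs a family of planned t tests over cells of an analysis table and
#' applies Benjamini-Hochberg adjustment within the family. Paired
#' contrasts use the paired t test on participant-matched values;
#' independent contrasts use Welch's t test. Contrasts with fewer than two
#' complete observations in a cell are skipped with a message.
#'
#' @param data Long-format data frame.
#' @param dv Dependent-variable column name.
#' @param cell Column defining the contrasted cells (e.g. `"condition"` or
#'   `"group"`).
#' @param pairs List of length-2 character vectors naming cell levels.
#' @param paired Logical: paired (within-participant) contrasts?
#' @param id Participant identifier column (used for pairing).
#' @param subset Optional logical vector selecting rows of `data` first.
#' @return Data frame of class `contrast_result`: `contrast`, `t`, `df`,
#'   `p`, `p_adj`, `d` (Cohen), `n1`, `n2`.
#' @export
planned_contrasts <- function(data, dv, cell, pairs, paired = FALSE,
                              id = "participant_id", subset = NULL) {
  if (!is.null(subset)) data <- data[subset, , drop = FALSE]
  one <- function(pr) {
    a <- data[data[[cell]] == pr[1L], c(id, dv)]
    b <- data[data[[cell]] == pr[2L], c(id, dv)]
    if (paired) {
      m <- merge(a, b, by = id)
      m <- m[complete.cases(m), ]
      x <- m[[paste0(dv, ".x")]]; y <- m[[paste0(dv, ".y")]]
      if (nrow(m) < 2L) return(NULL)
      if (sd(x - y) == 0) {
        tt <- list(statistic = 0, parameter = nrow(m) - 1L, p.value = 1)
      } else {
        tt <- t.test(x, y, paired = TRUE)
      }
      dd <- if (sd(x - y) == 0) 0 else cohens_d(x, y, paired = TRUE)
      n1 <- n2 <- nrow(m)
    } else {
      x <- a[[dv]][!is.na(a[[dv]])]; y <- b[[dv]][!is.na(b[[dv]])]
      if (length(x) < 2L || length(y) < 2L) return(NULL)
      tt <- t.test(x, y, var.equal = FALSE)
      dd <- cohens_d(x, y)
      n1 <- length(x); n2 <- length(y)
    }
    data.frame(contrast = paste(pr, collapse = " vs "),
               t = unname(tt$statistic), df = unname(tt$parameter),
               p = tt$p.value, d = dd, n1 = n1, n2 = n2,
               stringsAsFactors = FALSE)
  }
  rows <- Filter(Negate(is.null), lapply(pairs, one))
  if (length(rows) < length(pairs))
    message("planned_contrasts: ", length(pairs) - length(rows),
            " contrast(s) skipped (insufficient data)")
  if (!length(rows))
    return(structure(data.frame(), class = c("contrast_result", "data.frame")))
  out <- do.call(rbind, rows)
  out$p_adj <- bh_adjust(out$p)
  out <- out[, c("contrast", "t", "df", "p", "p_adj", "d", "n1", "n2")]
  rownames(out) <- NULL
  class(out) <- c("contrast_result", "data.frame")
  out
}
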