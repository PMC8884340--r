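#' Backward stepwise ordinary least squares
#'
#' Starts from the full model and iteratively removes the predictor with
#' the largest coefficient p-value above `removal_alpha` until every
#' remaining predictor is below the threshold (or none remain). Perfectly
#' collinear predictors (aliased coefficients) are dropped first with a
#' message. The final model's coefficient p-values receive
#' Benjamini-Hochberg adjustment (one family per model, intercept
#' included, matching how regression tables are reported).
#'
#' @param data Data frame.
#' @param response Response column name.
#' @param predictors Character vector of initial predictor column names.
#' @param removal_alpha Removal threshold on coefficient p-values
#'   (default 0.10; the elimination criterion is a configuration choice).
#' @return Object of class `stepwise_result`: list with `retained`
#'   (character), `coefficients` (data frame: `term`, `B`, `SE`, `t`, `p`,
#'   `p_adj`), `r_squared`, `adj_r_squared`, `F`, `df1`, `df2`, `model_p`,
#'   `steps` (character log of removals), `model` (the final `lm`).
#' @export
backward_stepwise <- function(data, response, predictors,
                              removal_alpha = 0.10) {
  d <- data[, c(response, predictors), drop = FALSE]
  d <- d[complete.cases(d), , drop = FALSE]
  if (nrow(d) <= length(predictors) + 1L)
    warning("n (", nrow(d), ") close to or below predictor count (",
            length(predictors), "); estimates unstable")
  current <- predictors
  steps <- character(0)
  repeat {
    form <- if (length(current))
      as.formula(paste(response, "~", paste(sprintf("`%s`", current),
                                            collapse = " + ")))
    else as.formula(paste(response, "~ 1"))
    fit <- lm(form, data = d)
    aliased <- names(which(is.na(coef(fit))))
    if (length(aliased)) {
      bad <- gsub("`", "", aliased)
      steps <- c(steps, paste("dropped (aliased):", paste(bad, collapse = ", ")))
      current <- setdiff(current, bad)
      next
    }
    if (!length(current)) break
    ct <- summary(fit)$coefficients
    pv <- ct[setdiff(rownames(ct), "(Intercept)"), "Pr(>|t|)", drop = TRUE]
    names(pv) <- gsub("`", "", setdiff(rownames(ct), "(Intercept)"))
    pv[is.na(pv)] <- 1   # saturated fit: no residual df, nothing testable
    worst <- names(pv)[which.max(pv)]
    if (max(pv) <= removal_alpha) break
    steps <- c(steps, sprintf("removed %s (p = %.4f)", worst, max(pv)))
    current <- setdiff(current, worst)
  }
  sm <- summary(fit)
  ct <- sm$coefficients
  coefs <- data.frame(term = gsub("`", "", rownames(ct)),
                      B = ct[, "Estimate"], SE = ct[, "Std. Error"],
                      t = ct[, "t value"], p = ct[, "Pr(>|t|)"],
                      stringsAsFactors = FALSE)
  coefs$p_adj <- bh_adjust(coefs$p)
  rownames(coefs) <- NULL
  fs <- sm$fstatistic
  structure(list(
    retained = current,
    coefficients = coefs,
    r_squared = sm$r.squared,
    adj_r_squared = sm$adj.r.squared,
    F = if (is.null(fs)) NA_real_ else unname(fs[1L]),
    df1 = if (is.null(fs)) NA_real_ else unname(fs[2L]),
    df2 = if (is.null(fs)) NA_real_ else unname(fs[3L]),
    model_p = if (is.null(fs)) NA_real_
              else pf(fs[1L], fs[2L], fs[3L], lower.tail = FALSE),
    steps = steps,
    model = fit),
    class = "stepwise_result")
}

#' @export
print.stepwise_result <- function(x, ...) {
  cat("Backward stepwise OLS: retained",
      if (length(x$retained)) paste(x$retained, collapse = ", ")
      else "(intercept only)", "\n")
  cat(sprintf("R^2 = %.3f, F(%g, %g) = %.3f, p = %.4f\n",
              x$r_squared, x$df1, x$df2, x$F, x$model_p))
  print(x$coefficients, digits = 3)
  invisible(x)
}
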