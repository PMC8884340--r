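#' Two-way mixed (split-plot) repeated-measures ANOVA
#'
#' One between-subject factor (e.g. group) crossed with one within-subject
#' factor (e.g. condition or language). Participants with incomplete
#' within-factor cells are dropped listwise (with a message). Two
#' conventions for the within-subject tests are reported: the univariate
#' split-plot F (error term = subject-by-within interaction) and the
#' multivariate test on within-subject contrast scores (Wilks' lambda,
#' exact F since each hypothesis has one degree of freedom in the
#' between-design). Effect sizes are partial eta squared,
#' `SS_effect / (SS_effect + SS_error)` (for the multivariate rows,
#' `1 - lambda`). No sphericity correction is applied by default.
#'
#' @param data Data frame in long format.
#' @param dv Name of the numeric dependent variable column.
#' @param within Name of the within-subject factor column.
#' @param between Name of the between-subject factor column.
#' @param id Name of the participant identifier column.
#' @return Data frame of class `anova_result`: columns `effect`,
#'   `approach`, `F`, `df1`, `df2`, `p`, `pes`, `n` (participants used).
#' @export
mixed_anova <- function(data, dv, within, between, id = "participant_id") {
  d <- data.frame(y = as.numeric(data[[dv]]),
                  w = as.character(data[[within]]),
                  b = as.character(data[[between]]),
                  s = as.character(data[[id]]),
                  stringsAsFactors = FALSE)
  d <- d[complete.cases(d), ]
  k <- length(unique(d$w))
  if (k < 2L || length(unique(d$b)) < 2L)
    stop("both factors need at least 2 levels")
  # listwise deletion of participants lacking complete within cells
  cnt <- table(d$s, d$w)
  complete <- rownames(cnt)[apply(cnt == 1L, 1L, all)]
  dropped <- setdiff(unique(d$s), complete)
  if (length(dropped))
    message("mixed_anova: dropping ", length(dropped),
            " participant(s) with incomplete cells")
  d <- d[d$s %in% complete, ]
  n <- length(complete)
  g <- length(unique(d$b))
  d$w <- factor(d$w); d$b <- factor(d$b); d$s <- factor(d$s)

  fit <- aov(y ~ b * w + Error(s / w), data = d)
  sm <- summary(fit)
  ss <- function(stratum, term) {
    tab <- sm[[stratum]][[1L]]
    i <- match(term, trimws(rownames(tab)))
    list(ss = tab[i, "Sum Sq"], df = tab[i, "Df"],
         F = if ("F value" %in% colnames(tab)) tab[i, "F value"] else NA_real_,
         p = if ("Pr(>F)" %in% colnames(tab)) tab[i, "Pr(>F)"] else NA_real_)
  }
  res_b <- ss("Error: s", "Residuals")
  eff_b <- ss("Error: s", "b")
  res_w <- ss("Error: s:w", "Residuals")
  eff_w <- ss("Error: s:w", "w")
  eff_i <- ss("Error: s:w", "b:w")
  uni <- data.frame(
    effect = c(between, within, paste0(between, ":", within)),
    approach = "univariate",
    F = c(eff_b$F, eff_w$F, eff_i$F),
    df1 = c(eff_b$df, eff_w$df, eff_i$df),
    df2 = c(res_b$df, res_w$df, res_w$df),
    p = c(eff_b$p, eff_w$p, eff_i$p),
    pes = c(eff_b$ss / (eff_b$ss + res_b$ss),
            eff_w$ss / (eff_w$ss + res_w$ss),
            eff_i$ss / (eff_i$ss + res_w$ss)),
    n = n, stringsAsFactors = FALSE)

  multi <- rbind(
    wilks_within(d, test = "within"),
    wilks_within(d, test = "interaction"))
  multi$effect <- c(within, paste0(between, ":", within))
  multi <- multi[, c("effect", "approach", "F", "df1", "df2", "p", "pes")]
  multi$n <- n

  out <- rbind(uni, multi)
  rownames(out) <- NULL
  class(out) <- c("anova_result", "data.frame")
  out
}

# Multivariate tests on within-subject contrast scores. Sum-to-zero group
# coding makes the intercept the unweighted grand mean, so the within main
# effect is the test of the contrast-score intercept; the interaction is
# the test of the group terms. Each hypothesis matrix has one row, so
# Wilks' lambda gives an exact F with df (k-1, n - g - k + 2).
wilks_within <- function(d, test) {
  Y <- tapply(d$y, list(d$s, d$w), mean)
  k <- ncol(Y)
  C <- diff(diag(k))               # successive-difference contrasts, k-1 rows
  Yc <- Y %*% t(C)
  b <- factor(d$b[match(rownames(Y), d$s)])
  g <- nlevels(b)
  X <- model.matrix(~ b, contrasts.arg = list(b = "contr.sum"))
  n <- nrow(Y)
  XtXi <- solve(crossprod(X))
  B <- XtXi %*% crossprod(X, Yc)
  E <- crossprod(Yc - X %*% B)
  ve <- n - g
  p <- k - 1L
  rows <- if (test == "within") matrix(c(1, rep(0, g - 1L)), nrow = 1L)
          else cbind(0, diag(g - 1L))
  q <- nrow(rows)
  LB <- rows %*% B
  H <- t(LB) %*% solve(rows %*% XtXi %*% t(rows)) %*% LB
  lambda <- det(E) / det(E + H)
  if (q == 1L) {
    df2 <- ve - p + 1L
    Fv <- (1 - lambda) / lambda * df2 / p
    pval <- pf(Fv, p, df2, lower.tail = FALSE)
    pes <- 1 - lambda
    data.frame(approach = "multivariate", F = Fv, df1 = p, df2 = df2,
               p = pval, pes = pes, stringsAsFactors = FALSE)
  } else {
    # Rao's approximation for general q
    s <- sqrt((p^2 * q^2 - 4) / (p^2 + q^2 - 5))
    m <- ve - (p - q + 1) / 2
    df2 <- m * s - (p * q) / 2 + 1
    lam_s <- lambda^(1 / s)
    Fv <- (1 - lam_s) / lam_s * df2 / (p * q)
    data.frame(approach = "multivariate", F = Fv, df1 = p * q, df2 = df2,
               p = pf(Fv, p * q, df2, lower.tail = FALSE),
               pes = 1 - lambda^(1 / s), stringsAsFactors = FALSE)
  }
}
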