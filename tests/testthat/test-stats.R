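test_that("mixed_anova univariate F matches the hand-computed SS oracle", {
  for (cfg in list(c(4, 2, 101), c(6, 3, 102), c(5, 4, 103))) {
    d <- make_mixed_data(cfg[1], cfg[2], cfg[3], group_eff = 0.8,
                         cond_eff = 0.5)
    res <- mixed_anova(d, "y", "w", "b", id = "s")
    ref <- ref_split_plot(d)
    uni <- res[res$approach == "univariate", ]
    expect_equal(uni$F, c(ref$F_b, ref$F_w, ref$F_i), tolerance = 1e-10)
    expect_equal(uni$pes, c(ref$pes_b, ref$pes_w, ref$pes_i),
                 tolerance = 1e-10)
  }
})

test_that("mixed_anova df conventions and degenerate cases", {
  d <- make_mixed_data(10, 4, 104)
  res <- mixed_anova(d, "y", "w", "b", id = "s")
  uni <- res[res$approach == "univariate", ]
  expect_equal(uni$df1, c(1, 3, 3))
  expect_equal(uni$df2, c(18, 54, 54))
  mv <- res[res$approach == "multivariate", ]
  # multivariate within tests: df (k-1, n - g - k + 2)
  expect_equal(mv$df1, c(3, 3))
  expect_equal(mv$df2, c(16, 16))
  # duplicated groups, column-centred noise: all effect SS vanish exactly
  withr::local_seed(105)
  a <- rnorm(4); E <- matrix(rnorm(12), 4, 3)
  E <- sweep(E, 2, colMeans(E))
  d2 <- expand.grid(s = sprintf("s%d", 1:8), w = paste0("c", 1:3),
                    stringsAsFactors = FALSE)
  d2$b <- ifelse(as.integer(sub("s", "", d2$s)) <= 4, "g1", "g2")
  i_subj <- ((as.integer(sub("s", "", d2$s)) - 1L) %% 4L) + 1L
  d2$y <- a[i_subj] + E[cbind(i_subj, as.integer(sub("c", "", d2$w)))]
  r2 <- mixed_anova(d2, "y", "w", "b", id = "s")
  expect_true(all(r2$F[r2$approach == "univariate"] < 1e-20))
  expect_error(mixed_anova(d[d$b == "g1", ], "y", "w", "b", id = "s"),
               "2 levels")
})

test_that("mixed_anova detects a planted group effect at study scale", {
  hits <- 0L
  for (seed in 1:20) {
    d <- make_mixed_data(14, 2, 200 + seed, group_eff = 1.85)
    res <- mixed_anova(d, "y", "w", "b", id = "s")
    p <- res$p[res$effect == "b"]
    if (p < 0.05) hits <- hits + 1L
  }
  expect_gte(hits, 18L)   # ~ d = 1.5 per subject-mean, power >> 0.9
})

test_that("incomplete participants are dropped listwise with a message", {
  d <- make_mixed_data(5, 3, 106)
  d <- d[!(d$s == "s01" & d$w == "c2"), ]
  expect_message(res <- mixed_anova(d, "y", "w", "b", id = "s"),
                 "dropping 1")
  expect_identical(unique(res$n), 9L)
})

test_that("bh_adjust equals the definitional oracle", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  withr::local_seed(31)
  for (k in 1:100) {
    p <- runif(sample(1:12, 1))
    expect_equal(bh_adjust(p), ref_bh(p), tolerance = 1e-12)
    expect_true(all(bh_adjust(p) >= p))
    expect_true(all(bh_adjust(p) <= 1))
  }
  # NA passthrough
  expect_identical(bh_adjust(c(0.1, NA))[2], NA_real_)
})

test_that("planned_contrasts: paired, Welch, invariance, skipping", {
  withr::local_seed(32)
  d <- data.frame(participant_id = rep(sprintf("p%02d", 1:12), 2),
                  condition = rep(c("A", "B"), each = 12),
                  y = c(rnorm(12, 1), rnorm(12, 0)))
  res <- planned_contrasts(d, "y", "condition", list(c("A", "B")),
                           paired = TRUE)
  expect_identical(res$df, 11)
  # identical vectors -> t = 0, p = 1
  d0 <- d; d0$y[13:24] <- d0$y[1:12]
  r0 <- planned_contrasts(d0, "y", "condition", list(c("A", "B")),
                          paired = TRUE)
  expect_identical(r0$t, 0)
  expect_identical(r0$p, 1)
  # constant shift leaves paired contrasts among shifted cells unchanged
  d1 <- d; d1$y <- d1$y + 5
  r1 <- planned_contrasts(d1, "y", "condition", list(c("A", "B")),
                          paired = TRUE)
  expect_equal(r1$t, res$t, tolerance = 1e-12)
  # Welch for independent contrasts
  g <- data.frame(participant_id = sprintf("q%02d", 1:20),
                  group = rep(c("G1", "G2"), each = 10),
                  y = c(rnorm(10, 0, 1), rnorm(10, 1, 3)))
  rw <- planned_contrasts(g, "y", "group", list(c("G1", "G2")))
  tt <- t.test(g$y[1:10], g$y[11:20])
  expect_equal(rw$t, unname(tt$statistic))
  expect_equal(rw$df, unname(tt$parameter))   # fractional Welch df
  expect_equal(rw$d, cohens_d(g$y[1:10], g$y[11:20]))
  # insufficient cells are skipped with a message
  expect_message(
    rs <- planned_contrasts(g[1:12, ], "y", "group",
                            list(c("G1", "G2"), c("G1", "G3"))),
    "skipped")
  expect_identical(nrow(rs), 1L)
  # BH within the declared family
  d3 <- rbind(d, data.frame(participant_id = rep(sprintf("p%02d", 1:12), 1),
                            condition = "C", y = rnorm(12, 0.5)))
  r3 <- planned_contrasts(d3, "y", "condition",
                          list(c("A", "B"), c("A", "C"), c("B", "C")),
                          paired = TRUE)
  expect_equal(r3$p_adj, ref_bh(r3$p), tolerance = 1e-12)
})

test_that("pca_varimax recovers planted loadings and preserves structure", {
  withr::local_seed(33)
  n <- 300
  L <- rbind(c(0.85, 0), c(0.8, 0), c(0.75, 0),
             c(0, 0.85), c(0, 0.8), c(0, 0.75))
  z <- matrix(rnorm(n * 2), n, 2)
  X <- z %*% t(L) + matrix(rnorm(n * 6, 0, 0.45), n, 6)
  colnames(X) <- paste0("v", 1:6)
  p <- pca_varimax(X)
  expect_identical(p$n_retained, 2L)
  # each planted variable loads saliently on exactly one rotated component
  lead <- apply(abs(p$rotated), 1, which.max)
  expect_identical(length(unique(lead[1:3])), 1L)
  expect_identical(length(unique(lead[4:6])), 1L)
  expect_false(lead[1] == lead[4])
  expect_true(all(apply(abs(p$rotated), 1, max) > 0.6))
  # invariants
  expect_true(all(diff(p$eigenvalues) <= 1e-12))
  expect_equal(rowSums(p$rotated^2), rowSums(p$loadings^2),
               tolerance = 1e-8)
  expect_equal(crossprod(p$rotation_matrix), diag(2), tolerance = 1e-10)
  expect_equal(unname(colMeans(p$scores)), c(0, 0), tolerance = 1e-10)
  expect_true(all(p$salient == (abs(p$rotated) > 0.6)))
})

test_that("pca_varimax edge cases", {
  withr::local_seed(34)
  # near-identity correlation: strict '>' retention boundary
  X <- matrix(rnorm(500 * 4), 500, 4)
  colnames(X) <- paste0("v", 1:4)
  p <- pca_varimax(X)
  expect_lt(p$n_retained, 4L)   # not every eigenvalue can exceed 1
  expect_gte(p$n_retained, 1L)
  Xc <- cbind(X, v5 = 1)
  expect_error(pca_varimax(Xc), "v5")
  expect_warning(pca_varimax(matrix(rnorm(12), 3, 4)), "unstable")
})

test_that("backward_stepwise eliminates noise and keeps signal", {
  withr::local_seed(35)
  n <- 60
  x1 <- rnorm(n); x2 <- rnorm(n); x3 <- rnorm(n)
  y <- 2 * x1 + rnorm(n, 0, 0.4)
  d <- data.frame(y, x1, x2, x3)
  r <- backward_stepwise(d, "y", c("x1", "x2", "x3"))
  expect_identical(r$retained, "x1")
  expect_gt(r$r_squared, 0.9)
  expect_equal(r$coefficients$p_adj, ref_bh(r$coefficients$p),
               tolerance = 1e-12)
  # all-noise predictors collapse to intercept-only
  y0 <- rnorm(n)
  r0 <- backward_stepwise(data.frame(y = y0, x1, x2, x3), "y",
                          c("x1", "x2", "x3"))
  expect_identical(r0$retained, character(0))
  # single strong predictor is untouched by the stepwise pass
  r1 <- backward_stepwise(d, "y", "x1")
  expect_identical(r1$retained, "x1")
  expect_equal(r1$coefficients$B[2], unname(coef(lm(y ~ x1))[2]))
  # perfect collinearity is dropped, not fatal
  d$x4 <- d$x1
  rc <- backward_stepwise(d, "y", c("x1", "x4", "x2"))
  expect_true("x1" %in% rc$retained || "x4" %in% rc$retained)
  expect_warning(backward_stepwise(d[1:4, ], "y", c("x1", "x2", "x3")),
                 "unstable|close")
})

test_that("the battery is deterministic given the analysis table", {
  lex <- bifluency_lexicon()
  coh <- generate_cohort(cohort_spec(n_bpwa = 8, n_hb = 6, seed = 77), lex)
  tab <- cohort_analysis_table(coh, lex)
  cat_tab <- tab[tab$condition %in% c("NS-L1", "NS-L2", "SS", "FS"), ]
  a1 <- mixed_anova(cat_tab, "n_switches", "condition", "group")
  a2 <- mixed_anova(cat_tab, "n_switches", "condition", "group")
  expect_identical(a1, a2)
})
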