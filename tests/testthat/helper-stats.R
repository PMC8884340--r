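# Hand-computed split-plot sums of squares for a balanced two-group by
# k-condition design: the independent oracle for mixed_anova.
ref_split_plot <- function(d) {
  gm <- mean(d$y)
  subj <- tapply(d$y, d$s, mean)
  grp_of_subj <- tapply(d$b, d$s, function(x) x[1])
  grp <- tapply(d$y, d$b, mean)
  cond <- tapply(d$y, d$w, mean)
  cell <- tapply(d$y, list(d$b, d$w), mean)
  k <- length(cond); n_s <- length(subj)
  ss_b <- sum(k * table(grp_of_subj) *
                (grp[names(table(grp_of_subj))] - gm)^2)
  ss_subj <- k * sum((subj - grp[grp_of_subj])^2)
  ss_w <- n_s * sum((cond - gm)^2)
  ss_i <- 0
  for (g in rownames(cell)) for (cw in colnames(cell)) {
    ng <- sum(grp_of_subj == g)
    ss_i <- ss_i + ng * (cell[g, cw] - grp[g] - cond[cw] + gm)^2
  }
  ss_tot <- sum((d$y - gm)^2)
  ss_res <- ss_tot - ss_b - ss_subj - ss_w - ss_i
  g <- length(grp)
  lapply(list(
    F_b = (ss_b / (g - 1)) / (ss_subj / (n_s - g)),
    F_w = (ss_w / (k - 1)) / (ss_res / ((n_s - g) * (k - 1))),
    F_i = (ss_i / ((g - 1) * (k - 1))) /
      (ss_res / ((n_s - g) * (k - 1))),
    pes_b = ss_b / (ss_b + ss_subj),
    pes_w = ss_w / (ss_w + ss_res),
    pes_i = ss_i / (ss_i + ss_res)), unname)
}

make_mixed_data <- function(n_per_group, k, seed, group_eff = 0,
                            cond_eff = 0) {
  withr::local_seed(seed)
  d <- expand.grid(s = sprintf("s%02d", seq_len(2 * n_per_group)),
                   w = paste0("c", seq_len(k)), stringsAsFactors = FALSE)
  d$b <- ifelse(as.integer(sub("s", "", d$s)) <= n_per_group, "g1", "g2")
  d$y <- rnorm(nrow(d)) + group_eff * (d$b == "g2") +
    cond_eff * (d$w == "c2") + rnorm(2 * n_per_group)[
      as.integer(sub("s", "", d$s))]
  d
}

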