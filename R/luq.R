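# Planted language-use-questionnaire (LUQ) factor structures. Loadings are
# the published rotated-component patterns for each group x language; the
# generator treats them as a linear latent-factor model on standardized
# scale, with uniqueness 1 - communality (floored) so variables have
# approximately unit variance.

luq_loading_matrix <- function(vars, k, values) {
  matrix(values, nrow = length(vars), ncol = k, byrow = TRUE,
         dimnames = list(vars, paste0("F", seq_len(k))))
}

#' Planted LUQ factor structures
#'
#' Returns the loading matrix, metric types and metric names for one of
#' the four group-by-language questionnaire structures: three factors for
#' the aphasia group's L1 (background, use/exposure, environment), two for
#' its L2, one for healthy bilinguals' L1 and two for their L2.
#'
#' @param group `"BPWA"` or `"HB"`.
#' @param language `"L1"` or `"L2"`.
#' @return List with `loadings` (variables x factors), `types` (named
#'   character: `"percent"`, `"years_aoa"` or `"years_edu"`), `n_factors`.
#' @export
luq_structure <- function(group = c("BPWA", "HB"), language = c("L1", "L2")) {
  group <- match.arg(group); language <- match.arg(language)
  if (group == "BPWA" && language == "L1") {
    vars <- c("pre_lar", "post_lar", "pre_use", "post_use",
              "family_proficiency", "education", "exposure", "confidence")
    L <- luq_loading_matrix(vars, 3L, c(
       0.85,  0.23, -0.01,
       0.46, -0.08,  0.58,
      -0.02,  0.90, -0.05,
       0.29,  0.83,  0.14,
      -0.08,  0.18,  0.89,
       0.74,  0.41,  0.08,
       0.50,  0.68,  0.21,
       0.72,  0.03,  0.08))
  } else if (group == "BPWA" && language == "L2") {
    vars <- c("aoa", "pre_lar", "post_lar", "pre_use", "post_use",
              "family_proficiency", "education", "exposure", "confidence")
    L <- luq_loading_matrix(vars, 2L, c(
      -0.84, -0.17,
       0.46,  0.63,
       0.01,  0.58,
       0.15,  0.75,
       0.15,  0.77,
       0.86,  0.07,
       0.50,  0.58,
       0.52,  0.69,
       0.85,  0.19))
  } else if (group == "HB" && language == "L1") {
    vars <- c("lar", "use", "family_proficiency", "education",
              "exposure", "confidence")
    L <- luq_loading_matrix(vars, 1L,
                            c(0.84, 0.50, 0.39, 0.94, 0.81, 0.81))
  } else {
    vars <- c("aoa", "lar", "use", "family_proficiency", "education",
              "exposure", "confidence")
    L <- luq_loading_matrix(vars, 2L, c(
      -0.81, -0.17,
       0.21,  0.83,
      -0.05,  0.77,
       0.80, -0.04,
       0.64,  0.58,
       0.58,  0.72,
       0.69,  0.58))
  }
  types <- rep("percent", length(vars))
  names(types) <- vars
  types[vars == "aoa"] <- "years_aoa"
  types[vars == "education"] <- "years_edu"
  list(loadings = L, types = types, n_factors = ncol(L))
}

#' Generate LUQ metric vectors with a planted factor structure
#'
#' Draws latent factors `z ~ N(0, I)` and sets standardized metrics to
#' `loadings %*% z + noise`, with uniqueness `1 - communality` (floored at
#' 0.05) so metrics have near-unit variance and the sample correlation
#' matrix carries the planted structure. Metrics are then rescaled into
#' instrument ranges: percentages to `[0, 100]` (post-injury variables
#' shifted down so post <= pre in expectation), age of acquisition to
#' years in `[0, 40]`, education to years in `[6, 22]`. Set
#' `rescale = FALSE` to keep the standardized scale (used by
#' factor-recovery checks, which are scale-invariant up to the clipping).
#'
#' @param n Number of participants.
#' @param structure A [luq_structure()] list.
#' @param noise_sd Multiplier on the uniqueness standard deviations
#'   (default 1; 0 gives rank-deficient data equal to the factor part).
#' @param rescale Rescale into instrument ranges? Default `TRUE`.
#' @return Matrix `n` x variables (column names from the structure).
#' @export
generate_luq <- function(n, structure, noise_sd = 1, rescale = TRUE) {
  L <- structure$loadings
  k <- ncol(L); p <- nrow(L)
  psi <- pmax(1 - rowSums(L^2), 0.05)
  z <- matrix(rnorm(n * k), n, k)
  eps <- matrix(rnorm(n * p), n, p)
  X <- z %*% t(L) + noise_sd * eps %*% diag(sqrt(psi), p)
  colnames(X) <- rownames(L)
  if (!rescale) return(X)
  for (v in colnames(X)) {
    X[, v] <- switch(structure$types[[v]],
      percent = {
        shift <- if (startsWith(v, "post_")) -8 else 0
        pmin(pmax(55 + shift + 18 * X[, v], 0), 100)
      },
      years_aoa = pmin(pmax(12 + 6 * X[, v], 0), 40),
      years_edu = pmin(pmax(14 + 3 * X[, v], 6), 22))
  }
  X
}

# Published group-level assessment score summaries (percent correct):
# mean and SD per instrument, used to simulate standardized assessment
# performance correlated with the latent ability factor.
assessment_norms <- function(group) {
  if (group == "BPWA") {
    data.frame(
      measure = c("naming_L1", "naming_L2", "bnt_L1", "bnt_L2",
                  "palpa_L1", "palpa_L2", "bat_L1", "bat_L2",
                  "papt", "rcpm"),
      mean = c(56.5, 42.7, 44.1, 32.8, 82.6, 74.8, 69.1, 64.6, 89.2, 74.5),
      sd = c(29.1, 29.0, 26.2, 24.0, 10.0, 13.2, 26.7, 20.3, 10.7, 16.9),
      stringsAsFactors = FALSE)
  } else {
    data.frame(
      measure = c("naming_L1", "naming_L2", "bnt_L1", "bnt_L2",
                  "palpa_L1", "palpa_L2", "bat_L1", "bat_L2", "papt"),
      mean = c(84.6, 78.6, 76.8, 62.8, 93.2, 87.5, 92.7, 83.5, 94.4),
      sd = c(9.6, 15.5, 15.2, 18.0, 6.9, 8.1, 11.0, 17.0, 5.7),
      stringsAsFactors = FALSE)
  }
}

#' Generate standardized assessment scores
#'
#' Scores are drawn around published group norms with a shared loading on
#' the participant's latent language ability, then clipped to the
#' instrument range `[0, 100]`.
#'
#' @param ability Numeric vector of latent ability z-scores.
#' @param group `"BPWA"` or `"HB"` (matrix reasoning is generated for the
#'   aphasia group only).
#' @param loading Correlation between ability and each score (default 0.7).
#' @return Matrix `length(ability)` x measures.
#' @export
generate_assessments <- function(ability, group, loading = 0.7) {
  norms <- assessment_norms(group)
  n <- length(ability)
  out <- vapply(seq_len(nrow(norms)), function(j) {
    raw <- norms$mean[j] + norms$sd[j] *
      (loading * ability + sqrt(1 - loading^2) * rnorm(n))
    pmin(pmax(raw, 0), 100)
  }, numeric(n))
  out <- matrix(out, nrow = n,
                dimnames = list(NULL, norms$measure))
  out
}
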