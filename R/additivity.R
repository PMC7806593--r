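#' Permutation-constructed additive null for a volatile blend
#'
#' Builds the null distribution of the Attraction Index a blend would show
#' if its constituents combined additively: each draw selects, uniformly
#' with replacement across draws, one observed per-replicate AI for every
#' constituent yeast and averages them. Constituents are sorted by name
#' before sampling so the null is invariant to the order in which they are
#' listed.
#'
#' @param constituent_ais Named list: one numeric vector of per-replicate
#'   AI values per constituent isolate (each of length >= 1).
#' @param n_permutations Number of draws (default 10000).
#' @param seed Optional integer seed; identical seed and inputs give
#'   identical draws.
#' @return An object of class `additive_null`: list with `draws`,
#'   `constituents` (sorted ids), `n_permutations`, `seed`.
#' @export
build_null <- function(constituent_ais, n_permutations = 10000, seed = NULL) {
  if (!is.list(constituent_ais) || is.null(names(constituent_ais)) ||
      any(!nzchar(names(constituent_ais)))) {
    stop("constituent_ais must be a named list of per-replicate AI vectors",
         call. = FALSE)
  }
  bad <- names(constituent_ais)[vapply(constituent_ais, function(v) {
    length(v) < 1 || !is.numeric(v) || any(!is.finite(v)) || any(abs(v) > 1)
  }, logical(1))]
  if (length(bad)) {
    stop(sprintf("no usable single-yeast AI replicates for constituent(s): %s",
                 paste(bad, collapse = ", ")), call. = FALSE)
  }
  n_permutations <- as.integer(n_permutations)
  stopifnot(n_permutations >= 1)
  ord <- sort(names(constituent_ais))
  if (!is.null(seed)) set.seed(seed)
  m <- vapply(constituent_ais[ord], function(v) {
    v[sample.int(length(v), n_permutations, replace = TRUE)]
  }, numeric(n_permutations))
  if (is.null(dim(m))) m <- matrix(m, nrow = n_permutations)
  structure(list(draws = rowMeans(m), constituents = ord,
                 n_permutations = n_permutations,
                 seed = if (is.null(seed)) NA_integer_ else as.integer(seed)),
            class = "additive_null")
}

#' @export
print.additive_null <- function(x, ...) {
  cat(sprintf("Additive null: %d draws over %d constituent(s) [%s]\n",
              x$n_permutations, length(x$constituents),
              paste(x$constituents, collapse = ", ")))
  cat(sprintf("  predicted AI (mean of draws): %.4f  range [%.3f, %.3f]\n",
              mean(x$draws), min(x$draws), max(x$draws)))
  invisible(x)
}

#' Permutation p-value against the additive null
#'
#' Compares an observed blend mean AI to the additive null. Tail
#' probabilities use the add-one estimator \eqn{(count + 1)/(N + 1)}, so a
#' p-value is never exactly zero; the two-sided p doubles the smaller tail
#' and is capped at 1.
#'
#' @param observed_mean_ai Observed mean AI of the blend's replicates.
#' @param null An `additive_null` from [build_null()].
#' @param sidedness `"two.sided"` (default), `"less"` (blend below
#'   additive) or `"greater"`.
#' @return The p-value, in (0, 1\].
#' @export
permutation_pvalue <- function(observed_mean_ai, null,
                               sidedness = "two.sided") {
  stopifnot(inherits(null, "additive_null"), length(null$draws) >= 1)
  alt <- match.arg(sidedness, c("two.sided", "greater", "less"))
  d <- null$draws
  N <- length(d)
  p_le <- (sum(d <= observed_mean_ai) + 1) / (N + 1)
  p_ge <- (sum(d >= observed_mean_ai) + 1) / (N + 1)
  switch(alt,
         two.sided = min(1, 2 * min(p_le, p_ge)),
         less = p_le,
         greater = p_ge)
}

#' Linear-model contrast of a blend against the additive expectation
#'
#' Least-squares fit of per-replicate AI on treatment indicators (cell
#' means) across the blend and its constituent single-yeast replicates; the
#' test statistic is the contrast (blend mean) - (weighted mean of
#' constituent means), referred to a t distribution on the pooled residual
#' degrees of freedom. The default weights are equal, matching blends mixed
#' in equal proportions.
#'
#' @param constituent_ais Named list of per-replicate AI vectors, each of
#'   length >= 2.
#' @param blend_ais Numeric vector of the blend's per-replicate AIs,
#'   length >= 2.
#' @param weights Optional positive constituent weights (recycled to the
#'   sorted constituent order); normalised internally.
#' @return A list with `estimate`, `se`, `t`, `df`, `p_value`.
#' @export
lm_interaction_test <- function(constituent_ais, blend_ais, weights = NULL) {
  if (length(blend_ais) < 2 ||
      any(vapply(constituent_ais, length, 1L) < 2)) {
    stop("lm_interaction_test: need >= 2 replicates in the blend and each constituent",
         call. = FALSE)
  }
  ord <- sort(names(constituent_ais))
  k <- length(ord)
  w <- if (is.null(weights)) rep(1 / k, k) else {
    stopifnot(length(weights) == k, all(weights > 0))
    weights / sum(weights)
  }
  dat <- data.frame(
    ai = c(unlist(constituent_ais[ord], use.names = FALSE), blend_ais),
    treatment = factor(
      c(rep(ord, vapply(constituent_ais[ord], length, 1L)),
        rep(".blend", length(blend_ais))),
      levels = c(ord, ".blend")))
  fit <- stats::lm(ai ~ 0 + treatment, data = dat)
  if (fit$rank < k + 1) stop("lm_interaction_test: rank-deficient design",
                             call. = FALSE)
  L <- c(-w, 1)
  est <- drop(L %*% stats::coef(fit))
  # a perfect fit (zero residual) is legitimate here; silence summary.lm
  se <- drop(sqrt(L %*% suppressWarnings(stats::vcov(fit)) %*% L))
  df <- stats::df.residual(fit)
  if (se == 0) {
    # zero residual variance: contrast either exactly additive or exactly not
    t <- if (abs(est) < sqrt(.Machine$double.eps)) 0 else sign(est) * Inf
  } else {
    t <- est / se
  }
  p <- if (is.infinite(t)) 0 else 2 * stats::pt(-abs(t), df)
  list(estimate = est, se = se, t = t, df = df, p_value = p)
}

#' Pooled-variance t-test of a blend against a single yeast
#'
#' Equal-variance two-sample t-test of the blend's per-replicate AIs
#' against a single yeast's (e.g. the best blend against the best single
#' isolate). The statistic is for mean(blend) - mean(single).
#'
#' @param blend_ais,single_ais Numeric vectors of per-replicate AIs, each
#'   of length >= 2.
#' @return A list with `t`, `df`, `p_value`.
#' @export
blend_vs_single_ttest <- function(blend_ais, single_ais) {
  stopifnot(length(blend_ais) >= 2, length(single_ais) >= 2)
  n1 <- length(blend_ais); n2 <- length(single_ais)
  sp2 <- ((n1 - 1) * stats::var(blend_ais) +
          (n2 - 1) * stats::var(single_ais)) / (n1 + n2 - 2)
  df <- n1 + n2 - 2
  if (sp2 == 0) {
    if (mean(blend_ais) == mean(single_ais)) {
      return(list(t = 0, df = df, p_value = 1))
    }
    stop("blend_vs_single_ttest: zero pooled variance with unequal means",
         call. = FALSE)
  }
  t <- (mean(blend_ais) - mean(single_ais)) / sqrt(sp2 * (1 / n1 + 1 / n2))
  list(t = t, df = df, p_value = 2 * stats::pt(-abs(t), df))
}

#' Full additivity test for one blend treatment
#'
#' Runs both inferential routes for a blend: the permutation test against
#' the additive null and (when every group has >= 2 replicates) the
#' linear-model contrast. Direction is `"below_additive"` /
#' `"above_additive"` only when the permutation p falls below `alpha`,
#' else `"consistent"`.
#'
#' @param constituent_ais Named list of single-yeast per-replicate AIs.
#' @param blend_ais Per-replicate AIs of the blend.
#' @param n_permutations,seed Passed to [build_null()].
#' @param alpha Significance level for the direction call.
#' @param sidedness Sidedness of the permutation p-value.
#' @return One-row data.frame: `observed_mean_ai`, `predicted_mean_ai`,
#'   `p_permutation`, `p_linear_model`, `n_permutations`, `seed`,
#'   `direction`.
#' @export
additivity_test <- function(constituent_ais, blend_ais,
                            n_permutations = 10000, seed = NULL,
                            alpha = 0.05, sidedness = "two.sided") {
  stopifnot(length(blend_ais) >= 1)
  null <- build_null(constituent_ais, n_permutations, seed)
  obs <- mean(blend_ais)
  pred <- mean(null$draws)
  p_perm <- permutation_pvalue(obs, null, sidedness)
  p_lm <- if (length(blend_ais) >= 2 &&
              all(vapply(constituent_ais, length, 1L) >= 2)) {
    lm_interaction_test(constituent_ais, blend_ais)$p_value
  } else NA_real_
  direction <- if (p_perm < alpha) {
    if (obs < pred) "below_additive" else "above_additive"
  } else "consistent"
  data.frame(observed_mean_ai = obs, predicted_mean_ai = pred,
             p_permutation = p_perm, p_linear_model = p_lm,
             n_permutations = null$n_permutations, seed = null$seed,
             direction = direction, stringsAsFactors = FALSE)
}
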