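#' Attraction Index from arm counts
#'
#' The Attraction Index of a two-choice run is
#' \deqn{AI = (n_{treatment} - n_{control}) / (n_{treatment} + n_{control}),}
#' the signed excess of flies choosing the treatment arm among all flies
#' that made a choice. +1 is total attraction, -1 total repulsion, 0
#' indifference. Flies that stayed in the central compartment do not enter
#' the index.
#'
#' @param n_treatment_arm,n_control_arm Non-negative integer counts
#'   (vectorised).
#' @return Numeric vector of AI values in \[-1, 1\].
#' @export
compute_ai <- function(n_treatment_arm, n_control_arm) {
  n_choosing <- n_treatment_arm + n_control_arm
  if (any(n_choosing < 1)) {
    stop("AI undefined when no fly made a choice; apply filter_informative() first",
         call. = FALSE)
  }
  (n_treatment_arm - n_control_arm) / n_choosing
}

#' Add per-replicate AI columns to a T-maze table
#'
#' @param reps A validated T-maze table of informative replicates.
#' @return The table with numeric columns `n_choosing` and `ai` appended.
#' @export
ai_table <- function(reps) {
  reps <- validate_tmaze(reps)
  reps$n_choosing <- reps$n_treatment_arm + reps$n_control_arm
  reps$ai <- compute_ai(reps$n_treatment_arm, reps$n_control_arm)
  reps
}

#' Summarise the replicates of one treatment for one fly species
#'
#' Gives the unweighted mean and standard error of the per-replicate AIs
#' (the quantity displayed as mean +/- SE bars) together with the pooled
#' treatment-arm and choosing counts used by the exact binomial choice test.
#'
#' @param reps Informative T-maze replicates sharing one `treatment_id` and
#'   one `fly_species`.
#' @return A one-row data.frame with `treatment_id`, `fly_species`,
#'   `n_replicates`, `mean_ai`, `se_ai` (`NA` for a single replicate),
#'   `pooled_k`, `pooled_n`.
#' @export
summarize_treatment <- function(reps) {
  d <- ai_table(reps)
  if (nrow(d) < 1) stop("summarize_treatment: empty input", call. = FALSE)
  if (length(unique(d$treatment_id)) != 1 ||
      length(unique(d$fly_species)) != 1) {
    stop("summarize_treatment: replicates must share one treatment and one species",
         call. = FALSE)
  }
  n <- nrow(d)
  data.frame(
    treatment_id = d$treatment_id[1],
    fly_species = d$fly_species[1],
    n_replicates = n,
    mean_ai = mean(d$ai),
    se_ai = if (n > 1) stats::sd(d$ai) / sqrt(n) else NA_real_,
    pooled_k = sum(d$n_treatment_arm),
    pooled_n = sum(d$n_choosing),
    stringsAsFactors = FALSE)
}

#' Summarise all treatment x species combinations
#'
#' @param reps Informative T-maze replicates (any mix of treatments and
#'   species).
#' @return A data.frame with one [summarize_treatment()] row per
#'   treatment x species combination, ordered by species then treatment.
#' @export
summarize_ai <- function(reps) {
  d <- validate_tmaze(reps)
  parts <- split(d, list(d$fly_species, d$treatment_id), drop = TRUE)
  out <- do.call(rbind, lapply(parts, summarize_treatment))
  out <- out[order(out$fly_species, out$treatment_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Exact binomial choice test on pooled counts
#'
#' Tests whether the pooled sum of choices across replicates of one
#' treatment departs from random choice (success probability 1/2). The
#' two-sided p-value uses the minimum-likelihood convention: the sum of the
#' probabilities of all outcomes no more likely than the observed one
#' (symmetric at p = 1/2, so equal to doubling the smaller tail, capped at
#' 1). Replicated tests for one treatment are pooled, not averaged.
#'
#' @param k Pooled treatment-arm count (successes).
#' @param n Pooled choosing count (trials), `n >= 1`.
#' @param sidedness `"two.sided"` (default), `"greater"` (attraction only)
#'   or `"less"` (repulsion only).
#' @return A list with `k`, `n`, `p_value` and `direction` (`"attraction"`
#'   if `k > n/2`, `"repulsion"` if `k < n/2`, else `"none"`).
#' @export
binomial_choice_test <- function(k, n, sidedness = "two.sided") {
  stopifnot(length(k) == 1, length(n) == 1, n >= 1, k >= 0, k <= n)
  alt <- match.arg(sidedness, c("two.sided", "greater", "less"))
  p <- stats::binom.test(k, n, p = 0.5, alternative = alt)$p.value
  direction <- if (k > n / 2) "attraction" else if (k < n / 2) "repulsion" else "none"
  list(k = as.integer(k), n = as.integer(n), p_value = p,
       direction = direction, sidedness = alt)
}

deviance_result <- function(fit, null) {
  dd <- stats::deviance(null) - stats::deviance(fit)
  ddf <- stats::df.residual(null) - stats::df.residual(fit)
  list(delta_deviance = dd, delta_df = ddf,
       p_value = stats::pchisq(dd, ddf, lower.tail = FALSE))
}

#' Deviance test for a treatment effect on choice
#'
#' Fits a replicate-level binomial logistic regression of treatment-arm
#' choices with treatment as the sole fixed factor, against the
#' intercept-only null, and returns the likelihood-ratio (deviance) test of
#' the treatment term. The deviance reduction and df difference are
#' reported as positive magnitudes.
#'
#' @param reps Informative T-maze replicates of one fly species spanning at
#'   least two treatments.
#' @return A list with `delta_deviance`, `delta_df`, `p_value`, and
#'   `overdispersion` (residual deviance / residual df of the treatment
#'   model; a ratio above 2 triggers a warning but no model change).
#' @export
treatment_effect_test <- function(reps) {
  d <- ai_table(reps)
  if (length(unique(d$treatment_id)) < 2) {
    stop("treatment_effect_test: need at least 2 treatments", call. = FALSE)
  }
  pooled <- tapply(d$n_treatment_arm, d$treatment_id, sum) /
    tapply(d$n_choosing, d$treatment_id, sum)
  if (any(pooled %in% c(0, 1))) {
    warning("complete separation: some treatment has all-or-none pooled choices",
            call. = FALSE)
  }
  fit <- stats::glm(cbind(n_treatment_arm, n_control_arm) ~ treatment_id,
                    family = stats::binomial(), data = d)
  null <- stats::glm(cbind(n_treatment_arm, n_control_arm) ~ 1,
                     family = stats::binomial(), data = d)
  out <- deviance_result(fit, null)
  rdf <- stats::df.residual(fit)
  out$overdispersion <- if (rdf > 0) stats::deviance(fit) / rdf else NA_real_
  if (is.finite(out$overdispersion) && out$overdispersion > 2) {
    warning(sprintf(
      "between-replicate overdispersion detected (residual deviance/df = %.2f)",
      out$overdispersion), call. = FALSE)
  }
  out
}

#' Two-way ANOVA of AI on fly species and yeast treatment
#'
#' Fits per-replicate AI on fly species, yeast treatment and their
#' interaction, and reports type-II F tests (appropriate for the unbalanced
#' replicate numbers typical of these assays). Degenerate layouts with zero
#' between-group variation report F = 0, p = 1 for the affected terms.
#'
#' @param reps Informative T-maze replicates spanning at least two species
#'   and two treatments, with every species x treatment cell non-empty.
#' @return A data.frame with columns `term`, `df_num`, `df_den`, `F`, `p`
#'   for the species, treatment and interaction terms.
#' @export
species_by_yeast_anova <- function(reps) {
  d <- ai_table(reps)
  d$fly_species <- factor(d$fly_species)
  d$treatment_id <- factor(d$treatment_id)
  if (nlevels(d$fly_species) < 2 || nlevels(d$treatment_id) < 2) {
    stop("species_by_yeast_anova: need >= 2 levels of species and treatment",
         call. = FALSE)
  }
  cells <- table(d$fly_species, d$treatment_id)
  if (any(cells == 0)) {
    empty <- which(cells == 0, arr.ind = TRUE)
    combos <- paste(rownames(cells)[empty[, 1]],
                    colnames(cells)[empty[, 2]], sep = " x ")
    stop(sprintf("species_by_yeast_anova: empty design cell(s): %s",
                 paste(combos, collapse = ", ")), call. = FALSE)
  }
  ns <- nlevels(d$fly_species)
  nt <- nlevels(d$treatment_id)
  if (stats::var(d$ai) < .Machine$double.eps) {
    # constant response: no variation to apportion
    return(data.frame(
      term = c("fly_species", "yeast_treatment", "species:treatment"),
      df_num = c(ns - 1L, nt - 1L, (ns - 1L) * (nt - 1L)),
      df_den = nrow(d) - ns * nt,
      F = 0, p = 1, stringsAsFactors = FALSE))
  }
  fit <- stats::lm(ai ~ fly_species * treatment_id, data = d)
  aj <- suppressWarnings(car::Anova(fit, type = 2))
  terms <- c("fly_species", "treatment_id", "fly_species:treatment_id")
  df_den <- aj[["Df"]][rownames(aj) == "Residuals"]
  Fv <- aj[["F value"]][match(terms, rownames(aj))]
  pv <- aj[["Pr(>F)"]][match(terms, rownames(aj))]
  ssq <- aj[["Sum Sq"]][match(terms, rownames(aj))]
  degenerate <- !is.finite(Fv) & ssq < sqrt(.Machine$double.eps)
  Fv[degenerate] <- 0
  pv[degenerate] <- 1
  data.frame(
    term = c("fly_species", "yeast_treatment", "species:treatment"),
    df_num = aj[["Df"]][match(terms, rownames(aj))],
    df_den = df_den,
    F = Fv,
    p = pv,
    stringsAsFactors = FALSE)
}

#' Central-compartment retention comparison across fly species
#'
#' Computes the per-species proportion of flies that never left the central
#' compartment and tests whether retention differs between species with a
#' binomial logistic regression (stay vs leave on species) deviance test.
#' All replicates contribute, including no-choice runs.
#'
#' @param reps A validated T-maze table spanning at least two fly species.
#' @return A list with `proportions` (data.frame: `fly_species`, `n_centre`,
#'   `n_total`, `retention`) and `test` (a deviance test as in
#'   [treatment_effect_test()]).
#' @export
retention_test <- function(reps) {
  d <- validate_tmaze(reps)
  if (length(unique(d$fly_species)) < 2) {
    stop("retention_test: need at least 2 fly species", call. = FALSE)
  }
  d$n_left <- d$n_treatment_arm + d$n_control_arm
  agg <- do.call(rbind, lapply(split(d, d$fly_species), function(s) {
    data.frame(fly_species = s$fly_species[1],
               n_centre = sum(s$n_centre),
               n_total = sum(s$n_centre + s$n_left),
               stringsAsFactors = FALSE)
  }))
  agg$retention <- agg$n_centre / agg$n_total
  rownames(agg) <- NULL
  fit <- stats::glm(cbind(n_centre, n_left) ~ fly_species,
                    family = stats::binomial(), data = d)
  null <- stats::glm(cbind(n_centre, n_left) ~ 1,
                     family = stats::binomial(), data = d)
  list(proportions = agg, test = deviance_result(fit, null))
}
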