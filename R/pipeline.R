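## Orchestration of the full study-shaped analysis: laboratory screen,
## blend additivity study, field trial. Each runner takes validated (or
## validatable) tables, executes the stages in a fixed order, optionally
## writes CSV outputs, and returns everything as a list.

write_outputs <- function(out, out_dir, prefix = "") {
  if (is.null(out_dir)) return(invisible(NULL))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  for (nm in names(out)) {
    utils::write.csv(out[[nm]], file.path(out_dir,
                                          paste0(prefix, nm, ".csv")),
                     row.names = FALSE)
  }
  invisible(NULL)
}

#' Run the laboratory attraction analysis
#'
#' Executes the laboratory stages in order: omit no-choice replicates,
#' per-replicate AI, per-treatment mean +/- SE summaries with pooled exact
#' binomial choice tests, a per-species deviance test of the treatment
#' effect, the species x treatment two-way ANOVA (when both factors have
#' two or more levels), and the central-compartment retention comparison
#' (when there are two or more species). Control treatments (e.g.
#' juice-vs-juice) are flagged `bias_check` in the summary so their
#' binomial tests read as apparatus bias checks.
#'
#' @param tmaze A T-maze table (path or data.frame).
#' @param treatments Optional treatment table (path or data.frame) used to
#'   flag controls.
#' @param config A run configuration list (see [default_run_config()]).
#' @param out_dir Optional directory for CSV outputs (`ai_summary.csv`,
#'   `deviance_tests.csv`, `anova.csv`, `retention.csv`).
#' @param quiet Suppress progress messages.
#' @return A list with `ai_summary`, `deviance_tests`, `anova` (or `NULL`),
#'   `retention` (or `NULL`) and `dropped` (the omitted no-choice
#'   replicates).
#' @export
run_lab_analysis <- function(tmaze, treatments = NULL,
                             config = default_run_config(),
                             out_dir = NULL, quiet = FALSE) {
  config <- validate_run_config(config)
  if (is.character(tmaze)) tmaze <- read_tmaze_table(tmaze)
  tmaze <- validate_tmaze(tmaze)
  if (is.character(treatments)) treatments <- read_treatment_table(treatments)
  flt <- filter_informative(tmaze, quiet = quiet)
  kept <- flt$kept

  summary <- summarize_ai(kept)
  bt <- mapply(function(k, n) binomial_choice_test(k, n, config$sidedness),
               summary$pooled_k, summary$pooled_n, SIMPLIFY = FALSE)
  summary$p_binomial <- vapply(bt, `[[`, 1, "p_value")
  summary$direction <- vapply(bt, `[[`, "", "direction")
  summary$bias_check <- if (!is.null(treatments)) {
    summary$treatment_id %in% treatments$treatment_id[treatments$is_control]
  } else FALSE

  dev_tests <- do.call(rbind, lapply(split(kept, kept$fly_species),
                                     function(s) {
    if (length(unique(s$treatment_id)) < 2) return(NULL)
    r <- treatment_effect_test(s)
    data.frame(fly_species = s$fly_species[1],
               delta_deviance = r$delta_deviance, delta_df = r$delta_df,
               p_value = r$p_value, overdispersion = r$overdispersion,
               stringsAsFactors = FALSE)
  }))
  if (!is.null(dev_tests)) rownames(dev_tests) <- NULL

  anova_tab <- NULL
  if (length(unique(kept$fly_species)) >= 2 &&
      length(unique(kept$treatment_id)) >= 2) {
    anova_tab <- species_by_yeast_anova(kept)
  }
  retention <- NULL
  if (length(unique(tmaze$fly_species)) >= 2) {
    rt <- retention_test(tmaze)
    retention <- rt$proportions
    retention$delta_deviance <- rt$test$delta_deviance
    retention$delta_df <- rt$test$delta_df
    retention$p_value <- rt$test$p_value
  }
  out <- list(ai_summary = summary, deviance_tests = dev_tests,
              anova = anova_tab, retention = retention,
              dropped = flt$dropped)
  write_outputs(Filter(Negate(is.null),
                       out[c("ai_summary", "deviance_tests", "anova",
                             "retention")]), out_dir)
  out
}

#' Run the blend additivity analysis
#'
#' Extends [run_lab_analysis()] with the additivity stage: for every
#' treatment whose constituent list names two or more isolates, the
#' permutation additive null is built from the single-isolate per-replicate
#' AIs found in the same data set and the blend is tested by both the
#' permutation and the linear-model route. The most attractive blend is
#' also compared to the most attractive single constituent isolate by an
#' equal-variance t-test (or to `reference_single` when given). Per-blend
#' permutation seeds are derived from `config$rng_seed` in a fixed
#' (sorted) blend order, so reruns are bit-identical.
#'
#' @param tmaze T-maze table containing both single-isolate and blend
#'   replicates.
#' @param treatments Treatment table defining each blend's constituents.
#' @param config Run configuration (uses `n_permutations`, `rng_seed`,
#'   `alpha`, `sidedness`).
#' @param reference_single Single-isolate treatment id for the
#'   blend-vs-single t-test; default picks the constituent single with the
#'   highest mean AI.
#' @param out_dir Optional output directory (`additivity.csv`,
#'   `blend_vs_single.csv` in addition to the laboratory outputs).
#' @param quiet Suppress progress messages.
#' @return The [run_lab_analysis()] list plus `additivity` and
#'   `blend_vs_single`.
#' @export
run_combo_analysis <- function(tmaze, treatments,
                               config = default_run_config(),
                               reference_single = NULL,
                               out_dir = NULL, quiet = FALSE) {
  config <- validate_run_config(config)
  if (is.character(tmaze)) tmaze <- read_tmaze_table(tmaze)
  if (is.character(treatments)) treatments <- read_treatment_table(treatments)
  treatments <- validate_treatments(treatments)
  lab <- run_lab_analysis(tmaze, treatments, config, out_dir = NULL,
                          quiet = quiet)
  kept <- ai_table(filter_informative(tmaze, quiet = TRUE)$kept)

  is_blend <- vapply(treatments$constituents, length, 1L) >= 2 &
    !treatments$is_control
  blend_ids <- sort(treatments$treatment_id[is_blend])
  ais_of <- function(id) kept$ai[kept$treatment_id == id]
  addv <- NULL
  for (i in seq_along(blend_ids)) {
    b <- blend_ids[i]
    cons <- treatments$constituents[[match(b, treatments$treatment_id)]]
    cons_ais <- stats::setNames(lapply(cons, ais_of), cons)
    blend_ais <- ais_of(b)
    if (length(blend_ais) < 1) {
      stop(sprintf("blend '%s' has no informative replicates", b),
           call. = FALSE)
    }
    row <- additivity_test(cons_ais, blend_ais,
                           n_permutations = config$n_permutations,
                           seed = stage_seed(config$rng_seed, i),
                           alpha = config$alpha,
                           sidedness = config$sidedness)
    addv <- rbind(addv, cbind(data.frame(treatment_id = b,
                                         stringsAsFactors = FALSE), row))
  }

  bvs <- NULL
  if (length(blend_ids)) {
    blend_means <- vapply(blend_ids, function(b) mean(ais_of(b)), 1)
    best_blend <- blend_ids[which.max(blend_means)]
    cons <- treatments$constituents[[match(best_blend,
                                           treatments$treatment_id)]]
    single <- if (!is.null(reference_single)) reference_single else {
      cons[which.max(vapply(cons, function(s) mean(ais_of(s)), 1))]
    }
    tt <- blend_vs_single_ttest(ais_of(best_blend), ais_of(single))
    bvs <- data.frame(blend = best_blend, single = single,
                      t = tt$t, df = tt$df, p_value = tt$p_value,
                      stringsAsFactors = FALSE)
  }
  out <- c(lab, list(additivity = addv, blend_vs_single = bvs))
  write_outputs(Filter(Negate(is.null),
                       out[c("ai_summary", "deviance_tests", "anova",
                             "retention", "additivity",
                             "blend_vs_single")]), out_dir)
  out
}

field_stage <- function(traps, alpha, adjustment) {
  total <- traps$n_suzukii_female + traps$n_suzukii_male
  kw <- kruskal_wallis(total, traps$treatment_id)
  dunn <- dunn_posthoc(total, traps$treatment_id, alpha = alpha,
                       method = adjustment)
  glm_res <- fit_trap_glm(traps)
  ## consensus: a pair differs only when Dunn (adjusted) and the CI-overlap
  ## route agree
  emm <- glm_res$emm
  ci_sep <- function(a, b) {
    ia <- match(a, emm$treatment_id); ib <- match(b, emm$treatment_id)
    emm$lower95[ia] > emm$upper95[ib] || emm$lower95[ib] > emm$upper95[ia]
  }
  pairs <- dunn$pairs
  pairs$ci_separated <- mapply(ci_sep, pairs$treatment_a, pairs$treatment_b)
  pairs$consensus_significant <- pairs$p_adjusted < alpha &
    pairs$ci_separated
  list(
    kw = data.frame(H = kw$H, df = kw$df, p_value = kw$p_value),
    dunn = pairs,
    dunn_grouping = data.frame(treatment_id = names(dunn$grouping),
                               letters = unname(dunn$grouping),
                               stringsAsFactors = FALSE),
    glm_emm = cbind(emm,
                    delta_deviance = glm_res$deviance_test$delta_deviance,
                    delta_df = glm_res$deviance_test$delta_df,
                    p_deviance = glm_res$deviance_test$p_value,
                    overdispersion = glm_res$overdispersion))
}

#' Run the field-trap analysis
#'
#' Analyses per-trap *D. suzukii* totals with Kruskal-Wallis plus Dunn's
#' post-hoc (Benjamini-Hochberg adjusted, with compact letters), and the
#' sex-split counts with the blocked Poisson GLM and estimated-marginal-
#' mean 95% intervals (with overlap grouping numbers). When a positive
#' control lure is named, the whole analysis is repeated with it removed,
#' mirroring the yeast-only comparison. A pairwise difference is marked
#' consensus-significant only when the Dunn and CI-overlap routes agree.
#'
#' @param traps Trap table (path or data.frame).
#' @param treatments Optional treatment table (path or data.frame).
#' @param config Run configuration (uses `alpha`, `adjustment_method`).
#' @param positive_control Treatment id of the commercial lure to drop in
#'   the secondary analysis, or `NULL` for the full analysis only.
#' @param out_dir Optional output directory (`field_kw.csv`, `dunn.csv`,
#'   `glm_emm.csv`, plus `no_lure_*` copies for the secondary analysis).
#' @param quiet Suppress progress messages.
#' @return A list with `full` and (when applicable) `no_lure`, each holding
#'   `kw`, `dunn`, `dunn_grouping` and `glm_emm`.
#' @export
run_field_analysis <- function(traps, treatments = NULL,
                               config = default_run_config(),
                               positive_control = NULL,
                               out_dir = NULL, quiet = FALSE) {
  config <- validate_run_config(config)
  if (is.character(traps)) traps <- read_trap_table(traps)
  traps <- validate_traps(traps)
  if (is.character(treatments)) treatments <- read_treatment_table(treatments)
  full <- field_stage(traps, config$alpha, config$adjustment_method)
  out <- list(full = full)
  if (!is.null(positive_control)) {
    if (!positive_control %in% traps$treatment_id) {
      stop(sprintf("positive control '%s' not present in trap data",
                   positive_control), call. = FALSE)
    }
    sub <- traps[traps$treatment_id != positive_control, , drop = FALSE]
    out$no_lure <- field_stage(sub, config$alpha, config$adjustment_method)
  }
  if (!is.null(out_dir)) {
    write_outputs(list(field_kw = full$kw, dunn = full$dunn,
                       dunn_grouping = full$dunn_grouping,
                       glm_emm = full$glm_emm), out_dir)
    if (!is.null(out$no_lure)) {
      nl <- out$no_lure
      write_outputs(list(field_kw = nl$kw, dunn = nl$dunn,
                         dunn_grouping = nl$dunn_grouping,
                         glm_emm = nl$glm_emm), out_dir,
                    prefix = "no_lure_")
    }
  }
  out
}

#' Write a run manifest
#'
#' Records the configuration, input file digests, seed, output paths and
#' package version so a run can be reproduced byte-for-byte.
#'
#' @param path Output JSON path.
#' @param config Run configuration list.
#' @param inputs Named character vector of input file paths (digested with
#'   MD5 when they exist).
#' @param outputs Character vector of output paths.
#' @return `path`, invisibly.
#' @export
write_manifest <- function(path, config, inputs = character(),
                           outputs = character()) {
  digests <- if (length(inputs)) {
    existing <- inputs[file.exists(inputs)]
    as.list(tools::md5sum(existing))
  } else list()
  manifest <- list(
    package = "yeastlure",
    version = as.character(utils::packageVersion("yeastlure")),
    config = config,
    input_md5 = digests,
    outputs = as.list(outputs))
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}
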