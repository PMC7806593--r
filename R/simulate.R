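## Synthetic-data generators. They emulate the structure the statistics
## assume: cohorts of 60-80 flies per T-maze with high central-compartment
## retention, per-fly independent two-arm choices, blend attraction equal
## to the constituent mean plus an interaction offset, and blocked Poisson
## trap counts with lognormal block effects.

clamp_ai <- function(a) pmin(pmax(a, -1), 1)

#' Simulate T-maze replicates for a set of treatments
#'
#' Each fly independently stays in the central compartment with probability
#' `retention`; conditional on choosing, it picks the treatment arm with
#' probability `(1 + a) / 2` where `a` is the treatment's true Attraction
#' Index. So `E[n_centre] = n_flies * retention` and the conditional
#' expectation of the replicate AI is `a`.
#'
#' @param true_ai Named numeric vector of true AI values, one per
#'   treatment, each in \[-1, 1\].
#' @param n_replicates Integer, scalar or named per treatment.
#' @param retention Probability a fly never leaves the centre, in \[0, 1\].
#' @param n_flies Either a length-2 range (uniform integer draw per
#'   replicate, default `c(60, 80)`) or a single fixed cohort size.
#' @param fly_species Species token stamped on every replicate.
#' @param seed Optional integer seed (deterministic output when set).
#' @return A schema-valid T-maze table.
#' @export
simulate_tmaze <- function(true_ai, n_replicates = 6, retention = 0,
                           n_flies = c(60, 80),
                           fly_species = "D_suzukii", seed = NULL) {
  stopifnot(is.numeric(true_ai), !is.null(names(true_ai)),
            all(abs(true_ai) <= 1), retention >= 0, retention <= 1)
  if (!is.null(seed)) set.seed(seed)
  nrep <- if (length(n_replicates) == 1) {
    stats::setNames(rep(n_replicates, length(true_ai)), names(true_ai))
  } else n_replicates[names(true_ai)]
  rows <- lapply(names(true_ai), function(trt) {
    m <- nrep[[trt]]
    n <- if (length(n_flies) == 2) {
      sample(seq(n_flies[1], n_flies[2]), m, replace = TRUE)
    } else rep(n_flies, m)
    centre <- stats::rbinom(m, n, retention)
    choosing <- n - centre
    k <- stats::rbinom(m, choosing, (1 + true_ai[[trt]]) / 2)
    data.frame(
      replicate_id = sprintf("%s_%s_r%02d", fly_species, trt, seq_len(m)),
      fly_species = fly_species,
      treatment_id = trt,
      n_treatment_arm = k,
      n_control_arm = choosing - k,
      n_centre = centre,
      stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Simulate a blend study: single-yeast and blend replicates
#'
#' The true AI of every blend is the mean of its constituents' true AIs
#' plus the blend's interaction offset `delta`, clamped into \[-1, 1\]
#' (clamping is reported). Singles and blends are generated by
#' [simulate_tmaze()] from one seeded stream in a fixed order.
#'
#' @param single_ai Named true AIs of the single isolates.
#' @param blends Named list: blend treatment id -> character vector of
#'   constituent isolate ids (all present in `single_ai`).
#' @param delta Interaction offset(s): scalar or named per blend; 0 means
#'   additive.
#' @param n_replicates,retention,n_flies,fly_species As in
#'   [simulate_tmaze()]; `n_replicates` applies to singles and blends.
#' @param seed Optional integer seed.
#' @return A list with `singles` and `blends` (T-maze tables), `treatments`
#'   (treatment table covering both) and `true_blend_ai`.
#' @export
simulate_blend_study <- function(single_ai, blends, delta = 0,
                                 n_replicates = 6, retention = 0,
                                 n_flies = c(60, 80),
                                 fly_species = "D_suzukii", seed = NULL) {
  stopifnot(is.list(blends), !is.null(names(blends)))
  unknown <- setdiff(unique(unlist(blends)), names(single_ai))
  if (length(unknown)) {
    stop(sprintf("blend constituents without single-yeast true AI: %s",
                 paste(unknown, collapse = ", ")), call. = FALSE)
  }
  dl <- if (length(delta) == 1) {
    stats::setNames(rep(delta, length(blends)), names(blends))
  } else delta[names(blends)]
  raw <- vapply(names(blends), function(b) {
    mean(single_ai[blends[[b]]]) + dl[[b]]
  }, 1)
  blend_ai <- clamp_ai(raw)
  if (any(blend_ai != raw)) {
    message(sprintf("blend true AI clamped into [-1, 1] for: %s",
                    paste(names(blends)[blend_ai != raw], collapse = ", ")))
  }
  if (!is.null(seed)) set.seed(seed)
  singles <- simulate_tmaze(single_ai, n_replicates, retention, n_flies,
                            fly_species, seed = NULL)
  blends_df <- simulate_tmaze(blend_ai, n_replicates, retention, n_flies,
                              fly_species, seed = NULL)
  treatments <- data.frame(
    treatment_id = c(names(single_ai), names(blends)),
    label = c(names(single_ai), names(blends)),
    stringsAsFactors = FALSE)
  treatments$constituents <- c(as.list(names(single_ai)), unname(blends))
  treatments$is_control <- FALSE
  list(singles = singles, blends = blends_df,
       treatments = validate_treatments(treatments),
       true_blend_ai = blend_ai)
}

#' Simulate blocked field-trap counts
#'
#' Counts for trap (treatment t, block b, sex s) are Poisson with mean
#' `exp(log(mean_t * frac_s) + u_b)` where `u_b ~ Normal(0, sigma_block^2)`
#' is a shared block effect; `mean_t` is the expected per-trap total count
#' (both sexes) in a typical block and `frac_s` the sex split.
#' Other-Drosophila counts are Poisson with a common mean. The realised
#' block effects are attached as `attr(x, "block_effects")`.
#'
#' @param treatment_means Named expected per-trap total counts.
#' @param n_blocks Number of randomised blocks (each holds one trap per
#'   treatment).
#' @param sigma_block SD of the Normal block effect on the log scale.
#' @param female_fraction Expected fraction of *D. suzukii* that are
#'   female.
#' @param other_mean Poisson mean of non-suzukii Drosophila per trap.
#' @param site,session Tokens stamped on every record.
#' @param seed Optional integer seed.
#' @return A schema-valid trap table with one row per trap x block.
#' @export
simulate_field <- function(treatment_means, n_blocks = 6, sigma_block = 0.3,
                           female_fraction = 0.55, other_mean = 5,
                           site = "site1", session = "s1", seed = NULL) {
  stopifnot(is.numeric(treatment_means), !is.null(names(treatment_means)),
            all(treatment_means >= 0), n_blocks >= 1, sigma_block >= 0)
  if (!is.null(seed)) set.seed(seed)
  u <- stats::rnorm(n_blocks, 0, sigma_block)
  grid <- expand.grid(block = seq_len(n_blocks),
                      treatment_id = names(treatment_means),
                      stringsAsFactors = FALSE)
  mu_f <- treatment_means[grid$treatment_id] * female_fraction *
    exp(u[grid$block])
  mu_m <- treatment_means[grid$treatment_id] * (1 - female_fraction) *
    exp(u[grid$block])
  out <- data.frame(
    block_id = sprintf("b%02d", grid$block),
    site = site,
    session = session,
    treatment_id = grid$treatment_id,
    n_suzukii_female = stats::rpois(nrow(grid), mu_f),
    n_suzukii_male = stats::rpois(nrow(grid), mu_m),
    n_other_drosophila = stats::rpois(nrow(grid), other_mean),
    stringsAsFactors = FALSE)
  attr(out, "block_effects") <- u
  out
}

## ---- study-shaped presets -------------------------------------------------
## True parameter values emulate the magnitudes typical of yeast-volatile
## choice assays: a handful of clearly attractive isolates (AI 0.2-0.4),
## many near-indifferent ones, one repulsive combination for one species,
## retention between 40% and 70%, and field count means spanning 10-500.

single_isolates <- function() {
  c(M_pulcherrima = 0, P_pijperi = 0, H_uvarum_201 = 0, C_zemplinina = 0,
    T_delbrueckii = 0, S_cerevisiae = 0, H_occidentalis = 0, C_apicola = 0,
    P_kluyveri = 0, S_uvarum = 0, C_argentea = 0, L_thermotolerans = 0)
}

#' Preset: single-isolate laboratory screen across three fly species
#'
#' Twelve yeast isolates plus a sterile-juice control screened against
#' three Drosophila species, with species-specific attraction profiles and
#' central-compartment retention (0.69, 0.42, 0.62). Most treatments have 6
#' replicates; two isolates and the control have more, mirroring a screen
#' in which some isolates are retested.
#'
#' @param seed Integer seed.
#' @return A list with `tmaze` (T-maze table) and `treatments`.
#' @export
simulate_lab_single <- function(seed = 1) {
  base <- single_isolates()
  profiles <- list(
    D_suzukii = list(
      ai = replace(base, c("M_pulcherrima", "P_pijperi", "H_uvarum_201",
                           "C_zemplinina"), c(0.36, 0.28, 0.25, 0.06)),
      retention = 0.69),
    D_melanogaster = list(
      ai = replace(base, c("M_pulcherrima", "C_zemplinina", "P_pijperi",
                           "T_delbrueckii", "S_cerevisiae", "H_occidentalis",
                           "C_apicola", "P_kluyveri"),
                   c(0.29, 0.13, 0.12, 0.31, 0.25, 0.18, 0.18, 0.09)),
      retention = 0.42),
    D_simulans = list(
      ai = replace(base, c("H_occidentalis", "P_kluyveri", "M_pulcherrima"),
                   c(0.28, 0.12, -0.20)),
      retention = 0.62))
  set.seed(seed)
  tabs <- lapply(names(profiles), function(sp) {
    pr <- profiles[[sp]]
    ai <- c(pr$ai, juice_control = 0)
    nrep <- stats::setNames(rep(6L, length(ai)), names(ai))
    nrep[c("P_kluyveri", "C_zemplinina")] <- 18L
    nrep["juice_control"] <- 9L
    simulate_tmaze(ai, n_replicates = nrep, retention = pr$retention,
                   fly_species = sp, seed = NULL)
  })
  treatments <- data.frame(
    treatment_id = c(names(base), "juice_control"),
    label = c(gsub("_", " ", names(base)), "sterile juice vs juice"),
    stringsAsFactors = FALSE)
  treatments$constituents <- as.list(treatments$treatment_id)
  treatments$is_control <- treatments$treatment_id == "juice_control"
  list(tmaze = do.call(rbind, tabs),
       treatments = validate_treatments(treatments))
}

#' Preset: blend study in the laboratory
#'
#' Twelve single isolates plus ten blends of two to twelve constituents for
#' one fly species, at 6 replicates per treatment with retention 0.69. Two
#' blends (the five most attractive isolates together, and all twelve) are
#' generated below their additive expectation (offsets -0.25 and -0.20);
#' all other blends are additive.
#'
#' @param seed Integer seed.
#' @return The [simulate_blend_study()] list, whose `treatments` also cover
#'   the singles.
#' @export
simulate_lab_blend <- function(seed = 1) {
  ai <- replace(single_isolates(),
                c("M_pulcherrima", "P_pijperi", "H_uvarum_201",
                  "C_zemplinina", "C_argentea"),
                c(0.36, 0.28, 0.25, 0.06, 0.10))
  blends <- list(
    mp_hu = c("M_pulcherrima", "H_uvarum_201"),
    mp_pp = c("M_pulcherrima", "P_pijperi"),
    pp_hu = c("P_pijperi", "H_uvarum_201"),
    mp_pp_hu = c("M_pulcherrima", "P_pijperi", "H_uvarum_201"),
    hu_cz = c("H_uvarum_201", "C_zemplinina"),
    hu_sc = c("H_uvarum_201", "S_cerevisiae"),
    sc_ca = c("S_cerevisiae", "C_apicola"),
    sc_su_ca = c("S_cerevisiae", "S_uvarum", "C_apicola"),
    five_attractive = c("M_pulcherrima", "P_pijperi", "H_uvarum_201",
                        "C_zemplinina", "C_argentea"),
    all_twelve = names(single_isolates()))
  delta <- stats::setNames(rep(0, length(blends)), names(blends))
  delta[c("five_attractive", "all_twelve")] <- c(-0.25, -0.20)
  simulate_blend_study(ai, blends, delta = delta, n_replicates = 6,
                       retention = 0.69, seed = seed)
}

#' Preset: single-bait field trial
#'
#' Five yeast baits plus water (negative control), sterile juice and a
#' commercial lure (positive control) in six randomised blocks, with
#' per-trap expected totals spanning 10 (water) to 237 (best yeast) and 500
#' (lure), block SD 0.3 on the log scale.
#'
#' @param seed Integer seed.
#' @return A list with `traps` (trap table) and `treatments`.
#' @export
simulate_field_single <- function(seed = 1) {
  means <- c(water = 10, S_cerevisiae = 45, juice = 50, P_pijperi = 60,
             M_pulcherrima = 139, H_uvarum_11382 = 141, H_uvarum_201 = 237,
             gasser_lure = 500)
  traps <- simulate_field(means, n_blocks = 6, sigma_block = 0.3,
                          seed = seed)
  treatments <- data.frame(
    treatment_id = names(means),
    label = names(means),
    stringsAsFactors = FALSE)
  treatments$constituents <- as.list(names(means))
  treatments$is_control <- names(means) %in% c("water", "juice",
                                               "gasser_lure")
  list(traps = traps, treatments = validate_treatments(treatments))
}
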