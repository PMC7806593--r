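#' @keywords internal
"_PACKAGE"

## Fixed CSV schemas shared by all stages. Comma-separated, UTF-8, header
## row required; counts are fly tallies and must be non-negative integers.

TMAZE_COLS <- c("replicate_id", "fly_species", "treatment_id",
                "n_treatment_arm", "n_control_arm", "n_centre")
TRAP_COLS <- c("block_id", "site", "session", "treatment_id",
               "n_suzukii_female", "n_suzukii_male", "n_other_drosophila")
TREATMENT_COLS <- c("treatment_id", "label", "constituents", "is_control")

check_schema <- function(df, cols, what) {
  missing <- setdiff(cols, names(df))
  if (length(missing)) {
    stop(sprintf("%s table is missing required column(s): %s",
                 what, paste(missing, collapse = ", ")), call. = FALSE)
  }
  invisible(df)
}

## counts must be integer-valued and >= 0; offending rows reported by
## data row number (header excluded)
check_counts <- function(df, cols, what) {
  for (col in cols) {
    x <- df[[col]]
    if (!is.numeric(x)) {
      stop(sprintf("%s column '%s' must be numeric counts", what, col),
           call. = FALSE)
    }
    bad <- which(!is.finite(x) | x < 0 | x != trunc(x))
    if (length(bad)) {
      stop(sprintf(
        "%s column '%s': row(s) %s contain negative or non-integer counts",
        what, col, paste(bad, collapse = ", ")), call. = FALSE)
    }
    df[[col]] <- as.integer(x)
  }
  df
}

check_token <- function(df, cols, what) {
  for (col in cols) {
    x <- as.character(df[[col]])
    bad <- which(is.na(x) | !nzchar(trimws(x)))
    if (length(bad)) {
      stop(sprintf("%s column '%s': row(s) %s are empty",
                   what, col, paste(bad, collapse = ", ")), call. = FALSE)
    }
    df[[col]] <- x
  }
  df
}

#' Read a T-maze replicate table
#'
#' Reads and validates a CSV of T-maze runs, one row per replicate with the
#' counts of flies found in the treatment arm, the control arm and the
#' central compartment at the end of the run.
#'
#' @param path Path to a CSV file with columns `replicate_id`, `fly_species`,
#'   `treatment_id`, `n_treatment_arm`, `n_control_arm`, `n_centre`.
#' @return A `data.frame` with the schema columns; counts are integer-valued.
#' @export
read_tmaze_table <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  validate_tmaze(df)
}

#' Validate a T-maze replicate table
#'
#' @param df A data.frame with the T-maze schema columns.
#' @return The validated data.frame (invisibly the same object).
#' @export
validate_tmaze <- function(df) {
  check_schema(df, TMAZE_COLS, "tmaze")
  df <- check_token(df, c("replicate_id", "fly_species", "treatment_id"),
                    "tmaze")
  df <- check_counts(df, c("n_treatment_arm", "n_control_arm", "n_centre"),
                     "tmaze")
  df[TMAZE_COLS]
}

#' Write a T-maze replicate table
#'
#' @param df A validated T-maze table.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_tmaze_table <- function(df, path) {
  df <- validate_tmaze(df)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a field-trap table
#'
#' One row per trap x session: block, site, session, treatment and sex-split
#' *D. suzukii* counts plus other-Drosophila counts.
#'
#' @param path Path to a CSV file with columns `block_id`, `site`, `session`,
#'   `treatment_id`, `n_suzukii_female`, `n_suzukii_male`,
#'   `n_other_drosophila`.
#' @return A validated `data.frame`.
#' @export
read_trap_table <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  validate_traps(df)
}

#' Validate a field-trap table
#'
#' Enforces the count invariants and that each (block, treatment, session)
#' combination appears at most once.
#'
#' @param df A data.frame with the trap schema columns.
#' @return The validated data.frame.
#' @export
validate_traps <- function(df) {
  check_schema(df, TRAP_COLS, "traps")
  df <- check_token(df, c("block_id", "site", "session", "treatment_id"),
                    "traps")
  df <- check_counts(df, c("n_suzukii_female", "n_suzukii_male",
                           "n_other_drosophila"), "traps")
  key <- paste(df$block_id, df$treatment_id, df$session, sep = "\r")
  if (anyDuplicated(key)) {
    dup <- df[duplicated(key), , drop = FALSE]
    stop(sprintf(
      "traps table: duplicated (block, treatment, session) combination(s): %s",
      paste(unique(paste(dup$block_id, dup$treatment_id, dup$session,
                         sep = "/")), collapse = ", ")), call. = FALSE)
  }
  df[TRAP_COLS]
}

#' Write a field-trap table
#'
#' @param df A validated trap table.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_trap_table <- function(df, path) {
  df <- validate_traps(df)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a treatment table
#'
#' Treatments are single yeast isolates, equal-parts blends of isolates, or
#' control media (sterile juice, water, commercial lure) flagged
#' `is_control`. Constituents are stored semicolon-joined in the CSV and
#' returned as a list column.
#'
#' @param path Path to a CSV with columns `treatment_id`, `label`,
#'   `constituents` (semicolon-joined isolate ids), `is_control`.
#' @return A `data.frame` with a list column `constituents`.
#' @export
read_treatment_table <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  validate_treatments(df)
}

#' Validate a treatment table
#'
#' @param df A data.frame with the treatment schema columns; `constituents`
#'   may be a semicolon-joined character column or a list column.
#' @return The validated data.frame with `constituents` as a list column and
#'   `is_control` logical.
#' @export
validate_treatments <- function(df) {
  check_schema(df, TREATMENT_COLS, "treatments")
  df <- check_token(df, c("treatment_id", "label"), "treatments")
  if (anyDuplicated(df$treatment_id)) {
    stop("treatments table: duplicated treatment_id", call. = FALSE)
  }
  cons <- df$constituents
  if (!is.list(cons)) {
    cons <- strsplit(as.character(cons), ";", fixed = TRUE)
    cons <- lapply(cons, trimws)
  }
  ctl <- df$is_control
  if (!is.logical(ctl)) {
    ctl <- as.character(ctl)
    ctl <- tolower(trimws(ctl)) %in% c("true", "t", "1", "yes")
  }
  for (i in seq_len(nrow(df))) {
    ci <- cons[[i]]
    ci <- ci[nzchar(ci)]
    if (length(ci) < 1) {
      stop(sprintf("treatment '%s': constituents must be non-empty",
                   df$treatment_id[i]), call. = FALSE)
    }
    if (anyDuplicated(ci)) {
      stop(sprintf("treatment '%s': duplicated constituents",
                   df$treatment_id[i]), call. = FALSE)
    }
    if (ctl[i] && length(ci) != 1) {
      stop(sprintf(
        "control treatment '%s' must have a single pseudo-constituent",
        df$treatment_id[i]), call. = FALSE)
    }
    cons[[i]] <- ci
  }
  out <- df[c("treatment_id", "label")]
  out$constituents <- cons
  out$is_control <- ctl
  out
}

#' Write a treatment table
#'
#' @param df A validated treatment table (list-column `constituents`).
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_treatment_table <- function(df, path) {
  df <- validate_treatments(df)
  flat <- data.frame(
    treatment_id = df$treatment_id,
    label = df$label,
    constituents = vapply(df$constituents, paste, "", collapse = ";"),
    is_control = df$is_control,
    stringsAsFactors = FALSE)
  utils::write.csv(flat, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Split T-maze replicates into informative and no-choice sets
#'
#' Replicates in which no fly left the central compartment carry no choice
#' information and are omitted from all attraction analyses (they still
#' contribute to central-compartment retention).
#'
#' @param reps A validated T-maze table.
#' @param quiet Suppress the log message listing dropped replicate ids.
#' @return A list with data.frames `kept` (replicates with at least one
#'   choosing fly) and `dropped` (the no-choice replicates).
#' @export
filter_informative <- function(reps, quiet = FALSE) {
  reps <- validate_tmaze(reps)
  choosing <- reps$n_treatment_arm + reps$n_control_arm
  keep <- choosing >= 1
  dropped <- reps[!keep, , drop = FALSE]
  if (!quiet && nrow(dropped)) {
    message(sprintf("dropped %d no-choice replicate(s): %s", nrow(dropped),
                    paste(dropped$replicate_id, collapse = ", ")))
  }
  list(kept = reps[keep, , drop = FALSE], dropped = dropped)
}

#' Read a run configuration
#'
#' Reads a YAML run configuration and merges it over the defaults. Unknown
#' keys are retained (e.g. input/output paths used by the command-line
#' driver).
#'
#' @param path Path to a YAML file, or `NULL` for pure defaults.
#' @return A named list with at least `alpha`, `n_permutations`, `rng_seed`,
#'   `adjustment_method` and `sidedness`.
#' @export
read_run_config <- function(path = NULL) {
  cfg <- default_run_config()
  if (!is.null(path)) {
    user <- yaml::read_yaml(path)
    if (!is.null(user)) cfg <- utils::modifyList(cfg, user)
  }
  validate_run_config(cfg)
}

#' Default run configuration
#'
#' @return The default configuration list: `alpha = 0.05`,
#'   `n_permutations = 10000`, `rng_seed = 1`, `adjustment_method = "BH"`,
#'   `sidedness = "two.sided"`.
#' @export
default_run_config <- function() {
  list(alpha = 0.05, n_permutations = 10000L, rng_seed = 1L,
       adjustment_method = "BH", sidedness = "two.sided")
}

validate_run_config <- function(cfg) {
  if (!is.numeric(cfg$alpha) || cfg$alpha <= 0 || cfg$alpha >= 1) {
    stop("run config: alpha must lie strictly between 0 and 1", call. = FALSE)
  }
  if (!is.numeric(cfg$n_permutations) || cfg$n_permutations < 1) {
    stop("run config: n_permutations must be >= 1", call. = FALSE)
  }
  cfg$n_permutations <- as.integer(cfg$n_permutations)
  if (!cfg$sidedness %in% c("two.sided", "greater", "less")) {
    stop("run config: sidedness must be two.sided, greater or less",
         call. = FALSE)
  }
  cfg
}

## derive a stage seed from the master seed; keeps within 32-bit range
stage_seed <- function(seed, k) {
  as.integer((as.numeric(seed) + 7919 * as.numeric(k)) %% 2147483647)
}
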