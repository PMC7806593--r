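#' Kruskal-Wallis test across bait treatments
#'
#' Tie-corrected rank test of trap counts across treatments. An all-tied
#' data set (every count identical) reports H = 0, p = 1.
#'
#' @param x Numeric observations (e.g. trap counts).
#' @param g Grouping vector (treatment ids), same length as `x`.
#' @return A list with `H`, `df` and `p_value`.
#' @export
kruskal_wallis <- function(x, g) {
  if (!is.factor(g)) g <- factor(g)  # keep caller-declared empty levels
  if (nlevels(g) < 2) stop("kruskal_wallis: need >= 2 groups", call. = FALSE)
  if (any(table(g) == 0)) {
    stop(sprintf("kruskal_wallis: empty group(s): %s",
                 paste(levels(g)[table(g) == 0], collapse = ", ")),
         call. = FALSE)
  }
  if (length(x) < 2) stop("kruskal_wallis: need >= 2 observations",
                          call. = FALSE)
  if (length(unique(x)) == 1) {
    return(list(H = 0, df = nlevels(g) - 1L, p_value = 1))
  }
  kt <- stats::kruskal.test(x, g)
  list(H = unname(kt$statistic), df = unname(kt$parameter),
       p_value = kt$p.value)
}

## insert-and-absorb compact letter display over a significance matrix:
## start from one class of all levels, split every class containing a
## significantly different pair, then absorb classes that are subsets.
## Two levels share a symbol iff they are not significantly different.
compact_letters <- function(levs, sig, symbols = letters) {
  stopifnot(is.matrix(sig), nrow(sig) == length(levs))
  classes <- list(levs)
  for (i in seq_along(levs)) {
    for (j in seq_along(levs)) {
      if (j <= i || !sig[i, j]) next
      a <- levs[i]; b <- levs[j]
      hit <- vapply(classes, function(cl) a %in% cl && b %in% cl, logical(1))
      if (!any(hit)) next
      new <- list()
      for (k in seq_along(classes)) {
        cl <- classes[[k]]
        if (hit[k]) {
          new <- c(new, list(setdiff(cl, a)), list(setdiff(cl, b)))
        } else {
          new <- c(new, list(cl))
        }
      }
      # absorb: drop any class contained in another
      keep <- rep(TRUE, length(new))
      for (k in seq_along(new)) {
        for (l in seq_along(new)) {
          if (k != l && keep[l] &&
              all(new[[k]] %in% new[[l]]) &&
              (length(new[[k]]) < length(new[[l]]) || k > l)) {
            keep[k] <- FALSE
            break
          }
        }
      }
      classes <- new[keep]
    }
  }
  # order classes by first member for a stable display
  first <- vapply(classes, function(cl) min(match(cl, levs)), 1L)
  classes <- classes[order(first)]
  if (length(classes) > length(symbols)) {
    symbols <- as.vector(outer(symbols, c("", symbols), function(a, b)
      paste0(b, a)))
  }
  out <- vapply(levs, function(l) {
    paste(symbols[which(vapply(classes, function(cl) l %in% cl, logical(1)))],
          collapse = "")
  }, "")
  names(out) <- levs
  out
}

#' Dunn's post-hoc comparisons after Kruskal-Wallis
#'
#' Pairwise z statistics from mean-rank differences with the tie-corrected
#' variance
#' \deqn{z_{ij} = (\bar R_i - \bar R_j) / \sqrt{\left(\frac{N(N+1)}{12} -
#'   \frac{\sum (t^3 - t)}{12(N-1)}\right)\left(\frac{1}{n_i} +
#'   \frac{1}{n_j}\right)},}
#' p-values adjusted across all pairs (Benjamini-Hochberg by default), and
#' a compact letter display where two treatments share a letter iff their
#' adjusted p-value is at least `alpha`.
#'
#' @param x Numeric observations.
#' @param g Grouping vector, same length as `x`.
#' @param alpha Significance level for the letter display.
#' @param method Adjustment method for [stats::p.adjust()].
#' @return A list with `pairs` (data.frame `treatment_a`, `treatment_b`,
#'   `z`, `p_raw`, `p_adjusted`) and `grouping` (named letter strings).
#' @export
dunn_posthoc <- function(x, g, alpha = 0.05, method = "BH") {
  if (!is.factor(g)) g <- factor(g)
  kw_check <- kruskal_wallis(x, g)  # enforces preconditions
  N <- length(x)
  r <- rank(x)
  rbar <- tapply(r, g, mean)
  n <- tabulate(g)
  tie <- table(x)
  C <- sum(tie^3 - tie)
  v0 <- N * (N + 1) / 12 - C / (12 * (N - 1))
  levs <- levels(g)
  k <- length(levs)
  pairs <- utils::combn(k, 2)
  z <- apply(pairs, 2, function(ij) {
    i <- ij[1]; j <- ij[2]
    v <- v0 * (1 / n[i] + 1 / n[j])
    if (v <= 0) 0 else (rbar[i] - rbar[j]) / sqrt(v)
  })
  p_raw <- 2 * stats::pnorm(-abs(z))
  p_adj <- stats::p.adjust(p_raw, method = method)
  tab <- data.frame(treatment_a = levs[pairs[1, ]],
                    treatment_b = levs[pairs[2, ]],
                    z = z, p_raw = p_raw, p_adjusted = p_adj,
                    stringsAsFactors = FALSE)
  sig <- matrix(FALSE, k, k, dimnames = list(levs, levs))
  for (m in seq_len(ncol(pairs))) {
    s <- p_adj[m] < alpha
    sig[pairs[1, m], pairs[2, m]] <- s
    sig[pairs[2, m], pairs[1, m]] <- s
  }
  list(pairs = tab, grouping = compact_letters(levs, sig))
}

#' Poisson GLM of blocked trap counts with marginal means
#'
#' Analyses sex-split *D. suzukii* trap counts at the trap x sex grain with
#' a log-link Poisson model `count ~ treatment + sex + block`. Block enters
#' as a fixed factor by default (`random_block = TRUE` switches to a
#' random-intercept Poisson mixed model via lme4). Reports the deviance
#' (likelihood-ratio) test for dropping treatment, per-treatment estimated
#' marginal means on the count scale with 95% Wald intervals (averaged over
#' sex and block on the link scale before back-transforming), an overlap
#' grouping of the intervals (numbers; sharing a number means overlapping
#' CIs), and the Pearson overdispersion ratio.
#'
#' @param records A validated trap table ([read_trap_table()] schema).
#' @param random_block Use a random block intercept instead of fixed block
#'   effects.
#' @param alpha Kept at 0.05-style 95% intervals; currently informational.
#' @return A list with `emm` (data.frame `treatment_id`, `mean`, `lower95`,
#'   `upper95`, `group`), `deviance_test`, `overdispersion` and the fitted
#'   model as `fit`.
#' @export
fit_trap_glm <- function(records, random_block = FALSE, alpha = 0.05) {
  records <- validate_traps(records)
  long <- rbind(
    data.frame(count = records$n_suzukii_female, sex = "female",
               treatment_id = records$treatment_id,
               block_id = records$block_id, stringsAsFactors = FALSE),
    data.frame(count = records$n_suzukii_male, sex = "male",
               treatment_id = records$treatment_id,
               block_id = records$block_id, stringsAsFactors = FALSE))
  long$treatment_id <- factor(long$treatment_id)
  long$sex <- factor(long$sex)
  long$block_id <- factor(long$block_id)
  blocks_per_trt <- tapply(long$block_id, long$treatment_id,
                           function(b) length(unique(b)))
  if (any(blocks_per_trt < 2)) {
    stop(sprintf("fit_trap_glm: treatment(s) present in < 2 blocks: %s",
                 paste(names(blocks_per_trt)[blocks_per_trt < 2],
                       collapse = ", ")), call. = FALSE)
  }
  zero_trt <- names(which(tapply(long$count, long$treatment_id, sum) == 0))
  if (length(zero_trt)) {
    warning(sprintf("all-zero counts for treatment(s): %s; lower CI bound set to 0",
                    paste(zero_trt, collapse = ", ")), call. = FALSE)
  }
  one_trt <- nlevels(long$treatment_id) == 1
  if (random_block) {
    fit <- lme4::glmer(count ~ treatment_id + sex + (1 | block_id),
                       family = stats::poisson(), data = long)
    null <- lme4::glmer(count ~ sex + (1 | block_id),
                        family = stats::poisson(), data = long)
    lrt <- stats::anova(null, fit)
    dev_test <- list(delta_deviance = lrt$Chisq[2],
                     delta_df = lrt$Df[2],
                     p_value = lrt$`Pr(>Chisq)`[2])
    prs <- stats::residuals(fit, type = "pearson")
    rdf <- nrow(long) - length(lme4::fixef(fit)) - 1
  } else {
    rhs <- if (one_trt) "sex + block_id" else "treatment_id + sex + block_id"
    fit <- stats::glm(stats::reformulate(rhs, "count"),
                      family = stats::poisson(), data = long)
    if (one_trt) {
      dev_test <- list(delta_deviance = NA_real_, delta_df = NA_integer_,
                       p_value = NA_real_)
    } else {
      null <- stats::glm(count ~ sex + block_id,
                         family = stats::poisson(), data = long)
      dev_test <- deviance_result(fit, null)
    }
    prs <- stats::residuals(fit, type = "pearson")
    rdf <- stats::df.residual(fit)
  }
  overdispersion <- sum(prs^2) / rdf
  em <- if (one_trt && !random_block) {
    emmeans::emmeans(fit, ~1, type = "response")
  } else {
    emmeans::emmeans(fit, ~treatment_id, type = "response")
  }
  es <- as.data.frame(summary(em))
  mean_col <- intersect(c("rate", "response", "emmean"), names(es))[1]
  lcl <- intersect(c("asymp.LCL", "lower.CL"), names(es))[1]
  ucl <- intersect(c("asymp.UCL", "upper.CL"), names(es))[1]
  trt_ids <- if (one_trt) levels(long$treatment_id) else
    as.character(es$treatment_id)
  emm <- data.frame(treatment_id = trt_ids,
                    mean = es[[mean_col]],
                    lower95 = es[[lcl]], upper95 = es[[ucl]],
                    stringsAsFactors = FALSE)
  if (length(zero_trt)) {
    emm$lower95[emm$treatment_id %in% zero_trt] <- 0
  }
  k <- nrow(emm)
  sig <- matrix(FALSE, k, k, dimnames = list(emm$treatment_id,
                                             emm$treatment_id))
  for (i in seq_len(k)) for (j in seq_len(k)) {
    if (i < j) {
      disjoint <- emm$lower95[i] > emm$upper95[j] ||
        emm$lower95[j] > emm$upper95[i]
      sig[i, j] <- sig[j, i] <- disjoint
    }
  }
  emm$group <- unname(compact_letters(emm$treatment_id, sig,
                                      symbols = as.character(1:50)))
  list(emm = emm, deviance_test = dev_test,
       overdispersion = overdispersion, fit = fit)
}
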