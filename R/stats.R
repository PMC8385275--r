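# Group comparisons and association analyses for weekly SAM vectors:
# one-way ANOVA, per-group Gaussian regressions of self-report outcomes on
# ambiance measures, and Benjamini-Hochberg FDR control across the grid.

SAM_MEASURES <- c("AL0", "AL1", "AL2", "AL3", "entropy")
SELF_REPORTS <- c("PHQ9", "GAD7", "extraversion", "agreeableness",
                  "conscientiousness", "neuroticism", "openness",
                  "n_contacts")

#' One-way analysis of variance
#'
#' Classical between/within sum-of-squares F test of equal group means,
#' fitted through `stats::lm`/`stats::anova`.
#'
#' @param values Numeric observations.
#' @param groups Group labels, one per observation (>= 2 groups, each with
#'   >= 2 observations).
#' @return List with `F`, `p`, `df_between`, `df_within`.
#' @export
one_way_anova <- function(values, groups) {
  groups <- factor(groups)
  if (nlevels(groups) < 2) stop("need at least 2 groups", call. = FALSE)
  if (any(table(groups) < 2)) {
    stop("every group needs at least 2 observations", call. = FALSE)
  }
  fit <- stats::anova(stats::lm(values ~ groups))
  list(F = fit$`F value`[1], p = fit$`Pr(>F)`[1],
       df_between = fit$Df[1], df_within = fit$Df[2])
}

#' Association between one ambiance measure and one outcome
#'
#' Gaussian-family GLM with identity link of the outcome on the ambiance
#' measure, fitted within one participant group — one cell of the
#' association grid. Returns the slope, its t statistic and p-value.
#'
#' @param x Ambiance-measure values (predictor).
#' @param y Outcome values (response).
#' @param measure,outcome,group Labels carried into the result.
#' @return Tibble row with `measure`, `outcome`, `group`, `coefficient`,
#'   `t`, `p`, `n`.
#' @export
glm_assoc <- function(x, y, measure = "x", outcome = "y", group = "all") {
  keep <- is.finite(x) & is.finite(y)
  x <- x[keep]; y <- y[keep]
  if (length(x) < 3) stop("need at least 3 paired observations", call. = FALSE)
  if (stats::sd(x) == 0) {
    stop("constant predictor: the ambiance measure does not vary in group '",
         group, "'", call. = FALSE)
  }
  fit <- stats::glm(y ~ x, family = stats::gaussian())
  co <- summary(fit)$coefficients
  tibble::tibble(measure = measure, outcome = outcome, group = group,
                 coefficient = co["x", "Estimate"], t = co["x", "t value"],
                 p = co["x", "Pr(>|t|)"], n = length(x))
}

#' Benjamini-Hochberg step-up FDR adjustment
#'
#' Adjusted p-values follow the step-up rule
#' `p_adj_(i) = min_{j >= i} (m / j) * p_(j)` capped at 1; a hypothesis is
#' rejected when its adjusted p-value falls below `q`. Tiers at
#' q = 0.1 / 0.05 / 0.01 are reported as significance stars.
#'
#' @param p Raw p-values in `[0, 1]`.
#' @param q FDR level for the rejection flags (default 0.05).
#' @return List with `adjusted`, `reject`, and `stars` (`*` FDR < 0.1,
#'   `**` FDR < 0.05, `***` FDR < 0.01).
#' @export
bh_fdr <- function(p, q = 0.05) {
  if (any(!is.finite(p)) || any(p < 0 | p > 1)) {
    stop("p-values must lie in [0, 1]", call. = FALSE)
  }
  adjusted <- stats::p.adjust(p, method = "BH")
  stars <- ifelse(adjusted < 0.01, "***",
           ifelse(adjusted < 0.05, "**",
           ifelse(adjusted < 0.1, "*", "")))
  list(adjusted = adjusted, reject = adjusted < q, stars = stars)
}

rdirichlet <- function(n, alpha) {
  g <- matrix(stats::rgamma(n * length(alpha), shape = alpha), n,
              length(alpha), byrow = TRUE)
  g / rowSums(g)
}

default_sam_means <- function() {
  rbind(control    = c(35, 25, 30, 10),
        depression = c(55, 25, 15, 5),
        psychosis  = c(55, 20, 15, 10))
}

default_outcome_means <- function() {
  m <- rbind(
    control    = c(3.0,  4.0, 13, 15, 15, 9, 14, 5),
    depression = c(19.7, 14.9, 10, 15, 11, 15, 14, 5),
    psychosis  = c(15.2, 16.3, 12, 12, 11, 13, 14, 5))
  colnames(m) <- SELF_REPORTS
  m
}

#' Generate a synthetic participant cohort
#'
#' Simulates weekly SAM vectors and self-report scores for a three-group
#' cohort. Per-participant level fractions are drawn from a Dirichlet
#' distribution on the 4-simplex around the group's mean profile
#' (`concentration` controls spread); entropy is computed from the sampled
#' fractions; outcomes are group baselines plus linear functions of the
#' SAM measures (slopes in `effects`, per percent / per nat) plus Gaussian
#' noise.
#'
#' @param group_sizes Named integer vector; default the pilot-study sizes
#'   `c(control = 13, depression = 11, psychosis = 8)`.
#' @param sam_means Matrix (groups x 4) of mean level percentages, rows
#'   summing to 100.
#' @param outcome_means Matrix (groups x 8) of outcome baselines.
#' @param effects Matrix (8 outcomes x 5 measures) of slopes; default all
#'   zero (outcomes independent of ambiance).
#' @param noise_sd Outcome noise standard deviation(s), scalar or length 8.
#' @param concentration Dirichlet concentration (sum of alphas).
#' @param seed Integer seed.
#' @return Tibble with `participant`, `group`, `AL0`..`AL3`, `entropy`,
#'   and the eight self-report columns; generating parameters attached as
#'   the `"params"` attribute.
#' @export
generate_cohort <- function(group_sizes = c(control = 13, depression = 11,
                                            psychosis = 8),
                            sam_means = default_sam_means(),
                            outcome_means = default_outcome_means(),
                            effects = matrix(0, 8, 5,
                                             dimnames = list(SELF_REPORTS,
                                                             SAM_MEASURES)),
                            noise_sd = 3, concentration = 30, seed = 1) {
  sam_means <- as.matrix(sam_means)
  if (any(sam_means < 0) || any(abs(rowSums(sam_means) - 100) > 1e-6)) {
    stop("each row of sam_means must be non-negative and sum to 100",
         call. = FALSE)
  }
  if (length(noise_sd) == 1) noise_sd <- rep(noise_sd, length(SELF_REPORTS))
  groups <- names(group_sizes) %||% rownames(sam_means)
  with_seed(seed, {
    rows <- lapply(seq_along(group_sizes), function(gi) {
      n <- group_sizes[gi]
      fr <- 100 * rdirichlet(n, concentration * sam_means[gi, ] / 100)
      ent <- apply(fr, 1, sam_entropy)
      sam <- cbind(fr, ent)
      colnames(sam) <- SAM_MEASURES
      out <- sapply(seq_along(SELF_REPORTS), function(oi) {
        outcome_means[gi, oi] + drop(sam %*% effects[oi, ]) +
          stats::rnorm(n, sd = noise_sd[oi])
      })
      if (n == 1) out <- matrix(out, nrow = 1)
      colnames(out) <- SELF_REPORTS
      out[, "n_contacts"] <- pmin(10, pmax(0, round(out[, "n_contacts"])))
      tibble::tibble(group = groups[gi], !!!as.data.frame(sam),
                     !!!as.data.frame(out))
    })
    cohort <- dplyr::bind_rows(rows)
    cohort <- tibble::add_column(cohort,
                                 participant = sprintf("P%02d",
                                                       seq_len(nrow(cohort))),
                                 .before = 1)
    attr(cohort, "params") <- list(group_sizes = group_sizes,
                                   sam_means = sam_means,
                                   outcome_means = outcome_means,
                                   effects = effects, noise_sd = noise_sd,
                                   concentration = concentration, seed = seed)
    cohort
  })
}

#' Group-comparison ANOVA table over the SAM measures
#'
#' For each ambiance measure, reports the overall three-group ANOVA and
#' pairwise two-group ANOVAs of the reference group against every other
#' group (the reporting style used for group contrasts of time-budget
#' measures).
#'
#' @param cohort A cohort tibble (see [generate_cohort()]) with `group`
#'   and the SAM measure columns.
#' @param measures Measure columns to test.
#' @param reference Reference group label for pairwise contrasts.
#' @return Tibble with `measure`, `comparison`, `F`, `p`, `df_between`,
#'   `df_within`.
#' @export
anova_table <- function(cohort, measures = SAM_MEASURES,
                        reference = "control") {
  groups <- unique(cohort$group)
  others <- setdiff(groups, reference)
  rows <- list()
  for (m in measures) {
    ov <- one_way_anova(cohort[[m]], cohort$group)
    rows[[length(rows) + 1L]] <- tibble::tibble(
      measure = m, comparison = "overall", F = ov$F, p = ov$p,
      df_between = ov$df_between, df_within = ov$df_within)
    for (g in others) {
      sub <- cohort[cohort$group %in% c(reference, g), ]
      pw <- one_way_anova(sub[[m]], sub$group)
      rows[[length(rows) + 1L]] <- tibble::tibble(
        measure = m, comparison = paste(reference, "vs", g), F = pw$F,
        p = pw$p, df_between = pw$df_between, df_within = pw$df_within)
    }
  }
  dplyr::bind_rows(rows)
}

#' Per-group association grid with FDR control
#'
#' Regresses every self-report outcome on every ambiance measure within
#' each group and adjusts the p-values with the Benjamini-Hochberg
#' procedure, by default across the full measures x outcomes x groups
#' family.
#'
#' @param cohort Cohort tibble with `group`, SAM measures and outcomes.
#' @param measures,outcomes Column sets forming the grid.
#' @param fdr_family `"grid"` (one family for the full grid, default) or
#'   `"group"` (adjust within each group separately).
#' @param q FDR level for rejection flags.
#' @return Tibble, one row per measure x outcome x group, with
#'   `coefficient`, `t`, `p`, `p_adj`, `reject`, `stars`.
#' @export
association_grid <- function(cohort, measures = SAM_MEASURES,
                             outcomes = SELF_REPORTS,
                             fdr_family = c("grid", "group"), q = 0.05) {
  fdr_family <- match.arg(fdr_family)
  rows <- list()
  for (g in unique(cohort$group)) {
    sub <- cohort[cohort$group == g, ]
    for (m in measures) {
      for (o in outcomes) {
        rows[[length(rows) + 1L]] <-
          glm_assoc(sub[[m]], sub[[o]], measure = m, outcome = o, group = g)
      }
    }
  }
  grid <- dplyr::bind_rows(rows)
  if (fdr_family == "grid") {
    adj <- bh_fdr(grid$p, q = q)
    grid$p_adj <- adj$adjusted
    grid$reject <- adj$reject
    grid$stars <- adj$stars
  } else {
    grid <- grid |>
      dplyr::group_by(.data$group) |>
      dplyr::group_modify(function(d, key) {
        adj <- bh_fdr(d$p, q = q)
        d$p_adj <- adj$adjusted
        d$reject <- adj$reject
        d$stars <- adj$stars
        d
      }) |>
      dplyr::ungroup()
  }
  grid
}
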