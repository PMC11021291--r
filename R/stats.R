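#' One-sample location test against zero with a normality gate
#'
#' Tests whether per-participant preference indices differ from zero. A
#' Shapiro-Wilk test at alpha = .05 gates the choice: a one-sample
#' t-test when normality is not rejected, otherwise a Wilcoxon
#' signed-rank test (exact for n <= 25 when the data permit). Two-sided
#' p values. A constant sample is flagged degenerate rather than tested.
#'
#' @param values Numeric vector (one value per participant), `n >= 3`.
#' @param mu Null location (0).
#' @return A one-row tibble: `test`, `statistic`, `p`, `n`,
#'   `normality_p`, `degenerate`.
#' @export
#' @examples
#' location_test(c(0.04, 0.09, 0.05, 0.02, 0.08))
location_test <- function(values, mu = 0) {
  n <- length(values)
  if (n < 3) {
    abort("Location test needs at least 3 values.",
          class = "stmcit_data_error")
  }
  if (sd(values) == 0) {
    return(tibble(test = NA_character_, statistic = NA_real_, p = NA_real_,
                  n = n, normality_p = NA_real_, degenerate = TRUE))
  }
  norm_p <- shapiro.test(values)$p.value
  if (norm_p >= 0.05) {
    ht <- t.test(values, mu = mu)
    tibble(test = "t", statistic = unname(ht$statistic), p = ht$p.value,
           n = n, normality_p = norm_p, degenerate = FALSE)
  } else {
    exact <- n <= 25 && !any(duplicated(abs(values - mu))) &&
      !any(values == mu)
    ht <- suppressWarnings(wilcox.test(values, mu = mu, exact = exact))
    tibble(test = "wilcoxon", statistic = unname(ht$statistic),
           p = ht$p.value, n = n, normality_p = norm_p, degenerate = FALSE)
  }
}

#' Mixed ANOVA on preference indices
#'
#' Standard sums-of-squares mixed ANOVA with one between-subjects factor
#' (`group`) and one within-subjects factor (`phase`), as applied to one
#' preference index per participant and phase. Returns F, degrees of
#' freedom, p, and partial eta squared (SS_effect / (SS_effect +
#' SS_error of the effect's stratum)) for Group, Phase and Group x
#' Phase. The design must be balanced (equal group sizes, complete
#' phases).
#'
#' @param data A data frame with columns `participant_id`, `group`,
#'   `phase` and the response.
#' @param response Name of the response column (default `"index"`).
#' @return A tibble of class `cit_anova` with one row per effect:
#'   `effect`, `df`, `df_error`, `F`, `p`, `pes`; the fitted `aov`
#'   object and the data are kept as attributes for post hoc tests.
#' @export
mixed_anova <- function(data, response = "index") {
  needed <- c("participant_id", "group", "phase", response)
  missing <- setdiff(needed, names(data))
  if (length(missing) > 0) {
    abort(paste0("Missing column(s): ", paste(missing, collapse = ", ")),
          class = "stmcit_data_error")
  }
  model_df <- data.frame(
    # participants are nested within groups; compose the id so that the
    # same label reused across groups stays a distinct subject
    participant_id = factor(paste(data$group, data$participant_id,
                                  sep = ":")),
    group = factor(data$group),
    phase = factor(data$phase),
    y = data[[response]]
  )
  cell_n <- count(model_df, .data$group, .data$phase)
  if (length(unique(cell_n$n)) != 1) {
    abort("Unbalanced design: equal group sizes and complete phases required.",
          class = "stmcit_design_error")
  }
  if (nlevels(model_df$phase) < 2) {
    abort("At least two phase levels required.",
          class = "stmcit_design_error")
  }
  # do.call embeds the data in the recorded call so downstream
  # emmeans::recover_data can re-evaluate it in any environment
  fit <- do.call(stats::aov, list(
    y ~ group * phase + Error(participant_id), data = model_df
  ))
  strata <- summary(fit)
  between <- as.data.frame(strata[["Error: participant_id"]][[1]])
  within <- as.data.frame(strata[["Error: Within"]][[1]])
  rn_b <- trimws(rownames(between))
  rn_w <- trimws(rownames(within))
  ss_b_err <- between[rn_b == "Residuals", "Sum Sq"]
  ss_w_err <- within[rn_w == "Residuals", "Sum Sq"]
  pick <- function(tab, rn, term, ss_err) {
    row <- tab[rn == term, ]
    tibble(
      effect = term,
      df = row$Df,
      df_error = tab[rn == "Residuals", "Df"],
      `F` = row$`F value`,
      p = row$`Pr(>F)`,
      pes = row$`Sum Sq` / (row$`Sum Sq` + ss_err)
    )
  }
  out <- bind_rows(
    pick(between, rn_b, "group", ss_b_err),
    pick(within, rn_w, "phase", ss_w_err),
    pick(within, rn_w, "group:phase", ss_w_err)
  )
  out$effect <- c("Group", "Phase", "Group:Phase")
  structure(out, class = c("cit_anova", class(out)),
            fit = fit, model_data = model_df)
}

#' Tukey post hoc comparisons of the group-by-phase cell means
#'
#' All pairwise comparisons among the group x phase cells (15
#' comparisons for 3 groups x 2 phases), with p values adjusted by the
#' studentized-range (Tukey) method for the full family of pairwise
#' estimates. Built on estimated marginal means from the fitted mixed
#' ANOVA.
#'
#' @param anova_result A [mixed_anova()] result.
#' @return A tibble: `contrast`, `estimate`, `se`, `df`, `t`, `p_adj`.
#' @export
tukey_posthoc <- function(anova_result) {
  fit <- attr(anova_result, "fit")
  mdata <- as.data.frame(attr(anova_result, "model_data"))
  if (is.null(fit)) {
    abort("Expected a mixed_anova() result.", class = "stmcit_design_error")
  }
  if (nlevels(mdata$group) * nlevels(mdata$phase) < 2) {
    abort("Post hoc tests need at least 2 cells.",
          class = "stmcit_design_error")
  }
  emm <- suppressMessages(
    emmeans::emmeans(fit, ~ group * phase, data = mdata)
  )
  prs <- summary(emmeans::contrast(emm, method = "pairwise",
                                   adjust = "tukey"))
  tibble(
    contrast = as.character(prs$contrast),
    estimate = prs$estimate,
    se = prs$SE,
    df = prs$df,
    t = prs$t.ratio,
    p_adj = prs$p.value
  )
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a mixed ANOVA result
#'
#' @param x A `cit_anova` object.
#' @param ... Unused.
#' @return The effect table as a plain tibble.
#' @export
tidy.cit_anova <- function(x, ...) {
  as_tibble(unclass(x)[c("effect", "df", "df_error", "F", "p", "pes")])
}

#' One-line summary of a mixed ANOVA result
#'
#' @param x A `cit_anova` object.
#' @param ... Unused.
#' @return A one-row tibble with the interaction F, p and partial eta
#'   squared and the number of effects.
#' @export
glance.cit_anova <- function(x, ...) {
  inter <- filter(as_tibble(unclass(x)[c("effect", "F", "p", "pes")]),
                  .data$effect == "Group:Phase")
  tibble(n_effects = nrow(x), interaction_F = inter$`F`,
         interaction_p = inter$p, interaction_pes = inter$pes)
}
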