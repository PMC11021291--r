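test_that("location test: gate, closed-form t, degenerate samples", {
  res <- location_test(c(1, 2, 3, 4, 5))
  expect_equal(res$test, "t")
  expect_equal(res$statistic, mean(1:5) / (sd(1:5) / sqrt(5)))
  # all values identical: flagged, not tested
  z <- location_test(rep(0, 10))
  expect_true(z$degenerate)
  expect_true(is.na(z$p))
  # strongly skewed sample fails the normality gate and uses Wilcoxon
  skewed <- c(rep(0.01, 12), 2, 4, 8)
  res2 <- location_test(skewed)
  expect_equal(res2$test, "wilcoxon")
  expect_lt(res2$normality_p, 0.05)
  expect_error(location_test(c(1, 2)), class = "stmcit_data_error")
})

test_that("location test detects the reported phase-1 effect size reliably", {
  # n = 15 draws from Normal(0.06, 0.05): p < .01 in >= 80% of repetitions
  hits <- vapply(1:20, function(i) {
    vals <- withr::with_seed(3000 + i, rnorm(15, 0.06, 0.05))
    location_test(vals)$p < 0.01
  }, logical(1))
  expect_gte(mean(hits), 0.8)
})

test_that("type-I error stays near 5% under the unbiased generator", {
  # participant-level phase-1 indices from the chain core with no bias:
  # 200 cohorts of 15 participants x 32 trials
  cfg <- gaze_config(theta_orient = 0, theta_avoid = 0)
  n_cohorts <- 200
  per_part <- 32
  n_trials <- n_cohorts * 15 * per_part
  d <- withr::with_seed(42, {
    bias <- matrix(FALSE, n_trials, 4)
    bias[, 1] <- TRUE
    ev <- stmcit:::sim_chain(bias, 1, 1, cfg, screen_geometry())
    fx <- ev[ev$event == "fixation" & ev$state <= 4, ]
    ov <- stmcit:::interval_overlap(fx$onset, fx$offset, 200, 1000)
    fam <- rowsum(ov * (fx$state == 1), fx$trial)
    unk <- rowsum(ov * (fx$state != 1), fx$trial) / 3
    (fam - unk) / 800
  })
  part <- colMeans(matrix(d, nrow = per_part))
  cohort <- matrix(part, nrow = 15)
  rejections <- apply(cohort, 2, function(v) location_test(v)$p < 0.05)
  expect_gte(mean(rejections), 0.02)
  expect_lte(mean(rejections), 0.08)
})

# Hand-decomposable balanced 2 (group) x 2 (phase) x 2 (participant)
# fixture: textbook sums-of-squares arithmetic done independently here.
anova_fixture <- function() {
  tidyr::crossing(group = c("g1", "g2"), pid = c("a", "b"),
                  phase = c(1, 2)) |>
    dplyr::mutate(
      participant_id = paste(group, pid),
      index = c(1, 2, 3, 5, 2, 4, 6, 9)
    )
}

hand_anova <- function(d) {
  # cell/marginal means
  gm <- mean(d$index)
  subj <- tapply(d$index, d$participant_id, mean)
  grp <- tapply(d$index, d$group, mean)
  ph <- tapply(d$index, d$phase, mean)
  cell <- tapply(d$index, list(d$group, d$phase), mean)
  n_subj <- 2; n_grp <- 2; n_ph <- 2
  ss_group <- n_subj * n_ph * sum((grp - gm)^2)
  ss_subj <- n_ph * sum((subj - gm)^2)
  ss_between_err <- ss_subj - ss_group
  ss_phase <- n_grp * n_subj * sum((ph - gm)^2)
  inter <- outer(grp - gm, ph - gm, "+") + gm
  ss_inter <- n_subj * sum((cell - inter)^2)
  ss_total <- sum((d$index - gm)^2)
  ss_within_err <- ss_total - ss_subj - ss_phase - ss_inter
  list(
    F_group = (ss_group / 1) / (ss_between_err / 2),
    F_phase = (ss_phase / 1) / (ss_within_err / 2),
    F_inter = (ss_inter / 1) / (ss_within_err / 2),
    pes_group = ss_group / (ss_group + ss_between_err),
    pes_phase = ss_phase / (ss_phase + ss_within_err),
    pes_inter = ss_inter / (ss_inter + ss_within_err)
  )
}

test_that("mixed ANOVA matches an independent textbook SS decomposition", {
  d <- anova_fixture()
  res <- mixed_anova(d)
  hand <- hand_anova(d)
  expect_equal(res$`F`[res$effect == "Group"], hand$F_group)
  expect_equal(res$`F`[res$effect == "Phase"], hand$F_phase)
  expect_equal(res$`F`[res$effect == "Group:Phase"], hand$F_inter)
  expect_equal(res$pes[res$effect == "Group"], hand$pes_group)
  expect_equal(res$pes[res$effect == "Phase"], hand$pes_phase)
  expect_equal(res$pes[res$effect == "Group:Phase"], hand$pes_inter)
  expect_true(all(res$pes >= 0 & res$pes <= 1))
  td <- generics::tidy(res)
  expect_equal(td$`F`, res$`F`)
  gl <- generics::glance(res)
  expect_equal(gl$interaction_F, hand$F_inter)
})

test_that("a phase-balanced perturbation leaves the Phase effect null", {
  # phase means identical by construction, but residual variance is real
  d <- anova_fixture() |>
    dplyr::group_by(participant_id) |>
    dplyr::mutate(index = index[1]) |>
    dplyr::ungroup()
  d$index <- d$index + rep(c(0.5, -0.5, -0.5, 0.5), 2)
  res <- mixed_anova(d)
  expect_lt(res$`F`[res$effect == "Phase"], 1e-10)
})

test_that("unbalanced designs are rejected explicitly", {
  d <- anova_fixture()[-1, ]
  expect_error(mixed_anova(d), class = "stmcit_design_error")
  expect_error(mixed_anova(anova_fixture()[, -5]),
               class = "stmcit_data_error")
})

test_that("Tukey post hoc: 15 comparisons, equal means give p = 1, adjustment never helps", {
  # 3 groups x 2 phases with equal cell means and symmetric noise
  d <- tidyr::crossing(group = c("g1", "g2", "g3"), pid = 1:3,
                       phase = c(1, 2)) |>
    dplyr::mutate(participant_id = paste(group, pid),
                  index = rep(c(-1, 0, 1), 6))
  res <- mixed_anova(d)
  ph <- tukey_posthoc(res)
  expect_equal(nrow(ph), 15)
  expect_true(all(ph$p_adj == 1))

  # one outlying cell: its five comparisons carry the smallest p values
  d2 <- tidyr::crossing(group = c("g1", "g2", "g3"), pid = 1:4,
                        phase = c(1, 2)) |>
    dplyr::mutate(participant_id = paste(group, pid))
  d2$index <- withr::with_seed(5, rnorm(nrow(d2), 0, 0.1))
  d2$index[d2$group == "g2" & d2$phase == 2] <-
    d2$index[d2$group == "g2" & d2$phase == 2] + 3
  ph2 <- tukey_posthoc(mixed_anova(d2))
  outlier_rows <- grepl("g2 phase2", ph2$contrast)
  expect_equal(sum(outlier_rows), 5)
  expect_true(max(ph2$p_adj[outlier_rows]) <
                min(ph2$p_adj[!outlier_rows]))
  # adjusted p >= unadjusted pairwise p
  p_unadj <- 2 * stats::pt(-abs(ph2$t), ph2$df)
  expect_true(all(ph2$p_adj >= p_unadj - 1e-12))
})
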