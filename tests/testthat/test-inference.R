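# The analysis stack: RT filter, GLMM fits, LR tests, binned surfaces,
# inverted-U fit, recognition summaries, RM-ANOVA, group contrasts.

make_rt_trials <- function(n = 200, seed = 1, subject = "s1") {
  set.seed(seed)
  data.frame(subject_id = subject, rt_ms = rlnorm(n, log(600), 0.2),
             response = "short", stringsAsFactors = FALSE)
}

test_that("RT filter removes exactly the z-score outliers, per subject", {
  tr <- make_rt_trials(500, seed = 2)
  # homogeneous: nothing removed
  fl <- filter_rt_outliers(tr)
  expect_equal(sum(fl$n_removed), 0L)
  expect_equal(nrow(fl$trials), 500L)
  # inject gross outliers and compare against a direct z-score oracle
  tr2 <- tr
  tr2$rt_ms[c(17L, 250L)] <- exp(log(600) + 10 * 0.2)
  fl2 <- filter_rt_outliers(tr2)
  z <- (log(tr2$rt_ms) - mean(log(tr2$rt_ms))) / sd(log(tr2$rt_ms))
  expect_identical(which(abs(z) > 3), sort(c(17L, 250L)))
  expect_identical(sort(as.integer(rownames(fl2$removed))), c(17L, 250L))
  expect_equal(unname(fl2$n_removed["s1"]), 2L)
  # nothing kept violates the original threshold (fixed-threshold property)
  kept_z <- z[as.integer(rownames(fl2$trials))]
  expect_true(all(abs(kept_z) <= 3))
  # upper-tail-only variant keeps fast outliers
  tr3 <- tr
  tr3$rt_ms[5L] <- exp(log(600) - 10 * 0.2)
  expect_equal(sum(filter_rt_outliers(tr3, tail = "upper")$n_removed), 0L)
  expect_equal(sum(filter_rt_outliers(tr3, tail = "both")$n_removed), 1L)
})

test_that("subjects with too few trials pass through with a warning", {
  tr <- rbind(make_rt_trials(5, seed = 3, subject = "tiny"),
              make_rt_trials(100, seed = 4, subject = "big"))
  expect_warning(fl <- filter_rt_outliers(tr), "tiny")
  expect_equal(sum(fl$trials$subject_id == "tiny"), 5L)
  expect_error(filter_rt_outliers(data.frame(subject_id = "x",
                                             rt_ms = -1)), "positive")
})

test_that("fixed-effects-only fit matches the IRLS oracle", {
  stim <- toy_stimuli()
  tr <- simulate_bisection(stim, n_subjects = 4L, seed = 6)
  fit <- fit_choice_glmm(tr, stim$records, random = "none")
  d <- merge(tr, stim$records, by = "image_id")
  img <- unique(d[, c("image_id", "memorability", "A")])
  mem_c <- d$memorability - mean(img$memorability)
  A_c <- (d$A - mean(img$A)) / sd(img$A)
  X <- cbind(1, mem_c, A_c, mem_c * A_c)
  beta <- oracle_irls_logit(X, as.integer(d$response == "long"))
  got <- fit$coefficients$estimate[match(
    c("(Intercept)", "mem_c", "A_c", "mem_c:A_c"), fit$coefficients$term)]
  expect_equal(got, unname(beta), tolerance = 1e-4)
})

test_that("constant responses raise a separation error", {
  stim <- toy_stimuli()
  tr <- simulate_bisection(stim, n_subjects = 2L, seed = 8)
  tr$response <- "long"
  expect_error(fit_choice_glmm(tr, stim$records), "separation")
})

test_that("the mixed fit recovers generator coefficients (one replicate)", {
  stim <- toy_stimuli()
  pars <- choice_model_params()
  tr <- simulate_bisection(stim, pars, n_subjects = 20L, seed = 9)
  # the generator has a strong duration effect; the recovery fit must model
  # it (omitting it attenuates the other logit coefficients)
  fit <- fit_choice_glmm(tr, stim$records, duration_term = TRUE, nAGQ = 0L)
  expect_true(fit$converged)
  co <- fit$coefficients
  est <- function(t) co$estimate[co$term == t]
  expect_lt(abs(est("mem_c") - pars$beta_mem), 0.4)
  expect_lt(abs(est("A_c") - pars$beta_speed), 0.25)
  expect_gt(est("mem_c"), 0)
  expect_lt(est("A_c"), 0)
  expect_true(all(fit$coefficients$se > 0))
  expect_length(fit$random_effect_sds, 2L)
})

test_that("lr_test handles null comparisons, bookkeeping, and non-nesting", {
  stim <- toy_stimuli()
  tr <- simulate_bisection(stim, n_subjects = 4L, seed = 10)
  full <- fit_choice_glmm(tr, stim$records, random = "intercept",
                          nAGQ = 0L)
  same <- fit_choice_glmm(tr, stim$records, random = "intercept",
                          nAGQ = 0L)
  red <- fit_choice_glmm(tr, stim$records, fixed = c("memorability",
                                                     "speed"),
                         random = "intercept", nAGQ = 0L)
  mem_only <- fit_choice_glmm(tr, stim$records, fixed = "memorability",
                              random = "intercept", nAGQ = 0L)
  # identical models: chi2 = 0, p = 1
  null_cmp <- lr_test(full, same)
  expect_equal(null_cmp$value, 0)
  expect_equal(null_cmp$p, 1)
  # df equals the number of dropped fixed effects
  expect_equal(lr_test(full, red)$df, 1)
  expect_equal(lr_test(full, mem_only)$df, 2)
  expect_gte(lr_test(full, red)$value, 0)
  expect_error(lr_test(red, full), "not nested")
})

test_that("binned surfaces equal brute-force group means", {
  stim <- toy_stimuli()
  tr <- simulate_bisection(stim, n_subjects = 1L, seed = 12)[1:30, ]
  surf <- binned_psychometric(tr, stim$records, n_mem_bins = 2L,
                              n_speed_bins = 2L)
  d <- merge(tr, stim$records, by = "image_id")
  img <- unique(d[, c("image_id", "memorability", "A")])
  sp <- -(d$A - mean(img$A)) / sd(img$A)
  mem <- d$memorability
  sedges <- seq(min(sp), max(sp), length.out = 3L)
  medges <- seq(min(mem), max(mem), length.out = 3L)
  for (i in 1:2) for (j in 1:2) {
    in_m <- mem >= medges[i] & (if (i == 2) mem <= medges[3] else
      mem < medges[2])
    in_s <- sp >= sedges[j] & (if (j == 2) sp <= sedges[3] else
      sp < sedges[2])
    k <- in_m & in_s
    expect_equal(surf$cell_counts[i, j], sum(k))
    if (any(k))
      expect_equal(surf$cell_means[i, j], mean(d$response[k] == "long"))
  }
  # constant responses give all-1 cells; 11-bin layout gives 11 cells
  tr_all <- tr; tr_all$response <- "long"
  s2 <- binned_psychometric(tr_all, stim$records, n_mem_bins = 0L,
                            n_speed_bins = 11L)
  expect_length(s2$cell_means, 11L)
  expect_true(all(s2$cell_means[s2$cell_counts > 0] == 1))
})

test_that("a noiseless parabola is recovered exactly by fit_inverted_u", {
  s <- seq(-1, 3, length.out = 11L)
  surf <- structure(list(layout = "speed_only", speed_centers = s,
                         cell_means = -0.5 * (s - 1)^2 + 0.8,
                         cell_counts = rep(100, 11L)),
                    class = "binned_surface")
  fit <- fit_inverted_u(surf)
  expect_true(fit$inverted_u)
  expect_equal(fit$M1, 0.5, tolerance = 1e-10)
  expect_equal(fit$M2, 1, tolerance = 1e-10)
  expect_equal(fit$M3, 0.8, tolerance = 1e-10)
  expect_lt(fit$rss, 1e-18)
  # monotone (convex-compatible) data are flagged
  surf$cell_means <- 0.05 + 0.08 * seq_len(11L)^2 / 11
  expect_false(fit_inverted_u(surf)$inverted_u)
  surf$cell_means[4:11] <- NA
  expect_error(fit_inverted_u(surf), "4 non-missing")
})

test_that("recognition summaries match hand-computed proportions", {
  toy <- data.frame(
    subject_id = rep(c("s1", "s2"), each = 6),
    bin = rep(c(1, 1, 2, 2, 1, 2), 2),
    is_old = rep(c(1, 1, 1, 1, 0, 0), 2),
    response = c("old", "new", "old", "old", "new", "old",
                 "old", "old", "new", "old", "old", "new"))
  rs <- recognition_summary(toy)
  # s1: bin1 1/2, bin2 2/2; s2: bin1 2/2, bin2 1/2
  expect_equal(unname(rs$subject_matrix["s1", ]), c(0.5, 1.0))
  expect_equal(unname(rs$subject_matrix["s2", ]), c(1.0, 0.5))
  expect_equal(unname(rs$bin_hit_rates), c(0.75, 0.75))
  expect_equal(rs$spread, 0)
  expect_equal(rs$overall_hit_rate, 6 / 8)
  expect_equal(rs$fa_rate, 2 / 4)
  # perfect responder: all ones, zero spread
  perf <- toy; perf$response <- ifelse(perf$is_old == 1, "old", "new")
  rp <- recognition_summary(perf)
  expect_true(all(rp$subject_matrix == 1))
  expect_equal(rp$spread, 0)
})

test_that("rm_anova matches the textbook decomposition and df bookkeeping", {
  # 20 subjects x 7 bins: df = (6, 114)
  set.seed(14)
  m <- matrix(runif(140), 20, 7)
  res <- rm_anova(m)
  expect_equal(res$df, c(6, 114))
  # all-equal cells: no effect
  flat <- rm_anova(matrix(0.5, 5, 4))
  expect_equal(flat$value, 0)
  expect_equal(flat$partial_eta_sq, 0)
  # 3 x 3 hand table vs the explicit sum-of-squares oracle and aov()
  h <- matrix(c(0.2, 0.4, 0.6,
                0.3, 0.5, 0.8,
                0.1, 0.5, 0.7), 3, 3, byrow = TRUE)
  got <- rm_anova(h)
  want <- oracle_rm_anova(h)
  expect_equal(got$value, want$F, tolerance = 1e-12)
  expect_equal(got$df, want$df)
  expect_equal(got$partial_eta_sq, want$eta, tolerance = 1e-12)
  df_aov <- data.frame(y = as.vector(h),
                       subj = factor(rep(1:3, 3)),
                       bin = factor(rep(1:3, each = 3)))
  aov_tab <- summary(aov(y ~ bin + Error(subj), df_aov))
  f_aov <- aov_tab[["Error: Within"]][[1]]["bin", "F value"]
  expect_equal(got$value, f_aov, tolerance = 1e-10)
  expect_error(rm_anova(h[1, , drop = FALSE]), "2 complete subjects")
})

test_that("group contrasts match pooled t tests with Bonferroni correction", {
  # identical groups: null contrast
  v <- rep(c(0.5, 0.6, 0.7), 2)
  g <- rep(c("a", "b"), each = 3)
  res0 <- group_contrast(v, g)
  expect_equal(res0$t, 0)
  expect_equal(res0$cohens_d, 0)
  expect_equal(res0$p_corrected, 1)
  # 3 groups: 3 comparisons, factor-3 correction
  set.seed(15)
  v3 <- rnorm(15); g3 <- rep(c("a", "b", "c"), each = 5)
  res3 <- group_contrast(v3, g3)
  expect_equal(nrow(res3), 3L)
  expect_equal(res3$p_corrected, pmin(1, res3$p * 3))
  # toy 2 x 5: against t.test's pooled-variance computation
  x <- c(1.1, 0.9, 1.3, 1.0, 1.2); y <- c(0.7, 0.8, 0.6, 0.9, 0.8)
  res <- group_contrast(c(x, y), rep(c("g1", "g2"), each = 5))
  tt <- t.test(x, y, var.equal = TRUE)
  expect_equal(res$t, unname(tt$statistic), tolerance = 1e-12)
  expect_equal(res$p, tt$p.value, tolerance = 1e-12)
  sp <- sqrt((4 * var(x) + 4 * var(y)) / 8)
  expect_equal(res$cohens_d, (mean(x) - mean(y)) / sp, tolerance = 1e-12)
  expect_error(group_contrast(1:3, c("a", "a", "b")), "at least 2")
})
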