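# Synthetic experiment generators.

test_that("duration grid is geometric with the stated endpoints", {
  g <- make_duration_grid()
  expect_equal(g[1L], 300)
  expect_equal(g[7L], 900)
  expect_equal(g[4L], 300 * sqrt(3), tolerance = 1e-12)
  expect_equal(diff(log(g)), rep(log(900 / 300) / 6, 6), tolerance = 1e-12)
  expect_error(make_duration_grid(lo = 0), "positive")
  expect_error(make_duration_grid(lo = 900, hi = 300), "lo < hi")
  expect_error(make_duration_grid(n = 1), "n must be")
})

test_that("the bisection schedule is exact: 7 x 196 balanced trials", {
  stim <- toy_stimuli()
  tr <- simulate_bisection(stim, n_subjects = 2L, seed = 1)
  expect_equal(nrow(tr), 2L * 1372L)
  for (s in unique(tr$subject_id)) {
    d <- tr[tr$subject_id == s, ]
    expect_equal(nrow(d), 1372L)
    # every image exactly once per block, 7 times overall
    expect_equal(unname(table(table(d$image_id))), 196L, ignore_attr = TRUE)
    expect_true(all(table(d$image_id, d$block) == 1L))
    # each duration 196 times per subject, 28 per block
    expect_equal(unname(table(d$duration_ms)), rep(196L, 7L),
                 ignore_attr = TRUE)
    expect_true(all(table(d$duration_ms, d$block) == 28L))
  }
  expect_true(all(tr$rt_ms > 0))
})

test_that("generation is deterministic given config + seed", {
  stim <- toy_stimuli()
  t1 <- simulate_bisection(stim, n_subjects = 2L, seed = 7)
  t2 <- simulate_bisection(stim, n_subjects = 2L, seed = 7)
  expect_identical(t1, t2)
  r1 <- simulate_recognition(toy_recog_stimuli(), n_subjects = 2L, seed = 7)
  r2 <- simulate_recognition(toy_recog_stimuli(), n_subjects = 2L, seed = 7)
  expect_identical(r1, r2)
  s1 <- make_synthetic_score_table(500, seed = 7)
  s2 <- make_synthetic_score_table(500, seed = 7)
  expect_identical(s1, s2)
})

test_that("null choice model gives a fair coin", {
  stim <- toy_stimuli()
  pars <- choice_model_params(beta0 = 0, beta_dur = 0, beta_mem = 0,
                              beta_speed = 0, beta_interaction = 0,
                              sd_subject_intercept = 0,
                              sd_subject_speed_slope = 0)
  tr <- simulate_bisection(stim, pars, n_subjects = 20L, seed = 3)
  p <- mean(tr$response == "long")
  mc_se <- 0.5 / sqrt(nrow(tr))
  expect_lt(abs(p - 0.5), 3 * mc_se)
})

test_that("a pure memorability effect shows up monotonically across bins", {
  stim <- toy_stimuli()
  pars <- choice_model_params(beta0 = 0, beta_dur = 0, beta_mem = 2,
                              beta_speed = 0, beta_interaction = 0,
                              sd_subject_intercept = 0,
                              sd_subject_speed_slope = 0)
  tr <- simulate_bisection(stim, pars, n_subjects = 8L, seed = 5)
  mem <- stim$records$memorability[match(tr$image_id,
                                         stim$records$image_id)]
  bins <- assign_memorability_bins(mem, 7, min(mem), max(mem))
  p_bin <- tapply(tr$response == "long", bins, mean)
  expect_true(all(diff(p_bin) > 0))
})

test_that("inverted-U model evaluates as a symmetric quadratic", {
  m <- inverted_u_model(0.2, 0.3, 0.8)
  f <- function(s) -m$M1 * (s - m$M2)^2 + m$M3
  expect_equal(f(m$M2), m$M3)
  expect_equal(f(m$M2 + 0.5), f(m$M2 - 0.5))
  expect_error(inverted_u_model(-1, 0, 0.5), "M1")
  expect_error(inverted_u_model(1, 0, 0), "M3")
  expect_error(inverted_u_model(1, 0, 1.5), "M3")
  # the memorability map applies the three stated modulations
  map <- inverted_u_map()
  lo <- map(0.2); hi <- map(1.0)
  expect_gt(lo$M1, hi$M1)    # wider spread at high memorability
  expect_lt(lo$M2, hi$M2)    # peak displaced to faster speeds
  expect_lt(lo$M3, hi$M3)    # higher peak
})

test_that("inverted-U trials reproduce the generating parabola in 11 bins", {
  stim <- toy_stimuli()
  rec <- code_covariates(stim$records)
  const_map <- function(mem) inverted_u_model(0.15, 0, 0.7)
  n_subj <- 73L   # ~1e5 trials
  tr <- simulate_bisection_inverted_u(stim, const_map,
                                      n_subjects = n_subj, seed = 11)
  s <- -rec$A_c[match(tr$image_id, rec$image_id)]
  p_true <- pmin(pmax(-0.15 * s^2 + 0.7, 1e-3), 1 - 1e-3)
  edges <- seq(min(s), max(s), length.out = 12L)
  bins <- assign_memorability_bins(s, 11L, edges[1L], edges[12L])
  y <- as.integer(tr$response == "long")
  for (b in 1:11) {
    i <- which(bins == b)
    mc_se <- sqrt(0.25 / length(i))
    expect_lt(abs(mean(y[i]) - mean(p_true[i])), 3 * mc_se)
  }
})

test_that("recognition generator honors its degenerate and chance settings", {
  stim <- toy_recog_stimuli()
  # perfect memory
  r <- simulate_recognition(stim, n_subjects = 2L, hit_model = function(m, a)
    1, fa_rate = 0, seed = 1)
  expect_true(all(r$correct == 1L))
  expect_equal(nrow(r), 2L * 2L * 196L)   # 196 old + 196 new per subject
  # chance responder
  r2 <- simulate_recognition(stim, n_subjects = 10L,
                             hit_model = function(m, a) 0.5, fa_rate = 0.5,
                             seed = 2)
  acc <- mean(r2$correct)
  expect_lt(abs(acc - 0.5), 3 * sqrt(0.25 / nrow(r2)))
  expect_error(simulate_recognition(stim, fa_rate = 1.5), "fa_rate")
})

test_that("synthetic score tables match their stated joint structure", {
  st <- make_synthetic_score_table(392, seed = 1)
  expect_equal(nrow(st), 392L)
  expect_false(anyDuplicated(st$image_id) > 0)
  expect_true(all(st$memorability >= 0.2 & st$memorability <= 1))
  # rank correlation target at n = 50k
  big <- make_synthetic_score_table(50000, seed = 2)
  rho <- cor(big$memorability, big$A, method = "spearman")
  expect_lt(abs(rho - (-0.1134)), 0.02)
  # heteroscedasticity: more memorable images spread wider in A
  mid <- make_synthetic_score_table(10000, seed = 3)
  qs <- quantile(mid$memorability, c(1 / 3, 2 / 3))
  v_lo <- var(mid$A[mid$memorability <= qs[1L]])
  v_hi <- var(mid$A[mid$memorability >= qs[2L]])
  expect_gt(v_hi, v_lo)
})
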