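# Generators for complete synthetic experiments: bisection trial tables with
# logit choice structure and lognormal RTs, the inverted-U generative
# alternative, next-day recognition tables, and synthetic image score tables.

#' Log-spaced duration grid
#'
#' `d_k = lo * (hi/lo)^((k-1)/(n-1))`, the geometric spacing of the bisection
#' task's seven durations between 300 and 900 ms.
#'
#' @param lo,hi endpoints in ms, `0 < lo < hi`.
#' @param n number of durations (>= 2).
#' @return numeric vector of length `n`, first `lo`, last `hi`.
#' @export
make_duration_grid <- function(lo = 300, hi = 900, n = 7L) {
  if (lo <= 0) stop("lo must be positive", call. = FALSE)
  if (!(lo < hi)) stop("need lo < hi", call. = FALSE)
  if (n < 2L) stop("n must be >= 2", call. = FALSE)
  lo * (hi / lo)^((seq_len(n) - 1) / (n - 1))
}

#' Cohort layout
#'
#' @param n_groups number of groups (default 3: one per sampling strategy).
#' @param n_subjects_per_group subjects per group (default 20).
#' @param seed integer seed.
#' @return an object of class `cohort_config`.
#' @export
cohort_config <- function(n_groups = 3L, n_subjects_per_group = 20L,
                          seed = 1L) {
  stopifnot(n_groups >= 1L, n_subjects_per_group >= 1L)
  structure(list(n_groups = as.integer(n_groups),
                 n_subjects_per_group = as.integer(n_subjects_per_group),
                 seed = as.integer(seed)),
            class = "cohort_config")
}

#' Parameters of the generative logit choice model
#'
#' The probability of responding "long" is
#' `plogis(beta0 + beta_dur*z + beta_mem*mem_c + beta_speed*A_c +
#' beta_interaction*mem_c*A_c + u_subj + v_subj*A_c)` where `z` is the
#' standardized log duration and `mem_c`, `A_c` are the centered/standardized
#' covariates produced by [code_covariates()] — the same coding the inference
#' stage fits, so recovered coefficients are directly comparable.
#' `beta_speed < 0` encodes "faster (more negative A) images are judged
#' longer". Reaction times are lognormal with a small injected-outlier
#' fraction so the log-RT filter has work to do.
#'
#' @param beta0 intercept.
#' @param beta_dur slope on standardized log duration.
#' @param beta_mem slope on centered memorability.
#' @param beta_speed slope on standardized `A`.
#' @param beta_interaction memorability-by-speed interaction slope.
#' @param sd_subject_intercept,sd_subject_speed_slope SDs of the Gaussian
#'   per-subject random intercept and speed slope (>= 0).
#' @param rt_meanlog,rt_sdlog lognormal RT parameters (log-ms).
#' @param rt_outlier_frac fraction of trials whose RT is multiplied by
#'   `rt_outlier_factor`.
#' @param rt_outlier_factor multiplicative outlier size.
#' @return an object of class `choice_model_params`.
#' @export
choice_model_params <- function(beta0 = 0, beta_dur = 2, beta_mem = 1.2,
                                beta_speed = -0.8, beta_interaction = 0.5,
                                sd_subject_intercept = 0.5,
                                sd_subject_speed_slope = 0.3,
                                rt_meanlog = log(600), rt_sdlog = 0.25,
                                rt_outlier_frac = 0.01,
                                rt_outlier_factor = 5) {
  if (sd_subject_intercept < 0 || sd_subject_speed_slope < 0)
    stop("random-effect sds must be >= 0", call. = FALSE)
  structure(as.list(environment()), class = "choice_model_params")
}

#' Center/standardize the image covariates
#'
#' Memorability is centered (its natural unit, probability of recognition, is
#' kept); `A` is standardized because its raw scale is arbitrary (~1e-5 for
#' natural images). Constant columns map to zero. Both generator and fitter
#' use this coding, computed over the unique images of the analyzed set.
#'
#' @param records image records with `memorability` and `A`.
#' @return `records` with columns `mem_c` and `A_c` added, plus attributes
#'   `mem_center`, `A_center`, `A_scale`.
#' @export
code_covariates <- function(records) {
  m0 <- mean(records$memorability)
  a0 <- mean(records$A)
  as <- stats::sd(records$A)
  if (!is.finite(as) || as == 0) as <- 1
  records$mem_c <- records$memorability - m0
  records$A_c <- (records$A - a0) / as
  attr(records, "mem_center") <- m0
  attr(records, "A_center") <- a0
  attr(records, "A_scale") <- as
  records
}

test_records <- function(stimuli) {
  if (inherits(stimuli, "stimulus_set")) {
    rec <- stimuli$records
    rec <- rec[rec$image_id %in% stimuli$test, , drop = FALSE]
  } else rec <- stimuli
  need <- c("image_id", "memorability", "A")
  miss <- setdiff(need, names(rec))
  if (length(miss))
    stop("stimulus records lack column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  if (anyNA(rec$memorability) || anyNA(rec$A))
    stop("missing covariates for some images", call. = FALSE)
  rec
}

# shared trial scaffold: 7 blocks x n_img trials, each image once per block,
# durations balanced over the grid within block, both orders shuffled
schedule_blocks <- function(n_img, durations, n_blocks) {
  n_per <- n_img / length(durations)
  if (n_per != round(n_per))
    stop("image count must be a multiple of the duration-grid size",
         call. = FALSE)
  blocks <- lapply(seq_len(n_blocks), function(b) {
    data.frame(block = b,
               img = sample.int(n_img),
               duration_ms = sample(rep(durations, times = n_per)))
  })
  out <- do.call(rbind, blocks)
  out$trial_index <- seq_len(nrow(out))
  out
}

draw_rts <- function(n, params) {
  rt <- stats::rlnorm(n, params$rt_meanlog, params$rt_sdlog)
  out <- stats::runif(n) < params$rt_outlier_frac
  rt[out] <- rt[out] * params$rt_outlier_factor
  rt
}

finish_trials <- function(sch, rec, p_long, params, subject_id, group) {
  y <- stats::rbinom(nrow(sch), 1L, p_long)
  data.frame(subject_id = subject_id, group = group, block = sch$block,
             trial_index = sch$trial_index,
             image_id = rec$image_id[sch$img],
             duration_ms = sch$duration_ms,
             response = ifelse(y == 1L, "long", "short"),
             rt_ms = draw_rts(nrow(sch), params),
             stringsAsFactors = FALSE)
}

#' Simulate a temporal-bisection session under the logit choice model
#'
#' Per subject: a random intercept and speed slope are drawn, then
#' `n_blocks` blocks are scheduled with every test image shown once per block
#' and durations balanced over the grid within block (196 images x 7 blocks =
#' 1372 trials at the defaults).
#'
#' @param stimuli a `stimulus_set` (its test half is used) or a data frame of
#'   image records.
#' @param params a [choice_model_params()].
#' @param n_subjects number of simulated subjects.
#' @param durations duration grid (ms).
#' @param n_blocks number of blocks.
#' @param group label stored in the `group` column.
#' @param subject_offset added to subject numbering (for multi-group tables).
#' @param seed integer seed; same inputs + seed give an identical table.
#' @return a `trial_table` data frame: `subject_id`, `group`, `block`,
#'   `trial_index`, `image_id`, `duration_ms`, `response`, `rt_ms`.
#' @export
simulate_bisection <- function(stimuli, params = choice_model_params(),
                               n_subjects = 20L,
                               durations = make_duration_grid(),
                               n_blocks = 7L, group = "group1",
                               subject_offset = 0L, seed = 1L) {
  stopifnot(inherits(params, "choice_model_params"))
  rec <- code_covariates(test_records(stimuli))
  set.seed(seed)
  zlog <- (log(durations) - mean(log(durations))) / stats::sd(log(durations))
  zmap <- stats::setNames(zlog, format(durations, digits = 15))
  tabs <- vector("list", n_subjects)
  for (s in seq_len(n_subjects)) {
    u <- stats::rnorm(1, 0, params$sd_subject_intercept)
    v <- stats::rnorm(1, 0, params$sd_subject_speed_slope)
    sch <- schedule_blocks(nrow(rec), durations, n_blocks)
    z <- zmap[format(sch$duration_ms, digits = 15)]
    eta <- params$beta0 + params$beta_dur * z +
      params$beta_mem * rec$mem_c[sch$img] +
      params$beta_speed * rec$A_c[sch$img] +
      params$beta_interaction * rec$mem_c[sch$img] * rec$A_c[sch$img] +
      u + v * rec$A_c[sch$img]
    tabs[[s]] <- finish_trials(sch, rec, stats::plogis(eta), params,
                               sprintf("s%03d", s + subject_offset), group)
  }
  out <- do.call(rbind, tabs)
  rownames(out) <- NULL
  class(out) <- c("trial_table", class(out))
  out
}

#' Inverted-U (quadratic) duration-choice model
#'
#' `P(long | speed) = -M1 * (speed - M2)^2 + M3`: `M1 > 0` controls the
#' curve's width (larger = narrower), `M2` the vertex location on the speed
#' axis, `M3` in `(0, 1]` the peak probability.
#'
#' @param M1 curvature (> 0).
#' @param M2 vertex speed (standardized-`A` units).
#' @param M3 peak `P(long)` in `(0, 1]`.
#' @return an object of class `inverted_u_model`.
#' @export
inverted_u_model <- function(M1, M2, M3) {
  if (M1 <= 0) stop("M1 must be > 0", call. = FALSE)
  if (M3 <= 0 || M3 > 1) stop("M3 must lie in (0, 1]", call. = FALSE)
  structure(list(M1 = M1, M2 = M2, M3 = M3), class = "inverted_u_model")
}

#' Memorability-scaled family of inverted-U models
#'
#' Linear interpolation over the memorability range implementing the three
#' stated modulations: more memorable images get wider curves (`M1`
#' decreasing), vertices displaced to faster speeds (`M2` increasing — note
#' the speed axis here is `-A_c`-like: larger `M2` on the standardized-`A`
#' axis means the peak sits at slower-coded values, so `M2` is expressed on
#' the *speediness* axis `s = -A_c`), and higher peaks (`M3` increasing).
#'
#' @param M1_range `c(at mem lo, at mem hi)`, decreasing.
#' @param M2_range vertex speediness, increasing.
#' @param M3_range peak height, increasing, within `(0, 1]`.
#' @param mem_range memorability endpoints of the interpolation.
#' @return a function `mem -> inverted_u_model`.
#' @export
inverted_u_map <- function(M1_range = c(0.25, 0.10),
                           M2_range = c(-0.3, 0.5),
                           M3_range = c(0.56, 0.80),
                           mem_range = c(0.2, 1.0)) {
  stopifnot(M1_range[1L] >= M1_range[2L], M2_range[1L] <= M2_range[2L],
            M3_range[1L] <= M3_range[2L], all(M3_range > 0 & M3_range <= 1))
  function(mem) {
    w <- (mem - mem_range[1L]) / (mem_range[2L] - mem_range[1L])
    w <- pmin(pmax(w, 0), 1)
    inverted_u_model(M1_range[1L] + w * diff(M1_range),
                     M2_range[1L] + w * diff(M2_range),
                     M3_range[1L] + w * diff(M3_range))
  }
}

#' Simulate bisection data from the inverted-U generative rule
#'
#' The "speediness" of an image is `s = -A_c` (standardized `A`, sign flipped
#' so larger = faster), and `P(long) = clip(-M1*(s - M2)^2 + M3, eps, 1-eps)`
#' with the `(M1, M2, M3)` triple supplied per image by `u_model_map`
#' evaluated at its memorability. Scheduling and RTs are as in
#' [simulate_bisection()].
#'
#' @param stimuli a `stimulus_set` or image records.
#' @param u_model_map function `mem -> inverted_u_model`; default
#'   [inverted_u_map()].
#' @param n_subjects number of subjects.
#' @param durations duration grid.
#' @param n_blocks number of blocks.
#' @param eps clipping bound keeping probabilities inside `(0, 1)`; the raw
#'   quadratic can leave `[0, 1]`.
#' @param group,subject_offset,seed as in [simulate_bisection()].
#' @param rt_params a [choice_model_params()] supplying the RT model only.
#' @return a `trial_table` data frame.
#' @export
simulate_bisection_inverted_u <- function(stimuli,
                                          u_model_map = inverted_u_map(),
                                          n_subjects = 20L,
                                          durations = make_duration_grid(),
                                          n_blocks = 7L, eps = 1e-3,
                                          group = "group1",
                                          subject_offset = 0L, seed = 1L,
                                          rt_params = choice_model_params()) {
  rec <- code_covariates(test_records(stimuli))
  ms <- lapply(rec$memorability, u_model_map)
  bad <- !vapply(ms, inherits, logical(1), "inverted_u_model")
  if (any(bad)) stop("u_model_map must return inverted_u_model objects",
                     call. = FALSE)
  s <- -rec$A_c
  p_img <- vapply(seq_along(ms), function(i) {
    m <- ms[[i]]
    -m$M1 * (s[i] - m$M2)^2 + m$M3
  }, numeric(1))
  p_img <- pmin(pmax(p_img, eps), 1 - eps)
  set.seed(seed)
  tabs <- vector("list", n_subjects)
  for (subj in seq_len(n_subjects)) {
    sch <- schedule_blocks(nrow(rec), durations, n_blocks)
    tabs[[subj]] <- finish_trials(sch, rec, p_img[sch$img], rt_params,
                                  sprintf("s%03d", subj + subject_offset),
                                  group)
  }
  out <- do.call(rbind, tabs)
  rownames(out) <- NULL
  class(out) <- c("trial_table", class(out))
  out
}

#' Simulate the next-day old/new recognition session
#'
#' Old (test) items are endorsed "old" with a probability graded over the
#' stimulus bins: bin `j` of `nb` has expected hit rate
#' `base_hit - spread/2 + spread*(j-1)/(nb-1)`, so the range of expected
#' per-bin hit rates equals `spread` exactly (bins are ordered along the
#' sampling axis: slow -> fast or low -> high memorability). Foils are
#' endorsed "old" with probability `fa_rate`. A custom `hit_model(mem, A)`
#' overrides the bin-graded rule.
#'
#' @param stimuli a `stimulus_set` (test + foil halves with bins).
#' @param n_subjects number of subjects.
#' @param base_hit mean expected hit rate.
#' @param spread expected range (max - min) of per-bin hit rates.
#' @param fa_rate false-alarm probability in `[0, 1]` (the degenerate
#'   endpoints model a perfect or maximally liberal responder).
#' @param hit_model optional function `(mem, A) -> probability`.
#' @param group label.
#' @param seed integer seed.
#' @return a `recognition_table` data frame: `subject_id`, `group`,
#'   `image_id`, `bin`, `is_old`, `response`, `correct`.
#' @export
simulate_recognition <- function(stimuli, n_subjects = 20L, base_hit = 0.5,
                                 spread = 0.17, fa_rate = 0.3,
                                 hit_model = NULL, group = "group1",
                                 seed = 1L) {
  stopifnot(inherits(stimuli, "stimulus_set"))
  if (fa_rate < 0 || fa_rate > 1)
    stop("fa_rate must lie in [0, 1]", call. = FALSE)
  rec <- stimuli$records
  old <- rec[rec$image_id %in% stimuli$test, , drop = FALSE]
  new <- rec[rec$image_id %in% stimuli$foil, , drop = FALSE]
  if (is.null(hit_model)) {
    nb <- max(rec$bin)
    targets <- if (nb == 1L) base_hit else
      base_hit - spread / 2 + spread * (seq_len(nb) - 1) / (nb - 1)
    p_old <- targets[old$bin]
  } else {
    p_old <- mapply(hit_model, old$memorability, old$A)
  }
  if (any(p_old < 0 | p_old > 1))
    stop("hit probabilities must lie in [0, 1]", call. = FALSE)
  set.seed(seed)
  tabs <- vector("list", n_subjects)
  for (s in seq_len(n_subjects)) {
    yo <- stats::rbinom(nrow(old), 1L, p_old)
    yn <- stats::rbinom(nrow(new), 1L, fa_rate)
    tabs[[s]] <- data.frame(
      subject_id = sprintf("s%03d", s),
      group = group,
      image_id = c(old$image_id, new$image_id),
      bin = c(old$bin, new$bin),
      is_old = rep(c(1L, 0L), c(nrow(old), nrow(new))),
      response = ifelse(c(yo, yn) == 1L, "old", "new"),
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, tabs)
  out$correct <- as.integer((out$is_old == 1L) == (out$response == "old"))
  rownames(out) <- NULL
  class(out) <- c("recognition_table", class(out))
  out
}

# Internal: delivered Spearman correlation is attenuated by the
# heteroscedastic scaling of A (rank mixing across memorability levels);
# measure the attenuation once with a deterministic internal Monte-Carlo
# stream and solve for the latent copula correlation.
calibrate_latent_spearman <- function(target, mem_shape, hetero, A_dist,
                                      n = 200000L) {
  if (target == 0 || hetero == 0) return(target)
  probe <- max(abs(target), 0.1) * sign(target)
  r <- 2 * sin(pi * probe / 6)
  old_seed <- if (exists(".Random.seed", globalenv()))
    get(".Random.seed", globalenv()) else NULL
  set.seed(20260909L)
  z1 <- stats::rnorm(n); e <- stats::rnorm(n)
  z2 <- r * z1 + sqrt(1 - r^2) * e
  mem <- 0.2 + 0.8 * stats::qbeta(stats::pnorm(z1), mem_shape[1L],
                                  mem_shape[2L])
  q2 <- if (A_dist == "uniform")
    stats::qunif(stats::pnorm(z2), -sqrt(3), sqrt(3)) else z2
  a <- (1 + hetero * (mem - 0.2) / 0.8) * q2
  delivered <- stats::cor(rank(mem), rank(a))
  if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv())
  alpha <- delivered / probe
  target / alpha
}

#' Generate a synthetic image score table
#'
#' Emulates the joint structure of memorability and collapse-rate scores over
#' a large natural-image corpus: memorability on `[0.2, 1]` (scaled Beta), a
#' weak negative rank dependence between memorability and `A` (faster
#' collapse for more memorable images; Gaussian copula calibrated so the
#' delivered Spearman correlation matches `target_spearman` despite the
#' heteroscedastic scaling), and an `A` spread that grows with memorability.
#'
#' @param n_images number of records.
#' @param target_spearman target Spearman correlation between memorability
#'   and `A` (the corpus-level value is small and negative).
#' @param mem_shape Beta shape parameters of the memorability distribution.
#' @param A_mean,A_sd location and baseline scale of `A` (the natural-image
#'   scale is ~1e-5).
#' @param hetero heteroscedasticity factor: the SD of `A` grows linearly from
#'   `A_sd` at memorability 0.2 to `A_sd * (1 + hetero)` at 1.
#' @param A_dist conditional distribution of `A` given memorability:
#'   `"uniform"` (bounded support, unit variance before scaling; the default,
#'   so that equal-width speed bins with equal quotas are feasible the way
#'   they are for a real bounded corpus) or `"normal"`.
#' @param seed integer seed.
#' @return data frame `image_id`, `memorability`, `A` (plus `B`, `C` columns
#'   filled with representative constants for schema compatibility).
#' @export
make_synthetic_score_table <- function(n_images, target_spearman = -0.1134,
                                       mem_shape = c(2, 2),
                                       A_mean = -2.4e-05, A_sd = 1.0e-05,
                                       hetero = 1,
                                       A_dist = c("uniform", "normal"),
                                       seed = 1L) {
  if (n_images < 1L) stop("n_images must be >= 1", call. = FALSE)
  A_dist <- match.arg(A_dist)
  lat <- calibrate_latent_spearman(target_spearman, mem_shape, hetero,
                                   A_dist)
  r <- 2 * sin(pi * lat / 6)
  set.seed(seed)
  z1 <- stats::rnorm(n_images)
  z2 <- r * z1 + sqrt(1 - r^2) * stats::rnorm(n_images)
  mem <- 0.2 + 0.8 * stats::qbeta(stats::pnorm(z1), mem_shape[1L],
                                  mem_shape[2L])
  q2 <- if (A_dist == "uniform")
    stats::qunif(stats::pnorm(z2), -sqrt(3), sqrt(3)) else z2
  A <- A_mean + A_sd * (1 + hetero * (mem - 0.2) / 0.8) * q2
  data.frame(image_id = sprintf("img%06d", seq_len(n_images)),
             memorability = mem, A = A,
             B = rep(1, n_images), C = rep(log(100), n_images),
             stringsAsFactors = FALSE)
}
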