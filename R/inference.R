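# Analysis stage: log-RT outlier filtering, binomial mixed-effects fits with
# nested likelihood-ratio tests, binned psychometric surfaces, the quadratic
# inverted-U fit, recognition summaries, repeated-measures ANOVA and
# pairwise group contrasts.

#' Remove reaction-time outliers on the log scale, per subject
#'
#' For each subject the mean and SD of `ln(rt)` are computed and trials whose
#' log RT deviates by more than 3 SDs are dropped (two-sided by default; the
#' stricter reading "greater than" is available as `tail = "upper"`). Trials
#' exactly at the boundary are retained. Subjects with fewer than
#' `min_trials` trials are passed through unfiltered with a warning.
#'
#' @param trials trial table with `subject_id` and `rt_ms` columns.
#' @param n_sd threshold in SD units.
#' @param tail `"both"` or `"upper"`.
#' @param min_trials minimum trials per subject for filtering.
#' @return list with `trials` (kept rows), `n_removed` (named per subject),
#'   and `removed` (the dropped rows).
#' @export
filter_rt_outliers <- function(trials, n_sd = 3, tail = c("both", "upper"),
                               min_trials = 10L) {
  tail <- match.arg(tail)
  if (any(trials$rt_ms <= 0)) stop("rt_ms must be positive", call. = FALSE)
  keep <- logical(nrow(trials))
  subs <- unique(trials$subject_id)
  n_removed <- stats::setNames(integer(length(subs)), subs)
  for (s in subs) {
    i <- which(trials$subject_id == s)
    if (length(i) < min_trials) {
      warning(sprintf("subject %s has %d (< %d) trials; not filtered",
                      s, length(i), min_trials), call. = FALSE)
      keep[i] <- TRUE
      next
    }
    lr <- log(trials$rt_ms[i])
    z <- (lr - mean(lr)) / stats::sd(lr)
    ok <- if (tail == "both") abs(z) <= n_sd else z <= n_sd
    keep[i] <- ok
    n_removed[s] <- sum(!ok)
  }
  list(trials = trials[keep, , drop = FALSE],
       n_removed = n_removed,
       removed = trials[!keep, , drop = FALSE])
}

merge_covariates <- function(trials, scores) {
  if (!is.null(scores)) {
    cols <- c("image_id", "memorability", "A")
    miss <- setdiff(cols, names(scores))
    if (length(miss))
      stop("score table lacks column(s): ", paste(miss, collapse = ", "),
           call. = FALSE)
    trials$memorability <- NULL
    trials$A <- NULL
    idx <- match(trials$image_id, scores$image_id)
    if (anyNA(idx))
      stop("trials reference images absent from the score table",
           call. = FALSE)
    trials$memorability <- scores$memorability[idx]
    trials$A <- scores$A[idx]
  }
  if (!all(c("memorability", "A") %in% names(trials)))
    stop("trials lack covariates; supply a score table", call. = FALSE)
  if (anyNA(trials$memorability) || anyNA(trials$A))
    stop("missing covariates for some trials", call. = FALSE)
  # coding computed over the unique analyzed images, mirroring the generator
  img <- unique(trials[, c("image_id", "memorability", "A")])
  img <- code_covariates(img)
  idx <- match(trials$image_id, img$image_id)
  trials$mem_c <- img$mem_c[idx]
  trials$A_c <- img$A_c[idx]
  trials
}

#' Fit the binomial-logit mixed model of bisection choices
#'
#' Responses ("long" = 1) are modelled with a logit link; covariates use the
#' package-wide coding (memorability centered, `A` standardized over the
#' analyzed images; see [code_covariates()]). Random effects are Gaussian and
#' the marginal likelihood is maximized by lme4's Laplace approximation
#' (`nAGQ = 1`) or its faster penalized-likelihood step (`nAGQ = 0`), with
#' the bobyqa optimizer. Duration is omitted as a fixed effect by default and
#' available via `duration_term`.
#'
#' @param trials trial table (`subject_id`, `image_id`, `response`, and
#'   `duration_ms` when `duration_term = TRUE`).
#' @param scores optional image score table supplying `memorability` and `A`.
#' @param fixed character subset of
#'   `c("memorability", "speed", "interaction")`.
#' @param random `"intercept"`, `c("intercept", "speed")`, or `"none"`
#'   (plain logistic regression).
#' @param duration_term include standardized log duration as a fixed effect.
#' @param nAGQ integration setting passed to [lme4::glmer()].
#' @return an object of class `glmm_fit`: coefficient table (`estimate`,
#'   `se`, `z`), random-effect SDs, `loglik`, `npar`, `n_obs`, `converged`,
#'   the fitted model object, and the term specification.
#' @export
fit_choice_glmm <- function(trials, scores = NULL,
                            fixed = c("memorability", "speed", "interaction"),
                            random = c("intercept", "speed"),
                            duration_term = FALSE, nAGQ = 1L) {
  if (length(fixed))
    fixed <- match.arg(fixed, several.ok = TRUE)
  else fixed <- character(0)   # intercept-only model (LR-test baseline)
  if ("interaction" %in% fixed &&
      !all(c("memorability", "speed") %in% fixed))
    stop("interaction requires both main effects", call. = FALSE)
  d <- merge_covariates(as.data.frame(trials), scores)
  d$y <- as.integer(d$response == "long")
  if (length(unique(d$y)) < 2L)
    stop("response is constant: complete separation", call. = FALSE)
  if (length(unique(d$subject_id)) < 2L && !identical(random, "none"))
    stop("need at least 2 subjects for random effects", call. = FALSE)
  if (duration_term) {
    grid <- sort(unique(d$duration_ms))
    d$z_dur <- (log(d$duration_ms) - mean(log(grid))) / stats::sd(log(grid))
  }
  terms <- c(if (duration_term) "z_dur",
             if ("memorability" %in% fixed) "mem_c",
             if ("speed" %in% fixed) "A_c",
             if ("interaction" %in% fixed) "mem_c:A_c")
  rhs <- if (length(terms)) paste(terms, collapse = " + ") else "1"
  if (identical(random, "none")) {
    f <- stats::as.formula(paste("y ~", rhs))
    m <- stats::glm(f, family = stats::binomial(), data = d)
    ct <- summary(m)$coefficients
    fit <- list(coefficients = data.frame(term = rownames(ct),
                                          estimate = ct[, 1L], se = ct[, 2L],
                                          z = ct[, 3L], row.names = NULL),
                random_effect_sds = numeric(0),
                loglik = as.numeric(stats::logLik(m)),
                npar = attr(stats::logLik(m), "df"),
                n_obs = nrow(d), converged = m$converged,
                fixed_terms = terms, random = "none", model = m)
  } else {
    rterms <- if (identical(random, "intercept") ||
                  identical(random, c("intercept"))) "1"
              else if (setequal(random, c("intercept", "speed")))
                "1 + A_c"
              else stop("unsupported random spec", call. = FALSE)
    f <- stats::as.formula(
      paste0("y ~ ", rhs, " + (", rterms, " | subject_id)"))
    m <- lme4::glmer(f, data = d, family = stats::binomial(), nAGQ = nAGQ,
                     control = lme4::glmerControl(optimizer = "bobyqa",
                                                  calc.derivs = FALSE))
    ct <- summary(m)$coefficients
    vc <- as.data.frame(lme4::VarCorr(m))
    sds <- stats::setNames(vc$sdcor[is.na(vc$var2)],
                           paste0(vc$grp[is.na(vc$var2)], ".",
                                  vc$var1[is.na(vc$var2)]))
    msgs <- m@optinfo$conv$lme4$messages
    conv <- m@optinfo$conv$opt == 0 &&
      (is.null(msgs) || !any(grepl("failed to converge", msgs)))
    fit <- list(coefficients = data.frame(term = rownames(ct),
                                          estimate = ct[, 1L], se = ct[, 2L],
                                          z = ct[, 3L], row.names = NULL),
                random_effect_sds = sds,
                loglik = as.numeric(stats::logLik(m)),
                npar = attr(stats::logLik(m), "df"),
                n_obs = nrow(d), converged = conv,
                fixed_terms = terms, random = random, model = m)
  }
  class(fit) <- "glmm_fit"
  fit
}

#' @export
print.glmm_fit <- function(x, ...) {
  cat(sprintf("<glmm_fit> %d obs, logLik %.2f, %s\n", x$n_obs, x$loglik,
              if (x$converged) "converged" else "NOT converged"))
  print(x$coefficients, digits = 4)
  if (length(x$random_effect_sds)) {
    cat("random-effect SDs:\n")
    print(round(x$random_effect_sds, 4))
  }
  invisible(x)
}

#' Container for a single test statistic
#'
#' @param statistic_name one of `"chi_square"`, `"F"`, `"t"`.
#' @param value the statistic (chi-square and F must be >= 0).
#' @param df degrees of freedom (length 1 or 2).
#' @param p p value in `[0, 1]`.
#' @param correction `"none"` or `"bonferroni"`.
#' @param ... extra named scalars (e.g. `partial_eta_sq`, `cohens_d`).
#' @return an object of class `stat_result`.
#' @export
stat_result <- function(statistic_name, value, df, p, correction = "none",
                        ...) {
  stopifnot(p >= 0, p <= 1)
  if (statistic_name %in% c("chi_square", "F") && value < 0)
    stop(statistic_name, " must be >= 0", call. = FALSE)
  structure(c(list(statistic_name = statistic_name, value = value, df = df,
                   p = p, correction = correction), list(...)),
            class = "stat_result")
}

#' @export
print.stat_result <- function(x, ...) {
  cat(sprintf("<stat_result> %s(%s) = %.4g, p = %.4g%s\n", x$statistic_name,
              paste(signif(x$df, 6), collapse = ", "), x$value, x$p,
              if (x$correction != "none") paste0(" (", x$correction, ")")
              else ""))
  invisible(x)
}

#' Nested likelihood-ratio (chi-square) test between two fits
#'
#' @param full,reduced `glmm_fit` objects on the same data; the reduced
#'   model's fixed terms must be a strict subset of the full model's.
#' @return a `stat_result` with `statistic_name = "chi_square"`.
#' @export
lr_test <- function(full, reduced) {
  stopifnot(inherits(full, "glmm_fit"), inherits(reduced, "glmm_fit"))
  if (full$n_obs != reduced$n_obs)
    stop("models were fit to different data (n_obs differ)", call. = FALSE)
  if (!all(reduced$fixed_terms %in% full$fixed_terms))
    stop("models are not nested: reduced has terms absent from full",
         call. = FALSE)
  df <- full$npar - reduced$npar
  if (df == 0 && setequal(full$fixed_terms, reduced$fixed_terms)) {
    # identical specifications: the null comparison
    return(stat_result("chi_square", 0, 0, 1))
  }
  if (df <= 0)
    stop("models are not nested: full model has no extra parameters",
         call. = FALSE)
  chi2 <- max(0, 2 * (full$loglik - reduced$loglik))
  stat_result("chi_square", chi2, df,
              stats::pchisq(chi2, df, lower.tail = FALSE))
}

#' Binned psychometric surface of "long" responses
#'
#' Bins memorability and "speediness" (`-A_c`: standardized collapse rate,
#' sign flipped so larger = faster) into equal-width bins over their observed
#' ranges and records the pooled proportion of "long" responses per cell,
#' cell counts, and per-subject means for error bands. Set `n_mem_bins = 0`
#' for a speed-only layout (e.g. the 11-bin combined curve).
#'
#' @param trials trial table.
#' @param scores optional image score table with covariates.
#' @param n_mem_bins number of memorability bins (0 or `NULL` = speed only).
#' @param n_speed_bins number of speed bins.
#' @return an object of class `binned_surface`.
#' @export
binned_psychometric <- function(trials, scores = NULL, n_mem_bins = 7L,
                                n_speed_bins = 7L) {
  d <- merge_covariates(as.data.frame(trials), scores)
  d$y <- as.integer(d$response == "long")
  d$speed <- -d$A_c
  speed_only <- is.null(n_mem_bins) || n_mem_bins < 1L
  sedges <- seq(min(d$speed), max(d$speed), length.out = n_speed_bins + 1L)
  sbin <- assign_memorability_bins(d$speed, n_speed_bins,
                                   sedges[1L], sedges[n_speed_bins + 1L])
  subs <- sort(unique(d$subject_id))
  if (speed_only) {
    mean_ <- counts <- rep(NA_real_, n_speed_bins)
    subj <- matrix(NA_real_, length(subs), n_speed_bins,
                   dimnames = list(subs, NULL))
    for (j in seq_len(n_speed_bins)) {
      i <- which(sbin == j)
      counts[j] <- length(i)
      if (length(i)) mean_[j] <- mean(d$y[i])
      for (s in seq_along(subs)) {
        k <- i[d$subject_id[i] == subs[s]]
        if (length(k)) subj[s, j] <- mean(d$y[k])
      }
    }
    out <- list(layout = "speed_only", speed_edges = sedges,
                speed_centers = (sedges[-1L] + sedges[-length(sedges)]) / 2,
                mem_edges = NULL, mem_centers = NULL,
                cell_means = mean_, cell_counts = counts,
                subject_means = subj)
  } else {
    medges <- seq(min(d$memorability), max(d$memorability),
                  length.out = n_mem_bins + 1L)
    if (medges[1L] == medges[n_mem_bins + 1L])
      stop("memorability is constant; use a speed-only layout",
           call. = FALSE)
    mbin <- assign_memorability_bins(d$memorability, n_mem_bins,
                                     medges[1L], medges[n_mem_bins + 1L])
    mean_ <- counts <- matrix(NA_real_, n_mem_bins, n_speed_bins)
    for (i in seq_len(n_mem_bins)) for (j in seq_len(n_speed_bins)) {
      k <- which(mbin == i & sbin == j)
      counts[i, j] <- length(k)
      if (length(k)) mean_[i, j] <- mean(d$y[k])
    }
    out <- list(layout = "mem_by_speed", speed_edges = sedges,
                speed_centers = (sedges[-1L] + sedges[-length(sedges)]) / 2,
                mem_edges = medges,
                mem_centers = (medges[-1L] + medges[-length(medges)]) / 2,
                cell_means = mean_, cell_counts = counts,
                subject_means = NULL)
  }
  structure(out, class = "binned_surface")
}

#' Fit the inverted-U quadratic to a speed-only psychometric curve
#'
#' Weighted least squares of the per-bin proportions on `(1, s, s^2)` with
#' weights equal to cell counts. The quadratic `c0 + c1 s + c2 s^2` is
#' reported in vertex form: `M1 = -c2`, `M2 = -c1 / (2 c2)` (vertex
#' location), `M3 = c0 - c1^2 / (4 c2)` (vertex height). If the fitted
#' curvature is not negative the fit is flagged (`inverted_u = FALSE`); the
#' parameters are still reported.
#'
#' @param surface a speed-only `binned_surface` (>= 4 non-missing bins).
#' @return an object of class `inverted_u_fit`: `M1`, `M2`, `M3`,
#'   `inverted_u` flag, `rss` (weighted), and the raw polynomial
#'   coefficients.
#' @export
fit_inverted_u <- function(surface) {
  stopifnot(inherits(surface, "binned_surface"))
  if (surface$layout != "speed_only")
    stop("fit_inverted_u needs a speed-only surface", call. = FALSE)
  ok <- !is.na(surface$cell_means) & surface$cell_counts > 0
  if (sum(ok) < 4L)
    stop("need at least 4 non-missing bins", call. = FALSE)
  x <- surface$speed_centers[ok]
  y <- surface$cell_means[ok]
  w <- surface$cell_counts[ok]
  m <- stats::lm(y ~ x + I(x^2), weights = w)
  co <- stats::coef(m)
  c0 <- co[[1L]]; c1 <- co[[2L]]; c2 <- co[[3L]]
  concave <- is.finite(c2) && c2 < 0
  structure(list(M1 = -c2,
                 M2 = if (c2 != 0) -c1 / (2 * c2) else NA_real_,
                 M3 = if (c2 != 0) c0 - c1^2 / (4 * c2) else NA_real_,
                 inverted_u = concave,
                 rss = sum(w * stats::residuals(m)^2),
                 poly = c(c0 = c0, c1 = c1, c2 = c2)),
            class = "inverted_u_fit")
}

#' @export
print.inverted_u_fit <- function(x, ...) {
  cat(sprintf(
    "<inverted_u_fit> M1 = %.4g, M2 = %.4g, M3 = %.4g (%s), rss = %.3g\n",
    x$M1, x$M2, x$M3,
    if (x$inverted_u) "inverted-U" else "NO inverted-U: curvature >= 0",
    x$rss))
  invisible(x)
}

#' Summarize recognition performance per stimulus bin
#'
#' Hit rate is the proportion of old items endorsed "old". Per-bin hit rates
#' are subject means averaged across subjects; the spread is the range
#' (max - min) of those bin means.
#'
#' @param recog recognition table (`subject_id`, `bin`, `is_old`,
#'   `response`).
#' @return an object of class `recognition_summary`: `bin_hit_rates`,
#'   `spread`, `overall_hit_rate`, `fa_rate`, and the subjects-by-bins
#'   `subject_matrix`.
#' @export
recognition_summary <- function(recog) {
  d <- as.data.frame(recog)
  old <- d[d$is_old == 1L, , drop = FALSE]
  if (!nrow(old)) stop("no old items", call. = FALSE)
  subs <- sort(unique(old$subject_id))
  bins <- sort(unique(old$bin))
  mat <- matrix(NA_real_, length(subs), length(bins),
                dimnames = list(subs, paste0("bin", bins)))
  hit <- old$response == "old"
  for (s in seq_along(subs)) for (b in seq_along(bins)) {
    i <- old$subject_id == subs[s] & old$bin == bins[b]
    if (any(i)) mat[s, b] <- mean(hit[i])
  }
  bin_means <- colMeans(mat, na.rm = TRUE)
  bin_means[is.nan(bin_means)] <- NA_real_
  foil <- d[d$is_old == 0L, , drop = FALSE]
  structure(list(
    bin_hit_rates = bin_means,
    spread = if (all(is.na(bin_means))) NA_real_
             else max(bin_means, na.rm = TRUE) - min(bin_means, na.rm = TRUE),
    overall_hit_rate = mean(hit),
    fa_rate = if (nrow(foil)) mean(foil$response == "old") else NA_real_,
    subject_matrix = mat), class = "recognition_summary")
}

#' @export
print.recognition_summary <- function(x, ...) {
  cat(sprintf("<recognition_summary> overall hit %.3f, spread %.3f, FA %.3f\n",
              x$overall_hit_rate, x$spread, x$fa_rate))
  print(round(x$bin_hit_rates, 3))
  invisible(x)
}

#' One-way repeated-measures ANOVA over a subjects-by-bins matrix
#'
#' Subject is the blocking factor: `F = MS_bin / MS_error` with
#' `df = (b - 1, (b - 1)(n - 1))`, and partial eta squared
#' `SS_bin / (SS_bin + SS_error)`. Rows containing `NA` are dropped listwise.
#'
#' @param mat numeric matrix, subjects in rows, bins in columns.
#' @return a `stat_result` with `statistic_name = "F"` and
#'   `partial_eta_sq`.
#' @export
rm_anova <- function(mat) {
  mat <- as.matrix(mat)
  mat <- mat[stats::complete.cases(mat), , drop = FALSE]
  n <- nrow(mat); b <- ncol(mat)
  if (n < 2L) stop("need at least 2 complete subjects", call. = FALSE)
  if (b < 2L) stop("need at least 2 bins", call. = FALSE)
  grand <- mean(mat)
  ss_bin <- n * sum((colMeans(mat) - grand)^2)
  ss_subj <- b * sum((rowMeans(mat) - grand)^2)
  ss_tot <- sum((mat - grand)^2)
  ss_err <- ss_tot - ss_bin - ss_subj
  df1 <- b - 1L
  df2 <- (b - 1L) * (n - 1L)
  ms_err <- ss_err / df2
  f <- if (ms_err > 0) (ss_bin / df1) / ms_err else
    if (ss_bin == 0) 0 else Inf
  p <- if (is.finite(f)) stats::pf(f, df1, df2, lower.tail = FALSE) else 0
  stat_result("F", f, c(df1, df2), p,
              partial_eta_sq = if (ss_bin + ss_err > 0)
                ss_bin / (ss_bin + ss_err) else 0)
}

#' Pairwise group contrasts with Bonferroni correction
#'
#' Independent-samples pooled-variance t tests over all group pairs; p values
#' are multiplied by the number of comparisons (capped at 1) and Cohen's D is
#' the mean difference over the pooled SD.
#'
#' @param values numeric per-subject scores (e.g. mean hit rates).
#' @param groups group labels, same length as `values`.
#' @return data frame with one row per pair: `group1`, `group2`, `t`, `df`,
#'   `p`, `p_corrected`, `cohens_d`, and a `stat_results` attribute holding
#'   the corresponding `stat_result` objects.
#' @export
group_contrast <- function(values, groups) {
  stopifnot(length(values) == length(groups))
  gs <- sort(unique(as.character(groups)))
  if (length(gs) < 2L) stop("need at least 2 groups", call. = FALSE)
  sizes <- table(groups)
  if (any(sizes < 2L))
    stop("every group needs at least 2 subjects", call. = FALSE)
  pairs <- utils::combn(gs, 2L)
  m <- ncol(pairs)
  rows <- vector("list", m)
  stats_list <- vector("list", m)
  for (k in seq_len(m)) {
    g1 <- pairs[1L, k]; g2 <- pairs[2L, k]
    x <- values[groups == g1]; y <- values[groups == g2]
    n1 <- length(x); n2 <- length(y)
    sp2 <- ((n1 - 1) * stats::var(x) + (n2 - 1) * stats::var(y)) /
      (n1 + n2 - 2)
    se <- sqrt(sp2 * (1 / n1 + 1 / n2))
    tval <- if (se > 0) (mean(x) - mean(y)) / se else 0
    df <- n1 + n2 - 2
    p <- 2 * stats::pt(abs(tval), df, lower.tail = FALSE)
    pc <- min(1, p * m)
    d <- if (sp2 > 0) (mean(x) - mean(y)) / sqrt(sp2) else 0
    rows[[k]] <- data.frame(group1 = g1, group2 = g2, t = tval, df = df,
                            p = p, p_corrected = pc, cohens_d = d,
                            stringsAsFactors = FALSE)
    stats_list[[k]] <- stat_result("t", tval, df, pc,
                                   correction = "bonferroni", cohens_d = d)
  }
  out <- do.call(rbind, rows)
  attr(out, "stat_results") <- stats_list
  out
}
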