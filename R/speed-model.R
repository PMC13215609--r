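# Power-law model of entropy collapse, E_T = A * T^B + C. A is the "speed"
# proxy: negative for declining traces, more negative = faster collapse.

#' Evaluate the entropy-collapse power curve
#'
#' @param A,B,C curve parameters; `A` is the collapse rate, `B >= 0` the
#'   exponent, `C` the asymptote (nats).
#' @param n_timesteps number of timesteps; the curve is evaluated at
#'   `T = 1..n_timesteps`.
#' @return numeric vector of length `n_timesteps`.
#' @export
power_trace <- function(A, B, C, n_timesteps = 8L) {
  t <- seq_len(n_timesteps)
  A * t^B + C
}

#' Fit the entropy-collapse power curve by profiled least squares
#'
#' For fixed `B` the model `A * T^B + C` is linear in `(A, C)`, so the sum of
#' squares is profiled exactly: a deterministic multi-start grid over `B >= 0`
#' followed by golden-section refinement gives the global solution without the
#' ill-conditioned joint 3-parameter search (small `A` trades against large
#' `B`). The procedure involves no randomness.
#'
#' @param trace numeric entropy trace (length >= 4) or `entropy_trace`.
#' @param b_grid multi-start grid of exponent values.
#' @param b_max upper search bound for `B`.
#' @return an object of class `power_fit`: list with `A`, `B`, `C`, `rss`,
#'   `converged`, `n_starts_used`, `fitted`, `image_id`.
#' @export
fit_power_curve <- function(trace, b_grid = c(0.1, 0.25, 0.5, 1, 2, 4, 6),
                            b_max = 8) {
  id <- attr(trace, "image_id")
  y <- as.numeric(trace)
  n <- length(y)
  if (n < 4L)
    stop("trace must have at least 4 points (3 parameters + 1 df)",
         call. = FALSE)
  if (anyNA(y)) stop("trace contains NA", call. = FALSE)
  t <- seq_len(n)

  solve_b <- function(b) {
    # exact (A, C) for fixed exponent; guard the near-collinear b ~ 0 case
    x <- t^b
    fit <- stats::lm.fit(cbind(x, 1), y)
    co <- fit$coefficients
    if (anyNA(co)) return(list(rss = Inf, A = NA_real_, C = NA_real_))
    list(rss = sum(fit$residuals^2), A = co[[1L]], C = co[[2L]])
  }

  if (stats::sd(y) < 1e-12) {
    # constant trace: flat curve, A = 0 exactly
    fit <- structure(list(A = 0, B = 1, C = mean(y), rss = 0,
                          converged = TRUE, n_starts_used = 0L,
                          fitted = rep(mean(y), n), image_id = id),
                     class = "power_fit")
    return(fit)
  }

  b_grid <- sort(unique(pmin(pmax(b_grid, 1e-3), b_max)))
  rss_grid <- vapply(b_grid, function(b) solve_b(b)$rss, numeric(1))
  best <- which.min(rss_grid)
  lo <- if (best > 1L) b_grid[best - 1L] else 1e-3
  hi <- if (best < length(b_grid)) b_grid[best + 1L] else b_max
  opt <- stats::optimize(function(b) solve_b(b)$rss, c(lo, hi), tol = 1e-12)
  # the bracket from the coarse grid can miss the basin; keep the better one
  cand <- if (opt$objective <= rss_grid[best]) opt$minimum else b_grid[best]
  sol <- solve_b(cand)
  if (!is.finite(sol$rss)) {
    return(structure(list(A = NA_real_, B = NA_real_, C = NA_real_,
                          rss = Inf, converged = FALSE,
                          n_starts_used = length(b_grid),
                          fitted = rep(NA_real_, n), image_id = id),
                     class = "power_fit"))
  }
  structure(list(A = sol$A, B = cand, C = sol$C, rss = sol$rss,
                 converged = TRUE, n_starts_used = length(b_grid),
                 fitted = sol$A * t^cand + sol$C, image_id = id),
            class = "power_fit")
}

#' @export
print.power_fit <- function(x, ...) {
  cat(sprintf("<power_fit> A = %.6g, B = %.4g, C = %.4g, rss = %.3g (%s)\n",
              x$A, x$B, x$C, x$rss,
              if (x$converged) "converged" else "NOT converged"))
  invisible(x)
}

#' Order fits from fastest to slowest collapse
#'
#' Lower (more negative) `A` means faster entropy collapse, i.e. a "faster"
#' image. Ties on `A` are broken by lexicographic image id, so the ordering is
#' invariant to input order.
#'
#' @param fits list of `power_fit` objects, or a numeric vector of `A` values.
#' @param ids image identifiers; defaults to the fits' own ids.
#' @return integer permutation of `seq_along(fits)`, fastest first.
#' @export
speed_order <- function(fits, ids = NULL) {
  if (is.numeric(fits)) {
    A <- fits
    if (is.null(ids)) ids <- sprintf("img%05d", seq_along(A))
  } else {
    bad <- vapply(fits, function(f) !isTRUE(f$converged), logical(1))
    if (any(bad))
      stop("unconverged fits: ",
           paste(vapply(fits[bad], function(f)
             if (is.null(f$image_id)) "<unnamed>" else f$image_id,
             character(1)), collapse = ", "), call. = FALSE)
    A <- vapply(fits, function(f) f$A, numeric(1))
    if (is.null(ids))
      ids <- vapply(fits, function(f)
        if (is.null(f$image_id)) "" else f$image_id, character(1))
  }
  order(A, ids)
}

#' Configure the entropy-threshold duration-categorization proxy
#'
#' Maps a probe duration onto a recurrent timestep (the 7 log-spaced
#' durations map linearly onto timesteps 2..8 by default) and classifies the
#' duration "long" when the entropy at the probe timestep has already fallen
#' to or below the threshold.
#'
#' @param threshold entropy threshold in nats, strictly inside `(0, ln K)`.
#' @param n_classes softmax width `K` used for the upper bound check.
#' @param durations the duration grid (ms).
#' @param timesteps probe timesteps, one per grid duration.
#' @return an object of class `proxy_config`.
#' @export
proxy_config <- function(threshold, n_classes = 100L,
                         durations = make_duration_grid(),
                         timesteps = seq.int(2L, length(durations) + 1L)) {
  if (threshold <= 0 || threshold >= log(n_classes))
    stop(sprintf("threshold must lie in (0, ln K) = (0, %.4f)",
                 log(n_classes)), call. = FALSE)
  stopifnot(length(durations) == length(timesteps), all(timesteps >= 1L))
  structure(list(threshold = threshold, n_classes = as.integer(n_classes),
                 durations = durations, timesteps = as.integer(timesteps)),
            class = "proxy_config")
}

#' Categorize a duration as "short" or "long" via the entropy proxy
#'
#' @param trace entropy trace.
#' @param cfg a [proxy_config()].
#' @param duration_ms probe duration; snapped to the nearest grid duration in
#'   log space.
#' @return `"long"` if the entropy at the probe timestep is `<=` threshold
#'   (the collapse has already happened when the probe arrives), else
#'   `"short"`. A value exactly at threshold counts as "long".
#' @export
proxy_categorize <- function(trace, cfg, duration_ms) {
  stopifnot(inherits(cfg, "proxy_config"))
  y <- as.numeric(trace)
  k <- which.min(abs(log(duration_ms) - log(cfg$durations)))
  probe <- cfg$timesteps[k]
  if (probe > length(y))
    stop("probe timestep exceeds trace length", call. = FALSE)
  if (y[probe] <= cfg$threshold) "long" else "short"
}
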