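# Independent brute-force oracles used across the suite. These deliberately
# re-derive results by enumeration or textbook formulas, not by calling the
# code paths they check.

# selection sort of (A, id) pairs: fastest (most negative A) first
oracle_speed_order <- function(A, ids) {
  n <- length(A)
  remaining <- seq_len(n)
  out <- integer(0)
  while (length(remaining)) {
    best <- remaining[1L]
    for (j in remaining[-1L]) {
      if (A[j] < A[best] || (A[j] == A[best] && ids[j] < ids[best]))
        best <- j
    }
    out <- c(out, best)
    remaining <- setdiff(remaining, best)
  }
  out
}

# brute-force extreme-speed selection: explicit per-bin loop over sorted rows
oracle_select_extreme <- function(records, n_bins, lo, hi, total,
                                  direction) {
  w <- (hi - lo) / n_bins
  quota <- total %/% n_bins
  extra <- total %% n_bins
  picked <- character(0)
  for (b in seq_len(n_bins)) {
    q <- quota + as.integer(b <= extra)
    in_bin <- character(0)
    a_bin <- numeric(0)
    for (i in seq_len(nrow(records))) {
      m <- records$memorability[i]
      bi <- if (m == hi) n_bins else floor((m - lo) / w) + 1
      if (!is.na(bi) && m >= lo && m <= hi && bi == b) {
        in_bin <- c(in_bin, records$image_id[i])
        a_bin <- c(a_bin, records$A[i])
      }
    }
    if (length(in_bin) < q) stop("oracle: under-filled bin ", b)
    ord <- if (direction == "slow") order(-a_bin, in_bin)
           else order(a_bin, in_bin)
    picked <- c(picked, in_bin[ord[seq_len(q)]])
  }
  picked
}

# brute-force constant-memorability selection (band filter + A bins,
# bin 1 = slowest i.e. highest A)
oracle_select_constmem <- function(records, n_bins, center, tol, total) {
  band <- records[abs(records$memorability - center) <= tol, , drop = FALSE]
  lo <- min(band$A); hi <- max(band$A)
  w <- (hi - lo) / n_bins
  quota <- total %/% n_bins
  extra <- total %% n_bins
  picked <- character(0)
  for (b in seq_len(n_bins)) {
    q <- quota + as.integer(b <= extra)
    ids <- character(0); a <- numeric(0)
    for (i in seq_len(nrow(band))) {
      x <- band$A[i]
      bi <- if (x == hi) n_bins else floor((x - lo) / w) + 1
      bi <- n_bins + 1 - bi   # flip so bin 1 = slowest
      if (bi == b) { ids <- c(ids, band$image_id[i]); a <- c(a, band$A[i]) }
    }
    if (length(ids) < q) stop("oracle: under-filled A bin ", b)
    ord <- order(-a, ids)
    picked <- c(picked, ids[ord[seq_len(q)]])
  }
  picked
}

# iteratively reweighted least squares for logistic regression
oracle_irls_logit <- function(X, y, tol = 1e-12, max_iter = 100) {
  beta <- rep(0, ncol(X))
  for (it in seq_len(max_iter)) {
    eta <- drop(X %*% beta)
    mu <- 1 / (1 + exp(-eta))
    w <- mu * (1 - mu)
    z <- eta + (y - mu) / w
    beta_new <- solve(crossprod(X, w * X), crossprod(X, w * z))
    if (max(abs(beta_new - beta)) < tol) return(drop(beta_new))
    beta <- drop(beta_new)
  }
  beta
}

# textbook one-way repeated-measures decomposition via explicit double loops
oracle_rm_anova <- function(mat) {
  n <- nrow(mat); b <- ncol(mat)
  grand <- mean(mat)
  ss_bin <- 0
  for (j in seq_len(b)) ss_bin <- ss_bin + n * (mean(mat[, j]) - grand)^2
  ss_subj <- 0
  for (i in seq_len(n)) ss_subj <- ss_subj + b * (mean(mat[i, ]) - grand)^2
  ss_tot <- 0
  for (i in seq_len(n)) for (j in seq_len(b))
    ss_tot <- ss_tot + (mat[i, j] - grand)^2
  ss_err <- ss_tot - ss_bin - ss_subj
  f <- (ss_bin / (b - 1)) / (ss_err / ((b - 1) * (n - 1)))
  list(F = f, df = c(b - 1, (b - 1) * (n - 1)),
       eta = ss_bin / (ss_bin + ss_err))
}

# random toy score table for sampler property tests
random_toy_table <- function(n, seed) {
  set.seed(seed)
  data.frame(image_id = sprintf("t%03d", sample.int(999, n)),
             memorability = round(runif(n, 0.2, 1), 3),
             A = round(rnorm(n), 3),
             stringsAsFactors = FALSE)
}

# small standard stimulus set used by behavior/inference tests: 196 images
# spanning memorability and A
toy_stimuli <- function(seed = 42, n = 196) {
  set.seed(seed)
  rec <- data.frame(image_id = sprintf("img%03d", seq_len(n)),
                    memorability = runif(n, 0.2, 1),
                    A = runif(n, -1, 1) * 1e-5 - 2e-5,
                    bin = rep(1:7, length.out = n),
                    stringsAsFactors = FALSE)
  structure(list(test = rec$image_id, foil = character(0), bins = NULL,
                 records = rec),
            class = "stimulus_set")
}

# full test + foil stimulus set (196 + 196) with bin-ordered speeds, as the
# recognition generator expects
toy_recog_stimuli <- function(seed = 43) {
  set.seed(seed)
  n <- 392
  rec <- data.frame(image_id = sprintf("rimg%03d", seq_len(n)),
                    memorability = runif(n, 0.2, 1),
                    A = runif(n, -1, 1) * 1e-5 - 2e-5,
                    bin = rep(rep(1:7, each = 28), 2),
                    stringsAsFactors = FALSE)
  structure(list(test = rec$image_id[1:196], foil = rec$image_id[197:392],
                 bins = stats::setNames(rec$bin, rec$image_id),
                 records = rec),
            class = "stimulus_set")
}
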