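# Stimulus sampling: the three selection strategies over an
# (image_id, memorability, A) score table, plus the 392 -> 196 + 196
# test/foil split.

#' Describe a sampling strategy
#'
#' @param strategy one of `"slow_speed"` (per memorability bin, take the
#'   slowest images, i.e. highest `A`), `"constant_memorability"` (hold
#'   memorability at 0.5 and span the `A` range in 7 equal-width bins), or
#'   `"high_speed_memorability"` (per memorability bin, take the fastest
#'   images, i.e. most negative `A`).
#' @param n_bins number of bins (memorability bins, or `A` bins for the
#'   constant-memorability strategy).
#' @param mem_range memorability range sampled for the bin partition.
#' @param total total number of images selected before the test/foil split.
#' @param mem_center memorability level held constant
#'   (constant-memorability only).
#' @param mem_tolerance half-width of the memorability band accepted around
#'   `mem_center`; scores are continuous, so exact equality is unrealistic.
#' @return an object of class `sampling_plan`.
#' @export
sampling_plan <- function(strategy = c("slow_speed", "constant_memorability",
                                       "high_speed_memorability"),
                          n_bins = 7L, mem_range = c(0.2, 1.0),
                          total = 392L, mem_center = 0.5,
                          mem_tolerance = 0.005) {
  strategy <- match.arg(strategy)
  if (n_bins < 1L) stop("n_bins must be >= 1", call. = FALSE)
  stopifnot(mem_range[1L] < mem_range[2L], total >= n_bins,
            mem_tolerance >= 0)
  structure(list(strategy = strategy, n_bins = as.integer(n_bins),
                 mem_range = as.numeric(mem_range), total = as.integer(total),
                 mem_center = mem_center, mem_tolerance = mem_tolerance),
            class = "sampling_plan")
}

# per-bin quotas: equal split, remainder (if any) to the lowest-index bins
bin_quotas <- function(total, n_bins) {
  q <- rep(total %/% n_bins, n_bins)
  r <- total %% n_bins
  if (r > 0) q[seq_len(r)] <- q[seq_len(r)] + 1L
  q
}

#' Assign records to equal-width bins on a covariate range
#'
#' Intervals are half-open `[edge_i, edge_{i+1})` except the last, which is
#' closed at `hi`. Values outside `[lo, hi]` get `NA` and are counted in the
#' `n_excluded` attribute.
#'
#' @param x numeric values (e.g. memorability scores).
#' @param n_bins number of bins.
#' @param lo,hi range endpoints, `lo < hi`.
#' @return integer vector of bin indices in `1..n_bins` (NA outside range)
#'   with attribute `n_excluded`.
#' @export
assign_memorability_bins <- function(x, n_bins = 7L, lo = 0.2, hi = 1.0) {
  if (n_bins < 1L) stop("n_bins must be >= 1", call. = FALSE)
  if (!(lo < hi)) stop("need lo < hi", call. = FALSE)
  if (length(x) < 1L) stop("no records", call. = FALSE)
  w <- (hi - lo) / n_bins
  b <- floor((x - lo) / w) + 1L
  b[x == hi] <- n_bins           # closed upper boundary
  out <- x < lo | x > hi
  b[out] <- NA_integer_
  b <- as.integer(pmin(b, n_bins))   # guard fp spill just under hi
  attr(b, "n_excluded") <- sum(out)
  b
}

# rows of df sorted by A (direction "slow" = descending A, "fast" =
# ascending), ties by image_id; returns the first `quota` image_ids
take_extreme <- function(df, quota, direction) {
  ord <- if (direction == "slow") order(-df$A, df$image_id)
         else order(df$A, df$image_id)
  df$image_id[ord[seq_len(quota)]]
}

validate_records <- function(records) {
  need <- c("image_id", "memorability", "A")
  miss <- setdiff(need, names(records))
  if (length(miss))
    stop("score table lacks column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  if (anyDuplicated(records$image_id))
    stop("duplicate image_id in score table", call. = FALSE)
  if (any(records$memorability < 0 | records$memorability > 1))
    stop("memorability outside [0, 1]", call. = FALSE)
  records
}

#' Select stimuli at a speed extreme within each memorability bin
#'
#' Implements the slow-speed strategy (per memorability bin, the images with
#' the highest `A`, i.e. slowest collapse) and the
#' high-speed-plus-memorability strategy (the most negative `A`, i.e. fastest)
#' over equal-count quotas per bin.
#'
#' @param records data frame with columns `image_id`, `memorability`, `A`.
#' @param plan a [sampling_plan()] with strategy `"slow_speed"` or
#'   `"high_speed_memorability"`.
#' @return data frame of selected records with a `bin` column, ready for
#'   [split_test_foil()].
#' @export
select_extreme_speed <- function(records, plan) {
  stopifnot(inherits(plan, "sampling_plan"))
  if (!plan$strategy %in% c("slow_speed", "high_speed_memorability"))
    stop("plan strategy must be slow_speed or high_speed_memorability",
         call. = FALSE)
  records <- validate_records(records)
  direction <- if (plan$strategy == "slow_speed") "slow" else "fast"
  bins <- assign_memorability_bins(records$memorability, plan$n_bins,
                                   plan$mem_range[1L], plan$mem_range[2L])
  quotas <- bin_quotas(plan$total, plan$n_bins)
  picked <- vector("list", plan$n_bins)
  for (b in seq_len(plan$n_bins)) {
    df <- records[which(bins == b), , drop = FALSE]
    if (nrow(df) < quotas[b])
      stop(sprintf("memorability bin %d holds %d records, needs %d",
                   b, nrow(df), quotas[b]), call. = FALSE)
    picked[[b]] <- take_extreme(df, quotas[b], direction)
  }
  sel_ids <- unlist(picked, use.names = FALSE)
  out <- records[match(sel_ids, records$image_id), , drop = FALSE]
  out$bin <- rep(seq_len(plan$n_bins), times = quotas)
  rownames(out) <- NULL
  out
}

#' Select stimuli of constant memorability spanning the speed range
#'
#' Filters to a narrow memorability band around `plan$mem_center`, partitions
#' the band's observed `A` range into `n_bins` equal-width bins, and takes an
#' equal quota per `A` bin (the highest-`A` records of each bin, ties by id).
#' Bin 1 is the slowest (highest `A`), bin `n_bins` the fastest.
#'
#' @param records data frame with columns `image_id`, `memorability`, `A`.
#' @param plan a [sampling_plan()] with strategy `"constant_memorability"`.
#' @return data frame of selected records with a `bin` column (slow -> fast).
#' @export
select_constant_memorability <- function(records, plan) {
  stopifnot(inherits(plan, "sampling_plan"),
            plan$strategy == "constant_memorability")
  records <- validate_records(records)
  band <- records[abs(records$memorability - plan$mem_center) <=
                    plan$mem_tolerance, , drop = FALSE]
  if (nrow(band) < plan$total)
    stop(sprintf(
      "only %d records within %.3g of memorability %.3g, need %d",
      nrow(band), plan$mem_tolerance, plan$mem_center, plan$total),
      call. = FALSE)
  lo <- min(band$A); hi <- max(band$A)
  if (!(lo < hi)) stop("degenerate A range in the memorability band",
                       call. = FALSE)
  abin <- assign_memorability_bins(band$A, plan$n_bins, lo, hi)
  # bin 1 = lowest A = fastest; flip so bin 1 is slowest, matching the
  # slow -> fast bin semantics of the other strategies' recognition axis
  abin <- plan$n_bins + 1L - abin
  quotas <- bin_quotas(plan$total, plan$n_bins)
  picked <- vector("list", plan$n_bins)
  for (b in seq_len(plan$n_bins)) {
    df <- band[which(abin == b), , drop = FALSE]
    if (nrow(df) < quotas[b])
      stop(sprintf("A bin %d holds %d records, needs %d",
                   b, nrow(df), quotas[b]), call. = FALSE)
    picked[[b]] <- take_extreme(df, quotas[b], "slow")
  }
  sel_ids <- unlist(picked, use.names = FALSE)
  out <- band[match(sel_ids, band$image_id), , drop = FALSE]
  out$bin <- rep(seq_len(plan$n_bins), times = quotas)
  rownames(out) <- NULL
  out
}

#' Split a selection into test and foil halves
#'
#' By default the split is stratified within bins (foils were "sampled in the
#' same manner" as test images, implying matched composition): each bin's
#' quota is split as evenly as possible, odd remainders alternating. A plain
#' unstratified random split is available with `stratified = FALSE`.
#'
#' @param selected data frame from a `select_*` function (columns `image_id`,
#'   `bin`, ...), or a character vector of ids (treated as one bin).
#' @param seed integer seed for the permutation.
#' @param stratified split 50/50 within each bin (default) or over the pool.
#' @return an object of class `stimulus_set`: list with `test`, `foil`
#'   (character ids), `bins` (named bin index per id), and `records`.
#' @export
split_test_foil <- function(selected, seed = 1L, stratified = TRUE) {
  if (is.character(selected))
    selected <- data.frame(image_id = selected, bin = 1L,
                           stringsAsFactors = FALSE)
  if (anyDuplicated(selected$image_id))
    stop("duplicate ids in selection", call. = FALSE)
  n <- nrow(selected)
  if (n %% 2L != 0L) stop("selection size must be even", call. = FALSE)
  set.seed(seed)
  test <- character(0)
  if (stratified) {
    extra <- 0L   # alternate which half gets an odd bin's extra item
    for (b in sort(unique(selected$bin))) {
      ids <- selected$image_id[selected$bin == b]
      k <- length(ids) %/% 2L
      if (length(ids) %% 2L == 1L) { k <- k + extra; extra <- 1L - extra }
      test <- c(test, sample(ids)[seq_len(k)])
    }
  } else {
    test <- sample(selected$image_id)[seq_len(n %/% 2L)]
  }
  foil <- setdiff(selected$image_id, test)
  bins <- stats::setNames(selected$bin, selected$image_id)
  structure(list(test = test, foil = foil, bins = bins, records = selected),
            class = "stimulus_set")
}

#' @export
print.stimulus_set <- function(x, ...) {
  cat(sprintf("<stimulus_set> %d test + %d foil images over %d bins\n",
              length(x$test), length(x$foil), length(unique(x$bins))))
  invisible(x)
}

#' Run a sampling strategy end to end
#'
#' @param records score table (`image_id`, `memorability`, `A`, ...).
#' @param plan a [sampling_plan()].
#' @param seed seed for the test/foil split.
#' @param stratified passed to [split_test_foil()].
#' @return a `stimulus_set`.
#' @export
sample_stimuli <- function(records, plan, seed = 1L, stratified = TRUE) {
  sel <- if (plan$strategy == "constant_memorability")
    select_constant_memorability(records, plan)
  else select_extreme_speed(records, plan)
  split_test_foil(sel, seed = seed, stratified = stratified)
}

#' Manifest data frame for a stimulus set
#'
#' @param set a `stimulus_set`.
#' @return data frame `image_id`, `set` (test/foil), `bin`, plus covariates.
#' @export
stimulus_manifest <- function(set) {
  stopifnot(inherits(set, "stimulus_set"))
  df <- set$records
  df$set <- ifelse(df$image_id %in% set$test, "test", "foil")
  df[, c("image_id", "set", "bin",
         intersect(c("memorability", "A", "B", "C"), names(df)))]
}
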