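# CSV schemas, run configuration, seed derivation, and the umbrella pipeline.

table_schemas <- list(
  scores = list(
    image_id = list(type = "character"),
    memorability = list(type = "numeric", range = c(0, 1)),
    A = list(type = "numeric"),
    B = list(type = "numeric", optional = TRUE),
    C = list(type = "numeric", optional = TRUE)),
  trials = list(
    subject_id = list(type = "character"),
    group = list(type = "character", optional = TRUE),
    block = list(type = "integer"),
    trial_index = list(type = "integer"),
    image_id = list(type = "character"),
    duration_ms = list(type = "numeric", range = c(1e-9, Inf)),
    response = list(type = "character", values = c("short", "long")),
    rt_ms = list(type = "numeric", range = c(1e-9, Inf))),
  recognition = list(
    subject_id = list(type = "character"),
    group = list(type = "character", optional = TRUE),
    image_id = list(type = "character"),
    bin = list(type = "integer", optional = TRUE),
    is_old = list(type = "integer", values = 0:1),
    response = list(type = "character", values = c("old", "new")),
    correct = list(type = "integer", values = 0:1, optional = TRUE)))

#' Load and validate a CSV table against a named schema
#'
#' Checks that required columns are present, coerces each to its declared
#' type, and range/level-checks values; failures name the offending column
#' and (for cells) the row. Row order is preserved.
#'
#' @param path CSV file path (comma-separated, header required, UTF-8).
#' @param schema `"scores"`, `"trials"`, `"recognition"`, or a schema list of
#'   the same shape as the built-ins.
#' @return validated data frame.
#' @export
load_table <- function(path, schema) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  if (is.character(schema)) {
    if (!schema %in% names(table_schemas))
      stop("unknown schema: ", schema, call. = FALSE)
    schema <- table_schemas[[schema]]
  }
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = "character", check.names = FALSE)
  required <- names(schema)[!vapply(schema, function(s)
    isTRUE(s$optional), logical(1))]
  miss <- setdiff(required, names(df))
  if (length(miss))
    stop("missing column(s): ", paste(miss, collapse = ", "), call. = FALSE)
  for (col in intersect(names(schema), names(df))) {
    sp <- schema[[col]]
    raw <- df[[col]]
    val <- switch(sp$type,
      character = raw,
      numeric = suppressWarnings(as.numeric(raw)),
      integer = suppressWarnings(as.integer(raw)))
    bad <- which(is.na(val) & !is.na(raw) & raw != "" & raw != "NA")
    if (length(bad))
      stop(sprintf("column '%s': unparseable value '%s' at row %d",
                   col, raw[bad[1L]], bad[1L]), call. = FALSE)
    if (!is.null(sp$range)) {
      out <- which(!is.na(val) & (val < sp$range[1L] | val > sp$range[2L]))
      if (length(out))
        stop(sprintf("column '%s': value %s at row %d outside [%g, %g]",
                     col, format(val[out[1L]]), out[1L],
                     sp$range[1L], sp$range[2L]), call. = FALSE)
    }
    if (!is.null(sp$values)) {
      out <- which(!is.na(val) & !val %in% sp$values)
      if (length(out))
        stop(sprintf("column '%s': disallowed value '%s' at row %d",
                     col, format(val[out[1L]]), out[1L]), call. = FALSE)
    }
    df[[col]] <- val
  }
  df
}

#' Write a table as CSV (the package interchange format)
#'
#' @param df data frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_table <- function(df, path) {
  utils::write.csv(as.data.frame(df), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

run_config_defaults <- function() list(
  seed = 1L,
  strategies = c("slow_speed", "constant_memorability",
                 "high_speed_memorability"),
  score_source = "synthetic",
  images_dir = NULL,
  n_images = 20000L,
  mem_tolerance = 0.02,
  n_subjects_per_group = 20L,
  behavior_model = "logit",
  behavior = list(),
  recognition = list(base_hit = 0.5, spread = 0.17, fa_rate = 0.3),
  network = list(),
  analysis = list(rt_filter_tail = "both", n_mem_bins = 7L,
                  n_speed_bins = 7L, n_speed_bins_combined = 11L,
                  duration_term = FALSE, nAGQ = 0L))

#' Build a validated pipeline configuration
#'
#' Unknown keys are rejected; the object round-trips losslessly through
#' [write_run_config()] / [read_run_config()].
#'
#' @param ... overrides of the defaults: `seed`, `strategies`,
#'   `score_source` (`"synthetic"` or `"images"`), `images_dir`, `n_images`,
#'   `mem_tolerance`, `n_subjects_per_group`, `behavior_model` (`"logit"` or
#'   `"inverted_u"`), `behavior` (arguments to [choice_model_params()]),
#'   `recognition` (`base_hit`, `spread`, `fa_rate`), `network` (arguments to
#'   [network_config()]), `analysis` (`rt_filter_tail`, `n_mem_bins`,
#'   `n_speed_bins`, `n_speed_bins_combined`, `duration_term`, `nAGQ`).
#' @return an object of class `run_config`.
#' @export
run_config <- function(...) {
  cfg <- run_config_defaults()
  ov <- list(...)
  unknown <- setdiff(names(ov), names(cfg))
  if (length(unknown))
    stop("unknown config key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  for (k in names(ov)) {
    if (k %in% c("recognition", "analysis", "behavior", "network") &&
        length(ov[[k]])) {
      sub <- cfg[[k]]
      if (k %in% c("recognition", "analysis")) {
        bad <- setdiff(names(ov[[k]]), names(sub))
        if (length(bad))
          stop("unknown config key(s): ",
               paste(paste0(k, ".", bad), collapse = ", "), call. = FALSE)
      }
      sub[names(ov[[k]])] <- ov[[k]]
      cfg[[k]] <- sub
    } else cfg[[k]] <- ov[[k]]
  }
  stopifnot(cfg$score_source %in% c("synthetic", "images"),
            cfg$behavior_model %in% c("logit", "inverted_u"),
            all(cfg$strategies %in% c("slow_speed", "constant_memorability",
                                      "high_speed_memorability")),
            cfg$n_subjects_per_group >= 1L, cfg$n_images >= 1L)
  cfg$seed <- as.integer(cfg$seed)
  structure(cfg, class = "run_config")
}

#' @rdname run_config
#' @param config a `run_config`.
#' @param path JSON file path.
#' @export
write_run_config <- function(config, path) {
  stopifnot(inherits(config, "run_config"))
  jsonlite::write_json(unclass(config), path, auto_unbox = TRUE,
                       digits = NA, null = "null", pretty = TRUE)
  invisible(path)
}

#' @rdname run_config
#' @export
read_run_config <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  raw <- raw[!vapply(raw, is.null, logical(1))]
  do.call(run_config, raw)
}

# per-stage substreams from one global seed; values stay far below 2^31
derive_seed <- function(seed, stage) {
  stages <- c(scores = 1L, sample = 2L, simulate = 3L, analyze = 4L,
              recognition = 5L)
  if (!stage %in% names(stages)) stop("unknown stage: ", stage)
  as.integer((as.numeric(seed) %% 100003) * 9973 +
               stages[[stage]] * 7919) %% 999999937L
}

strategy_models <- function(strategy) {
  # fixed/random specs per group, mirroring how a constant-memorability set
  # removes memorability from the model
  if (strategy == "constant_memorability")
    list(fixed = "speed", random = "intercept")
  else
    list(fixed = c("memorability", "speed", "interaction"),
         random = c("intercept", "speed"))
}

# nested LR tests dropping one term at a time (interaction from the full
# model; each main effect from the no-interaction model)
term_lr_tests <- function(trials, scores, fixed, random, duration_term,
                          nAGQ) {
  fit1 <- function(fx) fit_choice_glmm(trials, scores, fixed = fx,
                                       random = random,
                                       duration_term = duration_term,
                                       nAGQ = nAGQ)
  rows <- list()
  if ("interaction" %in% fixed) {
    full <- fit1(fixed)
    mains <- setdiff(fixed, "interaction")
    lr <- lr_test(full, fit1(mains))
    rows[["interaction"]] <- c(term = "interaction", chi_square = lr$value,
                               df = lr$df, p = lr$p)
    base <- mains
  } else base <- fixed
  base_fit <- fit1(base)
  for (tm in base) {
    rest <- setdiff(base, tm)
    red <- if (length(rest)) fit1(rest) else
      fit_choice_glmm(trials, scores, fixed = character(0), random = random,
                      duration_term = duration_term, nAGQ = nAGQ)
    lr <- lr_test(base_fit, red)
    rows[[tm]] <- c(term = tm, chi_square = lr$value, df = lr$df, p = lr$p)
  }
  out <- as.data.frame(do.call(rbind, rows), stringsAsFactors = FALSE)
  out$chi_square <- as.numeric(out$chi_square)
  out$df <- as.numeric(out$df)
  out$p <- as.numeric(out$p)
  rownames(out) <- NULL
  out
}

#' Run the full pipeline: score, sample, simulate, analyze
#'
#' Executes the four stages in order, persisting every intermediate table as
#' CSV under `out_dir` and finishing with `manifest.json` recording the seed,
#' an MD5 hash of the serialized configuration, per-stage row counts, RT
#' filter removal counts, and model convergence flags. A stage failure aborts
#' with the stage name; tables already written are left in place.
#'
#' @param config a [run_config()].
#' @param out_dir output directory (created if needed).
#' @return the manifest, invisibly (a list).
#' @export
run_pipeline <- function(config, out_dir) {
  stopifnot(inherits(config, "run_config"))
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  manifest <- list(seed = config$seed, stages = list(), log = character(0))
  say <- function(fmt, ...) {
    line <- sprintf(fmt, ...)
    manifest$log <<- c(manifest$log, line)
    message("[chronosim] ", line)
  }
  cfg_path <- file.path(out_dir, "config.json")
  write_run_config(config, cfg_path)
  manifest$config_md5 <- unname(tools::md5sum(cfg_path))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("pipeline stage '%s' failed: %s", name,
                   conditionMessage(e)), call. = FALSE))
  }

  if (config$n_subjects_per_group < 5L)
    say("small-n warning: %d subjects per group",
        config$n_subjects_per_group)

  # -- stage 1: scores ------------------------------------------------------
  scores <- stage("scores", {
    if (config$score_source == "images") {
      net <- build_network(do.call(network_config, c(
        config$network, list(seed = derive_seed(config$seed, "scores")))))
      paths <- list.files(config$images_dir, full.names = TRUE,
                          pattern = "\\.(png|jpe?g|p[gpn]m)$")
      tab <- score_image_set(net, paths)
      mem_seed <- derive_seed(config$seed, "scores")
      set.seed(mem_seed)
      # fixture images carry no memorability; assign a synthetic score
      tab$memorability <- stats::runif(nrow(tab), 0.2, 1)
      tab[, c("image_id", "memorability", "A", "B", "C")]
    } else {
      make_synthetic_score_table(config$n_images,
                                 seed = derive_seed(config$seed, "scores"))
    }
  })
  write_table(scores, file.path(out_dir, "scores.csv"))
  manifest$stages$scores <- list(n_rows = nrow(scores))
  say("scores: %d images", nrow(scores))

  # -- stage 2: sample ------------------------------------------------------
  sets <- stage("sample", {
    lapply(config$strategies, function(strat) {
      plan <- sampling_plan(strat, mem_tolerance = config$mem_tolerance)
      sample_stimuli(scores, plan,
                     seed = derive_seed(config$seed, "sample"))
    })
  })
  names(sets) <- config$strategies
  man_all <- do.call(rbind, lapply(config$strategies, function(s) {
    m <- stimulus_manifest(sets[[s]]); m$strategy <- s; m
  }))
  write_table(man_all, file.path(out_dir, "stimuli.csv"))
  manifest$stages$sample <- list(n_rows = nrow(man_all))
  say("sample: %d stimuli over %d strategies", nrow(man_all), length(sets))

  # -- stage 3: simulate ----------------------------------------------------
  sim <- stage("simulate", {
    trials <- list(); recog <- list()
    for (i in seq_along(sets)) {
      strat <- config$strategies[i]
      sseed <- derive_seed(config$seed, "simulate") + i
      off <- (i - 1L) * config$n_subjects_per_group
      trials[[i]] <- if (config$behavior_model == "inverted_u")
        simulate_bisection_inverted_u(
          sets[[i]], n_subjects = config$n_subjects_per_group,
          group = strat, subject_offset = off, seed = sseed)
      else
        simulate_bisection(
          sets[[i]], do.call(choice_model_params, config$behavior),
          n_subjects = config$n_subjects_per_group,
          group = strat, subject_offset = off, seed = sseed)
      recog[[i]] <- simulate_recognition(
        sets[[i]], n_subjects = config$n_subjects_per_group,
        base_hit = config$recognition$base_hit,
        spread = config$recognition$spread,
        fa_rate = config$recognition$fa_rate,
        group = strat, seed = derive_seed(config$seed, "recognition") + i)
      recog[[i]]$subject_id <- sprintf("s%03d",
        as.integer(sub("^s", "", recog[[i]]$subject_id)) + off)
    }
    list(trials = do.call(rbind, trials), recog = do.call(rbind, recog))
  })
  write_table(sim$trials, file.path(out_dir, "trials.csv"))
  write_table(sim$recog, file.path(out_dir, "recognition_trials.csv"))
  manifest$stages$simulate <- list(n_trials = nrow(sim$trials),
                                   n_recognition = nrow(sim$recog))
  say("simulate: %d bisection + %d recognition trials",
      nrow(sim$trials), nrow(sim$recog))

  # -- stage 4: analyze -----------------------------------------------------
  res <- stage("analyze", {
    coefs <- list(); lrs <- list(); surf_rows <- list(); iu_rows <- list()
    rec_rows <- list(); hit_subj <- list()
    filt_counts <- list(); conv <- list()
    for (i in seq_along(sets)) {
      strat <- config$strategies[i]
      tr <- sim$trials[sim$trials$group == strat, , drop = FALSE]
      fl <- filter_rt_outliers(tr, tail = config$analysis$rt_filter_tail)
      filt_counts[[strat]] <- sum(fl$n_removed)
      say("analyze/%s: removed %d RT outliers", strat, sum(fl$n_removed))
      spec <- strategy_models(strat)
      small_n <- config$n_subjects_per_group < 5L
      random <- if (small_n) "intercept" else spec$random
      fit <- fit_choice_glmm(fl$trials, scores, fixed = spec$fixed,
                             random = random,
                             duration_term = config$analysis$duration_term,
                             nAGQ = config$analysis$nAGQ)
      conv[[strat]] <- fit$converged
      say("analyze/%s: GLMM %s", strat,
          if (fit$converged) "converged" else "did NOT converge")
      co <- fit$coefficients; co$group <- strat
      coefs[[strat]] <- co
      lr <- term_lr_tests(fl$trials, scores, spec$fixed, random,
                          config$analysis$duration_term,
                          config$analysis$nAGQ)
      lr$group <- strat
      lrs[[strat]] <- lr
      mem_sd <- stats::sd(scores$memorability[
        match(unique(fl$trials$image_id), scores$image_id)])
      surf <- if (strat == "constant_memorability" || mem_sd < 0.01)
        binned_psychometric(fl$trials, scores, n_mem_bins = 0L,
                            n_speed_bins = config$analysis$n_speed_bins)
      else binned_psychometric(fl$trials, scores,
                               n_mem_bins = config$analysis$n_mem_bins,
                               n_speed_bins = config$analysis$n_speed_bins)
      surf_rows[[strat]] <- surface_as_df(surf, strat)
      if (surf$layout == "speed_only") {
        iu <- fit_inverted_u(surf)
        iu_rows[[strat]] <- data.frame(group = strat, M1 = iu$M1,
                                       M2 = iu$M2, M3 = iu$M3,
                                       inverted_u = iu$inverted_u,
                                       rss = iu$rss)
      }
      rg <- sim$recog[sim$recog$group == strat, , drop = FALSE]
      rs <- recognition_summary(rg)
      an <- tryCatch(rm_anova(rs$subject_matrix), error = function(e) NULL)
      rec_rows[[strat]] <- data.frame(
        group = strat, overall_hit_rate = rs$overall_hit_rate,
        spread = rs$spread, fa_rate = rs$fa_rate,
        F_bins = if (is.null(an)) NA_real_ else an$value,
        df1 = if (is.null(an)) NA_real_ else an$df[1L],
        df2 = if (is.null(an)) NA_real_ else an$df[2L],
        p = if (is.null(an)) NA_real_ else an$p,
        partial_eta_sq = if (is.null(an)) NA_real_ else an$partial_eta_sq)
      hit_subj[[strat]] <- data.frame(
        group = strat,
        subject_id = rownames(rs$subject_matrix),
        hit_rate = rowMeans(rs$subject_matrix, na.rm = TRUE))
    }
    # 11-bin combined speed curve over the strategies covering the speed
    # range at ~constant memorability, when both are present
    comb <- intersect(c("constant_memorability", "high_speed_memorability"),
                      config$strategies)
    if (length(comb) >= 1L) {
      tr <- sim$trials[sim$trials$group %in% comb, , drop = FALSE]
      fl <- filter_rt_outliers(tr, tail = config$analysis$rt_filter_tail)
      surf11 <- binned_psychometric(
        fl$trials, scores, n_mem_bins = 0L,
        n_speed_bins = config$analysis$n_speed_bins_combined)
      surf_rows[["combined"]] <- surface_as_df(surf11, "combined")
      iu <- fit_inverted_u(surf11)
      iu_rows[["combined"]] <- data.frame(group = "combined", M1 = iu$M1,
                                          M2 = iu$M2, M3 = iu$M3,
                                          inverted_u = iu$inverted_u,
                                          rss = iu$rss)
    }
    hits <- do.call(rbind, hit_subj)
    contrasts <- if (length(unique(hits$group)) >= 2L)
      group_contrast(hits$hit_rate, hits$group) else NULL
    list(coefs = do.call(rbind, coefs), lrs = do.call(rbind, lrs),
         surfaces = do.call(rbind, surf_rows),
         inverted_u = if (length(iu_rows)) do.call(rbind, iu_rows) else NULL,
         recognition = do.call(rbind, rec_rows), contrasts = contrasts,
         filter_counts = filt_counts, converged = conv)
  })
  write_table(res$coefs, file.path(out_dir, "coefficients.csv"))
  write_table(res$lrs, file.path(out_dir, "lr_tests.csv"))
  write_table(res$surfaces, file.path(out_dir, "surface.csv"))
  if (!is.null(res$inverted_u))
    write_table(res$inverted_u, file.path(out_dir, "inverted_u.csv"))
  write_table(res$recognition, file.path(out_dir, "recognition.csv"))
  if (!is.null(res$contrasts))
    write_table(res$contrasts, file.path(out_dir, "group_contrasts.csv"))
  manifest$stages$analyze <- list(
    n_coefficients = nrow(res$coefs), n_lr_tests = nrow(res$lrs),
    rt_outliers_removed = res$filter_counts, converged = res$converged)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  say("done: outputs in %s", out_dir)
  invisible(manifest)
}

surface_as_df <- function(surf, label) {
  if (surf$layout == "speed_only") {
    data.frame(group = label, mem_bin = NA_integer_,
               speed_bin = seq_along(surf$cell_means),
               speed_center = surf$speed_centers,
               mem_center = NA_real_,
               p_long = surf$cell_means, n = surf$cell_counts)
  } else {
    nm <- nrow(surf$cell_means); ns <- ncol(surf$cell_means)
    data.frame(group = label,
               mem_bin = rep(seq_len(nm), times = ns),
               speed_bin = rep(seq_len(ns), each = nm),
               speed_center = rep(surf$speed_centers, each = nm),
               mem_center = rep(surf$mem_centers, times = ns),
               p_long = as.vector(surf$cell_means),
               n = as.vector(surf$cell_counts))
  }
}
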