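#' End-to-end pipeline orchestration
#'
#' `run_pipeline()` chains parse -> inclusion filter -> matching -> feature
#' extraction -> group statistics over a cohort directory and writes a
#' report bundle (CSV tables, log, provenance). Runs are deterministic given
#' the config and seed, and repeated runs over the same inputs produce
#' byte-identical outputs.
#'
#' @name pipeline
NULL

#' Pipeline run configuration
#'
#' @param input_root cohort directory: one canonical-dialect archive per
#'   participant subdirectory.
#' @param out_dir output directory for the report bundle.
#' @param dialect archive dialect name.
#' @param detector `"stub"` or `"template"`, see [face_detector()].
#' @param min_posts,min_span_days inclusion thresholds.
#' @param alpha significance level for the normality gate.
#' @param trim trimming proportion of the robust ANOVA.
#' @param seed integer seed recorded in provenance and used for matching.
#' @param match if `TRUE` (default) and the control pool is at least as
#'   large as the case group, controls are propensity-matched 1:1.
#' @param case_level,control_level group labels.
#' @param bh append Benjamini-Hochberg adjusted q column to the comparison
#'   table.
#' @param write_image_features also write the per-image feature table.
#' @return list of class `run_config`.
#' @export
run_config <- function(input_root, out_dir, dialect = "canonical",
                       detector = c("stub", "template"),
                       min_posts = 5, min_span_days = 90,
                       alpha = 0.05, trim = 0.20, seed = 1L,
                       match = TRUE, case_level = "SSD",
                       control_level = "HV", bh = FALSE,
                       write_image_features = FALSE) {
  detector <- match.arg(detector)
  stopifnot(dir.exists(input_root))
  structure(as.list(environment()), class = "run_config")
}

#' Per-image feature table of one archive
#'
#' @param archive a `participant_archive`.
#' @param detector a [face_detector()].
#' @param cutoff,tau see [aspect_features()].
#' @return data frame, one row per post image.
#' @export
image_feature_table <- function(archive, detector = face_detector("stub"),
                                cutoff = as.POSIXct("2016-01-01", tz = "UTC"),
                                tau = 0.005) {
  posts <- archive$posts
  recs <- lapply(seq_len(nrow(posts)), function(i) {
    post <- posts[i, , drop = FALSE]
    img <- if (post$missing_image) NULL else read_image(post$image_path)
    image_feature_record(img, post, detector = detector,
                         cutoff = cutoff, tau = tau)
  })
  out <- do.call(rbind, recs)
  out$participant_id <- archive$demographics$participant_id %||% NA_character_
  out
}

#' Run the full analysis pipeline
#'
#' @param config a [run_config()].
#' @return list with `features` (per-participant table), `comparison`
#'   (feature comparison table), `anova_timeofday` / `anova_weekday`
#'   (robust ANOVA tables), `regression_face_count`, `correlations`
#'   (Spearman checks of duration bias), `included`, `excluded`, `log`.
#'   The same tables are written as CSV under `config$out_dir` together
#'   with `run.log` and `provenance.json`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  set.seed(config$seed)
  log <- character()
  note <- function(...) {
    log <<- c(log, sprintf(...))
  }
  roots <- list.dirs(config$input_root, recursive = FALSE)
  roots <- roots[file.exists(file.path(roots, "demographics.json"))]
  if (length(roots) == 0L) stop("no participant archives under input_root")
  note("found %d participant archives", length(roots))

  archives <- lapply(roots, parse_archive, dialect = config$dialect)
  included <- list(); excluded <- character()
  for (a in archives) {
    pid <- a$demographics$participant_id
    n_missing <- sum(a$posts$missing_image)
    if (n_missing > 0) note("%s: %d missing/unreadable image(s)", pid, n_missing)
    filt <- inclusion_filter(a, config$min_posts, config$min_span_days)
    if (filt$included) {
      included[[pid]] <- a
    } else {
      excluded <- c(excluded, pid)
      note("excluded %s: %s", pid, filt$reason)
    }
  }
  groups <- vapply(included, function(a) a$demographics$group, character(1))
  n_case <- sum(groups == config$case_level)
  n_ctrl <- sum(groups == config$control_level)
  note("included: %d %s, %d %s", n_case, config$case_level,
       n_ctrl, config$control_level)
  if (n_case == 0L || n_ctrl == 0L) {
    stop("no included participants in group ",
         if (n_case == 0L) config$case_level else config$control_level)
  }

  demo_df <- do.call(rbind, lapply(included, function(a) {
    d <- a$demographics
    data.frame(participant_id = d$participant_id, group = d$group,
               age = d$age, sex = d$sex, race = d$race,
               stringsAsFactors = FALSE)
  }))
  keep <- names(included)
  match_result <- NULL
  if (isTRUE(config$match) && n_ctrl > n_case) {
    cases <- demo_df[demo_df$group == config$case_level, , drop = FALSE]
    ctrls <- demo_df[demo_df$group == config$control_level, , drop = FALSE]
    match_result <- propensity_match(cases, ctrls, seed = config$seed)
    keep <- c(cases$participant_id, match_result$pairs$control_id)
    note("matched %d pairs; %d controls unmatched",
         nrow(match_result$pairs), length(match_result$unmatched_controls))
  }
  included <- included[keep]

  detector <- face_detector(config$detector)
  feats <- do.call(rbind, lapply(included, participant_features,
                                 detector = detector))
  rownames(feats) <- NULL
  image_feats <- NULL
  if (isTRUE(config$write_image_features)) {
    image_feats <- do.call(rbind, lapply(included, image_feature_table,
                                         detector = detector))
    rownames(image_feats) <- NULL
  }

  comparison <- build_comparison_table(
    feats, case_level = config$case_level,
    control_level = config$control_level,
    alpha = config$alpha, bh = config$bh)

  long_of <- function(prefix, conds) {
    do.call(rbind, lapply(seq_len(nrow(feats)), function(i) {
      data.frame(id = feats$participant_id[i], group = feats$group[i],
                 condition = factor(conds, levels = conds),
                 value = as.numeric(feats[i, paste0(prefix, conds)]),
                 stringsAsFactors = FALSE)
    }))
  }
  try_anova <- function(conds, design) {
    tryCatch(robust_mixed_anova(long_of("rate_", conds), trim = config$trim),
             error = function(e) {
               note("robust ANOVA (%s) not computed: %s", design,
                    conditionMessage(e))
               NULL
             })
  }
  anova_tod <- try_anova(TIMEOFDAY_BINS, "timeofday")
  anova_wd <- try_anova(WEEKDAYS_ISO, "weekday")

  regression <- tryCatch(ols_regression(feats$face_count, feats),
                         error = function(e) {
                           note("face-count regression not computed: %s",
                                conditionMessage(e))
                           NULL
                         })
  try_corr <- function(x, y) {
    tryCatch(spearman_corr(x, y),
             error = function(e) list(rho = NA_real_, p = NA_real_))
  }
  corr_fol <- try_corr(feats$usage_months, feats$follower_count)
  corr_ratio <- try_corr(feats$usage_months,
                         feats$follower_following_ratio)
  correlations <- data.frame(
    pair = c("usage_months~follower_count",
             "usage_months~follower_following_ratio"),
    rho = c(corr_fol$rho, corr_ratio$rho),
    p = c(corr_fol$p, corr_ratio$p),
    stringsAsFactors = FALSE
  )

  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  wcsv <- function(x, f) write.csv(as.data.frame(x),
                                   file.path(config$out_dir, f),
                                   row.names = FALSE)
  wcsv(feats, "participant_features.csv")
  if (!is.null(image_feats)) wcsv(image_feats, "image_features.csv")
  wcsv(comparison, "comparison_table.csv")
  anova_rows <- rbind(
    if (!is.null(anova_tod)) cbind(design = "timeofday",
                                   as.data.frame(anova_tod)),
    if (!is.null(anova_wd)) cbind(design = "weekday",
                                  as.data.frame(anova_wd)))
  if (!is.null(anova_rows)) wcsv(anova_rows, "robust_anova.csv")
  wcsv(correlations, "correlations.csv")
  if (!is.null(regression)) {
    wcsv(regression$coefficients, "regression_face_count.csv")
  }
  if (!is.null(match_result)) {
    wcsv(match_result$pairs, "matched_pairs.csv")
    wcsv(match_result$balance, "balance_report.csv")
  }
  writeLines(log, file.path(config$out_dir, "run.log"))

  cfg_public <- config[setdiff(names(config), "out_dir")]
  cfg_json <- jsonlite::toJSON(cfg_public, auto_unbox = TRUE, digits = NA)
  cfg_file <- file.path(config$out_dir, "config.json")
  writeLines(cfg_json, cfg_file)
  provenance <- list(
    package = "instaphen",
    version = as.character(utils::packageVersion("instaphen")),
    seed = config$seed,
    config_md5 = unname(tools::md5sum(cfg_file)),
    n_included = length(included),
    n_excluded = length(excluded)
  )
  jsonlite::write_json(provenance,
                       file.path(config$out_dir, "provenance.json"),
                       auto_unbox = TRUE, pretty = TRUE)

  list(features = feats, image_features = image_feats,
       comparison = comparison,
       anova_timeofday = anova_tod, anova_weekday = anova_wd,
       regression_face_count = if (!is.null(regression)) regression[
         c("coefficients", "F", "df1", "df2", "p", "r_squared")],
       correlations = correlations, match = match_result,
       included = names(included), excluded = excluded, log = log)
}
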