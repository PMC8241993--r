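#' Analysis configuration
#'
#' Bundle of every tunable of the end-to-end analysis, with the defaults
#' used throughout: 10-minute bins, series harmonised to 4000 points
#' (minimum 3000), recurrence rate fixed at 0.05, minimum line lengths 2,
#' no embedding (amplitudes compared directly), 180-minute end-of-record
#' zero-run trimming, Bonferroni correction over the 7 recurrence
#' quantifiers.
#'
#' @param bin_minutes resampling bin width (minutes).
#' @param max_len,min_len length bounds after binning (points).
#' @param target_rr fixed recurrence rate.
#' @param l_min,v_min minimum diagonal / vertical line lengths.
#' @param embedding_dim,delay delay-embedding parameters.
#' @param theiler extra diagonals excluded around the LOI.
#' @param trim_zero_run_minutes non-wear trimming threshold (minutes).
#' @param bonferroni_m number of tests for the Bonferroni threshold.
#' @param seed seed used when the pipeline simulates its own input.
#' @return object of class `analysis_config`.
#' @export
analysis_config <- function(bin_minutes = 10, max_len = 4000, min_len = 3000,
                            target_rr = 0.05, l_min = 2, v_min = 2,
                            embedding_dim = 1, delay = 1, theiler = 0,
                            trim_zero_run_minutes = 180, bonferroni_m = 7,
                            seed = 1L) {
  stopifnot(bin_minutes > 0, max_len >= min_len, min_len > 0,
            target_rr > 0, target_rr < 1, l_min >= 1, v_min >= 1,
            embedding_dim >= 1, delay >= 1, theiler >= 0,
            trim_zero_run_minutes > 0, bonferroni_m >= 1)
  structure(as.list(environment()), class = "analysis_config")
}

rqa_quantifiers <- c("det", "l_avg", "l_ent", "lam", "lam_det_ratio",
                     "v_avg", "v_ent")
traditional_quantifiers <- c("mean_activity", "is_", "iv", "ra")

#' Analyse a single subject
#'
#' Runs preprocessing, the clutter check, recurrence quantification and
#' the traditional circadian measures for one subject. Exclusions
#' (insufficient data, cluttered recurrence plot, empty after trimming)
#' are returned as a status instead of propagating as errors.
#'
#' @param series raw [count_series].
#' @param config an [analysis_config()].
#' @return one-row data frame: `subject_id`, `status`
#'   (`"analyzed"`/`"excluded"`), `reason`, then epsilon/rr and the 7 RQA
#'   and 4 traditional quantifiers (NA when excluded).
#' @export
subject_measures <- function(series, config = analysis_config()) {
  id <- series$subject_id
  empty <- data.frame(
    subject_id = id, status = "excluded", reason = NA_character_,
    epsilon = NA_real_, rr = NA_real_,
    det = NA_real_, l_avg = NA_real_, l_ent = NA_real_, lam = NA_real_,
    lam_det_ratio = NA_real_, v_avg = NA_real_, v_ent = NA_real_,
    mean_activity = NA_real_, is_ = NA_real_, iv = NA_real_, ra = NA_real_,
    stringsAsFactors = FALSE
  )
  pre <- tryCatch(preprocess_series(series, config),
                  subject_exclusion = function(e) e)
  if (inherits(pre, "subject_exclusion")) {
    empty$reason <- pre$reason
    return(empty)
  }
  cl <- check_clutter(pre$ranks, config$target_rr)
  if (cl$exclude) {
    empty$reason <- cl$reason
    return(empty)
  }
  rq <- rqa_measures(pre$ranks, target_rr = config$target_rr,
                     l_min = config$l_min, v_min = config$v_min,
                     embedding_dim = config$embedding_dim,
                     delay = config$delay, theiler = config$theiler)
  circ <- tryCatch(circadian_measures(pre$trimmed),
                   subject_exclusion = function(e) {
                     data.frame(mean_activity = mean_activity(pre$trimmed),
                                is_ = NA_real_, iv = NA_real_, ra = NA_real_)
                   })
  out <- empty
  out$status <- "analyzed"
  out$epsilon <- rq$epsilon
  out$rr <- rq$rr
  for (q in rqa_quantifiers) out[[q]] <- rq[[q]]
  for (q in traditional_quantifiers) out[[q]] <- circ[[q]]
  out
}

#' Run the full case-control analysis pipeline
#'
#' Orchestrates simulate/read, preprocess, recurrence quantification,
#' circadian measures and group comparison. The input is either a
#' `cohort` from [gen_cohort()], a [cohort_spec()] (simulated on the
#' fly), or a directory containing per-subject CSVs plus a
#' `manifest.tsv` as written by [write_cohort()]. Every input subject
#' appears exactly once in the result, as analysed or excluded with a
#' reason; group comparisons are computed on the analysed subjects.
#'
#' @param input a `cohort`, a `cohort_spec`, or a directory path.
#' @param config an [analysis_config()].
#' @param output_dir optional directory; when given, writes `rqa.tsv`,
#'   `circadian.tsv`, `exclusions.tsv`, `comparison.tsv`,
#'   `regression.tsv` and `run.json` (config echo and counts).
#' @return list of class `pipeline_result`: `cohort_table` (per-subject
#'   quantifiers + status), `comparison` (RQA and traditional rows),
#'   `regression` (per-quantifier and combined logistic pseudo-R2),
#'   `exclusions`, `config`.
#' @export
run_pipeline <- function(input, config = analysis_config(),
                         output_dir = NULL) {
  cohort <- if (inherits(input, "cohort_spec")) {
    gen_cohort(input)
  } else if (inherits(input, "cohort")) {
    input
  } else if (is.character(input) && dir.exists(input)) {
    manifest <- utils::read.delim(file.path(input, "manifest.tsv"),
                                  stringsAsFactors = FALSE)
    recs <- lapply(seq_len(nrow(manifest)), function(i) {
      list(subject_id = manifest$subject_id[i], group = manifest$group[i],
           series = read_subject_csv(
             file.path(input, paste0(manifest$subject_id[i], ".csv"))))
    })
    names(recs) <- manifest$subject_id
    recs
  } else stop("run_pipeline: input must be a cohort, cohort_spec or directory")

  rows <- lapply(cohort, function(rec) {
    r <- subject_measures(rec$series, config)
    r$subject_id <- rec$subject_id
    r$group <- rec$group
    r
  })
  tab <- do.call(rbind, rows)
  rownames(tab) <- NULL

  analyzed <- tab[tab$status == "analyzed", ]
  excl <- tab[tab$status == "excluded", c("subject_id", "group", "reason")]
  for (g in c("N", "D")) {
    if (sum(analyzed$group == g) < 2) {
      stop("run_pipeline: fewer than 2 analyzable subjects in group ", g)
    }
  }

  comparison <- rbind(
    cbind(family = "rqa",
          compare_groups(analyzed, rqa_quantifiers,
                         m_tests = config$bonferroni_m)),
    cbind(family = "traditional",
          compare_groups(analyzed, traditional_quantifiers,
                         m_tests = length(traditional_quantifiers)))
  )

  # logistic pseudo-R2: each quantifier alone, then the combined sets
  complete <- analyzed[stats::complete.cases(
    analyzed[, c(rqa_quantifiers, traditional_quantifiers)]), ]
  reg_rows <- lapply(c(as.list(c(rqa_quantifiers, traditional_quantifiers)),
                       list(traditional_quantifiers, rqa_quantifiers,
                            c(traditional_quantifiers, rqa_quantifiers))),
                     function(pr) {
    fit <- logistic_fit(complete[, pr, drop = FALSE], complete$group, pr)
    data.frame(predictors = paste(pr, collapse = "+"),
               pseudo_r2 = fit$pseudo_r2, separation = fit$separation)
  })
  regression <- do.call(rbind, reg_rows)

  res <- structure(list(cohort_table = tab, comparison = comparison,
                        regression = regression, exclusions = excl,
                        config = config),
                   class = "pipeline_result")

  if (!is.null(output_dir)) {
    dir.create(output_dir, showWarnings = FALSE, recursive = TRUE)
    wt <- function(d, f) utils::write.table(
      d, file.path(output_dir, f), sep = "\t", row.names = FALSE, quote = FALSE)
    wt(analyzed[, c("subject_id", "group", "epsilon", "rr", rqa_quantifiers)],
       "rqa.tsv")
    wt(analyzed[, c("subject_id", "group", traditional_quantifiers)],
       "circadian.tsv")
    wt(excl, "exclusions.tsv")
    wt(comparison, "comparison.tsv")
    wt(regression, "regression.tsv")
    jsonlite::write_json(
      list(config = unclass(config),
           n_input = nrow(tab), n_analyzed = nrow(analyzed),
           n_excluded = nrow(excl),
           package_version = as.character(utils::packageVersion("rqact"))),
      file.path(output_dir, "run.json"), auto_unbox = TRUE, pretty = TRUE)
  }
  res
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat(sprintf("<pipeline_result> %d subjects: %d analyzed, %d excluded\n",
              nrow(x$cohort_table),
              sum(x$cohort_table$status == "analyzed"),
              nrow(x$exclusions)))
  print(x$comparison[, c("quantifier", "mean_N", "mean_D", "t", "p", "d")],
        digits = 3)
  invisible(x)
}

#' Render a recurrence plot to a raster image
#'
#' Time runs along both axes from the lower-left origin; recurrence
#' points are dark.
#'
#' @param rp a `recurrence_plot`.
#' @param path output PNG path.
#' @param ... passed to [graphics::image()].
#' @return `path`, invisibly.
#' @export
render_rp <- function(rp, path, ...) {
  stopifnot(inherits(rp, "recurrence_plot"))
  grDevices::png(path, width = 600, height = 600)
  on.exit(grDevices::dev.off())
  graphics::image(seq_len(rp$n), seq_len(rp$n), t(rp$R),
                  col = c("white", "black"), useRaster = TRUE,
                  xlab = "time", ylab = "time", ...)
  invisible(path)
}

#' @export
plot.recurrence_plot <- function(x, ...) {
  graphics::image(seq_len(x$n), seq_len(x$n), t(x$R),
                  col = c("white", "black"), useRaster = TRUE,
                  xlab = "time", ylab = "time", ...)
  invisible(x)
}
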