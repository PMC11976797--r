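# End-to-end orchestration: ground truth -> evaluation -> Experimental-Max
# -> difficulty -> clinical classification, with a machine-readable run
# manifest. All randomness flows from one top-level seed through named
# substreams.

#' Run the full assessment pipeline
#'
#' Stages that lack their inputs are skipped: without a replicate table the
#' packaged per-variant summaries provide the ground truth and the
#' Experimental-Max stage is omitted; without predictors the evaluation,
#' head-to-head and difficulty stages are omitted. The clinical
#' classification stage always runs on the annotation table.
#'
#' @param replicates optional raw replicate table (path or data.frame).
#' @param predictions optional predictor manifest path or list of
#'   [prediction_set()]s.
#' @param annotations annotation table; default [stk11_annotations()].
#' @param eval_mode `"full"` (all eligible variants) or `"missense_only"`
#'   (additionally drops non-missense variants).
#' @param n_boot bootstrap draws per metric.
#' @param n_experimental_max Experimental-Max realizations.
#' @param seed top-level seed (fans out to named substreams).
#' @param out_dir optional directory; when given, every result table is
#'   written as TSV plus a JSON run manifest, regenerated bit-identically
#'   for the same config and seed.
#' @return invisible list with every computed stage.
#' @export
run_stk11_pipeline <- function(replicates = NULL, predictions = NULL,
                               annotations = stk11_annotations(),
                               eval_mode = c("full", "missense_only"),
                               n_boot = 1000, n_experimental_max = 1000,
                               seed = 42, out_dir = NULL) {
  eval_mode <- match.arg(eval_mode)
  stopifnot(n_boot >= 1, n_experimental_max >= 1)

  if (!is.null(replicates)) {
    measurements <- read_replicates(replicates)
    truth <- build_ground_truth(measurements)
  } else {
    measurements <- NULL
    truth <- annotations[c("variant", "mean_rwt", "p25", "p75")]
    truth$label <- classify_activity(truth$mean_rwt)
  }
  eval_set <- build_evaluation_set(annotations,
                                   drop_non_missense = eval_mode == "missense_only")

  if (is.character(predictions)) predictions <- read_prediction_manifest(predictions)
  evaluation <- ranking <- h2h <- difficulty <- NULL
  if (!is.null(predictions) && length(predictions)) {
    evaluation <- evaluate_predictors(predictions, truth, eval_set,
                                      n_boot = n_boot, seed = seed)
    ranking <- rank_predictors(evaluation, two_stage = TRUE)
    h2h <- do.call(rbind, lapply(c("pearson", "kendall_tau", "auc"),
                                 function(m) head_to_head(evaluation, m)))
    competitive <- select_competitive(evaluation)
    if (length(competitive)) {
      nm <- vapply(predictions, `[[`, "", "name")
      difficulty <- difficulty_profile(predictions[match(competitive, nm)], truth)
    }
  }

  expmax <- NULL
  if (!is.null(measurements)) {
    expmax <- experimental_max(replicate_index(measurements), truth, eval_set,
                               n_realizations = n_experimental_max,
                               seed = substream_seed(seed, "experimental-max"))
  }

  acmg <- acmg_classify_all(annotations)

  result <- list(truth = truth, eval_set = eval_set, evaluation = evaluation,
                 ranking = ranking, head_to_head = h2h,
                 difficulty = difficulty, experimental_max = expmax,
                 acmg = acmg)

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    wtsv <- function(df, file)
      utils::write.table(df, file.path(out_dir, file), sep = "\t",
                         quote = FALSE, row.names = FALSE)
    wtsv(truth, "ground_truth.tsv")
    wtsv(eval_set$excluded, "excluded_variants.tsv")
    if (!is.null(evaluation)) {
      wtsv(evaluation$table, "metrics.tsv")
      wtsv(ranking$participants, "ranking_participants.tsv")
      wtsv(ranking$baselines, "ranking_baselines.tsv")
      wtsv(h2h, "head_to_head.tsv")
    }
    if (!is.null(difficulty)) {
      wtsv(data.frame(variant = rownames(difficulty$fpr), difficulty$fpr,
                      check.names = FALSE), "difficulty_fpr.tsv")
      wtsv(data.frame(variant = rownames(difficulty$fnr), difficulty$fnr,
                      check.names = FALSE), "difficulty_fnr.tsv")
    }
    if (!is.null(expmax)) {
      wtsv(data.frame(metric = colnames(expmax$draws), mean = unname(expmax$mean),
                      ci90_lo = expmax$ci90[1, ], ci90_hi = expmax$ci90[2, ]),
           "experimental_max.tsv")
    }
    wtsv(acmg, "acmg_classification.tsv")
    manifest <- list(
      package = "stk11eval",
      version = as.character(utils::packageVersion("stk11eval")),
      r_version = paste(R.version$major, R.version$minor, sep = "."),
      seed = seed, n_boot = n_boot, n_experimental_max = n_experimental_max,
      eval_mode = eval_mode, n_eval_variants = length(eval_set$variants),
      stages = names(Filter(Negate(is.null), result)))
    jsonlite::write_json(manifest, file.path(out_dir, "run_manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE)
  }
  invisible(result)
}
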