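# Per-variant prediction difficulty: FPR at each LoF variant and FNR at
# each WT-like variant, using the variant's own predicted activity as the
# decision threshold. Computed over all assayed variants, including those
# excluded from predictor comparison.

#' Select the competitive predictor subset for difficulty profiling
#'
#' Participants are first reduced to the best predictor per team (by average
#' rank), then everything — participant representatives and baselines — is
#' filtered at AUC strictly above the floor.
#'
#' @param evaluation a `predictor_evaluation` (or its table).
#' @param auc_floor minimum AUC, exclusive (default 0.8).
#' @param best_per_team reduce participants to one per team first.
#' @return character vector of predictor names; empty (with a warning) if
#'   none qualify.
#' @export
select_competitive <- function(evaluation, auc_floor = 0.8, best_per_team = TRUE) {
  tab <- if (inherits(evaluation, "predictor_evaluation")) evaluation$table else evaluation
  pool <- tab
  if (best_per_team && any(!tab$baseline)) {
    rk <- rank_predictors(tab, two_stage = TRUE)
    pool <- tab[tab$baseline | tab$predictor %in% rk$participants$predictor, ]
  }
  keep <- pool$predictor[pool$auc > auc_floor]
  if (!length(keep)) warning("no predictor exceeds the AUC floor of ", auc_floor)
  keep
}

#' False positive rate at a LoF variant
#'
#' Fraction of the WT-like set predicted to have strictly lower activity
#' than the LoF variant itself; ties do not count.
#'
#' @param variant name of the (LoF) probe variant.
#' @param scores named activity-scale scores covering the probe and the
#'   WT-like set (see [regression_view()]).
#' @param wt_like_set names of the WT-like variants.
#' @return rate in \[0, 1\].
#' @export
variant_fpr <- function(variant, scores, wt_like_set) {
  stopifnot(length(wt_like_set) > 0, variant %in% names(scores),
            all(wt_like_set %in% names(scores)))
  mean(scores[wt_like_set] < scores[[variant]])
}

#' False negative rate at a WT-like variant
#'
#' Fraction of the LoF set predicted to have strictly higher activity than
#' the WT-like variant itself.
#'
#' @param variant name of the (WT-like) probe variant.
#' @param scores named activity-scale scores.
#' @param lof_set names of the LoF variants.
#' @return rate in \[0, 1\].
#' @export
variant_fnr <- function(variant, scores, lof_set) {
  stopifnot(length(lof_set) > 0, variant %in% names(scores),
            all(lof_set %in% names(scores)))
  mean(scores[lof_set] > scores[[variant]])
}

#' Difficulty profile across competitive predictors
#'
#' Builds the variant-by-predictor FPR matrix (LoF variants) and FNR matrix
#' (WT-like variants), each with a per-variant average over predictors.
#' Missing scores are mean-imputed over the full variant set before rates
#' are computed; imputed entries are reported.
#'
#' @param predictions list of [prediction_set()]s (the competitive subset).
#' @param truth ground-truth data.frame (variant, label) covering all
#'   assayed variants.
#' @return list with `fpr` and `fnr` matrices (average in the last column)
#'   and `imputed`, a predictor -> variants list.
#' @export
difficulty_profile <- function(predictions, truth) {
  variants <- truth$variant
  lof <- variants[truth$label == "LoF"]
  wt <- variants[truth$label == "WT-like"]
  nm <- vapply(predictions, `[[`, "", "name")
  imputed <- list()
  views <- lapply(predictions, function(p) {
    pi <- impute_missing(p, variants)
    imputed[[p$name]] <<- pi$imputed
    regression_view(pi, variants)
  })
  fpr <- vapply(views, function(s)
    vapply(lof, variant_fpr, numeric(1), scores = s, wt_like_set = wt),
    numeric(length(lof)))
  fnr <- vapply(views, function(s)
    vapply(wt, variant_fnr, numeric(1), scores = s, lof_set = lof),
    numeric(length(wt)))
  fpr <- matrix(fpr, nrow = length(lof), dimnames = list(lof, nm))
  fnr <- matrix(fnr, nrow = length(wt), dimnames = list(wt, nm))
  list(fpr = cbind(fpr, average = rowMeans(fpr)),
       fnr = cbind(fnr, average = rowMeans(fnr)),
       imputed = imputed)
}
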