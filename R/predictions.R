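# Predictor score ingestion, orientation transforms, and mean imputation.

#' Construct a predictor score set
#'
#' A predictor declares its orientation exactly once, in its manifest:
#' `"activity"` scores approximate R-WT activity (higher = more wildtype
#' function), `"pathogenicity"` scores are on a damage scale in \[0, 1\]
#' (higher = more damaging). Orientation is never inferred from the score
#' distribution.
#'
#' @param name predictor name.
#' @param scores named numeric vector (variant -> score); NA = missing.
#' @param orientation `"activity"` or `"pathogenicity"`.
#' @param team team name for participant predictors, NA for baselines.
#' @param baseline logical; TRUE for publicly available baseline tools.
#' @return object of class `prediction_set`.
#' @export
prediction_set <- function(name, scores, orientation = c("activity", "pathogenicity"),
                           team = NA_character_, baseline = FALSE) {
  orientation <- match.arg(orientation)
  stopifnot(is.numeric(scores), !is.null(names(scores)), !anyDuplicated(names(scores)))
  if (all(is.na(scores))) stop("prediction set '", name, "' has no non-missing score")
  if (orientation == "pathogenicity" &&
      any(scores < 0 | scores > 1, na.rm = TRUE))
    warning("pathogenicity-orientation scores outside [0, 1] for '", name,
            "'; transform 1 - y is still applied")
  structure(list(name = name, scores = scores, orientation = orientation,
                 team = team, baseline = isTRUE(baseline),
                 imputed = character(0)),
            class = "prediction_set")
}

#' @export
print.prediction_set <- function(x, ...) {
  cat("Prediction set '", x$name, "' (", x$orientation, "): ",
      sum(!is.na(x$scores)), " scores, ", sum(is.na(x$scores)), " missing",
      if (length(x$imputed)) paste0(", ", length(x$imputed), " imputed"), "\n",
      sep = "")
  invisible(x)
}

pick_scores <- function(p, variants) {
  if (is.null(variants)) return(p$scores)
  out <- p$scores[variants]
  names(out) <- variants
  out
}

#' Activity-scale view of a predictor (for regression metrics)
#'
#' Activity-oriented scores pass through unaltered; pathogenicity-oriented
#' scores y are transformed to 1 - y so that higher means more wildtype-like
#' activity. Missing stays missing.
#'
#' @param p a [prediction_set()].
#' @param variants optional variant subset/order; default all scored variants.
#' @return named numeric vector on the activity scale.
#' @export
regression_view <- function(p, variants = NULL) {
  s <- pick_scores(p, variants)
  if (p$orientation == "pathogenicity") 1 - s else s
}

#' Risk-scale view of a predictor (for AUC)
#'
#' Higher output means more likely loss-of-function: activity-oriented
#' scores are negated, pathogenicity-oriented scores pass through unaltered.
#'
#' @inheritParams regression_view
#' @return named numeric vector on the risk scale.
#' @export
classification_view <- function(p, variants = NULL) {
  s <- pick_scores(p, variants)
  if (p$orientation == "activity") -s else s
}

#' Mean-impute missing predictions over an evaluation set
#'
#' Each missing score on the evaluation set is replaced by the arithmetic
#' mean of the predictor's non-missing scores on that same set, computed on
#' the predictor's native scale (before any orientation transform). Imputed
#' variants are recorded in the `imputed` field.
#'
#' @param p a [prediction_set()].
#' @param eval_set an [build_evaluation_set()] result or character vector of
#'   variant names.
#' @return a `prediction_set` complete on the evaluation set.
#' @export
impute_missing <- function(p, eval_set) {
  variants <- if (inherits(eval_set, "evaluation_set")) eval_set$variants else eval_set
  s <- p$scores[variants]
  names(s) <- variants
  if (all(is.na(s)))
    stop("predictor '", p$name, "' has no score on the evaluation set")
  miss <- names(s)[is.na(s)]
  s[miss] <- mean(s, na.rm = TRUE)
  out <- p
  out$scores <- s
  out$imputed <- miss
  out
}

#' Read a predictor manifest and its score files
#'
#' The manifest is a TSV with columns `predictor`, `orientation`, `team`,
#' `baseline` (TRUE/FALSE) and `file`; score files are two-column delimited
#' tables (variant, score) with missing encoded as empty or NA, resolved
#' relative to the manifest's directory.
#'
#' @param path manifest path.
#' @return named list of [prediction_set()] objects.
#' @export
read_prediction_manifest <- function(path) {
  man <- utils::read.table(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE)
  needed <- c("predictor", "orientation", "team", "baseline", "file")
  if (!all(needed %in% names(man)))
    stop("manifest lacks column(s): ",
         paste(setdiff(needed, names(man)), collapse = ", "))
  base <- dirname(path)
  sets <- lapply(seq_len(nrow(man)), function(i) {
    f <- man$file[i]
    if (!file.exists(f)) f <- file.path(base, man$file[i])
    tab <- utils::read.table(f, header = TRUE, sep = "\t", na.strings = c("", "NA"),
                             stringsAsFactors = FALSE)
    scores <- as.numeric(tab[[2]])
    names(scores) <- tab[[1]]
    prediction_set(man$predictor[i], scores, orientation = man$orientation[i],
                   team = if (is.na(man$team[i])) NA_character_ else man$team[i],
                   baseline = isTRUE(as.logical(man$baseline[i])))
  })
  names(sets) <- man$predictor
  sets
}
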