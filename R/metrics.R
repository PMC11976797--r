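# Evaluation metrics, stratified bootstrap uncertainty, predictor ranking,
# paired head-to-head significance, and inter-predictor correlations.

degenerate_metric <- function(msg) {
  stop(errorCondition(msg, class = c("stk11_degenerate_metric", "error", "condition")))
}

is_degenerate <- function(e) inherits(e, "stk11_degenerate_metric")

#' Pearson product-moment correlation
#'
#' @param truth,pred paired numeric vectors (activity scale).
#' @return correlation in \[-1, 1\]; a zero-variance side raises a
#'   degenerate-metric condition (handled by redraw in the bootstrap layer).
#' @export
metric_pearson <- function(truth, pred) {
  stopifnot(length(truth) == length(pred), length(truth) >= 3)
  if (stats::sd(truth) == 0 || stats::sd(pred) == 0)
    degenerate_metric("zero variance in Pearson input")
  stats::cor(truth, pred)
}

#' Kendall rank correlation (tau-b, tie-corrected)
#'
#' @inheritParams metric_pearson
#' @return tau-b in \[-1, 1\]; all-tied input on either side is degenerate.
#' @export
metric_kendall <- function(truth, pred) {
  stopifnot(length(truth) == length(pred), length(truth) >= 3)
  if (length(unique(truth)) == 1L || length(unique(pred)) == 1L)
    degenerate_metric("all values tied in Kendall input")
  stats::cor(truth, pred, method = "kendall")
}

#' Area under the ROC curve (Mann-Whitney form, midrank ties)
#'
#' Equals the probability that a random LoF variant receives a higher risk
#' score than a random WT-like variant, with ties counted one half.
#'
#' @param labels vector with "LoF" as the positive class (anything else is
#'   treated as WT-like).
#' @param risk numeric risk scores (higher = more likely LoF); see
#'   [classification_view()].
#' @return AUC in \[0, 1\]; single-class input is degenerate.
#' @export
metric_auc <- function(labels, risk) {
  stopifnot(length(labels) == length(risk))
  pos <- labels == "LoF"
  n1 <- sum(pos); n0 <- sum(!pos)
  if (n1 == 0L || n0 == 0L)
    degenerate_metric("single-class input in AUC")
  r <- rank(risk)                       # midranks
  (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Bootstrap index sets (plain or stratified)
#'
#' Produces the shared resampling plan used to evaluate every predictor on
#' identical bootstrap variant sets, which is what makes the paired win-count
#' test meaningful. Stratified sampling resamples with replacement within
#' each class so every bootstrap set preserves the LoF/WT-like class counts.
#'
#' @param n evaluation-set size (plain sampling).
#' @param labels class labels (required when `stratified = TRUE`).
#' @param n_boot number of bootstrap sets (default 1000).
#' @param stratified preserve class counts per bootstrap set.
#' @param seed RNG seed; required for reproducibility.
#' @return integer matrix, one column per bootstrap set.
#' @export
bootstrap_indices <- function(n = NULL, labels = NULL, n_boot = 1000,
                              stratified = FALSE, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (stratified) {
    stopifnot(!is.null(labels))
    n <- length(labels)
    classes <- split(seq_len(n), labels)
    if (any(lengths(classes) < 2L))
      stop("stratified bootstrap needs >= 2 variants per class")
    vapply(seq_len(n_boot), function(j) {
      idx <- unlist(lapply(classes, function(ix) sample(ix, length(ix), replace = TRUE)),
                    use.names = FALSE)
      sort(idx)
    }, integer(n))
  } else {
    stopifnot(!is.null(n))
    vapply(seq_len(n_boot), function(j) sample.int(n, n, replace = TRUE),
           integer(n))
  }
}

eval_one <- function(metric, truth, pred, labels, risk, idx) {
  switch(metric,
         pearson = metric_pearson(truth[idx], pred[idx]),
         kendall_tau = metric_kendall(truth[idx], pred[idx]),
         auc = metric_auc(labels[idx], risk[idx]),
         stop("unknown metric: ", metric))
}

#' Bootstrap estimate of an evaluation metric
#'
#' Computes the point estimate on the full evaluation set plus `n_boot`
#' bootstrap draws. Classification metrics (AUC) default to stratified
#' resampling preserving class counts; regression metrics use plain
#' resampling. A bootstrap set on which the metric is undefined (zero
#' variance, single class) is redrawn, up to `max_redraw` times.
#'
#' @param metric one of `"pearson"`, `"kendall_tau"`, `"auc"`.
#' @param truth ground-truth mean R-WT activities (regression metrics).
#' @param pred predictor scores on the activity scale (regression metrics).
#' @param labels ground-truth labels, "LoF"/"WT-like" (AUC).
#' @param risk predictor scores on the risk scale (AUC).
#' @param n_boot bootstrap draws (default 1000).
#' @param stratified default TRUE for AUC, FALSE otherwise.
#' @param seed RNG seed (used when `indices` is NULL, and for redraws).
#' @param indices optional pre-built index matrix from [bootstrap_indices()]
#'   shared across predictors for paired comparisons.
#' @param max_redraw bound on redraws per degenerate bootstrap set.
#' @return object of class `metric_estimate`: point value, `ci90` (5th/95th
#'   percentile of draws), `gauss95` (point +/- 1.96 bootstrap sd), `draws`.
#' @export
bootstrap_metric <- function(metric, truth = NULL, pred = NULL, labels = NULL,
                             risk = NULL, n_boot = 1000, stratified = NULL,
                             seed = NULL, indices = NULL, max_redraw = 100) {
  if (is.null(stratified)) stratified <- metric == "auc"
  n <- if (metric == "auc") length(labels) else length(truth)
  point <- eval_one(metric, truth, pred, labels, risk, seq_len(n))
  if (is.null(indices))
    indices <- bootstrap_indices(n = n, labels = labels, n_boot = n_boot,
                                 stratified = stratified, seed = seed)
  n_boot <- ncol(indices)
  draws <- numeric(n_boot)
  for (j in seq_len(n_boot)) {
    idx <- indices[, j]
    val <- tryCatch(eval_one(metric, truth, pred, labels, risk, idx),
                    stk11_degenerate_metric = function(e) NA_real_)
    tries <- 0L
    while (is.na(val)) {
      tries <- tries + 1L
      if (tries > max_redraw)
        stop("bootstrap set ", j, " degenerate after ", max_redraw, " redraws")
      idx <- if (stratified)
        bootstrap_indices(labels = labels, n_boot = 1, stratified = TRUE)[, 1]
      else
        sample.int(n, n, replace = TRUE)
      val <- tryCatch(eval_one(metric, truth, pred, labels, risk, idx),
                      stk11_degenerate_metric = function(e) NA_real_)
    }
    draws[j] <- val
  }
  ci90 <- unname(stats::quantile(draws, c(0.05, 0.95)))
  structure(list(metric = metric, point = point, ci90 = ci90,
                 gauss95 = c(point - 1.96 * stats::sd(draws),
                             point + 1.96 * stats::sd(draws)),
                 draws = draws, n_boot = n_boot),
            class = "metric_estimate")
}

#' @export
print.metric_estimate <- function(x, ...) {
  cat(sprintf("%s = %.3f [%.3f, %.3f] (90%% bootstrap CI, %d draws)\n",
              x$metric, x$point, x$ci90[1], x$ci90[2], x$n_boot))
  invisible(x)
}

#' Evaluate a collection of predictors on an evaluation set
#'
#' Imputes missing scores, builds one shared bootstrap plan per metric
#' family (plain for regression, stratified for classification) and computes
#' the three metric estimates for every predictor on identical bootstrap
#' variant sets.
#'
#' @param predictions list of [prediction_set()] objects.
#' @param truth ground-truth data.frame (variant, mean_rwt, label).
#' @param eval_set [build_evaluation_set()] result or character vector.
#' @param n_boot bootstrap draws per metric.
#' @param seed top-level seed; regression and classification resampling use
#'   derived substreams.
#' @return object of class `predictor_evaluation` with per-predictor
#'   `metric_estimate`s and a Table-4-shaped summary data.frame.
#' @export
evaluate_predictors <- function(predictions, truth, eval_set, n_boot = 1000,
                                seed = 1) {
  variants <- if (inherits(eval_set, "evaluation_set")) eval_set$variants else eval_set
  stopifnot(all(variants %in% truth$variant))
  truth <- truth[match(variants, truth$variant), ]
  reg_idx <- bootstrap_indices(n = length(variants), n_boot = n_boot,
                               seed = substream_seed(seed, "bootstrap-regression"))
  cls_idx <- bootstrap_indices(labels = truth$label, n_boot = n_boot,
                               stratified = TRUE,
                               seed = substream_seed(seed, "bootstrap-classification"))
  estimates <- lapply(predictions, function(p) {
    p <- impute_missing(p, variants)
    act <- regression_view(p, variants)
    rsk <- classification_view(p, variants)
    list(
      pearson = bootstrap_metric("pearson", truth = truth$mean_rwt, pred = act,
                                 indices = reg_idx),
      kendall_tau = bootstrap_metric("kendall_tau", truth = truth$mean_rwt,
                                     pred = act, indices = reg_idx),
      auc = bootstrap_metric("auc", labels = truth$label, risk = rsk,
                             indices = cls_idx),
      imputed = p$imputed
    )
  })
  names(estimates) <- vapply(predictions, `[[`, "", "name")
  tab <- do.call(rbind, lapply(seq_along(predictions), function(i) {
    e <- estimates[[i]]; p <- predictions[[i]]
    data.frame(predictor = p$name, team = p$team, baseline = p$baseline,
               pearson = e$pearson$point,
               pearson_lo = e$pearson$ci90[1], pearson_hi = e$pearson$ci90[2],
               kendall_tau = e$kendall_tau$point,
               kendall_lo = e$kendall_tau$ci90[1], kendall_hi = e$kendall_tau$ci90[2],
               auc = e$auc$point,
               auc_lo = e$auc$ci90[1], auc_hi = e$auc$ci90[2],
               n_imputed = length(e$imputed), stringsAsFactors = FALSE)
  }))
  structure(list(estimates = estimates, table = tab, variants = variants,
                 n_boot = n_boot, seed = seed),
            class = "predictor_evaluation")
}

#' @export
print.predictor_evaluation <- function(x, ...) {
  cat("Predictor evaluation on", length(x$variants), "variants,",
      x$n_boot, "bootstrap draws\n")
  print(x$table[, c("predictor", "pearson", "kendall_tau", "auc")], digits = 3)
  invisible(x)
}

rank_pool <- function(tab) {
  ranks <- vapply(c("pearson", "kendall_tau", "auc"),
                  function(m) rank(-tab[[m]], ties.method = "average"),
                  numeric(nrow(tab)))
  ranks <- matrix(ranks, nrow = nrow(tab),
                  dimnames = list(NULL, c("pearson_rank", "kendall_rank", "auc_rank")))
  out <- cbind(tab[, c("predictor", "pearson", "kendall_tau", "auc")],
               as.data.frame(ranks))
  out$avg_rank <- rowMeans(ranks)
  out[order(out$avg_rank, out$predictor), ]
}

#' Rank predictors by average rank over the three metrics
#'
#' Within a pool, predictors are ranked per metric (1 = best, ties given
#' average ranks) and ordered by the mean of the three ranks. With
#' `two_stage = TRUE` the participant pool is first reduced to the best
#' predictor per team before re-ranking the representatives. Baselines are
#' always ranked in a separate pool.
#'
#' @param x a `predictor_evaluation` or its summary table.
#' @param two_stage apply best-per-team selection to participants first.
#' @return list with `participants` and `baselines` ranking data.frames
#'   (ordered best first).
#' @export
rank_predictors <- function(x, two_stage = FALSE) {
  tab <- if (inherits(x, "predictor_evaluation")) x$table else x
  part <- tab[!tab$baseline, , drop = FALSE]
  base <- tab[tab$baseline, , drop = FALSE]
  if (two_stage && nrow(part)) {
    reps <- do.call(rbind, lapply(split(part, part$team), function(d) {
      r <- rank_pool(d)
      d[d$predictor == r$predictor[1], , drop = FALSE]
    }))
    part <- reps
  }
  list(participants = if (nrow(part)) rank_pool(part) else part,
       baselines = if (nrow(base)) rank_pool(base) else base)
}

#' Paired one-sided binomial win test between two bootstrap draw vectors
#'
#' Counts the bootstrap sets on which `draws_a` strictly exceeds `draws_b`
#' and computes the exact upper-tail probability that a Binomial(n, 1/2)
#' variable is at least the win count. The draws must come from the same
#' bootstrap index sets (see [bootstrap_indices()]); ties do not count as
#' wins.
#'
#' @param draws_a,draws_b equal-length paired metric draws.
#' @return list: `wins`, `ties`, `n`, `p_value`, `log10_p`.
#' @export
compare_binomial <- function(draws_a, draws_b) {
  if (length(draws_a) != length(draws_b))
    stop("paired draws must have equal length")
  n <- length(draws_a)
  wins <- sum(draws_a > draws_b)
  list(wins = wins, ties = sum(draws_a == draws_b), n = n,
       p_value = stats::pbinom(wins - 1, n, 0.5, lower.tail = FALSE),
       log10_p = stats::pbinom(wins - 1, n, 0.5, lower.tail = FALSE,
                               log.p = TRUE) / log(10))
}

#' All pairwise head-to-head win tests within an evaluation
#'
#' @param evaluation a `predictor_evaluation`.
#' @param metric which metric's draws to compare.
#' @return data.frame with one row per ordered predictor pair.
#' @export
head_to_head <- function(evaluation, metric = c("pearson", "kendall_tau", "auc")) {
  metric <- match.arg(metric)
  nm <- names(evaluation$estimates)
  pairs <- expand.grid(a = nm, b = nm, stringsAsFactors = FALSE)
  pairs <- pairs[pairs$a != pairs$b, ]
  res <- do.call(rbind, lapply(seq_len(nrow(pairs)), function(i) {
    cmp <- compare_binomial(evaluation$estimates[[pairs$a[i]]][[metric]]$draws,
                            evaluation$estimates[[pairs$b[i]]][[metric]]$draws)
    data.frame(a = pairs$a[i], b = pairs$b[i], metric = metric,
               wins = cmp$wins, ties = cmp$ties, p_value = cmp$p_value,
               stringsAsFactors = FALSE)
  }))
  rownames(res) <- NULL
  res
}

#' Pairwise predictor correlation matrix (truth on the diagonal)
#'
#' Off-diagonal entries give the correlation between two predictors'
#' activity-scale scores; each diagonal entry gives that predictor's
#' correlation with the experimental mean R-WT activity.
#'
#' @param predictions list of [prediction_set()]s.
#' @param truth ground-truth data.frame (variant, mean_rwt).
#' @param variants common variant set (e.g. the evaluation set minus
#'   non-missense variants).
#' @param metric `"pearson"` or `"kendall_tau"`.
#' @return square matrix, predictors in input order.
#' @export
predictor_correlations <- function(predictions, truth, variants,
                                   metric = c("pearson", "kendall_tau")) {
  metric <- match.arg(metric)
  fun <- if (metric == "pearson") metric_pearson else metric_kendall
  tr <- truth$mean_rwt[match(variants, truth$variant)]
  views <- lapply(predictions, function(p)
    regression_view(impute_missing(p, variants), variants))
  k <- length(views)
  m <- matrix(NA_real_, k, k,
              dimnames = rep(list(vapply(predictions, `[[`, "", "name")), 2))
  for (i in seq_len(k)) for (j in seq_len(k))
    m[i, j] <- if (i == j) fun(tr, views[[i]]) else fun(views[[i]], views[[j]])
  m
}

# Deterministic substream seed derived from a top-level seed and a stream
# name; kept below 2^31 so it is a valid R integer seed.
substream_seed <- function(seed, name) {
  h <- sum(utf8ToInt(name) * seq_along(utf8ToInt(name)))
  as.integer((as.numeric(seed) * 1009 + h) %% .Machine$integer.max)
}
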