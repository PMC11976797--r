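# Experimental-Max: a stochastic pseudo-predictor built from assay
# replicates that quantifies assay self-consistency and bounds achievable
# predictor performance.

#' Build a two-level replicate index from a raw replicate table
#'
#' Maps each variant to the biological replicates containing it, and each of
#' those to its technical-replicate R-WT values.
#'
#' @param measurements replicate table (see [read_replicates()]) or the
#'   output of [rwt_replicates()].
#' @return object of class `replicate_index`: named list, variant ->
#'   list(bio_rep -> numeric vector of technical R-WT values).
#' @export
replicate_index <- function(measurements) {
  rr <- if ("rwt" %in% names(measurements)) measurements else rwt_replicates(measurements)
  rr <- rr[!(rr$subject %in% CONTROL_TAGS), , drop = FALSE]
  idx <- lapply(split(rr, rr$subject), function(d)
    lapply(split(d$rwt, d$bio_rep), as.numeric))
  structure(idx, class = "replicate_index")
}

#' Draw one Experimental-Max prediction per variant
#'
#' For each variant: pick a biological replicate containing it uniformly at
#' random, then pick one technical-replicate R-WT value uniformly within it.
#' Biological replicates are equally likely regardless of how many technical
#' values they hold (two-level uniform, not pooled). Uses the current RNG
#' state; seed externally for reproducibility.
#'
#' @param index a [replicate_index()].
#' @param variants variants to predict (default: all indexed).
#' @return named numeric vector of sampled R-WT activities.
#' @export
sample_replicate_prediction <- function(index, variants = names(index)) {
  unknown <- setdiff(variants, names(index))
  if (length(unknown))
    stop("variant(s) absent from replicate index: ", paste(unknown, collapse = ", "))
  vapply(variants, function(v) {
    bios <- index[[v]]
    vals <- bios[[sample.int(length(bios), 1)]]
    vals[sample.int(length(vals), 1)]
  }, numeric(1))
}

#' Evaluate the Experimental-Max predictor
#'
#' Generates `n_realizations` stochastic predictors by replicate resampling;
#' each realization draws one prediction per evaluation-set variant and is
#' scored against the all-replicate ground truth: Pearson and Kendall tau-b
#' against mean R-WT activity, and AUC against the LoF/WT-like labels with
#' the negated sampled activity as risk score. Reported per metric are the
#' mean over realizations and the 5th/95th percentile of the realization
#' values. Realizations with a degenerate metric are redrawn.
#'
#' @param index a [replicate_index()] (or raw replicate table).
#' @param truth ground-truth data.frame (variant, mean_rwt, label).
#' @param eval_set evaluation set (object or character vector).
#' @param n_realizations number of resampled predictors (default 1000).
#' @param seed RNG seed.
#' @param max_redraw bound on redraws per degenerate realization.
#' @return object of class `experimental_max`: per-metric mean, `ci90` and
#'   the realization draws.
#' @export
experimental_max <- function(index, truth, eval_set, n_realizations = 1000,
                             seed = 1, max_redraw = 100) {
  if (!inherits(index, "replicate_index")) index <- replicate_index(index)
  variants <- if (inherits(eval_set, "evaluation_set")) eval_set$variants else eval_set
  stopifnot(all(variants %in% truth$variant))
  truth <- truth[match(variants, truth$variant), ]
  set.seed(seed)
  draws <- matrix(NA_real_, n_realizations, 3,
                  dimnames = list(NULL, c("pearson", "kendall_tau", "auc")))
  for (r in seq_len(n_realizations)) {
    tries <- 0L
    repeat {
      pred <- sample_replicate_prediction(index, variants)
      vals <- tryCatch(
        c(metric_pearson(truth$mean_rwt, pred),
          metric_kendall(truth$mean_rwt, pred),
          metric_auc(truth$label, -pred)),
        stk11_degenerate_metric = function(e) NULL)
      if (!is.null(vals)) break
      tries <- tries + 1L
      if (tries > max_redraw)
        stop("Experimental-Max realization degenerate after ", max_redraw,
             " redraws")
    }
    draws[r, ] <- vals
  }
  summ <- apply(draws, 2, function(d)
    c(mean = mean(d), stats::quantile(d, c(0.05, 0.95))))
  structure(list(mean = summ["mean", ],
                 ci90 = summ[c("5%", "95%"), ],
                 draws = draws, n_realizations = n_realizations, seed = seed),
            class = "experimental_max")
}

#' @export
print.experimental_max <- function(x, ...) {
  cat("Experimental-Max over", x$n_realizations, "replicate resamplings\n")
  for (m in colnames(x$draws))
    cat(sprintf("  %s = %.3f [%.3f, %.3f]\n", m, x$mean[m],
                x$ci90[1, m], x$ci90[2, m]))
  invisible(x)
}
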