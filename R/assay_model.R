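# Assay data model: R-WT normalization, replicate aggregation, ground-truth
# labels, and evaluation-set construction.

#' Reserved control tags in the replicate table
#'
#' `WT` (wildtype, positive control), `EV` (empty vector, baseline) and `KD`
#' (kinase-dead p.K78I, negative control). `KD` is carried as data but takes
#' no part in normalization.
#' @export
CONTROL_TAGS <- c("WT", "EV", "KD")

#' Normalize raw luciferase activity to relative-wildtype (R-WT) activity
#'
#' Scales a raw activity reading so that the empty-vector baseline maps to 0
#' and the wildtype control maps to 1:
#' \deqn{R\textrm{-}WT = (A_{var} - A_{EV}) / (A_{WT} - A_{EV})}
#' All three readings must come from the same biological and technical
#' replicate. The result is affine-invariant: shifting or positively scaling
#' all three raw readings leaves it unchanged.
#'
#' @param raw_var raw activity of the variant (arbitrary units); vectorized.
#' @param raw_ev matched empty-vector reading(s).
#' @param raw_wt matched wildtype reading(s).
#' @param context optional label (e.g. "bio 3 / tech 1") used in the error
#'   message when a replicate is degenerate.
#' @return dimensionless R-WT activity; 0 at the EV baseline, 1 at WT.
#' @export
rwt_normalize <- function(raw_var, raw_ev, raw_wt, context = NULL) {
  stopifnot(is.numeric(raw_var), is.numeric(raw_ev), is.numeric(raw_wt))
  bad <- raw_wt == raw_ev
  if (any(bad, na.rm = TRUE)) {
    where <- if (is.null(context)) which(bad) else context
    stop("degenerate replicate: WT and EV activity identical (",
         paste(where, collapse = ", "), ")", call. = FALSE)
  }
  (raw_var - raw_ev) / (raw_wt - raw_ev)
}

#' Read a long-format replicate table
#'
#' Expects columns `subject`, `bio_rep`, `tech_rep`, `raw_activity`. Every
#' (bio_rep, tech_rep) pair must carry both a WT and an EV reading and
#' (subject, bio_rep, tech_rep) must be unique; violations are rejected at
#' load time with a report rather than silently dropped.
#'
#' @param x path to a TSV/CSV file, or a data.frame already in this shape.
#' @param sep field separator when `x` is a path (default tab).
#' @return validated data.frame of replicate measurements.
#' @export
read_replicates <- function(x, sep = "\t") {
  df <- if (is.character(x)) {
    utils::read.table(x, header = TRUE, sep = sep, stringsAsFactors = FALSE)
  } else {
    as.data.frame(x)
  }
  needed <- c("subject", "bio_rep", "tech_rep", "raw_activity")
  missing_cols <- setdiff(needed, names(df))
  if (length(missing_cols))
    stop("replicate table lacks column(s): ", paste(missing_cols, collapse = ", "))
  if (!is.numeric(df$raw_activity))
    stop("raw_activity must be numeric")
  key <- paste(df$subject, df$bio_rep, df$tech_rep, sep = "\r")
  if (anyDuplicated(key)) {
    dups <- df[duplicated(key), needed[1:3], drop = FALSE]
    stop("duplicate (subject, bio_rep, tech_rep) rows, e.g. ",
         paste(dups[1, ], collapse = "/"))
  }
  pair <- interaction(df$bio_rep, df$tech_rep, drop = TRUE)
  has_wt <- tapply(df$subject == "WT", pair, any)
  has_ev <- tapply(df$subject == "EV", pair, any)
  bad <- levels(pair)[!(has_wt & has_ev)]
  if (length(bad))
    stop("replicate pair(s) lacking a matched WT or EV reading: ",
         paste(bad, collapse = ", "))
  df
}

#' Per-replicate R-WT activities for every subject
#'
#' Applies [rwt_normalize()] within each (bio_rep, tech_rep) pair using that
#' pair's own WT and EV readings. Control rows are retained (WT normalizes
#' to exactly 1 and EV to exactly 0 in every replicate).
#'
#' @param measurements validated replicate table (see [read_replicates()]).
#' @return data.frame with columns subject, bio_rep, tech_rep, rwt.
#' @export
rwt_replicates <- function(measurements) {
  df <- read_replicates(measurements)
  pair <- paste(df$bio_rep, df$tech_rep, sep = "/")
  wt <- df$raw_activity[df$subject == "WT"]
  names(wt) <- pair[df$subject == "WT"]
  ev <- df$raw_activity[df$subject == "EV"]
  names(ev) <- pair[df$subject == "EV"]
  rwt <- rwt_normalize(df$raw_activity, unname(ev[pair]), unname(wt[pair]),
                       context = unique(pair[wt[pair] == ev[pair]]))
  data.frame(subject = df$subject, bio_rep = df$bio_rep,
             tech_rep = df$tech_rep, rwt = rwt, stringsAsFactors = FALSE)
}

#' Aggregate per-replicate R-WT values into per-variant ground-truth rows
#'
#' The mean is taken over all per-(bio_rep, tech_rep) normalized values of a
#' variant; p25/p75 are the 25th/75th percentiles of the same values. The
#' percentile convention defaults to linear interpolation between order
#' statistics (`type = 7`, R's default) and is configurable.
#'
#' @param measurements replicate table (raw scale) or the output of
#'   [rwt_replicates()] (recognized by its `rwt` column).
#' @param quantile_type percentile convention passed to [stats::quantile()].
#' @return data.frame: variant, mean_rwt, p25, p75, n_values, n_bio.
#' @export
aggregate_replicates <- function(measurements, quantile_type = 7) {
  rr <- if ("rwt" %in% names(measurements)) measurements else rwt_replicates(measurements)
  rr <- rr[!(rr$subject %in% CONTROL_TAGS), , drop = FALSE]
  if (!nrow(rr)) stop("no variant measurements present")
  sp <- split(rr, rr$subject)
  out <- do.call(rbind, lapply(sp, function(d) {
    q <- stats::quantile(d$rwt, c(0.25, 0.75), type = quantile_type, names = FALSE)
    data.frame(variant = d$subject[1], mean_rwt = mean(d$rwt),
               p25 = q[1], p75 = q[2], n_values = nrow(d),
               n_bio = length(unique(d$bio_rep)), stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Threshold mean R-WT activity into LoF / WT-like labels
#'
#' A variant is loss-of-function when its mean R-WT activity is strictly
#' below the threshold (default 0.6); the boundary value itself is WT-like.
#'
#' @param mean_rwt numeric vector of mean R-WT activities.
#' @param threshold classification threshold on the R-WT scale.
#' @return character vector of labels, "LoF" or "WT-like".
#' @export
classify_activity <- function(mean_rwt, threshold = 0.6) {
  stopifnot(is.numeric(mean_rwt), all(is.finite(mean_rwt)))
  ifelse(mean_rwt < threshold, "LoF", "WT-like")
}

#' Build the per-variant ground-truth table from raw replicates
#'
#' @inheritParams aggregate_replicates
#' @inheritParams classify_activity
#' @return data.frame: variant, mean_rwt, p25, p75, label.
#' @export
build_ground_truth <- function(measurements, threshold = 0.6, quantile_type = 7) {
  gt <- aggregate_replicates(measurements, quantile_type = quantile_type)
  gt$label <- classify_activity(gt$mean_rwt, threshold)
  gt[c("variant", "mean_rwt", "p25", "p75", "label")]
}

is_missense <- function(variant) {
  grepl("^p\\.[A-Z][0-9]+[A-Z]$", variant)
}

#' Construct the predictor evaluation set from annotated variant records
#'
#' Variants carrying a non-conflicting definitive clinical assertion —
#' ClinVar P, LP, P/LP, B, LB or B/LB, or HGMD DM with no conflicting
#' ClinVar record — are excluded so that the evaluation set cannot contain
#' variants plausibly present in predictor training data. VUS, DM?,
#' conflicting (e.g. VUS/LB) and unannotated variants are retained.
#'
#' @param records data.frame with columns `variant`, `clinvar`, `hgmd`
#'   (NA = absent).
#' @param drop_non_missense also exclude non-missense variants (single
#'   amino-acid deletions etc.), giving the reduced missense-only set.
#' @return object of class `evaluation_set`: list with `variants` (retained,
#'   input order) and `excluded` (data.frame variant/reason).
#' @export
build_evaluation_set <- function(records, drop_non_missense = FALSE) {
  stopifnot(is.data.frame(records), all(c("variant", "clinvar") %in% names(records)))
  clinvar <- as.character(records$clinvar)
  hgmd <- if ("hgmd" %in% names(records)) as.character(records$hgmd) else rep(NA_character_, nrow(records))
  definitive_cv <- clinvar %in% c("P", "LP", "P/LP", "B", "LB", "B/LB")
  # HGMD DM counts only when ClinVar does not dispute it (absent or definitive)
  dm <- !is.na(hgmd) & hgmd == "DM"
  excl_cv <- definitive_cv
  excl_dm <- dm & (is.na(clinvar) | definitive_cv)
  reason <- rep(NA_character_, nrow(records))
  reason[excl_dm] <- paste("HGMD", hgmd[excl_dm])
  reason[excl_cv] <- paste("ClinVar", clinvar[excl_cv])
  if (drop_non_missense) {
    nm <- !is_missense(records$variant) & is.na(reason)
    reason[nm] <- "non-missense"
  }
  out <- list(
    variants = records$variant[is.na(reason)],
    excluded = data.frame(variant = records$variant[!is.na(reason)],
                          reason = reason[!is.na(reason)],
                          stringsAsFactors = FALSE)
  )
  class(out) <- "evaluation_set"
  out
}

#' @export
print.evaluation_set <- function(x, ...) {
  cat("Evaluation set:", length(x$variants), "variants retained,",
      nrow(x$excluded), "excluded\n")
  if (nrow(x$excluded))
    cat(paste0("  - ", x$excluded$variant, " (", x$excluded$reason, ")\n"), sep = "")
  invisible(x)
}
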