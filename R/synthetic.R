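# Synthetic assay and predictor generators emulating the structure of the
# STK11 luciferase challenge data: ~17 biological replicates each covering a
# subset of variants across 2-3 technical replicates, controls present in
# every replicate, each variant covered by 3-6 biological replicates,
# continuous activity on a 0-1+ scale, and predictor scores of either
# orientation with tunable noise and missingness.

#' Synthetic assay configuration
#'
#' Defaults encode the design of the real assay: 28 variants, 17 biological
#' replicates with 2-3 technical replicates each, 3-6 biological replicates
#' per variant, and a bimodal true-activity distribution (a low-activity
#' LoF component and a WT-like component) truncated to \[-0.2, 2\]. Noise
#' is applied on the R-WT scale so replicate dispersion is interpretable
#' against the 0.6 classification threshold; raw readings are then mapped
#' through per-replicate WT/EV baselines.
#'
#' @param n_variants number of variants.
#' @param n_bio_reps total biological replicates.
#' @param bio_reps_per_variant range (min, max) of biological replicates
#'   covering each variant.
#' @param tech_reps_per_bio range of technical replicates per biological
#'   replicate.
#' @param noise_sd replicate noise standard deviation on the R-WT scale.
#' @param mixture true-activity distribution: list with `weights`, `means`,
#'   `sds` and truncation `range`.
#' @param ev_base_range,wt_base_range raw-scale EV/WT baseline ranges drawn
#'   per (bio, tech) replicate (arbitrary luminescence units).
#' @return list of class `synthetic_config`.
#' @export
synthetic_config <- function(n_variants = 28, n_bio_reps = 17,
                             bio_reps_per_variant = c(3, 6),
                             tech_reps_per_bio = c(2, 3),
                             noise_sd = 0.1,
                             mixture = list(weights = c(0.5, 0.5),
                                            means = c(0.2, 1.1),
                                            sds = c(0.15, 0.25),
                                            range = c(-0.2, 2.0)),
                             ev_base_range = c(0.5, 1.5),
                             wt_base_range = c(2.5, 4.5)) {
  stopifnot(n_variants >= 1, n_bio_reps >= 1, noise_sd >= 0,
            bio_reps_per_variant[1] >= 1,
            bio_reps_per_variant[2] <= n_bio_reps,
            tech_reps_per_bio[1] >= 1,
            all(mixture$weights > 0), ev_base_range[1] < ev_base_range[2],
            wt_base_range[1] > ev_base_range[2])
  structure(as.list(environment()), class = "synthetic_config")
}

rtrunc_mixture <- function(n, mixture) {
  out <- numeric(0)
  while (length(out) < n) {
    comp <- sample.int(length(mixture$weights), n, replace = TRUE,
                       prob = mixture$weights)
    x <- stats::rnorm(n, mixture$means[comp], mixture$sds[comp])
    out <- c(out, x[x >= mixture$range[1] & x <= mixture$range[2]])
  }
  out[seq_len(n)]
}

#' Generate a synthetic raw replicate table
#'
#' Each variant is assigned to a random subset of biological replicates;
#' every (bio, tech) replicate carries WT, EV and KD readings. Raw activity
#' is `ev_base + (true_activity + noise) * (wt_base - ev_base)` with
#' per-replicate baselines, so synthetic WT and EV rows normalize back to
#' exactly 1 and 0 and, at `noise_sd = 0`, [aggregate_replicates()] recovers
#' the true activities exactly.
#'
#' @param config a [synthetic_config()].
#' @param seed RNG seed.
#' @return list: `measurements` (replicate table), `truth` (named vector of
#'   true R-WT activities), `config`, `seed`.
#' @export
generate_assay <- function(config = synthetic_config(), seed = 1) {
  stopifnot(inherits(config, "synthetic_config"))
  set.seed(seed)
  variants <- sprintf("var%02d", seq_len(config$n_variants))
  truth <- rtrunc_mixture(config$n_variants, config$mixture)
  names(truth) <- variants
  n_tech <- sample(seq(config$tech_reps_per_bio[1], config$tech_reps_per_bio[2]),
                   config$n_bio_reps, replace = TRUE)
  assign_bio <- lapply(variants, function(v) {
    k <- sample(seq(config$bio_reps_per_variant[1], config$bio_reps_per_variant[2]), 1)
    sort(sample.int(config$n_bio_reps, k))
  })
  names(assign_bio) <- variants
  rows <- list()
  for (b in seq_len(config$n_bio_reps)) {
    in_b <- variants[vapply(assign_bio, function(a) b %in% a, logical(1))]
    for (t in seq_len(n_tech[b])) {
      ev <- stats::runif(1, config$ev_base_range[1], config$ev_base_range[2])
      wt <- stats::runif(1, config$wt_base_range[1], config$wt_base_range[2])
      span <- wt - ev
      subj <- c("WT", "EV", "KD", in_b)
      act <- c(wt, ev,
               ev + (0 + stats::rnorm(1, 0, config$noise_sd)) * span,
               ev + (truth[in_b] + stats::rnorm(length(in_b), 0, config$noise_sd)) * span)
      rows[[length(rows) + 1L]] <- data.frame(
        subject = subj, bio_rep = b, tech_rep = t, raw_activity = unname(act),
        stringsAsFactors = FALSE)
    }
  }
  measurements <- do.call(rbind, rows)
  rownames(measurements) <- NULL
  list(measurements = measurements, truth = truth, config = config, seed = seed)
}

#' Generate a synthetic predictor for a known truth map
#'
#' Activity orientation adds Gaussian noise to the truth; pathogenicity
#' orientation returns `1 - clip(truth + noise, 0, 1)`. Missing scores are
#' injected completely at random at `missing_rate`.
#'
#' @param truth named numeric vector of true activities.
#' @param orientation `"activity"` or `"pathogenicity"`.
#' @param noise_sd Gaussian noise sd on the activity scale.
#' @param missing_rate fraction of scores replaced by NA.
#' @param seed RNG seed.
#' @param name predictor name.
#' @param team,baseline passed to [prediction_set()].
#' @return a [prediction_set()].
#' @export
generate_predictor <- function(truth, orientation = c("activity", "pathogenicity"),
                               noise_sd = 0, missing_rate = 0, seed = 1,
                               name = "synthetic", team = NA_character_,
                               baseline = FALSE) {
  orientation <- match.arg(orientation)
  stopifnot(length(truth) > 0, noise_sd >= 0,
            missing_rate >= 0, missing_rate < 1)
  set.seed(seed)
  y <- truth + stats::rnorm(length(truth), 0, noise_sd)
  if (orientation == "pathogenicity") y <- 1 - pmin(pmax(y, 0), 1)
  if (missing_rate > 0) {
    miss <- stats::runif(length(y)) < missing_rate
    if (all(miss)) miss[sample.int(length(y), 1)] <- FALSE
    y[miss] <- NA_real_
  }
  names(y) <- names(truth)
  prediction_set(name, y, orientation = orientation, team = team,
                 baseline = baseline)
}

#' Noise level targeting a Kendall tau against the truth
#'
#' Under a bivariate-normal approximation, tau = (2/pi) asin(rho), so the
#' additive noise sd that yields a target tau for truth with standard
#' deviation `truth_sd` is `truth_sd * sqrt(1/sin(pi tau/2)^2 - 1)`. The
#' truncation of the activity mixture makes this approximate, which is all
#' the calibration tests require.
#'
#' @param target_tau desired Kendall tau in (0, 1).
#' @param truth_sd standard deviation of the true activities.
#' @return Gaussian noise sd for [generate_predictor()].
#' @export
noise_for_tau <- function(target_tau, truth_sd) {
  stopifnot(target_tau > 0, target_tau < 1, truth_sd > 0)
  rho <- sin(pi * target_tau / 2)
  truth_sd * sqrt(1 / rho^2 - 1)
}
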