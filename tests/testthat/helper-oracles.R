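# Independent brute-force oracles, kept free of any package internals.

# Kendall tau-b by exhaustive pair enumeration; tied_x counts pairs tied in
# x (including both-tied), likewise tied_y.
oracle_tau_b <- function(x, y) {
  n <- length(x)
  nc <- nd <- tied_x <- tied_y <- 0
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    dx <- sign(x[j] - x[i]); dy <- sign(y[j] - y[i])
    if (dx == 0) tied_x <- tied_x + 1
    if (dy == 0) tied_y <- tied_y + 1
    if (dx != 0 && dy != 0) {
      if (dx == dy) nc <- nc + 1 else nd <- nd + 1
    }
  }
  n0 <- n * (n - 1) / 2
  (nc - nd) / sqrt((n0 - tied_x) * (n0 - tied_y))
}

# AUC by exhaustive pairwise concordance, ties half-credited.
oracle_auc <- function(labels, risk) {
  pos <- which(labels == "LoF"); neg <- which(labels != "LoF")
  tot <- 0
  for (i in pos) for (j in neg)
    tot <- tot + if (risk[i] > risk[j]) 1 else if (risk[i] == risk[j]) 0.5 else 0
  tot / (length(pos) * length(neg))
}

# Minimal hand-built replicate table: two bio reps, two tech reps each,
# every pair carrying WT/EV/KD, plus the given variant readings.
tiny_replicates <- function(variant_rwt = list(vA = c(1.0, 0.5, 0.9))) {
  rows <- list()
  for (b in 1:2) for (t in 1:2) {
    ev <- 1 + 0.1 * b; wt <- 3 + 0.2 * t
    rows[[length(rows) + 1]] <- data.frame(
      subject = c("WT", "EV", "KD"), bio_rep = b, tech_rep = t,
      raw_activity = c(wt, ev, ev), stringsAsFactors = FALSE)
  }
  tab <- do.call(rbind, rows)
  for (v in names(variant_rwt)) {
    vals <- variant_rwt[[v]]
    # place sequentially over (bio, tech) slots
    slots <- expand.grid(t = 1:2, b = 1:2)[seq_along(vals), ]
    for (k in seq_along(vals)) {
      b <- slots$b[k]; t <- slots$t[k]
      ev <- 1 + 0.1 * b; wt <- 3 + 0.2 * t
      tab <- rbind(tab, data.frame(subject = v, bio_rep = b, tech_rep = t,
                                   raw_activity = ev + vals[k] * (wt - ev),
                                   stringsAsFactors = FALSE))
    }
  }
  tab
}
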