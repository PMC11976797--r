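# ACMG/AMP point-based clinical variant classification combining functional
# assay results (PS3/BS3), population frequency (PM2/BS1), calibrated
# computational evidence (PP3/BP4) and co-located pathogenic variants (PM5).
#
# Point scale: supporting/moderate/strong/very strong evidence toward
# pathogenicity (benignity) = +1/+2/+4/+8 (-1/-2/-4/-8).

evidence_item <- function(code, points, rationale) {
  data.frame(code = code, points = as.integer(points), rationale = rationale,
             stringsAsFactors = FALSE)
}

no_evidence <- function() evidence_item(character(0), integer(0), character(0))

#' Functional assay evidence (PS3/BS3)
#'
#' Each assay contributes independently at supporting strength: a LoF result
#' gives PS3 with +1 point, a WT-like result gives BS3 with -1. Concordant
#' assays therefore net +2 or -2; discordant assays (as for p.H202R) net 0.
#' A missing label contributes nothing and is flagged in the rationale.
#'
#' @param luciferase_label,gelshift_label "LoF", "WT-like", or NA.
#' @return evidence-item data.frame (possibly 0 rows).
#' @export
acmg_functional <- function(luciferase_label, gelshift_label) {
  one <- function(label, assay) {
    if (is.na(label)) return(no_evidence())
    if (label == "LoF")
      evidence_item("PS3", 1L, paste(assay, "assay: LoF"))
    else
      evidence_item("BS3", -1L, paste(assay, "assay: WT-like"))
  }
  rbind(one(luciferase_label, "luciferase"), one(gelshift_label, "gel-shift"))
}

#' Population-frequency evidence (PM2/BS1)
#'
#' Absence from gnomAD (no allele count) gives PM2 at supporting strength
#' (+1). An allele frequency above the BS1 threshold (default 0.001, chosen
#' for an autosomal-dominant disorder) gives BS1 at strong strength (-4).
#' Presence at or below the threshold is indeterminate: no code.
#'
#' @param gnomad_ac allele count (NA = absent from gnomAD).
#' @param gnomad_af allele frequency in \[0, 1\] (NA when absent).
#' @param bs1_threshold allele-frequency threshold for BS1.
#' @return evidence-item data.frame (0 or 1 rows).
#' @export
acmg_population <- function(gnomad_ac, gnomad_af, bs1_threshold = 0.001) {
  if (is.na(gnomad_ac) || gnomad_ac < 1)
    return(evidence_item("PM2", 1L, "absent from gnomAD"))
  if (!is.na(gnomad_af) && gnomad_af > bs1_threshold)
    return(evidence_item("BS1", -4L,
                         sprintf("gnomAD AF %.3g > %.3g", gnomad_af, bs1_threshold)))
  no_evidence()
}

# Calibrated REVEL score intervals -> evidence strength. PP3 intervals are
# left-closed; BP4 intervals are right-closed; the gap (0.290, 0.644) and
# scores <= 0.003 carry no code.
acmg_computational_points <- function(revel) {
  if (revel >= 0.932 && revel <= 1) 4L
  else if (revel >= 0.773) 2L
  else if (revel >= 0.644) 1L
  else if (revel > 0.183 && revel <= 0.290) -1L
  else if (revel > 0.016 && revel <= 0.183) -2L
  else if (revel > 0.003 && revel <= 0.016) -4L
  else 0L
}

#' Computational evidence from a calibrated REVEL score (PP3/BP4)
#'
#' REVEL in \[0.644, 0.773), \[0.773, 0.932) or \[0.932, 1\] gives PP3 at
#' supporting (+1), moderate (+2) or strong (+4); REVEL in (0.183, 0.290\],
#' (0.016, 0.183\] or (0.003, 0.016\] gives BP4 at -1, -2 or -4. Scores in
#' the gap (0.290, 0.644), scores <= 0.003, and absent scores (e.g. for a
#' single-residue deletion) yield no code.
#'
#' @param revel REVEL score in \[0, 1\], or NA.
#' @return evidence-item data.frame (0 or 1 rows).
#' @export
acmg_computational <- function(revel) {
  if (is.na(revel)) return(no_evidence())
  if (revel < 0 || revel > 1) stop("REVEL score outside [0, 1]: ", revel)
  pts <- acmg_computational_points(revel)
  if (pts == 0L) return(no_evidence())
  evidence_item(if (pts > 0) "PP3" else "BP4", pts,
                sprintf("REVEL %.3g", revel))
}

#' Co-located pathogenic variant evidence (PM5)
#'
#' Considers P and LP missense variants at the same residue. PM5 triggers
#' when the tested variant's REVEL score, rounded to 2 decimals, is equal to
#' or higher than the (equally rounded) score of at least one co-located
#' P/LP variant. When triggered, points accumulate over ALL co-located P/LP
#' variants: +2 for the first P, +1 for the first LP, +1 for every
#' additional P or LP. Co-located B/LB entries are accepted but ignored.
#'
#' @param revel tested variant's REVEL score, or NA (no code).
#' @param colocated data.frame with columns `variant`, `class` ("P"/"LP"),
#'   `revel`; NULL or 0 rows means no co-located variants.
#' @return evidence-item data.frame (0 or 1 rows).
#' @export
acmg_colocated <- function(revel, colocated = NULL) {
  if (is.na(revel) || is.null(colocated) || !nrow(colocated)) return(no_evidence())
  keep <- colocated$class %in% c("P", "LP")
  colocated <- colocated[keep, , drop = FALSE]
  if (!nrow(colocated)) return(no_evidence())
  qualifies <- round(revel, 2) >= round(colocated$revel, 2)
  if (!any(qualifies)) return(no_evidence())
  n <- nrow(colocated)
  pts <- n + as.integer(any(colocated$class == "P"))
  evidence_item("PM5", pts,
                paste0("co-located P/LP: ",
                       paste(colocated$variant, collapse = ", ")))
}

#' Map a total point score to a clinical category
#'
#' Totals >= 10 give P; 6..9 LP; 0..5 VUS (subdivided: 0..1 VUS-low, 2..3
#' VUS-mid, 4..5 VUS-high); -6..-1 LB; <= -7 B.
#'
#' @param total integer total points; vectorized.
#' @return character vector of categories.
#' @export
acmg_categorize <- function(total) {
  stopifnot(all(total == round(total)))
  vapply(total, function(t) {
    if (t >= 10) "P"
    else if (t >= 6) "LP"
    else if (t >= 4) "VUS-high"
    else if (t >= 2) "VUS-mid"
    else if (t >= 0) "VUS-low"
    else if (t >= -6) "LB"
    else "B"
  }, character(1))
}

#' Classify one variant under the point-based evidence combination
#'
#' Assembles functional (PS3/BS3), population (PM2/BS1), computational
#' (PP3/BP4) and co-located (PM5) evidence, sums the points and maps the
#' total to a category. Case-level codes (PM6/PS2, PP1) are never applied
#' automatically but may be passed through `manual_items`.
#'
#' @param variant variant name (protein HGVS).
#' @param luciferase_label,gelshift_label assay labels ("LoF"/"WT-like"/NA).
#' @param gnomad_ac,gnomad_af gnomAD allele count/frequency (NA = absent).
#' @param revel REVEL score or NA.
#' @param colocated co-located variant data.frame (see [acmg_colocated()]).
#' @param manual_items optional extra evidence-item data.frame.
#' @param bs1_threshold allele-frequency threshold for BS1.
#' @return object of class `evidence_profile`: variant, items, total,
#'   category.
#' @export
acmg_classify <- function(variant, luciferase_label, gelshift_label,
                          gnomad_ac = NA, gnomad_af = NA, revel = NA,
                          colocated = NULL, manual_items = NULL,
                          bs1_threshold = 0.001) {
  items <- rbind(
    acmg_population(gnomad_ac, gnomad_af, bs1_threshold),
    acmg_functional(luciferase_label, gelshift_label),
    acmg_computational(revel),
    acmg_colocated(revel, colocated),
    manual_items)
  structure(list(variant = variant, items = items,
                 total = as.integer(sum(items$points)),
                 category = acmg_categorize(sum(items$points))),
            class = "evidence_profile")
}

#' @export
print.evidence_profile <- function(x, ...) {
  cat(x$variant, ": ", x$total, " points -> ", x$category, "\n", sep = "")
  if (nrow(x$items))
    cat(sprintf("  %s (%+d): %s\n", x$items$code, x$items$points,
                x$items$rationale), sep = "")
  invisible(x)
}

parse_colocated <- function(encoded) {
  if (is.na(encoded) || !nzchar(encoded)) return(NULL)
  parts <- strsplit(strsplit(encoded, ";", fixed = TRUE)[[1]], "|", fixed = TRUE)
  data.frame(variant = vapply(parts, `[`, "", 1),
             class = vapply(parts, `[`, "", 2),
             revel = as.numeric(vapply(parts, `[`, "", 3)),
             stringsAsFactors = FALSE)
}

#' Classify a table of annotated variants
#'
#' Runs [acmg_classify()] on every row of an annotation table (the shape
#' returned by [stk11_annotations()]): columns `variant`, `luciferase`,
#' `gelshift`, `gnomad_ac`, `gnomad_af`, `revel` and `colocated` (encoded
#' `"VAR|CLASS|REVEL;..."` or NA).
#'
#' @param annotations annotation data.frame.
#' @param bs1_threshold allele-frequency threshold for BS1.
#' @return data.frame with per-code points, total and final category per
#'   variant; the full profiles are attached as attribute `"profiles"`.
#' @export
acmg_classify_all <- function(annotations, bs1_threshold = 0.001) {
  profiles <- lapply(seq_len(nrow(annotations)), function(i) {
    a <- annotations[i, ]
    acmg_classify(a$variant, a$luciferase, a$gelshift,
                  gnomad_ac = a$gnomad_ac, gnomad_af = a$gnomad_af,
                  revel = a$revel, colocated = parse_colocated(a$colocated),
                  bs1_threshold = bs1_threshold)
  })
  code_points <- function(p, codes)
    sum(p$items$points[p$items$code %in% codes])
  pop_code <- function(p) {
    c <- intersect(p$items$code, c("PM2", "BS1"))
    if (length(c)) c else NA_character_
  }
  comp_code <- function(p) {
    c <- intersect(p$items$code, c("PP3", "BP4"))
    if (length(c)) c else NA_character_
  }
  out <- data.frame(
    variant = annotations$variant,
    pop_code = vapply(profiles, pop_code, character(1)),
    pop_points = vapply(profiles, code_points, numeric(1), c("PM2", "BS1")),
    func_points = vapply(profiles, code_points, numeric(1), c("PS3", "BS3")),
    comp_code = vapply(profiles, comp_code, character(1)),
    comp_points = vapply(profiles, code_points, numeric(1), c("PP3", "BP4")),
    pm5_points = vapply(profiles, code_points, numeric(1), "PM5"),
    total = vapply(profiles, `[[`, integer(1), "total"),
    category = vapply(profiles, `[[`, character(1), "category"),
    stringsAsFactors = FALSE)
  attr(out, "profiles") <- profiles
  out
}
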