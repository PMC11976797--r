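# Packaged transcriptions of the 28-variant STK11 challenge tables:
# per-variant assay summaries with clinical annotations, and the inputs plus
# expected outputs of the clinical classification. Treated as read-only
# test data and verified by checksum at load time.

FIXTURE_MD5 <- c(
  stk11_table3.tsv = "9d245f385484771cd37fdb60a59b987c",
  stk11_table5.tsv = "8b15e3475a7f5e0f1f45b5fec3e7ad28"
)

read_fixture <- function(name) {
  path <- system.file("extdata", name, package = "stk11eval", mustWork = TRUE)
  md5 <- unname(tools::md5sum(path))
  if (md5 != FIXTURE_MD5[[name]])
    stop("packaged fixture ", name, " failed its integrity check (md5 ", md5, ")")
  utils::read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE,
                    na.strings = "NA", quote = "")
}

#' Packaged STK11 challenge assay summary (28 variants)
#'
#' Per-variant mean R-WT activity with 25th/75th percentiles, binary labels
#' from both assays, and ClinVar (2024-01-27), HGMD (2021-04) and gnomAD
#' (v4.1) annotations.
#'
#' @return data.frame: variant, gdna, clinvar, hgmd, gnomad_ac, gnomad_af,
#'   mean_rwt, p25, p75, luciferase, gelshift.
#' @export
stk11_activity <- function() read_fixture("stk11_table3.tsv")

#' Packaged clinical-classification table (inputs and expected outputs)
#'
#' REVEL scores, co-located P/LP variants (encoded `"VAR|CLASS|REVEL;..."`)
#' and — for golden-testing the point engine — the expected per-code points,
#' totals and final categories.
#'
#' @return data.frame keyed by variant.
#' @export
stk11_classification <- function() read_fixture("stk11_table5.tsv")

#' Combined annotation records for the 28 assayed variants
#'
#' Joins the assay summary with the classification inputs into the shape
#' consumed by [acmg_classify_all()] and [build_evaluation_set()].
#'
#' @return data.frame: variant, gdna, clinvar, hgmd, gnomad_ac, gnomad_af,
#'   mean_rwt, p25, p75, luciferase, gelshift, revel, colocated.
#' @export
stk11_annotations <- function() {
  t3 <- stk11_activity()
  t5 <- stk11_classification()
  merge(t3, t5[c("variant", "revel", "colocated")], by = "variant",
        sort = FALSE)
}
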