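test_that("functional evidence nets +2 / 0 / -2 at supporting strength", {
  expect_equal(sum(acmg_functional("LoF", "LoF")$points), 2)
  expect_equal(sum(acmg_functional("WT-like", "WT-like")$points), -2)
  expect_equal(sum(acmg_functional("LoF", "WT-like")$points), 0)     # p.H202R
  one <- acmg_functional("LoF", NA)
  expect_equal(sum(one$points), 1)
  expect_identical(nrow(one), 1L)
})

test_that("population evidence distinguishes absent / rare / common", {
  pm2 <- acmg_population(NA, NA)
  expect_identical(pm2$code, "PM2")
  expect_identical(pm2$points, 1L)
  bs1 <- acmg_population(8225, 5.10e-3)                # p.F354L
  expect_identical(bs1$code, "BS1")
  expect_identical(bs1$points, -4L)
  expect_identical(nrow(acmg_population(16, 1.02e-5)), 0L)   # indeterminate
  expect_identical(nrow(acmg_population(5, 3.16e-6)), 0L)
})

test_that("computational evidence follows the calibrated score intervals", {
  cases <- list(
    list(0.932, "PP3", 4L),   # closed left endpoint of strong
    list(0.954, "PP3", 4L),
    list(0.931, "PP3", 2L),   # just below the strong cut
    list(0.871, "PP3", 2L),
    list(0.773, "PP3", 2L),
    list(0.728, "PP3", 1L),
    list(0.644, "PP3", 1L),
    list(0.290, "BP4", -1L),  # closed right endpoint of supporting-benign
    list(0.215, "BP4", -1L),
    list(0.183, "BP4", -2L),
    list(0.102, "BP4", -2L),
    list(0.016, "BP4", -4L),
    list(0.004, "BP4", -4L))
  for (cs in cases) {
    it <- acmg_computational(cs[[1]])
    expect_identical(it$code, cs[[2]])
    expect_identical(it$points, cs[[3]])
  }
  for (gap in c(0.424, 0.643, 0.2905, 0.003, 0.001)) # no-code zones
    expect_identical(nrow(acmg_computational(gap)), 0L)
  expect_identical(nrow(acmg_computational(NA)), 0L)
  expect_error(acmg_computational(1.2), "outside")
})

coloc <- function(...) {
  rows <- list(...)
  data.frame(variant = sapply(rows, `[[`, 1), class = sapply(rows, `[[`, 2),
             revel = as.numeric(sapply(rows, `[[`, 3)),
             stringsAsFactors = FALSE)
}

test_that("PM5 qualification rounds to 2 decimals and counts all co-located", {
  # p.R297M: 0.936 -> 0.94 >= 0.94, single P: +2
  expect_identical(acmg_colocated(0.936, coloc(c("R297S", "P", 0.94)))$points, 2L)
  # p.G163R: 0.933 -> 0.93 < 0.95, withheld
  expect_identical(nrow(acmg_colocated(0.933, coloc(c("G163D", "P", 0.95)))), 0L)
  # p.D194Y: qualifies via the 0.84 entry, accumulates over all three Ps
  d194 <- acmg_colocated(0.929, coloc(c("D194H", "P", 0.94),
                                      c("D194V", "P", 0.94),
                                      c("D194E", "P", 0.84)))
  expect_identical(d194$points, 4L)
  # p.W308R: two LPs -> first LP +1, additional +1
  expect_identical(acmg_colocated(0.881, coloc(c("W308C", "LP", 0.73),
                                               c("W308L", "LP", 0.84)))$points, 2L)
  # p.P179R: single LP -> +1
  expect_identical(acmg_colocated(0.939, coloc(c("P179Q", "LP", 0.94)))$points, 1L)
  # mixed P + LP -> 2 + 1
  expect_identical(acmg_colocated(0.95, coloc(c("X1", "P", 0.90),
                                              c("X2", "LP", 0.80)))$points, 3L)
  # B/LB co-located entries are ignored
  expect_identical(nrow(acmg_colocated(0.95, coloc(c("X1", "LB", 0.10)))), 0L)
  expect_identical(nrow(acmg_colocated(NA, coloc(c("X1", "P", 0.9)))), 0L)
})

test_that("categorize applies the point ranges with the VUS subdivision", {
  expect_identical(acmg_categorize(c(10, 12)), c("P", "P"))
  expect_identical(acmg_categorize(c(6, 7, 9)), c("LP", "LP", "LP"))
  expect_identical(acmg_categorize(c(4, 5)), c("VUS-high", "VUS-high"))
  expect_identical(acmg_categorize(c(2, 3)), c("VUS-mid", "VUS-mid"))
  expect_identical(acmg_categorize(c(0, 1)), c("VUS-low", "VUS-low"))
  expect_identical(acmg_categorize(c(-1, -6)), c("LB", "LB"))
  expect_identical(acmg_categorize(c(-7, -20)), c("B", "B"))
  # monotone non-decreasing in the pathogenicity ordering
  ord <- c("B", "LB", "VUS-low", "VUS-mid", "VUS-high", "LP", "P")
  cats <- match(acmg_categorize(-12:14), ord)
  expect_true(all(diff(cats) >= 0))
})

test_that("removing evidence moves the total in the expected direction", {
  p <- acmg_classify("x", "LoF", "LoF", revel = 0.95,
                     colocated = coloc(c("y", "P", 0.90)))
  benign_removed <- sum(p$items$points[p$items$points > 0])
  patho_removed <- sum(p$items$points[p$items$points < 0])
  expect_gte(benign_removed, p$total)   # dropping benign items never lowers
  expect_lte(patho_removed, p$total)    # dropping pathogenic items never raises
})

test_that("the engine reproduces every fixture classification row exactly", {
  got <- acmg_classify_all(stk11_annotations())
  exp <- stk11_classification()
  got <- got[match(exp$variant, got$variant), ]
  expect_equal(got$pop_points, exp$pop_points)
  expect_equal(got$func_points, exp$func_points)
  expect_equal(got$comp_points, exp$comp_points)
  expect_equal(got$pm5_points, exp$pm5_points)
  expect_equal(got$total, exp$total)
  expect_identical(got$category, exp$category)
  expect_identical(ifelse(is.na(got$pop_code), NA, got$pop_code), exp$pop_code)
})

test_that("single-variant anchors classify as published", {
  ann <- stk11_annotations()
  cl <- function(v) {
    a <- ann[ann$variant == v, ]
    acmg_classify(v, a$luciferase, a$gelshift, a$gnomad_ac, a$gnomad_af,
                  a$revel, stk11eval:::parse_colocated(a$colocated))
  }
  expect_identical(cl("p.G56W")$total, 7L);   expect_identical(cl("p.G56W")$category, "LP")
  expect_identical(cl("p.K84del")$total, -2L); expect_identical(cl("p.K84del")$category, "LB")
  expect_identical(cl("p.S31F")$total, 1L);   expect_identical(cl("p.S31F")$category, "VUS-low")
  expect_identical(cl("p.H202R")$total, 0L);  expect_identical(cl("p.H202R")$category, "VUS-low")
  expect_identical(cl("p.F354L")$total, -8L); expect_identical(cl("p.F354L")$category, "B")
})

test_that("6 LP and 10 LB among variants without a prior definitive assertion", {
  ann <- stk11_annotations()
  got <- acmg_classify_all(ann)
  prior <- ann$clinvar %in% c("P", "LP", "P/LP", "B", "LB", "B/LB")
  novel <- got[!prior[match(got$variant, ann$variant)], ]
  expect_identical(nrow(novel), 24L)
  expect_identical(sum(novel$category == "LP"), 6L)
  expect_identical(sum(novel$category == "LB"), 10L)
})
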