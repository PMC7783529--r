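four_tissue_world <- function(vols = rep(10, 4)) {
  tissues <- c("intestine", "hypodermis", "neurons", "pharynx")
  list(meas = toy_measurements(vols, paste0("c", 1:4), tissues),
       rec = data.frame(cell = paste0("c", 1:4), tissue = tissues,
                        somatic = TRUE, nuclei = 1L, ploidy_c = 2,
                        stringsAsFactors = FALSE))
}

test_that("summarize_tissues computes totals and renormalised fractions", {
  w <- four_tissue_world()
  s <- summarize_tissues(w$meas, w$rec)
  expect_setequal(s$tissue, unique(w$rec$tissue))
  expect_equal(s$volume_fraction, rep(0.25, 4))
  expect_equal(sum(s$volume_fraction), 1, tolerance = 1e-12)
  expect_equal(sum(s$nuclei_fraction), 1, tolerance = 1e-12)

  # excluding a tissue renormalises fractions but leaves totals untouched
  s2 <- summarize_tissues(w$meas, w$rec, exclude = "neurons")
  expect_equal(s2$volume_fraction, rep(1 / 3, 3))
  expect_identical(s2$total_volume,
                   s$total_volume[match(s2$tissue, s$tissue)])

  # sum of totals equals sum of cell volumes exactly (no exclusions)
  expect_identical(sum(s$total_volume), sum(w$meas$calibrated_volume_um3))

  # orphan measurement -> strict-join error
  orphan <- w$meas; orphan$cell[1L] <- "ghost"
  expect_error(summarize_tissues(orphan, w$rec), "ghost")
})

test_that("include_germline toggles the non-somatic pseudo-record", {
  meas <- toy_measurements(c(10, 10, 20, 4), c("a1", "b1", "germ", "cut"),
                           c("intestine", "neurons", "germline", "cuticle"))
  rec <- toy_anatomy()
  s_in <- summarize_tissues(meas, rec, include_germline = TRUE, exclude = "cuticle")
  s_out <- summarize_tissues(meas, rec, include_germline = FALSE, exclude = "cuticle")
  expect_true("germline" %in% s_in$tissue)
  expect_false("germline" %in% s_out$tissue)
  expect_equal(s_in$volume_fraction[s_in$tissue == "germline"], 0.5)
  expect_equal(s_out$volume_fraction, c(0.5, 0.5))
  # cuticle excluded from fractions in both
  expect_false("cuticle" %in% c(s_in$tissue, s_out$tissue))
})

test_that("merge_gonads folds somatic gonad and germline into one row", {
  meas <- toy_measurements(c(6, 3, 1), c("a1", "g1", "b1"),
                           c("intestine", "somatic gonad", "germline"))
  rec <- data.frame(cell = c("a1", "g1", "b1"),
                    tissue = c("intestine", "somatic gonad", "germline"),
                    somatic = c(TRUE, TRUE, FALSE),
                    nuclei = c(1L, 1L, 8L), ploidy_c = 2,
                    stringsAsFactors = FALSE)
  s <- merge_gonads(summarize_tissues(meas, rec))
  expect_setequal(s$tissue, c("intestine", "gonads"))
  expect_identical(s$total_volume[s$tissue == "gonads"], 4)
  expect_equal(sum(s$volume_fraction), 1, tolerance = 1e-12)
})

test_that("volume_per_genome normalises by diploid genome copies", {
  meas <- toy_measurements(c(320, 100, 278, 4), c("a1", "b1", "germ", "cut"),
                           c("intestine", "neurons", "germline", "cuticle"))
  rec <- toy_anatomy()
  rec$nuclei[rec$cell == "germ"] <- 139L   # hyp7-like syncytium
  pg <- volume_per_genome(meas, rec)
  expect_identical(pg$volume_per_genome[pg$cell == "a1"], 20)      # 320 / 16
  expect_identical(pg$volume_per_genome[pg$cell == "b1"], 100)     # diploid identity
  expect_identical(pg$volume_per_genome[pg$cell == "germ"], 2)     # 278 / 139
  expect_true(is.na(pg$volume_per_genome[pg$cell == "cut"]))       # 0 genomes
})

test_that("distribution_stats uses strict thresholds and is monotone and order-invariant", {
  d <- distribution_stats(c(1, 2, 3, 4), thresholds = 2.5)
  expect_identical(d$fractions_below, 0.5)

  d2 <- distribution_stats(c(1, 2, 3, 4), thresholds = c(0.5, 2, 2.0001, 10))
  expect_identical(d2$fractions_below, c(0, 0.25, 0.5, 1))   # strict at 2
  expect_identical(d2$fractions_at_or_below[2L], 0.5)        # non-strict differs
  expect_true(all(diff(d2$fractions_below) >= 0))

  set.seed(5)
  v <- stats::rlnorm(200, 5, 1)
  th <- c(50, 150, 500, 1500)
  expect_identical(distribution_stats(v, th)$fractions_below,
                   distribution_stats(sample(v), th)$fractions_below)
  expect_error(distribution_stats(numeric(0)), "no values")
  expect_error(distribution_stats(c(-1, 2)), "non-negative")
})

test_that("rank_tissues orders by volume with lexicographic flagged ties", {
  w <- four_tissue_world(c(3, 2, 1, 2))
  r <- rank_tissues(summarize_tissues(w$meas, w$rec))
  expect_identical(r$tissue, c("intestine", "hypodermis", "pharynx", "neurons"))
  expect_identical(r$tied, c(FALSE, TRUE, TRUE, FALSE))
  expect_true(attr(r, "ties"))
  r2 <- rank_tissues(summarize_tissues(four_tissue_world(c(4, 3, 2, 1))$meas, w$rec))
  expect_false(attr(r2, "ties"))
})

test_that("extreme_ratios reports top-cell and per-genome tissue ratios", {
  w <- four_tissue_world(c(10, 1, 1, 1))
  er <- extreme_ratios(w$meas, w$rec)
  expect_identical(er$top_ratio, 10)
  expect_identical(er$largest_cells[1L], "c1")
  # intestine (10 per genome) vs others (mean 1)
  expect_identical(unname(er$per_genome_ratio["intestine"]), 10)

  er_eq <- extreme_ratios(four_tissue_world(rep(2, 4))$meas, w$rec)
  expect_identical(er_eq$top_ratio, 1)
  expect_error(extreme_ratios(w$meas[1L, ], w$rec), "at least 2")
})
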