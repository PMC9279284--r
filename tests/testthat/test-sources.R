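test_that("surface signatures are thickness-weighted means over the top layer", {
  one <- core_profile(data.frame(
    top_depth = 0, thickness = 6, dry_bulk_density = 0.4,
    pb210_total = 100, ra226 = 20, oc_percent = 5,
    d13c = -27.3, cn_molar = 12.5), lake_id = "L1")
  sig <- surface_signature(one)
  expect_equal(sig$d13c, -27.3); expect_equal(sig$cn_molar, 12.5)
  # two 3-cm intervals at -28 and -26 permil -> -27
  two <- core_profile(data.frame(
    top_depth = c(0, 3), thickness = 3, dry_bulk_density = 0.4,
    pb210_total = 100, ra226 = 20, oc_percent = 5,
    d13c = c(-28, -26), cn_molar = c(10, 14)))
  expect_equal(surface_signature(two)$d13c, -27)
  expect_equal(surface_signature(two)$cn_molar, 12)
  # unequal thicknesses: hand-computed weighted mean; the 4-6 cm interval
  # also counts, the 6-10 cm one does not
  uneq <- core_profile(data.frame(
    top_depth = c(0, 4, 6), thickness = c(4, 2, 4), dry_bulk_density = 0.4,
    pb210_total = 100, ra226 = 20, oc_percent = 5,
    d13c = c(-30, -24, -20), cn_molar = c(8, 20, 30)))
  expect_equal(surface_signature(uneq)$d13c, (4 * -30 + 2 * -24) / 6)
  deep <- core_profile(data.frame(
    top_depth = 8, thickness = 4, dry_bulk_density = 0.4,
    pb210_total = 100, ra226 = 20, oc_percent = 5,
    d13c = -27, cn_molar = 12))
  expect_error(surface_signature(deep), "top 6 cm")
})

test_that("apportionment assigns points to containing rectangles", {
  em <- default_endmembers()
  inside_soil <- data.frame(d13c = c(-26, -25.5, -27), cn_molar = c(10, 12, 9))
  ap <- apportion_sources(inside_soil, em)
  expect_equal(unname(ap$contributions["C3 soil"]), 100)
  expect_equal(sum(ap$contributions) + ap$unclassified_pct, 100)
  # a point outside every rectangle is unclassified
  out <- apportion_sources(data.frame(d13c = -5, cn_molar = 50), em)
  expect_equal(out$unclassified_pct, 100)
  # a boundary point counts as inside
  edge <- apportion_sources(data.frame(d13c = -24, cn_molar = 14), em)
  expect_equal(unname(edge$contributions["C3 soil"]), 100)
  expect_error(apportion_sources(inside_soil[0, ], em), "empty")
})

test_that("known mixing proportions are recovered exactly from disjoint boxes", {
  em <- endmember_set(
    d13c_ranges = list(a = c(-35, -30), b = c(-28, -24), c = c(-20, -16),
                       d = c(-12, -9)),
    cn_ranges = list(a = c(4, 8), b = c(10, 14), c = c(16, 20), d = c(25, 30)))
  smp <- make_source_samples(em, c(a = 0.4, b = 0.3, c = 0.3, d = 0),
                             n = 1000, seed = 12)
  ap <- apportion_sources(smp$signatures, em)
  expect_equal(unname(ap$contributions[c("a", "b", "c", "d")]),
               c(40, 30, 30, 0))
  expect_equal(ap$unclassified_pct, 0)
  # assignments agree with the generator's truth labels
  expect_equal(ap$assignment, smp$truth)
})

test_that("contributions are permutation-invariant and rectangle-monotone", {
  em <- default_endmembers()
  smp <- make_source_samples(em, c("C3 soil" = 0.5, "C3 plants" = 0.3,
                                   "phytoplankton" = 0.1, "C4 plants" = 0),
                             n = 400, seed = 3)
  ap1 <- apportion_sources(smp$signatures, em)
  set.seed(1)
  shuffled <- smp$signatures[sample(nrow(smp$signatures)), ]
  ap2 <- apportion_sources(shuffled, em)
  expect_equal(ap1$contributions, ap2$contributions)
  # shrinking the soil rectangle never increases its contribution
  em_small <- em
  em_small[em_small$source == "C3 soil", c("d13c_min", "cn_max")] <- c(-28, 12)
  ap3 <- apportion_sources(smp$signatures, em_small)
  expect_lte(ap3$contributions[["C3 soil"]], ap1$contributions[["C3 soil"]])
})

test_that("points inside overlapping rectangles are counted unclassified", {
  em <- endmember_set(d13c_ranges = list(a = c(-30, -20), b = c(-25, -15)),
                      cn_ranges = list(a = c(5, 15), b = c(10, 20)))
  ap <- apportion_sources(data.frame(d13c = c(-22, -28, -17),
                                     cn_molar = c(12, 8, 18)), em)
  expect_equal(ap$n_ambiguous, 1)
  expect_equal(unname(ap$contributions), c(100 / 3, 100 / 3))
  expect_equal(ap$unclassified_pct, 100 / 3)
})

test_that("endmember YAML config round-trips", {
  path <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c("endmembers:",
               "  C3 soil: {d13c: [-30, -24], cn: [8, 14]}",
               "  phytoplankton: {d13c: [-35, -28], cn: [4, 8]}"), path)
  em <- read_endmembers(path)
  expect_s3_class(em, "endmember_set")
  expect_equal(nrow(em), 2)
  expect_equal(em$cn_max[em$source == "C3 soil"], 14)
})
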