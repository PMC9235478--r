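test_that("z-scores are computed from beta/se and bad rows are dropped and counted", {
  rows <- data.frame(
    snp = c("rs1", "rs2", "rs3", "rs4", "rs5"),
    chr = "1", pos = c(1000L, 2000L, 3000L, 4000L, 5000L),
    ea = c("A", "A", "A", "A", "A"), oa = c("G", "G", "G", "A", "G"),
    beta = c(0.1, 0.2, 0.3, 0.1, NA), se = c(0.05, 0, 0.1, 0.1, 0.1))
  scan <- read_sumstats(write_sumstats_fixture(rows), "t1")
  expect_equal(scan$z[scan$id == "rs1"], 2.0)
  expect_setequal(scan$id, c("rs1", "rs3"))
  drops <- attr(scan, "n_dropped")
  expect_equal(unname(drops["bad_se"]), 1L)      # rs2
  expect_equal(unname(drops["bad_alleles"]), 1L) # rs4 (ea == oa)
  expect_equal(unname(drops["nonfinite"]), 1L)   # rs5
})

test_that("a mapped z column is taken verbatim and alleles are uppercased", {
  rows <- data.frame(snp = "rs1", chr = "1", pos = 1000L,
                     ea = "a", oa = "g", zscore = 3.25)
  scan <- read_sumstats(write_sumstats_fixture(rows), "t1",
                        column_map = sumstats_columns(z = "zscore"))
  expect_equal(scan$z, 3.25)
  expect_equal(scan$ea, "A")
  expect_equal(scan$oa, "G")
})

test_that("a missing mapped column is a hard error naming the column", {
  rows <- data.frame(snp = "rs1", chr = "1", pos = 1L, ea = "A", oa = "G",
                     beta = 0.1)
  expect_error(read_sumstats(write_sumstats_fixture(rows), "t1"), "se")
})

test_that("duplicated ids keep the first occurrence with a warning", {
  rows <- data.frame(snp = c("rs1", "rs1"), chr = "1", pos = c(1L, 2L),
                     ea = "A", oa = "G", beta = c(0.1, 0.9), se = 0.1)
  expect_warning(scan <- read_sumstats(write_sumstats_fixture(rows), "t1"),
                 "duplicated")
  expect_equal(nrow(scan), 1L)
  expect_equal(scan$z, 1)
})

test_that("write/read round trip reproduces z-scores bit-identically", {
  set.seed(3)
  z <- rnorm(200) * exp(rnorm(200))
  scan <- make_scan("t1", sprintf("rs%d", 1:200), "A", "G", z)
  path <- tempfile(fileext = ".tsv")
  write_sumstats(scan, path)
  back <- read_sumstats(path, "t1")
  expect_identical(back$z, z)
})

test_that("harmonization flips swapped alleles, drops irreconcilable ones, intersects ids", {
  s1 <- make_scan("t1", c("rs1", "rs2", "rs3"), c("A", "A", "A"),
                  c("G", "G", "C"), c(2.0, 1.0, 0.5))
  s2 <- make_scan("t2", c("rs1", "rs2", "rs3", "rs4"),
                  c("G", "A", "A", "A"), c("A", "C", "C", "G"),
                  c(1.5, 0.7, 0.5, 0.1))
  panel <- harmonize_and_merge(list(s1, s2))
  # rs1: swapped -> sign flip; rs2: A/G vs A/C irreconcilable -> dropped;
  # rs3: A/C in both -> direct; rs4 absent from t1 -> outside intersection
  expect_setequal(panel$variants$id, c("rs1", "rs3"))
  expect_equal(panel$Z[panel$variants$id == "rs1", ], c(t1 = 2.0, t2 = -1.5))
  expect_equal(panel$Z[panel$variants$id == "rs3", ], c(t1 = 0.5, t2 = 0.5))
})

test_that("strand flips are resolved by reverse complement, palindromic variants flagged", {
  # t1 A/G vs t2 T/C: reverse-complement direct match, no sign flip
  s1 <- make_scan("t1", c("rs1", "rs2"), c("A", "A"), c("G", "T"), c(1.0, 2.0))
  s2 <- make_scan("t2", c("rs1", "rs2"), c("T", "T"), c("C", "A"), c(0.5, 1.5))
  panel <- harmonize_and_merge(list(s1, s2))
  expect_equal(unname(panel$Z[panel$variants$id == "rs1", 2]), 0.5)
  # rs2 is A/T palindromic: swapped orientation (sign flip), flagged ambiguous
  expect_true(panel$variants$ambiguous[panel$variants$id == "rs2"])
  expect_equal(unname(panel$Z[panel$variants$id == "rs2", 2]), -1.5)
  dropped <- harmonize_and_merge(list(s1, s2), drop_ambiguous = TRUE)
  expect_false("rs2" %in% dropped$variants$id)
})

test_that("merge is order-insensitive up to the reference-trait sign convention", {
  set.seed(7)
  ids <- sprintf("rs%d", 1:50)
  z1 <- rnorm(50); z2 <- rnorm(50)
  s1 <- make_scan("t1", ids, "A", "G", z1)
  s2 <- make_scan("t2", ids, "G", "A", z2)  # swapped orientation
  ab <- harmonize_and_merge(list(s1, s2))
  ba <- harmonize_and_merge(list(s2, s1))
  # re-express ba on t1's orientation: flip all signs (alleles were swapped)
  expect_equal(ab$Z[, "t1"], -ba$Z[match(ab$variants$id, ba$variants$id), "t1"])
  expect_equal(ab$Z[, "t2"], -ba$Z[match(ab$variants$id, ba$variants$id), "t2"])
  expect_lte(nrow(ab$Z), min(nrow(s1), nrow(s2)))
})

test_that("empty intersection and too-few scans are hard errors", {
  s1 <- make_scan("t1", "rs1", "A", "G", 1)
  s2 <- make_scan("t2", "rs2", "A", "G", 1)
  expect_error(harmonize_and_merge(list(s1, s2)), "shared")
  expect_error(harmonize_and_merge(list(s1)), "at least 2")
})

test_that("panel TSV round trip is bit-identical", {
  set.seed(9)
  panel <- planted_panel(50, matrix(c(3.3, -1.1), 1))
  path <- tempfile(fileext = ".tsv")
  write_panel(panel, path)
  back <- read_panel(path)
  expect_identical(back$Z, panel$Z)
  expect_equal(back$traits, panel$traits)
})
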