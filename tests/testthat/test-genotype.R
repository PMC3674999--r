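# Genotype reading, allele policies, and marker merging.

test_that("toy genotype table is read with B=0 / D=1 coding in input order", {
  panel <- read_genotype_table(write_toy_genotype())
  expect_s3_class(panel, "genotype_panel")
  expect_identical(panel$strains, c("BXD1", "BXD2", "BXD3"))
  expect_identical(colnames(panel$calls), c("m1", "m2"))
  # m1: B,D,B ; m2: D,D,B  -> strains x markers
  expect_equal(unname(panel$calls),
               matrix(c(0L, 1L, 0L, 1L, 1L, 0L), nrow = 3))
  expect_equal(panel$markers$interval_start_bp, c(1000L, 2000L))
})

test_that("heterozygous and unknown calls follow the configured policy", {
  path <- write_toy_genotype(extra_rows = "chr1\tm3\t3000\tH\tD\tB")
  expect_error(read_genotype_table(path), "m3.*BXD1|BXD1.*m3")
  suppressMessages(
    panel <- read_genotype_table(path, policy = "drop")
  )
  expect_identical(colnames(panel$calls), c("m1", "m2"))
})

test_that("malformed tables are rejected with informative errors", {
  bad_sym <- write_toy_genotype(extra_rows = "chr1\tm3\t3000\tZ\tD\tB")
  expect_error(read_genotype_table(bad_sym), "unknown allele symbol 'Z'")
  dup <- write_toy_genotype(extra_rows = "chr1\tm1\t3000\tB\tD\tB")
  expect_error(read_genotype_table(dup), "duplicate marker id")
})

test_that("non-monotone positions warn and are stably re-sorted", {
  path <- tempfile(fileext = ".tsv")
  writeLines(c("Chr\tLocus\tPosition\ts1\ts2",
               "chr1\tm2\t5000\tB\tD",
               "chr1\tm1\t1000\tD\tB"), path)
  expect_warning(panel <- read_genotype_table(path), "re-sorting")
  expect_identical(colnames(panel$calls), c("m1", "m2"))
  expect_equal(panel$markers$interval_start_bp, c(1000L, 5000L))
})

test_that("Mb positions are converted to bp", {
  path <- tempfile(fileext = ".tsv")
  writeLines(c("Chr\tLocus\tPosition\ts1\ts2",
               "chr1\tm1\t1.5\tB\tD"), path)
  panel <- read_genotype_table(path, position_unit = "Mb")
  expect_equal(panel$markers$interval_start_bp, 1500000L)
})

test_that("write/read round-trips a genotype panel", {
  panel <- read_genotype_table(write_toy_genotype())
  out <- tempfile(fileext = ".tsv")
  write_genotype_table(panel, out)
  back <- read_genotype_table(out)
  expect_equal(back$calls, panel$calls)
  expect_equal(back$markers$interval_start_bp, panel$markers$interval_start_bp)
})

test_that("adjacent identical marker columns are merged into one interval", {
  calls <- cbind(m1 = c(0L, 1L, 0L), m2 = c(1L, 1L, 0L),
                 m3 = c(1L, 1L, 0L), m4 = c(0L, 0L, 1L))
  panel <- toy_panel(calls, positions = c(100, 200, 300, 400))
  merged <- merge_identical_markers(panel)
  expect_equal(nrow(merged$markers), 3)
  expect_identical(merged$markers$marker_id, c("m1", "m2", "m4"))
  # merged marker spans [start(m2), end(m3)] and records both members
  expect_equal(merged$markers$interval_start_bp[2], 200)
  expect_equal(merged$markers$interval_end_bp[2], 300)
  expect_identical(merged$markers$member_ids[[2]], c("m2", "m3"))
  # idempotent
  expect_equal(merge_identical_markers(merged)$markers, merged$markers)
})

test_that("merging respects chromosome boundaries and distinct columns", {
  calls <- cbind(m1 = c(0L, 1L), m2 = c(0L, 1L))
  across <- toy_panel(calls, chromosome = c("chr1", "chr2"))
  expect_equal(nrow(merge_identical_markers(across)$markers), 2)
  distinct <- toy_panel(cbind(m1 = c(0L, 1L), m2 = c(1L, 1L)))
  expect_equal(merge_identical_markers(distinct)$calls, distinct$calls)
})

test_that("merging preserves strains and per-strain allele information", {
  set.seed(42)
  for (rep in 1:5) {
    calls <- matrix(rbinom(8 * 12, 1, 0.5), 8, 12)
    panel <- toy_panel(calls)
    merged <- merge_identical_markers(panel)
    expect_identical(merged$strains, panel$strains)
    # projecting merged calls back onto members reproduces the original
    for (j in seq_len(nrow(merged$markers))) {
      for (mem in merged$markers$member_ids[[j]]) {
        expect_equal(unname(merged$calls[, j]), unname(panel$calls[, mem]))
      }
    }
    # no two adjacent same-chromosome columns identical after merging
    if (ncol(merged$calls) > 1) {
      for (j in 2:ncol(merged$calls)) {
        expect_false(all(merged$calls[, j] == merged$calls[, j - 1]))
      }
    }
  }
})
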