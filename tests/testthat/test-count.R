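make_pool <- function(seqs, ids = NULL) {
  ids <- ids %||% sprintf("m%d", seq_along(seqs))
  reference_pool(ids, seqs, rep(1 / length(seqs), length(seqs)))
}
`%||%` <- function(a, b) if (is.null(a)) b else a

test_that("exact matches are counted and totals always balance", {
  pool <- make_pool(c(strrep("ACGT", 5), strrep("TGCA", 5)))
  reads <- reads_from_seq(c(strrep("ACGT", 5), strrep("ACGT", 5),
                            strrep("TGCA", 5), strrep("GGGG", 5)))
  ct <- count_reads(reads, pool, max_mismatches = 0)
  expect_equal(unname(ct$counts), c(2, 1))
  expect_equal(ct$unassigned, 1)
  expect_equal(ct$depth + ct$unassigned, nrow(reads))
})

test_that("mismatch threshold is a hard boundary", {
  ref <- strrep("ACGT", 5)
  mutated <- paste0("T", substr(ref, 2, 20))
  pool <- make_pool(ref)
  expect_equal(count_reads(reads_from_seq(mutated), pool,
                           max_mismatches = 0)$unassigned, 1)
  ct1 <- count_reads(reads_from_seq(mutated), pool, max_mismatches = 1)
  expect_equal(unname(ct1$counts), 1)
  expect_error(count_reads(reads_from_seq(ref), pool, max_mismatches = 3),
               class = "srnabias_invalid_argument")
})

test_that("3' length tolerance is prefix-anchored and bounded", {
  ref <- strrep("ACGT", 5)
  pool <- make_pool(ref)
  longer2 <- paste0(ref, "TG")   # read runs 2 nt past the reference
  shorter2 <- substr(ref, 1, 18)
  longer3 <- paste0(ref, "TGG")
  ct <- count_reads(reads_from_seq(c(longer2, shorter2, longer3)), pool)
  expect_equal(unname(ct$counts), 2)
  expect_equal(ct$unassigned, 1)
})

test_that("multimapping reads are shared fractionally across ties", {
  a <- paste0(strrep("ACGT", 5), "AA")
  b <- paste0(strrep("ACGT", 5), "CC")
  pool <- make_pool(c(a, b))
  # the bare 20-mer is 2 nt short of both references, mismatch-free
  ct <- count_reads(reads_from_seq(strrep("ACGT", 5)), pool)
  expect_equal(unname(ct$counts), c(0.5, 0.5))
  expect_equal(ct$depth, 1)
  # a closer reference (smaller length difference) wins the tie
  pool2 <- make_pool(c(a, paste0(strrep("ACGT", 5), "A")))
  ct2 <- count_reads(reads_from_seq(strrep("ACGT", 5)), pool2)
  expect_equal(unname(ct2$counts), c(0, 1))
})

test_that("an empty read set yields an all-zero table", {
  pool <- make_pool(strrep("ACGT", 5))
  ct <- count_reads(read_set(character(0), character(0), character(0)), pool)
  expect_equal(unname(ct$counts), 0)
  expect_equal(ct$unassigned, 0)
})

test_that("error-free simulated reads recover the truth table exactly", {
  pool <- build_equimolar_pool(100, seed = 41)
  prof <- sample_bias_profile(pool, sigma_log2 = 1.5, dimer_rate = 0.03,
                              seed = 42)
  lib <- simulate_library(pool, prof, 20000, seed = 43)
  tr <- trim_adapter(lib$reads)
  ct <- count_reads(tr$kept, pool)
  expect_equal(unname(ct$counts[lib$truth$ref_id]),
               as.numeric(lib$truth$realized_count))
  expect_equal(ct$unassigned, 0)
})

test_that("count tables round-trip through TSV", {
  pool <- make_pool(c(strrep("ACGT", 5), strrep("TGCA", 5)))
  ct <- count_reads(reads_from_seq(strrep("ACGT", 5)), pool,
                    library_id = "libA")
  path <- withr::local_tempfile(fileext = ".tsv")
  write_count_table(ct, path)
  back <- read_count_table(path)
  expect_equal(back$counts, ct$counts)
  expect_equal(back$library_id, "libA")
  expect_equal(back$unassigned, ct$unassigned)
})

test_that("subsampling returns exactly the target depth in input order", {
  reads <- planted_adapter_reads(500, seed = 3)
  sub <- subsample_reads(reads, 120, seed = 4)
  expect_equal(nrow(sub), 120)
  expect_true(all(diff(match(sub$read_id, reads$read_id)) > 0))
  expect_identical(subsample_reads(reads, 120, seed = 4), sub)
  # full-depth subsample is the identity
  expect_identical(subsample_reads(reads, nrow(reads), seed = 9)$read_id,
                   reads$read_id)
})

test_that("oversubsampling errors name both depths", {
  reads <- planted_adapter_reads(50, seed = 3)
  err <- expect_error(subsample_reads(reads, 51, seed = 1),
                      class = "srnabias_insufficient_depth")
  expect_match(conditionMessage(err), "51")
  expect_match(conditionMessage(err), "50")
})

test_that("nested subsampling behaves like direct subsampling", {
  # D1 then D2 < D1 should leave a reference's read share hypergeometric
  # around its library share, just as a direct D2 subsample does
  pool <- build_equimolar_pool(10, seed = 51)
  prof <- sample_bias_profile(pool, sigma_log2 = 0, dimer_rate = 0, seed = 1)
  lib <- simulate_library(pool, prof, 4000, seed = 52)
  target <- pool$ref_id[1]
  share <- function(rs) mean(grepl(paste0(":", target, "$"), rs$read_id))
  p0 <- share(lib$reads)
  nested <- vapply(1:60, function(s) {
    share(subsample_reads(subsample_reads(lib$reads, 2000, seed = s),
                          400, seed = s + 1000))
  }, numeric(1))
  direct <- vapply(1:60, function(s) {
    share(subsample_reads(lib$reads, 400, seed = s + 2000))
  }, numeric(1))
  se <- sqrt(p0 * (1 - p0) / 400) / sqrt(60)
  expect_lt(abs(mean(nested) - p0), 4 * se)
  expect_lt(abs(mean(nested) - mean(direct)), 6 * se)
})
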