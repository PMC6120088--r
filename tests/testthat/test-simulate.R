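test_that("simulated libraries emit exactly the requested depth", {
  pool <- build_equimolar_pool(50, seed = 1)
  prof <- sample_bias_profile(pool, sigma_log2 = 1, dimer_rate = 0.05,
                              seed = 2)
  for (depth in c(1, 997, 20000)) {
    lib <- simulate_library(pool, prof, depth, seed = 3)
    expect_equal(nrow(lib$reads), depth)
    expect_equal(lib$n_dimer, floor(0.05 * depth))
    expect_equal(sum(lib$truth$realized_count), depth - lib$n_dimer)
    expect_true(all(nchar(lib$reads$quality) == nchar(lib$reads$sequence)))
  }
})

test_that("read sequences are insert plus adapter truncated to read length", {
  seqs <- c(strrep("A", 22), strrep("C", 30))
  pool <- reference_pool(c("a", "c"), seqs, c(0.5, 0.5))
  prof <- bias_profile(c("a", "c"), c(1, 1), c(0.9, 0.9))
  lib <- simulate_library(pool, prof, depth = 200, read_length = 36, seed = 1)
  ad <- "TGGAATTCTCGGGTGCCAAGG"
  a_reads <- lib$reads$sequence[grepl(":a$", lib$reads$read_id)]
  c_reads <- lib$reads$sequence[grepl(":c$", lib$reads$read_id)]
  # 22 nt insert + first 14 adapter nt
  expect_true(all(a_reads == paste0(strrep("A", 22), substr(ad, 1, 14))))
  # 30 nt insert + first 6 adapter nt
  expect_true(all(c_reads == paste0(strrep("C", 30), substr(ad, 1, 6))))
  expect_true(all(nchar(lib$reads$sequence) == 36))
})

test_that("U-containing pool sequences are emitted as DNA", {
  pool <- reference_pool("u1", paste0(strrep("ACGU", 5)), 1)
  prof <- bias_profile("u1", 1, 0.9)
  lib <- simulate_library(pool, prof, depth = 5, read_length = 36, seed = 1)
  expect_false(any(grepl("U", lib$reads$sequence)))
  expect_true(startsWith(lib$reads$sequence[1], strrep("ACGT", 5)))
})

test_that("adapter-dimer reads are bare adapter and absent at rate zero", {
  pool <- build_equimolar_pool(10, seed = 1)
  prof0 <- sample_bias_profile(pool, dimer_rate = 0, seed = 2)
  lib0 <- simulate_library(pool, prof0, 2000, seed = 3)
  ad <- "TGGAATTCTCGGGTGCCAAGG"
  expect_equal(sum(lib0$reads$sequence == ad), 0)
  prof <- sample_bias_profile(pool, dimer_rate = 0.1, seed = 2)
  lib <- simulate_library(pool, prof, 2000, seed = 3)
  expect_equal(sum(lib$reads$sequence == ad), 200)
})

test_that("simulation and FASTQ output are byte-identical per seed", {
  pool <- build_equimolar_pool(20, seed = 1)
  prof <- sample_bias_profile(pool, seed = 2)
  a <- simulate_library(pool, prof, 5000, seed = 9)
  b <- simulate_library(pool, prof, 5000, seed = 9)
  c <- simulate_library(pool, prof, 5000, seed = 10)
  expect_identical(a, b)
  expect_false(identical(a$reads$sequence, c$reads$sequence))
  f1 <- withr::local_tempfile(fileext = ".fastq")
  f2 <- withr::local_tempfile(fileext = ".fastq")
  write_fastq(a$reads, f1)
  write_fastq(b$reads, f2)
  expect_identical(readLines(f1), readLines(f2))
  back <- read_fastq(f1)
  expect_equal(back$sequence, a$reads$sequence)
  expect_equal(back$read_id, a$reads$read_id)
})

test_that("unbiased equimolar simulation matches the multinomial oracle", {
  # binomial mean/variance under the stated multinomial: every count within
  # 5 standard deviations of depth/n
  n <- 100
  depth <- 50000
  pool <- build_equimolar_pool(n, seed = 21)
  prof <- sample_bias_profile(pool, sigma_log2 = 0, gc_pcr_slope = 0,
                              dimer_rate = 0, seed = 1)
  lib <- simulate_library(pool, prof, depth, seed = 5)
  p <- 1 / n
  sdev <- sqrt(depth * p * (1 - p))
  expect_true(all(abs(lib$truth$realized_count - depth * p) <= 5 * sdev))
})

test_that("unbiased counts pass a chi-square goodness-of-fit sweep", {
  # with all capture and PCR weights equal, uniform expectation should not
  # be rejected at alpha = 0.001 in more than 2 of 20 seeds
  pool <- build_equimolar_pool(200, seed = 31)
  prof <- sample_bias_profile(pool, sigma_log2 = 0, gc_pcr_slope = 0,
                              dimer_rate = 0, seed = 1)
  rejections <- sum(vapply(1:20, function(s) {
    lib <- simulate_library(pool, prof, 100000, seed = s)
    stats::chisq.test(lib$truth$realized_count)$p.value < 0.001
  }, logical(1)))
  expect_lte(rejections, 2)
})

test_that("simulation rejects invalid arguments", {
  pool <- build_equimolar_pool(5, seed = 1)
  prof <- sample_bias_profile(pool, seed = 1)
  expect_error(simulate_library(pool, prof, 0),
               class = "srnabias_invalid_argument")
  expect_error(simulate_library(pool, prof, 10, adapter = "ACGTN"),
               class = "srnabias_invalid_argument")
  expect_error(simulate_library(pool, prof, 10, adapter = ""),
               class = "srnabias_invalid_argument")
})
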