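equi_pool <- function(n) {
  reference_pool(sprintf("m%03d", 1:n), random_dna(n, rep(21, n), seed = n),
                 rep(1 / n, n))
}

counts_for <- function(pool, obs, id = "lib") {
  count_table(id, stats::setNames(obs, pool$ref_id))
}

test_that("a perfectly uniform library has zero fold-deviation everywhere", {
  pool <- equi_pool(8)
  fdt <- fold_deviation(counts_for(pool, rep(500, 8)), pool)
  expect_equal(fdt$log2_fd, rep(0, 8))
  expect_equal(attr(fdt, "summary")$percent_accurate, 100)
  expect_true(all(fdt$bias_class == "accurate"))
})

test_that("fold-deviation reproduces the expected-count arithmetic", {
  # one member at a quarter of its expected 1000 reads: log2(250/1000) = -2
  n <- 963
  pool <- build_equimolar_pool(n, seed = 61)
  obs <- rep((963000 - 250) / 962, n)
  obs[5] <- 250
  fdt <- fold_deviation(counts_for(pool, obs), pool)
  expect_equal(fdt$expected[5], 1000)
  expect_equal(fdt$log2_fd[5], -2)
  expect_equal(fdt$bias_class[5], "under")
})

test_that("classification respects inclusive boundaries and the threshold", {
  pool <- equi_pool(3)
  o <- c(125, 1000, 4000)
  fdt <- fold_deviation(counts_for(pool, o), pool)
  fd <- log2(o / (sum(o) / 3))
  expect_equal(fdt$log2_fd, fd)
  expect_equal(fdt$bias_class, ifelse(fd < -1, "under",
                                      ifelse(fd > 1, "over", "accurate")))
  expect_equal(attr(fdt, "summary")$percent_accurate, 100 / 3)

  # exact boundary: observed = expected / 2 gives log2_fd = -1 -> accurate
  pool2 <- equi_pool(4)
  obs2 <- c(0.5, 7 / 6, 7 / 6, 7 / 6) * 1000
  fdt2 <- fold_deviation(counts_for(pool2, obs2), pool2, tau = 1)
  expect_equal(fdt2$log2_fd[1], -1)
  expect_equal(fdt2$bias_class[1], "accurate")
})

test_that("percentages agree with a brute-force loop and sum to 100", {
  pool <- build_equimolar_pool(963, seed = 62)
  obs <- srnabias:::with_seed(63, stats::rpois(963, 2000) *
                                2^stats::rnorm(963, 0, 1.5))
  fdt <- fold_deviation(counts_for(pool, obs), pool, tau = 1)
  s <- attr(fdt, "summary")
  # brute force over the emitted table
  n_u <- 0; n_a <- 0; n_o <- 0
  for (i in seq_len(nrow(fdt))) {
    if (fdt$observed[i] == 0) n_u <- n_u + 1
    else if (fdt$log2_fd[i] < -1) n_u <- n_u + 1
    else if (fdt$log2_fd[i] > 1) n_o <- n_o + 1
    else n_a <- n_a + 1
  }
  expect_equal(s$percent_under, 100 * n_u / 963)
  expect_equal(s$percent_accurate, 100 * n_a / 963)
  expect_equal(s$percent_over, 100 * n_o / 963)
  expect_lt(abs(s$percent_under + s$percent_accurate + s$percent_over - 100),
            1e-6)
})

test_that("fold-deviation is invariant to count rescaling", {
  pool <- equi_pool(12)
  obs <- srnabias:::with_seed(64, stats::runif(12, 10, 5000))
  f1 <- fold_deviation(counts_for(pool, obs), pool)
  f2 <- fold_deviation(counts_for(pool, obs * 7.5), pool)
  expect_equal(f1$log2_fd, f2$log2_fd)
})

test_that("raising one member's count never lowers its fold-deviation", {
  pool <- equi_pool(10)
  obs <- rep(100, 10)
  fds <- vapply(c(100, 150, 400, 1000, 5000), function(v) {
    o <- obs
    o[3] <- v
    fold_deviation(counts_for(pool, o), pool)$log2_fd[3]
  }, numeric(1))
  expect_true(all(diff(fds) > 0))
})

test_that("undetected members are floored, flagged and counted as under", {
  pool <- equi_pool(5)
  obs <- c(0, 400, 400, 400, 400)
  fdt <- fold_deviation(counts_for(pool, obs), pool)
  expect_equal(fdt$bias_class[1], "undetected")
  expect_equal(fdt$log2_fd[1], log2(0.5 / fdt$expected[1]))
  s <- attr(fdt, "summary")
  expect_equal(s$percent_under, 20)
  expect_equal(s$percent_undetected, 20)
  # omit policy drops them from the denominator
  fdt2 <- fold_deviation(counts_for(pool, obs), pool, zero_policy = "omit")
  expect_equal(attr(fdt2, "summary")$percent_accurate, 100)
})

test_that("degenerate tables raise classed errors", {
  pool <- equi_pool(3)
  expect_error(fold_deviation(counts_for(pool, c(0, 0, 0)), pool),
               class = "srnabias_data_error")
  fdt <- fold_deviation(counts_for(pool, c(10, 10, 10)), pool)
  expect_error(classify_bias(fdt, tau = 0),
               class = "srnabias_invalid_argument")
})

test_that("the Welch t-test matches the textbook formula", {
  a <- c(70, 72, 74)
  b <- c(30, 32, 34)
  got <- compare_percent_unbiased(a, b)
  want <- oracle_welch(a, b)
  expect_lt(abs(unname(got$statistic) - want$t), 1e-10)
  expect_lt(abs(got$p.value - want$p), 1e-10)
  # antisymmetry
  rev <- compare_percent_unbiased(b, a)
  expect_equal(unname(rev$statistic), -unname(got$statistic))
  expect_equal(rev$p.value, got$p.value)
  # identical groups with variance: t = 0, p = 1
  same <- compare_percent_unbiased(a, a)
  expect_equal(unname(same$statistic), 0)
  expect_equal(same$p.value, 1)
  expect_error(compare_percent_unbiased(c(50, 50), c(50, 50)),
               class = "srnabias_data_error")
  expect_error(compare_percent_unbiased(70, c(30, 32)),
               class = "srnabias_invalid_argument")
})
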