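test_that("correlation matrix has unit diagonal and matches the formula", {
  pool <- build_equimolar_pool(60, seed = 101)
  prof <- sample_bias_profile(pool, sigma_log2 = 1.5, dimer_rate = 0,
                              seed = 102)
  # dilution emulation: same capture profile, tenfold depth steps
  libs <- lapply(c(20000, 2000, 200), function(d) {
    lib <- simulate_library(pool, prof, d, seed = d)
    tr <- trim_adapter(lib$reads)
    count_reads(tr$kept, pool, library_id = sprintf("input_%d", d))
  })
  r <- pairwise_pearson(libs, ref_universe = pool$ref_id)
  expect_equal(dim(r), c(3, 3))
  expect_equal(unname(diag(r)), rep(1, 3))
  expect_true(all(r >= -1 & r <= 1))
  expect_equal(r, t(r))
  for (i in 1:2) {
    for (j in (i + 1):3) {
      want <- oracle_pearson(unname(libs[[i]]$counts[pool$ref_id]),
                             unname(libs[[j]]$counts[pool$ref_id]))
      expect_lt(abs(r[i, j] - want), 1e-12)
    }
  }
})

test_that("identical and rescaled libraries correlate perfectly", {
  a <- count_table("a", c(x = 10, y = 200, z = 3000))
  b <- count_table("b", c(x = 20, y = 400, z = 6000))
  r <- pairwise_pearson(list(a, b))
  expect_equal(r["a", "b"], 1)
})

test_that("zero-variance vectors are flagged rather than silent NaN", {
  a <- count_table("a", c(x = 5, y = 5, z = 5))
  b <- count_table("b", c(x = 1, y = 2, z = 3))
  expect_warning(r <- pairwise_pearson(list(a, b)), "zero-variance")
  expect_true(is.na(r["a", "b"]))
  expect_equal(attr(r, "flagged"), "a")
  expect_equal(unname(diag(r)), c(1, 1))
})

test_that("standard curves recover slope, efficiency and concentration", {
  # perfect doubling per cycle: tenfold dilutions spaced log2(10) cycles
  conc <- 2e-10 / 10^(0:7)   # 200 pM down to 20 aM
  std <- data.frame(concentration = conc,
                    cq = 10 + log2(10) * (0:7))
  fit <- standard_curve_quantify(qpcr_panel(std, cq_sample = 15))
  expect_lt(abs(fit$slope - (-3.3219)), 1e-3)
  expect_lt(abs(fit$efficiency - 1), 1e-3)
  # interpolation identity: a sample Cq equal to a standard's Cq
  fit2 <- standard_curve_quantify(qpcr_panel(std, cq_sample = std$cq[3]))
  expect_equal(fit2$concentration, std$concentration[3], tolerance = 1e-9)
})

test_that("noiseless log-linear standards are fit to machine precision", {
  for (slope in c(-3.1, -3.5, -4.2)) {
    conc <- 1e-9 / 10^(0:5)
    std <- data.frame(concentration = conc,
                      cq = 12 + slope * log10(conc / conc[1]))
    fit <- standard_curve_quantify(qpcr_panel(std, cq_sample = 14))
    expect_equal(fit$slope, slope, tolerance = 1e-12)
    truth <- 10^((14 - fit$intercept) / slope)
    expect_equal(fit$concentration, truth, tolerance = 1e-12)
  }
})

test_that("noisy standards stay within two-fold of truth almost always", {
  conc <- 2e-10 / 10^(0:7)
  truth <- 1e-12
  ok <- vapply(1:100, function(s) {
    srnabias:::with_seed(s, {
      cq_clean <- 10 + log2(10) * (0:7)
      intercept <- 10 + log2(10) * log10(2e-10)  # cq = intercept - log2(10)*log10(conc)
      std <- data.frame(concentration = conc,
                        cq = cq_clean + rnorm(8, 0, 0.1))
      cq_s <- intercept - log2(10) * log10(truth)
      fit <- standard_curve_quantify(qpcr_panel(std, cq_sample = cq_s))
      abs(log2(fit$concentration / truth)) <= 1
    })
  }, logical(1))
  expect_gte(sum(ok), 95)
})

test_that("invalid standard curves raise errors", {
  std_up <- data.frame(concentration = c(1e-9, 1e-10, 1e-11),
                       cq = c(30, 25, 20))  # Cq falling with dilution
  expect_error(standard_curve_quantify(qpcr_panel(std_up, 22)),
               class = "srnabias_data_error")
  expect_error(qpcr_panel(data.frame(concentration = c(1e-9, 1e-10),
                                     cq = c(20, 23)), 21),
               class = "srnabias_invalid_argument")
})

test_that("qPCR panels round-trip through TSV", {
  path <- withr::local_tempfile(fileext = ".tsv")
  tab <- data.frame(mirna = rep(c("miR-16", "miR-29a"), each = 3),
                    cq_sample = rep(c(21.5, 25.0), each = 3),
                    concentration = rep(c(1e-9, 1e-10, 1e-11), 2),
                    cq = c(18, 21.3, 24.6, 19, 22.4, 25.7))
  write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  panels <- read_qpcr_panels(path)
  expect_named(panels, c("miR-16", "miR-29a"))
  expect_equal(panels[["miR-16"]]$cq_sample, 21.5)
  fit <- standard_curve_quantify(panels[["miR-29a"]])
  expect_lt(fit$slope, 0)
})

test_that("rank concordance detects order agreement and disagreement", {
  seq_ab <- c(a = 1000, b = 300, c = 80, d = 10)
  qpcr_same <- c(a = 5e-9, b = 2e-9, c = 6e-10, d = 3e-11)
  rc <- rank_concordance(seq_ab, qpcr_same)
  expect_true(rc$rank_match)
  expect_lt(abs(rc$r_log10 - oracle_pearson(log10(seq_ab),
                                            log10(qpcr_same[names(seq_ab)]))),
            1e-12)
  qpcr_rev <- c(a = 3e-11, b = 6e-10, c = 2e-9, d = 5e-9)
  expect_false(rank_concordance(seq_ab, qpcr_rev)$rank_match)
  err <- expect_error(rank_concordance(seq_ab, c(a = 1, b = 1, zz = 1, d = 1)),
                      class = "srnabias_data_error")
  expect_match(conditionMessage(err), "zz")
  expect_match(conditionMessage(err), "c")
})
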