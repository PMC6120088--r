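#' Library-preparation bias profile
#'
#' A bias profile is the simulator's ground truth for one library
#' preparation chemistry ("kit"): a relative ligation (capture) efficiency
#' `e_i` per reference sequence, a per-cycle PCR duplication probability
#' `q_i`, a global adapter-dimer read rate and a PCR cycle count. Ligation
#' efficiencies are relative — the best-captured sequence has `e = 1` — so
#' a sequence with `e_i = 2^-10` is captured 1024-fold less efficiently
#' than the best one.
#'
#' @param ref_id Character vector of reference ids.
#' @param ligation_efficiency Numeric in (0, 1], with `max == 1`.
#' @param pcr_efficiency Numeric in (0, 1]: per-cycle duplication
#'   probability of each sequence.
#' @param dimer_rate Fraction of final reads that are adapter-dimer
#'   (adapter-only) reads, in `[0, 1)`.
#' @param pcr_cycles Number of PCR amplification cycles (0-25; bias studies
#'   keep this below 20).
#' @param log2_ligation_raw Optional: the unnormalized log2 ligation draws
#'   (kept by [sample_bias_profile()] as ground truth for tests).
#' @param seed Optional integer recording the seed the profile was drawn
#'   with.
#'
#' @return A `bias_profile` object (list with a per-reference data frame
#'   `efficiencies` plus the global parameters).
#' @export
bias_profile <- function(ref_id, ligation_efficiency, pcr_efficiency,
                         dimer_rate = 0, pcr_cycles = 0,
                         log2_ligation_raw = NULL, seed = NA_integer_) {
  n <- length(ref_id)
  if (n == 0L) stop_invalid("bias profile needs at least one reference")
  if (length(ligation_efficiency) != n || length(pcr_efficiency) != n) {
    stop_invalid("per-reference fields must match ref_id length")
  }
  if (any(ligation_efficiency <= 0) || any(ligation_efficiency > 1)) {
    stop_invalid("ligation efficiencies must lie in (0, 1]")
  }
  if (abs(max(ligation_efficiency) - 1) > 1e-12) {
    stop_invalid("ligation efficiencies are relative: max must equal 1")
  }
  if (any(pcr_efficiency <= 0) || any(pcr_efficiency > 1)) {
    stop_invalid("PCR efficiencies must lie in (0, 1]")
  }
  if (dimer_rate < 0 || dimer_rate >= 1) {
    stop_invalid("dimer_rate must lie in [0, 1)")
  }
  if (!is_count(pcr_cycles) || pcr_cycles > 25) {
    stop_invalid("pcr_cycles must be an integer in [0, 25]")
  }
  eff <- data.frame(ref_id = as.character(ref_id),
                    ligation_efficiency = ligation_efficiency,
                    pcr_efficiency = pcr_efficiency,
                    stringsAsFactors = FALSE)
  if (!is.null(log2_ligation_raw)) eff$log2_ligation_raw <- log2_ligation_raw
  structure(list(efficiencies = eff,
                 dimer_rate = dimer_rate,
                 pcr_cycles = as.integer(pcr_cycles),
                 seed = seed),
            class = "bias_profile")
}

#' Draw a bias profile for a reference pool
#'
#' Ligation efficiencies are drawn log2-normally: `e_i = 2^x` with
#' `x ~ Normal(0, sigma_log2)`, then divided by the maximum so the
#' best-captured sequence has efficiency 1. `sigma_log2` controls the bias
#' spread; two-adapter chemistries show multiplicative spreads around
#' 2^16-fold, consistent with `sigma_log2` near 3, while low-bias
#' chemistries correspond to values below 1. PCR efficiency depends
#' linearly on the GC content of each sequence (PCR favors GC-rich
#' templates): `q_i = clamp(q_base + gc_pcr_slope * (GC_i - 0.5), 0.05, 1)`.
#'
#' @param pool A [reference_pool()].
#' @param sigma_log2 Standard deviation of the log2 ligation efficiency
#'   draws (>= 0; 0 gives a perfectly unbiased profile).
#' @param gc_pcr_slope Change in per-cycle PCR efficiency per unit GC
#'   fraction.
#' @param q_base Baseline per-cycle PCR efficiency at 50% GC.
#' @param dimer_rate,pcr_cycles,seed See [bias_profile()].
#'
#' @return A [bias_profile()] aligned to `pool$ref_id`, carrying the raw
#'   (pre-normalization) log2 draws in `efficiencies$log2_ligation_raw`.
#' @examples
#' pool <- build_equimolar_pool(20, seed = 1)
#' prof <- sample_bias_profile(pool, sigma_log2 = 0, seed = 1)
#' stopifnot(all(prof$efficiencies$ligation_efficiency == 1))
#' @export
sample_bias_profile <- function(pool, sigma_log2 = 3, gc_pcr_slope = 0.2,
                                q_base = 0.9, dimer_rate = 0.02,
                                pcr_cycles = 5, seed = 1) {
  stopifnot(inherits(pool, "reference_pool"))
  if (!is.numeric(sigma_log2) || length(sigma_log2) != 1L || sigma_log2 < 0) {
    stop_invalid("sigma_log2 must be a single number >= 0")
  }
  n <- nrow(pool)
  x <- with_seed(seed, rnorm(n, mean = 0, sd = sigma_log2))
  e <- 2^(x - max(x))          # divide by max in log space: max e_i = 1
  gc <- gc_fraction(pool$sequence)
  q <- pmin(1, pmax(0.05, q_base + gc_pcr_slope * (gc - 0.5)))
  bias_profile(pool$ref_id, ligation_efficiency = e, pcr_efficiency = q,
               dimer_rate = dimer_rate, pcr_cycles = pcr_cycles,
               log2_ligation_raw = x, seed = seed)
}

#' @export
print.bias_profile <- function(x, ...) {
  e <- x$efficiencies$ligation_efficiency
  cat(sprintf(paste0("bias_profile: %d references; ligation efficiency span ",
                     "%.1f log2 units; PCR %d cycles (q in [%.2f, %.2f]); ",
                     "dimer rate %.3f\n"),
              nrow(x$efficiencies), log2(max(e) / min(e)), x$pcr_cycles,
              min(x$efficiencies$pcr_efficiency),
              max(x$efficiencies$pcr_efficiency), x$dimer_rate))
  invisible(x)
}

#' Write a bias profile to TSV
#'
#' Columns: `ref_id`, `ligation_efficiency`, `pcr_efficiency`, plus header
#' comment lines recording `dimer_rate`, `pcr_cycles` and the seed.
#'
#' @param profile A [bias_profile()].
#' @param path Output TSV path.
#' @return `profile`, invisibly.
#' @export
write_bias_profile <- function(profile, path) {
  stopifnot(inherits(profile, "bias_profile"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# dimer_rate=%.10g pcr_cycles=%d seed=%s",
                     profile$dimer_rate, profile$pcr_cycles,
                     as.character(profile$seed)), con)
  write.table(profile$efficiencies, con, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(profile)
}
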