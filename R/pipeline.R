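# Benchmark orchestration: configuration, seeding, stage execution, report
# bundle. All randomness derives from the single config seed, so re-running
# a config reproduces every output byte for byte.

default_kits <- function() {
  list(
    list(name = "lowbias", sigma_log2 = 0.5, gc_pcr_slope = 0.2,
         q_base = 0.9, dimer_rate = 0.02, pcr_cycles = 5),
    list(name = "highbias", sigma_log2 = 3.0, gc_pcr_slope = 0.2,
         q_base = 0.9, dimer_rate = 0.10, pcr_cycles = 5)
  )
}

config_schema <- list(
  version = NULL, seed = NULL, pool = c("size", "length_low", "length_high",
                                        "gc_range", "fasta", "fractions"),
  kits = c("name", "sigma_log2", "gc_pcr_slope", "q_base", "dimer_rate",
           "pcr_cycles"),
  replicates = NULL, depth = NULL, read_length = NULL, adapter = NULL,
  trimming = c("max_error_rate", "min_length", "min_overlap"),
  thresholds = c("tau", "tau_d", "tau_pool", "min_reads", "subsample_depth"),
  biological = c("depth", "sigma_log2_abundance", "pseudocount"),
  dilution = c("depths", "kit"),
  write_fastq = NULL
)

#' Benchmark configuration
#'
#' Builds (and validates) the configuration driving [run_benchmark()]. The
#' defaults encode the conventions of the equimolar-pool benchmark: a
#' 963-member pool, triplicate libraries, the standard small-RNA 3'
#' adapter with trimming at 10% error rate and 15 nt minimum length,
#' subsampling to 200,000 trimmed reads with a 5-read detection threshold,
#' and two-fold accuracy/discordance thresholds. Two simulated kits are
#' preconfigured: a low-bias single-adapter-style chemistry
#' (`sigma_log2 = 0.5`) and a heavily biased two-adapter-style chemistry
#' (`sigma_log2 = 3`).
#'
#' @param ... Named overrides of the default fields (nested lists are
#'   merged key-wise). Unknown keys are errors.
#' @return A validated `benchmark_config` list.
#' @examples
#' cfg <- benchmark_config(depth = 1e5, replicates = 2)
#' stopifnot(cfg$depth == 1e5)
#' @export
benchmark_config <- function(...) {
  defaults <- list(
    version = 1L,
    seed = 1L,
    pool = list(size = 963L, length_low = 19L, length_high = 24L,
                gc_range = c(0.2, 0.8), fasta = NULL, fractions = NULL),
    kits = default_kits(),
    replicates = 3L,
    depth = 2e6,
    read_length = 36L,
    adapter = "TGGAATTCTCGGGTGCCAAGG",
    trimming = list(max_error_rate = 0.1, min_length = 15L, min_overlap = 3L),
    thresholds = list(tau = 1, tau_d = 1, tau_pool = 1,
                      min_reads = c(5, 10), subsample_depth = 2e5),
    biological = list(depth = 1e6, sigma_log2_abundance = 3,
                      pseudocount = 0.5),
    dilution = list(depths = c(1e6, 1e5, 1e4), kit = "lowbias"),
    write_fastq = TRUE
  )
  validate_benchmark_config(merge_config(defaults, list(...)))
}

merge_config <- function(base, over) {
  if (length(over) == 0L) return(base)
  if (is.null(names(over)) || any(!nzchar(names(over)))) {
    stop_invalid("configuration overrides must be named")
  }
  for (k in names(over)) {
    if (k %in% c("kits") || !is.list(base[[k]]) || !is.list(over[[k]])) {
      base[k] <- over[k]   # keeps NULL assignments from dropping the key
    } else {
      base[[k]] <- merge_config(base[[k]], over[[k]])
    }
  }
  base
}

validate_benchmark_config <- function(config) {
  unknown <- setdiff(names(config), names(config_schema))
  if (length(unknown)) {
    stop_invalid("unknown configuration keys: ", paste(unknown, collapse = ", "))
  }
  for (k in names(config_schema)) {
    keys <- config_schema[[k]]
    if (is.null(keys) || is.null(config[[k]]) || k == "kits") next
    bad <- setdiff(names(config[[k]]), keys)
    if (length(bad)) {
      stop_invalid("unknown keys under '", k, "': ", paste(bad, collapse = ", "))
    }
  }
  if (!identical(as.integer(config$version), 1L)) {
    stop_invalid("unsupported configuration version: ", config$version)
  }
  if (!is_count(config$replicates, min = 1)) {
    stop_invalid("replicates must be >= 1")
  }
  if (!is_count(config$depth, min = 1)) stop_invalid("depth must be >= 1")
  if (length(config$kits) < 1L) stop_invalid("need at least one kit")
  kit_names <- vapply(config$kits, function(k) k$name %||% "", character(1))
  if (any(!nzchar(kit_names)) || anyDuplicated(kit_names)) {
    stop_invalid("every kit needs a unique name")
  }
  for (kit in config$kits) {
    bad <- setdiff(names(kit), config_schema$kits)
    if (length(bad)) {
      stop_invalid("unknown keys for kit '", kit$name, "': ",
                   paste(bad, collapse = ", "))
    }
  }
  th <- config$thresholds
  if (any(c(th$tau, th$tau_d, th$tau_pool, th$min_reads) <= 0) ||
      th$subsample_depth <= 0) {
    stop_invalid("all thresholds must be positive")
  }
  if (!is_count(config$seed)) stop_invalid("seed must be a nonnegative integer")
  if (!is.null(config$dilution) &&
      !(config$dilution$kit %in% kit_names)) {
    stop_invalid("dilution kit '", config$dilution$kit, "' is not a configured kit")
  }
  class(config) <- c("benchmark_config", "list")
  config
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Read a benchmark configuration from YAML
#'
#' Unknown keys are rejected; omitted keys take the [benchmark_config()]
#' defaults.
#'
#' @param path YAML file path.
#' @return A validated `benchmark_config`.
#' @export
read_benchmark_config <- function(path) {
  raw <- yaml::read_yaml(path)
  if (!is.list(raw)) stop_data("configuration file is not a YAML mapping")
  do.call(benchmark_config, raw)
}

benchmark_pool <- function(config) {
  pc <- config$pool
  if (!is.null(pc$fasta)) {
    read_pool(pc$fasta, pc$fractions)
  } else {
    build_equimolar_pool(pc$size, pc$length_low, pc$length_high, pc$gc_range,
                         seed = derive_seed(config$seed, 5L))
  }
}

kit_profile <- function(pool, kit, seed) {
  sample_bias_profile(pool,
                      sigma_log2 = kit$sigma_log2 %||% 3,
                      gc_pcr_slope = kit$gc_pcr_slope %||% 0.2,
                      q_base = kit$q_base %||% 0.9,
                      dimer_rate = kit$dimer_rate %||% 0.02,
                      pcr_cycles = kit$pcr_cycles %||% 5,
                      seed = seed)
}

# Kit-level fold-deviation table: per-miRNA mean of per-replicate log2_fd
# (and of observed/expected counts), reclassified at the same tau.
kit_level_fdt <- function(fdts, library_id = "kit") {
  stopifnot(length(fdts) >= 1L)
  base <- fdts[[1L]]
  if (length(fdts) > 1L) {
    base$log2_fd <- rowMeans(vapply(fdts, function(f) f$log2_fd,
                                    numeric(nrow(base))))
    base$observed <- rowMeans(vapply(fdts, function(f) f$observed,
                                     numeric(nrow(base))))
    base$expected <- rowMeans(vapply(fdts, function(f) f$expected,
                                     numeric(nrow(base))))
  }
  attr(base, "library_id") <- library_id
  classify_bias(base, tau = attr(fdts[[1L]], "tau"))
}

stage_log <- function(fmt, ..., t0 = NULL) {
  msg <- sprintf(fmt, ...)
  if (!is.null(t0)) {
    msg <- sprintf("%s [%.1fs]", msg, as.numeric(proc.time()[3] - t0))
  }
  message("[srnabias] ", msg)
}

# Run one library through simulate -> trim -> count -> fold-deviation and
# write its artifacts under dir/prefix*.
process_library <- function(pool, profile, depth, config, seed, dir, prefix,
                            library_id, pool_for_fd = pool) {
  lib <- simulate_library(pool, profile, depth,
                          read_length = config$read_length,
                          adapter = config$adapter, seed = seed)
  if (isTRUE(config$write_fastq)) {
    write_fastq(lib$reads, file.path(dir, paste0(prefix, ".fastq")))
  }
  write.table(lib$truth, file.path(dir, paste0(prefix, "_truth.tsv")),
              sep = "\t", quote = FALSE, row.names = FALSE)
  tr <- trim_adapter(lib$reads, adapter = config$adapter,
                     max_error_rate = config$trimming$max_error_rate,
                     min_length = config$trimming$min_length,
                     min_overlap = config$trimming$min_overlap)
  write_trim_report(tr, file.path(dir, paste0(prefix, "_trim.tsv")),
                    library_id = library_id)
  ct <- count_reads(tr$kept, pool_for_fd, library_id = library_id)
  write_count_table(ct, file.path(dir, paste0(prefix, "_counts.tsv")))
  fdt <- fold_deviation(ct, pool_for_fd, tau = config$thresholds$tau)
  write_fold_deviation(fdt, file.path(dir, paste0(prefix, "_fold_deviation.tsv")),
                       file.path(dir, paste0(prefix, "_fd_summary.tsv")))
  list(lib = lib, trim = tr, counts = ct, fdt = fdt)
}

#' Run the full bias benchmark
#'
#' Executes every stage of the benchmark in dependency order for a
#' [benchmark_config()]: equimolar-pool library simulation per kit and
#' replicate, adapter trimming, reference counting, fold-deviation and
#' bias classification, the percent-unbiased t-test between the first
#' (reference) kit and each other kit, equal-depth subsampled detection,
#' a shared biological sample with cross-kit FN/FP attribution, and a
#' dilution series with pairwise Pearson correlations. All outputs (TSVs,
#' optional FASTQs and figures, and a machine-readable `summary.json`)
#' carry the config hash; re-running the same config reproduces them
#' byte for byte.
#'
#' @param config A `benchmark_config` (or path to a YAML config).
#' @param outdir Output directory (created if needed).
#' @param figures Render SVG figures (fold-deviation histograms, detection
#'   curves, FN/FP scatters).
#' @return Invisibly, the summary list written to `summary.json`.
#' @export
run_benchmark <- function(config, outdir, figures = TRUE) {
  if (is.character(config)) config <- read_benchmark_config(config)
  stopifnot(inherits(config, "benchmark_config"))
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  t_all <- proc.time()[3]

  cfg_path <- file.path(outdir, "config.yaml")
  yaml::write_yaml(unclass(config), cfg_path)
  config_hash <- unname(tools::md5sum(cfg_path))
  stage_log("config hash %s, seed %d", config_hash, config$seed)

  t0 <- proc.time()[3]
  pool <- benchmark_pool(config)
  write_pool(pool, file.path(outdir, "pool.fasta"),
             file.path(outdir, "pool_fractions.tsv"))
  stage_log("pool: %d references", nrow(pool), t0 = t0)

  kit_names <- vapply(config$kits, `[[`, character(1), "name")
  th <- config$thresholds
  kit_results <- list()
  detection_rows <- list()
  pa_rows <- list()

  for (k in seq_along(config$kits)) {
    kit <- config$kits[[k]]
    kdir <- file.path(outdir, "kits", kit$name)
    dir.create(kdir, recursive = TRUE, showWarnings = FALSE)
    profile <- kit_profile(pool, kit, seed = derive_seed(config$seed, 11L, k))
    write_bias_profile(profile, file.path(kdir, "profile.tsv"))

    fdts <- list()
    for (r in seq_len(config$replicates)) {
      t0 <- proc.time()[3]
      res <- tryCatch(
        process_library(pool, profile, config$depth, config,
                        seed = derive_seed(config$seed, 23L, k, r),
                        dir = kdir, prefix = sprintf("rep%d", r),
                        library_id = sprintf("%s_rep%d", kit$name, r)),
        error = function(e) {
          stop_data("stage failure in kit '", kit$name, "' replicate ", r,
                    ": ", conditionMessage(e))
        })
      fdts[[r]] <- res$fdt
      pa_rows[[length(pa_rows) + 1L]] <- data.frame(
        kit = kit$name, replicate = r,
        percent_accurate = percent_accurate(res$fdt),
        percent_under = attr(res$fdt, "summary")$percent_under,
        percent_over = attr(res$fdt, "summary")$percent_over,
        depth_assigned = attr(res$fdt, "depth"))

      # equal-depth detection on trimmed reads
      sub_d <- th$subsample_depth
      if (nrow(res$trim$kept) >= sub_d) {
        sub <- subsample_reads(res$trim$kept, sub_d,
                               seed = derive_seed(config$seed, 31L, k, r))
        sct <- count_reads(sub, pool,
                           library_id = sprintf("%s_rep%d_sub", kit$name, r))
        for (mr in th$min_reads) {
          detection_rows[[length(detection_rows) + 1L]] <- data.frame(
            kit = kit$name, replicate = r, depth = sub_d, min_reads = mr,
            n_detected = count_detected(sct, mr))
        }
      }
      stage_log("kit %s rep %d: depth %d, %.1f%% accurate", kit$name, r,
                config$depth, percent_accurate(res$fdt), t0 = t0)
    }
    kfdt <- kit_level_fdt(fdts, library_id = kit$name)
    write_fold_deviation(kfdt, file.path(kdir, "pool_fd_kit.tsv"),
                         file.path(kdir, "pool_fd_kit_summary.tsv"))
    if (figures) {
      dir.create(file.path(outdir, "figures"), showWarnings = FALSE)
      plot_fold_deviation(kfdt, file.path(outdir, "figures",
                                          paste0("fold_deviation_", kit$name,
                                                 ".svg")))
    }
    kit_results[[kit$name]] <- list(profile = profile, fdts = fdts,
                                    kit_fdt = kfdt)
  }

  pa <- do.call(rbind, pa_rows)
  write.table(pa, file.path(outdir, "percent_accurate.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  if (length(detection_rows)) {
    det <- do.call(rbind, detection_rows)
    write.table(det, file.path(outdir, "detection.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
  } else det <- NULL

  # percent-unbiased t-test: first kit is the reference chemistry
  ttests <- list()
  if (length(kit_names) >= 2L && config$replicates >= 2L) {
    ref_pa <- pa$percent_accurate[pa$kit == kit_names[1]]
    for (kn in kit_names[-1]) {
      tt <- tryCatch(compare_percent_unbiased(ref_pa,
                                              pa$percent_accurate[pa$kit == kn]),
                     srnabias_data_error = function(e) NULL)
      if (!is.null(tt)) {
        ttests[[kn]] <- data.frame(kit_a = kit_names[1], kit_b = kn,
                                   t = unname(tt$statistic),
                                   p_value = tt$p.value)
      }
    }
    if (length(ttests)) {
      write.table(do.call(rbind, ttests), file.path(outdir, "ttest.tsv"),
                  sep = "\t", quote = FALSE, row.names = FALSE)
    }
  }

  # biological sample shared across kits, FN/FP attribution vs reference kit
  crosskit_summaries <- list()
  bio_pool <- NULL
  if (length(kit_names) >= 2L && !is.null(config$biological)) {
    t0 <- proc.time()[3]
    bdir <- file.path(outdir, "biological")
    dir.create(bdir, showWarnings = FALSE)
    bio_x <- with_seed(derive_seed(config$seed, 41L),
                       rnorm(nrow(pool), 0, config$biological$sigma_log2_abundance))
    bio_frac <- 2^bio_x / sum(2^bio_x)
    bio_pool <- reference_pool(pool$ref_id, pool$sequence, bio_frac)
    write.table(data.frame(ref_id = pool$ref_id, fraction = bio_frac),
                file.path(bdir, "true_fractions.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    bio_counts <- list()
    for (k in seq_along(config$kits)) {
      kit <- config$kits[[k]]
      lib <- simulate_library(bio_pool, kit_results[[kit$name]]$profile,
                              config$biological$depth,
                              read_length = config$read_length,
                              adapter = config$adapter,
                              seed = derive_seed(config$seed, 43L, k))
      tr <- trim_adapter(lib$reads, adapter = config$adapter,
                         max_error_rate = config$trimming$max_error_rate,
                         min_length = config$trimming$min_length,
                         min_overlap = config$trimming$min_overlap)
      ct <- count_reads(tr$kept, pool,
                        library_id = paste0(kit$name, "_bio"))
      write_count_table(ct, file.path(bdir, paste0(kit$name, "_counts.tsv")))
      bio_counts[[kit$name]] <- ct
    }
    ckdir <- file.path(outdir, "crosskit")
    dir.create(ckdir, showWarnings = FALSE)
    for (kn in kit_names[-1]) {
      diff <- differential_quantification(bio_counts[[kn]],
                                          bio_counts[[kit_names[1]]],
                                          eval_set = pool$ref_id,
                                          pseudocount = config$biological$pseudocount)
      cmp <- attribute_fn_fp(diff, kit_results[[kn]]$kit_fdt,
                             kit_results[[kit_names[1]]]$kit_fdt,
                             tau_d = th$tau_d, tau_pool = th$tau_pool)
      write_kit_comparison(cmp, file.path(ckdir,
                                          paste0(kn, "_vs_", kit_names[1], ".tsv")))
      if (figures) {
        plot_kit_comparison(cmp, file.path(outdir, "figures",
                                           paste0("crosskit_", kn, ".svg")))
      }
      crosskit_summaries[[kn]] <- list(
        focal_kit = kn, reference_kit = kit_names[1],
        fn_rate = attr(cmp, "fn_rate"), fp_rate = attr(cmp, "fp_rate"),
        percent_discordant = 100 * mean(abs(cmp$diff_log2) > th$tau_d))
    }
    stage_log("biological sample + crosskit attribution", t0 = t0)
  }

  # dilution series: one kit, shared profile, depths in decreasing steps.
  # Emulates tenfold input dilutions of a biological total-RNA sample, so
  # the libraries share the biological abundance spread when a biological
  # sample is configured (raw-count correlations then measure concordance
  # of real signal, not just bias).
  dilution_summary <- NULL
  if (!is.null(config$dilution)) {
    t0 <- proc.time()[3]
    ddir <- file.path(outdir, "dilution")
    dir.create(ddir, showWarnings = FALSE)
    dkit <- config$dilution$kit
    dil_pool <- if (is.null(bio_pool)) pool else bio_pool
    tabs <- list()
    for (j in seq_along(config$dilution$depths)) {
      d <- config$dilution$depths[j]
      lib <- simulate_library(dil_pool, kit_results[[dkit]]$profile, d,
                              read_length = config$read_length,
                              adapter = config$adapter,
                              seed = derive_seed(config$seed, 53L, j))
      tr <- trim_adapter(lib$reads, adapter = config$adapter,
                         max_error_rate = config$trimming$max_error_rate,
                         min_length = config$trimming$min_length,
                         min_overlap = config$trimming$min_overlap)
      tabs[[j]] <- count_reads(tr$kept, pool,
                               library_id = sprintf("dilution_%g", d))
      write_count_table(tabs[[j]], file.path(ddir, sprintf("depth_%g_counts.tsv", d)))
    }
    r <- pairwise_pearson(tabs, ref_universe = pool$ref_id)
    write.table(data.frame(library_id = rownames(r), r, check.names = FALSE),
                file.path(ddir, "pearson.tsv"), sep = "\t", quote = FALSE,
                row.names = FALSE)
    adj <- vapply(seq_len(nrow(r) - 1L),
                  function(i) r[i, i + 1L], numeric(1))
    dilution_summary <- list(kit = dkit, depths = config$dilution$depths,
                             pearson_adjacent = adj,
                             pearson_min = min(r[upper.tri(r)]))
    stage_log("dilution series: adjacent r = %s",
              paste(sprintf("%.3f", adj), collapse = ", "), t0 = t0)
  }

  summary <- list(
    config_hash = config_hash,
    seed = config$seed,
    pool_size = nrow(pool),
    depth = config$depth,
    replicates = config$replicates,
    kits = lapply(kit_names, function(kn) {
      rows <- pa[pa$kit == kn, ]
      list(name = kn,
           percent_accurate = rows$percent_accurate,
           percent_accurate_mean = mean(rows$percent_accurate),
           detected = if (!is.null(det)) {
             lapply(split(det[det$kit == kn, ], det$min_reads[det$kit == kn]),
                    function(d) list(min_reads = d$min_reads[1],
                                     depth = d$depth[1],
                                     mean = mean(d$n_detected),
                                     sd = sd(d$n_detected)))
           })
    }),
    ttests = unname(lapply(ttests, function(d) as.list(d))),
    crosskit = unname(crosskit_summaries),
    dilution = dilution_summary
  )
  jsonlite::write_json(summary, file.path(outdir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       null = "null")
  stage_log("benchmark complete", t0 = t_all)
  invisible(summary)
}
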