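#' Count references detected at a read-count threshold
#'
#' Number of pool members with at least `min_reads` assigned reads — the
#' detection statistic used when libraries are compared at equal
#' subsampled depth (conventional thresholds: 5 reads at 200,000-read
#' depth, 10 reads for deep-coverage curves).
#'
#' @param counts A [count_table()].
#' @param min_reads Detection threshold (>= 1).
#' @return Number of detected references.
#' @examples
#' ct <- count_table("lib", c(a = 3, b = 5, c = 7))
#' stopifnot(count_detected(ct, 5) == 2)
#' @export
count_detected <- function(counts, min_reads = 5) {
  stopifnot(inherits(counts, "count_table"))
  if (!is.numeric(min_reads) || min_reads < 1) {
    stop_invalid("min_reads must be >= 1")
  }
  sum(counts$counts >= min_reads)
}

#' Detection-versus-depth curve by random subsampling
#'
#' For each target depth, draws `n_draws` independent uniform subsamples
#' of the reads, counts them against the pool and records how many
#' references reach `min_reads` reads. Read-to-reference assignment is
#' computed once on the full read set (assignment is per-read
#' deterministic), so each draw only resamples read indices.
#'
#' @param reads A [read_set()] of trimmed reads.
#' @param pool A [reference_pool()].
#' @param depths Increasing vector of subsample depths
#'   (`max(depths) <= nrow(reads)`).
#' @param min_reads Detection threshold.
#' @param n_draws Subsample draws averaged per depth.
#' @param seed Integer seed.
#' @param max_mismatches,length_tolerance Passed to the read matcher (see
#'   [count_reads()]).
#' @param library_id Label recorded in the summary.
#'
#' @return A `detection_summary` data frame: `library_id`, `depth`,
#'   `min_reads`, `mean_detected`, `sd_detected`, `n_draws`.
#' @export
detection_curve <- function(reads, pool, depths, min_reads = 5, n_draws = 10,
                            seed = 1, max_mismatches = 0, length_tolerance = 2,
                            library_id = "library") {
  stopifnot(inherits(reads, "read_set"), inherits(pool, "reference_pool"))
  if (!is_count(n_draws, min = 1)) stop_invalid("n_draws must be >= 1")
  n <- nrow(reads)
  bad <- depths[depths > n]
  if (length(bad)) {
    stop_depth("depth ", format(bad[1], scientific = FALSE),
               " exceeds the library size of ", n, " reads")
  }
  useq <- unique(reads$sequence)
  uidx <- match(reads$sequence, useq)
  asg <- match_unique_reads(useq, pool, max_mismatches, length_tolerance)
  # triplets: unique-seq u contributes weight w to reference k
  trip_u <- rep(seq_along(useq), lengths(asg$ref_idx))
  trip_k <- unlist(asg$ref_idx, use.names = FALSE)
  trip_w <- rep(asg$weight, lengths(asg$ref_idx))

  detected <- with_seed(seed, {
    lapply(depths, function(d) {
      vapply(seq_len(n_draws), function(i) {
        take <- sample.int(n, as.integer(d))
        freq <- tabulate(uidx[take], nbins = length(useq))
        counts <- numeric(nrow(pool))
        contrib <- trip_w * freq[trip_u]
        nz <- contrib > 0
        if (any(nz)) {
          agg <- rowsum(contrib[nz], trip_k[nz])
          counts[as.integer(rownames(agg))] <- agg[, 1]
        }
        sum(counts >= min_reads)
      }, numeric(1))
    })
  })
  out <- data.frame(library_id = library_id,
                    depth = as.numeric(depths),
                    min_reads = min_reads,
                    mean_detected = vapply(detected, mean, numeric(1)),
                    sd_detected = vapply(detected, sd, numeric(1)),
                    n_draws = n_draws,
                    stringsAsFactors = FALSE)
  class(out) <- c("detection_summary", "data.frame")
  out
}

#' Small-RNA class composition of a library
#'
#' Read-weighted percentage of assigned reads per small-RNA class (miRNA,
#' piRNA, ...). References without a label fall into class `"other"`.
#' Percentages sum to 100.
#'
#' @param counts A [count_table()].
#' @param class_map Named character vector (`ref_id -> class`) or a data
#'   frame with columns `ref_id` and `class`.
#' @return Named numeric vector of percentages, decreasing.
#' @examples
#' ct <- count_table("lib", c(a = 1790, b = 8210))
#' pc <- class_composition(ct, c(a = "piRNA", b = "miRNA"))
#' stopifnot(abs(pc[["piRNA"]] - 17.9) < 1e-9)
#' @export
class_composition <- function(counts, class_map) {
  stopifnot(inherits(counts, "count_table"))
  if (is.data.frame(class_map)) {
    if (!all(c("ref_id", "class") %in% names(class_map))) {
      stop_invalid("class_map data frame needs columns ref_id and class")
    }
    class_map <- stats::setNames(as.character(class_map$class),
                                 class_map$ref_id)
  }
  if (counts$depth <= 0) stop_data("empty library: no assigned reads")
  cls <- class_map[names(counts$counts)]
  cls[is.na(cls)] <- "other"
  pct <- 100 * tapply(unname(counts$counts), unname(cls), sum) / counts$depth
  sort(stats::setNames(as.numeric(pct), names(pct)), decreasing = TRUE)
}

#' Plot a detection-versus-depth curve
#'
#' @param summaries A `detection_summary` (rows from one or more
#'   libraries; [detection_curve()] outputs can be `rbind`-ed).
#' @param path Optional output file (`.svg`, `.png`, `.pdf`).
#' @return The ggplot object, invisibly when written to file.
#' @export
plot_detection_curve <- function(summaries, path = NULL) {
  p <- ggplot2::ggplot(as.data.frame(summaries),
                       ggplot2::aes(x = .data$depth, y = .data$mean_detected,
                                    colour = .data$library_id)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "subsampled depth (reads)",
                  y = sprintf("references detected (>= %s reads)",
                              summaries$min_reads[1])) +
    ggplot2::theme_minimal()
  if (is.null(path)) return(p)
  save_plot(path, p)
  invisible(p)
}
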