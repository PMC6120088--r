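#' Per-reference fold-deviation from expected counts
#'
#' The central bias statistic of the equimolar-pool benchmark. For each
#' pool member `i`, the expected count is `E_i = depth * f_i` with `depth`
#' the sum of assigned counts and `f_i` the expected molar fraction; the
#' fold-deviation is `log2(O_i / E_i)`. Members observed within plus or
#' minus `tau` log2 units (default two-fold) are classified `accurate`;
#' below, `under`; above, `over`. Members with zero observed counts are
#' classified `undetected`: their `log2_fd` is floored at
#' `log2(0.5 / E_i)` for plotting only, and in the percentage summary they
#' count as under-represented (an undetected pool member is maximally
#' under-represented). With `zero_policy = "omit"` they are excluded from
#' the percentage denominators instead.
#'
#' @param counts A [count_table()] over the pool universe.
#' @param pool A [reference_pool()].
#' @param tau Accuracy threshold in log2 units (boundaries inclusive).
#' @param zero_policy `"undetected_as_under"` (default) or `"omit"`.
#'
#' @return A `fold_deviation_table`: data frame with columns `ref_id`,
#'   `observed`, `expected`, `log2_fd`, `bias_class`, carrying attributes
#'   `tau`, `depth`, `library_id`, `zero_policy` and `summary` (a list with
#'   `percent_under`, `percent_accurate`, `percent_over`,
#'   `percent_undetected`; the first three sum to 100).
#' @examples
#' pool <- build_equimolar_pool(4, seed = 1)
#' ct <- count_table("lib", setNames(c(100, 100, 100, 100), pool$ref_id))
#' fdt <- fold_deviation(ct, pool)
#' stopifnot(all(fdt$log2_fd == 0), attr(fdt, "summary")$percent_accurate == 100)
#' @export
fold_deviation <- function(counts, pool, tau = 1,
                           zero_policy = c("undetected_as_under", "omit")) {
  stopifnot(inherits(counts, "count_table"), inherits(pool, "reference_pool"))
  zero_policy <- match.arg(zero_policy)
  m <- match(pool$ref_id, names(counts$counts))
  if (anyNA(m)) {
    stop_data("count table is missing pool references: ",
              paste(utils::head(pool$ref_id[is.na(m)], 3L), collapse = ", "))
  }
  observed <- unname(counts$counts[m])
  depth <- sum(observed)
  if (depth <= 0) stop_data("empty library: no reads assigned to the pool")
  expected <- depth * pool$expected_fraction
  detected <- observed > 0
  log2_fd <- ifelse(detected, log2(observed / expected), log2(0.5 / expected))
  out <- data.frame(ref_id = pool$ref_id,
                    observed = observed,
                    expected = expected,
                    log2_fd = log2_fd,
                    bias_class = NA_character_,
                    stringsAsFactors = FALSE)
  class(out) <- c("fold_deviation_table", "data.frame")
  attr(out, "depth") <- depth
  attr(out, "library_id") <- counts$library_id
  attr(out, "zero_policy") <- zero_policy
  classify_bias(out, tau = tau)
}

#' Classify fold-deviations at a threshold
#'
#' Recomputes bias classes and percentage summaries of a fold-deviation
#' table at threshold `tau`. Boundaries are inclusive: `log2_fd` of exactly
#' `-tau` or `tau` is `accurate` ("within" a two-fold deviation includes
#' two-fold itself). Undetected members keep class `undetected` regardless
#' of their floored `log2_fd`.
#'
#' @param fdt A `fold_deviation_table` from [fold_deviation()].
#' @param tau Accuracy threshold in log2 units (> 0).
#' @return The table with updated `bias_class` and `summary`/`tau`
#'   attributes.
#' @export
classify_bias <- function(fdt, tau = 1) {
  stopifnot(inherits(fdt, "fold_deviation_table"))
  if (!is.numeric(tau) || length(tau) != 1L || tau <= 0) {
    stop_invalid("tau must be a single number > 0")
  }
  detected <- fdt$observed > 0
  cls <- ifelse(!detected, "undetected",
                ifelse(fdt$log2_fd < -tau, "under",
                       ifelse(fdt$log2_fd > tau, "over", "accurate")))
  fdt$bias_class <- cls
  n_und <- sum(cls == "undetected")
  denom <- if (identical(attr(fdt, "zero_policy"), "omit")) {
    nrow(fdt) - n_und
  } else {
    nrow(fdt)
  }
  if (denom <= 0) stop_data("no detected pool members to classify")
  under_n <- sum(cls == "under") +
    if (identical(attr(fdt, "zero_policy"), "omit")) 0L else n_und
  attr(fdt, "tau") <- tau
  attr(fdt, "summary") <- list(
    percent_under = 100 * under_n / denom,
    percent_accurate = 100 * sum(cls == "accurate") / denom,
    percent_over = 100 * sum(cls == "over") / denom,
    percent_undetected = 100 * n_und / nrow(fdt)
  )
  fdt
}

#' @export
print.fold_deviation_table <- function(x, ...) {
  s <- attr(x, "summary")
  cat(sprintf(paste0("fold_deviation_table '%s': %d references, depth %.6g, ",
                     "tau = %.3g\n  under %.1f%% | accurate %.1f%% | over ",
                     "%.1f%% (undetected %.1f%%)\n"),
              attr(x, "library_id"), nrow(x), attr(x, "depth"),
              attr(x, "tau"), s$percent_under, s$percent_accurate,
              s$percent_over, s$percent_undetected))
  invisible(x)
}

#' Percent of pool members accurately quantified
#'
#' Convenience accessor for the `percent_accurate` entry of a
#' fold-deviation table's summary (the "percent unbiased" statistic used
#' to compare kits).
#'
#' @param fdt A `fold_deviation_table`.
#' @return A single percentage.
#' @export
percent_accurate <- function(fdt) {
  stopifnot(inherits(fdt, "fold_deviation_table"))
  attr(fdt, "summary")$percent_accurate
}

#' Compare percent-unbiased between two kits
#'
#' Welch two-sample two-sided t-test on replicate-level percentages of
#' accurately quantified pool members (one percentage per replicate
#' library). Welch's form is used because no equal-variance assumption is
#' warranted; at triplicate scale the difference from the pooled test is
#' negligible.
#'
#' @param group_a,group_b Numeric vectors of replicate percentages (each
#'   length >= 2).
#' @return The `htest` object from [stats::t.test()] (`statistic` holds t,
#'   `p.value` the two-sided p-value).
#' @examples
#' tt <- compare_percent_unbiased(c(70, 72, 74), c(30, 32, 34))
#' stopifnot(tt$p.value < 0.001)
#' @export
compare_percent_unbiased <- function(group_a, group_b) {
  if (length(group_a) < 2L || length(group_b) < 2L) {
    stop_invalid("each group needs at least 2 replicate percentages")
  }
  if (var(group_a) == 0 && var(group_b) == 0) {
    stop_data("degenerate variance: both groups are constant; ",
              "a t-statistic is undefined")
  }
  t.test(group_a, group_b, var.equal = FALSE, alternative = "two.sided")
}

#' Write a fold-deviation table (and summary) to TSV
#'
#' @param fdt A `fold_deviation_table`.
#' @param path Per-reference TSV path.
#' @param summary_path Optional one-row summary TSV path (percentages,
#'   depth, tau).
#' @return `fdt`, invisibly.
#' @export
write_fold_deviation <- function(fdt, path, summary_path = NULL) {
  stopifnot(inherits(fdt, "fold_deviation_table"))
  write.table(as.data.frame(fdt), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  if (!is.null(summary_path)) {
    s <- attr(fdt, "summary")
    write.table(data.frame(library_id = attr(fdt, "library_id"),
                           depth = attr(fdt, "depth"),
                           tau = attr(fdt, "tau"),
                           percent_under = s$percent_under,
                           percent_accurate = s$percent_accurate,
                           percent_over = s$percent_over,
                           percent_undetected = s$percent_undetected),
                summary_path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(fdt)
}

#' Plot the fold-deviation distribution of a library
#'
#' Histogram/density of per-reference log2 fold-deviations with vertical
#' lines at `-tau` and `tau`, the conventional rendering of the equimolar
#' benchmark.
#'
#' @param fdt A `fold_deviation_table`.
#' @param path Optional output file (`.svg`, `.png`, `.pdf`); when `NULL`
#'   the ggplot object is returned unrendered.
#' @return The ggplot object, invisibly when written to file.
#' @export
plot_fold_deviation <- function(fdt, path = NULL) {
  stopifnot(inherits(fdt, "fold_deviation_table"))
  tau <- attr(fdt, "tau")
  s <- attr(fdt, "summary")
  df <- as.data.frame(fdt)
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$log2_fd)) +
    ggplot2::geom_histogram(bins = 60, fill = "grey65", colour = "grey30",
                            linewidth = 0.2) +
    ggplot2::geom_vline(xintercept = c(-tau, tau), linetype = "dashed",
                        colour = "red3") +
    ggplot2::labs(
      x = "log2 fold-deviation from equimolar expectation",
      y = "references",
      title = sprintf("%s: %.1f%% accurately quantified",
                      attr(fdt, "library_id"), s$percent_accurate)
    ) +
    ggplot2::theme_minimal()
  if (is.null(path)) return(p)
  save_plot(path, p)
  invisible(p)
}
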