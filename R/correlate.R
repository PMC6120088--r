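#' Pairwise Pearson correlation between libraries
#'
#' Correlates per-reference read counts between libraries over a shared
#' universe (references absent from a table count as zero) — the standard
#' concordance check for dilution-series libraries. Raw counts are
#' correlated by default, matching the convention of reporting raw reads
#' mapping to miRNAs; `normalize = "rpm"` correlates reads-per-million
#' instead.
#'
#' @param tables List of two or more [count_table()]s.
#' @param ref_universe Character vector of ref_ids; default is the union
#'   of all table universes.
#' @param normalize `"raw"` (default) or `"rpm"`.
#'
#' @return Symmetric correlation matrix with unit diagonal, dimnames =
#'   library ids. Pairs involving a zero-variance count vector are `NA`
#'   and listed in the `flagged` attribute (with a warning) rather than
#'   silently `NaN`.
#' @examples
#' a <- count_table("d100", c(x = 100, y = 200, z = 400))
#' b <- count_table("d10", c(x = 11, y = 19, z = 42))
#' r <- pairwise_pearson(list(a, b))
#' stopifnot(r["d100", "d10"] > 0.9)
#' @export
pairwise_pearson <- function(tables, ref_universe = NULL,
                             normalize = c("raw", "rpm")) {
  normalize <- match.arg(normalize)
  if (length(tables) < 2L) stop_invalid("need at least 2 count tables")
  lapply(tables, function(t) stopifnot(inherits(t, "count_table")))
  if (is.null(ref_universe)) {
    ref_universe <- unique(unlist(lapply(tables, function(t) names(t$counts))))
  }
  if (length(ref_universe) == 0L) stop_invalid("ref universe is empty")
  ids <- vapply(tables, function(t) t$library_id, character(1))
  if (anyDuplicated(ids)) ids <- make.unique(ids)
  M <- vapply(tables, function(t) {
    v <- t$counts[ref_universe]
    v[is.na(v)] <- 0
    if (normalize == "rpm" && t$depth > 0) v <- v / t$depth * 1e6
    unname(v)
  }, numeric(length(ref_universe)))
  colnames(M) <- ids
  zerovar <- apply(M, 2, function(v) var(v) == 0)
  r <- suppressWarnings(cor(M, method = "pearson"))
  flagged <- NULL
  if (any(zerovar)) {
    bad <- which(zerovar)
    for (b in bad) {
      r[b, ] <- NA_real_
      r[, b] <- NA_real_
    }
    flagged <- ids[bad]
    warning("zero-variance count vector(s): ", paste(flagged, collapse = ", "),
            "; their correlations are NA", call. = FALSE)
  }
  diag(r) <- 1
  attr(r, "flagged") <- flagged
  r
}

#' qPCR standard-curve panel for one miRNA
#'
#' Holds the quantification cycle (Cq) of the biological sample and a
#' standard dilution series of the corresponding synthetic miRNA at known
#' concentrations (at least 3 points; qPCR validation panels typically
#' span up to 8 logs, e.g. 200 pM down to 20 aM).
#'
#' @param standards Data frame with columns `concentration` (molar, all
#'   distinct, > 0) and `cq` (cycles).
#' @param cq_sample Cq of the biological sample.
#' @param mirna Optional miRNA name.
#' @return A `qpcr_panel` object (standards sorted by decreasing
#'   concentration).
#' @export
qpcr_panel <- function(standards, cq_sample, mirna = NA_character_) {
  if (!is.data.frame(standards) ||
      !all(c("concentration", "cq") %in% names(standards))) {
    stop_invalid("standards must be a data frame with columns concentration, cq")
  }
  if (nrow(standards) < 3L) stop_invalid("need at least 3 standard points")
  if (any(standards$concentration <= 0)) {
    stop_invalid("standard concentrations must be > 0")
  }
  if (anyDuplicated(standards$concentration)) {
    stop_invalid("standard concentrations must be strictly decreasing (distinct)")
  }
  standards <- standards[order(standards$concentration, decreasing = TRUE), ,
                         drop = FALSE]
  rownames(standards) <- NULL
  structure(list(standards = standards, cq_sample = as.numeric(cq_sample),
                 mirna = mirna),
            class = "qpcr_panel")
}

#' Absolute quantification from a qPCR standard curve
#'
#' Least-squares fit of `cq = slope * log10(concentration) + intercept` to
#' the standard dilution series; the sample concentration is read off the
#' curve as `10^((cq_sample - intercept) / slope)` and the amplification
#' efficiency is `10^(-1/slope) - 1` (a perfect doubling per cycle gives a
#' slope of -3.3219 and 100% efficiency).
#'
#' @param panel A [qpcr_panel()].
#' @return A list of class `standard_curve_fit`: `slope` (cycles per log10
#'   concentration), `intercept` (cycles), `concentration` (molar estimate
#'   for the sample), `efficiency` (fraction), `r_squared`.
#' @examples
#' std <- data.frame(concentration = 10^-(9:12),
#'                   cq = 20 + log2(10) * (0:3))
#' fit <- standard_curve_quantify(qpcr_panel(std, cq_sample = 21))
#' stopifnot(abs(fit$slope + log2(10)) < 1e-9)
#' @export
standard_curve_quantify <- function(panel) {
  stopifnot(inherits(panel, "qpcr_panel"))
  fit <- lm(cq ~ log10(concentration), data = panel$standards)
  slope <- unname(coef(fit)[2])
  intercept <- unname(coef(fit)[1])
  if (!is.finite(slope) || slope >= 0) {
    stop_data("invalid standard curve: slope must be negative (got ",
              format(slope), "); Cq must increase as concentration decreases")
  }
  sst <- sum((panel$standards$cq - mean(panel$standards$cq))^2)
  r2 <- 1 - sum(stats::residuals(fit)^2) / sst
  structure(list(slope = slope,
                 intercept = intercept,
                 concentration = 10^((panel$cq_sample - intercept) / slope),
                 efficiency = 10^(-1 / slope) - 1,
                 r_squared = r2,
                 mirna = panel$mirna),
            class = "standard_curve_fit")
}

#' @export
print.standard_curve_fit <- function(x, ...) {
  cat(sprintf(paste0("standard_curve_fit%s: slope %.4f cycles/log10, ",
                     "efficiency %.1f%%, R^2 %.4f\n  estimated sample ",
                     "concentration: %.4g M\n"),
              if (is.na(x$mirna)) "" else paste0(" (", x$mirna, ")"),
              x$slope, 100 * x$efficiency, x$r_squared, x$concentration))
  invisible(x)
}

#' Read qPCR panels from TSV
#'
#' Long format: columns `mirna`, `cq_sample`, `concentration`, `cq` — one
#' row per standard point, `cq_sample` repeated within each miRNA.
#'
#' @param path TSV path.
#' @return Named list of [qpcr_panel()]s, one per miRNA.
#' @export
read_qpcr_panels <- function(path) {
  tab <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("mirna", "cq_sample", "concentration", "cq")
  if (!all(need %in% names(tab))) {
    stop_data("qPCR TSV needs columns: ", paste(need, collapse = ", "))
  }
  by_mir <- split(tab, tab$mirna)
  lapply(by_mir, function(d) {
    qpcr_panel(d[, c("concentration", "cq")], cq_sample = d$cq_sample[1],
               mirna = d$mirna[1])
  })
}

#' Rank and correlation concordance of sequencing versus qPCR
#'
#' Compares normalized sequencing abundances with qPCR absolute
#' concentrations for the same miRNAs: exact rank-order agreement, plus
#' Pearson correlation on log10 abundances (and on the linear scale,
#' since conventions differ).
#'
#' @param seq_abundance Named numeric: miRNA -> normalized reads (> 0).
#' @param qpcr_abundance Named numeric: miRNA -> molar concentration
#'   (> 0); same names as `seq_abundance`.
#' @return List: `rank_match` (logical), `r_log10`, `r_linear`.
#' @examples
#' rc <- rank_concordance(c(a = 100, b = 10), c(a = 2e-9, b = 3e-10))
#' stopifnot(rc$rank_match)
#' @export
rank_concordance <- function(seq_abundance, qpcr_abundance) {
  sn <- names(seq_abundance)
  qn <- names(qpcr_abundance)
  if (is.null(sn) || is.null(qn)) stop_invalid("abundance vectors must be named")
  if (!setequal(sn, qn) || length(sn) != length(qn)) {
    stop_data("key sets differ; only in sequencing: ",
              paste(setdiff(sn, qn), collapse = ", "),
              "; only in qPCR: ", paste(setdiff(qn, sn), collapse = ", "))
  }
  if (length(sn) < 2L) stop_invalid("need at least 2 shared miRNAs")
  q <- qpcr_abundance[sn]
  list(rank_match = all(rank(seq_abundance, ties.method = "average") ==
                          rank(q, ties.method = "average")),
       r_log10 = cor(log10(seq_abundance), log10(q)),
       r_linear = cor(as.numeric(seq_abundance), as.numeric(q)))
}
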