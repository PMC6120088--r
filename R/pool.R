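#' Reference pool of small RNA sequences
#'
#' A reference pool holds the mature small-RNA sequences against which
#' libraries are counted, together with the expected molar fraction of each
#' sequence. For the equimolar benchmark pool every fraction is `1/n`, so
#' the expected read count of sequence `i` at assigned depth `D` is
#' `E_i = D / n`.
#'
#' @param ref_id Character vector of unique sequence identifiers.
#' @param sequence Character vector of sequences over `{A,C,G,T,U}`,
#'   lengths 15-35 nt.
#' @param expected_fraction Numeric vector of molar fractions, each > 0,
#'   summing to 1 (tolerance 1e-9).
#'
#' @return A `reference_pool`: a data frame with columns `ref_id`,
#'   `sequence`, `expected_fraction`.
#' @examples
#' pool <- reference_pool(c("a", "b"), c("ACGUACGUACGUACGUACGU",
#'                                       "UGCAUGCAUGCAUGCAUGCA"),
#'                        c(0.5, 0.5))
#' @export
reference_pool <- function(ref_id, sequence, expected_fraction) {
  ref_id <- as.character(ref_id)
  sequence <- as.character(sequence)
  n <- length(ref_id)
  if (n == 0L) stop_invalid("a reference pool needs at least one entry")
  if (length(sequence) != n || length(expected_fraction) != n) {
    stop_invalid("ref_id, sequence and expected_fraction must have equal length")
  }
  if (anyDuplicated(ref_id)) {
    stop_invalid("ref_ids must be unique; duplicated: ",
                 paste(unique(ref_id[duplicated(ref_id)])[1:3], collapse = ", "))
  }
  check_dna(sequence, "pool sequence", alphabet = "ACGTU")
  len <- nchar(sequence)
  if (any(len < 15L | len > 35L)) {
    stop_invalid("pool sequence lengths must be in [15, 35] nt")
  }
  if (any(expected_fraction <= 0)) {
    stop_invalid("expected_fractions must all be > 0")
  }
  if (abs(sum(expected_fraction) - 1) > 1e-9) {
    stop_invalid("expected_fractions must sum to 1 (got ",
                 format(sum(expected_fraction), digits = 12), ")")
  }
  out <- data.frame(ref_id = ref_id, sequence = sequence,
                    expected_fraction = expected_fraction,
                    stringsAsFactors = FALSE)
  class(out) <- c("reference_pool", "data.frame")
  out
}

#' Build an equimolar pool of random reference sequences
#'
#' Generates `n` distinct random sequences emulating a synthetic equimolar
#' miRNA reference pool (such as the 963-member pools used to validate
#' sequencing assays). Each sequence gets a uniform random length in
#' `[length_low, length_high]` and a per-sequence GC content drawn uniformly
#' from `gc_range`; every entry receives expected fraction `1/n`.
#'
#' @param n Number of pool members.
#' @param length_low,length_high Sequence length bounds in nt (within
#'   15-35).
#' @param gc_range Length-2 numeric, per-sequence target GC content range.
#' @param seed Integer seed; the same seed reproduces the pool exactly.
#'
#' @return A [reference_pool()] of `n` entries, fractions all `1/n`.
#' @examples
#' pool <- build_equimolar_pool(10, seed = 1)
#' stopifnot(all(pool$expected_fraction == 0.1))
#' @export
build_equimolar_pool <- function(n, length_low = 19, length_high = 24,
                                 gc_range = c(0.2, 0.8), seed = 1) {
  if (!is_count(n, min = 1)) stop_invalid("n must be an integer >= 1")
  if (!is_count(length_low) || !is_count(length_high) ||
      length_low < 15 || length_high > 35 || length_low > length_high) {
    stop_invalid("need 15 <= length_low <= length_high <= 35")
  }
  if (length(gc_range) != 2L || gc_range[1] > gc_range[2] ||
      gc_range[1] < 0 || gc_range[2] > 1) {
    stop_invalid("gc_range must be an increasing pair within [0, 1]")
  }
  n <- as.integer(n)
  lengths <- seq.int(length_low, length_high)
  if (n > 0.5 * sum(4^lengths)) {
    stop_data("cannot draw ", n, " distinct sequences of length ",
              length_low, "-", length_high)
  }
  seqs <- with_seed(seed, {
    acc <- character(0)
    for (round in 1:60) {
      need <- n - length(acc)
      if (need <= 0L) break
      L <- if (length(lengths) == 1L) rep.int(lengths, need) else {
        sample(lengths, need, replace = TRUE)
      }
      gc <- runif(need, gc_range[1], gc_range[2])
      fresh <- vapply(seq_len(need), function(i) {
        p <- c((1 - gc[i]) / 2, gc[i] / 2, gc[i] / 2, (1 - gc[i]) / 2)
        paste(sample(c("A", "C", "G", "T"), L[i], replace = TRUE, prob = p),
              collapse = "")
      }, character(1))
      acc <- unique(c(acc, fresh))
    }
    acc
  })
  if (length(seqs) < n) {
    stop_data("could not generate ", n, " distinct sequences of length ",
              length_low, "-", length_high)
  }
  reference_pool(ref_id = sprintf("synth-miR-%0*d", max(4L, nchar(n)), seq_len(n)),
                 sequence = seqs[seq_len(n)],
                 expected_fraction = rep(1 / n, n))
}

#' Read and write reference pools
#'
#' A pool is stored as a FASTA file of sequences plus a sidecar TSV of
#' expected molar fractions (columns `ref_id`, `fraction`). On write, `U` is
#' converted to `T` (DNA alphabet).
#'
#' @param pool A [reference_pool()].
#' @param fasta Path to the FASTA file.
#' @param fractions Path to the fractions TSV. For `read_pool()`, `NULL`
#'   means equimolar fractions `1/n`.
#' @return `write_pool()` returns `pool` invisibly; `read_pool()` returns a
#'   [reference_pool()].
#' @export
write_pool <- function(pool, fasta, fractions = NULL) {
  stopifnot(inherits(pool, "reference_pool"))
  seqs <- Biostrings::DNAStringSet(as_dna(pool$sequence))
  names(seqs) <- pool$ref_id
  Biostrings::writeXStringSet(seqs, filepath = fasta, format = "fasta")
  if (!is.null(fractions)) {
    write.table(data.frame(ref_id = pool$ref_id,
                           fraction = pool$expected_fraction),
                fractions, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(pool)
}

#' @rdname write_pool
#' @export
read_pool <- function(fasta, fractions = NULL) {
  seqs <- Biostrings::readDNAStringSet(fasta, format = "fasta")
  ids <- sub("\\s.*$", "", names(seqs))
  frac <- if (is.null(fractions)) {
    rep(1 / length(seqs), length(seqs))
  } else {
    tab <- read.delim(fractions, stringsAsFactors = FALSE)
    if (!all(c("ref_id", "fraction") %in% names(tab))) {
      stop_data("fractions TSV needs columns ref_id and fraction")
    }
    m <- match(ids, tab$ref_id)
    if (anyNA(m)) {
      stop_data("fractions TSV is missing entries for: ",
                paste(utils::head(ids[is.na(m)], 3L), collapse = ", "))
    }
    tab$fraction[m]
  }
  reference_pool(ids, as.character(seqs), frac)
}

#' @export
print.reference_pool <- function(x, ...) {
  cat(sprintf("reference_pool: %d sequences, lengths %d-%d nt%s\n",
              nrow(x), min(nchar(x$sequence)), max(nchar(x$sequence)),
              if (length(unique(x$expected_fraction)) == 1L) " (equimolar)" else ""))
  print(utils::head(as.data.frame(x), 5L))
  if (nrow(x) > 5L) cat("...\n")
  invisible(x)
}
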