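#' Trim the 3' adapter from reads
#'
#' Error-tolerant 3' adapter trimming with the semantics of the standard
#' small-RNA trimming invocation (`-a <adapter> -m 15`): the best occurrence
#' of the adapter — the full adapter anywhere in the read, or an adapter
#' prefix running off the read's 3' end — is located allowing mismatches and
#' indels (unit cost) at a rate of at most `max_error_rate` errors per
#' aligned adapter base. Longer adapter matches are preferred, ties broken
#' by the leftmost occurrence. The occurrence and everything 3' of it are
#' removed. Reads with no qualifying occurrence are kept untrimmed; kept
#' reads shorter than `min_length` are discarded and counted.
#'
#' @param reads A [read_set()].
#' @param adapter 3' adapter DNA sequence.
#' @param max_error_rate Maximum errors per aligned adapter base, in
#'   `[0, 0.5)`.
#' @param min_length Minimum kept read length in nt; shorter reads are
#'   discarded (`-m`).
#' @param min_overlap Minimum aligned adapter length for a 3'-end partial
#'   occurrence to count (guards against trimming on 1-2 nt coincidences;
#'   the conventional default is 3).
#'
#' @return A `trim_result`: list with `kept` (a [read_set()] of trimmed
#'   reads), `n_input`, `n_trimmed`, `n_untrimmed`, `n_discarded_short`.
#'   Always `n_input == nrow(kept) + n_discarded_short`.
#' @examples
#' rs <- read_set("r1", paste0("ACGTACGTACGTACGTACGT", "TGGAATTCTCGGGTGCCAAGG"),
#'                strrep("I", 41))
#' tr <- trim_adapter(rs)
#' stopifnot(tr$kept$sequence == "ACGTACGTACGTACGTACGT")
#' @export
trim_adapter <- function(reads, adapter = "TGGAATTCTCGGGTGCCAAGG",
                         max_error_rate = 0.1, min_length = 15,
                         min_overlap = 3) {
  stopifnot(inherits(reads, "read_set"))
  if (!nzchar(adapter)) stop_invalid("adapter must be non-empty")
  check_dna(adapter, "adapter")
  if (!is.numeric(max_error_rate) || max_error_rate < 0 || max_error_rate >= 0.5) {
    stop_invalid("max_error_rate must lie in [0, 0.5)")
  }
  if (!is_count(min_length, min = 1)) stop_invalid("min_length must be >= 1")
  if (!is_count(min_overlap, min = 1)) stop_invalid("min_overlap must be >= 1")
  adapter <- as_dna(adapter)

  n_input <- nrow(reads)
  if (n_input == 0L) {
    return(structure(list(kept = reads, n_input = 0L, n_trimmed = 0L,
                          n_untrimmed = 0L, n_discarded_short = 0L),
                     class = "trim_result"))
  }
  pos <- trim_positions_cpp(reads$sequence, adapter, max_error_rate,
                            as.integer(min_overlap))
  trimmed <- pos >= 0L
  keep_len <- pos
  keep_len[!trimmed] <- nchar(reads$sequence[!trimmed])
  long_enough <- keep_len >= min_length
  kept <- data.frame(read_id = reads$read_id[long_enough],
                     sequence = substr(reads$sequence[long_enough], 1L,
                                       keep_len[long_enough]),
                     quality = substr(reads$quality[long_enough], 1L,
                                      keep_len[long_enough]),
                     stringsAsFactors = FALSE)
  class(kept) <- c("read_set", "data.frame")
  structure(list(kept = kept,
                 n_input = n_input,
                 n_trimmed = sum(trimmed),
                 n_untrimmed = sum(!trimmed),
                 n_discarded_short = sum(!long_enough)),
            class = "trim_result")
}

#' @export
print.trim_result <- function(x, ...) {
  cat(sprintf(paste0("trim_result: %d reads in; %d with adapter, %d without; ",
                     "%d discarded (< min length); %d kept\n"),
              x$n_input, x$n_trimmed, x$n_untrimmed, x$n_discarded_short,
              nrow(x$kept)))
  invisible(x)
}

#' Write a trimming report to TSV
#'
#' One row with the trim tallies of [trim_adapter()].
#'
#' @param trim A `trim_result`.
#' @param path Output TSV path.
#' @param library_id Library label for the report row.
#' @return `trim`, invisibly.
#' @export
write_trim_report <- function(trim, path, library_id = "library") {
  stopifnot(inherits(trim, "trim_result"))
  write.table(data.frame(library_id = library_id,
                         n_input = trim$n_input,
                         n_trimmed = trim$n_trimmed,
                         n_untrimmed = trim$n_untrimmed,
                         n_discarded_short = trim$n_discarded_short,
                         n_kept = nrow(trim$kept)),
              path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(trim)
}
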