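#' Read sets
#'
#' A read set holds ordered FASTQ records as a data frame with columns
#' `read_id`, `sequence` and `quality`. Quality strings always have the
#' same length as their sequence.
#'
#' @param read_id,sequence,quality Character vectors of equal length.
#' @return A `read_set` data frame.
#' @export
read_set <- function(read_id, sequence, quality) {
  n <- length(read_id)
  if (length(sequence) != n || length(quality) != n) {
    stop_invalid("read_id, sequence and quality must have equal length")
  }
  if (n > 0L) {
    if (any(nchar(sequence) < 1L)) stop_invalid("read sequences must be non-empty")
    if (any(nchar(quality) != nchar(sequence))) {
      stop_invalid("quality strings must match sequence lengths")
    }
  }
  out <- data.frame(read_id = as.character(read_id),
                    sequence = as.character(sequence),
                    quality = as.character(quality),
                    stringsAsFactors = FALSE)
  class(out) <- c("read_set", "data.frame")
  out
}

#' @export
print.read_set <- function(x, ...) {
  cat(sprintf("read_set: %d reads, lengths %s nt\n", nrow(x),
              if (nrow(x)) paste0(min(nchar(x$sequence)), "-",
                                  max(nchar(x$sequence))) else "-"))
  print(utils::head(as.data.frame(x), 3L))
  if (nrow(x) > 3L) cat("...\n")
  invisible(x)
}

#' Simulate a sequencing library from a reference pool
#'
#' Generates single-end reads under a two-stage capture model with known
#' ground truth:
#'
#' 1. **Ligation/capture.** Pre-PCR molecule counts are multinomial with
#'    probabilities proportional to `expected_fraction * ligation_efficiency`.
#' 2. **PCR.** Each captured molecule of reference `i` is weighted by
#'    `(1 + q_i)^c` (deterministic expected amplification over `c` cycles);
#'    final read counts are multinomial over these weights.
#'
#' `floor(dimer_rate * depth)` reads are adapter-dimer reads consisting of
#' the adapter sequence alone. Every miRNA read is the reference sequence
#' (U converted to T) followed by the 3' adapter, truncated to
#' `read_length`; qualities are a constant high-quality symbol because no
#' downstream stage consumes them. The emitted read count equals `depth`
#' exactly and read order is shuffled.
#'
#' @param pool A [reference_pool()].
#' @param profile A [bias_profile()] covering every pool member.
#' @param depth Total number of reads to emit.
#' @param read_length Read length in nt (36 for MiSeq-style runs, 50 for
#'   NextSeq-style runs).
#' @param adapter 3' adapter DNA sequence appended to each insert.
#' @param seed Integer seed; all randomness in the call flows from it.
#'
#' @return A list of class `simulated_library`: `reads` (a [read_set()]),
#'   `truth` (data frame `ref_id`, `true_fraction`, `ligation_efficiency`,
#'   `pcr_weight`, `realized_count`), `n_dimer` and `depth`.
#' @examples
#' pool <- build_equimolar_pool(5, seed = 1)
#' prof <- sample_bias_profile(pool, sigma_log2 = 0, dimer_rate = 0, seed = 1)
#' lib <- simulate_library(pool, prof, depth = 100, seed = 1)
#' stopifnot(nrow(lib$reads) == 100, sum(lib$truth$realized_count) == 100)
#' @export
simulate_library <- function(pool, profile, depth, read_length = 36,
                             adapter = "TGGAATTCTCGGGTGCCAAGG", seed = 1) {
  stopifnot(inherits(pool, "reference_pool"), inherits(profile, "bias_profile"))
  if (!is_count(depth, min = 1)) stop_invalid("depth must be an integer >= 1")
  if (!is_count(read_length, min = 15)) {
    stop_invalid("read_length must be an integer >= 15")
  }
  if (!nzchar(adapter)) stop_invalid("adapter must be non-empty")
  check_dna(adapter, "adapter")
  adapter <- as_dna(adapter)

  eff <- profile$efficiencies
  m <- match(pool$ref_id, eff$ref_id)
  if (anyNA(m)) {
    stop_data("profile is missing pool references: ",
              paste(utils::head(pool$ref_id[is.na(m)], 3L), collapse = ", "))
  }
  e <- eff$ligation_efficiency[m]
  q <- eff$pcr_efficiency[m]
  w <- (1 + q)^profile$pcr_cycles
  depth <- as.integer(depth)
  n_dimer <- as.integer(floor(profile$dimer_rate * depth))
  depth_eff <- depth - n_dimer

  # capture and amplification collapse into one multinomial: ligation
  # selects molecules with probability proportional to f_i * e_i and the
  # deterministic PCR weight (1 + q_i)^c rescales each reference's share.
  # A single draw keeps the per-reference counts exactly multinomial (no
  # extra resampling variance), which is what makes closed-form oracles
  # for the downstream statistics possible.
  p_capture <- pool$expected_fraction * e * w
  counts <- with_seed(seed, {
    if (depth_eff > 0L) {
      as.vector(rmultinom(1, depth_eff, p_capture))
    } else integer(nrow(pool))
  })

  dna <- as_dna(pool$sequence)
  read_tpl <- substr(paste0(dna, adapter), 1L, read_length)
  dimer_tpl <- substr(adapter, 1L, read_length)
  seqs <- c(rep.int(read_tpl, counts), rep.int(dimer_tpl, n_dimer))
  origin <- c(rep.int(pool$ref_id, counts), rep.int("adapter-dimer", n_dimer))
  ord <- with_seed(derive_seed(seed, 7L), sample.int(depth))
  seqs <- seqs[ord]
  origin <- origin[ord]
  qual_by_len <- strrep("I", seq_len(max(nchar(seqs))))
  reads <- read_set(
    read_id = sprintf("sim:%07d:%s", seq_len(depth), origin),
    sequence = seqs,
    quality = qual_by_len[nchar(seqs)]
  )
  truth <- data.frame(ref_id = pool$ref_id,
                      true_fraction = pool$expected_fraction,
                      ligation_efficiency = e,
                      pcr_weight = w,
                      realized_count = counts,
                      stringsAsFactors = FALSE)
  structure(list(reads = reads, truth = truth, n_dimer = n_dimer,
                 depth = depth),
            class = "simulated_library")
}

#' @export
print.simulated_library <- function(x, ...) {
  cat(sprintf("simulated_library: %d reads (%d adapter-dimer), %d references\n",
              x$depth, x$n_dimer, nrow(x$truth)))
  invisible(x)
}

#' FASTQ input and output
#'
#' Standard 4-line FASTQ, read and written through Biostrings. Paths ending
#' in `.gz` are compressed.
#'
#' @param reads A [read_set()].
#' @param path FASTQ file path (plain or `.gz`).
#' @return `write_fastq()` returns `reads` invisibly; `read_fastq()`
#'   returns a [read_set()].
#' @export
write_fastq <- function(reads, path) {
  stopifnot(inherits(reads, "read_set"))
  seqs <- Biostrings::DNAStringSet(reads$sequence)
  names(seqs) <- reads$read_id
  Biostrings::writeXStringSet(seqs, filepath = path, format = "fastq",
                              qualities = Biostrings::BStringSet(reads$quality),
                              compress = grepl("\\.gz$", path))
  invisible(reads)
}

#' @rdname write_fastq
#' @export
read_fastq <- function(path) {
  seqs <- Biostrings::readDNAStringSet(path, format = "fastq",
                                       with.qualities = TRUE)
  read_set(read_id = names(seqs),
           sequence = as.character(seqs),
           quality = as.character(S4Vectors::mcols(seqs)$qualities))
}

#' Write simulator ground truth to TSV
#'
#' Columns: `ref_id`, `true_fraction`, `ligation_efficiency`, `pcr_weight`,
#' `realized_count`.
#'
#' @param lib A `simulated_library` from [simulate_library()].
#' @param path Output TSV path.
#' @return `lib`, invisibly.
#' @export
write_truth <- function(lib, path) {
  stopifnot(inherits(lib, "simulated_library"))
  write.table(lib$truth, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(lib)
}
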