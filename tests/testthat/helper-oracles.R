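# Independent oracles used across tests. These deliberately use different
# algorithms from the package implementation (naive enumeration, textbook
# formulas) so agreement is evidence, not tautology.

# Brute-force 3' adapter occurrence search: enumerate every start s and
# aligned adapter prefix length j, computing edit distances with
# utils::adist. An occurrence is (s, j) with either j == nchar(adapter)
# (full adapter, segment end free) or the segment pinned to the read's 3'
# end; it qualifies when errors <= rate * j and j >= min_overlap. Longest
# j wins, then smallest s. Returns the trim position s, or -1.
oracle_trim_pos <- function(seq, adapter, rate = 0.1, min_overlap = 3) {
  n <- nchar(seq)
  m <- nchar(adapter)
  best_j <- -1L
  best_s <- -1L
  consider <- function(j, s) {
    if (j > best_j) {
      best_j <<- j
      best_s <<- s
    } else if (j == best_j && s < best_s) {
      best_s <<- s
    }
  }
  for (s in 0:(n - 1)) {
    tail_seg <- substr(seq, s + 1, n)
    # full adapter, any segment length
    segs <- vapply(seq_len(n - s), function(t) substr(seq, s + 1, s + t), "")
    if (min(utils::adist(adapter, segs)) <= rate * m && m >= min_overlap) {
      consider(m, s)
    }
    # adapter prefix pinned to the 3' end
    for (j in min_overlap:(m - 1)) {
      if (utils::adist(substr(adapter, 1, j), tail_seg)[1, 1] <= rate * j) {
        consider(j, s)
      }
    }
  }
  if (best_j < 0) -1L else best_s
}

oracle_trim <- function(reads, adapter, rate = 0.1, min_length = 15,
                        min_overlap = 3) {
  pos <- vapply(reads$sequence, oracle_trim_pos, integer(1),
                adapter = adapter, rate = rate, min_overlap = min_overlap,
                USE.NAMES = FALSE)
  keep <- ifelse(pos >= 0L, pos, nchar(reads$sequence))
  data.frame(read_id = reads$read_id,
             sequence = substr(reads$sequence, 1, keep),
             kept = keep >= min_length,
             trimmed = pos >= 0L,
             stringsAsFactors = FALSE)
}

# Textbook Welch two-sample t-test.
oracle_welch <- function(a, b) {
  va <- var(a) / length(a)
  vb <- var(b) / length(b)
  t <- (mean(a) - mean(b)) / sqrt(va + vb)
  df <- (va + vb)^2 / (va^2 / (length(a) - 1) + vb^2 / (length(b) - 1))
  list(t = t, df = df, p = 2 * pt(-abs(t), df))
}

# Pearson correlation from the raw covariance formula.
oracle_pearson <- function(x, y) {
  n <- length(x)
  sxy <- sum((x - mean(x)) * (y - mean(y)))
  sxy / sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
}

# Quick read_set around bare sequences.
reads_from_seq <- function(seqs, prefix = "r") {
  read_set(sprintf("%s%04d", prefix, seq_along(seqs)), seqs,
           strrep("I", nchar(seqs)))
}

random_dna <- function(n, len, seed = NULL) {
  draw <- function() {
    vapply(len, function(L) paste(sample(c("A", "C", "G", "T"), L,
                                         replace = TRUE), collapse = ""),
           character(1))
  }
  if (is.null(seed)) draw() else srnabias:::with_seed(seed, draw())
}

ADAPTER <- "TGGAATTCTCGGGTGCCAAGG"

# Reads with planted adapter occurrences for trimmer tests: full internal,
# 3'-partial, with planted substitution/indel errors, or no adapter.
planted_adapter_reads <- function(n, seed, read_length = 36,
                                  adapter = ADAPTER) {
  srnabias:::with_seed(seed, {
    seqs <- vapply(seq_len(n), function(i) {
      kind <- sample(c("full", "partial", "errors", "none"), 1)
      insert_len <- sample(8:28, 1)
      insert <- paste(sample(c("A", "C", "G", "T"), insert_len, TRUE),
                      collapse = "")
      if (kind == "none") {
        paste(sample(c("A", "C", "G", "T"), read_length, TRUE), collapse = "")
      } else {
        ad <- adapter
        if (kind == "errors") {
          ab <- strsplit(ad, "")[[1]]
          for (k in seq_len(sample(1:2, 1))) {
            op <- sample(c("sub", "ins", "del"), 1)
            pos <- sample(length(ab), 1)
            if (op == "sub") {
              ab[pos] <- sample(setdiff(c("A", "C", "G", "T"), ab[pos]), 1)
            } else if (op == "ins") {
              ab <- append(ab, sample(c("A", "C", "G", "T"), 1), after = pos)
            } else if (length(ab) > 3) {
              ab <- ab[-pos]
            }
          }
          ad <- paste(ab, collapse = "")
        }
        full <- paste0(insert, ad)
        tail_fill <- paste(sample(c("A", "C", "G", "T"),
                                  max(0, read_length - nchar(full)), TRUE),
                           collapse = "")
        substr(paste0(full, tail_fill), 1, read_length)
      }
    }, character(1))
    reads_from_seq(seqs)
  })
}
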