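#' Per-library reference count tables
#'
#' A count table holds, for one library, the reads assigned to each
#' reference in a pool (the full pool universe, zeros included), the
#' assigned depth and the number of unassigned reads. Counts may be
#' fractional when a read matches several references equally well (each
#' receives `1/k`).
#'
#' @param library_id Library label.
#' @param counts Named numeric vector of per-reference counts (>= 0).
#' @param unassigned Number of reads that matched no reference.
#' @return A `count_table` object.
#' @export
count_table <- function(library_id, counts, unassigned = 0) {
  if (is.null(names(counts)) || anyDuplicated(names(counts))) {
    stop_invalid("counts must be named with unique ref_ids")
  }
  if (any(counts < 0)) stop_invalid("counts must be >= 0")
  if (!is_count(round(unassigned, 6))) stop_invalid("unassigned must be >= 0")
  structure(list(library_id = as.character(library_id),
                 counts = counts,
                 depth = sum(counts),
                 unassigned = as.numeric(unassigned)),
            class = "count_table")
}

#' @export
print.count_table <- function(x, ...) {
  cat(sprintf(paste0("count_table '%s': %d references, %.6g assigned reads, ",
                     "%.6g unassigned\n"),
              x$library_id, length(x$counts), x$depth, x$unassigned))
  invisible(x)
}

# Match unique read sequences against a reference pool.
#
# A read is assigned to a reference when the two agree over their shared
# prefix (length = the shorter of the two) with at most `max_mismatches`
# substitutions, and their lengths differ by at most `length_tolerance` nt
# (3' length variation; tolerates isomiR-like ends). Among qualifying
# references the fewest mismatches win, then the smallest length
# difference; remaining ties share the read fractionally.
#
# Returns a list with per-unique-sequence assignment: `useq`, and parallel
# lists `ref_idx` (integer vectors, possibly empty) and `weight` (1/k).
match_unique_reads <- function(useq, pool, max_mismatches, length_tolerance) {
  ref_dna <- as_dna(pool$sequence)
  ref_len <- nchar(ref_dna)
  # An exact full-length match is the unique best assignment (0 mismatches,
  # 0 length difference) — valid as a shortcut only while pool sequences
  # are distinct.
  exact <- if (anyDuplicated(ref_dna)) rep(NA_integer_, length(useq)) else {
    match(useq, ref_dna)
  }
  ref_raw <- lapply(ref_dna, charToRaw)
  ulen <- nchar(useq)

  ref_idx <- vector("list", length(useq))
  for (u in seq_along(useq)) {
    if (!is.na(exact[u])) {
      ref_idx[[u]] <- exact[u]
      next
    }
    cand <- which(abs(ref_len - ulen[u]) <= length_tolerance)
    if (length(cand) == 0L) {
      ref_idx[[u]] <- integer(0)
      next
    }
    uraw <- charToRaw(useq[u])
    mm <- integer(length(cand))
    dd <- integer(length(cand))
    for (k in seq_along(cand)) {
      rraw <- ref_raw[[cand[k]]]
      L <- min(length(uraw), length(rraw))
      mm[k] <- sum(uraw[seq_len(L)] != rraw[seq_len(L)])
      dd[k] <- abs(length(uraw) - length(rraw))
    }
    ok <- mm <= max_mismatches
    if (!any(ok)) {
      ref_idx[[u]] <- integer(0)
      next
    }
    best_mm <- min(mm[ok])
    sel <- ok & mm == best_mm
    best_dd <- min(dd[sel])
    ref_idx[[u]] <- cand[sel & dd == best_dd]
  }
  list(useq = useq, ref_idx = ref_idx,
       weight = vapply(ref_idx, function(ix) {
         if (length(ix)) 1 / length(ix) else 0
       }, numeric(1)))
}

#' Count reads against a reference pool
#'
#' Assigns each (trimmed) read to pool references with a prefix-anchored
#' ungapped matcher: a read matches a reference when both agree over their
#' shared prefix with at most `max_mismatches` substitutions and their
#' lengths differ by at most `length_tolerance` nt at the 3' end. A read
#' matching `k` references equally well is counted `1/k` to each
#' (fractional counting — deterministic and order-independent), so counts
#' may be rational. Reads matching nothing are tallied as `unassigned`.
#'
#' @param reads A [read_set()] of trimmed reads.
#' @param pool A [reference_pool()].
#' @param max_mismatches Maximum substitutions (0, 1 or 2).
#' @param length_tolerance Maximum 3' length difference in nt.
#' @param library_id Label recorded in the table.
#'
#' @return A [count_table()] over the full pool universe. Always
#'   `sum(counts) + unassigned == nrow(reads)`.
#' @examples
#' pool <- build_equimolar_pool(5, seed = 1)
#' rs <- read_set("r1", pool$sequence[1], strrep("I", nchar(pool$sequence[1])))
#' ct <- count_reads(rs, pool)
#' stopifnot(ct$counts[[pool$ref_id[1]]] == 1)
#' @export
count_reads <- function(reads, pool, max_mismatches = 0, length_tolerance = 2,
                        library_id = "library") {
  stopifnot(inherits(reads, "read_set"), inherits(pool, "reference_pool"))
  if (!max_mismatches %in% c(0, 1, 2)) {
    stop_invalid("max_mismatches must be 0, 1 or 2")
  }
  counts <- numeric(nrow(pool))
  names(counts) <- pool$ref_id
  if (nrow(reads) == 0L) {
    return(count_table(library_id, counts, unassigned = 0))
  }
  useq <- unique(reads$sequence)
  uidx <- match(reads$sequence, useq)
  freq <- tabulate(uidx, nbins = length(useq))
  asg <- match_unique_reads(useq, pool, max_mismatches, length_tolerance)
  unassigned <- 0
  for (u in seq_along(useq)) {
    ix <- asg$ref_idx[[u]]
    if (length(ix)) {
      counts[ix] <- counts[ix] + freq[u] * asg$weight[u]
    } else {
      unassigned <- unassigned + freq[u]
    }
  }
  count_table(library_id, counts, unassigned = unassigned)
}

#' Read and write count tables
#'
#' Long TSV format with columns `library_id`, `ref_id`, `count`, `depth`,
#' `unassigned` (the last two repeated per row).
#'
#' @param counts A [count_table()].
#' @param path TSV path.
#' @return `write_count_table()` returns `counts` invisibly;
#'   `read_count_table()` returns a [count_table()].
#' @export
write_count_table <- function(counts, path) {
  stopifnot(inherits(counts, "count_table"))
  write.table(data.frame(library_id = counts$library_id,
                         ref_id = names(counts$counts),
                         count = unname(counts$counts),
                         depth = counts$depth,
                         unassigned = counts$unassigned),
              path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(counts)
}

#' @rdname write_count_table
#' @export
read_count_table <- function(path) {
  tab <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("library_id", "ref_id", "count", "unassigned")
  if (!all(need %in% names(tab))) {
    stop_data("count table TSV needs columns: ", paste(need, collapse = ", "))
  }
  counts <- tab$count
  names(counts) <- tab$ref_id
  count_table(tab$library_id[1], counts, unassigned = tab$unassigned[1])
}
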