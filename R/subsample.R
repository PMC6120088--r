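#' Subsample reads to a fixed depth
#'
#' Uniform sampling without replacement of exactly `target_depth` reads,
#' used to compare libraries at equal depth (e.g. 200,000 trimmed reads per
#' library before counting detected miRNAs). Output preserves the input
#' read order and is deterministic for a fixed seed.
#'
#' @param reads A [read_set()].
#' @param target_depth Number of reads to keep (`<= nrow(reads)`).
#' @param seed Integer seed.
#'
#' @return A [read_set()] of exactly `target_depth` reads.
#' @examples
#' rs <- read_set(paste0("r", 1:10), strrep("ACGT", 5 + 0:9),
#'                strrep("I", 4 * (5 + 0:9)))
#' sub <- subsample_reads(rs, 4, seed = 1)
#' stopifnot(nrow(sub) == 4)
#' @export
subsample_reads <- function(reads, target_depth, seed = 1) {
  stopifnot(inherits(reads, "read_set"))
  if (!is_count(target_depth, min = 0)) {
    stop_invalid("target_depth must be a nonnegative integer")
  }
  n <- nrow(reads)
  if (target_depth > n) {
    stop_depth("cannot subsample ", format(target_depth, scientific = FALSE),
               " reads from a library of ", n, " reads")
  }
  idx <- with_seed(seed, sort(sample.int(n, as.integer(target_depth))))
  out <- reads[idx, , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("read_set", "data.frame")
  out
}
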