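# Internal helpers: seeded RNG scope, classed errors, small validators.

# Evaluate `code` under a fixed RNG state, restoring the caller's state on
# exit. RNG kind is pinned so results do not depend on session options.
with_seed <- function(seed, code) {
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed)) {
    stop_invalid("seed must be a single finite number")
  }
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed), kind = "Mersenne-Twister",
           normal.kind = "Inversion", sample.kind = "Rejection")
  force(code)
}

stop_invalid <- function(...) {
  stop(errorCondition(paste0(...),
                      class = c("srnabias_invalid_argument", "srnabias_error")))
}

stop_data <- function(...) {
  stop(errorCondition(paste0(...),
                      class = c("srnabias_data_error", "srnabias_error")))
}

stop_depth <- function(...) {
  stop(errorCondition(paste0(...),
                      class = c("srnabias_insufficient_depth", "srnabias_error")))
}

is_count <- function(x, min = 0) {
  is.numeric(x) && length(x) == 1L && is.finite(x) && x >= min &&
    abs(x - round(x)) < 1e-8
}

# DNA/RNA helpers ------------------------------------------------------------

# Uppercase and convert U -> T (sequencers report the DNA alphabet).
as_dna <- function(x) chartr("u", "T", chartr("U", "T", toupper(x)))

check_dna <- function(x, what = "sequence", alphabet = "ACGT") {
  bad <- grepl(sprintf("[^%s]", alphabet), as_dna(x))
  if (any(bad)) {
    stop_invalid(what, " contains characters outside {", alphabet, "}: ",
                 paste(utils::head(x[bad], 3L), collapse = ", "))
  }
  invisible(x)
}

gc_fraction <- function(x) {
  x <- as_dna(x)
  vapply(x, function(s) {
    b <- strsplit(s, "", fixed = TRUE)[[1L]]
    mean(b %in% c("G", "C"))
  }, numeric(1), USE.NAMES = FALSE)
}

# Save a ggplot through an explicit grDevices device (deterministic output;
# no optional device packages involved).
save_plot <- function(path, p, width = 6, height = 4, dpi = 150) {
  ext <- tolower(tools::file_ext(path))
  dev <- switch(ext,
                svg = grDevices::svg,
                png = grDevices::png,
                pdf = grDevices::pdf,
                stop_invalid("unsupported figure format: .", ext))
  ggplot2::ggsave(path, p, device = dev, width = width, height = height,
                  dpi = dpi)
  invisible(p)
}

# Derive a child seed from a base seed; stays below 2^31.
derive_seed <- function(seed, ...) {
  offs <- c(...)
  s <- as.double(seed)
  for (o in offs) s <- (s * 69069 + o) %% 2147483629
  as.integer(s)
}
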