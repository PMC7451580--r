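#' Read a single-column sample of positive values
#'
#' Samples are plain CSV: one strictly positive value per line, with an
#' optional single header line. Nonpositive or non-numeric entries are an
#' error naming the offending row numbers; a short summary (n, min, max,
#' sample skewness) is emitted as a message.
#'
#' @param path Path to the file.
#' @param quiet Suppress the summary message.
#' @return Numeric vector of positive values.
#' @export
read_sample_csv <- function(path, quiet = FALSE) {
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  lines <- trimws(readLines(path, warn = FALSE))
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) abort("file is empty.")
  first_row <- 1L
  if (is.na(suppressWarnings(as.numeric(lines[1])))) first_row <- 2L # header
  if (first_row > length(lines)) abort("file contains a header but no data.")
  vals <- suppressWarnings(as.numeric(lines[first_row:length(lines)]))
  rows <- seq.int(first_row, length(lines))
  bad_num <- rows[is.na(vals)]
  if (length(bad_num) > 0L) {
    abort(sprintf("non-numeric values at rows: %s",
                  paste(head(bad_num, 5L), collapse = ", ")))
  }
  bad_pos <- rows[vals <= 0]
  if (length(bad_pos) > 0L) {
    abort(sprintf("nonpositive values (support is x > 0) at rows: %s",
                  paste(head(bad_pos, 5L), collapse = ", ")))
  }
  if (!quiet) {
    m <- mean(vals); s <- sd(vals)
    skew <- if (s > 0) mean((vals - m)^3) / s^3 else NA_real_
    message(sprintf("read %d values: min %.6g, max %.6g, skewness %.3f",
                    length(vals), min(vals), max(vals), skew))
  }
  vals
}

#' Generate a reproducible synthetic sample fixture
#'
#' Draws `n` values from a registry family by quantile inversion under
#' `seed`, optionally inflating a fraction of draws into the extreme tail
#' (the `q > 0.99` region) to emulate the contaminated, right-skewed shape
#' of heavy-tailed loss data. When `path` is given, the sample is written as
#' a one-column CSV (header `value`) together with a JSON manifest
#' (`<path>.manifest.json`) holding the full generating specification, so
#' the file can be regenerated bit-exactly.
#'
#' @param family Registry family identifier.
#' @param params Parameter vector in the family's order.
#' @param n Sample size (`>= 1`).
#' @param seed Integer seed (required).
#' @param contamination Fraction in `[0, 0.2]` of draws forced into the
#'   extreme tail.
#' @param path Optional output CSV path.
#' @return The sample vector, invisibly when written to `path`.
#' @examples
#' x <- generate_fixture("tihtw", c(1.4, 0.03, 2), n = 64, seed = 7)
#' @export
generate_fixture <- function(family, params, n, seed, contamination = 0,
                             path = NULL) {
  reg <- get_family(family)
  if (n < 1) abort("`n` must be >= 1.")
  if (missing(seed)) abort("`seed` is required.")
  if (contamination < 0 || contamination > 0.2) {
    abort("`contamination` must lie in [0, 0.2].")
  }
  u <- withr::with_seed(as.integer(seed), {
    u <- runif(n)
    if (contamination > 0) {
      inflate <- runif(n) < contamination
      u[inflate] <- 0.99 + 0.01 * runif(sum(inflate))
    }
    u
  })
  x <- reg$quantile(u, unname(params))
  if (!is.null(path)) {
    ok <- tryCatch(
      {
        writeLines(c("value", format(x, digits = 17)), path)
        TRUE
      },
      error = function(e) FALSE, warning = function(w) FALSE
    )
    if (!ok) abort(sprintf("cannot write to: %s", path))
    manifest <- list(
      family = family, params = as.numeric(params), n = as.integer(n),
      seed = as.integer(seed), contamination = contamination,
      generator = paste0("tiht ", as.character(utils::packageVersion("tiht")))
    )
    jsonlite::write_json(manifest, paste0(path, ".manifest.json"),
                         auto_unbox = TRUE, digits = NA)
    return(invisible(x))
  }
  x
}
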