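#' @keywords internal
"_PACKAGE"

## Conventions used throughout the package:
##  - pixel coordinates are 0-based and pixel-centered, x to the right, y down;
##  - times are seconds from the start of the recording;
##  - embryo axes are A-P (x, anterior = +x), D-V (y), L-R (z).

abort <- function(...) stop(..., call. = FALSE)

`%||%` <- function(a, b) if (is.null(a)) b else a

is_number <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)

check_number <- function(x, name, min = -Inf, max = Inf) {
  if (!is_number(x) || x < min || x > max)
    abort(sprintf("`%s` must be a single finite number in [%s, %s]",
                  name, format(min), format(max)))
  x
}

check_count <- function(x, name, min = 0L) {
  if (!is_number(x) || x != round(x) || x < min)
    abort(sprintf("`%s` must be an integer >= %d", name, min))
  as.integer(x)
}

#' Evaluate an expression under a temporary RNG state
#'
#' Seeds the global RNG, evaluates `expr`, and restores whatever random state
#' existed before the call, so generators are bit-reproducible without
#' disturbing the caller's random stream.
#'
#' @param seed integer seed.
#' @param expr expression to evaluate.
#' @return the value of `expr`.
#' @keywords internal
with_seed <- function(seed, expr) {
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) runif(1)
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  expr
}

#' Centered moving average with shrinking end windows
#'
#' @param v numeric vector.
#' @param window odd window width (>= 1).
#' @return smoothed vector of the same length; timepoint `i` is the mean of
#'   the values within `(window - 1) / 2` positions of `i`, truncated at the
#'   ends of the series.
#' @keywords internal
moving_average <- function(v, window) {
  window <- check_count(window, "window", min = 1L)
  if (window %% 2L == 0L) abort("`window` must be odd")
  n <- length(v)
  if (window > n) abort(sprintf("`window` (%d) exceeds series length (%d)",
                                window, n))
  h <- (window - 1L) %/% 2L
  cs <- cumsum(c(0, v))
  lo <- pmax(seq_len(n) - h, 1L)
  hi <- pmin(seq_len(n) + h, n)
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}

## simple parameter fingerprint for output headers (no external digest dep)
param_hash <- function(x) {
  s <- paste(deparse(x), collapse = "")
  bytes <- utf8ToInt(s)
  h <- 5381
  for (b in bytes) h <- (h * 33 + b) %% 2^31
  sprintf("%08x", h)
}

output_header <- function(seed, params = NULL, reproducible = TRUE) {
  ver <- as.character(utils::packageVersion("rosettes"))
  lines <- c(
    sprintf("# rosettes %s", ver),
    sprintf("# seed=%s params=%s", format(seed), param_hash(params))
  )
  if (!reproducible)
    lines <- c(lines, sprintf("# written=%s", format(Sys.time())))
  lines
}

write_csv_with_header <- function(df, path, seed = NA, params = NULL,
                                  reproducible = TRUE) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(output_header(seed, params, reproducible), con)
  utils::write.csv(df, con, row.names = FALSE)
  invisible(path)
}

read_csv_skip_comments <- function(path) {
  utils::read.csv(path, comment.char = "#")
}
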