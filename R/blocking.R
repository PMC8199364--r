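# Block averaging over a trailing analysis window.  Every trajectory-level
# summary in the package reports mean +/- std-across-blocks through this
# routine.

#' Block average of a time series
#'
#' The trailing `window` of the series is split into `n_blocks` contiguous
#' equal-duration blocks; the result is the mean of the block means and the
#' population standard deviation across block means as the error bar.
#'
#' @param values numeric series.
#' @param times sample times (ns); defaults to the sample index.
#' @param window trailing window duration (ns); NULL uses the whole series.
#' @param n_blocks number of blocks (>= 2 so an error bar exists).
#' @param circular treat values as angles in degrees (circular means and
#'   wrapped deviations).
#' @return object of class `block_result`: list with `mean`, `error`,
#'   `n_blocks`, `block_means`, `window` = c(t_start, t_end).
#' @export
block_average <- function(values, times = NULL, window = NULL, n_blocks = 5L,
                          circular = FALSE) {
  values <- as.numeric(values)
  if (is.null(times)) times <- seq_along(values) - 1
  if (length(times) != length(values)) stop("times and values lengths differ")
  if (n_blocks < 2L) stop("n_blocks must be >= 2 for an error bar")
  t_end <- max(times)
  span <- t_end - min(times)
  if (is.null(window)) window <- span
  if (window > span + 1e-9) stop("window exceeds the series span")
  t_start <- t_end - window
  sel <- times >= t_start - 1e-12
  tv <- times[sel]; vv <- values[sel]
  # block k covers [t_start + (k-1) w/n, t_start + k w/n), last block closed
  edges <- t_start + window * seq(0L, n_blocks) / n_blocks
  idx <- findInterval(tv, edges, rightmost.closed = TRUE)
  idx[idx > n_blocks] <- n_blocks
  mean_fun <- if (circular) circular_mean else mean
  block_means <- vapply(seq_len(n_blocks), function(k) {
    if (!any(idx == k)) stop("block ", k, " of ", n_blocks, " is empty")
    mean_fun(vv[idx == k])
  }, numeric(1L))
  if (circular) {
    m <- circular_mean(block_means)
    err <- sqrt(mean(wrap_angle(block_means - m)^2))
  } else {
    m <- mean(block_means)
    err <- sqrt(mean((block_means - m)^2))
  }
  structure(list(mean = m, error = err, n_blocks = n_blocks,
                 block_means = block_means, window = c(t_start, t_end)),
            class = "block_result")
}

#' @export
print.block_result <- function(x, ...) {
  cat(sprintf("<block_result> %.6g +/- %.3g (%d blocks over [%.3g, %.3g] ns)\n",
              x$mean, x$error, x$n_blocks, x$window[1L], x$window[2L]))
  invisible(x)
}
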