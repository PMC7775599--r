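#' @useDynLib larvaphenome, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats aov TukeyHSD kruskal.test median p.adjust pchisq pnorm
#'   rbinom rexp rlnorm rnorm rpois runif sd setNames t.test wilcox.test var
#' @importFrom utils read.csv write.csv packageVersion head tail
NULL

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Indices of samples falling in a half-open time window
#'
#' All windows in this package are half-open `[start, end)`: a sample at
#' exactly `end` belongs to the next window.
#'
#' @param t numeric vector of sample times (seconds).
#' @param window length-2 numeric `c(start_s, end_s)`.
#' @return integer indices of samples with `start <= t < end`.
#' @keywords internal
window_idx <- function(t, window) {
  stopifnot(length(window) == 2L, window[2] > window[1])
  which(t >= window[1] & t < window[2])
}

check_window <- function(window, t, what = "window") {
  if (length(window) != 2L || !is.numeric(window) || window[2] <= window[1])
    stop(what, " must be numeric c(start, end) with end > start", call. = FALSE)
  dt <- t[2] - t[1]
  if (window[1] < t[1] - 1e-9 || window[2] > t[length(t)] + dt + 1e-9)
    stop(what, " [", window[1], ", ", window[2],
         ") lies outside the recorded time range [", t[1], ", ",
         t[length(t)] + dt, ")", call. = FALSE)
  invisible(window)
}

# sampling interval of the tracking system, seconds (5 Hz)
DEFAULT_DT <- 0.2
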