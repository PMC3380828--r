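## SLIM-style sliding-linear-model FDR q-values.
##
## Under the two-group mixture model the survival count N(lambda) =
## #{p > lambda} is approximately n * pi0 * (1 - lambda) for lambda large
## enough that alternatives are exhausted. A through-origin line is fitted to
## N(lambda) against (1 - lambda) in sliding windows over the lambda grid;
## the window where the fit is most linear (smallest residual standard error
## relative to its mean) provides the slope, and pi0 = slope / n. The
## q-values are then the pi0-scaled Benjamini-Hochberg adjusted p-values,
## which keeps them monotone in p and bounded by 1.

#' SLIM q-values (sliding linear model FDR adjustment)
#'
#' Estimates the proportion of true nulls pi0 with a sliding linear model
#' over a lambda grid and returns `q = pi0 * BH(p)`, clipped to 1. For fewer
#' than `fallbackN` p-values the pi0 estimate is unstable and plain
#' Benjamini-Hochberg is used instead (with a message).
#'
#' @param p numeric p-values in `[0, 1]`; NaN/NA is an error.
#' @param lambda grid of tail thresholds (default 0.01 to 0.95 by 0.01).
#' @param windowSize number of consecutive grid points per sliding window.
#' @param fallbackN minimum n for the pi0 estimate (default 100).
#' @return q-values, same order as `p`, with the pi0 estimate attached as
#'   `attr(q, "pi0")`.
#' @export
adjustPvaluesSlim <- function(p, lambda = seq(0.01, 0.95, by = 0.01),
                              windowSize = 10L, fallbackN = 100L) {
    if (any(is.na(p)) || any(is.nan(p)))
        stop("NA/NaN p-value passed to SLIM adjustment")
    stopifnot(all(p >= 0 & p <= 1))
    n <- length(p)
    if (n < fallbackN) {
        message("fewer than ", fallbackN,
                " p-values: falling back to Benjamini-Hochberg")
        q <- stats::p.adjust(p, "BH")
        attr(q, "pi0") <- 1
        return(q)
    }
    nExceed <- vapply(lambda, function(l) sum(p > l), numeric(1))
    x <- 1 - lambda
    nw <- length(lambda) - windowSize + 1L
    slope <- rse <- numeric(nw)
    for (w in seq_len(nw)) {
        i <- w:(w + windowSize - 1L)
        s <- sum(x[i] * nExceed[i]) / sum(x[i]^2)  # through-origin LS
        res <- nExceed[i] - s * x[i]
        slope[w] <- s
        rse[w] <- sqrt(mean(res^2)) / max(s * mean(x[i]), 1)
    }
    pi0 <- min(1, max(0, slope[which.min(rse)] / n))
    q <- pmin(1, pi0 * stats::p.adjust(p, "BH"))
    attr(q, "pi0") <- pi0
    q
}
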