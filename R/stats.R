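# Exact and asymptotic Wilcoxon signed-rank and Mann-Whitney U tests.
#
# The exact paths compute the full null distribution of the rank-sum
# statistic by convolution over the (tie-adjusted, mid-ranked) ranks --
# equivalent to enumerating all 2^n sign assignments (signed rank) or all
# choose(n1+n2, n1) group labelings (U test), but feasible at the default
# crossover sizes. Mid-ranks can be half-integers, so ranks are doubled to
# integers internally. Two-tailed p = min(1, 2 * min(lower, upper tail)).

.twoTailed <- function(lower, upper) min(1, 2 * min(lower, upper))

#' Wilcoxon signed-rank test for paired differences
#'
#' Zero differences are dropped (Wilcoxon's original convention), absolute
#' differences are mid-ranked, and the statistic is the sum of ranks of the
#' positive differences. For `n_effective <= exactLimit` the two-tailed p is
#' exact over all sign assignments; beyond that a normal approximation with
#' continuity and tie corrections is used.
#'
#' @param diffs Numeric vector of paired differences (e.g. aerobe GC minus
#'   anaerobe GC per pair).
#' @param exactLimit Largest `n_effective` for which the exact distribution
#'   is enumerated (default 25).
#' @param method `"auto"`, `"exact"` or `"approximate"`.
#' @return An object of class `htest` with `statistic` (W), `p.value`,
#'   `parameter` (`n_effective`) and `method`.
#' @examples
#' wilcoxonSignedRank(c(1, 2, 3, 4, 5))$p.value  # 2/32
#' @export
wilcoxonSignedRank <- function(diffs, exactLimit = 25L,
                               method = c("auto", "exact", "approximate")) {
  method <- match.arg(method)
  stopifnot(is.numeric(diffs), all(is.finite(diffs)))
  nZero <- sum(diffs == 0)
  d <- diffs[diffs != 0]
  n <- length(d)
  if (n == 0L)
    stop("degenerate data: all differences are zero", call. = FALSE)
  r <- rank(abs(d))
  W <- sum(r[d > 0])
  exact <- switch(method, auto = n <= exactLimit, exact = TRUE,
                  approximate = FALSE)
  if (exact) {
    r2 <- as.integer(round(2 * r))
    total <- sum(r2)
    # counts[s + 1] = number of sign assignments with doubled rank sum s
    counts <- numeric(total + 1L)
    counts[1L] <- 1
    for (rr in r2) {
      shifted <- c(numeric(rr), counts[seq_len(total + 1L - rr)])
      counts <- counts + shifted
    }
    w2 <- as.integer(round(2 * W))
    lower <- sum(counts[seq_len(w2 + 1L)]) / 2^n
    upper <- sum(counts[(w2 + 1L):(total + 1L)]) / 2^n
    p <- .twoTailed(lower, upper)
    meth <- "exact"
  } else {
    mu <- n * (n + 1) / 4
    ties <- table(r)
    s2 <- n * (n + 1) * (2 * n + 1) / 24 - sum(ties^3 - ties) / 48
    z <- (W - mu - sign(W - mu) * 0.5) / sqrt(s2)
    if (W == mu) z <- 0
    p <- min(1, 2 * pnorm(-abs(z)))
    meth <- "normal approximation"
  }
  structure(list(statistic = c(W = W), p.value = p,
                 parameter = c(n_effective = n, n_zero_dropped = nZero),
                 method = paste("Wilcoxon signed-rank test,", meth),
                 data.name = deparse(substitute(diffs))),
            class = "htest")
}

#' Mann-Whitney U test for two independent samples
#'
#' Mid-ranks the pooled sample, computes `U1 = R1 - n1 (n1 + 1) / 2` for the
#' first sample, and returns a two-tailed p: exact over all group labelings
#' when `n1 + n2 <= exactLimit`, otherwise a normal approximation with
#' continuity and tie corrections.
#'
#' @param x,y Non-empty numeric samples.
#' @param exactLimit Largest pooled size for the exact path (default 20).
#' @param method `"auto"`, `"exact"` or `"approximate"`.
#' @return An object of class `htest` with `statistic` (U of the first
#'   sample), `p.value`, sample sizes in `parameter`, and `method`.
#' @examples
#' mannWhitneyU(c(1, 2), c(3, 4))$p.value  # 1/3
#' @export
mannWhitneyU <- function(x, y, exactLimit = 20L,
                         method = c("auto", "exact", "approximate")) {
  method <- match.arg(method)
  if (length(x) == 0L || length(y) == 0L)
    stop("both samples must be non-empty", call. = FALSE)
  stopifnot(all(is.finite(x)), all(is.finite(y)))
  n1 <- length(x); n2 <- length(y); N <- n1 + n2
  r <- rank(c(x, y))
  R1 <- sum(r[seq_len(n1)])
  U1 <- R1 - n1 * (n1 + 1) / 2
  exact <- switch(method, auto = N <= exactLimit, exact = TRUE,
                  approximate = FALSE)
  if (exact) {
    r2 <- as.integer(round(2 * r))
    total <- sum(r2)
    # dist[[k + 1]][s + 1] = number of k-subsets of the ranks with doubled
    # rank sum s (without replacement).
    dist <- vector("list", n1 + 1L)
    dist[[1L]] <- c(1, numeric(total))
    for (k in seq_len(n1)) dist[[k + 1L]] <- numeric(total + 1L)
    for (rr in r2) {
      for (k in rev(seq_len(n1))) {
        prev <- dist[[k]]
        dist[[k + 1L]] <- dist[[k + 1L]] +
          c(numeric(rr), prev[seq_len(total + 1L - rr)])
      }
    }
    counts <- dist[[n1 + 1L]]
    nTot <- choose(N, n1)
    s2stat <- as.integer(round(2 * R1))
    lower <- sum(counts[seq_len(s2stat + 1L)]) / nTot
    upper <- sum(counts[(s2stat + 1L):(total + 1L)]) / nTot
    p <- .twoTailed(lower, upper)
    meth <- "exact"
  } else {
    mu <- n1 * n2 / 2
    ties <- table(r)
    s2 <- n1 * n2 / 12 * ((N + 1) - sum(ties^3 - ties) / (N * (N - 1)))
    z <- (U1 - mu - sign(U1 - mu) * 0.5) / sqrt(s2)
    if (U1 == mu) z <- 0
    p <- min(1, 2 * pnorm(-abs(z)))
    meth <- "normal approximation"
  }
  structure(list(statistic = c(U = U1), p.value = p,
                 parameter = c(n_x = n1, n_y = n2),
                 method = paste("Mann-Whitney U test,", meth),
                 data.name = paste(deparse(substitute(x)), "and",
                                   deparse(substitute(y)))),
            class = "htest")
}
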