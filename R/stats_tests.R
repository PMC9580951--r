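# Native implementations of the statistical machinery the analyses rely
# on; base R's wilcox.test / chisq.test / phyper / p.adjust serve as
# independent cross-checks in the test suite, never as the implementation.

test_result <- function(statistic, p_value, method, n) {
  stopifnot(is.finite(statistic), p_value >= 0, p_value <= 1)
  structure(list(statistic = statistic, p_value = p_value,
                 method = method, n = n),
            class = "test_result")
}

#' @export
print.test_result <- function(x, ...) {
  cat(sprintf("<test_result> %s: statistic = %.6g, p = %.4g (n = %s)\n",
              x$method, x$statistic, x$p_value,
              paste(x$n, collapse = "/")))
  invisible(x)
}

#' Two-sided Wilcoxon rank-sum test
#'
#' Exact permutation p-value (full enumeration of group assignments)
#' when the combined sample size is at most 12 and there are no ties;
#' otherwise the normal approximation with mid-ranks, tie-corrected
#' variance and continuity correction. The statistic is the
#' Mann-Whitney U of the first sample.
#'
#' @param x,y numeric samples (non-empty).
#' @return a `test_result` (`statistic` = U, two-sided `p_value`,
#'   `n` = c(nx, ny)).
#' @export
wilcoxon_rank_sum <- function(x, y) {
  x <- as.numeric(x); y <- as.numeric(y)
  if (!length(x) || !length(y))
    stop("both samples must be non-empty", call. = FALSE)
  if (anyNA(x) || anyNA(y)) stop("samples must not contain NA",
                                 call. = FALSE)
  nx <- length(x); ny <- length(y); n <- nx + ny
  comb <- c(x, y)
  r <- rank(comb)
  u <- sum(r[seq_len(nx)]) - nx * (nx + 1) / 2
  ties <- table(comb)
  exact <- n <= 12L && all(ties == 1L)
  mu <- nx * ny / 2
  if (exact) {
    # enumerate all choose(n, nx) group assignments
    dev_obs <- abs(u - mu)
    assigns <- utils::combn(n, nx)
    hits <- 0L
    for (j in seq_len(ncol(assigns))) {
      uj <- sum(r[assigns[, j]]) - nx * (nx + 1) / 2
      if (abs(uj - mu) >= dev_obs - 1e-12) hits <- hits + 1L
    }
    p <- hits / ncol(assigns)
    method <- "wilcoxon_exact"
  } else {
    tie_term <- sum(ties^3 - ties)
    sigma2 <- nx * ny / 12 * ((n + 1) - tie_term / (n * (n - 1)))
    if (sigma2 <= 0) {
      p <- 1
    } else {
      z <- u - mu
      z <- z - sign(z) * 0.5  # continuity correction
      z <- z / sqrt(sigma2)
      p <- min(1, 2 * stats::pnorm(-abs(z)))
    }
    method <- "wilcoxon_normal_approx"
  }
  test_result(u, p, method, c(nx, ny))
}

#' Pearson chi-square test on a 2x2 table
#'
#' Statistic n(ad - bc)^2 / ((a+b)(c+d)(a+c)(b+d)) with 1 degree of
#' freedom; no continuity correction by default (Yates available by
#' flag). A table with an empty margin raises a typed
#' `brdnet_degenerate_table` condition rather than returning NaN.
#'
#' @param table 2x2 matrix of non-negative counts.
#' @param yates apply Yates' continuity correction?
#' @return a `test_result`.
#' @export
chi_square_2x2 <- function(table, yates = FALSE) {
  if (!is.matrix(table) || !all(dim(table) == c(2L, 2L)) ||
      any(table < 0))
    stop("table must be a 2x2 matrix of non-negative counts",
         call. = FALSE)
  a <- table[1, 1]; b <- table[1, 2]; c <- table[2, 1]; d <- table[2, 2]
  n <- a + b + c + d
  margins <- c(a + b, c + d, a + c, b + d)
  if (any(margins == 0)) {
    cond <- structure(
      class = c("brdnet_degenerate_table", "error", "condition"),
      list(message = "degenerate 2x2 table: empty margin",
           call = sys.call(-1)))
    stop(cond)
  }
  num <- abs(a * d - b * c)
  if (yates) num <- max(0, num - n / 2)
  stat <- n * num^2 / prod(margins)
  test_result(stat, stats::pchisq(stat, df = 1, lower.tail = FALSE),
              if (yates) "chi_square_yates" else "chi_square", n)
}

#' Hypergeometric upper-tail probability
#'
#' P(X >= k) where X counts successes in `n` draws without replacement
#' from a population of size `N` containing `K` successes. Computed as a
#' log-space sum of the PMF, stable for populations of ~2e4 genes. This
#' is the over-representation p-value of gene-set enrichment.
#'
#' @param N population (background) size.
#' @param K number of successes in the population (gene-set size).
#' @param n number of draws (signature size).
#' @param k observed overlap.
#' @return the upper-tail probability.
#' @export
hypergeometric_tail <- function(N, K, n, k) {
  vals <- c(N = N, K = K, n = n, k = k)
  if (any(vals != round(vals)) || any(vals < 0))
    stop("all arguments must be non-negative integers", call. = FALSE)
  if (K > N || n > N || k > min(K, n))
    stop("violated bounds: need K <= N, n <= N, k <= min(K, n)",
         call. = FALSE)
  if (k == 0) return(1)
  i <- k:min(K, n)
  logs <- lchoose(K, i) + lchoose(N - K, n - i) - lchoose(N, n)
  mx <- max(logs)
  min(1, exp(mx + log(sum(exp(logs - mx)))))
}

#' Benjamini-Hochberg q-values
#'
#' Step-up false-discovery-rate adjustment: q_(i) = min_{j >= i}
#' m p_(j) / j, clipped to [0,1], returned in the input order.
#'
#' @param p_values numeric vector of p-values in [0,1].
#' @return numeric vector of q-values, same length and order.
#' @export
benjamini_hochberg <- function(p_values) {
  p <- as.numeric(p_values)
  if (!length(p)) return(numeric(0))
  if (anyNA(p) || any(p < 0 | p > 1))
    stop("p-values must lie in [0,1]", call. = FALSE)
  m <- length(p)
  ord <- order(p)
  q_sorted <- pmin(1, cummin(rev(m * p[ord] / seq_len(m)))[m:1])
  q <- numeric(m)
  q[ord] <- q_sorted
  q
}
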