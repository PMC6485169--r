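#' Head-to-head 2x2 contingency table
#'
#' Builds the win/loss table feeding the exact tests: over paired per-target
#' values of two algorithms, a target counts as a success for an algorithm
#' iff its value is strictly better or tied (ties credit both sides, so the
#' success columns can sum to more than the number of targets).
#'
#' @param values1,values2 equal-length paired per-target metric values.
#' @param better `"lower"` (energies, lRMSD) or `"higher"` (TM, GDT).
#' @return 2x2 integer matrix of class `contingency_table`:
#'   rows = algorithms, columns = successes/failures.
#' @examples
#' head_to_head(c(1, 2, 3), c(2, 3, 4), better = "lower")
#' @export
head_to_head <- function(values1, values2, better = c("lower", "higher")) {
  better <- match.arg(better)
  if (length(values1) != length(values2))
    stop("paired value lists differ in length")
  if (better == "higher") {
    values1 <- -values1
    values2 <- -values2
  }
  a <- sum(values1 <= values2)
  c_ <- sum(values2 <= values1)
  n <- length(values1)
  contingency_table(a, n - a, c_, n - c_)
}

#' Construct / validate a 2x2 contingency table
#'
#' @param a,b successes and failures of algorithm 1.
#' @param c,d successes and failures of algorithm 2.
#' @return 2x2 integer matrix of class `contingency_table`.
#' @export
contingency_table <- function(a, b, c, d) {
  x <- c(a, b, c, d)
  if (any(x < 0) || any(x != round(x)))
    stop("counts must be non-negative integers")
  if (a + b != c + d)
    stop("rows must have equal totals (same number of targets)")
  structure(matrix(as.integer(x), 2, 2, byrow = TRUE,
                   dimnames = list(c("alg1", "alg2"),
                                   c("success", "failure"))),
            class = c("contingency_table", "matrix"))
}

as_table <- function(tab) {
  if (inherits(tab, "contingency_table")) return(tab)
  m <- as.matrix(tab)
  if (!all(dim(m) == c(2, 2))) stop("need a 2x2 table")
  contingency_table(m[1, 1], m[1, 2], m[2, 1], m[2, 2])
}

#' One-sided Fisher exact test
#'
#' Conditional exact test that algorithm 1's success rate exceeds algorithm
#' 2's: the hypergeometric upper tail P(X >= a) with all margins fixed,
#' computed with stable log-space tail sums.
#'
#' @param tab a 2x2 table (`contingency_table` or matrix
#'   `rbind(c(a, b), c(c, d))`).
#' @return p-value.
#' @examples
#' fisher_one_sided(rbind(c(8, 2), c(2, 8)))  # 2126/184756
#' @export
fisher_one_sided <- function(tab) {
  tab <- as_table(tab)
  a <- tab[1, 1]; b <- tab[1, 2]; c_ <- tab[2, 1]; d <- tab[2, 2]
  # X ~ Hypergeometric(row1 total draws from a+c successes in n)
  stats::phyper(a - 1, a + c_, b + d, a + b, lower.tail = FALSE)
}

#' Two-sided Fisher exact test (doubling convention)
#'
#' `min(1, 2 * one-sided p)` -- the doubling convention for two-sided exact
#' tests on 2x2 tables.
#'
#' @inheritParams fisher_one_sided
#' @return p-value.
#' @export
fisher_two_sided <- function(tab) {
  min(1, 2 * fisher_one_sided(tab))
}

# Wald statistic with pooled variance for all outcomes (x1, x2) of two
# binomials with n1 and n2 trials; 0/0 (pooled rate 0 or 1) is defined as 0.
wald_pooled <- function(n1, n2) {
  x1 <- matrix(0:n1, n1 + 1, n2 + 1)
  x2 <- matrix(0:n2, n1 + 1, n2 + 1, byrow = TRUE)
  p1 <- x1 / n1
  p2 <- x2 / n2
  pp <- (x1 + x2) / (n1 + n2)
  den <- sqrt(pp * (1 - pp) * (1 / n1 + 1 / n2))
  t <- (p1 - p2) / den
  t[den == 0] <- 0
  t
}

#' One-sided Barnard exact test
#'
#' Unconditional exact test that algorithm 1's success rate exceeds
#' algorithm 2's. Rows are treated as independent binomials; the p-value is
#' the maximum over the nuisance success probability pi of the probability
#' of outcomes whose Wald statistic (pooled variance) reaches the observed
#' one. Outcomes tied with the observed statistic are included (a relative
#' tolerance guards against floating-point ties). The nuisance maximization
#' scans a grid and refines the best point by local univariate
#' optimization, both restricted to `[grid, 1 - grid]`; the open-interval
#' supremum for degenerate tables is attained at the boundary, so the clamp
#' is part of the test's definition here.
#'
#' @inheritParams fisher_one_sided
#' @param grid nuisance grid resolution (and domain clamp).
#' @return p-value.
#' @examples
#' barnard_one_sided(rbind(c(6, 4), c(5, 5)))
#' @export
barnard_one_sided <- function(tab, grid = 1e-4) {
  tab <- as_table(tab)
  if (grid <= 0) stop("grid resolution must be positive")
  n1 <- sum(tab[1, ]); n2 <- sum(tab[2, ])
  t <- wald_pooled(n1, n2)
  t_obs <- t[tab[1, 1] + 1, tab[2, 1] + 1]
  sel <- which(t >= t_obs - 1e-7 * max(1, abs(t_obs)), arr.ind = TRUE)
  x1 <- sel[, 1] - 1
  x2 <- sel[, 2] - 1
  tail_prob <- function(pi)
    sum(exp(stats::dbinom(x1, n1, pi, log = TRUE) +
            stats::dbinom(x2, n2, pi, log = TRUE)))
  pis <- seq(grid, 1 - grid, by = grid)
  vals <- vapply(pis, tail_prob, numeric(1))
  i <- which.max(vals)
  lo <- max(grid, pis[i] - grid)
  hi <- min(1 - grid, pis[i] + grid)
  opt <- stats::optimize(tail_prob, c(lo, hi), maximum = TRUE)
  min(1, max(vals[i], opt$objective))
}

#' @export
print.contingency_table <- function(x, ...) {
  cat("<contingency_table> (", sum(x[1, ]), "targets )\n")
  print(unclass(x))
  cat("Fisher one-sided:", format(fisher_one_sided(x), digits = 4),
      " two-sided:", format(fisher_two_sided(x), digits = 4), "\n")
  invisible(x)
}
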