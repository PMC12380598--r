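#' Two-sided Fisher's exact test for a 2x2 table
#'
#' Conditional exact test on a 2x2 contingency table (rows = carrier /
#' non-carrier, columns = the two response groups). The two-sided p-value is
#' the sum of hypergeometric probabilities of all tables with the observed
#' margins whose probability does not exceed that of the observed table.
#'
#' @param table 2x2 integer matrix, or the four counts \code{a, b, c, d}
#'   given positionally (row-wise).
#' @param a,b,c,d Counts when \code{table} is not a matrix.
#' @param alternative \code{"two.sided"} (default), \code{"less"} or
#'   \code{"greater"} (one-sided on the odds ratio).
#' @return The p-value.
#' @examples
#' fisherExact2x2(matrix(c(5, 0, 0, 5), 2, byrow = TRUE))
#' fisherExact2x2(a = 10, b = 1, c = 40, d = 99)
#' @export
fisherExact2x2 <- function(table = NULL, a, b, c, d,
                           alternative = "two.sided") {
  alternative <- match.arg(alternative,
                           base::c("two.sided", "less", "greater"))
  if (is.null(table))
    table <- matrix(base::c(a, b, c, d), 2L, 2L, byrow = TRUE)
  table <- as.matrix(table)
  if (!identical(dim(table), base::c(2L, 2L))) stop("need a 2x2 table")
  if (any(table < 0) || any(table != round(table)))
    stop("counts must be non-negative integers")
  if (sum(table) == 0) stop("table total must be positive")
  min(1, stats::fisher.test(table, alternative = alternative)$p.value)
}

#' Rank-sum (Wilcoxon/Mann-Whitney) test with exact tied enumeration
#'
#' Two-sample location test on mid-ranks. When the total sample size is at
#' most \code{exact_cap}, the null distribution of the rank-sum statistic is
#' obtained by complete enumeration of all group assignments (valid under
#' ties, where the classical exact distribution does not apply); the
#' two-sided p-value counts assignments whose rank sum deviates from its
#' enumeration mean by at least the observed deviation. Above the cap a
#' normal approximation with mid-rank tie correction is used.
#'
#' @param x,y Numeric vectors (each non-empty).
#' @param exact_cap Maximum total size for exact enumeration (default 12).
#' @param mode \code{"auto"} (cap-based), \code{"exact"} or
#'   \code{"normal_approx"}.
#' @return List with \code{statistic} (rank sum of \code{x} on mid-ranks),
#'   \code{p.value} and \code{method}.
#' @examples
#' rankSumTest(c(1, 2, 3), c(4, 5, 6))$p.value  # 2/20
#' @export
rankSumTest <- function(x, y, exact_cap = 12L,
                        mode = c("auto", "exact", "normal_approx")) {
  mode <- match.arg(mode)
  x <- as.numeric(x); y <- as.numeric(y)
  if (!length(x) || !length(y)) stop("both groups must be non-empty")
  n1 <- length(x); n <- n1 + length(y)
  r <- rank(c(x, y))
  w <- sum(r[seq_len(n1)])
  use_exact <- switch(mode, auto = n <= exact_cap, exact = TRUE, normal_approx = FALSE)
  if (use_exact) {
    idx <- combn(n, n1)
    sums <- colSums(matrix(r[idx], nrow = n1))
    mu <- mean(sums)
    p <- mean(abs(sums - mu) >= abs(w - mu) - 1e-9)
    method <- "exact enumeration"
  } else {
    mu <- n1 * (n + 1) / 2
    ties <- table(r)
    sigma2 <- n1 * (n - n1) / 12 * ((n + 1) - sum(ties^3 - ties) / (n * (n - 1)))
    if (sigma2 <= 0) return(list(statistic = w, p.value = 1, method = "normal approximation"))
    z <- (w - mu) / sqrt(sigma2)
    p <- 2 * pnorm(-abs(z))
    method <- "normal approximation"
  }
  list(statistic = w, p.value = min(1, p), method = method)
}

#' Spearman rank correlation
#'
#' Correlation of mid-ranks with a two-sided p-value from the
#' t-approximation, \eqn{t = \rho \sqrt{(n-2)/(1-\rho^2)}} on \eqn{n-2}
#' degrees of freedom.
#'
#' @param x,y Numeric vectors of equal length >= 3; pairs with any NA are
#'   dropped.
#' @return List with \code{rho}, \code{p.value} and \code{n}.
#' @examples
#' spearmanCor(1:10, exp(1:10))$rho  # 1
#' @export
spearmanCor <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  keep <- !is.na(x) & !is.na(y)
  x <- x[keep]; y <- y[keep]
  n <- length(x)
  if (n < 3) stop("need at least 3 complete pairs")
  rx <- rank(x); ry <- rank(y)
  if (sd(rx) == 0 || sd(ry) == 0)
    stop("correlation undefined: a vector is constant after ranking")
  rho <- cor(rx, ry)
  if (1 - rho^2 < .Machine$double.eps) {
    p <- 0
  } else {
    tt <- rho * sqrt((n - 2) / (1 - rho^2))
    p <- 2 * pt(-abs(tt), df = n - 2)
  }
  list(rho = rho, p.value = p, n = n)
}

#' Benjamini-Hochberg false discovery rate
#'
#' Step-up adjusted p-values (q-values) controlling the FDR.
#'
#' @param p Numeric vector of p-values in (0, 1]; NA passed through.
#' @return Vector of q-values, same order as input.
#' @export
bhFDR <- function(p) {
  if (any(!is.na(p) & (p <= 0 | p > 1))) stop("p-values must lie in (0, 1]")
  p.adjust(p, method = "BH")
}

#' Empirical p-value with add-one smoothing
#'
#' Permutation/randomization p-value \eqn{(1 + k) / (B + 1)} where \eqn{k}
#' counts null statistics at least as extreme as the observed one. Never
#' returns 0; the best attainable value is \eqn{1/(B+1)}.
#'
#' @param observed Observed statistic (finite scalar).
#' @param null_stats Numeric vector of \eqn{B >= 1} null statistics.
#' @param direction \code{"ge"}: extreme = null >= observed (large statistics
#'   are extreme); \code{"le"}: null <= observed (e.g. when the statistic is
#'   itself a p-value); \code{"two_sided"}: |null| >= |observed| (signed
#'   statistics centred at 0).
#' @return The empirical p-value.
#' @examples
#' empiricalP(10, rnorm(999), "ge")  # 1/1000 when observed exceeds all nulls
#' @export
empiricalP <- function(observed, null_stats, direction = c("ge", "le", "two_sided")) {
  direction <- match.arg(direction)
  if (!is.finite(observed)) stop("observed statistic must be finite")
  if (!length(null_stats) || any(!is.finite(null_stats)))
    stop("null_stats must be a non-empty finite vector")
  k <- switch(direction,
    ge = sum(null_stats >= observed),
    le = sum(null_stats <= observed),
    two_sided = sum(abs(null_stats) >= abs(observed))
  )
  (1 + k) / (length(null_stats) + 1)
}

#' Default significance thresholds
#'
#' Significance conventions used across the analyses: 0.1 for DNA-level
#' alteration tests (mutation and CNV prevalence) and 0.05 for RNA-level
#' tests (gene-set scores, copy-number/expression testing).
#'
#' @return Named list with elements \code{dna} and \code{rna}.
#' @export
significanceThresholds <- function() list(dna = 0.1, rna = 0.05)
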