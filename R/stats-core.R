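# Self-contained nonparametric statistics: exact/approximate Mann-Whitney,
# Fisher's exact 2x2, two-sample Kolmogorov-Smirnov, Benjamini-Hochberg FDR.
# Implemented from first principles; base R supplies only distribution
# primitives (dhyper, pnorm). Used by every analysis module.

new_test_result <- function(statistic, p_value, method, n_a, n_b, extra = list()) {
  stopifnot(p_value > 0, p_value <= 1)
  structure(c(list(statistic = statistic, p_value = p_value,
                   method = method, n_a = n_a, n_b = n_b), extra),
            class = "ct_test_result")
}

#' @export
print.ct_test_result <- function(x, ...) {
  cat(sprintf("test result: statistic=%.6g p=%.4g method=%s (n_a=%d, n_b=%d)\n",
              x$statistic, x$p_value, x$method, x$n_a, x$n_b))
  invisible(x)
}

# U statistic for sample a against b: number of (a_i, b_j) pairs with
# a_i > b_j, counting ties as 1/2.
.mwu_u <- function(a, b) {
  r <- rank(c(a, b))
  sum(r[seq_along(a)]) - length(a) * (length(a) + 1) / 2
}

#' Mann-Whitney U test (Wilcoxon rank-sum)
#'
#' Two-sided Mann-Whitney U test. When both group sizes are at most
#' `exact_limit` the p-value is exact, obtained by enumerating all
#' `choose(n_a + n_b, n_a)` assignments of the pooled observed values to the
#' two groups (a permutation-exact computation, hence valid under ties).
#' Otherwise the normal approximation with tie-corrected variance and a
#' continuity correction of 1/2 is used. The two-sided p-value is
#' `min(1, 2 * min(P(U <= u), P(U >= u)))`.
#'
#' @param a,b Numeric vectors (non-empty).
#' @param exact_limit Largest per-group size for which full enumeration is
#'   attempted (default 8; `choose(16, 8)` = 12870 assignments).
#' @return A `ct_test_result` with `statistic` = U for `a` versus `b`.
#' @examples
#' mann_whitney_u(c(1, 2), c(3, 4))   # U = 0, exact p = 1/3
#' @export
mann_whitney_u <- function(a, b, exact_limit = 8) {
  a <- as.numeric(a); b <- as.numeric(b)
  if (length(a) == 0L || length(b) == 0L)
    stop("mann_whitney_u: empty sample")
  if (anyNA(a) || anyNA(b)) stop("mann_whitney_u: NA in input")
  na <- length(a); nb <- length(b)
  u_obs <- .mwu_u(a, b)
  if (na <= exact_limit && nb <= exact_limit) {
    pooled <- c(a, b)
    idx <- utils::combn(na + nb, na)
    us <- apply(idx, 2L, function(ix) .mwu_u(pooled[ix], pooled[-ix]))
    eps <- 1e-9
    p_low <- mean(us <= u_obs + eps)
    p_high <- mean(us >= u_obs - eps)
    p <- min(1, 2 * min(p_low, p_high))
    return(new_test_result(u_obs, p, "exact", na, nb))
  }
  # normal approximation, tie-corrected variance, continuity correction
  n <- na + nb
  pooled <- c(a, b)
  tie_tab <- table(pooled)
  tie_term <- sum(tie_tab^3 - tie_tab) / (n * (n - 1))
  mu <- na * nb / 2
  sigma2 <- na * nb / 12 * ((n + 1) - tie_term)
  if (sigma2 <= 0) {                       # every value tied
    return(new_test_result(u_obs, 1, "normal_approx", na, nb))
  }
  z <- (abs(u_obs - mu) - 0.5) / sqrt(sigma2)
  z <- max(z, 0)
  p <- min(1, 2 * pnorm(z, lower.tail = FALSE))
  p <- max(p, .Machine$double.xmin)
  new_test_result(u_obs, p, "normal_approx", na, nb)
}

#' Fisher's exact test for a 2x2 table
#'
#' Two-sided p-value by summing hypergeometric probabilities of all tables
#' (with the observed margins) whose probability does not exceed the observed
#' table's. The reported odds ratio is the conditional maximum-likelihood
#' estimate under the noncentral hypergeometric distribution.
#'
#' @param table 2x2 matrix (or length-4 vector, row-major) of non-negative
#'   integer counts.
#' @return A `ct_test_result`; `statistic` is the cMLE odds ratio, and the
#'   raw table is carried in `$table`.
#' @export
fisher_exact_2x2 <- function(table) {
  x <- matrix(as.numeric(table), nrow = 2, byrow = !is.matrix(table))
  if (any(x < 0) || any(x != round(x))) stop("fisher_exact_2x2: cells must be non-negative integers")
  a <- x[1, 1]
  m <- x[1, 1] + x[2, 1]     # first-column margin
  n <- x[1, 2] + x[2, 2]
  k <- x[1, 1] + x[1, 2]     # first-row margin
  lo <- max(0, k - n); hi <- min(k, m)
  if (lo == hi) {            # degenerate margin: single possible table
    return(new_test_result(1, 1, "exact", sum(x[1, ]), sum(x[2, ]),
                           extra = list(table = x, note = "zero-margin table")))
  }
  support <- lo:hi
  dens <- dhyper(support, m, n, k)
  p <- sum(dens[dens <= dens[support == a] * (1 + 1e-7)])
  p <- min(1, max(p, .Machine$double.xmin))
  or <- .fisher_or_cmle(a, m, n, k, support, lo, hi)
  new_test_result(or, p, "exact", sum(x[1, ]), sum(x[2, ]),
                  extra = list(table = x, odds_ratio = or))
}

# conditional MLE of the odds ratio: maximize noncentral hypergeometric
# likelihood in psi; mean of the noncentral distribution equals `a` at the MLE.
.fisher_or_cmle <- function(a, m, n, k, support, lo, hi) {
  if (a == lo) return(0)
  if (a == hi) return(Inf)
  ncmean <- function(psi) {
    logw <- dhyper(support, m, n, k, log = TRUE) + support * log(psi)
    logw <- logw - max(logw)
    w <- exp(logw)
    sum(support * w) / sum(w)
  }
  f <- function(lp) ncmean(exp(lp)) - a
  lim <- 50
  root <- uniroot(f, lower = -lim, upper = lim, tol = 1e-9)
  exp(root$root)
}

#' Two-sample Kolmogorov-Smirnov test
#'
#' D is the supremum absolute difference of the two empirical CDFs; the
#' two-sided p-value uses the asymptotic Kolmogorov distribution evaluated at
#' `sqrt(n_eff) * D` with effective size `n_a * n_b / (n_a + n_b)`.
#'
#' @param a,b Numeric vectors.
#' @return A `ct_test_result` with `statistic` = D.
#' @export
ks_two_sample <- function(a, b) {
  a <- sort(as.numeric(a)); b <- sort(as.numeric(b))
  na <- length(a); nb <- length(b)
  if (na < 1L || nb < 1L) stop("ks_two_sample: empty sample")
  pooled <- sort(unique(c(a, b)))
  ecdf_at <- function(s, x) findInterval(x, s) / length(s)
  d <- max(abs(ecdf_at(a, pooled) - ecdf_at(b, pooled)))
  ne <- na * nb / (na + nb)
  lambda <- sqrt(ne) * d
  p <- .kolmogorov_sf(lambda)
  p <- min(1, max(p, .Machine$double.xmin))
  new_test_result(d, p, "normal_approx", na, nb)
}

# survival function of the Kolmogorov distribution
.kolmogorov_sf <- function(lambda) {
  if (lambda <= 0) return(1)
  k <- 1:100
  s <- 2 * sum((-1)^(k - 1) * exp(-2 * k^2 * lambda^2))
  min(1, max(s, 0))
}

#' Benjamini-Hochberg step-up q-values
#'
#' `q_i = min_{j >= rank(i)} ( m * p_(j) / j )`, clipped at 1. Order of the
#' input is preserved; NA p-values yield NA q-values and are excluded from m.
#'
#' @param pvalues Numeric vector of p-values in \[0, 1\].
#' @return Numeric vector of q-values, same length and order.
#' @export
bh_fdr <- function(pvalues) {
  p <- as.numeric(pvalues)
  ok <- !is.na(p)
  if (any(p[ok] < 0 | p[ok] > 1)) stop("bh_fdr: p-values must lie in [0, 1]")
  q <- rep(NA_real_, length(p))
  m <- sum(ok)
  if (m == 0L) return(q)
  ord <- order(p[ok])
  ps <- p[ok][ord]
  qs <- rev(cummin(rev(m * ps / seq_len(m))))
  qs <- pmin(qs, 1)
  qok <- numeric(m)
  qok[ord] <- qs
  q[ok] <- qok
  q
}
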