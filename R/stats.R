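#' Nonparametric and standardized-regression statistics
#'
#' The statistical battery used throughout the sector analysis, implemented
#' from definitions: Spearman rank correlation with mid-ranks, standardized
#' multiple regression, Steel-Dwass all-pairs comparison with studentized-range
#' adjustment, the Mann-Whitney U test (normal approximation and exact
#' enumeration), and the Fisher-z comparison of two correlation coefficients.
#'
#' @name stats-battery
NULL

#' Spearman rank correlation
#'
#' Pearson correlation of mid-ranks (average ranks for ties). The two-sided
#' p-value uses the large-sample t approximation with n - 2 degrees of
#' freedom.
#'
#' @param x,y Numeric vectors of equal length >= 3, finite values.
#' @return List of class `correlation_result`: `r`, `p`, `n`,
#'   `method = "spearman"`.
#' @export
spearman_cor <- function(x, y) {
  stopifnot(is.numeric(x), is.numeric(y))
  if (length(x) != length(y)) stop("length mismatch", call. = FALSE)
  keep <- is.finite(x) & is.finite(y)
  x <- x[keep]; y <- y[keep]
  n <- length(x)
  if (n < 3) stop("need at least 3 complete observations", call. = FALSE)
  rx <- rank(x); ry <- rank(y)
  if (stats::sd(rx) == 0 || stats::sd(ry) == 0) {
    stop("undefined correlation: zero variance in ranks", call. = FALSE)
  }
  r <- stats::cor(rx, ry)
  r <- max(-1, min(1, r))
  if (abs(r) == 1) {
    p <- 0
  } else {
    tstat <- r * sqrt((n - 2) / (1 - r^2))
    p <- 2 * stats::pt(-abs(tstat), df = n - 2)
  }
  structure(list(r = r, p = p, n = n, method = "spearman"),
            class = "correlation_result")
}

#' Standardized multiple regression
#'
#' Ordinary least squares on the z-scored outcome and z-scored predictors;
#' the coefficients are standardized betas and the p-values come from the
#' usual t statistics. No variable selection is performed: all predictors are
#' entered simultaneously.
#'
#' @param y Numeric outcome vector.
#' @param X Numeric matrix or data frame of predictors (columns named).
#' @return List of class `regression_result`: tibble `coefficients` with
#'   `predictor`, `beta`, `p`; plus `n` and `outcome` label.
#' @param outcome Optional outcome label carried into the result.
#' @export
regress_standardized <- function(y, X, outcome = "y") {
  X <- as.matrix(X)
  stopifnot(is.numeric(y), is.numeric(X), nrow(X) == length(y))
  keep <- is.finite(y) & apply(X, 1, function(r) all(is.finite(r)))
  y <- y[keep]; X <- X[keep, , drop = FALSE]
  n <- length(y)
  p <- ncol(X)
  if (n <= p + 1) stop("too few observations for the predictor count",
                       call. = FALSE)
  sds <- apply(X, 2, stats::sd)
  if (stats::sd(y) == 0 || any(sds == 0)) {
    stop("constant outcome or predictor column", call. = FALSE)
  }
  Z <- scale(X)
  if (qr(cbind(1, Z))$rank < p + 1) {
    stop("collinearity: predictor matrix is rank deficient", call. = FALSE)
  }
  zy <- as.numeric(scale(y))
  fit <- stats::lm(zy ~ Z)
  sm <- summary(fit)$coefficients
  idx <- seq_len(p) + 1
  coefs <- tibble::tibble(
    predictor = colnames(X) %||% paste0("x", seq_len(p)),
    beta = unname(sm[idx, "Estimate"]),
    p = unname(sm[idx, "Pr(>|t|)"])
  )
  structure(list(coefficients = coefs, n = n, outcome = outcome),
            class = "regression_result")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Steel-Dwass all-pairs comparison
#'
#' Nonparametric multiple comparison of all group pairs. For each unordered
#' pair the two groups are pooled, mid-ranks assigned, and the rank-sum of the
#' first group standardized with the tie-corrected variance; the adjusted
#' two-sided p-value is obtained from the studentized-range distribution with
#' `k` groups and infinite degrees of freedom via `t = sqrt(2) * |z|`.
#'
#' @param groups Named (or unnamed) list of >= 2 numeric vectors, each with
#'   >= 2 observations.
#' @return Tibble of class `all_pairs_result`: `group1`, `group2`,
#'   `statistic` (the standardized z) and `p` (adjusted), one row per
#'   unordered pair.
#' @export
steel_dwass <- function(groups) {
  stopifnot(is.list(groups), length(groups) >= 2)
  if (any(!vapply(groups, is.numeric, logical(1))) ||
      any(vapply(groups, length, integer(1)) < 2)) {
    stop("each group must be numeric with at least 2 observations",
         call. = FALSE)
  }
  k <- length(groups)
  nm <- names(groups) %||% paste0("g", seq_len(k))
  pairs <- utils::combn(k, 2)
  res <- vapply(seq_len(ncol(pairs)), function(col) {
    i <- pairs[1, col]; j <- pairs[2, col]
    z <- pairwise_ranksum_z(groups[[i]], groups[[j]], continuity = FALSE)
    p <- stats::ptukey(sqrt(2) * abs(z), nmeans = k, df = Inf,
                       lower.tail = FALSE)
    c(z, p)
  }, numeric(2))
  structure(
    tibble::tibble(group1 = nm[pairs[1, ]], group2 = nm[pairs[2, ]],
                   statistic = res[1, ], p = res[2, ]),
    class = c("all_pairs_result", class(tibble::tibble()))
  )
}

# Standardized Wilcoxon rank-sum z for two samples, mid-ranks, tie-corrected
# variance; optional continuity correction.
pairwise_ranksum_z <- function(a, b, continuity = FALSE) {
  m <- length(a); n <- length(b); N <- m + n
  r <- rank(c(a, b))
  Tsum <- sum(r[seq_len(m)])
  mu <- m * (N + 1) / 2
  ties <- table(c(a, b))
  tie_term <- sum(ties^3 - ties)
  v <- m * n / 12 * ((N + 1) - tie_term / (N * (N - 1)))
  if (v <= 0) return(0)
  d <- Tsum - mu
  if (continuity) d <- sign(d) * max(0, abs(d) - 0.5)
  d / sqrt(v)
}

#' Mann-Whitney U test (two-sided)
#'
#' The default normal approximation standardizes U with the tie-corrected
#' variance and a 0.5 continuity correction. `method = "exact"` enumerates all
#' `choose(m + n, m)` assignments of the pooled values (ties handled by
#' mid-rank U) and is available for small samples; `"auto"` picks the exact
#' method when the enumeration is at most `exact_limit` assignments.
#'
#' @param a,b Non-empty numeric vectors.
#' @param method `"normal"`, `"exact"` or `"auto"`.
#' @param correct Apply the continuity correction in the normal approximation.
#' @param exact_limit Maximum number of enumerated assignments for
#'   `method = "auto"`.
#' @return Two-sided p-value.
#' @export
mann_whitney <- function(a, b, method = c("normal", "exact", "auto"),
                         correct = TRUE, exact_limit = 20000) {
  method <- match.arg(method)
  stopifnot(is.numeric(a), is.numeric(b))
  a <- a[is.finite(a)]; b <- b[is.finite(b)]
  if (length(a) == 0 || length(b) == 0) {
    stop("both samples must be non-empty", call. = FALSE)
  }
  m <- length(a); n <- length(b); N <- m + n
  if (method == "auto") {
    method <- if (choose(N, m) <= exact_limit) "exact" else "normal"
  }
  if (method == "exact") {
    pooled <- c(a, b)
    r <- rank(pooled)
    u_of <- function(sel) sum(r[sel]) - m * (m + 1) / 2
    u_obs <- u_of(seq_len(m))
    sets <- utils::combn(N, m)
    u_all <- apply(sets, 2, u_of)
    center <- m * n / 2
    mean(abs(u_all - center) >= abs(u_obs - center) - 1e-9)
  } else {
    z <- pairwise_ranksum_z(a, b, continuity = correct)
    min(1, 2 * stats::pnorm(-abs(z)))
  }
}

#' Compare two independent correlation coefficients
#'
#' Fisher-z test: `z = (atanh(r1) - atanh(r2)) / sqrt(1/(n1-3) + 1/(n2-3))`,
#' two-sided p from the standard normal.
#'
#' @param r1,r2 Correlation coefficients, `|r| < 1`.
#' @param n1,n2 Sample sizes, each >= 4.
#' @return Two-sided p-value.
#' @examples
#' compare_correlations(0.8, 50, 0.0, 50)
#' @export
compare_correlations <- function(r1, n1, r2, n2) {
  stopifnot(n1 >= 4, n2 >= 4)
  if (abs(r1) >= 1 || abs(r2) >= 1) {
    stop("correlations must satisfy |r| < 1", call. = FALSE)
  }
  z <- (atanh(r1) - atanh(r2)) / sqrt(1 / (n1 - 3) + 1 / (n2 - 3))
  2 * stats::pnorm(-abs(z))
}
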