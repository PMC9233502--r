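# Nonparametric tests with exact small-sample branches. The exact branches
# enumerate the full permutation / sign-flip distribution; two-sided p-values
# double the smaller tail (capped at 1).

.enum_cache <- new.env(parent = emptyenv())

comb_matrix <- function(n, k) {
  key <- paste0("C", n, "_", k)
  if (is.null(.enum_cache[[key]]))
    .enum_cache[[key]] <- utils::combn(n, k)
  .enum_cache[[key]]
}

sign_matrix <- function(n) {
  key <- paste0("S", n)
  if (is.null(.enum_cache[[key]])) {
    m <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
    dimnames(m) <- NULL
    .enum_cache[[key]] <- m
  }
  .enum_cache[[key]]
}

two_sided_from_tails <- function(lower, upper) min(1, 2 * min(lower, upper))

new_test_result <- function(statistic, p_value, method, exact) {
  structure(list(statistic = statistic, p_value = p_value, method = method,
                 exact = exact), class = "dp_test")
}

#' @export
print.dp_test <- function(x, ...) {
  cat(sprintf("%s: statistic = %g, p = %.4g (%s)\n", x$method, x$statistic,
              x$p_value, if (x$exact) "exact" else "normal approximation"))
  invisible(x)
}

#' Mann-Whitney U test
#'
#' Rank-sum test for two unpaired samples, with midranks for ties. For
#' combined sample sizes up to `exact_max` the p-value is computed by full
#' enumeration of all group labelings; beyond that a normal approximation
#' with tie correction and continuity correction is used. Two-sided p by
#' doubling the smaller tail, capped at 1.
#'
#' @param x,y numeric samples.
#' @param exact_max largest `n1 + n2` for which the exact branch is used.
#' @return a `dp_test` with the U statistic (for `x`) and two-sided p.
#' @export
mann_whitney <- function(x, y, exact_max = 12L) {
  stopifnot(length(x) >= 1L, length(y) >= 1L)
  n1 <- length(x); n2 <- length(y); n <- n1 + n2
  pooled <- c(x, y)
  if (length(unique(pooled)) == 1L)
    return(new_test_result(n1 * n2 / 2, 1, "mann_whitney", n <= exact_max))
  r <- rank(pooled)
  u_obs <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  if (n <= exact_max) {
    cm <- comb_matrix(n, n1)
    r1 <- colSums(matrix(r[cm], nrow = n1))
    u_all <- r1 - n1 * (n1 + 1) / 2
    p <- two_sided_from_tails(mean(u_all <= u_obs + 1e-9),
                              mean(u_all >= u_obs - 1e-9))
    return(new_test_result(u_obs, p, "mann_whitney", TRUE))
  }
  mu <- n1 * n2 / 2
  ties <- table(pooled)
  tie_term <- sum(ties^3 - ties) / (n * (n - 1))
  sig <- sqrt(n1 * n2 / 12 * ((n + 1) - tie_term))
  z <- (u_obs - mu - sign(u_obs - mu) * 0.5) / sig
  new_test_result(u_obs, min(1, 2 * stats::pnorm(-abs(z))),
                  "mann_whitney", FALSE)
}

#' Wilcoxon matched-pairs signed-rank test
#'
#' Paired-sample signed-rank test. Zero differences are dropped (Wilcoxon's
#' original rule); ties among the absolute differences use midranks. For up
#' to `exact_max` nonzero pairs the p-value enumerates all sign patterns;
#' beyond that a normal approximation with tie correction is used.
#'
#' @param x,y paired numeric samples of equal length.
#' @param exact_max largest number of nonzero pairs for the exact branch.
#' @return a `dp_test` with the positive-rank-sum statistic W and two-sided
#'   p.
#' @export
wilcoxon_signed_rank <- function(x, y, exact_max = 12L) {
  stopifnot(length(x) == length(y))
  d <- x - y
  d <- d[d != 0]
  n <- length(d)
  if (n == 0L)
    return(new_test_result(0, 1, "wilcoxon_signed_rank", TRUE))
  r <- rank(abs(d))
  w_obs <- sum(r[d > 0])
  if (n <= exact_max) {
    sm <- sign_matrix(n)
    w_all <- as.numeric(sm %*% r)
    p <- two_sided_from_tails(mean(w_all <= w_obs + 1e-9),
                              mean(w_all >= w_obs - 1e-9))
    return(new_test_result(w_obs, p, "wilcoxon_signed_rank", TRUE))
  }
  mu <- n * (n + 1) / 4
  ties <- table(abs(d))
  sig <- sqrt(n * (n + 1) * (2 * n + 1) / 24 - sum(ties^3 - ties) / 48)
  z <- (w_obs - mu - sign(w_obs - mu) * 0.5) / sig
  new_test_result(w_obs, min(1, 2 * stats::pnorm(-abs(z))),
                  "wilcoxon_signed_rank", FALSE)
}

#' Paired t test
#'
#' Standard paired-sample t statistic with a two-sided p-value from the t
#' distribution on `n - 1` degrees of freedom.
#'
#' @param x,y paired numeric samples of equal length (>= 2), with nonzero
#'   difference variance.
#' @return a `dp_test` with the t statistic and two-sided p.
#' @export
paired_t <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 2L)
  d <- x - y
  sdd <- stats::sd(d)
  if (sdd == 0) stop("zero variance of paired differences")
  n <- length(d)
  tstat <- mean(d) / (sdd / sqrt(n))
  new_test_result(tstat, 2 * stats::pt(-abs(tstat), n - 1), "paired_t", TRUE)
}
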