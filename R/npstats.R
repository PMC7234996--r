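#' Midranks
#'
#' Ranks with tied values sharing the average of the ranks they span; ranks
#' always sum to `n (n + 1) / 2`.
#'
#' @param values numeric vector of finite values.
#' @return Numeric vector of midranks.
#' @examples
#' midranks(c(10, 20, 20, 30))
#' @export
midranks <- function(values) {
  if (length(values) < 1L) .fail("need at least one value")
  if (any(!is.finite(values))) .fail("non-finite value(s) in input")
  rank(values, ties.method = "average")
}

# Tie-corrected Kruskal-Wallis H for one response vector.
# g_idx: integer group index 1..k; ng: group sizes (precomputed).
.kw_h <- function(values, g_idx, ng, warn_degenerate = TRUE) {
  n <- length(values)
  r <- rank(values, ties.method = "average")
  rg <- vapply(split(r, g_idx), sum, 0)
  h <- 12 / (n * (n + 1)) * sum(rg^2 / ng) - 3 * (n + 1)
  if (anyDuplicated(values)) {
    t_g <- tabulate(match(values, values))
    t_g <- t_g[t_g > 1L]
    cc <- 1 - sum(t_g^3 - t_g) / (n^3 - n)
    if (cc == 0) {
      if (warn_degenerate)
        warning("all values identical; H defined as 0")
      return(0)
    }
    h <- h / cc
  }
  h
}

# match(values, values) marks each element's first occurrence; tabulate of
# that gives tie-group sizes.  Kept internal; exercised via kruskal_wallis.

#' Tie-corrected Kruskal-Wallis test
#'
#' Computes `H = [12 / (N (N + 1)) * sum_i R_i^2 / n_i - 3 (N + 1)] / C`
#' with tie correction `C = 1 - sum_g (t_g^3 - t_g) / (N^3 - N)`, and the
#' chi-square upper-tail p-value on `k - 1` degrees of freedom.  When every
#' value is identical (`C = 0`) the statistic is defined as 0 with a
#' warning: a constant response carries no evidence against the null.
#'
#' @param values numeric response vector.
#' @param groups group labels (factor or coercible), `k >= 2` levels each
#'   with at least one observation; total `N >= 3`.
#' @return An object of class `"kw_result"`: list with `H`, `k`,
#'   `n_per_group`, `chisq_p`.
#' @examples
#' kruskal_wallis(c(1, 2, 3, 4, 5, 6), rep(c("a", "b"), each = 3))
#' @export
kruskal_wallis <- function(values, groups) {
  if (length(values) != length(groups))
    .fail("'values' and 'groups' must have the same length")
  if (anyNA(values) || anyNA(groups)) .fail("missing values not allowed")
  if (any(!is.finite(values))) .fail("non-finite value(s) in response")
  g <- if (is.factor(groups)) groups else factor(groups)
  ng <- tabulate(g, nlevels(g))
  if (nlevels(g) < 2L) .fail("need at least 2 groups")
  if (any(ng == 0L)) .fail("empty group(s): ",
                           paste(levels(g)[ng == 0L], collapse = ", "))
  if (length(values) < 3L) .fail("need at least 3 observations in total")
  h <- .kw_h(values, as.integer(g), ng)
  out <- list(H = h, k = nlevels(g),
              n_per_group = setNames(ng, levels(g)),
              chisq_p = pchisq(h, df = nlevels(g) - 1L, lower.tail = FALSE))
  class(out) <- "kw_result"
  out
}

#' @export
print.kw_result <- function(x, ...) {
  cat("Kruskal-Wallis (tie-corrected): H =", format(x$H, digits = 4),
      " k =", x$k, "\n  n =", paste(x$n_per_group, collapse = "/"),
      "  chi-square p =", format(x$chisq_p, digits = 4), "\n")
  invisible(x)
}

# Vectorized H over the columns of a tips x replicates matrix, fixed labels.
# The fast path used to turn simulated Brownian replicates into a null
# distribution of H.  Degenerate (all-tied) columns yield H = 0 silently.
.kw_h_columns <- function(x, groups) {
  g <- factor(groups)
  ng <- tabulate(g, nlevels(g))
  gi <- as.integer(g)
  vapply(seq_len(ncol(x)), function(j)
    .kw_h(x[, j], gi, ng, warn_degenerate = FALSE), 0)
}

#' Mann-Whitney U test
#'
#' Two-sided Wilcoxon rank-sum comparison.  The p-value is exact (full
#' enumeration of rank configurations, via the exact null distribution of
#' the statistic) when `n1 + n2 <= 12` and there are no ties; otherwise a
#' tie-adjusted normal approximation with continuity correction is used and
#' the two-sided p is `min(1, 2 * one-sided)`.  The reported `U` is
#' referenced to the smaller group (first group on a size tie), so
#' `0 <= U <= n1 * n2`.
#'
#' @param a,b numeric vectors, both non-empty.
#' @return An object of class `"mw_result"`: list with `U`, `p_two_sided`,
#'   `method` (`"exact"` or `"normal-approximation"`), `n1`, `n2`.
#' @examples
#' mann_whitney(c(1, 2, 3), c(4, 5, 6))   # U = 0, exact p = 0.1
#' @export
mann_whitney <- function(a, b) {
  if (!length(a) || !length(b)) .fail("both groups must be non-empty")
  if (any(!is.finite(c(a, b)))) .fail("non-finite value(s) in input")
  n1 <- length(a); n2 <- length(b)
  r <- rank(c(a, b), ties.method = "average")
  u1 <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  u <- if (n1 <= n2) u1 else n1 * n2 - u1
  exact <- (n1 + n2) <= 12L && !anyDuplicated(c(a, b))
  p <- suppressWarnings(
    wilcox.test(a, b, alternative = "two.sided", exact = exact,
                correct = TRUE)$p.value)
  # every value tied across both groups: zero-variance normal approximation
  # is indeterminate, and "no evidence of a difference" is the correct call
  if (!is.finite(p)) p <- 1
  out <- list(U = u, p_two_sided = min(1, p),
              method = if (exact) "exact" else "normal-approximation",
              n1 = n1, n2 = n2)
  class(out) <- "mw_result"
  out
}

#' @export
print.mw_result <- function(x, ...) {
  cat("Mann-Whitney: U =", x$U, " n =", x$n1, "vs", x$n2,
      "\n  two-sided p =", format(x$p_two_sided, digits = 4),
      paste0("(", x$method, ")"), "\n")
  invisible(x)
}

#' Nearest-rank empirical percentile
#'
#' The `m`-th smallest value with `m = ceiling(q / 100 * n)`.  No
#' interpolation: the definition is exact and reproducible for any `n`,
#' in particular the 95th percentile of a 1000-value empirical null is its
#' 950th order statistic.
#'
#' @param h_values numeric vector (e.g. simulated null H values), length
#'   `>= 20`.
#' @param q percentile in `(0, 100)`.
#' @return The threshold value.
#' @examples
#' empirical_percentile(1:1000, 95)   # 950
#' @export
empirical_percentile <- function(h_values, q = 95) {
  n <- length(h_values)
  if (n < 20L) .fail("need at least 20 values for an empirical percentile")
  if (!is.numeric(q) || length(q) != 1L || q <= 0 || q >= 100)
    .fail("'q' must lie strictly between 0 and 100")
  if (any(!is.finite(h_values))) .fail("non-finite value(s) in null")
  sort(h_values)[ceiling(q / 100 * n)]
}

#' Empirical p-value against a simulated null
#'
#' The add-one estimator `(1 + #\{h >= observed\}) / (1 + n)` never returns
#' 0 from a finite simulation; the raw proportion `#\{h >= observed\} / n`
#' is also available (both are reported in pipeline records, since either
#' convention is in use in the literature).
#'
#' @param h_values numeric vector of simulated null statistics.
#' @param observed observed statistic.
#' @param method `"add-one"` (default) or `"raw"`.
#' @return A p-value in `[0, 1]` (strictly positive for `"add-one"`).
#' @examples
#' empirical_p(c(5, 6, 7), 6)   # (1 + 2) / 4
#' @export
empirical_p <- function(h_values, observed, method = c("add-one", "raw")) {
  method <- match.arg(method)
  if (!length(h_values)) .fail("empty null")
  cnt <- sum(h_values >= observed)
  if (method == "add-one") (1 + cnt) / (1 + length(h_values))
  else cnt / length(h_values)
}
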