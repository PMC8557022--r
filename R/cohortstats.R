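# Cohort-table statistics: two-sample t-test from summary statistics,
# exact 2x2 Fisher test, and exact small-sample Mann-Whitney. These are the
# tests behind a typical case-control demographics table (mean +- SD rows,
# count rows, and skewed continuous rows respectively).

#' Two-sample t-test from summary statistics
#'
#' @param mean1,sd1,n1 Group 1 summary (n >= 2, sd >= 0).
#' @param mean2,sd2,n2 Group 2 summary.
#' @param variant `"student"` (pooled variance) or `"welch"`
#'   (Satterthwaite df).
#' @return A one-row tibble `t`, `df`, `p` (two-sided).
#' @export
ttest_from_summary <- function(mean1, sd1, n1, mean2, sd2, n2,
                               variant = c("student", "welch")) {
  variant <- match.arg(variant)
  stopifnot(n1 >= 2, n2 >= 2, sd1 >= 0, sd2 >= 0)
  if (sd1 == 0 && sd2 == 0) {
    if (isTRUE(all.equal(mean1, mean2))) {
      return(tibble(t = 0, df = NA_real_, p = 1))
    }
    abort("zero variance in both groups with unequal means",
          class = "degenerate_variance")
  }
  if (variant == "student") {
    sp2 <- ((n1 - 1) * sd1^2 + (n2 - 1) * sd2^2) / (n1 + n2 - 2)
    t <- (mean1 - mean2) / sqrt(sp2 * (1 / n1 + 1 / n2))
    df <- n1 + n2 - 2
  } else {
    v1 <- sd1^2 / n1; v2 <- sd2^2 / n2
    t <- (mean1 - mean2) / sqrt(v1 + v2)
    df <- (v1 + v2)^2 / (v1^2 / (n1 - 1) + v2^2 / (n2 - 1))
  }
  tibble(t = t, df = df, p = 2 * pt(-abs(t), df))
}

#' Exact two-sided Fisher test for a 2x2 table
#'
#' Two-sided p is the sum of hypergeometric probabilities of all tables
#' with the same margins whose point probability does not exceed that of
#' the observed table (with a `1 + 1e-7` relative tolerance), the
#' convention of `stats::fisher.test`.
#'
#' @param a,b,c,d Cell counts, row-wise: `(a, b)` / `(c, d)`.
#' @return A one-row tibble `p`.
#' @export
fisher_exact_2x2 <- function(a, b, c, d) {
  counts <- c(a, b, c, d)
  if (any(counts < 0) || any(counts != round(counts))) {
    abort("counts must be non-negative integers", class = "invalid_argument")
  }
  if (sum(counts) == 0) abort("at least one positive margin required",
                              class = "invalid_argument")
  tibble(p = fisher.test(matrix(counts, 2, 2, byrow = TRUE))$p.value)
}

#' Exact two-sided Mann-Whitney U test
#'
#' For combined sample sizes up to `max_exact` the p-value is exact,
#' enumerating all `choose(n1 + n2, n1)` group assignments (so ties are
#' handled exactly); larger samples use the normal approximation with tie
#' correction.
#'
#' @param x,y Numeric samples (non-empty).
#' @param max_exact Largest combined n for exact enumeration (default 20).
#' @return A one-row tibble `U`, `p`, `method`.
#' @export
mannwhitney_exact <- function(x, y, max_exact = 20) {
  if (!length(x) || !length(y)) abort("empty group",
                                      class = "invalid_argument")
  n1 <- length(x); n2 <- length(y)
  r <- rank(c(x, y))
  u_obs <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  u_stat <- min(u_obs, n1 * n2 - u_obs)
  if (n1 + n2 <= max_exact) {
    combined <- c(x, y)
    rr <- rank(combined)
    idx <- combn(n1 + n2, n1)
    us <- colSums(matrix(rr[idx], nrow = n1)) - n1 * (n1 + 1) / 2
    # two-sided: distance of U from its mean at least the observed distance
    mu <- n1 * n2 / 2
    p <- mean(abs(us - mu) >= abs(u_obs - mu) - 1e-9)
    method <- "exact"
  } else {
    mu <- n1 * n2 / 2
    nt <- table(r)
    tie_term <- sum(nt^3 - nt) / ((n1 + n2) * (n1 + n2 - 1))
    sigma <- sqrt(n1 * n2 / 12 * (n1 + n2 + 1 - tie_term))
    z <- (u_obs - mu) / sigma
    p <- min(1, 2 * stats::pnorm(-abs(z)))
    method <- "normal_approx"
  }
  tibble(U = u_stat, p = p, method = method)
}

#' Cohort comparison table
#'
#' Convenience wrapper producing a demographics-table row per variable:
#' numeric variables get the summary t-test (or exact Mann-Whitney when
#' `test = "mannwhitney"`), two-level categorical variables the exact
#' Fisher test.
#'
#' @param sheet Sample sheet with `group` plus the variables.
#' @param vars Character vector of column names to compare.
#' @param tests Optional named character vector overriding the per-variable
#'   test (`"ttest"`, `"mannwhitney"`, `"fisher"`).
#' @return A tibble, one row per variable, with group summaries, `test`,
#'   and `p`.
#' @export
cohort_table <- function(sheet, vars, tests = NULL) {
  check_sheet(sheet)
  purrr::map_dfr(vars, function(v) {
    x <- sheet[[v]][sheet$group == "case"]
    y <- sheet[[v]][sheet$group == "control"]
    test <- if (!is.null(tests) && v %in% names(tests)) tests[[v]]
            else if (is.numeric(sheet[[v]])) "ttest" else "fisher"
    if (test == "ttest") {
      p <- ttest_from_summary(mean(x), sd(x), length(x),
                              mean(y), sd(y), length(y))$p
      tibble(variable = v, test = "t-test",
             case_summary = sprintf("%.1f ± %.1f", mean(x), sd(x)),
             control_summary = sprintf("%.1f ± %.1f", mean(y), sd(y)),
             p = p)
    } else if (test == "mannwhitney") {
      tibble(variable = v, test = "Mann-Whitney",
             case_summary = sprintf("%.1f ± %.1f", mean(x), sd(x)),
             control_summary = sprintf("%.1f ± %.1f", mean(y), sd(y)),
             p = mannwhitney_exact(x, y)$p)
    } else {
      lv <- sort(unique(c(x, y)))
      if (length(lv) != 2) abort("fisher rows need exactly 2 levels")
      p <- fisher_exact_2x2(sum(x == lv[1]), sum(x == lv[2]),
                            sum(y == lv[1]), sum(y == lv[2]))$p
      tibble(variable = v, test = "Fisher",
             case_summary = sprintf("%d/%d", sum(x == lv[1]), length(x)),
             control_summary = sprintf("%d/%d", sum(y == lv[1]), length(y)),
             p = p)
    }
  })
}
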