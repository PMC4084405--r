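#' Coefficient of variation
#'
#' Sample standard deviation (n - 1 denominator) divided by the mean. This is
#' the dispersion metric used throughout the pipeline to quantify how much a
#' lesion un-masks hidden population variability in burst or flexion counts.
#'
#' @param x Numeric vector, length >= 2.
#' @return The coefficient of variation, a single number.
#' @examples
#' coef_variation(c(2, 4, 6))   # sd = 2, mean = 4 -> 0.5
#' @export
coef_variation <- function(x) {
  stopifnot(is.numeric(x))
  x <- x[is.finite(x)]
  if (length(x) < 2L) stop("coef_variation() needs at least 2 finite values")
  m <- mean(x)
  if (m == 0) stop("coef_variation() undefined for zero mean")
  stats::sd(x) / m
}

#' Brown-Forsythe (Levene median) test for equality of variances
#'
#' One-way ANOVA F test on absolute deviations from each group's median,
#' the robust form of Levene's test. Used to ask whether a lesioned cohort is
#' more variable than its sham/pre-lesion counterpart.
#'
#' @param group_a,group_b Numeric vectors, each of length >= 3.
#' @return A list with elements `statistic` (F), `p.value`, and `df`
#'   (numerator and denominator degrees of freedom).
#' @export
levene_median_test <- function(group_a, group_b) {
  stopifnot(is.numeric(group_a), is.numeric(group_b))
  if (length(group_a) < 3L || length(group_b) < 3L)
    stop("levene_median_test() needs n >= 3 per group")
  za <- abs(group_a - stats::median(group_a))
  zb <- abs(group_b - stats::median(group_b))
  if (all(za == 0) && all(zb == 0))
    return(list(statistic = 0, p.value = 1,
                df = c(1L, length(za) + length(zb) - 2L)))
  z <- c(za, zb)
  g <- factor(rep(c("a", "b"), c(length(za), length(zb))))
  fit <- stats::anova(stats::aov(z ~ g))
  list(statistic = unname(fit[["F value"]][1L]),
       p.value = unname(fit[["Pr(>F)"]][1L]),
       df = c(fit[["Df"]][1L], fit[["Df"]][2L]))
}

#' Ordinary least-squares regression of y on x
#'
#' Thin wrapper around [stats::lm()] returning the quantities the cohort
#' analyses report: slope, intercept, R-squared and the (two-tailed) p value
#' of the slope's F test.
#'
#' @param x,y Numeric vectors of equal length, n >= 3; `x` must vary.
#' @return A list with `slope`, `intercept`, `r.squared`, `p.value`, `n`.
#' @export
linear_regression <- function(x, y) {
  stopifnot(is.numeric(x), is.numeric(y), length(x) == length(y))
  keep <- is.finite(x) & is.finite(y)
  x <- x[keep]; y <- y[keep]
  if (length(x) < 3L) stop("linear_regression() needs n >= 3")
  if (stats::var(x) == 0) stop("linear_regression() needs var(x) > 0")
  fit <- stats::lm(y ~ x)
  sm <- summary(fit)
  pv <- if (sm$sigma == 0) 0 else {
    f <- sm$fstatistic
    unname(stats::pf(f[1L], f[2L], f[3L], lower.tail = FALSE))
  }
  list(slope = unname(stats::coef(fit)[2L]),
       intercept = unname(stats::coef(fit)[1L]),
       r.squared = sm$r.squared,
       p.value = pv,
       n = length(x))
}

#' Percent change between a paired before/after measurement
#'
#' @param before,after Numeric scalars (or equal-length vectors); `before`
#'   must be strictly positive.
#' @return `100 * (after - before) / before`. A 5-to-3 burst reduction gives
#'   -40; 6-to-5 gives -16.67.
#' @export
percent_change <- function(before, after) {
  stopifnot(is.numeric(before), is.numeric(after),
            length(before) == length(after))
  if (any(before <= 0)) stop("percent_change() needs before > 0")
  100 * (after - before) / before
}

#' Paired two-tailed t test
#'
#' @param a,b Numeric vectors of equal length (pairs).
#' @return A list with `t`, `p.value`, `df`, `mean.difference`.
#' @export
paired_t_test <- function(a, b) {
  stopifnot(is.numeric(a), is.numeric(b), length(a) == length(b))
  d <- a - b
  if (length(d) < 2L) stop("paired_t_test() needs at least 2 pairs")
  if (stats::var(d) == 0)
    stop("paired_t_test() undefined: zero variance of paired differences")
  ht <- stats::t.test(a, b, paired = TRUE)
  list(t = unname(ht$statistic), p.value = ht$p.value,
       df = unname(ht$parameter), mean.difference = mean(d))
}

#' One-way ANOVA with optional Holm-Sidak pairwise follow-up
#'
#' @param groups A named or unnamed list of numeric vectors (n >= 2 each).
#' @param pairwise If `TRUE`, also return all pairwise Welch-free (pooled-SD)
#'   t comparisons with Holm-Sidak adjusted p values.
#' @return A list with `F`, `p.value`, `df`, and (optionally) a data frame
#'   `pairwise` of comparisons.
#' @export
one_way_anova <- function(groups, pairwise = FALSE) {
  stopifnot(is.list(groups), length(groups) >= 2L)
  lens <- lengths(groups)
  if (any(lens < 2L)) stop("one_way_anova() needs n >= 2 per group")
  if (is.null(names(groups)) || any(names(groups) == ""))
    names(groups) <- paste0("g", seq_along(groups))
  y <- unlist(groups, use.names = FALSE)
  g <- factor(rep(names(groups), lens), levels = names(groups))
  fit <- stats::anova(stats::aov(y ~ g))
  out <- list(F = unname(fit[["F value"]][1L]),
              p.value = unname(fit[["Pr(>F)"]][1L]),
              df = c(fit[["Df"]][1L], fit[["Df"]][2L]))
  if (pairwise) {
    k <- length(groups)
    mse <- fit[["Mean Sq"]][2L]
    dfe <- fit[["Df"]][2L]
    cmb <- utils::combn(k, 2)
    pr <- apply(cmb, 2, function(ij) {
      i <- ij[1L]; j <- ij[2L]
      se <- sqrt(mse * (1 / lens[[i]] + 1 / lens[[j]]))
      tval <- unname((mean(groups[[i]]) - mean(groups[[j]])) / se)
      c(t = tval, p = 2 * stats::pt(abs(tval), dfe, lower.tail = FALSE))
    })
    m <- ncol(cmb)
    ord <- order(pr["p", ])
    padj <- numeric(m)
    # Holm-Sidak: step-down Sidak adjustment
    running <- 0
    for (r in seq_len(m)) {
      idx <- ord[r]
      adj <- 1 - (1 - pr["p", idx])^(m - r + 1)
      running <- max(running, adj)
      padj[idx] <- min(1, running)
    }
    out$pairwise <- data.frame(
      group1 = names(groups)[cmb[1L, ]],
      group2 = names(groups)[cmb[2L, ]],
      t = pr["t", ],
      p.value = pr["p", ],
      p.adjusted = padj,
      row.names = NULL)
  }
  out
}
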