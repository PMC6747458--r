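#' Two-sided Mann-Whitney U test
#'
#' Rank-sum comparison of two independent samples, the test used for all
#' unpaired group comparisons in the study design this package emulates.
#' The exact two-sided p-value (from the full null distribution of U) is
#' used when `n_x + n_y <= 12` and there are no ties in the pooled
#' sample; otherwise the normal approximation with tie correction is
#' used. The method actually applied is recorded in the result.
#'
#' @param x,y numeric samples (each non-empty).
#' @return an object of class `rq_test` with fields `test_name`,
#'   `statistic` (U for `x`), `p_value`, `method`, `n`.
#' @examples
#' mann_whitney_u(c(1, 2, 3), c(4, 5, 6))  # U = 0, exact p = 0.1
#' @export
mann_whitney_u <- function(x, y) {
  x <- as.numeric(x); y <- as.numeric(y)
  if (length(x) < 1 || length(y) < 1) stop("both samples must be non-empty")
  nx <- length(x); ny <- length(y)
  pooled <- c(x, y)
  r <- rank(pooled)
  U <- sum(r[seq_len(nx)]) - nx * (nx + 1) / 2
  ties <- any(duplicated(pooled))
  if (nx + ny <= 12 && !ties) {
    # exact two-sided p from the null distribution of U
    p <- 2 * min(stats::pwilcox(U, nx, ny),
                 1 - stats::pwilcox(U - 1, nx, ny))
    method <- "exact"
  } else {
    mu <- nx * ny / 2
    tie_tab <- table(pooled)
    n <- nx + ny
    sigma2 <- nx * ny / 12 *
      ((n + 1) - sum(tie_tab^3 - tie_tab) / (n * (n - 1)))
    if (sigma2 <= 0) {
      p <- 1
    } else {
      z <- (U - mu) / sqrt(sigma2)
      p <- 2 * stats::pnorm(-abs(z))
    }
    method <- "normal_approximation"
  }
  structure(list(test_name = "mann_whitney_u", statistic = U,
                 p_value = min(1, p), method = method, n = c(nx, ny)),
            class = "rq_test")
}

#' Two-sided Wilcoxon signed-rank test
#'
#' Paired comparison used for OHT versus contralateral eyes of the same
#' animals. Zero differences are dropped before ranking (the original
#' convention of the test), and the number dropped is recorded. With at
#' most 12 nonzero pairs the exact two-sided p-value is used: from the
#' closed-form null distribution when the absolute differences are
#' untied, by full enumeration of the 2^m sign patterns (on mid-ranks)
#' when they are tied. Larger samples use the tie-corrected normal
#' approximation.
#'
#' @param x,y paired numeric samples of equal length.
#' @return an `rq_test` with `statistic` = W (sum of positive ranks),
#'   `p_value`, `method`, `n` (nonzero pairs), `n_zero_dropped`.
#' @examples
#' wilcoxon_signed_rank(c(1, 2, 3), c(2, 3, 4))  # W = 0, exact p = 0.25
#' @export
wilcoxon_signed_rank <- function(x, y) {
  x <- as.numeric(x); y <- as.numeric(y)
  if (length(x) != length(y)) stop("samples must be paired (equal length)")
  d <- x - y
  n_zero <- sum(d == 0)
  d <- d[d != 0]
  m <- length(d)
  if (m == 0) stop("all paired differences are zero")
  r <- rank(abs(d))
  W <- sum(r[d > 0])
  ties <- any(duplicated(abs(d)))
  if (m <= 12) {
    if (!ties) {
      p <- 2 * min(stats::psignrank(W, m), 1 - stats::psignrank(W - 1, m))
    } else {
      # enumerate all sign patterns on the mid-ranks
      signs <- as.matrix(expand.grid(rep(list(c(0, 1)), m)))
      w_all <- as.numeric(signs %*% r)
      p <- 2 * min(mean(w_all <= W), mean(w_all >= W))
    }
    method <- "exact"
  } else {
    mu <- m * (m + 1) / 4
    tie_tab <- table(r)
    sigma2 <- m * (m + 1) * (2 * m + 1) / 24 -
      sum(tie_tab^3 - tie_tab) / 48
    z <- (W - mu) / sqrt(sigma2)
    p <- 2 * stats::pnorm(-abs(z))
    method <- "normal_approximation"
  }
  structure(list(test_name = "wilcoxon_signed_rank", statistic = W,
                 p_value = min(1, p), method = method, n = m,
                 n_zero_dropped = n_zero),
            class = "rq_test")
}

#' One-way ANOVA with Bonferroni-corrected pairwise comparisons
#'
#' Used for comparisons among the four retinal zones within a treatment
#' group. The omnibus F test is the standard one-way analysis of
#' variance; every pairwise mean comparison is then tested with pooled-SD
#' t tests and Bonferroni adjustment (raw p times the number of pairs,
#' capped at 1).
#'
#' @param values numeric response.
#' @param groups factor (or coercible) of group labels, 2 or more levels
#'   each with n >= 2.
#' @return an `rq_test` with `statistic` = F, `p_value` (omnibus),
#'   `pairwise` (data frame: `group1`, `group2`, `adjusted_p`).
#' @export
anova_bonferroni <- function(values, groups) {
  groups <- factor(groups)
  if (nlevels(groups) < 2) stop("need at least 2 groups")
  if (any(table(groups) < 2)) stop("every group needs n >= 2")
  within_var <- tapply(values, groups, stats::var)
  if (all(within_var == 0))
    stop("zero within-group variance everywhere: F is undefined")
  fit <- stats::aov(values ~ groups)
  tab <- summary(fit)[[1]]
  Fstat <- tab[1, "F value"]
  p <- tab[1, "Pr(>F)"]
  pw <- stats::pairwise.t.test(values, groups, pool.sd = TRUE,
                               p.adjust.method = "bonferroni")
  pm <- pw$p.value
  pairs <- which(!is.na(pm), arr.ind = TRUE)
  pairwise <- data.frame(
    group1 = rownames(pm)[pairs[, 1]],
    group2 = colnames(pm)[pairs[, 2]],
    adjusted_p = pm[pairs],
    stringsAsFactors = FALSE
  )
  structure(list(test_name = "anova_bonferroni", statistic = Fstat,
                 p_value = p, method = "exact", pairwise = pairwise,
                 n = as.integer(table(groups))),
            class = "rq_test")
}

#' @export
print.rq_test <- function(x, ...) {
  cat(sprintf("<rq_test> %s: statistic = %.4g, p = %.4g (%s)\n",
              x$test_name, x$statistic, x$p_value, x$method))
  invisible(x)
}

#' Mean and SD summary of one metric in one group
#'
#' Group results are reported as mean plus/minus standard deviation (SD,
#' n - 1 denominator). A single observation is reported with SD 0 and
#' flagged.
#'
#' @param values numeric, non-empty.
#' @param group,metric labels carried into the summary.
#' @return data frame row: `group`, `metric`, `n`, `mean`, `sd`,
#'   `single_observation`.
#' @export
summarize_metric <- function(values, group = NA_character_,
                             metric = NA_character_) {
  values <- as.numeric(values)
  if (length(values) < 1) stop("cannot summarize an empty sample")
  single <- length(values) == 1
  data.frame(group = group, metric = metric, n = length(values),
             mean = mean(values),
             sd = if (single) 0 else stats::sd(values),
             single_observation = single,
             stringsAsFactors = FALSE)
}
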