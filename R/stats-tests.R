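# The group-comparison battery: Welch t, Fisher exact, Pearson
# correlation, one-way repeated-measures ANOVA with Bonferroni post hoc,
# and the Friedman test with Conover's post hoc. All p values two-sided.
# Standard tests wrap their base-R implementations; Friedman and Conover
# are implemented here because the tie-corrected statistic and the rank
# post hoc are not available in base R.

test_result <- function(method, statistic = NA_real_, df = NA_real_,
                        df2 = NA_real_, p, estimate = NA_real_,
                        n1 = NA_integer_, n2 = NA_integer_,
                        adjusted = FALSE, procedure = NA_character_,
                        note = NA_character_) {
  tibble::tibble(method = method, statistic = statistic, df = df, df2 = df2,
                 p = p, estimate = estimate, n1 = n1, n2 = n2,
                 adjusted = adjusted, procedure = procedure, note = note)
}

#' Welch's heteroscedastic two-sample t test
#'
#' Two-sided, unequal-variance t test with Welch-Satterthwaite degrees of
#' freedom. When both samples are constant the result is flagged
#' degenerate: p = 1 if the means agree, p = 0 otherwise.
#'
#' @param x,y Numeric samples (each n >= 2).
#' @return One-row result tibble (method, statistic, df, p, ...).
#' @export
welch_t_test <- function(x, y) {
  if (length(x) < 2 || length(y) < 2) stop("each sample needs n >= 2")
  if (stats::var(x) == 0 && stats::var(y) == 0) {
    same <- isTRUE(all.equal(mean(x), mean(y)))
    return(test_result("Welch t-test", statistic = if (same) 0 else Inf,
                       df = NA_real_, p = if (same) 1 else 0,
                       estimate = mean(x) - mean(y),
                       n1 = length(x), n2 = length(y),
                       note = "degenerate: zero variance in both samples"))
  }
  tt <- stats::t.test(x, y, var.equal = FALSE)
  test_result("Welch t-test", statistic = unname(tt$statistic),
              df = unname(tt$parameter), p = tt$p.value,
              estimate = mean(x) - mean(y),
              n1 = length(x), n2 = length(y))
}

#' Fisher's exact test for a 2x2 table
#'
#' Two-sided p as the sum of hypergeometric probabilities of all tables
#' with the same margins whose probability does not exceed the observed
#' table's.
#'
#' @param table 2x2 matrix of non-negative integer counts, or a length-4
#'   vector (a, b, c, d, row-wise).
#' @return One-row result tibble; `estimate` is the conditional odds-ratio
#'   MLE.
#' @export
fisher_exact_2x2 <- function(table) {
  m <- if (is.matrix(table)) table else matrix(as.numeric(table), 2, byrow = TRUE)
  if (any(dim(m) != 2)) stop("table must be 2x2")
  if (any(m < 0) || any(m != round(m))) stop("cells must be non-negative integers")
  if (sum(m) < 1) stop("table total must be >= 1")
  ft <- stats::fisher.test(m)
  test_result("Fisher exact test", p = ft$p.value,
              estimate = unname(ft$estimate),
              n1 = sum(m[1, ]), n2 = sum(m[2, ]))
}

#' Pearson correlation with least-squares line
#'
#' Product-moment r with the two-sided p from
#' `t = r * sqrt((n - 2) / (1 - r^2))` on n - 2 df, plus the OLS slope and
#' intercept of y on x. Zero variance in either variable yields an
#' undefined-r report (r = NA), not r = 0.
#'
#' @param x,y Numeric samples of equal length, n >= 3.
#' @return One-row tibble with columns r, slope, intercept added.
#' @export
pearson_correlation <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  if (length(x) < 3) stop("correlation needs n >= 3")
  out <- test_result("Pearson correlation", p = NA_real_,
                     n1 = length(x), n2 = length(x))
  if (stats::var(x) == 0 || stats::var(y) == 0) {
    out$note <- "undefined: zero variance"
    out$r <- NA_real_; out$slope <- NA_real_; out$intercept <- NA_real_
    return(out)
  }
  ct <- stats::cor.test(x, y, method = "pearson")
  fit <- stats::coef(stats::lm(y ~ x))
  out$statistic <- unname(ct$statistic)
  out$df <- unname(ct$parameter)
  out$p <- ct$p.value
  out$estimate <- unname(ct$estimate)
  out$r <- unname(ct$estimate)
  out$slope <- unname(fit[2])
  out$intercept <- unname(fit[1])
  out
}

as_block_matrix <- function(tab) {
  tab <- as.matrix(tab)
  if (anyNA(tab)) stop("missing cells are not allowed (no imputation)")
  if (nrow(tab) < 2 || ncol(tab) < 2) {
    stop("need at least 2 blocks and 2 treatments")
  }
  tab
}

#' One-way repeated-measures ANOVA
#'
#' Blocks (subjects) in rows, treatments in columns. Fits
#' `y ~ treatment + Error(block)` and partitions
#' `SS_total = SS_subjects + SS_treatment + SS_error`.
#'
#' @param tab Complete numeric blocks-by-treatments matrix.
#' @return One-row tibble with F statistic, df = k - 1,
#'   df2 = (n - 1)(k - 1), p, and the sum-of-squares partition columns
#'   `ss_subjects`, `ss_treatment`, `ss_error`, `ss_total`.
#' @export
rm_anova <- function(tab) {
  tab <- as_block_matrix(tab)
  n <- nrow(tab); k <- ncol(tab)
  d <- data.frame(y = as.vector(tab),
                  block = factor(rep(seq_len(n), times = k)),
                  treat = factor(rep(seq_len(k), each = n)))
  fit <- stats::aov(y ~ treat + Error(block), data = d)
  s <- summary(fit)
  within <- as.data.frame(s[["Error: Within"]][[1]])
  strata <- as.data.frame(s[["Error: block"]][[1]])
  rn <- trimws(rownames(within))
  ss_treat <- within[rn == "treat", "Sum Sq"]
  ss_err <- within[rn == "Residuals", "Sum Sq"]
  ss_subj <- strata[trimws(rownames(strata)) == "Residuals", "Sum Sq"]
  ss_tot <- sum((d$y - mean(d$y))^2)
  if (ss_treat < 1e-12 * max(ss_tot, 1)) {
    fstat <- 0; p <- 1
  } else {
    fstat <- within[rn == "treat", "F value"]
    p <- within[rn == "treat", "Pr(>F)"]
  }
  out <- test_result("Repeated-measures ANOVA", statistic = fstat,
                     df = k - 1, df2 = (n - 1) * (k - 1), p = p,
                     n1 = n, n2 = k)
  out$ss_subjects <- ss_subj
  out$ss_treatment <- ss_treat
  out$ss_error <- ss_err
  out$ss_total <- ss_tot
  out
}

#' Bonferroni adjustment
#'
#' `p_adj = min(1, p * m)` for `m` comparisons.
#'
#' @param p Vector of p values in [0, 1].
#' @param m Number of comparisons (defaults to `length(p)`).
#' @return Adjusted p values.
#' @export
bonferroni_adjust <- function(p, m = length(p)) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) stop("p values must lie in [0, 1]")
  pmin(1, p * m)
}

friedman_ranks <- function(tab) {
  t(apply(tab, 1, rank))  # mid-ranks for ties
}

#' Friedman rank test with tie correction
#'
#' Within-block mid-ranks; the statistic uses the tie-corrected form
#' `chi2 = (k - 1) * sum((R_j - n(k+1)/2)^2) / (A - C)` with
#' `A = sum(r_ij^2)` and `C = n k (k+1)^2 / 4`, which reduces to
#' `12/(n k (k+1)) * sum(R_j^2) - 3 n (k+1)` when there are no ties.
#' p from the chi-squared distribution with k - 1 df.
#'
#' @param tab Complete blocks-by-treatments matrix.
#' @return One-row result tibble.
#' @export
friedman_test <- function(tab) {
  tab <- as_block_matrix(tab)
  n <- nrow(tab); k <- ncol(tab)
  r <- friedman_ranks(tab)
  rj <- colSums(r)
  a <- sum(r^2)
  cc <- n * k * (k + 1)^2 / 4
  num <- (k - 1) * sum((rj - n * (k + 1) / 2)^2)
  if (a - cc <= 0) {
    # all observations tied within every block
    return(test_result("Friedman test", statistic = 0, df = k - 1, p = 1,
                       n1 = n, n2 = k,
                       note = "all values tied; statistic 0 by convention"))
  }
  stat <- num / (a - cc)
  test_result("Friedman test", statistic = stat, df = k - 1,
              p = stats::pchisq(stat, df = k - 1, lower.tail = FALSE),
              n1 = n, n2 = k)
}

#' Conover's all-pairs post hoc test after Friedman
#'
#' For each treatment pair, `t = |R_i - R_j| / SE` with
#' `SE = sqrt(2 n (A - B) / ((n - 1)(k - 1)))`, where `A = sum(r_ij^2)`
#' and `B = sum(R_j^2) / n` (Conover 1999); two-sided p from the t
#' distribution with (n - 1)(k - 1) df. Unadjusted and
#' Bonferroni-adjusted p values are both returned.
#'
#' @param tab Complete blocks-by-treatments matrix.
#' @return Tibble with one row per pair: treatment_1, treatment_2,
#'   statistic, df, p, p_bonferroni.
#' @export
conover_posthoc <- function(tab) {
  tab <- as_block_matrix(tab)
  n <- nrow(tab); k <- ncol(tab)
  r <- friedman_ranks(tab)
  rj <- colSums(r)
  a <- sum(r^2)
  b <- sum(rj^2) / n
  se <- sqrt(2 * n * max(a - b, 0) / ((n - 1) * (k - 1)))
  df <- (n - 1) * (k - 1)
  labels <- colnames(tab) %||% as.character(seq_len(k))
  pairs <- utils::combn(k, 2)
  m <- ncol(pairs)
  res <- lapply(seq_len(m), function(q) {
    i <- pairs[1, q]; j <- pairs[2, q]
    diffr <- abs(rj[i] - rj[j])
    if (se == 0) {
      # perfectly consistent rankings: zero residual rank variance
      stat <- if (diffr == 0) 0 else Inf
      p <- if (diffr == 0) 1 else 0
    } else {
      stat <- diffr / se
      p <- 2 * stats::pt(-stat, df = df)
    }
    tibble::tibble(treatment_1 = labels[i], treatment_2 = labels[j],
                   statistic = stat, df = df, p = p)
  })
  out <- dplyr::bind_rows(res)
  out$p_bonferroni <- bonferroni_adjust(out$p, m)
  out
}
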