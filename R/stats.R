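# Inferential tests: two-sided Brunner-Munzel rank test (with permutation
# variant for small samples), two-tailed Fisher's exact test, and the
# Bonferroni significance adjustment, plus the significance-band formatter.

#' Brunner-Munzel two-sided rank test
#'
#' Nonparametric test of the relative effect `p = P(X < Y) + 0.5 P(X = Y)`
#' against 0.5, using mid-ranks for ties. The default uses the studentised
#' statistic with Satterthwaite-approximated degrees of freedom and a
#' two-sided t p-value; `method = "permutation"` replaces the t reference
#' with the permutation distribution of the statistic (recommended for
#' samples under about 10).
#'
#' @param x,y numeric samples.
#' @param conf_level confidence level for the relative-effect interval.
#' @param method `"t"` (default) or `"permutation"`.
#' @param n_perm permutation resamples.
#' @return List of class `bm_test`: `statistic`, `df`, `p_value`,
#'   `estimate` (relative effect), `conf_int`, `n`.
#' @export
brunner_munzel <- function(x, y, conf_level = 0.95,
                           method = c("t", "permutation"), n_perm = 4000L) {
  method <- match.arg(method)
  x <- x[is.finite(x)]; y <- y[is.finite(y)]
  n1 <- length(x); n2 <- length(y)
  if (n1 == 0L || n2 == 0L) stop("empty sample")
  if (n1 < 10 || n2 < 10)
    warning("small sample (n < 10); consider method = 'permutation'")
  core <- function(x, y) {
    n1 <- length(x); n2 <- length(y)
    r <- rank(c(x, y))
    r1 <- rank(x); r2 <- rank(y)
    m1 <- mean(r[seq_len(n1)]); m2 <- mean(r[n1 + seq_len(n2)])
    pst <- (m2 - (n2 + 1) / 2) / n1
    v1 <- sum((r[seq_len(n1)] - r1 - m1 + (n1 + 1) / 2)^2) / (n1 - 1)
    v2 <- sum((r[n1 + seq_len(n2)] - r2 - m2 + (n2 + 1) / 2)^2) / (n2 - 1)
    if (v1 == 0 && v2 == 0)
      return(list(stat = 0, df = Inf, pst = pst, v1 = v1, v2 = v2,
                  degenerate = TRUE))
    stat <- n1 * n2 * (m2 - m1) / (n1 + n2) / sqrt(n1 * v1 + n2 * v2)
    df <- (n1 * v1 + n2 * v2)^2 /
      ((n1 * v1)^2 / (n1 - 1) + (n2 * v2)^2 / (n2 - 1))
    list(stat = stat, df = df, pst = pst, v1 = v1, v2 = v2,
         degenerate = FALSE)
  }
  obs <- core(x, y)
  if (obs$degenerate) {
    p <- if (obs$pst == 0.5) 1 else 0
    return(structure(list(statistic = obs$stat, df = NA_real_, p_value = p,
                          estimate = obs$pst,
                          conf_int = c(obs$pst, obs$pst), n = c(n1, n2),
                          method = method, degenerate = TRUE),
                     class = "bm_test"))
  }
  if (method == "t") {
    p <- 2 * stats::pt(abs(obs$stat), obs$df, lower.tail = FALSE)
  } else {
    pool <- c(x, y)
    stats_perm <- vapply(seq_len(n_perm), function(i) {
      idx <- sample.int(n1 + n2, n1)
      core(pool[idx], pool[-idx])$stat
    }, 0)
    p <- (1 + sum(abs(stats_perm) >= abs(obs$stat))) / (n_perm + 1)
  }
  se_p <- sqrt(obs$v1 / (n1 * n2^2) + obs$v2 / (n2 * n1^2))
  tq <- stats::qt(1 - (1 - conf_level) / 2, obs$df)
  ci <- pmin(pmax(obs$pst + c(-1, 1) * tq * se_p, 0), 1)
  structure(list(statistic = obs$stat, df = obs$df, p_value = min(1, p),
                 estimate = obs$pst, conf_int = ci, n = c(n1, n2),
                 method = method, degenerate = FALSE),
            class = "bm_test")
}

#' @export
print.bm_test <- function(x, ...) {
  cat(sprintf("Brunner-Munzel test: p(X<Y)+.5p(X=Y) = %.3f [%.3f, %.3f], t = %.3f, df = %.1f, p = %.3g (%s)\n",
              x$estimate, x$conf_int[1], x$conf_int[2], x$statistic, x$df,
              x$p_value, x$method))
  invisible(x)
}

#' Two-tailed Fisher's exact test
#'
#' Exact test of association in a 2x2 table. The two-tailed p-value sums the
#' hypergeometric probabilities of all tables (with the observed margins) no
#' more probable than the observed one; the odds ratio is the conditional
#' maximum-likelihood estimate with its exact conditional-likelihood
#' confidence interval.
#'
#' @param tab 2x2 matrix or table of non-negative integer counts.
#' @param conf_level confidence level (default 0.95).
#' @return List of class `fisher_result`: `p_value`, `odds_ratio`,
#'   `conf_int`, `table`, `degenerate` (TRUE when a margin is zero).
#' @export
fisher_exact <- function(tab, conf_level = 0.95) {
  tab <- as.matrix(tab)
  stopifnot(all(dim(tab) == c(2, 2)), all(tab >= 0),
            all(tab == round(tab)))
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) {
    return(structure(list(p_value = 1, odds_ratio = NA_real_,
                          conf_int = c(NA_real_, NA_real_), table = tab,
                          degenerate = TRUE),
                     class = "fisher_result"))
  }
  ft <- stats::fisher.test(tab, conf.level = conf_level)
  structure(list(p_value = ft$p.value,
                 odds_ratio = unname(ft$estimate),
                 conf_int = as.numeric(ft$conf.int), table = tab,
                 degenerate = FALSE),
            class = "fisher_result")
}

#' @export
print.fisher_result <- function(x, ...) {
  cat(sprintf("Fisher's exact test: OR = %.2f (%.2f-%.2f, 95%% CI), p = %.3g\n",
              x$odds_ratio, x$conf_int[1], x$conf_int[2], x$p_value))
  invisible(x)
}

#' Bonferroni-adjusted significance level
#'
#' @param alpha family-wise level (e.g. 0.05).
#' @param m number of tests (>= 1).
#' @return `alpha / m`.
#' @examples
#' bonferroni_adjust(0.05, 5)  # 0.01
#' @export
bonferroni_adjust <- function(alpha, m) {
  stopifnot(alpha > 0, alpha <= 1, m >= 1)
  alpha / m
}

#' Significance band marker
#'
#' Formats a p-value into the conventional bands: `ns` (p > 0.01), `*`
#' (0.001 < p < 0.01), `**` (p < 0.001), `***` (p < 0.0001).
#'
#' @param p p-value(s).
#' @return Character marker(s).
#' @export
significance_marker <- function(p) {
  vapply(p, function(pp) {
    if (pp < 1e-4) "***" else if (pp < 1e-3) "**"
    else if (pp < 0.01) "*" else "ns"
  }, "")
}
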