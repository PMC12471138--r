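test_result <- function(statistic, p_value, test_name, n1, n2, method = NA_character_) {
  structure(list(statistic = unname(statistic),
                 p_value = min(max(unname(p_value), 0), 1),
                 test_name = test_name, n1 = n1, n2 = n2, method = method),
            class = "test_result")
}

#' @export
print.test_result <- function(x, ...) {
  cat(sprintf("%s: statistic = %.6g, p = %.4g (n1 = %d, n2 = %d)\n",
              x$test_name, x$statistic, x$p_value, x$n1, x$n2))
  invisible(x)
}

# asymptotic Kolmogorov distribution tail, with the small-sample correction
# lambda = (sqrt(ne) + 0.12 + 0.11 / sqrt(ne)) * D
kolmogorov_p <- function(d, ne) {
  lambda <- (sqrt(ne) + 0.12 + 0.11 / sqrt(ne)) * d
  if (lambda < 1e-3) return(1)
  k <- 1:101
  p <- 2 * sum((-1)^(k - 1) * exp(-2 * k^2 * lambda^2))
  min(max(p, 0), 1)
}

#' Two-sample Kolmogorov-Smirnov test
#'
#' Statistic `D = sup |F1 - F2|` over the pooled sample points; p-value from
#' the asymptotic Kolmogorov distribution with effective sample size
#' `n1 n2 / (n1 + n2)` (the convention of the usual two-sample routines).
#'
#' @param xs,ys non-empty numeric samples.
#' @return A `test_result` with elements `statistic` (D), `p_value`,
#'   `test_name`, `n1`, `n2`.
#' @export
ks_two_sample <- function(xs, ys) {
  xs <- as.numeric(xs); ys <- as.numeric(ys)
  if (length(xs) == 0L || length(ys) == 0L) stop("samples must be non-empty")
  n1 <- length(xs); n2 <- length(ys)
  pts <- sort(unique(c(xs, ys)))
  f1 <- vapply(pts, function(t) mean(xs <= t), numeric(1))
  f2 <- vapply(pts, function(t) mean(ys <= t), numeric(1))
  d <- max(abs(f1 - f2))
  ne <- n1 * n2 / (n1 + n2)
  test_result(d, kolmogorov_p(d, ne), "two-sample Kolmogorov-Smirnov", n1, n2,
              method = "asymptotic")
}

#' Wilcoxon-Mann-Whitney rank-sum test
#'
#' Mann-Whitney U statistic with midrank ties. The p-value is exact (from
#' the null Wilcoxon distribution) when both samples are tie-free and
#' smaller than `exact_limit`, otherwise the normal approximation with tie
#' and continuity corrections is used.
#'
#' @param xs,ys non-empty numeric samples.
#' @param exact_limit use the exact null distribution when
#'   `max(n1, n2) < exact_limit` and there are no ties.
#' @return A `test_result` with the U statistic (pairs where `xs` exceeds
#'   `ys`, ties counted half).
#' @export
rank_sum <- function(xs, ys, exact_limit = 50) {
  xs <- as.numeric(xs); ys <- as.numeric(ys)
  if (length(xs) == 0L || length(ys) == 0L) stop("samples must be non-empty")
  n1 <- length(xs); n2 <- length(ys)
  pooled <- c(xs, ys)
  r <- rank(pooled)                       # midranks
  u <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  ties <- table(pooled)
  has_ties <- any(ties > 1)
  if (!has_ties && max(n1, n2) < exact_limit) {
    p <- if (u > n1 * n2 / 2) {
      stats::pwilcox(u - 1, n1, n2, lower.tail = FALSE)
    } else {
      stats::pwilcox(u, n1, n2)
    }
    return(test_result(u, min(2 * p, 1), "Wilcoxon-Mann-Whitney", n1, n2,
                       method = "exact"))
  }
  n <- n1 + n2
  mu <- n1 * n2 / 2
  tie_term <- sum(ties^3 - ties) / (n * (n - 1))
  sigma2 <- n1 * n2 / 12 * ((n + 1) - tie_term)
  if (sigma2 <= 0) {
    return(test_result(u, 1, "Wilcoxon-Mann-Whitney", n1, n2, method = "normal"))
  }
  z <- u - mu
  z <- z - sign(z) * 0.5                  # continuity correction
  p <- 2 * stats::pnorm(-abs(z) / sqrt(sigma2))
  test_result(u, min(p, 1), "Wilcoxon-Mann-Whitney", n1, n2, method = "normal")
}

# KS distance between a sample and the normal law fitted to it
lilliefors_statistic <- function(xs) {
  n <- length(xs)
  z <- sort((xs - mean(xs)) / stats::sd(xs))
  fz <- stats::pnorm(z)
  max(max(seq_len(n) / n - fz), max(fz - (seq_len(n) - 1) / n))
}

#' Lilliefors normality test (Monte-Carlo p-value)
#'
#' Kolmogorov-Smirnov distance between the sample and the normal
#' distribution with the sample's own mean and standard deviation. Because
#' the parameters are estimated, the standard KS null does not apply; the
#' p-value is drawn from a seeded Monte-Carlo null of `n_mc` standard-normal
#' samples of the same size, `p = (1 + #{D_null >= D}) / (n_mc + 1)`.
#'
#' @param xs numeric sample with `n >= 4` and positive variance.
#' @param n_mc number of Monte-Carlo null replicates.
#' @param seed RNG seed for the null draws (results are reproducible for a
#'   fixed seed; the caller's RNG state is untouched).
#' @return A `test_result` (n2 is `NA`).
#' @export
lilliefors <- function(xs, n_mc = 2000, seed = 1) {
  xs <- as.numeric(xs)
  n <- length(xs)
  if (n < 4L) stop("lilliefors requires n >= 4")
  if (stats::sd(xs) == 0) stop("zero variance sample")
  d <- lilliefors_statistic(xs)
  null_d <- with_seed(seed, {
    m <- matrix(stats::rnorm(n * n_mc), nrow = n)
    apply(m, 2, lilliefors_statistic)
  })
  p <- (1 + sum(null_d >= d)) / (n_mc + 1)
  test_result(d, p, "Lilliefors", n, NA_integer_, method = "monte-carlo")
}

#' Group summary table with pairwise Kolmogorov-Smirnov comparisons
#'
#' For every feature column: per-group mean and sample standard deviation
#' (n - 1 denominator), plus the two-sample KS test of each non-reference
#' group against the reference group. No multiple-comparison correction is
#' applied by default; `p_adjust = "BH"` switches on Benjamini-Hochberg
#' adjustment across the comparisons of each feature set.
#'
#' @param features data.frame of numeric feature columns plus a group
#'   column.
#' @param group_col name of the group column.
#' @param feature_cols feature columns to summarize; default all numeric
#'   columns except `group_col`.
#' @param reference reference (healthy) group; default the first group in
#'   order of appearance.
#' @param p_adjust `"none"` (default) or `"BH"`.
#' @return A data.frame with columns `feature`, `group`, `n`, `mean`, `sd`,
#'   `ks_statistic`, `ks_p` (`NA` for the reference group).
#' @export
summarize_groups <- function(features, group_col = "group",
                             feature_cols = NULL, reference = NULL,
                             p_adjust = c("none", "BH")) {
  p_adjust <- match.arg(p_adjust)
  groups <- unique(as.character(features[[group_col]]))
  if (length(groups) < 2L) stop("at least 2 groups are required")
  if (is.null(reference)) reference <- groups[1]
  if (!reference %in% groups) stop("reference group not present")
  if (is.null(feature_cols)) {
    feature_cols <- setdiff(names(features)[vapply(features, is.numeric, logical(1))],
                            group_col)
  }
  sizes <- table(features[[group_col]])
  if (any(sizes < 2)) stop("every group needs >= 2 members (SD undefined)")

  rows <- list()
  for (f in feature_cols) {
    ref_vals <- features[[f]][features[[group_col]] == reference]
    for (g in groups) {
      vals <- features[[f]][features[[group_col]] == g]
      if (g == reference) {
        ks <- list(statistic = NA_real_, p_value = NA_real_)
      } else {
        ks <- ks_two_sample(vals, ref_vals)
      }
      rows[[length(rows) + 1L]] <- data.frame(
        feature = f, group = g, n = length(vals),
        mean = mean(vals), sd = stats::sd(vals),
        ks_statistic = ks$statistic, ks_p = ks$p_value,
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  if (p_adjust == "BH") {
    idx <- !is.na(out$ks_p)
    out$ks_p_adj <- NA_real_
    out$ks_p_adj[idx] <- stats::p.adjust(out$ks_p[idx], method = "BH")
  }
  out
}
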