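#' Kruskal-Wallis omnibus test with eta-squared effect size
#'
#' Tie-corrected Kruskal-Wallis H across k groups (via
#' [stats::kruskal.test()]), chi-squared p-value on k - 1 df, and the
#' eta-squared effect size `(H - k + 1) / (n - k)` attached. When every
#' value in every group is identical the statistic is defined as H = 0,
#' p = 1 (no information, not an error).
#'
#' @param groups A named or unnamed list of numeric vectors, one per group
#'   (k >= 2, each non-empty).
#' @return An object of class `kw_result`: `H`, `df`, `p`, `eta2_H`, `k`,
#'   `n`.
#' @export
kruskal_wallis <- function(groups) {
  stopifnot(is.list(groups), length(groups) >= 2)
  if (any(vapply(groups, length, 1L) == 0L))
    stop("all groups must be non-empty", call. = FALSE)
  k <- length(groups)
  n <- sum(lengths(groups))
  vals <- unlist(groups)
  if (length(unique(vals)) == 1L) {
    H <- 0; p <- 1
  } else {
    kt <- stats::kruskal.test(groups)
    H <- unname(kt$statistic)
    p <- kt$p.value
  }
  structure(list(H = H, df = k - 1L, p = p,
                 eta2_H = if (n > k) eta_squared_H(H, k, n) else NA_real_,
                 k = k, n = n),
            class = "kw_result")
}

#' @export
print.kw_result <- function(x, ...) {
  cat(sprintf("Kruskal-Wallis: H(%d) = %.2f, p = %.4g, eta2_H = %.3f (n = %d)\n",
              x$df, x$H, x$p, x$eta2_H, x$n))
  invisible(x)
}

#' Eta-squared effect size for a Kruskal-Wallis statistic
#'
#' `eta2_H = (H - k + 1) / (n - k)`, the rank-based analogue of
#' eta-squared, expressed as a proportion. It is centred at 0 under the
#' null (E\[H\] = k - 1), so small-sample values can come out slightly
#' negative; they are reported as computed.
#'
#' @param H Kruskal-Wallis statistic.
#' @param k Number of groups.
#' @param n Total number of observations (must exceed `k`).
#' @return The effect size as a proportion.
#' @export
eta_squared_H <- function(H, k, n) {
  if (n <= k) stop("`n` must exceed `k`", call. = FALSE)
  (H - k + 1) / (n - k)
}

#' Dunn's post hoc pairwise tests
#'
#' Pairwise comparisons of mean ranks following a Kruskal-Wallis omnibus
#' test. Ranks are computed jointly over all k groups; for a pair (i, j),
#' \deqn{z = (\bar R_i - \bar R_j) / \sqrt{ [N(N+1)/12 -
#'   \sum(t^3 - t)/(12(N-1))] (1/n_i + 1/n_j) }}
#' with the tie correction in the pooled variance, and a two-sided normal
#' p-value. The sign convention is `z > 0` when group i's mean rank
#' exceeds group j's.
#'
#' @param groups Named list of numeric vectors (names become pair labels).
#' @param adjust `"none"` (default: raw p-values are reported) or
#'   `"holm"`.
#' @return A data frame of class `dunn_result`: `group1`, `group2`, `z`,
#'   `p`, one row per unordered pair. If the pooled variance is zero (all
#'   values tied) `z` is `NA` with a warning of class `undefined_z`.
#' @export
dunn_test <- function(groups, adjust = c("none", "holm")) {
  adjust <- match.arg(adjust)
  stopifnot(is.list(groups), length(groups) >= 2)
  if (is.null(names(groups)))
    names(groups) <- paste0("G", seq_along(groups))
  vals <- unlist(groups)
  N <- length(vals)
  r <- rank(vals)
  g <- rep(names(groups), lengths(groups))
  rbar <- tapply(r, g, mean)
  tie_tab <- table(vals)
  tie_term <- sum(tie_tab^3 - tie_tab) / (12 * (N - 1))
  v0 <- N * (N + 1) / 12 - tie_term
  pairs <- utils::combn(names(groups), 2)
  zs <- ps <- numeric(ncol(pairs))
  for (c in seq_len(ncol(pairs))) {
    i <- pairs[1, c]; j <- pairs[2, c]
    se2 <- v0 * (1 / length(groups[[i]]) + 1 / length(groups[[j]]))
    if (se2 <= 0) {
      warning(warningCondition("zero pooled variance: all values tied, z undefined",
                               class = "undefined_z"))
      zs[c] <- NA_real_; ps[c] <- NA_real_
    } else {
      zs[c] <- (rbar[[i]] - rbar[[j]]) / sqrt(se2)
      ps[c] <- 2 * stats::pnorm(-abs(zs[c]))
    }
  }
  if (adjust == "holm") ps <- stats::p.adjust(ps, "holm")
  out <- data.frame(group1 = pairs[1, ], group2 = pairs[2, ], z = zs, p = ps,
                    stringsAsFactors = FALSE)
  class(out) <- c("dunn_result", "data.frame")
  out
}

#' Spearman rank correlation
#'
#' Pearson correlation of average ranks with a t approximation for the
#' p-value (`t = rho * sqrt((n-2)/(1-rho^2))` on n - 2 df), which handles
#' ties.
#'
#' @param x,y Paired numeric vectors, n >= 4, finite.
#' @return A list: `rho`, `p`, `n`. Constant input yields `rho = NA` with
#'   a warning of class `undefined_rho`.
#' @export
spearman_rank <- function(x, y) {
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 4) stop("need at least 4 complete pairs", call. = FALSE)
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    warning(warningCondition("constant input: rho undefined",
                             class = "undefined_rho"))
    return(list(rho = NA_real_, p = NA_real_, n = n))
  }
  rho <- stats::cor(rank(x), rank(y))
  if (abs(rho) >= 1) {
    p <- 0
  } else {
    tt <- rho * sqrt((n - 2) / (1 - rho^2))
    p <- 2 * stats::pt(-abs(tt), n - 2)
  }
  list(rho = rho, p = p, n = n)
}

#' Flag upper-quantile outliers
#'
#' Flags values strictly above the q-th empirical quantile, computed with
#' the linear-interpolation convention ([stats::quantile()] type 7). Used
#' for the sensitivity re-analysis that drops extreme thresholds
#' (q = 0.975 flags at most the top 2.5%).
#'
#' @param values Numeric vector, n >= 2.
#' @param q Quantile, default 0.975.
#' @return Logical vector: `TRUE` where the value is flagged.
#' @export
flag_outliers <- function(values, q = 0.975) {
  if (length(values) < 2) stop("need at least 2 values", call. = FALSE)
  thr <- stats::quantile(values, q, type = 7, names = FALSE)
  values > thr
}

#' Omnibus + post hoc report over fitted psychometric parameters
#'
#' Runs the Kruskal-Wallis omnibus test (with eta-squared effect size) and
#' Dunn's pairwise tests for each psychometric parameter across groups,
#' plus upper-quantile outlier flags on the threshold.
#'
#' @param fits A data frame with a `group` column and one column per
#'   parameter in `params`.
#' @param params Parameter columns to analyse.
#' @param outlier_q Quantile for threshold outlier flagging.
#' @return A list (one element per parameter) with `omnibus` (`kw_result`)
#'   and `pairwise` (`dunn_result`), plus `threshold_outliers` (a data
#'   frame of flagged participants) and `underpowered` (TRUE if any group
#'   has fewer than 2 observations).
#' @export
group_stats_report <- function(fits,
                               params = c("threshold", "slope", "lam",
                                          "gamma", "eta"),
                               outlier_q = 0.975) {
  stopifnot("group" %in% names(fits))
  groups_of <- function(col) split(fits[[col]], fits$group)
  out <- list()
  for (p in params) {
    if (!p %in% names(fits)) next
    gl <- lapply(groups_of(p), function(v) v[is.finite(v)])
    gl <- gl[lengths(gl) > 0]
    out[[p]] <- list(omnibus = kruskal_wallis(gl),
                     pairwise = suppressWarnings(dunn_test(gl)))
  }
  thr_ok <- is.finite(fits$threshold)
  flags <- rep(FALSE, nrow(fits))
  if (sum(thr_ok) >= 2) flags[thr_ok] <- flag_outliers(fits$threshold[thr_ok],
                                                       outlier_q)
  out$threshold_outliers <- fits[flags,
                                 intersect(c("participant", "participant_id",
                                             "group", "threshold"),
                                           names(fits)), drop = FALSE]
  out$underpowered <- any(table(fits$group) < 2)
  out
}
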