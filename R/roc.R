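#' Empirical ROC and AUC with DeLong confidence interval
#'
#' Nonparametric (trapezoidal / Mann-Whitney) AUC for discriminating cases
#' from controls on a scalar marker, oriented so that higher marker values
#' indicate a case: `AUC = U / (n_case * n_control)` with ties counted
#' one-half. Computed with the pROC package; the 95% CI uses DeLong's
#' method.
#'
#' @param cases Marker values (e.g. fitted intelligibility thresholds) in
#'   the case group.
#' @param controls Marker values in the control group.
#' @return An object of class `roc_result`: `auc`, `ci_lo`, `ci_hi`,
#'   `method = "empirical"`, `ci_method = "delong"` and `curve`, a data
#'   frame of (`fpr`, `tpr`) points from (0,0) to (1,1). If either group
#'   is a single repeated value the DeLong variance degenerates: the AUC
#'   is still returned but the CI is `NA` with a warning of class
#'   `undefined_ci`.
#' @export
empirical_auc <- function(cases, controls) {
  if (length(cases) == 0 || length(controls) == 0)
    stop("both groups must be non-empty", call. = FALSE)
  resp <- c(rep(0L, length(controls)), rep(1L, length(cases)))
  pred <- c(controls, cases)
  r <- pROC::roc(resp, pred, levels = c(0, 1), direction = "<", quiet = TRUE)
  auc <- as.numeric(pROC::auc(r))
  degenerate <- length(unique(cases)) == 1L && length(unique(controls)) == 1L
  ci <- if (degenerate) NULL else
    tryCatch(suppressWarnings(as.numeric(pROC::ci.auc(r, method = "delong"))),
             error = function(e) NULL)
  if (is.null(ci) || !all(is.finite(ci))) {
    warning(warningCondition("DeLong variance degenerate: CI undefined",
                             class = "undefined_ci"))
    ci <- c(NA_real_, auc, NA_real_)
  }
  co <- pROC::coords(r, "all", ret = c("specificity", "sensitivity"),
                     transpose = FALSE)
  curve <- data.frame(fpr = rev(1 - co$specificity), tpr = rev(co$sensitivity))
  structure(list(auc = auc, ci_lo = ci[1], ci_hi = ci[3],
                 method = "empirical", ci_method = "delong", curve = curve),
            class = "roc_result")
}

#' Binormal (parametric) AUC with bootstrap confidence interval
#'
#' Assumes Gaussian marker distributions in each group:
#' `AUC = Phi((mu_case - mu_control) / sqrt(sd_case^2 + sd_control^2))`
#' from the sample means and SDs. The 95% CI is a percentile bootstrap
#' (resampling both groups).
#'
#' @inheritParams empirical_auc
#' @param n_boot Bootstrap replicates for the CI.
#' @param seed Seed for the bootstrap.
#' @return An object of class `roc_result` with `method = "binormal"`,
#'   `ci_method = "bootstrap"` and a parametric (`fpr`, `tpr`) curve. Zero
#'   pooled variance yields `auc = NA` with a warning of class
#'   `undefined_auc`.
#' @export
binormal_auc <- function(cases, controls, n_boot = 2000, seed = 1L) {
  if (length(cases) < 2 || length(controls) < 2)
    stop("need >= 2 values per group for parametric estimates", call. = FALSE)
  bn <- function(ca, co) {
    s2 <- stats::var(ca) + stats::var(co)
    if (s2 <= 0) return(NA_real_)
    stats::pnorm((mean(ca) - mean(co)) / sqrt(s2))
  }
  auc <- bn(cases, controls)
  if (is.na(auc)) {
    warning(warningCondition("zero pooled variance: binormal AUC undefined",
                             class = "undefined_auc"))
    return(structure(list(auc = NA_real_, ci_lo = NA_real_, ci_hi = NA_real_,
                          method = "binormal", ci_method = "bootstrap",
                          curve = NULL),
                     class = "roc_result"))
  }
  boots <- withr::with_seed(seed, vapply(seq_len(n_boot), function(i) {
    bn(sample(cases, replace = TRUE), sample(controls, replace = TRUE))
  }, numeric(1)))
  ci <- stats::quantile(boots, c(0.025, 0.975), na.rm = TRUE, names = FALSE)
  ## binormal curve: TPR = Phi(a + b * qnorm(FPR)) with a = dmu/sd_case,
  ## b = sd_control/sd_case
  a <- (mean(cases) - mean(controls)) / stats::sd(cases)
  b <- stats::sd(controls) / stats::sd(cases)
  fpr <- seq(0, 1, length.out = 101)
  tpr <- stats::pnorm(a + b * stats::qnorm(fpr))
  tpr[1] <- 0; tpr[101] <- 1
  structure(list(auc = auc, ci_lo = ci[1], ci_hi = ci[2], method = "binormal",
                 ci_method = "bootstrap",
                 curve = data.frame(fpr = fpr, tpr = tpr)),
            class = "roc_result")
}

#' @export
print.roc_result <- function(x, ...) {
  cat(sprintf("ROC (%s): AUC = %.3f, 95%% CI (%.3f, %.3f) [%s]\n",
              x$method, x$auc, x$ci_lo, x$ci_hi, x$ci_method))
  invisible(x)
}
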