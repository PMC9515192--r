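#' Pixel-wise confusion counts
#'
#' @param predicted binary/logical mask of predicted positives.
#' @param truth binary/logical mask of true positives, same shape.
#' @param region optional evaluation region mask; counts are restricted to
#'   it.
#' @return An object of class `confusion_counts` with `tp`, `fp`, `fn`,
#'   `tn`.
#' @export
confusion_counts <- function(predicted, truth, region = NULL) {
  if (!all(dim2(predicted) == dim2(truth)))
    stop("predicted and truth shapes differ")
  p <- as.logical(predicted); y <- as.logical(truth)
  if (!is.null(region)) {
    if (!all(dim2(region) == dim2(predicted)))
      stop("evaluation region shape differs")
    keep <- as.logical(region)
    p <- p[keep]; y <- y[keep]
  }
  structure(list(tp = sum(p & y), fp = sum(p & !y),
                 fn = sum(!p & y), tn = sum(!p & !y)),
            class = "confusion_counts")
}

dim2 <- function(x) if (is.null(dim(x))) length(x) else dim(x)

#' Classification quality indicators
#'
#' Precision (fraction of predicted-positive pixels that are truly
#' positive), sensitivity (recall), specificity, accuracy, and the F1
#' score (harmonic mean of precision and sensitivity). Metrics with a zero
#' denominator are reported as `NA` (explicitly undefined), never silently
#' as 0 or 1.
#'
#' @param counts a [confusion_counts()].
#' @return An object of class `class_metrics`; fields are fractions in
#'   \[0, 1\] (multiply by 100 for percent).
#' @export
classification_metrics <- function(counts) {
  stopifnot(inherits(counts, "confusion_counts"))
  tp <- counts$tp; fp <- counts$fp; fn <- counts$fn; tn <- counts$tn
  rat <- function(a, b) if (b > 0) a / b else NA_real_
  precision <- rat(tp, tp + fp)
  sensitivity <- rat(tp, tp + fn)
  specificity <- rat(tn, tn + fp)
  accuracy <- rat(tp + tn, tp + fp + fn + tn)
  f1 <- if (!is.na(precision) && !is.na(sensitivity) &&
            precision + sensitivity > 0)
    2 * precision * sensitivity / (precision + sensitivity) else NA_real_
  structure(list(precision = precision, sensitivity = sensitivity,
                 specificity = specificity, accuracy = accuracy, f1 = f1),
            class = "class_metrics")
}

#' @export
print.class_metrics <- function(x, ...) {
  for (nm in names(x))
    cat(sprintf("%-12s %s\n", nm,
                if (is.na(x[[nm]])) "undefined" else sprintf("%.4f", x[[nm]])))
  invisible(x)
}

#' Spearman rank correlation test
#'
#' Rank correlation with average ranks for ties and a two-sided p-value:
#' exact by permutation enumeration for n <= 10, t-approximation above.
#'
#' @param x,y numeric vectors of equal length >= 3.
#' @return An object of class `correlation_result`: `rho`, `p_value`, `n`.
#' @export
spearman_test <- function(x, y) {
  if (length(x) != length(y)) stop("x and y lengths differ")
  n <- length(x)
  if (n < 3) stop("need at least 3 observations")
  if (sd(x) == 0 || sd(y) == 0)
    stop("constant vector: correlation undefined")
  rx <- rank(x); ry <- rank(y)
  rho <- cor(rx, ry)
  if (n <= 10) {
    p <- spearman_perm_pvalue_cpp(rx, ry)
  } else {
    tt <- rho * sqrt((n - 2) / max(1 - rho^2, 1e-12))
    p <- 2 * pt(-abs(tt), df = n - 2)
  }
  structure(list(rho = rho, p_value = min(p, 1), n = n),
            class = "correlation_result")
}

#' @export
print.correlation_result <- function(x, ...) {
  cat(sprintf("Spearman rho = %.3f, p = %.4g, n = %d\n",
              x$rho, x$p_value, x$n))
  invisible(x)
}

#' Disc-based dry-mass estimate of a log
#'
#' `dry mass log = (fresh mass log / fresh mass disc) * dry mass disc`:
#' the standard subsampling estimator where a short disc cut from the log
#' is dried and weighed, and its fresh:dry ratio is transferred to the
#' rest of the log.
#'
#' @param fresh_mass_log,fresh_mass_disc,dry_mass_disc masses in grams;
#'   vectors are accepted.
#' @return Estimated dry mass of the log in grams.
#' @export
estimate_log_dry_mass <- function(fresh_mass_log, fresh_mass_disc,
                                  dry_mass_disc) {
  if (any(fresh_mass_disc <= 0)) stop("fresh_mass_disc must be positive")
  if (any(fresh_mass_log <= 0) || any(dry_mass_disc <= 0))
    stop("masses must be positive")
  (fresh_mass_log / fresh_mass_disc) * dry_mass_disc
}

#' Relative dry-mass loss
#'
#' `100 * (initial - final) / initial` percent; negative values (apparent
#' mass gain) are allowed — they arise from subsampling error in the
#' disc-based initial-mass estimate.
#'
#' @param initial_dry,final_dry dry masses in grams.
#' @return Percent mass loss.
#' @export
relative_mass_loss <- function(initial_dry, final_dry) {
  if (any(initial_dry <= 0)) stop("initial dry mass must be positive")
  100 * (initial_dry - final_dry) / initial_dry
}
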