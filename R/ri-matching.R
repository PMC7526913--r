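#' Image contrast of a region of interest
#'
#' Contrast is the ratio of the maximum to the minimum gray value inside
#' the region of interest, the statistic used to score DIC images of
#' specimens across a dilution series of the mounting medium: the ratio
#' bottoms out when the medium's refractive index matches the specimen's.
#'
#' @param image 2D numeric matrix of gray values.
#' @param roi logical mask of the same dimensions, or a two-column matrix
#'   of (row, col) pixel indices.
#' @return max/min gray over the ROI (>= 1).
#' @export
image_contrast <- function(image, roi) {
  stopifnot(is.matrix(image))
  if (is.logical(roi)) {
    if (!identical(dim(roi), dim(image)))
      stop("logical roi must match image dimensions")
    vals <- image[roi]
  } else if (is.matrix(roi) && ncol(roi) == 2) {
    if (any(roi < 1) || any(roi[, 1] > nrow(image)) ||
        any(roi[, 2] > ncol(image)))
      stop("roi indices out of image bounds")
    vals <- image[roi]
  } else stop("roi must be a logical mask or an index matrix")
  if (length(vals) == 0) stop("roi is empty")
  mn <- min(vals)
  if (mn <= 0) stop("minimum gray value in roi must be > 0 ",
                    "(contrast max/min undefined at 0)")
  max(vals) / mn
}

#' Find the contrast-minimizing concentration
#'
#' Averages contrast replicates per concentration and returns the
#' concentration with the lowest mean — the estimated refractive-index
#' matching point. Exact ties are resolved toward the smallest
#' concentration and flagged.
#'
#' @param series a `contrast_series` (see [simulate_contrast_series()]).
#' @return A list with `concentration_pct` (the argmin), `tie` (logical),
#'   and `table`, a data frame of per-concentration mean contrast, sd and
#'   replicate count.
#' @export
find_matching_concentration <- function(series) {
  series <- as_contrast_series(series)
  agg <- stats::aggregate(contrast ~ concentration_pct, data = series,
                          FUN = function(v) c(mean = mean(v), sd = stats::sd(v),
                                              n = length(v)))
  tab <- data.frame(concentration_pct = agg$concentration_pct,
                    mean_contrast = agg$contrast[, "mean"],
                    sd_contrast = agg$contrast[, "sd"],
                    n = agg$contrast[, "n"])
  tab <- tab[order(tab$concentration_pct), , drop = FALSE]
  rownames(tab) <- NULL
  mmin <- min(tab$mean_contrast)
  at_min <- which(tab$mean_contrast == mmin)
  list(concentration_pct = tab$concentration_pct[at_min[1]],
       tie = length(at_min) > 1L,
       table = tab)
}

#' Welch's two-sample t-test
#'
#' Unequal-variance t-test with Welch-Satterthwaite degrees of freedom and
#' a two-sided p-value, with explicit handling of degenerate inputs (both
#' samples constant). The test statistic has the sign of
#' `mean(a) - mean(b)`.
#'
#' @param a,b numeric samples of size >= 2.
#' @return list with `t`, `df`, `p`.
#' @export
welch_t_test <- function(a, b) {
  if (length(a) < 2 || length(b) < 2)
    stop("each sample must have at least 2 observations")
  va <- stats::var(a); vb <- stats::var(b)
  if (va == 0 && vb == 0) {
    if (mean(a) == mean(b)) return(list(t = 0, df = Inf, p = 1))
    stop("both samples have zero variance but different means: ",
         "t statistic undefined")
  }
  ht <- stats::t.test(a, b, var.equal = FALSE)
  list(t = unname(ht$statistic), df = unname(ht$parameter),
       p = unname(ht$p.value))
}

#' Holm-Sidak step-down multiple-testing adjustment
#'
#' Step-down Sidak procedure applied to a family of m p-values: sort
#' ascending, adjust the i-th smallest to `1 - (1 - p)^(m - i + 1)`,
#' enforce monotonicity, and map back to the input order. This is the
#' adjustment used for the pairwise comparisons of each dilution against
#' the matched (30% iodixanol) group.
#'
#' @param pvalues raw p-values in \[0, 1\].
#' @param alpha family-wise error rate for the rejection flags.
#' @return list with `adjusted` p-values (input order) and `reject`.
#' @export
holm_sidak <- function(pvalues, alpha = 0.05) {
  if (any(pvalues < 0 | pvalues > 1)) stop("p-values must lie in [0, 1]")
  m <- length(pvalues)
  ord <- order(pvalues)
  ps <- pvalues[ord]
  adj <- 1 - (1 - ps)^(m - seq_len(m) + 1)
  adj <- cummax(adj)
  out <- numeric(m)
  out[ord] <- pmin(adj, 1)
  list(adjusted = out, reject = out <= alpha)
}

#' Summarize a contrast series against the matched concentration
#'
#' Convenience report for the RI-matching assay: per-concentration mean
#' contrast with 95% confidence intervals, plus Welch p-values of each
#' concentration against the contrast-minimizing one, Holm-Sidak adjusted.
#'
#' @param series a `contrast_series`.
#' @param alpha family-wise error rate.
#' @return A data frame, one row per concentration, with attribute
#'   `matched_concentration_pct`.
#' @export
ri_matching_report <- function(series, alpha = 0.05) {
  series <- as_contrast_series(series)
  fit <- find_matching_concentration(series)
  tab <- fit$table
  hw <- stats::qt(0.975, pmax(tab$n - 1, 1)) * tab$sd_contrast / sqrt(tab$n)
  tab$ci_lo <- tab$mean_contrast - hw
  tab$ci_hi <- tab$mean_contrast + hw
  ref <- series$contrast[series$concentration_pct == fit$concentration_pct]
  others <- setdiff(tab$concentration_pct, fit$concentration_pct)
  praw <- vapply(others, function(cc) {
    welch_t_test(series$contrast[series$concentration_pct == cc], ref)$p
  }, 0)
  adj <- holm_sidak(praw, alpha)
  tab$p_adj <- NA_real_
  tab$p_adj[match(others, tab$concentration_pct)] <- adj$adjusted
  attr(tab, "matched_concentration_pct") <- fit$concentration_pct
  tab
}
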