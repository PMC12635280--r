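## Statistical battery: logPDR histogram features, a self-contained
## Wilcoxon rank-sum test (exact enumeration for small untied samples,
## tie-corrected normal approximation otherwise), Pearson correlation,
## the iterative t-based Welch sample-size calculation, and a
## deterministic report assembler.

#' logPDR histogram features over a region
#'
#' Applies a base-10 log to the (positive, epsilon-floored) PDR values
#' of a region and summarises the distribution with its median, mode
#' and 10th percentile — chosen because PDR spans several orders of
#' magnitude with a heavy left mass. The mode is the centre of the
#' tallest Freedman-Diaconis histogram bin (ties to the lower bin).
#'
#' @param pdr_values Positive PDR values of the ROI.
#' @param roi_name Label recorded in the output.
#' @return List of class `logpdr_features`: `roi`, `median`, `mode`,
#'   `p10`, `n_voxels`.
#' @export
logpdr_features <- function(pdr_values, roi_name = "roi") {
  if (length(pdr_values) == 0) stop("empty ROI")
  if (any(pdr_values <= 0)) stop("PDR values must be > 0 (epsilon-floored upstream)")
  x <- log10(pdr_values)
  med <- stats::median(x)
  p10 <- stats::quantile(x, 0.10, names = FALSE)
  rng <- range(x)
  if (rng[1] == rng[2]) {
    mode <- x[1]
  } else {
    bw <- 2 * stats::IQR(x) / length(x)^(1 / 3)
    if (bw <= 0) bw <- diff(rng) / max(1, ceiling(sqrt(length(x))))
    breaks <- seq(rng[1], rng[2] + bw, by = bw)
    counts <- tabulate(findInterval(x, breaks, rightmost.closed = TRUE),
                       nbins = length(breaks) - 1)
    i <- which.max(counts) # which.max takes the first (lower) tie
    mode <- (breaks[i] + breaks[i + 1]) / 2
  }
  structure(list(roi = roi_name, median = med, mode = mode, p10 = p10,
                 n_voxels = length(pdr_values)),
            class = "logpdr_features")
}

#' Wilcoxon rank-sum test
#'
#' Rank-sum statistic of the first sample with midranks for ties.
#' Exact two-sided p by complete enumeration of rank assignments when
#' `min(n, m) <= 10` and there are no ties; otherwise a normal
#' approximation with tie correction and continuity correction.
#'
#' @param x,y Numeric samples (nonempty).
#' @param alternative Only "two.sided" is implemented.
#' @return List: `statistic` (rank sum of x), `p_value`, `n`, `m`,
#'   `method` ("exact" or "approximate").
#' @export
wilcoxon_ranksum <- function(x, y, alternative = "two.sided") {
  stopifnot(length(x) > 0, length(y) > 0)
  alternative <- match.arg(alternative, "two.sided")
  n <- length(x); m <- length(y)
  pooled <- c(x, y)
  r <- rank(pooled) # midranks
  w <- sum(r[seq_len(n)])
  ties <- any(duplicated(pooled))
  if (length(unique(pooled)) == 1) {
    warning("all pooled values identical; p = 1")
    return(list(statistic = w, p_value = 1, n = n, m = m,
                method = "degenerate"))
  }
  mu <- n * (n + m + 1) / 2
  if (!ties && min(n, m) <= 10 && choose(n + m, n) <= 5e5) {
    ## enumerate all C(n+m, n) assignments of ranks to the first sample
    combs <- utils::combn(n + m, n)
    ws <- colSums(matrix(seq_len(n + m)[combs], nrow = n))
    p <- mean(abs(ws - mu) >= abs(w - mu) - 1e-9)
    method <- "exact"
  } else {
    tie_tab <- table(pooled)
    sigma2 <- n * m / 12 *
      ((n + m + 1) - sum(tie_tab^3 - tie_tab) / ((n + m) * (n + m - 1)))
    z <- (abs(w - mu) - 0.5) / sqrt(sigma2)
    p <- min(1, 2 * stats::pnorm(z, lower.tail = FALSE))
    method <- "approximate"
  }
  list(statistic = w, p_value = p, n = n, m = m, method = method)
}

#' Pearson correlation with t-based p value
#'
#' @param a,b Numeric vectors, length >= 3, both nonconstant.
#' @return List: `r`, `p_value`, `n`.
#' @export
pearson_corr <- function(a, b) {
  stopifnot(length(a) == length(b))
  n <- length(a)
  if (n < 3) stop("need n >= 3")
  if (stats::sd(a) == 0 || stats::sd(b) == 0)
    stop("correlation undefined for constant input")
  r <- sum((a - mean(a)) * (b - mean(b))) /
    sqrt(sum((a - mean(a))^2) * sum((b - mean(b))^2))
  r <- max(-1, min(1, r))
  tstat <- r * sqrt((n - 2) / max(1 - r^2, .Machine$double.eps))
  p <- 2 * stats::pt(abs(tstat), df = n - 2, lower.tail = FALSE)
  list(r = r, p_value = min(1, p), n = n)
}

#' Welch two-sample sample size (iterative t-based)
#'
#' Smallest equal per-group n >= 2 with
#' `n >= (t_{1-a/2, nu} + t_{power, nu})^2 (sd1^2 + sd2^2) / delta^2`,
#' where nu is the Welch-Satterthwaite degrees of freedom evaluated at
#' the current n, iterated to a fixed point. A z-quantile mode is
#' available for comparison; it returns a smaller n because the normal
#' quantiles understate the t tails at moderate df.
#'
#' @param mean1,sd1,mean2,sd2 Group summaries (sd > 0, means differ).
#' @param alpha Two-sided significance level. Default 0.05.
#' @param power Target power. Default 0.80.
#' @param use_t Iterative t-based calculation (default) or single-shot
#'   z approximation.
#' @return Integer n per group.
#' @export
welch_sample_size <- function(mean1, sd1, mean2, sd2,
                              alpha = 0.05, power = 0.80, use_t = TRUE) {
  if (sd1 <= 0 || sd2 <= 0) stop("standard deviations must be > 0")
  if (mean1 == mean2) stop("no finite n can separate equal means")
  if (alpha <= 0 || alpha >= 1 || power <= 0 || power >= 1)
    stop("alpha and power must be in (0, 1)")
  delta2 <- (mean1 - mean2)^2
  v <- sd1^2 + sd2^2
  n <- max(2, ceiling((stats::qnorm(1 - alpha / 2) + stats::qnorm(power))^2 *
                        v / delta2))
  if (!use_t) return(as.integer(n))
  for (i in 1:200) {
    nu <- welch_satterthwaite_df(sd1, n, sd2, n)
    n_new <- max(2, ceiling((stats::qt(1 - alpha / 2, nu) +
                               stats::qt(power, nu))^2 * v / delta2))
    if (n_new == n) break
    n <- n_new
  }
  as.integer(n)
}

#' Welch-Satterthwaite degrees of freedom
#' @param sd1,n1,sd2,n2 Group SDs and sizes.
#' @return Effective df.
#' @export
welch_satterthwaite_df <- function(sd1, n1, sd2, n2) {
  a <- sd1^2 / n1; b <- sd2^2 / n2
  (a + b)^2 / (a^2 / (n1 - 1) + b^2 / (n2 - 1))
}

#' Assemble the statistics report
#'
#' Deterministic summary of a pipeline run: per-algorithm TIZ-versus-
#' contralateral and TIZ-versus-rest-of-edema tests, logPDR features,
#' cross-algorithm Dice, thresholds, and (when a covariate table is
#' supplied) feature-covariate correlations. Significance level 0.05
#' recorded.
#'
#' @param tiz_pdr_values,contralateral_pdr_values,edema_rest_pdr_values
#'   PDR value vectors for the tested regions.
#' @param thresholds Named list of computed thresholds
#'   (theta_tiz, thr_ncbv, thr_ktrans).
#' @param dice_cross_algorithm Scalar or NA.
#' @param covariates Optional data.frame with numeric covariate columns
#'   aligned to `feature_values` rows (generic subject-level use).
#' @param feature_values Optional data.frame of logPDR features per
#'   subject for the correlation block.
#' @param log_base Recorded log base for the features. Default 10.
#' @return List of class `stats_report` (JSON-serialisable).
#' @export
build_report <- function(tiz_pdr_values, contralateral_pdr_values,
                         edema_rest_pdr_values = NULL,
                         thresholds = list(),
                         dice_cross_algorithm = NA_real_,
                         covariates = NULL, feature_values = NULL,
                         log_base = 10) {
  test_tiz_contra <- wilcoxon_ranksum(tiz_pdr_values,
                                      contralateral_pdr_values)
  test_tiz_edema <- if (!is.null(edema_rest_pdr_values) &&
                        length(edema_rest_pdr_values) > 0)
    wilcoxon_ranksum(tiz_pdr_values, edema_rest_pdr_values) else NULL
  feats <- list(
    tiz = logpdr_features(tiz_pdr_values, "tiz"),
    contralateral = logpdr_features(contralateral_pdr_values,
                                    "contralateral")
  )
  correlations <- NULL
  if (!is.null(covariates) && !is.null(feature_values)) {
    correlations <- list()
    for (cv in names(covariates)) {
      for (ft in names(feature_values)) {
        ok <- is.finite(covariates[[cv]]) & is.finite(feature_values[[ft]])
        if (sum(ok) >= 3 && stats::sd(covariates[[cv]][ok]) > 0 &&
            stats::sd(feature_values[[ft]][ok]) > 0) {
          correlations[[paste(ft, cv, sep = "_vs_")]] <-
            pearson_corr(feature_values[[ft]][ok], covariates[[cv]][ok])
        }
      }
    }
  } else if (!is.null(feature_values) && is.null(covariates)) {
    correlations <- list(absent = TRUE)
  }
  structure(list(
    alpha = 0.05,
    log_base = log_base,
    tests = list(tiz_vs_contralateral = test_tiz_contra,
                 tiz_vs_rest_of_edema = test_tiz_edema),
    features = feats,
    thresholds = thresholds,
    dice_cross_algorithm = dice_cross_algorithm,
    correlations = correlations
  ), class = "stats_report")
}
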