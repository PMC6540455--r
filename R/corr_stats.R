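#' Correlation coefficient with significance
#'
#' The statistical kernel of every screening stage: the sample Pearson
#' product-moment coefficient (or Spearman's rank coefficient, i.e.
#' Pearson on mid-ranks) together with a two-sided p-value from the
#' classical t transformation, `t = r * sqrt((n - 2) / (1 - r^2))`
#' referred to a central t distribution with `n - 2` degrees of freedom.
#' No multiple-testing correction is applied anywhere in the package's
#' screens — the thresholds are raw, and callers that screen many
#' features report the implied expected false-positive count.
#'
#' @param x,y numeric vectors of equal length `n >= 3` with nonzero
#'   variance (for Spearman: nonzero rank variance).
#' @param method `"pearson"` or `"spearman"`.
#' @return a one-row data.frame with columns `r`, `p`, `n`.
#' @examples
#' cor_record(c(1, 2, 3, 4, 5), c(1, 3, 2, 5, 4))  # r = 0.8
#' @export
cor_record <- function(x, y, method = c("pearson", "spearman")) {
  method <- match.arg(method)
  stopifnot(length(x) == length(y))
  n <- length(x)
  if (n < 3) stop("need n >= 3 paired observations", call. = FALSE)
  if (any(!is.finite(x)) || any(!is.finite(y)))
    stop("non-finite values in input", call. = FALSE)
  if (method == "spearman") {
    x <- rank(x); y <- rank(y)  # mid-ranks for ties
  }
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("degenerate input: zero variance", call. = FALSE)
  r <- stats::cor(x, y)
  data.frame(r = r, p = cor_pvalue(r, n), n = n)
}

#' Two-sided p-value for a correlation coefficient
#'
#' Exact under bivariate normality for testing zero correlation:
#' `t = r * sqrt((n - 2) / (1 - r^2))`, `p = 2 * P(T_{n-2} > |t|)`.
#' At `|r| == 1` the t statistic is infinite; the smallest positive
#' double is returned so that downstream strict `p < p_max` filters
#' behave sensibly.
#'
#' @param r correlation coefficient(s) in `[-1, 1]`; vectorised.
#' @param n paired sample count, `n >= 3`.
#' @return p-value(s) in `(0, 1]`.
#' @export
cor_pvalue <- function(r, n) {
  if (any(n < 3)) stop("need n >= 3", call. = FALSE)
  if (any(abs(r) > 1 + 1e-12, na.rm = TRUE))
    stop("|r| > 1", call. = FALSE)
  r <- pmin(1, pmax(-1, r))
  p <- ifelse(abs(r) == 1,
              .Machine$double.xmin,
              2 * stats::pt(-abs(r) * sqrt((n - 2) / (1 - r^2)), df = n - 2))
  pmin(p, 1)
}

#' Effective |r| cutoff implied by a p-value threshold
#'
#' Inverts the t map: the smallest `|r|` for which the two-sided p at
#' `n` paired samples falls below `p_max`. With few samples this is the
#' binding constraint of a joint `|r| >= r_min AND p < p_max` screen
#' (e.g. at `n = 6`, `p < 0.05` requires `|r| > 0.811`, well above an
#' `r_min` of 0.5).
#'
#' @param n paired sample count.
#' @param p_max two-sided significance threshold.
#' @return the implied cutoff on `|r|`.
#' @examples
#' effective_r_cutoff(6, 0.05)
#' @export
effective_r_cutoff <- function(n, p_max) {
  stopifnot(n >= 3, p_max > 0, p_max < 1)
  t_crit <- stats::qt(1 - p_max / 2, df = n - 2)
  t_crit / sqrt(n - 2 + t_crit^2)
}

#' Correlate every feature of a matrix against a reference profile
#'
#' One record per feature, input order preserved. Zero-variance
#' features are not errors at matrix scale: they are flagged
#' (`degenerate = TRUE`, `r`/`p` set to `NA`) and excluded by
#' downstream screens, with a count reported via a message, so that
#' runs over accession-scale matrices survive constant probes.
#'
#' @param m an [expr_matrix()] (or plain matrix with rownames).
#' @param ref numeric reference vector, one value per sample of `m`.
#' @param method `"pearson"` or `"spearman"`.
#' @return data.frame with columns `feature_id`, `r`, `p`, `n`,
#'   `degenerate`.
#' @export
cor_to_reference <- function(m, ref, method = c("pearson", "spearman")) {
  method <- match.arg(method)
  v <- if (is_expr_matrix(m)) .values(m) else as.matrix(m)
  if (length(ref) != ncol(v))
    stop("length(ref) must equal the sample count of m", call. = FALSE)
  n <- ncol(v)
  if (n < 3) stop("need >= 3 samples", call. = FALSE)
  if (method == "spearman") {
    v <- t(apply(v, 1, rank))
    ref <- rank(ref)
  }
  if (stats::sd(ref) == 0)
    stop("degenerate reference: zero variance", call. = FALSE)
  degenerate <- apply(v, 1, stats::sd) == 0
  r <- rep(NA_real_, nrow(v))
  if (any(!degenerate))
    r[!degenerate] <- drop(stats::cor(t(v[!degenerate, , drop = FALSE]), ref))
  p <- rep(NA_real_, nrow(v))
  p[!degenerate] <- cor_pvalue(r[!degenerate], n)
  if (any(degenerate))
    message(sprintf("cor_to_reference: %d zero-variance feature(s) flagged",
                    sum(degenerate)))
  data.frame(feature_id = rownames(v), r = r, p = p, n = n,
             degenerate = degenerate, stringsAsFactors = FALSE)
}
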