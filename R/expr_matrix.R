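#' Expression matrix container
#'
#' A lightweight features-by-samples numeric matrix used throughout the
#' package. Rows are features (exon-array probesets or gene symbols),
#' columns are samples. Values are normalized expression on whatever
#' scale the platform delivers (log2 intensity for arrays, CPM for
#' RNA-seq); the `scale` tag records which, so that stages with scale
#' requirements (log-ratio profiles, the cumulative-proportion
#' transform) can refuse unsuitable input instead of silently computing
#' nonsense.
#'
#' Invariants enforced at construction: unique, non-empty, case-sensitive
#' feature and sample identifiers (surrounding whitespace is trimmed);
#' all values finite. Missing values are a hard error — every downstream
#' correlation then has an unambiguous paired sample count.
#'
#' @param values numeric matrix, features in rows, samples in columns.
#'   Row and column names supply the identifiers unless `feature_ids` /
#'   `sample_ids` are given.
#' @param feature_ids,sample_ids optional character vectors overriding
#'   the dimnames of `values`.
#' @param scale `"log"` or `"linear"`.
#' @param platform free-text platform label carried along for provenance.
#' @return an object of class `expr_matrix`: a numeric matrix with
#'   attributes `scale_tag` and `platform_tag`.
#' @examples
#' m <- expr_matrix(matrix(rnorm(6), 3, 2,
#'                         dimnames = list(c("p1", "p2", "p3"),
#'                                         c("s1", "s2"))))
#' dim(m)
#' @export
expr_matrix <- function(values, feature_ids = NULL, sample_ids = NULL,
                        scale = c("log", "linear"), platform = "") {
  scale <- match.arg(scale)
  if (!is.matrix(values) || !is.numeric(values))
    stop("`values` must be a numeric matrix", call. = FALSE)
  if (is.null(feature_ids)) feature_ids <- rownames(values)
  if (is.null(sample_ids)) sample_ids <- colnames(values)
  if (is.null(feature_ids) || is.null(sample_ids))
    stop("feature and sample identifiers are required", call. = FALSE)
  feature_ids <- trimws(as.character(feature_ids))
  sample_ids <- trimws(as.character(sample_ids))
  if (length(feature_ids) != nrow(values))
    stop("length(feature_ids) != nrow(values)", call. = FALSE)
  if (length(sample_ids) != ncol(values))
    stop("length(sample_ids) != ncol(values)", call. = FALSE)
  .check_unique(feature_ids, "feature")
  .check_unique(sample_ids, "sample")
  bad <- which(!is.finite(values), arr.ind = TRUE)
  if (nrow(bad) > 0)
    stop(sprintf("non-finite value at feature '%s', sample '%s'",
                 feature_ids[bad[1, 1]], sample_ids[bad[1, 2]]),
         call. = FALSE)
  dimnames(values) <- list(feature_ids, sample_ids)
  structure(values, scale_tag = scale, platform_tag = platform,
            class = c("expr_matrix", "matrix", "array"))
}

.check_unique <- function(ids, what) {
  if (any(!nzchar(ids)))
    stop(sprintf("empty %s identifier", what), call. = FALSE)
  dup <- ids[duplicated(ids)]
  if (length(dup) > 0)
    stop(sprintf("duplicate %s identifier: '%s'", what, dup[1]),
         call. = FALSE)
  invisible(TRUE)
}

#' @export
`[.expr_matrix` <- function(x, i, j, ..., drop = FALSE) {
  out <- NextMethod(drop = drop)
  if (is.matrix(out))
    out <- structure(out,
                     scale_tag = attr(x, "scale_tag"),
                     platform_tag = attr(x, "platform_tag"),
                     class = class(x))
  out
}

#' @export
print.expr_matrix <- function(x, ...) {
  cat(sprintf("expr_matrix: %d features x %d samples [%s scale%s]\n",
              nrow(x), ncol(x), attr(x, "scale_tag"),
              if (nzchar(attr(x, "platform_tag")))
                paste0(", ", attr(x, "platform_tag")) else ""))
  n_r <- min(nrow(x), 5L); n_c <- min(ncol(x), 6L)
  print(unclass(x)[seq_len(n_r), seq_len(n_c), drop = FALSE], ...)
  if (nrow(x) > n_r || ncol(x) > n_c)
    cat(sprintf("... (%d more features, %d more samples)\n",
                nrow(x) - n_r, ncol(x) - n_c))
  invisible(x)
}

#' @rdname expr_matrix
#' @param x object to test.
#' @export
is_expr_matrix <- function(x) inherits(x, "expr_matrix")

# strip class but keep dimnames; internal convenience
.values <- function(m) {
  attr(m, "scale_tag") <- NULL
  attr(m, "platform_tag") <- NULL
  unclass(m)
}

scale_tag <- function(m) attr(m, "scale_tag")
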