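#' Ward/Euclidean hierarchical clustering
#'
#' Agglomerative clustering of the rows of `points` under Ward's
#' minimum-variance criterion with Euclidean distance: at each step the
#' pair of clusters whose merge least increases the total within-cluster
#' sum of squares is joined. Dispatches to [stats::hclust()] with
#' `method = "ward.D2"`, whose merge heights equal
#' `sqrt(2 * delta-ESS)` of each merge, so heights are non-decreasing.
#' Leaves are reordered smaller-subtree-first for reproducible heatmap
#' export.
#'
#' @param points numeric matrix, items in rows (an [expr_matrix()] works;
#'   cluster samples by passing `t(m)`).
#' @return an object of class `hclust` (merge matrix, heights, labels).
#' @export
ward_linkage <- function(points) {
  v <- if (is_expr_matrix(points)) .values(points) else as.matrix(points)
  if (nrow(v) < 2) stop("need >= 2 items to cluster", call. = FALSE)
  if (any(!is.finite(v))) stop("non-finite values", call. = FALSE)
  stats::hclust(stats::dist(v, method = "euclidean"), method = "ward.D2")
}

#' Cut a dendrogram into a named k-way partition
#'
#' Undoes the last `k - 1` merges of the tree. When a driver reference
#' vector is supplied (one value per item), clusters are ranked by their
#' mean reference value, high first (ties broken by cluster size), and
#' named accordingly: `"high"`, `"medium"`, `"low"` for `k = 3` — the
#' conventional partition of tumours by driver expression — otherwise
#' `"rank1"`, `"rank2"`, ...
#'
#' @param tree an `hclust` object from [ward_linkage()].
#' @param k number of clusters, `2 <= k <=` leaf count.
#' @param reference optional numeric vector, named by item or in tree
#'   label order, used to rank and name the clusters.
#' @return list with `labels` (integer cluster index per item, named),
#'   `k`, `ranked` (cluster indices ordered by descending mean
#'   reference, or `NULL`), `names` (per-item cluster name, or `NULL`).
#' @export
cut_partition <- function(tree, k, reference = NULL) {
  stopifnot(inherits(tree, "hclust"))
  n <- length(tree$labels %||% tree$order)
  if (k < 1 || k > n) stop("invalid k", call. = FALSE)
  labels <- stats::cutree(tree, k = k)
  ranked <- cluster_names <- NULL
  if (!is.null(reference) && k >= 1) {
    if (!is.null(names(reference)) && !is.null(names(labels)))
      reference <- reference[names(labels)]
    if (length(reference) != length(labels))
      stop("reference length must match item count", call. = FALSE)
    means <- tapply(reference, labels, mean)
    sizes <- tapply(reference, labels, length)
    ranked <- order(-means, -sizes)  # cluster indices, high mean first
    rank_of <- match(labels, ranked)
    nm <- if (k == 3) c("high", "medium", "low") else
      paste0("rank", seq_len(k))
    cluster_names <- stats::setNames(nm[rank_of], names(labels))
  }
  list(labels = labels, k = k, ranked = ranked, names = cluster_names)
}

#' Log-ratio expression profiles
#'
#' Centres every gene row of a log-scale matrix by its median (or mean)
#' across samples, turning log expression into the log ratio to the
#' gene's typical sample — the profile form used for sample-similarity
#' heatmaps. Linear-scale input is refused: take log2 first.
#'
#' Note that centring genes does not in general leave between-sample
#' Pearson correlations (computed across genes) unchanged; it does only
#' when all gene centres are equal.
#'
#' @param m a log-scale [expr_matrix()].
#' @param center `"median"` (default) or `"mean"`.
#' @return an [expr_matrix()] of centred rows (log scale).
#' @export
log_ratio_profiles <- function(m, center = c("median", "mean")) {
  center <- match.arg(center)
  stopifnot(is_expr_matrix(m))
  if (scale_tag(m) != "log")
    stop("log_ratio_profiles needs log-scale input; log-transform first",
         call. = FALSE)
  v <- .values(m)
  ctr <- if (center == "median") apply(v, 1, stats::median) else
    rowMeans(v)
  expr_matrix(v - ctr, scale = "log",
              platform = attr(m, "platform_tag") %||% "")
}

#' Sample-by-sample correlation matrix
#'
#' Symmetric matrix with unit diagonal whose `(i, j)` entry is the
#' Pearson (or Spearman) correlation of the expression vectors of
#' samples `i` and `j` across all features. A constant sample vector
#' has no defined correlation: its row and column are `NA` (diagonal
#' kept at 1) and a message reports the flagged samples.
#'
#' @param m an [expr_matrix()] (features x samples).
#' @param method `"pearson"` or `"spearman"`.
#' @return square numeric matrix, sample ids on both dimnames.
#' @export
sample_cor_matrix <- function(m, method = c("pearson", "spearman")) {
  method <- match.arg(method)
  v <- if (is_expr_matrix(m)) .values(m) else as.matrix(m)
  if (ncol(v) < 2) stop("need >= 2 samples", call. = FALSE)
  const <- apply(v, 2, stats::sd) == 0
  cc <- suppressWarnings(stats::cor(v, method = method))
  if (any(const)) {
    cc[const, ] <- NA_real_
    cc[, const] <- NA_real_
    message(sprintf("sample_cor_matrix: %d constant sample(s) flagged",
                    sum(const)))
  }
  diag(cc) <- 1
  cc[] <- (cc + t(cc)) / 2  # enforce exact symmetry
  cc
}
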