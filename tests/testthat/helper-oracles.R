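# Independent oracles used across the suite. These deliberately avoid
# the package's own code paths: plain-formula Pearson, exhaustive
# permutation enumeration, and a naive recompute-all-variances Ward.

# Pearson by the raw deviation-cross-product formula
naive_pearson <- function(x, y) {
  dx <- x - mean(x); dy <- y - mean(y)
  sum(dx * dy) / sqrt(sum(dx^2) * sum(dy^2))
}

all_permutations <- function(v) {
  if (length(v) == 1) return(list(v))
  out <- vector("list", 0)
  for (i in seq_along(v))
    for (rest in all_permutations(v[-i]))
      out[[length(out) + 1]] <- c(v[i], rest)
  out
}

# exact two-sided permutation p-value for zero correlation
perm_pvalue <- function(x, y) {
  r_obs <- abs(naive_pearson(x, y))
  rs <- vapply(all_permutations(y),
               function(yy) abs(naive_pearson(x, yy)), numeric(1))
  mean(rs >= r_obs - 1e-12)
}

# naive O(n^3) Ward: at each step recompute every pairwise increase in
# total within-cluster sum of squares and merge the minimum.
# Returns hclust-comparable merge rows and heights sqrt(2 * deltaESS).
naive_ward <- function(x) {
  x <- as.matrix(x)
  n <- nrow(x)
  clusters <- lapply(seq_len(n), identity)
  ids <- -seq_len(n)
  merge <- matrix(0L, n - 1, 2)
  d_ess <- numeric(n - 1)
  for (step in seq_len(n - 1)) {
    m <- length(clusters)
    best <- NULL; best_d <- Inf
    for (i in seq_len(m - 1)) for (j in (i + 1):m) {
      ci <- colMeans(x[clusters[[i]], , drop = FALSE])
      cj <- colMeans(x[clusters[[j]], , drop = FALSE])
      ni <- length(clusters[[i]]); nj <- length(clusters[[j]])
      d <- ni * nj / (ni + nj) * sum((ci - cj)^2)
      if (d < best_d) { best_d <- d; best <- c(i, j) }
    }
    i <- best[1]; j <- best[2]
    merge[step, ] <- sort(c(ids[i], ids[j]))
    d_ess[step] <- best_d
    clusters[[i]] <- c(clusters[[i]], clusters[[j]])
    ids[i] <- step
    clusters[[j]] <- NULL
    ids <- ids[-j]
  }
  list(merge = merge, height = sqrt(2 * d_ess))
}

# normalize an hclust merge matrix for comparison
norm_merge <- function(m) t(apply(m, 1, sort))

# small expr_matrix builder
toy_matrix <- function(values, features = NULL, samples = NULL,
                       scale = "log") {
  if (is.null(features)) features <- paste0("f", seq_len(nrow(values)))
  if (is.null(samples)) samples <- paste0("s", seq_len(ncol(values)))
  expr_matrix(as.matrix(values), feature_ids = features,
              sample_ids = samples, scale = scale)
}
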