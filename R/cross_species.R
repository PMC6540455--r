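#' Cumulative-proportion transform for cross-platform comparison
#'
#' Maps each sample's expression values onto `[0, 1)` by their
#' cumulative share of the sample total: values are sorted in
#' decreasing order and the gene at sorted position `i` receives
#' `1 - cumsum_i / total`. The most expressed gene therefore gets the
#' largest transformed value and the least expressed gene approaches
#' (or reaches) 0. The transform depends only on within-sample ranks
#' and relative magnitudes, so it is exactly invariant to positive
#' per-sample scaling — the property that makes heterogeneous
#' platforms comparable.
#'
#' Tied input values all receive the value computed at the end of
#' their tie block, making the result deterministic and independent of
#' input order; a fully constant sample maps to all zeros.
#'
#' Input must be on a linear, non-negative scale. Log-scale matrices
#' are refused unless `from_log2 = TRUE`, which de-logs (`2^x`) first:
#' the transform is meaningless on log values, and silent
#' auto-detection is deliberately not attempted.
#'
#' @param m an [expr_matrix()] with non-negative values (after
#'   de-logging), every sample with a positive total.
#' @param from_log2 de-log a log2-scale matrix before transforming.
#' @return an [expr_matrix()] of transformed values in `[0, 1)`,
#'   linear scale, original gene order.
#' @examples
#' m <- expr_matrix(matrix(c(1, 2, 3, 4), 4, 1,
#'                         dimnames = list(paste0("g", 1:4), "s1")),
#'                  scale = "linear")
#' cumulative_proportion_transform(m)[, 1]  # 0.0 0.1 0.3 0.6
#' @export
cumulative_proportion_transform <- function(m, from_log2 = FALSE) {
  stopifnot(is_expr_matrix(m))
  v <- .values(m)
  if (scale_tag(m) == "log") {
    if (!from_log2)
      stop(paste("log-scale input: the transform requires linear values;",
                 "set from_log2 = TRUE to de-log (2^x) first"),
           call. = FALSE)
    v <- 2^v
  }
  if (any(v < 0))
    stop("negative values: de-log or shift the input first", call. = FALSE)
  out <- apply(v, 2, .cpt_one_sample)
  if (!is.matrix(out)) out <- matrix(out, nrow(v), ncol(v))
  dimnames(out) <- dimnames(v)
  expr_matrix(out, scale = "linear",
              platform = attr(m, "platform_tag") %||% "")
}

.cpt_one_sample <- function(x) {
  total <- sum(x)
  if (total <= 0) stop("zero-total sample", call. = FALSE)
  ord <- order(x, decreasing = TRUE)
  trans_sorted <- 1 - cumsum(x[ord]) / total
  # ties take the value at the end of their block (the minimum within it)
  val <- trans_sorted
  i <- length(val)
  while (i >= 1) {
    j <- i
    while (j > 1 && x[ord][j - 1] == x[ord][j]) j <- j - 1
    val[j:i] <- trans_sorted[i]
    i <- j - 1
  }
  out <- numeric(length(x))
  out[ord] <- val
  out
}

#' Restrict two gene-level matrices to their shared genes
#'
#' Both matrices are subset to the intersection of their gene symbols
#' and reordered identically (the order of the first matrix). The
#' intersection size is reported via a message; an empty intersection
#' is an error.
#'
#' @param a,b gene-level [expr_matrix()] objects.
#' @return list of the two restricted matrices (`a`, `b`).
#' @export
intersect_shared_genes <- function(a, b) {
  stopifnot(is_expr_matrix(a), is_expr_matrix(b))
  shared <- intersect(rownames(a), rownames(b))
  if (length(shared) == 0) stop("no shared genes", call. = FALSE)
  message(sprintf("intersect_shared_genes: %d shared gene(s)",
                  length(shared)))
  list(a = a[shared, ], b = b[shared, ])
}

#' Pair orthologous genes across species into a combined cohort
#'
#' Rows are restricted to ortholog pairs whose first symbol is present
#' in `h` and second symbol in `m`; the two matrices' columns are then
#' concatenated. Row identifiers carry both symbols
#' (`"HUMAN|Mouse"`). The pairing depends only on symbol sets, not row
#' order. Inputs are expected to be already within-species intersected
#' and transformed onto a common scale (see
#' [cumulative_proportion_transform()]).
#'
#' @param h matrix for the first species (symbols match `map$symbol_a`).
#' @param m matrix for the second species (symbols match
#'   `map$symbol_b`).
#' @param map an [ortholog_map()].
#' @param datasets optional character vector (length = total samples)
#'   of dataset-of-origin labels.
#' @return a `combined_cohort`: list with `matrix` ([expr_matrix()],
#'   paired genes x all samples), `species` (per-sample label),
#'   `dataset` (per-sample label), `pairs` (data.frame of the retained
#'   symbol pairs).
#' @export
pair_orthologs <- function(h, m, map, datasets = NULL) {
  stopifnot(is_expr_matrix(h), is_expr_matrix(m),
            inherits(map, "ortholog_map"))
  keep <- map$symbol_a %in% rownames(h) & map$symbol_b %in% rownames(m)
  if (!any(keep)) stop("no ortholog pair present in both matrices",
                       call. = FALSE)
  pairs <- map[keep, , drop = FALSE]
  hv <- .values(h)[pairs$symbol_a, , drop = FALSE]
  mv <- .values(m)[pairs$symbol_b, , drop = FALSE]
  vals <- cbind(hv, mv)
  rownames(vals) <- paste(pairs$symbol_a, pairs$symbol_b, sep = "|")
  sp <- attr(map, "species")
  species <- c(rep(sp[1], ncol(hv)), rep(sp[2], ncol(mv)))
  if (is.null(datasets)) datasets <- species
  if (length(datasets) != ncol(vals))
    stop("datasets must label every sample", call. = FALSE)
  structure(list(matrix = expr_matrix(vals, scale = "linear",
                                      platform = "combined"),
                 species = stats::setNames(species, colnames(vals)),
                 dataset = stats::setNames(datasets, colnames(vals)),
                 pairs = data.frame(pairs, row.names = NULL)),
            class = "combined_cohort")
}

#' @export
print.combined_cohort <- function(x, ...) {
  cat(sprintf("combined_cohort: %d ortholog pairs x %d samples (%s)\n",
              nrow(x$matrix), ncol(x$matrix),
              paste(sprintf("%d %s", table(x$species),
                            names(table(x$species))), collapse = ", ")))
  invisible(x)
}

#' Transcriptome-wide sample correlogram of a combined cohort
#'
#' Spearman (default) sample-by-sample correlation matrix over all
#' paired genes, with a summary of the mean off-diagonal correlation
#' within each species and between species — the quantitative
#' cross-species comparison.
#'
#' @param cohort a [pair_orthologs()] result.
#' @param method `"spearman"` (default) or `"pearson"`.
#' @return list with `matrix` (square correlation matrix) and
#'   `summary` (named means: one per species, plus `between`).
#' @export
correlogram <- function(cohort, method = c("spearman", "pearson")) {
  method <- match.arg(method)
  stopifnot(inherits(cohort, "combined_cohort"))
  cc <- sample_cor_matrix(cohort$matrix, method = method)
  sp <- cohort$species
  off <- upper.tri(cc)
  same <- outer(sp, sp, "==")
  sums <- c()
  for (s in unique(sp)) {
    within <- outer(sp == s, sp == s, "&") & off
    sums[paste0("within_", s)] <- mean(cc[within], na.rm = TRUE)
  }
  sums["between"] <- mean(cc[!same & off], na.rm = TRUE)
  list(matrix = cc, summary = sums)
}

#' Per-sample transformed levels of one ortholog pair
#'
#' Extracts the transformed expression of a single gene pair across
#' the cohort, with species labels and the per-species median and IQR
#' (the summary conventionally plotted for a driver gene). A species
#' with a single sample has an undefined spread; its IQR is reported
#' as 0 and flagged.
#'
#' @param cohort a [pair_orthologs()] result.
#' @param symbol_a,symbol_b the pair's symbols (first/second species).
#' @return list with `table` (data.frame `sample`, `species`,
#'   `dataset`, `value`) and `stats` (data.frame `species`, `median`,
#'   `iqr`, `n`, `iqr_defined`).
#' @export
extract_gene_levels <- function(cohort, symbol_a, symbol_b) {
  stopifnot(inherits(cohort, "combined_cohort"))
  id <- paste(symbol_a, symbol_b, sep = "|")
  if (!id %in% rownames(cohort$matrix))
    stop(sprintf("gene pair '%s' absent from cohort", id), call. = FALSE)
  vals <- .values(cohort$matrix)[id, ]
  tab <- data.frame(sample = names(vals), species = unname(cohort$species),
                    dataset = unname(cohort$dataset), value = unname(vals),
                    stringsAsFactors = FALSE)
  st <- do.call(rbind, lapply(split(tab, tab$species), function(d) {
    n <- nrow(d)
    data.frame(species = d$species[1],
               median = stats::median(d$value),
               iqr = if (n > 1) stats::IQR(d$value, type = 7) else 0,
               n = n, iqr_defined = n > 1,
               stringsAsFactors = FALSE)
  }))
  rownames(st) <- NULL
  list(table = tab, stats = st)
}
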