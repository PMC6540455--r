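#' Screening thresholds for a driver-correlation signature
#'
#' @param r_min threshold on the absolute correlation coefficient,
#'   applied inclusively (`|r| >= r_min`) in both the probe screen and
#'   the gene filter. Default 0.5.
#' @param p_max two-sided significance threshold, applied strictly
#'   (`p < p_max`). Default 0.01, the exon-array convention; the
#'   gene-level RNA-seq path conventionally relaxes this to 0.05.
#' @param r_pair_min pairwise coherence threshold for the driver's own
#'   probes, applied to the signed coefficient (`r > r_pair_min`):
#'   coherent driver probes must be positively correlated, while the
#'   screens use `|r|`. Default 0.5.
#' @param aggregation probe-to-gene summary; only `"mean"` is offered.
#' @return a `screen_params` list.
#' @export
screen_params <- function(r_min = 0.5, p_max = 0.01, r_pair_min = 0.5,
                          aggregation = "mean") {
  aggregation <- match.arg(aggregation)
  stopifnot(r_min > 0, r_min <= 1, p_max > 0, p_max < 1,
            r_pair_min > 0, r_pair_min <= 1)
  structure(list(r_min = r_min, p_max = p_max, r_pair_min = r_pair_min,
                 aggregation = aggregation),
            class = "screen_params")
}

#' Select the coherent subset of a driver gene's probes
#'
#' Exon arrays interrogate a gene with several probesets; before a gene
#' can serve as the correlation reference its probes must agree with
#' one another. This returns the largest subset (of size >= 2, or the
#' first probe alone if no pair qualifies) in which every pair has a
#' signed Pearson `r > r_pair_min`. Subsets are enumerated exhaustively
#' (the probe count per gene is small — at most `max_exhaustive`);
#' among maximal subsets ties are broken by larger mean pairwise `r`,
#' then by input order. Result order follows input order.
#'
#' @param m an [expr_matrix()] at probe level.
#' @param target_probes probe ids annotated to the driver gene.
#' @param r_pair_min pairwise coherence threshold (signed).
#' @param max_exhaustive guard on the subset enumeration.
#' @return character vector of retained probe ids.
#' @export
select_coherent_probes <- function(m, target_probes, r_pair_min = 0.5,
                                   max_exhaustive = 15L) {
  target_probes <- as.character(target_probes)
  present <- target_probes %in% rownames(m)
  if (!any(present))
    stop("no target probe present in the matrix", call. = FALSE)
  target_probes <- target_probes[present]
  k <- length(target_probes)
  if (k == 1) return(target_probes)
  if (k > max_exhaustive)
    stop(sprintf("%d target probes exceed the exhaustive-search bound (%d)",
                 k, max_exhaustive), call. = FALSE)
  v <- .values(m)[target_probes, , drop = FALSE]
  cc <- suppressWarnings(stats::cor(t(v)))  # NA for zero-variance probes
  best <- NULL; best_mean <- -Inf
  for (size in k:2) {
    for (idx in utils::combn(k, size, simplify = FALSE)) {
      sub <- cc[idx, idx]
      off <- sub[upper.tri(sub)]
      if (all(is.finite(off)) && all(off > r_pair_min)) {
        m_r <- mean(off)
        if (is.null(best) || m_r > best_mean) {
          best <- idx; best_mean <- m_r
        }
      }
    }
    if (!is.null(best)) break
  }
  if (is.null(best)) return(target_probes[1])
  target_probes[sort(best)]
}

#' Screen probes by correlation with the driver's retained probes
#'
#' Keeps every probe whose Pearson correlation with at least one
#' retained driver probe satisfies `|r| >= r_min` and `p < p_max`.
#' The retained driver probes always pass (r = 1 with themselves).
#' Zero-variance probes are excluded, their count reported via a
#' message. A second message reports the expected false-positive count
#' of the raw screen (`feature count * p_max`), since no multiplicity
#' correction is applied.
#'
#' @param m probe-level [expr_matrix()].
#' @param retained_targets probe ids from [select_coherent_probes()].
#' @param params a [screen_params()].
#' @return character vector of screened probe ids, in input row order.
#' @export
screen_probes <- function(m, retained_targets, params = screen_params()) {
  retained_targets <- as.character(retained_targets)
  if (length(retained_targets) == 0)
    stop("no retained target probes", call. = FALSE)
  if (!all(retained_targets %in% rownames(m)))
    stop("retained target probe absent from matrix", call. = FALSE)
  v <- .values(m)
  n <- ncol(v)
  sds <- apply(v, 1, stats::sd)
  degenerate <- sds == 0
  if (any(degenerate))
    message(sprintf("screen_probes: %d zero-variance probe(s) excluded",
                    sum(degenerate)))
  message(sprintf("screen_probes: expected false positives at p < %g: %.1f",
                  params$p_max, sum(!degenerate) * params$p_max))
  tv <- t(v[retained_targets, , drop = FALSE])
  ok <- !degenerate
  rmat <- stats::cor(t(v[ok, , drop = FALSE]), tv)
  pass_r <- abs(rmat) >= params$r_min
  pmat <- matrix(cor_pvalue(rmat, n), nrow(rmat), ncol(rmat))
  pass <- rowSums(pass_r & pmat < params$p_max) > 0
  rownames(v)[ok][pass]
}

#' Robust per-feature standardisation (median/IQR)
#'
#' Each retained row is centred by its median across samples and scaled
#' by its interquartile range, so every retained row has median 0 and
#' IQR 1. Quantiles use linear interpolation between order statistics
#' (R's default, `type = 7`); the convention matters for boundary
#' probes and is therefore fixed and documented rather than
#' configurable. Rows with IQR 0 cannot be scaled and are dropped with
#' a warning; if every row is degenerate that is an error.
#'
#' @param m an [expr_matrix()].
#' @param subset optional feature ids to standardise (default: all).
#' @return an [expr_matrix()] of the standardised rows (unitless).
#' @export
robust_standardize <- function(m, subset = NULL) {
  v <- .values(m)
  if (!is.null(subset)) {
    subset <- as.character(subset)
    if (!all(subset %in% rownames(v)))
      stop("subset contains features absent from the matrix", call. = FALSE)
    v <- v[subset, , drop = FALSE]
  }
  med <- apply(v, 1, stats::median)
  iqr <- apply(v, 1, stats::IQR, type = 7)
  keep <- iqr > 0
  if (!any(keep)) stop("all rows have zero IQR", call. = FALSE)
  if (any(!keep))
    warning(sprintf("robust_standardize: dropped %d row(s) with zero IQR",
                    sum(!keep)), call. = FALSE)
  out <- (v[keep, , drop = FALSE] - med[keep]) / iqr[keep]
  expr_matrix(out, scale = "linear",
              platform = attr(m, "platform_tag") %||% "")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Aggregate standardised probes to gene level
#'
#' One output row per gene symbol owning at least one probe among the
#' input rows; each gene/sample value is the arithmetic mean of that
#' gene's standardised probe values, restricted to the probes actually
#' present (i.e. those that survived the screen). Probes without an
#' annotation entry are dropped with a reported count.
#'
#' @param std standardised probe-level [expr_matrix()].
#' @param annotation a [probe_annotation()].
#' @return gene-level [expr_matrix()] (rows named by gene symbol).
#' @export
aggregate_probes <- function(std, annotation) {
  stopifnot(inherits(annotation, "probe_annotation"))
  v <- .values(std)
  idx <- match(rownames(v), annotation$probe_id)
  unann <- is.na(idx)
  if (all(unann)) stop("no probe maps to any gene", call. = FALSE)
  if (any(unann))
    message(sprintf("aggregate_probes: dropped %d unannotated probe(s)",
                    sum(unann)))
  v <- v[!unann, , drop = FALSE]
  sym <- annotation$gene_symbol[idx[!unann]]
  sums <- rowsum(v, group = sym)
  counts <- as.vector(table(sym)[rownames(sums)])
  agg <- sums / counts
  expr_matrix(agg, scale = "linear",
              platform = attr(std, "platform_tag") %||% "")
}

#' Gene filter against the driver reference
#'
#' Correlates every gene row against the reference profile and retains
#' genes with `|r| >= r_min` and `p < p_max`. The driver gene itself
#' trivially correlates with its own reference; it is excluded from the
#' signature when `exclude_target` is `TRUE` (the default) and always
#' reported separately in the records.
#'
#' @param gene_matrix gene-level [expr_matrix()].
#' @param ref numeric reference vector (the driver profile).
#' @param params a [screen_params()].
#' @param target_gene gene symbol of the driver (may be absent).
#' @param exclude_target drop the driver from the signature list?
#' @return list with `records` (data.frame `gene_symbol`, `r`, `p`,
#'   `n`, `passes`, `is_target`) and `signature_genes`.
#' @export
filter_genes_by_correlation <- function(gene_matrix, ref,
                                        params = screen_params(),
                                        target_gene = NULL,
                                        exclude_target = TRUE) {
  rec <- cor_to_reference(gene_matrix, ref, method = "pearson")
  passes <- !rec$degenerate & abs(rec$r) >= params$r_min &
    rec$p < params$p_max
  is_target <- if (is.null(target_gene)) rep(FALSE, nrow(rec)) else
    rec$feature_id == target_gene
  records <- data.frame(gene_symbol = rec$feature_id, r = rec$r, p = rec$p,
                        n = rec$n, passes = passes, is_target = is_target,
                        stringsAsFactors = FALSE)
  sig <- records$gene_symbol[records$passes &
                               !(exclude_target & records$is_target)]
  list(records = records, signature_genes = sig)
}

#' Fit a driver-correlation signature on probe-level exon-array data
#'
#' The full probe-level procedure: (1) select the coherent subset of
#' the driver gene's probes ([select_coherent_probes()]); (2) screen
#' all probes for correlation with at least one retained driver probe
#' ([screen_probes()]); (3) standardise the screened probes by
#' median/IQR ([robust_standardize()]); (4) aggregate standardised
#' probes to genes by their mean ([aggregate_probes()]); (5) build the
#' driver reference as the aggregated driver row and retain genes
#' correlated with it at `|r| >= r_min`, `p < p_max`
#' ([filter_genes_by_correlation()]). The composition is deterministic
#' and invariant to feature and sample ordering of the input.
#'
#' @param m probe-level [expr_matrix()] of normalized log intensities.
#' @param annotation a [probe_annotation()] mapping probes to symbols.
#' @param target_gene driver gene symbol (must own >= 1 probe in `m`).
#' @param params a [screen_params()]; defaults to `r_min = 0.5`,
#'   `p_max = 0.01`.
#' @param reference `"aggregate"` (default) correlates genes against
#'   the aggregated driver row; `"per_probe"` correlates against each
#'   retained standardised driver probe and keeps genes passing for at
#'   least one, reporting each gene's strongest record.
#' @param exclude_target exclude the driver from the signature count?
#' @return an object of class `driver_signature`; see Details.
#' @details The returned list carries the driver symbol, retained
#'   driver probes, screened probe ids, the standardised probe matrix,
#'   the aggregated gene matrix, the reference vector, the per-gene
#'   correlation records, the signature gene list, the thresholds used,
#'   and all intermediate counts (`$counts`).
#' @seealso [gene_signature()] for gene-level (RNA-seq) input,
#'   [run_report()] for a serializable run summary.
#' @export
exon_signature <- function(m, annotation, target_gene,
                           params = screen_params(),
                           reference = c("aggregate", "per_probe"),
                           exclude_target = TRUE) {
  reference <- match.arg(reference)
  stopifnot(is_expr_matrix(m), inherits(annotation, "probe_annotation"))
  target_probes <- annotation$probe_id[annotation$gene_symbol == target_gene]
  target_probes <- target_probes[target_probes %in% rownames(m)]
  if (length(target_probes) == 0)
    stop(sprintf("target gene '%s' has no annotated probe in the matrix",
                 target_gene), call. = FALSE)
  retained <- select_coherent_probes(m, target_probes, params$r_pair_min)
  screened <- screen_probes(m, retained, params)
  std <- robust_standardize(m, subset = screened)
  gene_matrix <- aggregate_probes(std, annotation)
  if (!target_gene %in% rownames(gene_matrix))
    stop("driver gene lost during aggregation", call. = FALSE)
  ref <- .values(gene_matrix)[target_gene, ]
  if (reference == "aggregate") {
    flt <- filter_genes_by_correlation(gene_matrix, ref, params,
                                       target_gene, exclude_target)
  } else {
    tp <- retained[retained %in% rownames(std)]
    per <- lapply(tp, function(pb)
      filter_genes_by_correlation(gene_matrix, .values(std)[pb, ], params,
                                  target_gene, exclude_target))
    recs <- per[[1]]$records
    for (k in seq_along(per)[-1]) {
      alt <- per[[k]]$records
      better <- abs(alt$r) > abs(recs$r)
      recs[better, c("r", "p")] <- alt[better, c("r", "p")]
      recs$passes <- recs$passes | alt$passes
    }
    flt <- list(records = recs,
                signature_genes = recs$gene_symbol[
                  recs$passes & !(exclude_target & recs$is_target)])
  }
  out <- list(call = match.call(), level = "probe",
              target_gene = target_gene, params = params,
              reference_mode = reference, exclude_target = exclude_target,
              target_probes = target_probes,
              retained_target_probes = retained,
              screened_probes = screened,
              standardized = std, gene_matrix = gene_matrix,
              reference = ref, records = flt$records,
              signature_genes = flt$signature_genes,
              counts = c(target_probes = length(target_probes),
                         retained_target_probes = length(retained),
                         screened_probes = length(screened),
                         aggregated_genes = nrow(gene_matrix),
                         signature_genes = length(flt$signature_genes)))
  class(out) <- "driver_signature"
  out
}

#' Fit a driver-correlation signature on gene-level data
#'
#' The gene-level analog of [exon_signature()] for RNA-seq (CPM) or any
#' already-summarised expression matrix: every gene row is correlated
#' directly with the driver gene's row and retained when
#' `|r| >= r_min` and `p < p_max` jointly hold. With few samples the
#' p threshold is the binding constraint (see [effective_r_cutoff()]).
#'
#' @param m gene-level [expr_matrix()] (rows named by gene symbol).
#' @param target_gene driver gene symbol, present in `m`.
#' @param params a [screen_params()]; the conventional gene-level
#'   default is `p_max = 0.05`.
#' @inheritParams exon_signature
#' @return a `driver_signature` object.
#' @export
gene_signature <- function(m, target_gene,
                           params = screen_params(p_max = 0.05),
                           exclude_target = TRUE) {
  stopifnot(is_expr_matrix(m))
  if (!target_gene %in% rownames(m))
    stop(sprintf("target gene '%s' absent from the matrix", target_gene),
         call. = FALSE)
  ref <- .values(m)[target_gene, ]
  flt <- filter_genes_by_correlation(m, ref, params, target_gene,
                                     exclude_target)
  out <- list(call = match.call(), level = "gene",
              target_gene = target_gene, params = params,
              reference_mode = "gene_row", exclude_target = exclude_target,
              retained_target_probes = character(0),
              screened_probes = character(0),
              standardized = NULL, gene_matrix = m,
              reference = ref, records = flt$records,
              signature_genes = flt$signature_genes,
              counts = c(genes = nrow(m),
                         signature_genes = length(flt$signature_genes)))
  class(out) <- "driver_signature"
  out
}

#' @export
print.driver_signature <- function(x, ...) {
  cat(sprintf("Driver-correlation signature (%s-level)\n", x$level))
  cat(sprintf("  driver gene: %s\n", x$target_gene))
  if (x$level == "probe")
    cat(sprintf("  driver probes: %d annotated, %d retained as coherent\n",
                x$counts[["target_probes"]],
                x$counts[["retained_target_probes"]]))
  if (x$level == "probe")
    cat(sprintf("  screened probes: %d; aggregated genes: %d\n",
                x$counts[["screened_probes"]],
                x$counts[["aggregated_genes"]]))
  cat(sprintf("  thresholds: |r| >= %g, p < %g\n",
              x$params$r_min, x$params$p_max))
  cat(sprintf("  signature genes: %d%s\n", length(x$signature_genes),
              if (x$exclude_target) " (driver excluded)" else ""))
  invisible(x)
}

#' @export
summary.driver_signature <- function(object, ...) {
  rec <- object$records[object$records$passes & !object$records$is_target, ]
  rec <- rec[order(-abs(rec$r)), ]
  structure(list(fit = object, top = utils::head(rec, 10),
                 n_pos = sum(rec$r > 0), n_neg = sum(rec$r < 0)),
            class = "summary.driver_signature")
}

#' @export
print.summary.driver_signature <- function(x, ...) {
  print(x$fit)
  cat(sprintf("  positively correlated: %d; negatively: %d\n",
              x$n_pos, x$n_neg))
  cat("  strongest signature genes:\n")
  print(x$top, row.names = FALSE, digits = 3)
  invisible(x)
}

#' @export
coef.driver_signature <- function(object, ...) {
  rec <- object$records
  keep <- rec$passes & !(object$exclude_target & rec$is_target)
  stats::setNames(rec$r[keep], rec$gene_symbol[keep])
}

#' Heatmap of the fitted signature
#'
#' Draws the signature genes by samples matrix with Ward/Euclidean
#' dendrograms on both axes (base graphics heatmap; no annotation
#' aesthetics).
#'
#' @param x a `driver_signature`.
#' @param ... passed to [stats::heatmap()].
#' @export
plot.driver_signature <- function(x, ...) {
  v <- .values(x$gene_matrix)
  v <- v[rownames(v) %in% x$signature_genes, , drop = FALSE]
  if (nrow(v) < 2) stop("too few signature genes to plot", call. = FALSE)
  stats::heatmap(v, distfun = stats::dist,
                 hclustfun = function(d) stats::hclust(d, "ward.D2"),
                 scale = "none", ...)
  invisible(x)
}
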