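#' Serializable run report for a fitted signature
#'
#' Collects everything needed to audit a fit: the driver gene, the
#' thresholds, every intermediate count (annotated driver probes,
#' retained coherent probes, screened probes, aggregated genes,
#' signature genes), and the expected false-positive count implied by
#' the raw (uncorrected) significance threshold. Every count is
#' recomputable from the intermediates stored on the fit object.
#'
#' @param fit a `driver_signature` from [exon_signature()] or
#'   [gene_signature()].
#' @param seed optional integer recorded for provenance.
#' @return a plain list, suitable for [write_run_report()].
#' @export
run_report <- function(fit, seed = NULL) {
  stopifnot(inherits(fit, "driver_signature"))
  list(level = fit$level,
       target_gene = fit$target_gene,
       parameters = unclass(fit$params),
       reference_mode = fit$reference_mode,
       exclude_target = fit$exclude_target,
       counts = as.list(fit$counts),
       expected_false_positives = nrow(fit$records) * fit$params$p_max,
       signature_genes = fit$signature_genes,
       seed = seed)
}

#' @rdname run_report
#' @param path output path for the JSON report.
#' @export
write_run_report <- function(fit, path, seed = NULL) {
  jsonlite::write_json(run_report(fit, seed), path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}
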