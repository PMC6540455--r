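#' Read an expression matrix from delimited text
#'
#' Two dialects are supported. `"tsv"` is a plain delimited file with a
#' header row of sample identifiers and feature identifiers in the first
#' column. `"series_matrix"` is the GEO series-matrix style: the
#' expression table is fenced by the literal lines
#' `!series_matrix_table_begin` and `!series_matrix_table_end`, every
#' other `!`-prefixed header line is ignored (a count of ignored lines is
#' reported via a message), and quoted identifiers are unquoted. Only the
#' table block is consumed; this is deliberately not a full GEO client.
#'
#' Duplicate identifiers, empty identifiers, and non-numeric or missing
#' cells are load errors that name the offending feature/sample, because
#' the downstream correlation screens assume complete matrices with
#' unambiguous paired sample counts.
#'
#' @param path file path.
#' @param dialect `"tsv"` or `"series_matrix"`.
#' @param sep field separator for the `"tsv"` dialect (default tab).
#' @param scale,platform tags stored on the result, see [expr_matrix()].
#' @return an [expr_matrix()].
#' @export
read_expression_matrix <- function(path, dialect = c("tsv", "series_matrix"),
                                   sep = "\t", scale = c("log", "linear"),
                                   platform = "") {
  dialect <- match.arg(dialect)
  scale <- match.arg(scale)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (dialect == "series_matrix") {
    lines <- readLines(path)
    begin <- which(lines == "!series_matrix_table_begin")
    end <- which(lines == "!series_matrix_table_end")
    if (length(begin) != 1 || length(end) != 1 || end <= begin + 1)
      stop("series_matrix table fences not found in ", path, call. = FALSE)
    ignored <- sum(startsWith(lines, "!")) - 2L
    if (ignored > 0)
      message(sprintf("read_expression_matrix: ignored %d header line(s)",
                      ignored))
    lines <- lines[(begin + 1):(end - 1)]
    df <- utils::read.table(text = lines, sep = "\t", header = TRUE,
                            quote = "\"", check.names = FALSE,
                            colClasses = "character",
                            stringsAsFactors = FALSE)
  } else {
    df <- utils::read.table(path, sep = sep, header = TRUE, quote = "\"",
                            check.names = FALSE, colClasses = "character",
                            stringsAsFactors = FALSE)
  }
  if (ncol(df) < 2) stop("expression table needs id column plus >= 1 sample",
                         call. = FALSE)
  feature_ids <- trimws(df[[1]])
  sample_ids <- trimws(colnames(df)[-1])
  vals <- as.matrix(df[, -1, drop = FALSE])
  num <- suppressWarnings(matrix(as.numeric(vals), nrow(vals), ncol(vals)))
  bad <- which(is.na(num) | vals == "", arr.ind = TRUE)
  if (nrow(bad) > 0)
    stop(sprintf("non-numeric or missing cell at feature '%s', sample '%s'",
                 feature_ids[bad[1, 1]], sample_ids[bad[1, 2]]),
         call. = FALSE)
  expr_matrix(num, feature_ids = feature_ids, sample_ids = sample_ids,
              scale = scale, platform = platform)
}

#' Write an expression matrix as delimited text
#'
#' Values are written with full precision (`format(..., digits = 17)`
#' via `write.table`'s default numeric formatting is not used; values
#' are serialized with `sprintf("%.17g")`) so that a write/read
#' round trip reproduces the matrix exactly.
#'
#' @param m an [expr_matrix()].
#' @param path output path.
#' @param sep field separator.
#' @param id_column header name of the feature-id column.
#' @export
write_expression_matrix <- function(m, path, sep = "\t",
                                    id_column = "feature_id") {
  stopifnot(is_expr_matrix(m))
  txt <- matrix(sprintf("%.17g", .values(m)), nrow(m), ncol(m))
  df <- data.frame(rownames(m), txt, check.names = FALSE,
                   stringsAsFactors = FALSE)
  colnames(df) <- c(id_column, colnames(m))
  utils::write.table(df, path, sep = sep, quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read a probe-to-gene annotation table
#'
#' Two-column delimited file (`probe_id`, `gene_symbol`) with a header
#' row. Each probe must map to exactly one gene symbol; a probe listed
#' with two different symbols is an error naming the probe. A gene may
#' own many probes. Rows with an empty symbol are dropped and their
#' count reported via a message.
#'
#' @param path file path.
#' @param sep field separator.
#' @return a `probe_annotation`: data.frame with columns `probe_id`,
#'   `gene_symbol`, one row per probe.
#' @export
read_probe_annotation <- function(path, sep = "\t") {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.table(path, sep = sep, header = TRUE, quote = "\"",
                          colClasses = "character",
                          stringsAsFactors = FALSE)
  if (ncol(df) < 2) stop("annotation needs two columns", call. = FALSE)
  probe_annotation(trimws(df[[1]]), trimws(df[[2]]))
}

#' Construct a probe annotation in code
#'
#' @param probe_id,gene_symbol character vectors of equal length.
#' @return see [read_probe_annotation()].
#' @export
probe_annotation <- function(probe_id, gene_symbol) {
  stopifnot(length(probe_id) == length(gene_symbol))
  probe_id <- trimws(as.character(probe_id))
  gene_symbol <- trimws(as.character(gene_symbol))
  empty <- !nzchar(gene_symbol)
  if (any(empty)) {
    message(sprintf("probe_annotation: dropped %d row(s) with empty symbol",
                    sum(empty)))
    probe_id <- probe_id[!empty]
    gene_symbol <- gene_symbol[!empty]
  }
  dup <- duplicated(paste0(probe_id, "\r", gene_symbol))
  probe_id <- probe_id[!dup]
  gene_symbol <- gene_symbol[!dup]
  conflict <- probe_id[duplicated(probe_id)]
  if (length(conflict) > 0)
    stop(sprintf("probe '%s' maps to more than one gene symbol",
                 conflict[1]), call. = FALSE)
  structure(data.frame(probe_id = probe_id, gene_symbol = gene_symbol,
                       stringsAsFactors = FALSE),
            class = c("probe_annotation", "data.frame"))
}

#' Read a human/mouse ortholog symbol map
#'
#' Two-column delimited file of symbol pairs (species A symbol, species
#' B symbol) with a header. Ambiguous symbols — a symbol participating
#' in more than one pair — are handled by `policy`:
#' `"strict_one_to_one"` (default) drops every pair touching an
#' ambiguous symbol, so each retained symbol appears exactly once and
#' shared-gene intersections never double-count; `"first_wins"` keeps
#' the first pair seen for each symbol. Dropped pairs are counted in a
#' message.
#'
#' @param path file path.
#' @param policy ambiguity policy, see above.
#' @param sep field separator.
#' @param species character vector of length two labelling the columns.
#' @return an `ortholog_map`: data.frame with columns `symbol_a`,
#'   `symbol_b`, attribute `species`.
#' @export
read_ortholog_map <- function(path, policy = c("strict_one_to_one",
                                               "first_wins"),
                              sep = "\t", species = c("human", "mouse")) {
  policy <- match.arg(policy)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.table(path, sep = sep, header = TRUE, quote = "\"",
                          colClasses = "character",
                          stringsAsFactors = FALSE)
  if (nrow(df) == 0) stop("empty ortholog map: ", path, call. = FALSE)
  ortholog_map(trimws(df[[1]]), trimws(df[[2]]), policy = policy,
               species = species)
}

#' Construct an ortholog map in code
#'
#' @param symbol_a,symbol_b character vectors of paired symbols.
#' @inheritParams read_ortholog_map
#' @export
ortholog_map <- function(symbol_a, symbol_b,
                         policy = c("strict_one_to_one", "first_wins"),
                         species = c("human", "mouse")) {
  policy <- match.arg(policy)
  stopifnot(length(symbol_a) == length(symbol_b), length(species) == 2)
  keep <- nzchar(symbol_a) & nzchar(symbol_b)
  symbol_a <- symbol_a[keep]; symbol_b <- symbol_b[keep]
  if (length(symbol_a) == 0) stop("empty ortholog map", call. = FALSE)
  dup_pair <- duplicated(paste0(symbol_a, "\r", symbol_b))
  symbol_a <- symbol_a[!dup_pair]; symbol_b <- symbol_b[!dup_pair]
  amb_a <- symbol_a %in% symbol_a[duplicated(symbol_a)]
  amb_b <- symbol_b %in% symbol_b[duplicated(symbol_b)]
  ambiguous <- amb_a | amb_b
  if (policy == "strict_one_to_one") {
    dropped <- sum(ambiguous)
    symbol_a <- symbol_a[!ambiguous]; symbol_b <- symbol_b[!ambiguous]
  } else {
    keep <- !duplicated(symbol_a) & !duplicated(symbol_b)
    dropped <- sum(!keep)
    symbol_a <- symbol_a[keep]; symbol_b <- symbol_b[keep]
  }
  if (dropped > 0)
    message(sprintf("ortholog_map: dropped %d ambiguous pair(s) [%s]",
                    dropped, policy))
  if (length(symbol_a) == 0)
    stop("no unambiguous ortholog pairs remain", call. = FALSE)
  structure(data.frame(symbol_a = symbol_a, symbol_b = symbol_b,
                       stringsAsFactors = FALSE),
            species = species,
            class = c("ortholog_map", "data.frame"))
}

#' Write and re-read a signature gene table
#'
#' Serializes the gene-level correlation records of a fitted signature
#' (columns `gene_symbol`, `r`, `p`, `n`, `passes`) with full numeric
#' precision so the round trip is exact.
#'
#' @param records data.frame as found in `fit$records`, or a
#'   `driver_signature` fit (its records are used).
#' @param path output path.
#' @param sep field separator.
#' @export
write_gene_table <- function(records, path, sep = "\t") {
  if (inherits(records, "driver_signature")) records <- records$records
  stopifnot(is.data.frame(records))
  df <- data.frame(gene_symbol = records$gene_symbol,
                   r = sprintf("%.17g", records$r),
                   p = sprintf("%.17g", records$p),
                   n = records$n,
                   passes = records$passes,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = sep, quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_gene_table
#' @export
read_gene_table <- function(path, sep = "\t") {
  df <- utils::read.table(path, sep = sep, header = TRUE, quote = "\"",
                          stringsAsFactors = FALSE,
                          colClasses = c("character", "numeric", "numeric",
                                         "integer", "logical"))
  names(df) <- c("gene_symbol", "r", "p", "n", "passes")
  df
}
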