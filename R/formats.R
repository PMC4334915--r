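# Readers and writers for every external table the pipeline touches.
# All other modules operate on the in-memory domain types built here.

#' Describe a delimited-text dialect
#'
#' @param delimiter Single field-separator character.
#' @param has_header Whether the first non-comment line is a header.
#' @param comment_prefix Lines starting with this character are skipped.
#' @param na_token String standing for a missing value. Must not itself parse
#'   as a number, so missingness can never be confused with data.
#' @return A `table_dialect` object.
#' @export
table_dialect <- function(delimiter = "\t", has_header = TRUE,
                          comment_prefix = "#", na_token = "NA") {
  if (!is.character(delimiter) || nchar(delimiter) != 1L)
    stopf("delimiter must be a single character")
  if (!is.character(comment_prefix) || nchar(comment_prefix) != 1L)
    stopf("comment_prefix must be a single character")
  if (!is.na(suppressWarnings(as.numeric(na_token))))
    stopf("na_token %s parses as a number and would be ambiguous", na_token)
  structure(list(delimiter = delimiter, has_header = isTRUE(has_header),
                 comment_prefix = comment_prefix, na_token = na_token),
            class = "table_dialect")
}

## ---- hit tables (BLAST tabular, outfmt 6) -----------------------------------

hit_table_columns <- c("query", "subject", "identity", "length", "mismatches",
                       "gapopens", "qstart", "qend", "sstart", "send",
                       "evalue", "bitscore")

#' Construct a hit table
#'
#' A `hit_table` is a data frame of directed pairwise alignment hits in BLAST
#' tabular (outfmt 6) column order, optionally tagged with the query and
#' subject species and carrying optional `coverage` (fraction of query
#' aligned, 0..1) and `similarity` (percent) columns.
#'
#' @param df Data frame with at least the 12 outfmt-6 columns.
#' @param query_species,subject_species Species identifiers for the two sides.
#' @return A validated `hit_table`.
#' @export
hit_table <- function(df, query_species = NA_character_,
                      subject_species = NA_character_) {
  if (nrow(df) > 0L) {
    missing_cols <- setdiff(hit_table_columns, names(df))
    if (length(missing_cols))
      stopf("hit table is missing columns: %s", paste(missing_cols, collapse = ", "))
    if (any(df$evalue < 0)) stopf("e-values must be non-negative")
    if (any(df$identity < 0 | df$identity > 100))
      stopf("identity must lie in [0, 100]")
    if (!is.null(df$coverage) && any(!is.na(df$coverage) &
                                     (df$coverage < 0 | df$coverage > 1)))
      stopf("coverage must lie in [0, 1]")
    if (any(df$bitscore < 0)) stopf("bitscores must be non-negative")
  } else if (ncol(df) == 0L) {
    df <- as.data.frame(stats::setNames(
      replicate(12L, logical(0), simplify = FALSE), hit_table_columns))
  }
  structure(df, class = c("hit_table", "data.frame"),
            query_species = query_species, subject_species = subject_species)
}

#' Read a BLAST tabular hit file
#'
#' Parses a 12-column outfmt-6 file (query, subject, %identity, alignment
#' length, mismatches, gap opens, qstart, qend, sstart, send, e-value,
#' bitscore). Extra columns emitted by some BLAST variants (qlen, slen, ...)
#' are ignored with a notice. An empty file yields an empty table; a malformed
#' numeric field is an error naming the offending line.
#'
#' @param path File to read.
#' @param dialect A [table_dialect()]; hit files carry no header by default.
#' @param query_species,subject_species Optional species tags.
#' @return A [hit_table()] with one record per input row, order preserved.
#' @export
read_hit_table <- function(path, dialect = table_dialect(has_header = FALSE),
                           query_species = NA_character_,
                           subject_species = NA_character_) {
  if (!file.exists(path)) stopf("hit table file does not exist: %s", path)
  lines <- readLines(path, warn = FALSE)
  keep <- !startsWith(lines, dialect$comment_prefix) & nzchar(lines)
  line_no <- which(keep)
  lines <- lines[keep]
  if (dialect$has_header && length(lines)) {
    lines <- lines[-1L]
    line_no <- line_no[-1L]
  }
  if (!length(lines))
    return(hit_table(data.frame(), query_species, subject_species))
  fields <- strsplit(lines, dialect$delimiter, fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 12L))
    stopf("line %d of %s has %d fields; 12 outfmt-6 columns are required",
          line_no[which(nf < 12L)[1L]], path, nf[which(nf < 12L)[1L]])
  if (any(nf > 12L))
    message(sprintf("%s: ignoring %d extra column(s) beyond the 12 outfmt-6 fields",
                    path, max(nf) - 12L))
  mat <- t(vapply(fields, function(f) f[1:12], character(12L)))
  df <- data.frame(query = mat[, 1L], subject = mat[, 2L],
                   stringsAsFactors = FALSE)
  for (j in 3:12) {
    raw <- mat[, j]
    val <- suppressWarnings(as.numeric(raw))
    bad <- is.na(val) & raw != dialect$na_token
    if (any(bad))
      stopf("line %d of %s: cannot parse '%s' as a number in column %s",
            line_no[which(bad)[1L]], path, raw[which(bad)[1L]],
            hit_table_columns[j])
    df[[hit_table_columns[j]]] <- val
  }
  hit_table(df, query_species, subject_species)
}

#' Write a hit table as BLAST tabular text
#'
#' @param x A [hit_table()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_hit_table <- function(x, path) {
  stopifnot(inherits(x, "hit_table"))
  df <- as.data.frame(x)[, hit_table_columns, drop = FALSE]
  for (j in 3:12) df[[j]] <- format(df[[j]], digits = 15, trim = TRUE,
                                    scientific = NA)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

## ---- expression tables ------------------------------------------------------

#' Construct an expression table
#'
#' Genes x (timepoint, replicate) non-negative expression values for one
#' species, with per-gene transcript lengths. Columns are named
#' `<timepoint>_<replicate>`; replicate counts may differ between timepoints.
#'
#' @param values Non-negative numeric matrix; rownames are gene ids, colnames
#'   follow the `<timepoint>_<replicate>` convention.
#' @param species Species identifier.
#' @param lengths_bp Positive integer vector of transcript lengths, one per
#'   gene (required for RPKM conversion).
#' @param timepoints Ordered timepoint labels; defaults to their order of
#'   first appearance in the column names.
#' @return An `expression_table`.
#' @export
expression_table <- function(values, species, lengths_bp = NULL,
                             timepoints = NULL) {
  values <- as.matrix(values)
  if (is.null(rownames(values))) stopf("expression values need gene rownames")
  if (anyDuplicated(rownames(values)))
    stopf("duplicate gene id: %s",
          rownames(values)[anyDuplicated(rownames(values))])
  if (any(values < 0)) {
    idx <- which(values < 0, arr.ind = TRUE)[1L, ]
    stopf("negative expression value for gene %s in column %s",
          rownames(values)[idx[1L]], colnames(values)[idx[2L]])
  }
  parts <- strsplit(colnames(values), "_", fixed = TRUE)
  if (any(lengths(parts) != 2L))
    stopf("expression columns must be named <timepoint>_<replicate>")
  tp <- vapply(parts, `[`, "", 1L)
  rep_id <- vapply(parts, `[`, "", 2L)
  if (is.null(timepoints)) timepoints <- unique(tp)
  if (!setequal(unique(tp), timepoints))
    stopf("column timepoints do not match declared timepoints")
  if (length(timepoints) < 2L) stopf("at least 2 timepoints are required")
  if (!is.null(lengths_bp)) {
    if (length(lengths_bp) != nrow(values))
      stopf("lengths_bp must have one entry per gene")
    if (any(lengths_bp <= 0)) stopf("gene lengths must be positive")
    names(lengths_bp) <- rownames(values)
  }
  structure(list(species = species, genes = rownames(values),
                 lengths_bp = lengths_bp, values = values,
                 timepoints = as.character(timepoints),
                 col_timepoint = tp, col_replicate = rep_id),
            class = "expression_table")
}

#' Read a wide-format expression TSV
#'
#' Expects a `gene` column, an optional `length_bp` column, and one column
#' per `<timepoint>_<replicate>` combination. A `# species=<id>` comment line
#' declares the species unless overridden by the `species` argument.
#'
#' @param path File to read.
#' @param species Species id; overrides any declaration in the file.
#' @param n_timepoints If given, the parsed timepoint count is checked
#'   against it.
#' @return An [expression_table()].
#' @export
read_expression_table <- function(path, species = NULL, n_timepoints = NULL) {
  if (!file.exists(path)) stopf("expression table does not exist: %s", path)
  header <- readLines(path, n = 10L, warn = FALSE)
  decl <- grep("^#\\s*species=", header, value = TRUE)
  if (is.null(species))
    species <- if (length(decl)) sub("^#\\s*species=", "", decl[1L]) else
      stopf("%s declares no species; pass species= explicitly", path)
  df <- utils::read.delim(path, comment.char = "#", check.names = FALSE,
                          stringsAsFactors = FALSE)
  if (!"gene" %in% names(df)) stopf("%s lacks a 'gene' column", path)
  lengths_bp <- if ("length_bp" %in% names(df)) df$length_bp else NULL
  value_cols <- setdiff(names(df), c("gene", "length_bp"))
  values <- as.matrix(df[, value_cols, drop = FALSE])
  rownames(values) <- df$gene
  et <- expression_table(values, species = species, lengths_bp = lengths_bp)
  if (!is.null(n_timepoints) && length(et$timepoints) != n_timepoints)
    stopf("%s has %d timepoints, expected %d", path, length(et$timepoints),
          n_timepoints)
  et
}

#' Write an expression table as a wide TSV
#'
#' @param x An [expression_table()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_expression_table <- function(x, path) {
  stopifnot(inherits(x, "expression_table"))
  df <- data.frame(gene = x$genes, stringsAsFactors = FALSE)
  if (!is.null(x$lengths_bp)) df$length_bp <- unname(x$lengths_bp)
  vals <- as.data.frame(x$values)
  for (j in seq_along(vals)) vals[[j]] <- format(vals[[j]], digits = 15,
                                                 trim = TRUE, scientific = NA)
  df <- cbind(df, vals)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# species=%s", x$species), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

## ---- ortholog pair tables ---------------------------------------------------

#' Read a 3-column ortholog-pair TSV (gene_a, gene_b, evidence)
#'
#' @param path File to read.
#' @return Data frame with columns `gene_a`, `gene_b`, `evidence`.
#' @export
read_ortholog_pairs <- function(path) {
  df <- utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
  need <- c("gene_a", "gene_b", "evidence")
  if (!all(need %in% names(df)))
    stopf("%s must have columns %s", path, paste(need, collapse = ", "))
  df[, need]
}

#' Write an ortholog-pair TSV
#'
#' @param pairs Data frame with `gene_a`, `gene_b` and optionally `evidence`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_ortholog_pairs <- function(pairs, path) {
  if (is.null(pairs$evidence)) pairs$evidence <- "bbh"
  utils::write.table(pairs[, c("gene_a", "gene_b", "evidence")], path,
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

## ---- result reports ---------------------------------------------------------

signif_rec <- function(x, digits) {
  if (is.double(x)) return(signif(x, digits))
  if (is.list(x)) return(lapply(x, signif_rec, digits = digits))
  x
}

#' Serialize a result object to disk
#'
#' Flat tables go out as TSV, nested results as JSON with deterministic key
#' order and floats at a fixed number of significant digits, so identical
#' results produce byte-identical files.
#'
#' @param result One of the package's domain types (or any list/data frame).
#' @param path Output path.
#' @param digits Significant digits for floating-point fields.
#' @return `path`, invisibly.
#' @export
write_report <- function(result, path, digits = 6) UseMethod("write_report")

#' @export
write_report.data.frame <- function(result, path, digits = 6) {
  df <- as.data.frame(result)
  for (j in seq_along(df))
    if (is.double(df[[j]])) df[[j]] <- signif(df[[j]], digits)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @export
write_report.concordance_table <- function(result, path, digits = 6) {
  write_report.data.frame(result, path, digits)
}

#' Read a concordance table written by [write_report()]
#'
#' @param path File to read.
#' @return A `concordance_table` data frame.
#' @export
read_concordance_table <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  class(df) <- c("concordance_table", "data.frame")
  df
}

#' @export
write_report.ortholog_map <- function(result, path, digits = 6) {
  out <- list(
    species = as.list(result$species),
    threshold_evalue = result$threshold_evalue,
    n_pairs = nrow(result$pairs),
    pairs = if (nrow(result$pairs)) result$pairs else list(),
    paralogs = lapply(result$paralogs, as.list))
  jsonlite::write_json(signif_rec(out, digits), path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}

#' @export
write_report.clustering_result <- function(result, path, digits = 6) {
  out <- list(
    k = nrow(result$centroids),
    objective = result$objective,
    restart_objectives = result$restart_objectives,
    groups = result$groups,
    labels = as.list(stats::setNames(as.integer(result$labels),
                                     names(result$labels))),
    centroids = apply(result$centroids, 1L, as.list, simplify = FALSE))
  jsonlite::write_json(signif_rec(out, digits), path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}

#' @export
write_report.venn_decomposition <- function(result, path, digits = 6) {
  write_report.data.frame(result$assignments, path, digits)
}

#' @export
write_report.default <- function(result, path, digits = 6) {
  jsonlite::write_json(signif_rec(result, digits), path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}
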