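# Expression normalization pipeline: RPKM -> replicate means -> per-timepoint
# scaling to a common total -> unexpressed-gene filter -> per-gene z-scores ->
# combined two-species matrix. Each stage tags its output and refuses
# out-of-order input, making the implemented order explicit and testable.

new_normalized_matrix <- function(values, species, timepoints, stage,
                                  scaling_total = NA_real_,
                                  removed = character(0),
                                  excluded = character(0)) {
  structure(list(values = values, species = species,
                 timepoints = as.character(timepoints), stage = stage,
                 scaling_total = scaling_total, removed = removed,
                 excluded = excluded),
            class = "normalized_matrix")
}

check_stage <- function(x, expected) {
  stopifnot(inherits(x, "normalized_matrix"))
  if (!x$stage %in% expected)
    stopf("matrix is at stage '%s' but this step needs stage %s; run the pipeline in order (rpkm, average, scale, filter, standardize, combine)",
          x$stage, paste(sprintf("'%s'", expected), collapse = " or "))
  invisible(x)
}

#' Convert read counts to RPKM
#'
#' value = count * 1e9 / (length_bp * total_mapped), i.e. reads per kilobase
#' of transcript per million mapped reads; zero counts stay zero.
#'
#' @param counts An [expression_table()] of read counts with gene lengths.
#' @param total_mapped Positive mapped-read totals, one per
#'   `<timepoint>_<replicate>` column (named vector, or a single value
#'   recycled over columns).
#' @return An [expression_table()] of RPKM values.
#' @export
rpkm <- function(counts, total_mapped) {
  stopifnot(inherits(counts, "expression_table"))
  if (is.null(counts$lengths_bp))
    stopf("RPKM conversion needs gene lengths (length_bp)")
  cols <- colnames(counts$values)
  if (length(total_mapped) == 1L && is.null(names(total_mapped)))
    total_mapped <- stats::setNames(rep(total_mapped, length(cols)), cols)
  if (!all(cols %in% names(total_mapped)))
    stopf("total_mapped lacks entries for column(s): %s",
          paste(setdiff(cols, names(total_mapped)), collapse = ", "))
  tm <- total_mapped[cols]
  if (any(tm <= 0)) stopf("total mapped reads must be positive")
  vals <- counts$values * 1e9 /
    outer(as.numeric(counts$lengths_bp), as.numeric(tm))
  dimnames(vals) <- dimnames(counts$values)
  expression_table(vals, species = counts$species,
                   lengths_bp = counts$lengths_bp,
                   timepoints = counts$timepoints)
}

#' Average biological replicates per timepoint
#'
#' Arithmetic mean per gene per timepoint; replicate counts may differ
#' between timepoints.
#'
#' @param table An [expression_table()].
#' @return A `normalized_matrix` (genes x timepoints) at stage `averaged`.
#' @export
average_replicates <- function(table) {
  stopifnot(inherits(table, "expression_table"))
  tp <- table$timepoints
  vals <- vapply(tp, function(t) {
    idx <- table$col_timepoint == t
    if (!any(idx)) stopf("timepoint %s has no replicates", t)
    rowMeans(table$values[, idx, drop = FALSE])
  }, numeric(nrow(table$values)))
  vals <- matrix(vals, nrow = nrow(table$values),
                 dimnames = list(table$genes, tp))
  new_normalized_matrix(vals, rep(table$species, nrow(vals)), tp, "averaged")
}

#' Scale each species x timepoint column to a common total
#'
#' Multiplies every column by total / column sum, independently per species,
#' so both species' expression levels become comparable regardless of their
#' raw sequencing depth.
#'
#' @param matrix A `normalized_matrix` at stage `averaged`.
#' @param total Target column sum (default 1e7).
#' @return The matrix at stage `scaled`; every species x timepoint column
#'   sums to `total`.
#' @export
scale_to_total <- function(matrix, total = 1e7) {
  check_stage(matrix, "averaged")
  vals <- matrix$values
  for (sp in unique(matrix$species)) {
    rows <- matrix$species == sp
    sums <- colSums(vals[rows, , drop = FALSE])
    if (any(sums <= 0))
      stopf("species %s has zero total expression at timepoint %s; cannot scale",
            sp, matrix$timepoints[which(sums <= 0)[1L]])
    vals[rows, ] <- sweep(vals[rows, , drop = FALSE], 2L, total / sums, `*`)
  }
  new_normalized_matrix(vals, matrix$species, matrix$timepoints, "scaled",
                        scaling_total = total)
}

#' Remove genes not expressed throughout development
#'
#' Drops genes whose value is at or below `epsilon` at every timepoint of
#' their species; removed gene ids are reported in the `removed` field.
#'
#' @param matrix A `normalized_matrix` at stage `scaled`.
#' @param epsilon Expression floor (default 0: only all-zero genes go).
#' @return The matrix at stage `filtered`.
#' @export
filter_unexpressed <- function(matrix, epsilon = 0.0) {
  check_stage(matrix, "scaled")
  dead <- apply(matrix$values <= epsilon, 1L, all)
  new_normalized_matrix(matrix$values[!dead, , drop = FALSE],
                        matrix$species[!dead], matrix$timepoints, "filtered",
                        scaling_total = matrix$scaling_total,
                        removed = rownames(matrix$values)[dead])
}

#' Per-gene z-scores across timepoints
#'
#' (x - mean) / sd with the sample (n - 1) standard deviation. Rows with
#' zero variance have no defined Pearson correlation and are diverted to the
#' `excluded` field rather than clustered.
#'
#' @param matrix A `normalized_matrix` at stage `filtered`.
#' @return The matrix at stage `standardized`: every row has mean 0 and
#'   sample SD 1.
#' @export
standardize <- function(matrix) {
  check_stage(matrix, c("filtered", "scaled"))
  z <- zscore_rows(matrix$values)
  flat <- !is.finite(z$sd) | z$sd == 0
  new_normalized_matrix(z$values[!flat, , drop = FALSE],
                        matrix$species[!flat], matrix$timepoints,
                        "standardized", scaling_total = matrix$scaling_total,
                        removed = matrix$removed,
                        excluded = rownames(matrix$values)[flat])
}

#' Stack two standardized species matrices into one
#'
#' Row-binds the matrices, namespacing gene ids as `<species>::<gene>` so
#' both species' genes coexist in the collective clustering input.
#'
#' @param a,d `normalized_matrix` objects at stage `standardized` with
#'   identical timepoint labels.
#' @return A `normalized_matrix` at stage `combined`.
#' @export
combine_species <- function(a, d) {
  check_stage(a, "standardized")
  check_stage(d, "standardized")
  if (!identical(a$timepoints, d$timepoints))
    stopf("timepoint labels differ between the two species (%s vs %s)",
          paste(a$timepoints, collapse = "/"),
          paste(d$timepoints, collapse = "/"))
  va <- a$values; vd <- d$values
  rownames(va) <- paste(a$species, rownames(va), sep = "::")
  rownames(vd) <- paste(d$species, rownames(vd), sep = "::")
  new_normalized_matrix(rbind(va, vd), c(a$species, d$species),
                        a$timepoints, "combined",
                        scaling_total = a$scaling_total,
                        removed = c(a$removed, d$removed),
                        excluded = c(a$excluded, d$excluded))
}

#' Per-gene mean expression level of a scaled matrix
#'
#' Mean over timepoints of the post-scaling values; the quantity compared by
#' [call_alteration()].
#'
#' @param matrix A `normalized_matrix` at stage `scaled` or `filtered`.
#' @return Named numeric vector of per-gene means.
#' @export
mean_levels <- function(matrix) {
  check_stage(matrix, c("scaled", "filtered"))
  rowMeans(matrix$values)
}
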