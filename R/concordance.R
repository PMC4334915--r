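# Ortholog-pair concordance: classify each pair's temporal-expression
# relationship (match / similar / precocious / retarded), summarize class
# fractions, and call expression-level alterations.

concordance_classes <- c("match", "similar", "precocious", "retarded",
                         "unclassified")

#' Classify one ortholog pair's cluster relationship
#'
#' `match` if both genes sit in the same cluster; `similar` if in different
#' clusters of the same group; otherwise `precocious` or `retarded`
#' depending on which side occupies the down-regulated group. Under the
#' default `"down_in_a"` convention the pair is precocious when the
#' focal-species (A) gene is in the down group while the reference ortholog
#' is in the up group — the focal species switches its expression off
#' earlier, i.e. runs ahead; `"caption"` is the opposite orientation.
#' A missing cluster on either side gives `unclassified`.
#'
#' @param cluster_a,cluster_d Cluster indices (NA if the gene was filtered).
#' @param groups Group partition from [group_clusters()]
#'   (`list(down = ..., up = ...)`).
#' @param convention `"down_in_a"` (default) or `"caption"`.
#' @return One of match / similar / precocious / retarded / unclassified.
#' @export
classify_pair <- function(cluster_a, cluster_d, groups,
                          convention = c("down_in_a", "caption")) {
  convention <- match.arg(convention)
  if (is.na(cluster_a) || is.na(cluster_d)) return("unclassified")
  if (cluster_a == cluster_d) return("match")
  ga <- if (cluster_a %in% groups$down) "down" else "up"
  gd <- if (cluster_d %in% groups$down) "down" else "up"
  if (ga == gd) return("similar")
  early_a <- ga == "down"
  if (convention == "caption") early_a <- !early_a
  if (early_a) "precocious" else "retarded"
}

#' Classify every ortholog pair against a grouped clustering
#'
#' Looks up each pair's two genes in the combined clustering (rows are
#' namespaced `<species>::<gene>`) and applies [classify_pair()].
#'
#' @param pairs Data frame with columns `gene_a`, `gene_d` (and optionally
#'   `annotation`, carried through).
#' @param result A grouped `clustering_result` over the combined matrix.
#' @param species_a,species_d Species tags of the two columns.
#' @param convention Passed to [classify_pair()].
#' @return A `concordance_table` data frame: gene_a, gene_d, cluster_a,
#'   cluster_d, group_a, group_d, class (+ annotation if supplied).
#' @export
classify_pairs <- function(pairs, result, species_a, species_d,
                           convention = c("down_in_a", "caption")) {
  convention <- match.arg(convention)
  if (is.null(result$groups)) stopf("run group_clusters() first")
  lab <- result$labels
  ca <- unname(lab[paste0(species_a, "::", pairs$gene_a)])
  cd <- unname(lab[paste0(species_d, "::", pairs$gene_d)])
  grp <- function(cl) ifelse(is.na(cl), NA_character_,
                             ifelse(cl %in% result$groups$down, "down", "up"))
  cls <- vapply(seq_along(ca), function(i)
    classify_pair(ca[i], cd[i], result$groups, convention), character(1L))
  out <- data.frame(gene_a = pairs$gene_a, gene_d = pairs$gene_d,
                    cluster_a = ca, cluster_d = cd,
                    group_a = grp(ca), group_d = grp(cd),
                    class = cls, stringsAsFactors = FALSE)
  if (!is.null(pairs$annotation)) out$annotation <- pairs$annotation
  class(out) <- c("concordance_table", "data.frame")
  out
}

#' Concordance class fractions, overall and per annotation
#'
#' Fractions are over classified pairs (unclassified pairs are counted but
#' excluded from the denominator) and sum to 1. An empty annotation subset
#' is reported with n = 0 and no fractions.
#'
#' @param table A `concordance_table`.
#' @param by Optional column name (e.g. `"annotation"`) to stratify by.
#' @return List with `overall` (class, n, fraction) and, if `by` is given,
#'   `strata` (a data frame per level).
#' @export
summarize_concordance <- function(table, by = NULL) {
  if (!nrow(table)) stopf("concordance table is empty")
  tally <- function(df) {
    n <- as.integer(table(factor(df$class, levels = concordance_classes)))
    classified <- sum(n[concordance_classes != "unclassified"])
    data.frame(class = concordance_classes, n = n,
               fraction = if (classified > 0)
                 ifelse(concordance_classes == "unclassified", NA_real_,
                        n / classified) else NA_real_,
               stringsAsFactors = FALSE)
  }
  out <- list(overall = tally(table))
  if (!is.null(by)) {
    if (!by %in% names(table)) stopf("no column '%s' to stratify by", by)
    lv <- unique(table[[by]])
    out$strata <- lapply(stats::setNames(lv, lv), function(l)
      tally(table[table[[by]] == l, , drop = FALSE]))
  }
  out
}

#' Call expression-level alterations between orthologs
#'
#' Compares post-scaling per-gene mean expression levels. A focal-species
#' level at or below `trace_threshold` is `no_expression`; at least
#' `fold_threshold` times the reference level is `increased`; the reverse is
#' `depressed`; anything else is `comparable`.
#'
#' @param level_a,level_d Non-negative mean scaled expression levels
#'   (vectorized).
#' @param fold_threshold Fold change that counts as altered (default 4).
#' @param trace_threshold Level at or below which the focal gene counts as
#'   unexpressed (default 1, on the common 1e7 scale).
#' @return Character vector: no_expression / increased / depressed /
#'   comparable.
#' @export
call_alteration <- function(level_a, level_d, fold_threshold = 4.0,
                            trace_threshold = 1.0) {
  if (any(level_a < 0, na.rm = TRUE) || any(level_d < 0, na.rm = TRUE))
    stopf("expression levels must be non-negative")
  out <- rep("comparable", length(level_a))
  out[level_d >= fold_threshold * level_a] <- "depressed"
  out[level_a >= fold_threshold * level_d] <- "increased"
  out[level_a <= trace_threshold] <- "no_expression"
  out[is.na(level_a) | is.na(level_d)] <- NA_character_
  out
}

#' Attach alteration calls to a concordance table
#'
#' @param table A `concordance_table`.
#' @param levels_a,levels_d Named per-gene mean scaled levels (from
#'   [mean_levels()]); genes missing from the vectors get NA calls.
#' @param ... Passed to [call_alteration()].
#' @return The table with an `alteration` column.
#' @export
add_alterations <- function(table, levels_a, levels_d, ...) {
  la <- unname(levels_a[table$gene_a])
  ld <- unname(levels_d[table$gene_d])
  la[is.na(la)] <- 0  # filtered-out focal genes are unexpressed by definition
  table$alteration <- call_alteration(la, ld, ...)
  table
}
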