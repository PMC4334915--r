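# Reciprocal-best-hit orthology and four-species Venn-area decomposition.

#' Filter alignment hits on e-value, identity, coverage and similarity
#'
#' Each threshold is optional; an absent threshold imposes no constraint.
#' All bounds are inclusive ("greater/less than or equal"). Rows lacking a
#' value for a supplied threshold (e.g. no coverage column in plain outfmt-6
#' input) fail that constraint and are dropped with a notice.
#'
#' @param hits A [hit_table()].
#' @param max_evalue Keep hits with e-value <= this.
#' @param min_identity Keep hits with percent identity >= this.
#' @param min_coverage Keep hits with query coverage (0..1) >= this.
#' @param min_similarity Keep hits with percent similarity >= this.
#' @return The surviving subset, input order preserved.
#' @export
filter_hits <- function(hits, max_evalue = NULL, min_identity = NULL,
                        min_coverage = NULL, min_similarity = NULL) {
  stopifnot(inherits(hits, "hit_table"))
  if (nrow(hits) == 0L) return(hits)
  keep <- rep(TRUE, nrow(hits))
  take <- function(col, name) {
    v <- hits[[col]]
    if (is.null(v)) {
      message(sprintf("filter_hits: no %s column; %s constraint drops all rows",
                      col, name))
      v <- rep(NA_real_, nrow(hits))
    }
    v
  }
  if (!is.null(max_evalue)) keep <- keep & !is.na(hits$evalue) &
      hits$evalue <= max_evalue
  if (!is.null(min_identity)) keep <- keep & !is.na(hits$identity) &
      hits$identity >= min_identity
  if (!is.null(min_coverage)) {
    v <- take("coverage", "min_coverage")
    keep <- keep & !is.na(v) & v >= min_coverage
  }
  if (!is.null(min_similarity)) {
    v <- take("similarity", "min_similarity")
    keep <- keep & !is.na(v) & v >= min_similarity
  }
  out <- hits[keep, , drop = FALSE]
  hit_table(as.data.frame(out), attr(hits, "query_species"),
            attr(hits, "subject_species"))
}

#' Single best subject per query gene
#'
#' Bestness is by lowest e-value, ties broken by highest bitscore, then by
#' lexicographically smallest subject id, giving a single canonical best hit
#' per query. Queries without hits are absent from the map.
#'
#' @param hits A [hit_table()], already e-value filtered if desired.
#' @return Named character vector: query gene -> best subject gene.
#' @export
best_hits <- function(hits) {
  stopifnot(inherits(hits, "hit_table"))
  if (nrow(hits) == 0L) return(stats::setNames(character(0), character(0)))
  df <- as.data.frame(hits)
  ord <- order(df$query, df$evalue, -df$bitscore, df$subject,
               method = "radix")
  df <- df[ord, , drop = FALSE]
  first <- !duplicated(df$query)
  stats::setNames(df$subject[first], df$query[first])
}

# Lowest e-value per query among its hits (used to attach an evidence
# strength to each reciprocal pair).
best_evalues <- function(hits) {
  if (nrow(hits) == 0L) return(stats::setNames(numeric(0), character(0)))
  df <- as.data.frame(hits)
  ord <- order(df$query, df$evalue, -df$bitscore, df$subject, method = "radix")
  df <- df[ord, , drop = FALSE]
  first <- !duplicated(df$query)
  stats::setNames(df$evalue[first], df$query[first])
}

#' Reciprocal (bidirectional) best-hit orthologs between two species
#'
#' Both directed hit tables are filtered at `max_evalue`; the pair (a, b) is
#' an ortholog pair iff a's best surviving hit into the other species is b
#' and b's best surviving hit back is a. Genes with at least one surviving
#' hit that end up in no pair are recorded as paralogs of their species.
#'
#' @param hits_ab Hits with species A queries and species B subjects.
#' @param hits_ba The reverse direction.
#' @param max_evalue E-value threshold (default 1e-10).
#' @return An `ortholog_map`: `pairs` (data frame gene_a, gene_b, species_a,
#'   species_b, evalue), `paralogs` (per-species gene-id vectors), `species`,
#'   and `threshold_evalue`.
#' @export
bbh_orthologs <- function(hits_ab, hits_ba, max_evalue = 1e-10) {
  stopifnot(inherits(hits_ab, "hit_table"), inherits(hits_ba, "hit_table"))
  sp_a <- attr(hits_ab, "query_species")
  sp_b <- attr(hits_ab, "subject_species")
  if (!is.na(sp_a) || !is.na(sp_b)) {
    if (!identical(attr(hits_ba, "query_species"), sp_b) ||
        !identical(attr(hits_ba, "subject_species"), sp_a))
      stopf("species tags of the two hit tables are inconsistent (%s->%s vs %s->%s)",
            sp_a, sp_b, attr(hits_ba, "query_species"),
            attr(hits_ba, "subject_species"))
  }
  if (is.na(sp_a)) sp_a <- "A"
  if (is.na(sp_b)) sp_b <- "B"
  ab <- filter_hits(hits_ab, max_evalue = max_evalue)
  ba <- filter_hits(hits_ba, max_evalue = max_evalue)
  fwd <- best_hits(ab)
  rev <- best_hits(ba)
  mutual <- names(fwd)[!is.na(rev[fwd]) & rev[fwd] == names(fwd)]
  pairs <- data.frame(gene_a = mutual,
                      gene_b = unname(fwd[mutual]),
                      species_a = rep(sp_a, length(mutual)),
                      species_b = rep(sp_b, length(mutual)),
                      stringsAsFactors = FALSE)
  ev_a <- best_evalues(ab)
  ev_b <- best_evalues(ba)
  pairs$evalue <- if (nrow(pairs))
    pmin(ev_a[pairs$gene_a], ev_b[pairs$gene_b]) else numeric(0)
  pairs <- pairs[order(pairs$gene_a), , drop = FALSE]
  rownames(pairs) <- NULL
  seen_a <- unique(c(ab$query, ba$subject))
  seen_b <- unique(c(ba$query, ab$subject))
  paralogs <- list(sort(setdiff(seen_a, pairs$gene_a)),
                   sort(setdiff(seen_b, pairs$gene_b)))
  names(paralogs) <- c(sp_a, sp_b)
  structure(list(pairs = pairs, paralogs = paralogs,
                 species = c(sp_a, sp_b), threshold_evalue = max_evalue),
            class = "ortholog_map")
}

## ---- Venn decomposition -----------------------------------------------------

# Canonical area letters for a 4-species roster. Pairwise-only regions take
# A..F in combn(4, 2) order over roster positions; triple-only regions take
# G..J ordered by the excluded roster position (2, 4, 3, 1), which anchors G
# to the region absent from the second roster species; K is all four.
venn_letter_map <- function(roster) {
  stopifnot(length(roster) == 4L)
  lab <- character(0)
  combos <- utils::combn(4L, 2L)
  key <- function(idx) paste(sort(idx), collapse = ",")
  for (j in seq_len(ncol(combos)))
    lab[key(combos[, j])] <- LETTERS[j]            # A..F
  excl_order <- c(2L, 4L, 3L, 1L)
  for (j in seq_along(excl_order))
    lab[key(setdiff(1:4, excl_order[j]))] <- LETTERS[6L + j]  # G..J
  lab[key(1:4)] <- "K"
  lab
}

#' Decompose four species' genes into Venn areas
#'
#' Each gene is labelled by its ortholog-presence pattern over the other
#' three species: no orthologs anywhere makes it species-specific, otherwise
#' it falls into one of the 11 shared regions (6 pairwise-only, 4
#' triple-only, 1 all-four). Letters follow the canonical convention of
#' [venn_letter_map()] (K = shared by all four; G = the region absent from
#' the second roster species); explicit presence bitmasks are emitted
#' alongside so downstream code never depends on letters.
#'
#' @param maps List of the 6 pairwise `ortholog_map`s.
#' @param gene_universe Named list (one entry per species) of gene-id
#'   vectors; exactly 4 species.
#' @return A `venn_decomposition`: `assignments` (gene, species, bitmask,
#'   area), `counts` (species x area matrix), and `roster`.
#' @export
venn_decompose <- function(maps, gene_universe) {
  roster <- names(gene_universe)
  if (length(roster) != 4L) stopf("exactly 4 species are required")
  seen_pairs <- character(0)
  presence <- lapply(gene_universe, function(g) {
    m <- matrix(FALSE, length(g), 4L, dimnames = list(g, roster))
    m
  })
  for (m in maps) {
    stopifnot(inherits(m, "ortholog_map"))
    sp <- m$species
    if (!all(sp %in% roster))
      stopf("ortholog map species (%s) not in the roster",
            paste(sp, collapse = ", "))
    seen_pairs <- c(seen_pairs, paste(sort(sp), collapse = "|"))
    p <- m$pairs
    if (!nrow(p)) next
    bad_a <- setdiff(p$gene_a, gene_universe[[sp[1L]]])
    bad_b <- setdiff(p$gene_b, gene_universe[[sp[2L]]])
    if (length(bad_a) || length(bad_b))
      stopf("gene %s appears in an ortholog pair but not in the %s universe",
            c(bad_a, bad_b)[1L],
            if (length(bad_a)) sp[1L] else sp[2L])
    presence[[sp[1L]]][p$gene_a, sp[2L]] <- TRUE
    presence[[sp[2L]]][p$gene_b, sp[1L]] <- TRUE
  }
  expected <- apply(utils::combn(roster, 2L), 2L,
                    function(x) paste(sort(x), collapse = "|"))
  missing_pairs <- setdiff(expected, seen_pairs)
  if (length(missing_pairs))
    stopf("missing ortholog map for species pair(s): %s",
          paste(missing_pairs, collapse = ", "))
  letters_by_key <- venn_letter_map(roster)
  rows <- lapply(roster, function(sp) {
    m <- presence[[sp]]
    m[, sp] <- TRUE
    mask <- apply(m, 1L, function(r) paste(as.integer(r), collapse = ""))
    n_shared <- rowSums(m)
    key <- apply(m, 1L, function(r) paste(which(r), collapse = ","))
    area <- ifelse(n_shared == 1L, "species_specific",
                   unname(letters_by_key[key]))
    data.frame(gene = rownames(m), species = sp, bitmask = mask,
               area = area, stringsAsFactors = FALSE)
  })
  assignments <- do.call(rbind, rows)
  rownames(assignments) <- NULL
  area_levels <- c(LETTERS[1:11], "species_specific")
  counts <- table(factor(assignments$species, levels = roster),
                  factor(assignments$area, levels = area_levels))
  counts <- matrix(as.integer(counts), nrow = length(roster),
                   dimnames = list(roster, area_levels))
  structure(list(assignments = assignments, counts = counts, roster = roster),
            class = "venn_decomposition")
}
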