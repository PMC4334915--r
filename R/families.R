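# Gene-family assignment by homology propagation and lineage-dependent
# expansion/contraction flagging from family-size tables.

#' Propagate family membership from reference-species seed families
#'
#' Seed families partition (a subset of) the reference species' genes.
#' Every non-reference gene that is a reciprocal-best ortholog of a seeded
#' reference gene inherits that family; genes without an ortholog assignment
#' then inherit through their within-species homolog (paralog) links,
#' strongest link first. A gene reachable from two different families is
#' assigned to the one with the stronger (lower e-value) link, and the
#' conflict is counted in a notice. Cyclic link sets cannot loop: each pass
#' only assigns currently unassigned genes, and passes stop at a fixpoint.
#'
#' @param seed_families Named character vector (or data frame with columns
#'   `gene`, `family_id`) mapping reference genes to family ids.
#' @param ortholog_maps List of `ortholog_map`s; only pairs involving the
#'   reference species propagate membership.
#' @param paralog_links Optional named list (by species) of data frames with
#'   columns `gene`, `partner`, `evalue` describing within-species homolog
#'   links.
#' @param reference_species Species whose genes carry the seed families.
#' @return A `family_table`: `members` (data frame species, gene, family_id,
#'   origin, link_evalue) and `sizes` (family x species count matrix).
#' @export
assign_families <- function(seed_families, ortholog_maps,
                            paralog_links = NULL, reference_species) {
  if (is.data.frame(seed_families))
    seed_families <- stats::setNames(as.character(seed_families$family_id),
                                     seed_families$gene)
  key <- function(sp, g) paste(sp, g, sep = "\r")
  fam <- new.env(parent = emptyenv())
  put <- function(sp, g, id, origin, ev) {
    assign(key(sp, g), list(family_id = id, species = sp, gene = g,
                            origin = origin, evalue = ev), envir = fam)
  }
  for (g in names(seed_families))
    put(reference_species, g, seed_families[[g]], "seed", 0)

  # Direct ortholog propagation from seeded reference genes.
  for (m in ortholog_maps) {
    if (!reference_species %in% m$species || !nrow(m$pairs)) next
    ref_is_a <- m$species[1L] == reference_species
    ref_gene <- if (ref_is_a) m$pairs$gene_a else m$pairs$gene_b
    oth_gene <- if (ref_is_a) m$pairs$gene_b else m$pairs$gene_a
    oth_sp <- setdiff(m$species, reference_species)
    seeded <- ref_gene %in% names(seed_families)
    for (i in which(seeded))
      put(oth_sp, oth_gene[i], seed_families[[ref_gene[i]]], "ortholog",
          m$pairs$evalue[i])
  }

  # Paralog propagation: repeatedly assign unassigned genes through their
  # strongest link into an already assigned gene.
  n_conflicts <- 0L
  if (!is.null(paralog_links)) {
    edges <- do.call(rbind, lapply(names(paralog_links), function(sp) {
      df <- paralog_links[[sp]]
      if (is.null(df) || !nrow(df)) return(NULL)
      data.frame(species = sp, gene = df$gene, partner = df$partner,
                 evalue = df$evalue, stringsAsFactors = FALSE)
    }))
    if (!is.null(edges) && nrow(edges)) {
      # undirected: consider both orientations
      edges <- rbind(edges,
                     data.frame(species = edges$species, gene = edges$partner,
                                partner = edges$gene, evalue = edges$evalue))
      edges <- edges[order(edges$evalue, edges$species, edges$gene,
                           edges$partner, method = "radix"), , drop = FALSE]
      repeat {
        assigned_partner <- vapply(seq_len(nrow(edges)), function(i)
          exists(key(edges$species[i], edges$partner[i]), envir = fam),
          logical(1L))
        assigned_gene <- vapply(seq_len(nrow(edges)), function(i)
          exists(key(edges$species[i], edges$gene[i]), envir = fam),
          logical(1L))
        usable <- assigned_partner & !assigned_gene
        if (!any(usable)) break
        done <- character(0)
        for (i in which(usable)) {
          k <- key(edges$species[i], edges$gene[i])
          src <- get(key(edges$species[i], edges$partner[i]), envir = fam)
          if (k %in% done) {
            prev <- get(k, envir = fam)
            if (prev$family_id != src$family_id) n_conflicts <- n_conflicts + 1L
            next  # a stronger link already decided this gene
          }
          put(edges$species[i], edges$gene[i], src$family_id, "paralog",
              edges$evalue[i])
          done <- c(done, k)
        }
      }
    }
  }
  if (n_conflicts > 0L)
    message(sprintf("assign_families: %d gene(s) reachable from multiple families; strongest link kept",
                    n_conflicts))
  members <- do.call(rbind, lapply(ls(fam), function(k) {
    v <- get(k, envir = fam)
    data.frame(species = v$species, gene = v$gene, family_id = v$family_id,
               origin = v$origin, link_evalue = v$evalue,
               stringsAsFactors = FALSE)
  }))
  members <- members[order(members$family_id, members$species, members$gene), ]
  rownames(members) <- NULL
  structure(list(members = members, sizes = family_sizes(members)),
            class = "family_table")
}

#' Family x species size matrix from a member table
#'
#' @param members Data frame with `family_id` and `species` columns.
#' @param species Optional species order for the columns.
#' @return Integer matrix, families as rows.
#' @export
family_sizes <- function(members, species = NULL) {
  if (is.null(species)) species <- unique(members$species)
  tab <- table(factor(members$family_id),
               factor(members$species, levels = species))
  matrix(as.integer(tab), nrow = nrow(tab),
         dimnames = list(rownames(tab), species))
}

#' Flag lineage-dependent family expansions and contractions
#'
#' For each family the smallest per-species size (floored at 1) acts as the
#' baseline; every species whose size is at least `ratio_threshold` times
#' the baseline and at least `min_size` belongs to the expanded set. An
#' expanded set covering all but one species is reported as a contraction
#' ("lack of expansion") of the excluded species; a set matching a declared
#' lineage grouping is labelled with that group's name. A family absent from
#' a species simply has size 0.
#'
#' @param sizes Family x species count matrix (or a `family_table`).
#' @param ratio_threshold Fold-change over the baseline that counts as an
#'   expansion (default 3).
#' @param min_size Minimum absolute size of an expanded family member set
#'   (default 4); keeps 1-vs-2 noise from being called an expansion.
#' @param lineage_groups Optional named list of species vectors (e.g.
#'   `list("Group 2" = c("Asub", "Ppal"))`) for multi-species lineage
#'   patterns.
#' @return Data frame of `expansion_call`s: family_id, pattern
#'   (`expanded_in` / `contracted_in` / `none`), species (comma-joined),
#'   label, ratio.
#' @export
flag_expansions <- function(sizes, ratio_threshold = 3.0, min_size = 4L,
                            lineage_groups = NULL) {
  if (inherits(sizes, "family_table")) sizes <- sizes$sizes
  sizes <- as.matrix(sizes)
  if (ncol(sizes) < 2L) stopf("at least 2 species are required")
  species <- colnames(sizes)
  calls <- lapply(seq_len(nrow(sizes)), function(i) {
    s <- sizes[i, ]
    baseline <- max(min(s), 1)
    expanded <- species[s >= ratio_threshold * baseline & s >= min_size]
    if (!length(expanded)) {
      pattern <- "none"; who <- ""; label <- "none"
      ratio <- max(s, 1) / baseline
    } else {
      ratio <- min(s[expanded]) / baseline
      if (length(expanded) == length(species) - 1L) {
        excluded <- setdiff(species, expanded)
        pattern <- "contracted_in"; who <- excluded
        label <- sprintf("lack of expansion in %s", excluded)
      } else {
        pattern <- "expanded_in"; who <- paste(expanded, collapse = ",")
        grp <- NULL
        for (g in names(lineage_groups))
          if (setequal(lineage_groups[[g]], expanded)) grp <- g
        label <- if (!is.null(grp)) sprintf("expansion in %s", grp)
        else if (length(expanded) == 1L)
          sprintf("expansion in %s lineage", expanded)
        else sprintf("expansion in %s", paste(expanded, collapse = "+"))
      }
    }
    data.frame(family_id = rownames(sizes)[i] %||% as.character(i),
               pattern = pattern, species = who, label = label,
               ratio = ratio, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, calls)
  rownames(out) <- NULL
  out
}
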