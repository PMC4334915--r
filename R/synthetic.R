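# Synthetic-data generators with planted ground truth. These define the
# study conditions every pipeline stage is exercised under: hit tables with
# known reciprocal-best/Venn structure, family-size tables with known
# lineage expansions, and two-species 4-timepoint expression matrices built
# from temporal archetype profiles with known concordance classes.
# All generators are pure functions of (parameters, seed).

#' Build k temporal archetype profiles (z-scored)
#'
#' Constructs `n_down` strictly falling and `k - n_down` rising profiles on
#' the sphere of z-scored (mean 0, sample SD 1) time courses. Profiles are
#' combinations of orthonormal polynomial trend contrasts: the pure falling
#' and rising ramps sit on the linear axis, and the remaining archetypes sit
#' 50 degrees off it at evenly spread azimuths in the quadratic/cubic plane,
#' which staggers their peak times and guarantees mutual Pearson distance of
#' at least 0.3 for the default 8-archetype, 4-timepoint setting.
#'
#' @param k Number of archetypes (default 8).
#' @param n_timepoints Number of timepoints (default 4).
#' @param n_down Number of down-regulated archetypes (default 3).
#' @return k x n_timepoints matrix with a `direction` attribute
#'   (`"down"`/`"up"` per row); down archetypes occupy rows 1..n_down.
#' @export
make_archetypes <- function(k = 8L, n_timepoints = 4L, n_down = 3L) {
  if (n_down < 1L || n_down >= k) stopf("need 1 <= n_down < k")
  if (n_timepoints < 3L) stopf("at least 3 timepoints are required")
  deg <- min(3L, n_timepoints - 1L)
  basis <- unclass(stats::poly(seq_len(n_timepoints), degree = deg))
  L <- basis[, 1L]
  Q <- basis[, 2L]
  C <- if (deg >= 3L) basis[, 3L] else rep(0, n_timepoints)
  ray <- function(theta_deg, phi_deg) {
    th <- theta_deg * pi / 180
    ph <- phi_deg * pi / 180
    cos(th) * L + sin(th) * (cos(ph) * Q + sin(ph) * C)
  }
  fan <- function(m, theta_main, theta_off, phi0) {
    if (m == 1L) return(list(ray(theta_main, 0)))
    phis <- phi0 + (seq_len(m - 1L) - 1L) * 360 / (m - 1L)
    c(list(ray(theta_main, 0)), lapply(phis, function(p) ray(theta_off, p)))
  }
  rows <- c(fan(n_down, 180, 130, 45), fan(k - n_down, 0, 50, 0))
  arch <- do.call(rbind, rows) * sqrt(n_timepoints - 1L)
  rownames(arch) <- paste0("A", seq_len(k))
  dmin <- if (k > 1L) {
    d <- 1 - stats::cor(t(arch))
    min(d[upper.tri(d)])
  } else 2
  if (dmin < 0.3)
    warnf("archetypes are closer than Pearson distance 0.3 (min %.3f); consider fewer archetypes or more timepoints", dmin)
  structure(arch, direction = rep(c("down", "up"), c(n_down, k - n_down)))
}

#' Plant ortholog-pair concordance classes
#'
#' Draws each pair's class from `class_proportions` and picks archetypes
#' realizing it: `match` shares one archetype, `similar` takes two distinct
#' archetypes of the same direction, `precocious`/`retarded` take opposite
#' directions oriented by `convention` (default: a precocious pair has its
#' focal (A) gene on a down archetype and its reference gene on an up one).
#' The shared direction of match/similar pairs is down with probability
#' `down_share`.
#'
#' @param n_pairs Number of pairs.
#' @param archetypes Output of [make_archetypes()].
#' @param class_proportions Named proportions over match / similar /
#'   precocious / retarded; must sum to 1.
#' @param down_share P(down) for the shared direction of match/similar
#'   pairs (default 0.18, the reference species' down occupancy).
#' @param convention Orientation of precocious (see [classify_pair()]).
#' @param seed Optional seed.
#' @return Data frame: pair, class, arch_a, arch_d (archetype row indices).
#' @export
plant_ortholog_pairs <- function(n_pairs, archetypes,
                                 class_proportions = c(match = 0.18,
                                                       similar = 0.32,
                                                       precocious = 0.30,
                                                       retarded = 0.20),
                                 down_share = 0.18,
                                 convention = c("down_in_a", "caption"),
                                 seed = NULL) {
  convention <- match.arg(convention)
  if (abs(sum(class_proportions) - 1) > 1e-8)
    stopf("class proportions must sum to 1")
  dir <- attr(archetypes, "direction")
  down_idx <- which(dir == "down")
  up_idx <- which(dir == "up")
  if (length(down_idx) < 2L || length(up_idx) < 2L)
    stopf("similar pairs need at least 2 archetypes per direction")
  with_seed(seed, {
    cls <- sample(names(class_proportions), n_pairs, replace = TRUE,
                  prob = class_proportions)
    arch_a <- integer(n_pairs)
    arch_d <- integer(n_pairs)
    for (i in seq_len(n_pairs)) {
      pool_down <- stats::runif(1) < down_share
      shared <- if (pool_down) down_idx else up_idx
      if (cls[i] == "match") {
        arch_a[i] <- arch_d[i] <- sample(shared, 1L)
      } else if (cls[i] == "similar") {
        two <- sample(shared, 2L)
        arch_a[i] <- two[1L]; arch_d[i] <- two[2L]
      } else {
        a_down <- cls[i] == "precocious"
        if (convention == "caption") a_down <- !a_down
        arch_a[i] <- sample(if (a_down) down_idx else up_idx, 1L)
        arch_d[i] <- sample(if (a_down) up_idx else down_idx, 1L)
      }
    }
    data.frame(pair = seq_len(n_pairs), class = cls,
               arch_a = arch_a, arch_d = arch_d, stringsAsFactors = FALSE)
  })
}

#' Simulate two species' developmental time courses
#'
#' Each gene follows one archetype: its expected count at timepoint t is
#' base abundance x (offset + archetype value) x transcript length (kb) x
#' sequencing depth (millions), perturbed by multiplicative log-normal noise
#' of sdlog `noise_sd` per replicate. Counts are continuous expected
#' coverage values, so the zero-noise limit is exact: z-scoring a gene's
#' replicate-mean RPKM profile returns its archetype bit-for-bit. Paired
#' genes (from [plant_ortholog_pairs()]) take their planted archetypes and
#' map to gene i of each species; a `zero_fraction` of the unpaired genes is
#' all-zero to exercise the expression filter, and the remaining unpaired
#' genes are assigned directions so each species hits its target
#' down-regulated fraction.
#'
#' @param archetypes Output of [make_archetypes()].
#' @param n_genes Named 2-vector of gene counts (focal species first).
#' @param pairs Optional pair table from [plant_ortholog_pairs()].
#' @param down_fraction Target per-species fraction of genes on down
#'   archetypes (default 0.55 focal / 0.18 reference).
#' @param replicates Named per-species replicate counts (default 6 and 2).
#' @param timepoints Timepoint labels (default 0, 8, 16, 24 h).
#' @param noise_sd Log-normal sdlog of the multiplicative noise.
#' @param zero_fraction Fraction of genes planted all-zero.
#' @param offset Positive offset added to archetype z-values (default 3,
#'   clear of the largest archetype amplitude).
#' @param seed Optional seed.
#' @return List: `tables` (one [expression_table()] of counts per species),
#'   `total_mapped` (per-species named vectors), `pairs` (with gene ids
#'   attached), `truth` (per-gene species, gene, archetype, direction).
#' @export
simulate_timecourses <- function(archetypes,
                                 n_genes = c(Asub = 2000L, Ddis = 2000L),
                                 pairs = NULL,
                                 down_fraction = c(Asub = 0.55, Ddis = 0.18),
                                 replicates = c(Asub = 6L, Ddis = 2L),
                                 timepoints = c("0", "8", "16", "24"),
                                 noise_sd = 0.1, zero_fraction = 0.05,
                                 offset = 3, seed = NULL) {
  species <- names(n_genes)
  if (length(species) != 2L) stopf("exactly two species are required")
  n_tp <- length(timepoints)
  if (ncol(archetypes) != n_tp)
    stopf("archetypes have %d timepoints, expected %d", ncol(archetypes), n_tp)
  dir <- attr(archetypes, "direction")
  down_idx <- which(dir == "down")
  up_idx <- which(dir == "up")
  n_pairs <- if (is.null(pairs)) 0L else nrow(pairs)
  if (any(n_genes < n_pairs)) stopf("more pairs than genes in a species")
  with_seed(seed, {
    tables <- list()
    total_mapped <- list()
    truth <- list()
    for (si in 1:2) {
      sp <- species[si]
      n <- n_genes[[sp]]
      ids <- sprintf("%s_g%05d", tolower(sp), seq_len(n))
      arch_of <- rep(NA_integer_, n)
      if (n_pairs)
        arch_of[seq_len(n_pairs)] <- if (si == 1L) pairs$arch_a else pairs$arch_d
      unpaired <- setdiff(seq_len(n), seq_len(n_pairs))
      n_zero <- round(zero_fraction * n)
      zero_genes <- utils::tail(unpaired, n_zero)
      free <- setdiff(unpaired, zero_genes)
      target_down <- round(down_fraction[[sp]] * (n - n_zero))
      have_down <- sum(arch_of %in% down_idx, na.rm = TRUE)
      need_down <- min(max(target_down - have_down, 0L), length(free))
      down_free <- free[sample.int(length(free), need_down)]
      arch_of[down_free] <- down_idx[sample.int(length(down_idx), need_down,
                                                replace = TRUE)]
      rest <- setdiff(free, down_free)
      arch_of[rest] <- up_idx[sample.int(length(up_idx), length(rest),
                                         replace = TRUE)]
      arch_of[zero_genes] <- NA_integer_

      lens <- sample(300:6000, n, replace = TRUE)
      base <- 10^stats::runif(n, 0, 3)
      cols <- as.vector(t(outer(timepoints, seq_len(replicates[[sp]]),
                                paste, sep = "_")))
      depth <- round(stats::runif(length(cols), 4e6, 6e6))
      names(depth) <- cols
      vals <- matrix(0, n, length(cols), dimnames = list(ids, cols))
      col_tp <- rep(seq_len(n_tp), each = replicates[[sp]])
      live <- !is.na(arch_of)
      for (j in seq_along(cols)) {
        mu <- base[live] * (offset + archetypes[arch_of[live], col_tp[j]]) *
          (lens[live] / 1000) * (depth[j] / 1e6)
        if (noise_sd > 0)
          mu <- mu * exp(stats::rnorm(sum(live), 0, noise_sd))
        vals[live, j] <- mu
      }
      vals <- signif(vals, 12)  # survives decimal round-tripping exactly
      tables[[sp]] <- expression_table(vals, species = sp, lengths_bp = lens,
                                       timepoints = timepoints)
      total_mapped[[sp]] <- depth
      truth[[sp]] <- data.frame(species = sp, gene = ids,
                                archetype = arch_of,
                                direction = ifelse(is.na(arch_of), NA,
                                                   dir[arch_of]),
                                stringsAsFactors = FALSE)
    }
    if (n_pairs) {
      pairs$gene_a <- tables[[species[1L]]]$genes[seq_len(n_pairs)]
      pairs$gene_d <- tables[[species[2L]]]$genes[seq_len(n_pairs)]
    }
    list(tables = tables, total_mapped = total_mapped, pairs = pairs,
         truth = do.call(rbind, truth))
  })
}

## ---- hit tables with planted Venn structure ---------------------------------

random_hit_rows <- function(query, subject, evalue) {
  n <- length(query)
  len <- sample(100:500, n, replace = TRUE)
  data.frame(query = query, subject = subject,
             identity = round(stats::runif(n, 40, 99), 1),
             length = len,
             mismatches = sample(0:50, n, replace = TRUE),
             gapopens = sample(0:5, n, replace = TRUE),
             qstart = 1L, qend = len, sstart = 1L, send = len,
             evalue = evalue,
             bitscore = round(-10 * log10(evalue + 1e-300) +
                                stats::runif(n, 0, 5), 1),
             stringsAsFactors = FALSE)
}

#' Simulate directed hit tables with planted ortholog structure
#'
#' Plants ortholog groups (one gene per member species, mutual best hits at
#' e <= 1e-20 with strictly worse decoy hits on top), paralog-only genes
#' (one-directional surviving hits at 1e-15..1e-11 that fail the reciprocal
#' test), and species-specific genes (no hits, or hits weaker than 1e-10),
#' for a 4-species roster.
#'
#' @param n_genes Genes per species (default 200).
#' @param species Roster of 4 species ids.
#' @param weight_all4 Fraction of genes in all-four groups (default 0.45).
#' @param weight_triple Fraction per 3-species region (default 0.04).
#' @param weight_pair Fraction per 2-species region (default 0.02).
#' @param paralog_fraction Fraction of paralog-only genes (default 0.05).
#' @param decoy_fraction Fraction of grouped genes receiving an extra,
#'   strictly worse secondary hit (default 0.3).
#' @param seed Optional seed.
#' @return List: `hits` (12 directed [hit_table()]s named `"A->B"`),
#'   `universe` (per-species gene ids), `truth` (gene, species, bitmask,
#'   area, role), `paralog_links` (per-species within-species homolog links),
#'   `seed_families` (reference = first roster species; gene -> family id for
#'   its grouped genes), `group_of` (gene -> family id over all species).
#' @export
simulate_hit_tables <- function(n_genes = 200L,
                                species = c("Ddis", "Asub", "Ppal", "Dfas"),
                                weight_all4 = 0.45, weight_triple = 0.04,
                                weight_pair = 0.02, paralog_fraction = 0.05,
                                decoy_fraction = 0.3, seed = NULL) {
  if (length(species) != 4L) stopf("exactly 4 species are required")
  with_seed(seed, {
    universe <- stats::setNames(lapply(species, function(sp)
      sprintf("%s_%04d", tolower(sp), seq_len(n_genes))), species)
    used <- stats::setNames(rep(0L, 4L), species)
    take <- function(sp) {
      used[sp] <<- used[sp] + 1L
      if (used[sp] > n_genes) stopf("region weights exceed the gene budget")
      universe[[sp]][used[sp]]
    }
    regions <- c(list(1:4),
                 lapply(4:1, function(x) setdiff(1:4, x)),
                 lapply(seq_len(6), function(j) utils::combn(1:4, 2)[, j]))
    region_n <- c(round(weight_all4 * n_genes),
                  rep(round(weight_triple * n_genes), 4L),
                  rep(round(weight_pair * n_genes), 6L))
    groups <- list()
    gid <- 0L
    for (ri in seq_along(regions)) {
      for (g in seq_len(region_n[ri])) {
        gid <- gid + 1L
        members <- stats::setNames(
          vapply(species[regions[[ri]]], take, ""), species[regions[[ri]]])
        groups[[gid]] <- members
      }
    }
    fam_of <- new.env(parent = emptyenv())
    for (gi in seq_along(groups))
      for (g in groups[[gi]])
        assign(g, sprintf("FAM%04d", gi), envir = fam_of)

    keys <- character(0)
    for (a in species) for (b in species)
      if (a != b) keys <- c(keys, paste0(a, "->", b))
    rows <- stats::setNames(vector("list", length(keys)), keys)
    add_hit <- function(from, to, q, s, ev)
      rows[[paste0(from, "->", to)]][[length(rows[[paste0(from, "->", to)]]) + 1L]] <<-
        c(q, s, ev)

    for (members in groups) {
      sp_in <- names(members)
      for (a in sp_in) for (b in sp_in) {
        if (a == b) next
        add_hit(a, b, members[[a]], members[[b]], 10^-stats::runif(1, 20, 60))
      }
    }
    # decoy secondary hits between grouped genes, strictly worse than 1e-20
    grouped <- lapply(species, function(sp)
      universe[[sp]][seq_len(used[sp])])
    names(grouped) <- species
    for (a in species) for (b in setdiff(species, a)) {
      if (!length(grouped[[a]]) || length(grouped[[b]]) < 2L) next
      n_decoy <- round(decoy_fraction * length(grouped[[a]]) / 3)
      if (!n_decoy) next
      qs <- sample(grouped[[a]], n_decoy, replace = TRUE)
      for (q in qs)
        add_hit(a, b, q, sample(grouped[[b]], 1L), 10^-stats::runif(1, 12, 19))
    }
    # paralog-only genes: a surviving one-directional hit; the reciprocal
    # direction's best points elsewhere, so the gene joins no pair
    paralog_links <- stats::setNames(
      lapply(species, function(sp) NULL), species)
    n_para <- round(paralog_fraction * n_genes)
    if (n_para > 0L && any(!lengths(grouped)))
      stopf("paralog-only genes need at least one planted ortholog group per species")
    para <- list()
    for (sp in species) {
      ids <- vapply(seq_len(n_para), function(i) take(sp), "")
      para[[sp]] <- ids
      for (g in ids) {
        tgt_sp <- sample(setdiff(species, sp), 1L)
        add_hit(sp, tgt_sp, g, grouped[[tgt_sp]][sample.int(
          length(grouped[[tgt_sp]]), 1L)], 10^-stats::runif(1, 11, 15))
      }
      # within-species homolog links used for family propagation
      paralog_links[[sp]] <- data.frame(
        gene = ids,
        partner = grouped[[sp]][sample.int(length(grouped[[sp]]), n_para,
                                           replace = TRUE)],
        evalue = 10^-stats::runif(n_para, 12, 30), stringsAsFactors = FALSE)
    }
    # species-specific leftovers: half carry sub-threshold hits (> 1e-10)
    for (sp in species) {
      if (used[sp] >= n_genes) next
      left <- universe[[sp]][seq.int(used[sp] + 1L, n_genes)]
      weak <- left[seq_len(floor(length(left) / 2))]
      for (g in weak) {
        candidates <- setdiff(species, sp)
        candidates <- candidates[lengths(grouped[candidates]) > 0L]
        if (!length(candidates)) break
        tgt_sp <- candidates[sample.int(length(candidates), 1L)]
        add_hit(sp, tgt_sp, g, grouped[[tgt_sp]][sample.int(
          length(grouped[[tgt_sp]]), 1L)], 10^-stats::runif(1, 5, 9))
      }
    }
    hits <- stats::setNames(lapply(keys, function(k) {
      sp2 <- strsplit(k, "->", fixed = TRUE)[[1L]]
      r <- rows[[k]]
      if (!length(r))
        return(hit_table(data.frame(), sp2[1L], sp2[2L]))
      df <- random_hit_rows(vapply(r, `[`, "", 1L), vapply(r, `[`, "", 2L),
                            as.numeric(vapply(r, `[`, "", 3L)))
      df$evalue <- signif(df$evalue, 12)
      hit_table(df, sp2[1L], sp2[2L])
    }), keys)

    letters_by_key <- venn_letter_map(species)
    truth <- do.call(rbind, lapply(species, function(sp) {
      si <- match(sp, species)
      g <- universe[[sp]]
      present <- matrix(FALSE, length(g), 4L, dimnames = list(g, species))
      present[, si] <- TRUE
      for (members in groups)
        if (sp %in% names(members))
          present[members[[sp]], names(members)] <- TRUE
      mask <- apply(present, 1L, function(r) paste(as.integer(r), collapse = ""))
      key <- apply(present, 1L, function(r) paste(which(r), collapse = ","))
      area <- ifelse(rowSums(present) == 1L, "species_specific",
                     unname(letters_by_key[key]))
      role <- rep("species_specific", length(g))
      role[g %in% unlist(lapply(groups, function(m)
        if (sp %in% names(m)) m[[sp]] else NULL))] <- "ortholog"
      role[g %in% para[[sp]]] <- "paralog"
      data.frame(gene = g, species = sp, bitmask = mask, area = area,
                 role = role, stringsAsFactors = FALSE)
    }))
    rownames(truth) <- NULL
    ref <- species[1L]
    ref_grouped <- vapply(groups, function(m)
      if (ref %in% names(m)) m[[ref]] else NA_character_, "")
    seed_families <- stats::setNames(
      sprintf("FAM%04d", which(!is.na(ref_grouped))),
      ref_grouped[!is.na(ref_grouped)])
    group_of <- stats::setNames(
      unlist(lapply(seq_along(groups), function(gi)
        rep(sprintf("FAM%04d", gi), length(groups[[gi]])))),
      unlist(groups))
    list(hits = hits, universe = universe, truth = truth,
         paralog_links = paralog_links, seed_families = seed_families,
         group_of = group_of)
  })
}

#' Simulate a family-size table with planted lineage expansions
#'
#' Background families take a small base size with 0/1 jitter per species
#' (never enough to trip the expansion rule at its defaults). Planted
#' families force the rule to fire: single-species and lineage-group
#' expansions set the chosen species at least `ratio` times the rest, and
#' planted contractions ("lack of expansion") expand every species but one.
#'
#' @param n_families Total families (default 120).
#' @param species Roster (default the 4 dictyostelid tags).
#' @param n_single Planted single-species expansions (default 8).
#' @param n_lack Planted contractions (default 4).
#' @param lineage_groups Optional named list of species vectors; one planted
#'   expansion per group.
#' @param ratio Planted fold factor (default 3).
#' @param seed Optional seed.
#' @return List: `sizes` (family x species matrix), `truth` (family_id,
#'   pattern, species).
#' @export
simulate_family_sizes <- function(n_families = 120L,
                                  species = c("Ddis", "Asub", "Ppal", "Dfas"),
                                  n_single = 8L, n_lack = 4L,
                                  lineage_groups = NULL, ratio = 3,
                                  seed = NULL) {
  with_seed(seed, {
    n_sp <- length(species)
    sizes <- matrix(0L, n_families, n_sp,
                    dimnames = list(sprintf("OG%05d", seq_len(n_families)),
                                    species))
    base <- sample(1:3, n_families, replace = TRUE)
    for (j in seq_len(n_sp))
      sizes[, j] <- base + sample(0:1, n_families, replace = TRUE)
    planted <- data.frame(family_id = character(0), pattern = character(0),
                          species = character(0), stringsAsFactors = FALSE)
    slot <- 0L
    plant <- function(targets, pattern, who) {
      slot <<- slot + 1L
      lo <- sample(1:2, n_sp, replace = TRUE)
      sizes[slot, ] <<- lo
      hi <- max(4, ceiling(ratio * max(lo)) + sample(0:3, 1L))
      sizes[slot, targets] <<- hi + sample(0:2, length(targets), replace = TRUE)
      planted <<- rbind(planted, data.frame(
        family_id = rownames(sizes)[slot], pattern = pattern,
        species = who, stringsAsFactors = FALSE))
    }
    for (i in seq_len(n_single))
      plant(species[(i - 1L) %% n_sp + 1L], "expanded_in",
            species[(i - 1L) %% n_sp + 1L])
    for (i in seq_len(n_lack)) {
      excl <- species[(i - 1L) %% n_sp + 1L]
      plant(setdiff(species, excl), "contracted_in", excl)
    }
    for (g in names(lineage_groups))
      plant(lineage_groups[[g]], "expanded_in",
            paste(sort(lineage_groups[[g]]), collapse = ","))
    list(sizes = sizes, truth = planted)
  })
}
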