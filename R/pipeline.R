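# File-based stage driver: simulate -> orthology -> families -> normalize ->
# cluster -> concord, each stage reading the previous stage's artifacts and
# writing its own plus a provenance record (input checksums, parameters,
# seed, package version). No timestamps go into any artifact, so reruns
# with the same seed are byte-identical.

#' Pipeline configuration
#'
#' Defaults follow the study conditions: e-value threshold 1e-10 for
#' reciprocal best hits, per-timepoint scaling total 1e7, Pearson-distance
#' K-means with k = 8 and 100 random restarts, timepoints 0/8/16/24 h.
#'
#' @param outdir Output directory (created if needed).
#' @param seed Master seed; every stage derives its randomness from it.
#' @param species Roster of 4 species; the first is the reference.
#' @param species_a Focal species of the transcriptome comparison.
#' @param species_d Reference species of the transcriptome comparison.
#' @param max_evalue Reciprocal-best-hit e-value threshold.
#' @param scaling_total Per-timepoint column total after scaling.
#' @param k,restarts K-means cluster count and restart count.
#' @param timepoints Developmental timepoint labels.
#' @param epsilon Expression floor for the unexpressed-gene filter.
#' @param ratio_threshold,min_size Family-expansion rule parameters.
#' @param fold_threshold,trace_threshold Alteration-call thresholds.
#' @param convention Precocious-orientation convention.
#' @param n_genes_tc Genes per species in the simulated time courses.
#' @param n_pairs Planted ortholog pairs.
#' @param n_genes_venn Genes per species in the simulated hit tables.
#' @param noise_sd,zero_fraction Time-course noise and all-zero gene
#'   fraction.
#' @param class_proportions Planted concordance-class proportions.
#' @param down_fraction Planted per-species down-regulated fractions.
#' @return A `pipeline_config`.
#' @export
pipeline_config <- function(outdir, seed = 42L,
                            species = c("Ddis", "Asub", "Ppal", "Dfas"),
                            species_a = "Asub", species_d = "Ddis",
                            max_evalue = 1e-10, scaling_total = 1e7,
                            k = 8L, restarts = 100L,
                            timepoints = c("0", "8", "16", "24"),
                            epsilon = 0, ratio_threshold = 3.0,
                            min_size = 4L, fold_threshold = 4.0,
                            trace_threshold = 1.0,
                            convention = "down_in_a",
                            n_genes_tc = 2000L, n_pairs = 1000L,
                            n_genes_venn = 200L, noise_sd = 0.1,
                            zero_fraction = 0.05,
                            class_proportions = c(match = 0.18,
                                                  similar = 0.32,
                                                  precocious = 0.30,
                                                  retarded = 0.20),
                            down_fraction = NULL) {
  if (is.null(down_fraction))
    down_fraction <- stats::setNames(c(0.55, 0.18), c(species_a, species_d))
  structure(as.list(environment()), class = "pipeline_config")
}

stage_order <- c("simulate", "orthology", "families", "normalize",
                 "cluster", "concord")

art <- function(config, ...) file.path(config$outdir, ...)

require_artifacts <- function(config, paths, producer) {
  missing <- paths[!file.exists(paths)]
  if (length(missing))
    stopf("missing artifact %s; run stage '%s' first", missing[1L], producer)
}

write_provenance <- function(config, stage, inputs, params) {
  sums <- if (length(inputs))
    as.list(tools::md5sum(inputs)) else list()
  names(sums) <- basename(names(sums) %||% character(0))
  prov <- list(stage = stage, inputs = sums, params = params,
               seed = config$seed,
               package_version = as.character(utils::packageVersion("dictyComp")))
  jsonlite::write_json(prov, art(config, paste0("provenance_", stage, ".json")),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
}

stage_seed <- function(config, stage)
  (config$seed * 131L + match(stage, stage_order)) %% .Machine$integer.max

#' Run one pipeline stage
#'
#' Stage inputs must already exist on disk (produced by the previous stage
#' or supplied as user data in the same layout); otherwise the error names
#' the stage to run first. Outputs and a provenance JSON are written under
#' the configured output directory; a rerun with identical inputs and seed
#' reproduces every artifact byte for byte.
#'
#' @param name One of simulate, orthology, families, normalize, cluster,
#'   concord.
#' @param config A [pipeline_config()].
#' @return Invisible character vector of artifact paths written.
#' @export
run_stage <- function(name, config) {
  name <- match.arg(name, stage_order)
  dir.create(config$outdir, showWarnings = FALSE, recursive = TRUE)
  switch(name,
         simulate = stage_simulate(config),
         orthology = stage_orthology(config),
         families = stage_families(config),
         normalize = stage_normalize(config),
         cluster = stage_cluster(config),
         concord = stage_concord(config))
}

stage_simulate <- function(config) {
  sd0 <- stage_seed(config, "simulate")
  sim <- simulate_hit_tables(n_genes = config$n_genes_venn,
                             species = config$species, seed = sd0)
  arch <- make_archetypes(k = config$k, n_timepoints = length(config$timepoints))
  pairs <- plant_ortholog_pairs(config$n_pairs, arch,
                                class_proportions = config$class_proportions,
                                down_share = config$down_fraction[[config$species_d]],
                                convention = config$convention,
                                seed = sd0 + 1L)
  n_genes <- stats::setNames(rep(config$n_genes_tc, 2L),
                             c(config$species_a, config$species_d))
  tc <- simulate_timecourses(arch, n_genes = n_genes, pairs = pairs,
                             down_fraction = config$down_fraction,
                             timepoints = config$timepoints,
                             noise_sd = config$noise_sd,
                             zero_fraction = config$zero_fraction,
                             seed = sd0 + 2L)
  fam <- simulate_family_sizes(species = config$species, seed = sd0 + 3L)
  paths <- character(0)
  dir.create(art(config, "hits"), showWarnings = FALSE)
  for (k in names(sim$hits)) {
    p <- art(config, "hits", paste0(sub("->", "__", k, fixed = TRUE), ".tsv"))
    write_hit_table(sim$hits[[k]], p)
    paths <- c(paths, p)
  }
  for (sp in names(sim$universe)) {
    p <- art(config, paste0("universe_", sp, ".txt"))
    writeLines(sim$universe[[sp]], p)
    paths <- c(paths, p)
  }
  for (sp in names(sim$paralog_links)) {
    p <- art(config, paste0("paralog_links_", sp, ".tsv"))
    write_report(sim$paralog_links[[sp]], p)
    paths <- c(paths, p)
  }
  p <- art(config, "seed_families.tsv")
  write_report(data.frame(gene = names(sim$seed_families),
                          family_id = unname(sim$seed_families)), p)
  paths <- c(paths, p)
  p <- art(config, "family_sizes.tsv")
  write_report(data.frame(family_id = rownames(fam$sizes), fam$sizes,
                          check.names = FALSE), p)
  paths <- c(paths, p)
  for (sp in names(tc$tables)) {
    p <- art(config, paste0("expr_", sp, ".tsv"))
    write_expression_table(tc$tables[[sp]], p)
    paths <- c(paths, p)
    p <- art(config, paste0("total_mapped_", sp, ".tsv"))
    write_report(data.frame(column = names(tc$total_mapped[[sp]]),
                            total = unname(tc$total_mapped[[sp]])), p)
    paths <- c(paths, p)
  }
  p <- art(config, "pairs.tsv")
  write_report(data.frame(gene_a = tc$pairs$gene_a, gene_b = tc$pairs$gene_d,
                          evidence = "planted"), p)
  paths <- c(paths, p)
  p <- art(config, "truth.json")
  write_report(list(venn = sim$truth, group_of = as.list(sim$group_of),
                    family_sizes = fam$truth, labels = tc$truth,
                    pair_classes = tc$pairs), p)
  paths <- c(paths, p)
  write_provenance(config, "simulate", character(0),
                   list(n_genes_venn = config$n_genes_venn,
                        n_genes_tc = config$n_genes_tc,
                        n_pairs = config$n_pairs,
                        noise_sd = config$noise_sd))
  invisible(paths)
}

read_stage_hits <- function(config, a, b) {
  p <- art(config, "hits", paste0(a, "__", b, ".tsv"))
  require_artifacts(config, p, "simulate")
  read_hit_table(p, query_species = a, subject_species = b)
}

stage_orthology <- function(config) {
  sp <- config$species
  universes <- lapply(stats::setNames(sp, sp), function(s) {
    p <- art(config, paste0("universe_", s, ".txt"))
    require_artifacts(config, p, "simulate")
    readLines(p)
  })
  maps <- list()
  paths <- character(0)
  combos <- utils::combn(sp, 2L)
  for (j in seq_len(ncol(combos))) {
    a <- combos[1L, j]; b <- combos[2L, j]
    m <- bbh_orthologs(read_stage_hits(config, a, b),
                       read_stage_hits(config, b, a),
                       max_evalue = config$max_evalue)
    maps[[paste(a, b, sep = "|")]] <- m
    p <- art(config, paste0("orthologs_", a, "__", b, ".tsv"))
    write_ortholog_pairs(m$pairs, p)
    paths <- c(paths, p)
  }
  venn <- venn_decompose(maps, universes)
  p <- art(config, "venn.tsv")
  write_report(venn, p)
  paths <- c(paths, p)
  p <- art(config, "venn_summary.json")
  write_report(list(counts = as.data.frame(venn$counts),
                    roster = venn$roster), p)
  paths <- c(paths, p)
  write_provenance(config, "orthology",
                   list.files(art(config, "hits"), full.names = TRUE),
                   list(max_evalue = config$max_evalue))
  invisible(paths)
}

# Rebuild the 6 ortholog maps from hit tables (used by later stages).
derive_maps <- function(config) {
  combos <- utils::combn(config$species, 2L)
  maps <- list()
  for (j in seq_len(ncol(combos))) {
    a <- combos[1L, j]; b <- combos[2L, j]
    maps[[paste(a, b, sep = "|")]] <-
      bbh_orthologs(read_stage_hits(config, a, b),
                    read_stage_hits(config, b, a),
                    max_evalue = config$max_evalue)
  }
  maps
}

stage_families <- function(config) {
  p_seed <- art(config, "seed_families.tsv")
  p_sizes <- art(config, "family_sizes.tsv")
  require_artifacts(config, c(p_seed, p_sizes), "simulate")
  seeds <- utils::read.delim(p_seed, stringsAsFactors = FALSE)
  links <- lapply(stats::setNames(config$species, config$species),
                  function(s) {
                    p <- art(config, paste0("paralog_links_", s, ".tsv"))
                    if (file.exists(p))
                      utils::read.delim(p, stringsAsFactors = FALSE) else NULL
                  })
  ft <- assign_families(seeds, derive_maps(config), links,
                        reference_species = config$species[1L])
  paths <- art(config, "family_table.tsv")
  write_report(ft$members, paths)
  sizes <- utils::read.delim(p_sizes, check.names = FALSE,
                             stringsAsFactors = FALSE)
  m <- as.matrix(sizes[, -1L, drop = FALSE])
  rownames(m) <- sizes$family_id
  calls <- flag_expansions(m, ratio_threshold = config$ratio_threshold,
                           min_size = config$min_size)
  p <- art(config, "expansion_calls.tsv")
  write_report(calls, p)
  paths <- c(paths, p)
  write_provenance(config, "families", c(p_seed, p_sizes),
                   list(ratio_threshold = config$ratio_threshold,
                        min_size = config$min_size))
  invisible(paths)
}

normalize_species <- function(config, sp) {
  p_expr <- art(config, paste0("expr_", sp, ".tsv"))
  p_tm <- art(config, paste0("total_mapped_", sp, ".tsv"))
  require_artifacts(config, c(p_expr, p_tm), "simulate")
  et <- read_expression_table(p_expr)
  tm <- utils::read.delim(p_tm, stringsAsFactors = FALSE)
  counts <- rpkm(et, stats::setNames(tm$total, tm$column))
  scaled <- scale_to_total(average_replicates(counts),
                           total = config$scaling_total)
  filtered <- filter_unexpressed(scaled, epsilon = config$epsilon)
  list(filtered = filtered, standardized = standardize(filtered))
}

stage_normalize <- function(config) {
  a <- normalize_species(config, config$species_a)
  d <- normalize_species(config, config$species_d)
  combined <- combine_species(a$standardized, d$standardized)
  paths <- character(0)
  p <- art(config, "combined_matrix.tsv")
  write_report(data.frame(row = rownames(combined$values),
                          species = combined$species,
                          combined$values, check.names = FALSE), p)
  paths <- c(paths, p)
  for (side in list(list(sp = config$species_a, nm = a$filtered),
                    list(sp = config$species_d, nm = d$filtered))) {
    lv <- mean_levels(side$nm)
    p <- art(config, paste0("levels_", side$sp, ".tsv"))
    write_report(data.frame(gene = names(lv), level = unname(lv)), p)
    paths <- c(paths, p)
  }
  p <- art(config, "normalize_summary.json")
  write_report(list(
    scaling_total = config$scaling_total,
    removed = list(a = a$filtered$removed, d = d$filtered$removed),
    excluded = combined$excluded,
    n_rows = nrow(combined$values)), p)
  paths <- c(paths, p)
  write_provenance(config, "normalize",
                   c(art(config, paste0("expr_", config$species_a, ".tsv")),
                     art(config, paste0("expr_", config$species_d, ".tsv"))),
                   list(scaling_total = config$scaling_total,
                        epsilon = config$epsilon))
  invisible(paths)
}

read_combined_matrix <- function(config) {
  p <- art(config, "combined_matrix.tsv")
  require_artifacts(config, p, "normalize")
  df <- utils::read.delim(p, check.names = FALSE, stringsAsFactors = FALSE)
  vals <- as.matrix(df[, -(1:2), drop = FALSE])
  rownames(vals) <- df$row
  # re-standardize: the TSV carries 6-significant-digit values
  z <- zscore_rows(vals)
  new_normalized_matrix(z$values, df$species, colnames(vals), "combined",
                        scaling_total = config$scaling_total)
}

stage_cluster <- function(config) {
  combined <- read_combined_matrix(config)
  res <- kmeans_pearson(combined,
                        clustering_config(k = config$k,
                                          restarts = config$restarts,
                                          seed = stage_seed(config, "cluster")))
  res <- group_clusters(res)
  paths <- character(0)
  p <- art(config, "labels.tsv")
  grp <- ifelse(res$labels %in% res$groups$down, "down", "up")
  write_report(data.frame(row = names(res$labels), species = res$species,
                          cluster = as.integer(res$labels), group = grp), p)
  paths <- c(paths, p)
  p <- art(config, "centroids.tsv")
  write_report(data.frame(cluster = rownames(res$centroids), res$centroids,
                          check.names = FALSE), p)
  paths <- c(paths, p)
  p <- art(config, "cluster_summary.json")
  write_report(list(k = config$k, objective = res$objective,
                    restart_objectives = res$restart_objectives,
                    groups = res$groups,
                    fractions = cluster_fractions(res)), p)
  paths <- c(paths, p)
  write_provenance(config, "cluster", art(config, "combined_matrix.tsv"),
                   list(k = config$k, restarts = config$restarts))
  invisible(paths)
}

read_clustering <- function(config) {
  p_lab <- art(config, "labels.tsv")
  p_cen <- art(config, "centroids.tsv")
  require_artifacts(config, c(p_lab, p_cen), "cluster")
  lab <- utils::read.delim(p_lab, stringsAsFactors = FALSE)
  cen <- utils::read.delim(p_cen, check.names = FALSE, stringsAsFactors = FALSE)
  cmat <- as.matrix(cen[, -1L, drop = FALSE])
  rownames(cmat) <- cen$cluster
  down <- sort(unique(lab$cluster[lab$group == "down"]))
  up <- sort(unique(lab$cluster[lab$group == "up"]))
  structure(list(labels = stats::setNames(lab$cluster, lab$row),
                 centroids = cmat, species = lab$species,
                 groups = list(down = down, up = up)),
            class = "clustering_result")
}

stage_concord <- function(config) {
  p_pairs <- art(config, "pairs.tsv")
  require_artifacts(config, p_pairs, "simulate")
  pairs <- read_ortholog_pairs(p_pairs)
  names(pairs)[names(pairs) == "gene_b"] <- "gene_d"
  res <- read_clustering(config)
  ct <- classify_pairs(pairs, res, config$species_a, config$species_d,
                       convention = config$convention)
  read_levels <- function(sp) {
    df <- utils::read.delim(art(config, paste0("levels_", sp, ".tsv")),
                            stringsAsFactors = FALSE)
    stats::setNames(df$level, df$gene)
  }
  ct <- add_alterations(ct, read_levels(config$species_a),
                        read_levels(config$species_d),
                        fold_threshold = config$fold_threshold,
                        trace_threshold = config$trace_threshold)
  paths <- art(config, "concordance.tsv")
  write_report(ct, paths)
  summ <- summarize_concordance(ct)
  p <- art(config, "concordance_summary.json")
  write_report(list(overall = summ$overall,
                    alterations = as.list(table(ct$alteration))), p)
  paths <- c(paths, p)
  write_provenance(config, "concord",
                   c(p_pairs, art(config, "labels.tsv")),
                   list(convention = config$convention,
                        fold_threshold = config$fold_threshold,
                        trace_threshold = config$trace_threshold))
  invisible(paths)
}

#' Run the whole pipeline and write a summary report
#'
#' Executes simulate, orthology, families, normalize, cluster and concord in
#' order, then writes `summary.json` collecting the Venn counts, expansion
#' calls, per-species cluster fractions and concordance fractions. With
#' `truth_aware = TRUE` the summary also carries recovery metrics against
#' the planted truth (clustering adjusted Rand index, Venn area agreement,
#' concordance confusion).
#'
#' @param config A [pipeline_config()].
#' @param truth_aware Append recovery-vs-truth metrics (default TRUE).
#' @return The summary, invisibly.
#' @export
run_all <- function(config, truth_aware = TRUE) {
  for (s in stage_order) run_stage(s, config)
  venn <- utils::read.delim(art(config, "venn.tsv"), stringsAsFactors = FALSE)
  calls <- utils::read.delim(art(config, "expansion_calls.tsv"),
                             stringsAsFactors = FALSE)
  cluster_summary <- jsonlite::read_json(art(config, "cluster_summary.json"),
                                         simplifyVector = TRUE)
  concord <- read_concordance_table(art(config, "concordance.tsv"))
  summ <- summarize_concordance(concord)
  out <- list(species = config$species,
              venn_counts = as.list(table(venn$species, venn$area)),
              n_expansion_calls = sum(calls$pattern != "none"),
              cluster_fractions = cluster_summary$fractions,
              concordance = summ$overall)
  if (truth_aware) {
    truth <- jsonlite::read_json(art(config, "truth.json"),
                                 simplifyVector = TRUE)
    lab <- utils::read.delim(art(config, "labels.tsv"),
                             stringsAsFactors = FALSE)
    truth_lab <- truth$labels
    truth_key <- paste(truth_lab$species, truth_lab$gene, sep = "::")
    planted <- stats::setNames(truth_lab$archetype, truth_key)[lab$row]
    keep <- !is.na(planted)
    out$recovery <- list(
      clustering_ari = mclust::adjustedRandIndex(lab$cluster[keep],
                                                 planted[keep]),
      venn_agreement = {
        tv <- truth$venn
        key <- paste(tv$species, tv$gene)
        mean(venn$area == stats::setNames(tv$area, key)[
          paste(venn$species, venn$gene)])
      },
      concordance_confusion = {
        pc <- truth$pair_classes
        classified <- concord$class != "unclassified"
        mean(concord$class[classified] != pc$class[classified])
      })
  }
  write_report(out, art(config, "summary.json"))
  invisible(out)
}
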