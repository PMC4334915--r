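# Generator contracts: the planted truth must be recoverable by construction.

test_that("archetypes are z-scored, well separated, and split 3/5 by default", {
  a <- make_archetypes()
  expect_equal(dim(a), c(8L, 4L))
  expect_equal(attr(a, "direction"), rep(c("down", "up"), c(3, 5)))
  expect_equal(unname(rowMeans(a)), rep(0, 8))
  expect_equal(unname(apply(a, 1, sd)), rep(1, 8))
  d <- 1 - cor(t(a))
  expect_gte(min(d[upper.tri(d)]), 0.3)
  for (j in 1:3) expect_lt(a[j, 4], a[j, 1])
  for (j in 4:8) expect_gt(a[j, 4], a[j, 1])

  a2 <- make_archetypes(k = 2, n_down = 1)
  expect_equal(pearson_distance(a2[1, ], a2[2, ]), 2)
  expect_error(make_archetypes(k = 2, n_down = 2), "n_down")
})

test_that("planted pair classes respect their construction rules", {
  arch <- make_archetypes()
  all_match <- plant_ortholog_pairs(100, arch,
                                    class_proportions = c(match = 1,
                                                          similar = 0,
                                                          precocious = 0,
                                                          retarded = 0),
                                    seed = 61)
  expect_true(all(all_match$arch_a == all_match$arch_d))

  all_prec <- plant_ortholog_pairs(100, arch,
                                   class_proportions = c(match = 0,
                                                         similar = 0,
                                                         precocious = 1,
                                                         retarded = 0),
                                   seed = 63)
  dir <- attr(arch, "direction")
  expect_true(all(dir[all_prec$arch_a] == "down"))
  expect_true(all(dir[all_prec$arch_d] == "up"))

  # under the caption convention the orientation is reversed
  cap <- plant_ortholog_pairs(50, arch,
                              class_proportions = c(match = 0, similar = 0,
                                                    precocious = 1,
                                                    retarded = 0),
                              convention = "caption", seed = 65)
  expect_true(all(dir[cap$arch_a] == "up"))

  props <- c(match = 0.18, similar = 0.32, precocious = 0.30, retarded = 0.20)
  big <- plant_ortholog_pairs(2000, arch, class_proportions = props,
                              seed = 67)
  counts <- table(factor(big$class, levels = names(props)))
  for (cl in names(props)) {
    # 99.7% multinomial band
    se <- sqrt(2000 * props[cl] * (1 - props[cl]))
    expect_lt(abs(counts[cl] - 2000 * props[cl]), 3 * se + 1)
  }
})

test_that("the zero-noise limit reproduces archetypes exactly", {
  arch <- make_archetypes()
  tc <- simulate_timecourses(arch, n_genes = c(Asub = 100, Ddis = 100),
                             noise_sd = 0, zero_fraction = 0, seed = 69)
  for (sp in c("Asub", "Ddis")) {
    pre <- average_replicates(rpkm(tc$tables[[sp]], tc$total_mapped[[sp]]))
    z <- t(apply(pre$values, 1, function(x) (x - mean(x)) / sd(x)))
    planted <- tc$truth[tc$truth$species == sp, "archetype"]
    expect_equal(unname(z), unname(arch[planted, ]), tolerance = 1e-9)
  }
})

test_that("planted all-zero genes are exactly the ones the filter removes", {
  arch <- make_archetypes()
  tc <- simulate_timecourses(arch, n_genes = c(Asub = 200, Ddis = 200),
                             zero_fraction = 0.1, noise_sd = 0.1, seed = 71)
  for (sp in c("Asub", "Ddis")) {
    sc <- scale_to_total(average_replicates(
      rpkm(tc$tables[[sp]], tc$total_mapped[[sp]])))
    f <- filter_unexpressed(sc)
    planted_zero <- tc$truth$gene[tc$truth$species == sp &
                                    is.na(tc$truth$archetype)]
    expect_setequal(f$removed, planted_zero)
    expect_equal(length(planted_zero), 20L)
  }
})

test_that("generators are bit-reproducible under a fixed seed", {
  arch <- make_archetypes()
  pairs <- plant_ortholog_pairs(50, arch, seed = 73)
  t1 <- simulate_timecourses(arch, n_genes = c(Asub = 50, Ddis = 50),
                             pairs = pairs, seed = 75)
  t2 <- simulate_timecourses(arch, n_genes = c(Asub = 50, Ddis = 50),
                             pairs = pairs, seed = 75)
  expect_identical(t1, t2)
  p1 <- withr::local_tempfile(fileext = ".tsv")
  p2 <- withr::local_tempfile(fileext = ".tsv")
  write_expression_table(t1$tables$Asub, p1)
  write_expression_table(t2$tables$Asub, p2)
  expect_identical(readLines(p1), readLines(p2))

  h1 <- simulate_hit_tables(n_genes = 40, seed = 77)
  h2 <- simulate_hit_tables(n_genes = 40, seed = 77)
  expect_identical(h1, h2)
})

test_that("planted hit-table roles flow through the real orthology pipeline", {
  sim <- simulate_hit_tables(n_genes = 100, seed = 79)
  combos <- combn(names(sim$universe), 2)
  maps <- lapply(seq_len(ncol(combos)), function(j)
    bbh_orthologs(sim$hits[[paste0(combos[1, j], "->", combos[2, j])]],
                  sim$hits[[paste0(combos[2, j], "->", combos[1, j])]]))
  # paralog-planted genes appear in some map's paralog set, never in a pair
  paired <- unlist(lapply(maps, function(m) c(m$pairs$gene_a, m$pairs$gene_b)))
  paralogs <- unlist(lapply(maps, function(m) unlist(m$paralogs)))
  planted_para <- sim$truth$gene[sim$truth$role == "paralog"]
  expect_true(all(planted_para %in% paralogs))
  expect_length(intersect(planted_para, paired), 0L)
  # genes planted with only sub-threshold hits stay species-specific
  v <- venn_decompose(maps, sim$universe)
  planted_ss <- sim$truth$gene[sim$truth$role == "species_specific"]
  got <- v$assignments$area[match(planted_ss, v$assignments$gene)]
  expect_true(all(got == "species_specific"))
})

test_that("a 1e-9 hit leaves a gene species-specific at the 1e-10 threshold", {
  ab <- hit_table(hit_df_row("a1", "b1", 1e-9), "A", "B")
  ba <- hit_table(hit_df_row("b1", "a1", 1e-9), "B", "A")
  m <- bbh_orthologs(ab, ba, max_evalue = 1e-10)
  expect_equal(nrow(m$pairs), 0L)
  expect_length(unlist(m$paralogs), 0L)
})
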