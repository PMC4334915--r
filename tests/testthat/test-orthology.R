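# Reciprocal-best-hit inference and Venn decomposition against brute force.

test_that("hit filtering applies inclusive thresholds and preserves order", {
  df <- rbind(hit_df_row("g1", "h1", 1e-9),
              hit_df_row("g2", "h2", 1e-10),
              hit_df_row("g3", "h3", 1e-50, identity = 95.0),
              hit_df_row("g4", "h4", 1e-50, identity = 94.9))
  df$coverage <- c(0.9, 0.9, 0.80, 0.79)
  ht <- hit_table(df)
  expect_equal(filter_hits(ht, max_evalue = 1e-10)$query, c("g2", "g3", "g4"))
  kept <- filter_hits(ht, min_identity = 95, min_coverage = 0.80)
  expect_equal(kept$query, "g3")  # boundary values are retained
  expect_equal(as.data.frame(filter_hits(ht)), as.data.frame(ht),
               ignore_attr = TRUE)
})

test_that("best hits break ties by bitscore then subject id", {
  df <- rbind(hit_df_row("g1", "h1", 1e-50), hit_df_row("g1", "h2", 1e-30))
  expect_equal(best_hits(hit_table(df)), c(g1 = "h1"))
  df <- rbind(hit_df_row("g1", "h1", 1e-50, bitscore = 200),
              hit_df_row("g1", "h2", 1e-50, bitscore = 210))
  expect_equal(best_hits(hit_table(df)), c(g1 = "h2"))
  df <- rbind(hit_df_row("g1", "h2", 1e-50), hit_df_row("g1", "h1", 1e-50))
  expect_equal(best_hits(hit_table(df)), c(g1 = "h1"))
  expect_length(best_hits(hit_table(data.frame())), 0L)
})

test_that("reciprocal best hits form pairs and leftovers become paralogs", {
  ab <- hit_table(rbind(hit_df_row("a1", "b1", 1e-40),
                        hit_df_row("a2", "b1", 1e-20)), "A", "B")
  ba <- hit_table(rbind(hit_df_row("b1", "a1", 1e-40)), "B", "A")
  m <- bbh_orthologs(ab, ba)
  expect_equal(pair_keys(m), "a1|b1")
  expect_equal(m$paralogs$A, "a2")
  expect_length(m$paralogs$B, 0L)

  # a1's best is b1 but b1 points back at a2: nobody pairs
  ab <- hit_table(rbind(hit_df_row("a1", "b1", 1e-40)), "A", "B")
  ba <- hit_table(rbind(hit_df_row("b1", "a2", 1e-40),
                        hit_df_row("b1", "a1", 1e-20)), "B", "A")
  m <- bbh_orthologs(ab, ba)
  expect_equal(nrow(m$pairs), 0L)
  expect_true("a1" %in% m$paralogs$A)

  # everything above threshold: no pairs, no paralogs
  ab <- hit_table(hit_df_row("a1", "b1", 1e-5), "A", "B")
  ba <- hit_table(hit_df_row("b1", "a1", 1e-5), "B", "A")
  m <- bbh_orthologs(ab, ba, max_evalue = 1e-10)
  expect_equal(nrow(m$pairs), 0L)
  expect_length(unlist(m$paralogs), 0L)

  expect_error(bbh_orthologs(ab, hit_table(hit_df_row("c1", "a1", 1e-5),
                                           "C", "A")),
               "inconsistent")
})

test_that("reciprocal best hits agree with exhaustive enumeration and are symmetric", {
  set.seed(202)
  for (i in 1:40) {
    n <- sample(3:25, 1)
    ab <- random_hit_df(n, n, sample(5:60, 1), "a", "b")
    ba <- random_hit_df(n, n, sample(5:60, 1), "b", "a")
    m <- bbh_orthologs(hit_table(ab, "A", "B"), hit_table(ba, "B", "A"))
    expect_equal(pair_keys(m), oracle_bbh_pairs(ab, ba, 1e-10))
    m_rev <- bbh_orthologs(hit_table(ba, "B", "A"), hit_table(ab, "A", "B"))
    expect_equal(pair_keys(m),
                 sort(paste(m_rev$pairs$gene_b, m_rev$pairs$gene_a, sep = "|")))
  }
})

test_that("relaxing the e-value threshold only grows the surviving hit set", {
  set.seed(203)
  ab <- hit_table(random_hit_df(20, 20, 80))
  strict <- filter_hits(ab, max_evalue = 1e-20)
  loose <- filter_hits(ab, max_evalue = 1e-10)
  key <- function(h) paste(h$query, h$subject, h$evalue)
  expect_true(all(key(strict) %in% key(loose)))
})

test_that("venn decomposition recovers planted patterns and conserves totals", {
  sim <- simulate_hit_tables(n_genes = 80, seed = 3)
  roster <- names(sim$universe)
  combos <- combn(roster, 2)
  maps <- lapply(seq_len(ncol(combos)), function(j) {
    a <- combos[1, j]; b <- combos[2, j]
    bbh_orthologs(sim$hits[[paste0(a, "->", b)]],
                  sim$hits[[paste0(b, "->", a)]])
  })
  v <- venn_decompose(maps, sim$universe)
  idx <- match(paste(v$assignments$species, v$assignments$gene),
               paste(sim$truth$species, sim$truth$gene))
  expect_equal(v$assignments$bitmask, sim$truth$bitmask[idx])
  expect_equal(v$assignments$area, sim$truth$area[idx])
  expect_equal(unname(rowSums(v$counts)),
               unname(lengths(sim$universe)[rownames(v$counts)]))
  # anchors: all-four region is K; the region absent from roster species 2 is G
  all4 <- v$assignments[v$assignments$bitmask == "1111", "area"]
  expect_true(all(all4 == "K"))
  g <- v$assignments[v$assignments$bitmask == "1011", "area"]
  expect_true(length(g) > 0 && all(g == "G"))

  bad <- maps
  bad[[1]]$pairs$gene_a[1] <- "ghost_gene"
  expect_error(venn_decompose(bad, sim$universe), "ghost_gene")
})

test_that("genes with no surviving relations are species-specific", {
  sim <- simulate_hit_tables(n_genes = 30, weight_all4 = 0, weight_triple = 0,
                             weight_pair = 0, paralog_fraction = 0, seed = 9)
  combos <- combn(names(sim$universe), 2)
  maps <- lapply(seq_len(ncol(combos)), function(j) {
    a <- combos[1, j]; b <- combos[2, j]
    bbh_orthologs(sim$hits[[paste0(a, "->", b)]],
                  sim$hits[[paste0(b, "->", a)]])
  })
  v <- venn_decompose(maps, sim$universe)
  expect_true(all(v$assignments$area == "species_specific"))
})
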