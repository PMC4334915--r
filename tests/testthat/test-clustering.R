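# Pearson-distance K-means, centroid grouping, and occupancy summaries.

test_that("pearson distance behaves like 1 - r", {
  x <- c(1, 2, 3, 4)
  expect_equal(pearson_distance(x, x), 0)
  expect_equal(pearson_distance(x, 3 * x + 7), 0)
  expect_equal(pearson_distance(x, rev(x)), 2)
  expect_error(pearson_distance(x, rep(1, 4)), "zero-variance")
})

test_that("duplicated archetypes split perfectly with objective zero", {
  arch <- make_archetypes(k = 2, n_down = 1)
  x <- arch[rep(1:2, each = 50), ]
  rownames(x) <- sprintf("g%03d", 1:100)
  nm <- as_nm(x, rep("S", 100), "combined")
  res <- kmeans_pearson(nm, clustering_config(k = 2, restarts = 5, seed = 3))
  expect_equal(res$objective, 0)
  expect_equal(mclust::adjustedRandIndex(res$labels, rep(1:2, each = 50)), 1)
  expect_error(kmeans_pearson(nm, clustering_config(k = 200)), "exceeds")
})

test_that("the best restart never loses to any single restart", {
  set.seed(7)
  x <- matrix(rnorm(40), 10, 4, dimnames = list(sprintf("g%02d", 1:10), NULL))
  x <- t(apply(x, 1, function(v) (v - mean(v)) / sd(v)))
  nm <- as_nm(x, rep("S", 10), "combined")
  res <- kmeans_pearson(nm, clustering_config(k = 3, restarts = 100, seed = 11))
  expect_equal(res$objective, min(res$restart_objectives))
  expect_true(all(res$restart_objectives >= res$objective - 1e-12))
})

test_that("the objective is non-increasing within every restart", {
  arch <- make_archetypes()
  tc <- simulate_timecourses(arch, n_genes = c(Asub = 300, Ddis = 300),
                             noise_sd = 0.3, seed = 13)
  cm <- combine_species(normalize_chain(tc, "Asub"),
                        normalize_chain(tc, "Ddis"))
  res <- kmeans_pearson(cm, clustering_config(k = 8, restarts = 25, seed = 5))
  for (tr in res$objective_trace)
    expect_true(all(diff(tr) <= 1e-8))
})

test_that("identical seeds give identical clusterings", {
  arch <- make_archetypes()
  tc <- simulate_timecourses(arch, n_genes = c(Asub = 150, Ddis = 150),
                             noise_sd = 0.2, seed = 17)
  cm <- combine_species(normalize_chain(tc, "Asub"),
                        normalize_chain(tc, "Ddis"))
  r1 <- kmeans_pearson(cm, clustering_config(k = 8, restarts = 10, seed = 99))
  r2 <- kmeans_pearson(cm, clustering_config(k = 8, restarts = 10, seed = 99))
  expect_identical(r1$labels, r2$labels)
  expect_identical(r1$objective, r2$objective)
})

test_that("row scale before standardization cannot change the clustering", {
  set.seed(19)
  vals <- matrix(runif(80, 1, 100), 20, 4,
                 dimnames = list(sprintf("g%02d", 1:20), NULL))
  run <- function(v) {
    z <- standardize(as_nm(v, rep("S", 20), "filtered"))
    z$stage <- "combined"
    kmeans_pearson(z, clustering_config(k = 4, restarts = 5, seed = 23))
  }
  base <- run(vals)
  scaled <- vals
  scaled[7, ] <- scaled[7, ] * 50  # positive per-gene rescale
  res <- run(scaled)
  expect_identical(res$labels, base$labels)
  expect_identical(res$objective, base$objective)
})

test_that("grouping splits recovered centroids 3/5 with correct directions", {
  arch <- make_archetypes()
  tc <- simulate_timecourses(arch, n_genes = c(Asub = 400, Ddis = 400),
                             noise_sd = 0.1, seed = 29)
  cm <- combine_species(normalize_chain(tc, "Asub"),
                        normalize_chain(tc, "Ddis"))
  res <- group_clusters(kmeans_pearson(cm, clustering_config(k = 8,
                                                             restarts = 40,
                                                             seed = 31)))
  expect_length(res$groups$down, 3L)
  expect_length(res$groups$up, 5L)
  for (j in res$groups$down)
    expect_lt(res$centroids[j, 4], res$centroids[j, 1])
  for (j in res$groups$up)
    expect_gt(res$centroids[j, 4], res$centroids[j, 1])
  # planted direction agreement
  truth <- planted_labels_for(tc, res)
  dirs <- attr(arch, "direction")[truth]
  got <- ifelse(res$labels %in% res$groups$down, "down", "up")
  expect_gt(mean(got == dirs, na.rm = TRUE), 0.95)
})

test_that("grouping equals the exhaustive 2-partition oracle on random centroids", {
  set.seed(37)
  for (i in 1:25) {
    k <- sample(3:8, 1)
    cmat <- matrix(rnorm(k * 4), k, 4)
    cmat <- t(apply(cmat, 1, function(v) (v - mean(v)) / sd(v)))
    rownames(cmat) <- paste0("C", 1:k)
    res <- structure(list(labels = stats::setNames(sample(1:k, 30, TRUE),
                                                   sprintf("g%02d", 1:30)),
                          centroids = cmat, species = rep("S", 30)),
                     class = "clustering_result")
    grouped <- suppressWarnings(group_clusters(res))
    # recover the chosen split in original numbering by matching centroid rows
    old_of_new <- apply(grouped$centroids, 1, function(r)
      which(apply(cmat, 1, function(o) all(o == r)))[1])
    down_old <- sort(old_of_new[grouped$groups$down])
    oracle <- oracle_two_partition(cmat)
    side <- if (1 %in% down_old) down_old else
      sort(setdiff(1:k, down_old))
    expect_equal(unname(side), oracle)
  }
})

test_that("two opposed centroids split one per group", {
  arch <- make_archetypes(k = 2, n_down = 1)
  x <- arch[rep(1:2, each = 10), ]
  rownames(x) <- sprintf("g%02d", 1:20)
  nm <- as_nm(x, rep("S", 20), "combined")
  res <- group_clusters(kmeans_pearson(nm, clustering_config(k = 2,
                                                             restarts = 3,
                                                             seed = 41)))
  expect_equal(lengths(res$groups), c(down = 1L, up = 1L))
})

test_that("grouping agrees with average-linkage clustering on separated centroids", {
  arch <- make_archetypes()
  hc <- stats::hclust(stats::as.dist(1 - cor(t(arch))), method = "average")
  cut <- stats::cutree(hc, k = 2)
  res <- structure(list(labels = stats::setNames(rep(1:8, 3),
                                                 sprintf("g%02d", 1:24)),
                        centroids = arch, species = rep("S", 24)),
                   class = "clustering_result")
  grouped <- group_clusters(res)
  nd <- length(grouped$groups$down)
  remap <- unique(cbind(old = unname(res$labels), new = unname(grouped$labels)))
  down_old <- sort(remap[remap[, "new"] <= nd, "old"])
  expect_true(identical(sort(unname(which(cut == cut[1]))), down_old) ||
                identical(sort(unname(which(cut != cut[1]))), down_old))
})

test_that("cluster fractions are exact tallies that sum to one", {
  res <- structure(list(labels = stats::setNames(rep(1L, 100),
                                                 sprintf("g%03d", 1:100)),
                        centroids = matrix(rnorm(32), 8, 4),
                        species = rep("Asub", 100)),
                   class = "clustering_result")
  fr <- cluster_fractions(res)
  expect_equal(fr$fraction[fr$cluster == 1], 1.0)
  expect_equal(sum(fr$fraction), 1.0)

  set.seed(43)
  lab <- sample(1:8, 500, replace = TRUE)
  res$labels <- stats::setNames(lab, sprintf("g%03d", 1:500))
  res$species <- rep(c("Asub", "Ddis"), 250)
  fr <- cluster_fractions(res)
  for (sp in c("Asub", "Ddis")) {
    sub <- fr[fr$species == sp, ]
    expect_equal(sub$n, as.integer(table(factor(lab[res$species == sp],
                                                levels = 1:8))))
    expect_equal(sum(sub$fraction), 1.0)
  }
})
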