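# Normalization pipeline contracts, each stage against direct recomputation.

make_counts <- function(n = 20, reps = c(2L, 2L, 2L, 2L), seed = 1) {
  set.seed(seed)
  cols <- unlist(lapply(seq_along(reps), function(i)
    paste(c(0, 8, 16, 24)[i], seq_len(reps[i]), sep = "_")))
  vals <- matrix(rpois(n * length(cols), 50), n, length(cols),
                 dimnames = list(sprintf("g%03d", seq_len(n)), cols))
  expression_table(vals, species = "Asub",
                   lengths_bp = sample(300:6000, n, replace = TRUE))
}

test_that("rpkm matches its closed form", {
  vals <- matrix(c(10, 0), 1, 2, dimnames = list("g1", c("0_1", "8_1")))
  et <- expression_table(vals, "Asub", lengths_bp = 1000)
  out <- rpkm(et, c("0_1" = 1e6, "8_1" = 1e6))
  expect_equal(unname(out$values[1, ]), c(10, 0))

  et <- make_counts(n = 30, seed = 2)
  tm <- stats::setNames(round(runif(ncol(et$values), 1e6, 9e6)),
                        colnames(et$values))
  out <- rpkm(et, tm)
  manual <- et$values
  for (i in seq_len(nrow(manual))) for (j in seq_len(ncol(manual)))
    manual[i, j] <- et$values[i, j] * 1e9 / (et$lengths_bp[i] * tm[j])
  expect_equal(out$values, manual)
  expect_error(rpkm(et, 0), "positive")
})

test_that("replicate averaging is a per-timepoint arithmetic mean", {
  vals <- matrix(c(2, 4, 6, 6, 1, 3, 5, 7), 2, 4, byrow = TRUE,
                 dimnames = list(c("g1", "g2"),
                                 c("0_1", "0_2", "8_1", "8_2")))
  et <- expression_table(vals, "Asub")
  nm <- average_replicates(et)
  expect_equal(unname(nm$values["g1", ]), c(3, 6))
  expect_equal(nm$stage, "averaged")

  et1 <- expression_table(vals[, c(1, 3), drop = FALSE], "Asub")
  expect_equal(unname(average_replicates(et1)$values), unname(vals[, c(1, 3)]))

  et6 <- make_counts(n = 10, reps = rep(6L, 4), seed = 3)
  nm6 <- average_replicates(et6)
  for (t in c("0", "8", "16", "24"))
    expect_equal(nm6$values[, t],
                 rowMeans(et6$values[, et6$col_timepoint == t]))
})

test_that("column scaling hits the target total independently per species", {
  m <- as_nm(matrix(c(1, 2, 3, 4), 1, 4, dimnames = list("g1", NULL)),
             "Asub", "averaged")
  sc <- scale_to_total(m, 1e7)
  expect_equal(unname(colSums(sc$values)), rep(1e7, 4))

  already <- as_nm(matrix(1e7, 1, 4, dimnames = list("g1", NULL)),
                   "Asub", "averaged")
  expect_equal(scale_to_total(already)$values, already$values)

  set.seed(4)
  two <- as_nm(rbind(matrix(runif(40, 1, 10), 10, 4),
                     matrix(runif(40, 100, 1000), 10, 4)),
               rep(c("Asub", "Ddis"), each = 10), "averaged")
  rownames(two$values) <- sprintf("g%02d", 1:20)
  sc2 <- scale_to_total(two)
  for (sp in c("Asub", "Ddis"))
    expect_equal(unname(colSums(sc2$values[sc2$species == sp, ])),
                 rep(1e7, 4))

  zero <- as_nm(matrix(c(0, 1, 1, 1), 1, 4, dimnames = list("g1", NULL)),
                "Asub", "averaged")
  expect_error(scale_to_total(zero), "Asub.*timepoint")
})

test_that("the unexpressed filter removes exactly the all-low genes", {
  vals <- rbind(g1 = c(0, 0, 0, 0), g2 = c(0, 5, 0, 0),
                g3 = c(0.5, 0.9, 0.2, 0.8), g4 = c(2, 2, 2, 2))
  m <- as_nm(vals, rep("Asub", 4), "scaled")
  f0 <- filter_unexpressed(m)
  expect_equal(f0$removed, "g1")
  expect_true("g2" %in% rownames(f0$values))
  f1 <- filter_unexpressed(m, epsilon = 1.0)
  expect_setequal(f1$removed, c("g1", "g3"))
})

test_that("standardization yields exact z-scores and diverts flat rows", {
  m <- as_nm(rbind(g1 = c(1, 2, 3, 4), g2 = c(5, 5, 5, 5)),
             rep("Asub", 2), "filtered")
  z <- standardize(m)
  expect_equal(z$excluded, "g2")
  expect_equal(mean(z$values["g1", ]), 0)
  expect_equal(sd(z$values["g1", ]), 1)

  set.seed(5)
  r <- matrix(runif(60), 15, 4, dimnames = list(sprintf("g%02d", 1:15), NULL))
  zr <- standardize(as_nm(r, rep("Asub", 15), "filtered"))
  manual <- t(apply(r, 1, function(x) (x - mean(x)) / sd(x)))
  expect_equal(zr$values, manual)
})

test_that("combining species stacks rows bit-exactly under namespaced ids", {
  set.seed(6)
  za <- standardize(as_nm(matrix(runif(40), 10, 4,
                                 dimnames = list(sprintf("a%02d", 1:10), NULL)),
                          rep("Asub", 10), "filtered"))
  zd <- standardize(as_nm(matrix(runif(60), 15, 4,
                                 dimnames = list(sprintf("d%02d", 1:15), NULL)),
                          rep("Ddis", 15), "filtered"))
  cm <- combine_species(za, zd)
  expect_equal(nrow(cm$values), 25L)
  expect_identical(unname(cm$values["Asub::a03", ]),
                   unname(za$values["a03", ]))
  expect_identical(unname(cm$values["Ddis::d11", ]),
                   unname(zd$values["d11", ]))
  zd2 <- zd; zd2$timepoints <- c("0", "4", "8", "12")
  expect_error(combine_species(za, zd2), "timepoint labels differ")
})

test_that("stages refuse out-of-order input", {
  m <- as_nm(matrix(1:4, 1, 4, dimnames = list("g1", NULL)), "Asub", "averaged")
  expect_error(filter_unexpressed(m), "stage")
  expect_error(combine_species(m, m), "stage")
  raw <- as_nm(matrix(1:4, 1, 4, dimnames = list("g1", NULL)), "Asub", "scaled")
  expect_error(scale_to_total(raw), "stage")
})
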