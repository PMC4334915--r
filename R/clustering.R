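# Collective K-means under Pearson correlation distance with multi-restart
# selection, exact two-group partitioning of the centroids, and per-species
# cluster occupancy summaries.
#
# With rows z-scored to mean 0 / sample SD 1 over T timepoints,
# 1 - r(x, y) = ||x - y||^2 / (2 (T - 1)), so Lloyd iterations with
# mean-then-re-standardize centroid updates provably never increase the
# objective: the re-standardized mean is exactly the z-scored profile
# maximizing the summed correlation with the members.

#' Clustering configuration
#'
#' @param k Number of clusters (default 8).
#' @param restarts Independent random initializations; the restart with the
#'   lowest total within-cluster Pearson distance wins (default 100).
#' @param max_iter Lloyd iteration cap per restart (default 300); convergence
#'   is an exact label fixpoint.
#' @param seed Integer seed making the whole multi-restart run reproducible.
#' @return A `clustering_config`.
#' @export
clustering_config <- function(k = 8L, restarts = 100L, max_iter = 300L,
                              seed = NULL) {
  if (k < 2L) stopf("k must be at least 2")
  if (restarts < 1L) stopf("restarts must be at least 1")
  structure(list(k = as.integer(k), restarts = as.integer(restarts),
                 max_iter = as.integer(max_iter), seed = seed,
                 distance = "pearson"),
            class = "clustering_config")
}

#' Pearson correlation distance between two profiles
#'
#' d = 1 - r, in [0, 2]; invariant to positive affine transforms of either
#' profile. Zero-variance profiles have no defined correlation and are an
#' error (upstream [standardize()] excludes them).
#'
#' @param x,y Numeric profiles of equal length.
#' @return Distance in [0, 2].
#' @export
pearson_distance <- function(x, y) {
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stopf("Pearson distance is undefined for a zero-variance profile")
  1 - stats::cor(x, y)
}

# rows of m assumed z-scored (mean 0, sample sd 1); returns n x k Pearson
# correlation matrix against the k z-scored centroid rows.
cor_to_centroids <- function(m, centroids) {
  tcrossprod(m, centroids) / (ncol(m) - 1L)
}

# z-score the rows of a centroid matrix; degenerate rows are returned as NA
# and dealt with by the caller (reseeding).
standardize_centroids <- function(centroids) {
  mu <- rowMeans(centroids)
  s <- apply(centroids, 1L, stats::sd)
  out <- (centroids - mu) / ifelse(s > 0, s, NA_real_)
  out
}

#' K-means clustering under Pearson correlation distance
#'
#' Runs `restarts` independent Lloyd optimizations. Each restart draws k
#' distinct data rows as initial centroids, assigns every row to the nearest
#' centroid under 1 - r, and updates each centroid to the re-standardized
#' mean of its members; clusters that empty out are reseeded from the row
#' currently farthest from its centroid. Iteration stops at a label fixpoint
#' (or `max_iter`); the restart with the smallest total within-cluster
#' distance is returned.
#'
#' @param matrix A `normalized_matrix` at stage `combined` (or
#'   `standardized` for single-species use); all rows z-scored.
#' @param config A [clustering_config()].
#' @return A `clustering_result`: `labels` (named 1..k per row), `centroids`
#'   (k x timepoints, z-scored), `objective`, `restart_objectives`,
#'   `objective_trace` (per-restart iteration objectives, for convergence
#'   diagnostics), `species`, and `groups` (filled by [group_clusters()]).
#' @export
kmeans_pearson <- function(matrix, config = clustering_config()) {
  check_stage(matrix, c("combined", "standardized"))
  x <- matrix$values
  n <- nrow(x)
  k <- config$k
  if (k > n) stopf("k = %d exceeds the %d available rows", k, n)
  run <- function() {
    best <- NULL
    restart_obj <- numeric(config$restarts)
    traces <- vector("list", config$restarts)
    for (r in seq_len(config$restarts)) {
      centroids <- x[sample.int(n, k), , drop = FALSE]
      labels_prev <- integer(0)
      trace <- numeric(0)
      labels <- integer(n)
      for (it in seq_len(config$max_iter)) {
        cors <- cor_to_centroids(x, centroids)
        labels <- max.col(cors, ties.method = "first")
        # Reseed degenerate centroids from the row farthest from its own
        # centroid: clusters that emptied out, and duplicated centroids
        # (within Pearson distance 1e-10). Identical rows always co-assign,
        # so in the zero-noise limit a merged-archetype local optimum must
        # produce an empty or duplicate centroid; reseeding breaks it
        # without ever increasing the objective (the duplicate's members
        # fall back to its twin at the same distance).
        guard <- 0L
        repeat {
          guard <- guard + 1L
          empty <- setdiff(seq_len(k), unique(labels))
          dup <- integer(0)
          if (k > 1L) {
            ccor <- tcrossprod(centroids) / (ncol(x) - 1L)
            for (j in 2:k)
              if (any(1 - ccor[j, seq_len(j - 1L)] < 1e-10))
                dup <- c(dup, j)
          }
          bad <- union(empty, dup)
          if (!length(bad) || guard > k + 1L) break
          d_own <- 1 - cors[cbind(seq_len(n), labels)]
          for (j in bad) {
            far <- which.max(d_own)
            centroids[j, ] <- x[far, ]
            d_own[far] <- -1
          }
          cors <- cor_to_centroids(x, centroids)
          labels <- max.col(cors, ties.method = "first")
        }
        obj <- sum(1 - cors[cbind(seq_len(n), labels)])
        trace <- c(trace, obj)
        if (identical(labels, labels_prev)) break
        labels_prev <- labels
        sums <- rowsum(x, labels)
        centroids <- standardize_centroids(
          sums / as.vector(table(factor(labels, levels = seq_len(k)))))
        flat <- which(!is.finite(rowSums(centroids)))
        if (length(flat)) {
          # a degenerate (constant-mean) centroid is reseeded like an empty one
          d_own <- 1 - cors[cbind(seq_len(n), labels)]
          for (j in flat) {
            far <- which.max(d_own)
            centroids[j, ] <- x[far, ]
            d_own[far] <- -Inf
          }
        }
      }
      restart_obj[r] <- trace[length(trace)]
      traces[[r]] <- trace
      if (is.null(best) || restart_obj[r] < best$objective)
        best <- list(labels = labels, centroids = centroids,
                     objective = restart_obj[r])
    }
    list(best = best, restart_obj = restart_obj, traces = traces)
  }
  res <- with_seed(config$seed, run())
  labels <- stats::setNames(res$best$labels, rownames(x))
  centroids <- res$best$centroids
  rownames(centroids) <- paste0("C", seq_len(k))
  colnames(centroids) <- matrix$timepoints
  structure(list(labels = labels, centroids = centroids,
                 objective = res$best$objective,
                 restart_objectives = res$restart_obj,
                 objective_trace = res$traces,
                 species = matrix$species, timepoints = matrix$timepoints,
                 config = config, groups = NULL),
            class = "clustering_result")
}

# All 2-partitions of 1..k (subsets containing item 1), as logical masks.
two_partitions <- function(k) {
  masks <- list()
  for (code in 0:(2^(k - 1L) - 2L)) {
    inc <- c(TRUE, bitwAnd(code, 2^(seq_len(k - 1L) - 1L)) > 0)
    masks[[code + 1L]] <- inc
  }
  masks
}

#' Partition the k centroids into a down- and an up-regulated group
#'
#' Finds the exact best 2-partition of the centroids under the
#' average-linkage criterion: among all 2^(k-1) - 1 splits, the one with the
#' largest mean between-group Pearson distance (ties broken by enumeration
#' order). Each group is labelled by its mean centroid trend: `down` if the
#' last timepoint's mean falls below the first's, else `up`. Clusters are
#' then renumbered so the down group takes the lowest indices, ordered by
#' time of peak — a purely cosmetic convention for reporting.
#'
#' @param result A `clustering_result`.
#' @return The result with `groups` filled (`list(down = ..., up = ...)` of
#'   cluster indices after renumbering) and labels/centroids renumbered.
#' @export
group_clusters <- function(result) {
  stopifnot(inherits(result, "clustering_result"))
  cmat <- result$centroids
  k <- nrow(cmat)
  dmat <- 1 - stats::cor(t(cmat))
  best_mask <- NULL
  best_score <- -Inf
  for (mask in two_partitions(k)) {
    score <- mean(dmat[mask, !mask, drop = FALSE])
    if (score > best_score + 1e-12) {
      best_score <- score
      best_mask <- mask
    }
  }
  trend <- function(mask) {
    m <- colMeans(cmat[mask, , drop = FALSE])
    m[length(m)] - m[1L]
  }
  t1 <- trend(best_mask); t2 <- trend(!best_mask)
  if (sign(t1) == sign(t2))
    warnf("both centroid groups trend the same way; labelling by relative trend")
  down_mask <- if (t1 < t2) best_mask else !best_mask
  peak <- apply(cmat, 1L, which.max)
  old_order <- c(which(down_mask)[order(peak[down_mask], which(down_mask))],
                 which(!down_mask)[order(peak[!down_mask], which(!down_mask))])
  remap <- integer(k)
  remap[old_order] <- seq_len(k)
  n_down <- sum(down_mask)
  result$centroids <- cmat[old_order, , drop = FALSE]
  rownames(result$centroids) <- paste0("C", seq_len(k))
  result$labels[] <- remap[result$labels]
  result$groups <- list(down = seq_len(n_down),
                        up = seq.int(n_down + 1L, k))
  result
}

#' Per-species cluster occupancy
#'
#' @param result A `clustering_result` whose rows carry species tags.
#' @return Data frame with species, cluster, n and fraction (fractions sum
#'   to 1 within each species; clusters with no members appear with n = 0).
#' @export
cluster_fractions <- function(result) {
  stopifnot(inherits(result, "clustering_result"))
  k <- nrow(result$centroids)
  species <- unique(result$species)
  out <- do.call(rbind, lapply(species, function(sp) {
    lab <- result$labels[result$species == sp]
    n <- as.integer(table(factor(lab, levels = seq_len(k))))
    data.frame(species = sp, cluster = seq_len(k), n = n,
               fraction = n / length(lab), stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Fraction of a species' genes in the down-regulated group
#'
#' @param result A grouped `clustering_result`.
#' @param species Species tag to summarize.
#' @return Scalar fraction.
#' @export
down_fraction <- function(result, species) {
  if (is.null(result$groups)) stopf("run group_clusters() first")
  lab <- result$labels[result$species == species]
  mean(lab %in% result$groups$down)
}
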