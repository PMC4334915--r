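# Independent brute-force oracles and small fixture generators. These stay
# deliberately naive (explicit loops, no shared code with the package
# internals) so they can arbitrate the vectorized implementations.

# Random directed hit table between two species' gene sets, with deliberate
# e-value and bitscore ties to exercise tie-breaking.
random_hit_df <- function(n_query, n_subject, n_hits,
                          query_prefix = "a", subject_prefix = "b") {
  q <- sprintf("%s%02d", query_prefix, sample.int(n_query, n_hits, replace = TRUE))
  s <- sprintf("%s%02d", subject_prefix, sample.int(n_subject, n_hits, replace = TRUE))
  # coarse grids force frequent ties
  ev <- sample(c(1e-50, 1e-30, 1e-20, 1e-12, 1e-9, 1e-5), n_hits, replace = TRUE)
  bits <- sample(seq(50, 300, by = 10), n_hits, replace = TRUE)
  data.frame(query = q, subject = s, identity = 90, length = 100,
             mismatches = 0, gapopens = 0, qstart = 1, qend = 100,
             sstart = 1, send = 100, evalue = ev, bitscore = bits,
             stringsAsFactors = FALSE)
}

# Exhaustive single-best-subject map: scan all hits of each query.
oracle_best <- function(df) {
  out <- character(0)
  for (q in unique(df$query)) {
    rows <- df[df$query == q, , drop = FALSE]
    best <- rows[1L, ]
    for (i in seq_len(nrow(rows))[-1]) {
      r <- rows[i, ]
      better <- r$evalue < best$evalue ||
        (r$evalue == best$evalue && r$bitscore > best$bitscore) ||
        (r$evalue == best$evalue && r$bitscore == best$bitscore &&
           r$subject < best$subject)
      if (better) best <- r
    }
    out[q] <- best$subject
  }
  out
}

# Exhaustive mutual-best enumeration over all (a, b) gene pairs.
oracle_bbh_pairs <- function(df_ab, df_ba, max_evalue) {
  df_ab <- df_ab[df_ab$evalue <= max_evalue, , drop = FALSE]
  df_ba <- df_ba[df_ba$evalue <= max_evalue, , drop = FALSE]
  fwd <- oracle_best(df_ab)
  rev <- oracle_best(df_ba)
  pairs <- character(0)
  for (a in names(fwd)) for (b in names(rev)) {
    if (identical(unname(fwd[a]), b) && identical(unname(rev[b]), a))
      pairs <- c(pairs, paste(a, b, sep = "|"))
  }
  sort(pairs)
}

# Best 2-partition of centroids by mean between-group Pearson distance,
# enumerated with combn (a different code path than the package's bitmask
# enumeration).
oracle_two_partition <- function(cmat) {
  k <- nrow(cmat)
  dmat <- 1 - cor(t(cmat))
  best <- NULL
  best_score <- -Inf
  for (sz in 1:(k - 1)) {
    sets <- combn(k, sz, simplify = FALSE)
    for (s in sets) {
      score <- mean(dmat[s, setdiff(1:k, s), drop = FALSE])
      if (score > best_score + 1e-12) {
        best_score <- score
        best <- s
      }
    }
  }
  # normalize: report the side containing centroid 1
  if (1 %in% best) sort(best) else sort(setdiff(1:k, best))
}

# Build a normalized_matrix at a given stage directly (tests only).
as_nm <- function(values, species, stage, timepoints = NULL) {
  if (is.null(timepoints)) timepoints <- as.character(seq_len(ncol(values)))
  dictyComp:::new_normalized_matrix(values, species, timepoints, stage)
}

hit_df_row <- function(query, subject, evalue, bitscore = 200,
                       identity = 90) {
  data.frame(query = query, subject = subject, identity = identity,
             length = 100, mismatches = 0, gapopens = 0, qstart = 1,
             qend = 100, sstart = 1, send = 100, evalue = evalue,
             bitscore = bitscore, stringsAsFactors = FALSE)
}

pair_keys <- function(map) {
  if (!nrow(map$pairs)) return(character(0))
  sort(paste(map$pairs$gene_a, map$pairs$gene_b, sep = "|"))
}

# run the normalization chain on one simulated species
normalize_chain <- function(tc, sp, total = 1e7, epsilon = 0) {
  standardize(filter_unexpressed(scale_to_total(average_replicates(
    rpkm(tc$tables[[sp]], tc$total_mapped[[sp]])), total = total),
    epsilon = epsilon))
}

planted_labels_for <- function(tc, result) {
  key <- paste(tc$truth$species, tc$truth$gene, sep = "::")
  stats::setNames(tc$truth$archetype, key)[names(result$labels)]
}
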