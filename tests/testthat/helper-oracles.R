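# Independent oracles and fixture builders used across the suite.

# Quadratic substring-scan digestion oracle: loops over every start
# position, compares character by character, derives fragment sizes from
# the cut positions. Kept deliberately naive and loop-based.
naive_digest <- function(residues, site, cut_offset) {
  chars <- strsplit(residues, "", fixed = TRUE)[[1]]
  site_chars <- strsplit(site, "", fixed = TRUE)[[1]]
  n <- length(chars); k <- length(site_chars)
  cuts <- integer(0)
  if (n >= k) for (i in 1:(n - k + 1)) {
    hit <- TRUE
    for (j in 1:k) if (chars[i + j - 1] != site_chars[j]) { hit <- FALSE; break }
    if (hit) cuts <- c(cuts, i - 1 + cut_offset)
  }
  sizes <- diff(c(0, sort(cuts), n))
  sort(sizes[sizes > 0])
}

revcomp <- function(x)
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))

# Build count_estimate objects from planted integer log counts by routing
# them through real dilution series (tube positive iff d <= count, with a
# zero count meaning "never detected"). Series run deep enough to encode
# the largest planted count.
estimates_from_counts <- function(counts, group = "g", taxon = "t") {
  d_max <- max(6, counts)
  lapply(seq_along(counts), function(i) {
    pos <- if (counts[i] > 0) 0:d_max <= counts[i] else rep(FALSE, d_max + 1)
    estimate_log_count(
      dilution_series(sprintf("%s_%d", group, i), group, taxon, 0:d_max, pos,
                      max_exponent = d_max))
  })
}

# Naive average-linkage (UPGMA) oracle returning the cophenetic matrix:
# iterative merging where cluster-cluster distance is the mean over the
# original leaf pairs, and the cophenetic entry for a cross pair is the
# merge distance.
naive_upgma_cophenetic <- function(d) {
  ids <- rownames(d)
  clusters <- lapply(seq_along(ids), identity)
  coph <- matrix(0, nrow(d), ncol(d), dimnames = dimnames(d))
  while (length(clusters) > 1) {
    best <- c(NA, NA); best_d <- Inf
    for (i in seq_along(clusters)) for (j in seq_along(clusters)) {
      if (j <= i) next
      dd <- mean(d[clusters[[i]], clusters[[j]], drop = FALSE])
      if (dd < best_d) { best_d <- dd; best <- c(i, j) }
    }
    for (a in clusters[[best[1]]]) for (b in clusters[[best[2]]])
      coph[a, b] <- coph[b, a] <- best_d
    clusters[[best[1]]] <- c(clusters[[best[1]]], clusters[[best[2]]])
    clusters <- clusters[-best[2]]
  }
  coph
}

# Least-squares branch fit of a distance matrix onto a fixed topology;
# returns the residual sum of squares. Used to identify the generating
# topology among all candidate topologies, independently of any
# tree-building algorithm.
ls_topology_rss <- function(dm, tree) {
  labs <- rownames(dm)
  n_edge <- nrow(tree$edge)
  pairs <- t(utils::combn(labs, 2))
  X <- matrix(0, nrow(pairs), n_edge)
  for (k in seq_len(n_edge)) {
    t2 <- tree
    t2$edge.length <- rep(0, n_edge)
    t2$edge.length[k] <- 1
    cp <- ape::cophenetic.phylo(t2)
    X[, k] <- cp[cbind(pairs[, 1], pairs[, 2])]
  }
  y <- dm[cbind(pairs[, 1], pairs[, 2])]
  fit <- stats::lm.fit(X, y)
  sum(fit$residuals^2)
}

# Random additive distance matrix from a random binary tree.
random_additive_matrix <- function(n_taxa) {
  tr <- ape::rtree(n_taxa, rooted = FALSE,
                   br = function(k) stats::runif(k, 0.05, 0.5))
  list(tree = tr, dm = ape::cophenetic.phylo(tr))
}

# Mutate exactly one position of a DNA string (to a different base).
mutate_one <- function(seq, pos = NULL) {
  chars <- strsplit(seq, "", fixed = TRUE)[[1]]
  if (is.null(pos)) pos <- sample.int(length(chars), 1)
  chars[pos] <- setdiff(c("A", "C", "G", "T"), chars[pos])[1]
  paste(chars, collapse = "")
}
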