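# Phenotypic numerical taxonomy: Jaccard similarity over binary test
# panels (carbohydrate acidification, enzymatic reactions) and UPGMA
# dendrograms.

#' A binary phenotype panel for one strain
#'
#' @param strain_id Strain label.
#' @param tests Named logical vector: `TRUE` positive, `FALSE` negative,
#'   `NA` untested.
#' @return An object of class `phenotype_panel`.
#' @export
phenotype_panel <- function(strain_id, tests) {
  if (!is.logical(tests) || is.null(names(tests)) || !length(tests))
    abort("tests must be a named logical vector", "invalid_input")
  structure(list(strain_id = strain_id, tests = tests),
            class = "phenotype_panel")
}

#' Jaccard similarity of two phenotype panels
#'
#' Shared positives over shared positives plus mismatches, computed over
#' the tests where both strains have a result. Joint negatives are
#' excluded -- the defining property of the Jaccard index versus simple
#' matching: two strains are not similar merely because both fail the
#' same sugars -- and untested entries are excluded pairwise.
#'
#' @param a,b [phenotype_panel] objects sharing a test universe.
#' @return Similarity in `[0, 1]`.
#' @examples
#' a <- phenotype_panel("a", c(t1 = TRUE, t2 = TRUE, t3 = FALSE))
#' b <- phenotype_panel("b", c(t1 = TRUE, t2 = FALSE, t3 = FALSE))
#' jaccard_similarity(a, b)  # 0.5
#' @export
jaccard_similarity <- function(a, b) {
  stopifnot(inherits(a, "phenotype_panel"), inherits(b, "phenotype_panel"))
  common <- intersect(names(a$tests), names(b$tests))
  ta <- a$tests[common]; tb <- b$tests[common]
  keep <- !is.na(ta) & !is.na(tb)
  ta <- ta[keep]; tb <- tb[keep]
  if (!length(ta))
    abort(sprintf("no comparable tests between %s and %s",
                  a$strain_id, b$strain_id), "undefined_similarity")
  shared <- sum(ta & tb)
  mismatch <- sum(ta != tb)
  if (shared + mismatch == 0L)
    abort(sprintf("similarity undefined between %s and %s: no positive in either",
                  a$strain_id, b$strain_id), "undefined_similarity")
  shared / (shared + mismatch)
}

#' Pairwise Jaccard similarity matrix over phenotype panels
#'
#' @param panels List of [phenotype_panel] objects with unique strain ids.
#' @return Symmetric similarity matrix with unit diagonal.
#' @export
jaccard_matrix <- function(panels) {
  stopifnot(is.list(panels), all(vapply(panels, inherits, TRUE, "phenotype_panel")))
  ids <- vapply(panels, `[[`, "", "strain_id")
  if (anyDuplicated(ids)) abort("duplicate strain ids", "invalid_input")
  n <- length(panels)
  s <- diag(1, n); dimnames(s) <- list(ids, ids)
  if (n > 1) for (i in 1:(n - 1)) for (j in (i + 1):n)
    s[i, j] <- s[j, i] <- jaccard_similarity(panels[[i]], panels[[j]])
  s
}

#' UPGMA dendrogram from a similarity matrix
#'
#' Agglomerative average-linkage clustering on `distance = 1 - similarity`
#' (unweighted pair-group method: cluster-to-cluster distance is the mean
#' over all original pairs). Merge heights are non-decreasing, so the
#' dendrogram is ultrametric. Tied merges resolve to the lexicographically
#' smallest strain pair for determinism.
#'
#' @param similarities Symmetric similarity matrix in `[0, 1]` with strain
#'   ids as dimnames (e.g. from [jaccard_matrix()]); alternatively a
#'   distance matrix via `is_distance = TRUE`.
#' @param is_distance Interpret the input as distances directly.
#' @return An \pkg{ape} `phylo` object (rooted ultrametric dendrogram;
#'   node heights are half the merge distances so leaf-to-leaf path length
#'   equals the merge distance). Attribute `merges` holds the merge table
#'   (members and heights).
#' @export
upgma_tree <- function(similarities, is_distance = FALSE) {
  if (!is.matrix(similarities) || nrow(similarities) != ncol(similarities) ||
      !isTRUE(all.equal(similarities, t(similarities), tolerance = 1e-8)))
    abort("similarity matrix must be square and symmetric", "invalid_input")
  d <- if (is_distance) similarities else 1 - similarities
  ids <- rownames(d)
  if (is.null(ids)) ids <- paste0("s", seq_len(nrow(d)))
  n <- nrow(d)
  if (n < 2) abort("clustering needs at least 2 strains", "invalid_input")

  # explicit UPGMA agglomeration with lexicographic tie-breaking; heights
  # are the average original-pair distances at each merge
  clusters <- as.list(seq_len(n))          # member leaf indices
  labels <- ids                            # current cluster labels (lexic. ties)
  active <- seq_len(n)
  d0 <- d                                  # original leaf-leaf distances
  merges <- data.frame(left = character(0), right = character(0),
                       height = numeric(0), stringsAsFactors = FALSE)
  newick <- ids
  heights <- rep(0, n)                     # current node heights (ultrametric)
  avg_dist <- function(ci, cj)
    mean(d0[clusters[[ci]], clusters[[cj]], drop = FALSE])
  while (length(active) > 1L) {
    best <- NULL
    for (ii in seq_along(active)) for (jj in seq_along(active)) {
      if (jj <= ii) next
      ci <- active[ii]; cj <- active[jj]
      dd <- avg_dist(ci, cj)
      pair <- sort(c(labels[ci], labels[cj]))
      if (is.null(best) || dd < best$d - 1e-12 ||
          (abs(dd - best$d) <= 1e-12 &&
           (pair[1] < best$pair[1] ||
            (pair[1] == best$pair[1] && pair[2] < best$pair[2])))) {
        best <- list(i = ci, j = cj, d = dd, pair = pair)
      }
    }
    h <- best$d / 2
    merges <- rbind(merges, data.frame(
      left = labels[best$i], right = labels[best$j], height = h,
      stringsAsFactors = FALSE))
    k <- length(clusters) + 1L
    clusters[[k]] <- c(clusters[[best$i]], clusters[[best$j]])
    labels[k] <- min(labels[best$i], labels[best$j])
    newick[k] <- sprintf("(%s:%.15g,%s:%.15g)",
                         newick[best$i], h - heights[best$i],
                         newick[best$j], h - heights[best$j])
    heights[k] <- h
    active <- c(setdiff(active, c(best$i, best$j)), k)
  }
  tr <- ape::read.tree(text = paste0(newick[active], ";"))
  attr(tr, "merges") <- merges
  attr(tr, "method") <- "upgma"
  tr
}

#' Read phenotype panels from CSV
#'
#' Strains-by-tests table: first column `strain_id`, remaining columns one
#' per test with entries `+`, `-` or `NT`.
#'
#' @param path CSV path.
#' @return List of [phenotype_panel] objects.
#' @export
read_phenotype_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (names(df)[1] != "strain_id")
    abort("first column of a phenotype CSV must be strain_id", "invalid_input")
  tests <- names(df)[-1]
  lapply(seq_len(nrow(df)), function(i) {
    vals <- toupper(trimws(unlist(df[i, -1])))
    bad <- setdiff(unique(vals), c("+", "-", "NT"))
    if (length(bad))
      abort(sprintf("phenotype entries must be +, - or NT (got %s)",
                    paste(bad, collapse = ", ")), "invalid_input")
    phenotype_panel(df$strain_id[i],
                    stats::setNames(ifelse(vals == "NT", NA, vals == "+"), tests))
  })
}
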