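# Multilocus sequence analysis: allele databases, allele assignment,
# sequence types, fixed-order concatenation, identity-based distance
# matrices and neighbor-joining trees.

#' The seven MLSA housekeeping loci and their template sizes
#'
#' The scheme types strains on internal fragments of clpC, fusA, gyrB,
#' ileS, purF, rplB and rpoB. `MLSA_LOCI` also fixes the concatenation
#' order used throughout the package (the order the loci are listed in;
#' MLST databases differ on this, so it is pinned and documented).
#'
#' @format Named integer vector: locus -> template size in bp.
#' @export
MLSA_LOCI <- c(clpC = 501L, fusA = 666L, gyrB = 600L, ileS = 489L,
               purF = 627L, rplB = 591L, rpoB = 357L)

#' An allele database for the MLSA loci
#'
#' Per locus, a set of numbered allele sequences. Allele numbers are
#' unique per locus; sequences are validated against the locus template
#' size (exact match required at construction -- novel indel-bearing
#' alleles enter via [assign_allele()] which tolerates up to 10% length
#' deviation before flagging a quality failure).
#'
#' @param alleles Named list, one element per locus, each a named
#'   character vector of DNA strings with integer names (allele numbers).
#'   Empty loci are allowed (bootstrap case).
#' @param loci Named integer vector of template sizes.
#' @param strict_length If `TRUE` (default), constructor rejects alleles
#'   whose length differs from the template size.
#' @return An object of class `allele_db`.
#' @export
allele_db <- function(alleles = stats::setNames(vector("list", length(MLSA_LOCI)),
                                                names(MLSA_LOCI)),
                      loci = MLSA_LOCI, strict_length = TRUE) {
  stopifnot(is.list(alleles))
  unknown <- setdiff(names(alleles), names(loci))
  if (length(unknown))
    abort(sprintf("unknown locus in allele db: %s",
                  paste(unknown, collapse = ", ")), "invalid_input")
  for (locus in names(alleles)) {
    al <- alleles[[locus]]
    if (is.null(al) || !length(al)) { alleles[[locus]] <- character(0); next }
    nums <- suppressWarnings(as.integer(names(al)))
    if (anyNA(nums) || anyDuplicated(nums) || any(nums < 1L))
      abort(sprintf("%s: allele numbers must be unique positive integers", locus),
            "invalid_input")
    al <- vapply(al, check_dna, "", what = locus, USE.NAMES = TRUE)
    if (strict_length && any(nchar(al) != loci[[locus]]))
      abort(sprintf("%s: alleles must be %d bp", locus, loci[[locus]]),
            "invalid_input")
    alleles[[locus]] <- al
  }
  for (locus in setdiff(names(loci), names(alleles)))
    alleles[[locus]] <- character(0)
  structure(list(alleles = alleles[names(loci)], loci = loci),
            class = "allele_db")
}

#' @export
print.allele_db <- function(x, ...) {
  cat("<allele_db>\n")
  for (locus in names(x$loci))
    cat(sprintf("  %s (%d bp): %d allele(s)\n", locus, x$loci[[locus]],
                length(x$alleles[[locus]])))
  invisible(x)
}

#' Read an allele database from per-locus FASTA files
#'
#' One FASTA per locus named `<locus>.fasta` (or `.fa`), records headed
#' `<locus>_<number>`.
#'
#' @param dir Directory holding the per-locus FASTA files.
#' @param loci Named integer vector of template sizes.
#' @return An [allele_db].
#' @export
read_allele_db <- function(dir, loci = MLSA_LOCI) {
  alleles <- list()
  for (locus in names(loci)) {
    path <- file.path(dir, paste0(locus, c(".fasta", ".fa")))
    path <- path[file.exists(path)]
    if (!length(path)) next
    seqs <- Biostrings::readDNAStringSet(path[1])
    nums <- sub(paste0("^", locus, "_"), "", names(seqs))
    alleles[[locus]] <- stats::setNames(as.character(seqs), nums)
  }
  allele_db(alleles, loci)
}

#' Write an allele database to per-locus FASTA files
#'
#' @param db An [allele_db].
#' @param dir Output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_allele_db <- function(db, dir) {
  stopifnot(inherits(db, "allele_db"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (locus in names(db$loci)) {
    al <- db$alleles[[locus]]
    if (!length(al)) next
    x <- Biostrings::DNAStringSet(unname(al))
    names(x) <- paste0(locus, "_", names(al))
    Biostrings::writeXStringSet(x, file.path(dir, paste0(locus, ".fasta")))
  }
  invisible(dir)
}

#' Assign an allele number to a locus sequence
#'
#' Exact database match gives the existing allele number at 100% identity.
#' Otherwise the sequence is a novel allele: it receives the next free
#' integer for the locus and its identity to the nearest existing allele
#' (highest global-alignment identity, ties resolved to the lowest allele
#' number) is reported. A query whose length deviates from the locus
#' template by more than 10% is rejected as a sequencing-quality failure.
#'
#' @param locus_seq DNA string (or [annotated_sequence]) of the locus
#'   fragment.
#' @param locus Locus name, one of `names(db$loci)`.
#' @param db An [allele_db].
#' @return A list: `allele` (integer), `identity` (percent identity to the
#'   assigned or nearest allele), `is_novel`, `nearest` (allele number the
#'   identity refers to, `NA` for an empty locus).
#' @export
assign_allele <- function(locus_seq, locus, db) {
  stopifnot(inherits(db, "allele_db"))
  if (!locus %in% names(db$loci))
    abort(sprintf("unknown locus: %s", locus), "invalid_input")
  seq <- as_annotated_sequence(locus_seq, locus)$residues
  tmpl <- db$loci[[locus]]
  if (abs(nchar(seq) - tmpl) > 0.10 * tmpl)
    abort(sprintf("%s query is %d bp; deviates >10%% from the %d-bp template",
                  locus, nchar(seq), tmpl), "quality_failure")
  al <- db$alleles[[locus]]
  if (!length(al))
    return(list(allele = 1L, identity = NA_real_, is_novel = TRUE,
                nearest = NA_integer_))
  exact <- which(al == seq)
  if (length(exact)) {
    num <- as.integer(names(al)[exact[1]])
    return(list(allele = num, identity = 100, is_novel = FALSE, nearest = num))
  }
  nums <- as.integer(names(al))
  ids <- vapply(al, function(ref) pairwise_identity(seq, ref), 0)
  best <- order(-ids, nums)[1]
  list(allele = max(nums) + 1L, identity = unname(ids[best]), is_novel = TRUE,
       nearest = nums[best])
}

#' Build an allelic profile for a strain
#'
#' Runs [assign_allele()] for every locus, returning the seven-allele
#' profile plus per-locus nearest-allele identities.
#'
#' @param strain_id Strain label.
#' @param locus_seqs Named list/character vector of locus sequences
#'   covering every locus in `db`.
#' @param db An [allele_db].
#' @return An object of class `allelic_profile`: `strain_id`, `alleles`
#'   (named integer vector in locus order), `identity` (named numeric),
#'   `novel` (named logical).
#' @export
allelic_profile <- function(strain_id, locus_seqs, db) {
  stopifnot(inherits(db, "allele_db"))
  missing_loci <- setdiff(names(db$loci), names(locus_seqs))
  if (length(missing_loci))
    abort(sprintf("strain %s is missing locus: %s", strain_id,
                  paste(missing_loci, collapse = ", ")), "incomplete_profile")
  alleles <- integer(0); identity <- numeric(0); novel <- logical(0)
  for (locus in names(db$loci)) {
    a <- assign_allele(locus_seqs[[locus]], locus, db)
    alleles[locus] <- a$allele
    identity[locus] <- a$identity
    novel[locus] <- a$is_novel
  }
  structure(list(strain_id = strain_id, alleles = alleles,
                 identity = identity, novel = novel),
            class = "allelic_profile")
}

#' @export
print.allelic_profile <- function(x, ...) {
  cat(sprintf("<allelic_profile> %s\n", x$strain_id))
  for (locus in names(x$alleles))
    cat(sprintf("  %s: allele %d%s%s\n", locus, x$alleles[[locus]],
                if (x$novel[[locus]]) " (novel)" else "",
                if (is.na(x$identity[[locus]])) ""
                else sprintf(", identity %.2f%%", x$identity[[locus]])))
  invisible(x)
}

#' Look up (or register) a sequence type for an allelic profile
#'
#' Exact lookup of the seven-allele tuple in a sequence-type table. An
#' unseen tuple is `"novel"`; with `register = TRUE` it is added under the
#' next free ST number and the updated table is attached to the result.
#'
#' @param profile An [allelic_profile] (complete, all seven loci).
#' @param st_table Data frame with one column per locus plus `st`
#'   (integer). An empty/NULL table is the bootstrap case.
#' @param register Register novel tuples under the next free ST number?
#' @return A list: `st` (integer, or `"novel"` when unseen and
#'   `register = FALSE`), `st_table` (possibly extended).
#' @export
profile_to_st <- function(profile, st_table = NULL, register = FALSE) {
  stopifnot(inherits(profile, "allelic_profile"))
  loci <- names(MLSA_LOCI)
  if (!all(loci %in% names(profile$alleles)))
    abort("incomplete profile: all seven loci are required", "incomplete_profile")
  if (is.null(st_table) || !nrow(st_table)) {
    st_table <- stats::setNames(
      data.frame(matrix(integer(0), 0, length(loci) + 1)), c(loci, "st"))
  }
  hit <- rep(TRUE, nrow(st_table))
  for (locus in loci) hit <- hit & (st_table[[locus]] == profile$alleles[[locus]])
  if (any(hit)) return(list(st = st_table$st[which(hit)[1]], st_table = st_table))
  if (!register) return(list(st = "novel", st_table = st_table))
  new_st <- if (nrow(st_table)) max(st_table$st) + 1L else 1L
  row <- as.data.frame(as.list(profile$alleles[loci]))
  row$st <- new_st
  list(st = new_st, st_table = rbind(st_table, row))
}

#' Concatenate the seven locus sequences of a strain
#'
#' Joins the locus fragments in the fixed scheme order
#' clpC-fusA-gyrB-ileS-purF-rplB-rpoB regardless of input order. The
#' concatenated length is the sum of the input lengths (3831 bp for
#' full-template fragments).
#'
#' @param locus_seqs Named list/character vector of DNA strings covering
#'   all seven loci.
#' @param strain_id Label for the output sequence.
#' @param order Concatenation order; defaults to the scheme order.
#' @return An [annotated_sequence].
#' @export
concatenate_loci <- function(locus_seqs, strain_id = "strain",
                             order = names(MLSA_LOCI)) {
  missing_loci <- setdiff(order, names(locus_seqs))
  if (length(missing_loci))
    abort(sprintf("missing locus: %s", paste(missing_loci, collapse = ", ")),
          "incomplete_profile")
  parts <- vapply(order, function(l)
    as_annotated_sequence(locus_seqs[[l]], l)$residues, "")
  annotated_sequence(strain_id, paste(parts, collapse = ""))
}

#' Identity-based distance matrix over strains
#'
#' Pairwise distance `1 - identity/100` from global alignment of (usually
#' concatenated) strain sequences.
#'
#' @param seqs Named list/character vector of DNA strings, one per strain
#'   (names are strain ids).
#' @return A symmetric numeric matrix with zero diagonal.
#' @export
distance_matrix <- function(seqs) {
  if (is.list(seqs))
    seqs <- vapply(seqs, function(s) as_annotated_sequence(s)$residues, "")
  ids <- names(seqs)
  if (is.null(ids) || anyDuplicated(ids))
    abort("strain sequences must have unique names", "invalid_input")
  n <- length(seqs)
  d <- matrix(0, n, n, dimnames = list(ids, ids))
  if (n > 1) for (i in 1:(n - 1)) for (j in (i + 1):n) {
    d[i, j] <- d[j, i] <- 1 - pairwise_identity(seqs[[i]], seqs[[j]]) / 100
  }
  d
}

#' Neighbor-joining tree from a distance matrix
#'
#' Saitou-Nei neighbor joining (standard Q-criterion agglomeration, as
#' implemented in \pkg{ape}). NJ can produce negative branch lengths on
#' non-additive input; these are clamped to zero with the (negative)
#' excess moved onto the adjacent branches so that adjacent path lengths
#' are preserved, and a flag attribute records the adjustment.
#'
#' @param dm Symmetric numeric distance matrix with zero diagonal and at
#'   least 3 taxa.
#' @return An \pkg{ape} `phylo` object (unrooted, with branch lengths).
#'   Attribute `method` records `"nj"`.
#' @export
nj_tree <- function(dm) {
  if (!is.matrix(dm) || nrow(dm) != ncol(dm) ||
      !isTRUE(all.equal(dm, t(dm), tolerance = 1e-8)))
    abort("distance matrix must be square and symmetric", "invalid_input")
  if (nrow(dm) < 3)
    abort("a tree needs at least 3 taxa", "invalid_input")
  tr <- ape::nj(stats::as.dist(dm))
  clamped <- FALSE
  # clamp negative branch lengths; move the excess to adjacent branches
  for (k in seq_along(tr$edge.length)) {
    len <- tr$edge.length[k]
    if (len >= 0) next
    clamped <- TRUE
    child <- tr$edge[k, 2]
    adjacent <- which(tr$edge[, 1] == child)
    if (!length(adjacent))  # terminal edge: shift onto sibling edges
      adjacent <- setdiff(which(tr$edge[, 1] == tr$edge[k, 1]), k)
    tr$edge.length[adjacent] <- tr$edge.length[adjacent] + len
    tr$edge.length[k] <- 0
  }
  tr$edge.length[tr$edge.length < 0] <- 0
  attr(tr, "method") <- "nj"
  if (clamped) attr(tr, "flag") <- "negative branch length(s) clamped to 0"
  tr
}
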