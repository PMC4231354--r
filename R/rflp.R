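# In-silico PCR-RFLP typing: recognition-site scanning, restriction
# digestion, amplicon extraction, gel-observable filtering, pattern-library
# matching and combination-based species calls.

#' Define a restriction enzyme
#'
#' An enzyme is a literal (unambiguous) recognition site plus the cut
#' position within that site on the top strand. Only top-strand literal
#' sites are scanned during digestion; the two shipped enzymes (AluI,
#' TaqI) have palindromic sites so strand handling is immaterial for them,
#' but user-supplied non-palindromic enzymes are interpreted top-strand.
#'
#' @param name Enzyme name.
#' @param recognition_site Unambiguous DNA word, length >= 4.
#' @param cut_offset Integer in `0..nchar(site)`: the cut falls after
#'   `cut_offset` residues of the site (top strand).
#' @return An object of class `restriction_enzyme`.
#' @examples
#' restriction_enzyme("AluI", "AGCT", 2)
#' @export
restriction_enzyme <- function(name, recognition_site, cut_offset) {
  if (!is_string(name)) abort("name must be a single string", "invalid_input")
  recognition_site <- check_dna(recognition_site, "recognition_site",
                                allow_ambiguous = FALSE)
  if (nchar(recognition_site) < 4L)
    abort("recognition_site must be at least 4 bp", "invalid_input")
  cut_offset <- as.integer(cut_offset)
  if (is.na(cut_offset) || cut_offset < 0L || cut_offset > nchar(recognition_site))
    abort("cut_offset must lie within the recognition site", "invalid_input")
  structure(list(name = name, recognition_site = recognition_site,
                 cut_offset = cut_offset),
            class = "restriction_enzyme")
}

#' @export
print.restriction_enzyme <- function(x, ...) {
  site <- x$recognition_site
  cat(sprintf("<restriction_enzyme> %s: %s^%s\n", x$name,
              substr(site, 1, x$cut_offset),
              substr(site, x$cut_offset + 1, nchar(site))))
  invisible(x)
}

#' Shipped enzyme definitions
#'
#' AluI (AG^CT) and TaqI (T^CGA), the two enzymes of the 16S rRNA gene
#' PCR-RFLP typing scheme for dairy bifidobacteria.
#'
#' @param name `"AluI"` or `"TaqI"`.
#' @return A `restriction_enzyme`.
#' @export
default_enzyme <- function(name = c("AluI", "TaqI")) {
  name <- match.arg(name)
  switch(name,
         AluI = restriction_enzyme("AluI", "AGCT", 2L),
         TaqI = restriction_enzyme("TaqI", "TCGA", 1L))
}

#' Find restriction-enzyme cut positions
#'
#' Scans the top strand for literal occurrences of the recognition site
#' (overlapping occurrences included) and returns 0-based between-residue
#' cut coordinates. Ambiguity codes in the substrate never match: digestion
#' of a Sanger-ambiguous base is undefined, so the scan is conservative.
#'
#' @param seq An [annotated_sequence] or DNA string.
#' @param enzyme A [restriction_enzyme].
#' @return Integer vector of strictly increasing cut positions (possibly
#'   empty). A cut at position p separates residues `1..p` from `p+1..n`.
#' @examples
#' find_recognition_sites(annotated_sequence("x", "TTAGCTTT"),
#'                        default_enzyme("AluI"))
#' @export
find_recognition_sites <- function(seq, enzyme) {
  seq <- as_annotated_sequence(seq)
  stopifnot(inherits(enzyme, "restriction_enzyme"))
  s <- seq$residues
  site <- enzyme$recognition_site
  n <- nchar(s)
  k <- nchar(site)
  if (n < k) return(integer(0))
  starts <- 1:(n - k + 1L)
  hits <- starts[substring(s, starts, starts + k - 1L) == site]
  sort(hits - 1L + enzyme$cut_offset)
}

#' A set of restriction fragments
#'
#' Sizes in bp, ascending; `source_length` is the length of the digested
#' molecule so that conservation (`sum(sizes) == source_length`) can be
#' asserted for linear substrates. Fragments dropped by detection-limit
#' filtering are recorded in `flags` and no longer counted in `sizes`,
#' while `source_length` is kept.
#'
#' @param sizes Integer fragment sizes in bp.
#' @param source_length Length in bp of the digested molecule.
#' @param flags Character vector of notes.
#' @return An object of class `fragment_set`.
#' @export
fragment_set <- function(sizes, source_length, flags = character(0)) {
  sizes <- as.integer(sizes)
  if (any(is.na(sizes)) || any(sizes < 1L))
    abort("fragment sizes must be positive integers", "invalid_input")
  structure(list(sizes = sort(sizes), source_length = as.integer(source_length),
                 flags = flags),
            class = "fragment_set")
}

#' @export
print.fragment_set <- function(x, ...) {
  cat(sprintf("<fragment_set> %d fragment(s) of a %d-bp molecule: %s\n",
              length(x$sizes), x$source_length,
              paste(x$sizes, collapse = "-")))
  if (length(x$flags)) cat("  flags:", paste(x$flags, collapse = "; "), "\n")
  invisible(x)
}

#' Digest a linear DNA sequence with a restriction enzyme
#'
#' Fragment sizes are the gaps between consecutive cut positions plus both
#' molecule ends; with no recognition site the molecule is returned intact
#' as a single fragment. Zero-length fragments (a cut flush with a molecule
#' end, possible for enzymes with `cut_offset` 0 or `nchar(site)`) are not
#' physical fragments and are dropped; conservation of total length holds
#' regardless.
#'
#' @inheritParams find_recognition_sites
#' @return A [fragment_set] whose sizes sum to the sequence length.
#' @examples
#' digest(annotated_sequence("x", "TTAGCTTT"), default_enzyme("AluI"))
#' @export
digest <- function(seq, enzyme) {
  seq <- as_annotated_sequence(seq)
  cuts <- find_recognition_sites(seq, enzyme)
  n <- nchar(seq$residues)
  sizes <- diff(c(0L, cuts, n))
  fragment_set(sizes[sizes > 0L], n)
}

#' Extract a PCR amplicon delimited by two primers
#'
#' Finds the best (fewest-mismatch, then leftmost) ungapped match of the
#' forward primer and the best (fewest-mismatch, then rightmost) match of
#' the reverse-complemented reverse primer, and returns the subsequence
#' spanning both primer footprints. Failure to place either primer within
#' `max_mismatch` raises an `amplification_failure` condition rather than
#' returning an empty sequence, so a failed amplification is
#' distinguishable from a zero-length product.
#'
#' @param seq Template, an [annotated_sequence] or DNA string.
#' @param forward_primer,reverse_primer Primer sequences written 5'->3'
#'   (the reverse primer as on the opposite strand, as usually published).
#' @param max_mismatch Maximum number of mismatches tolerated per primer.
#' @return The amplicon as an [annotated_sequence].
#' @examples
#' f <- "AGTTTGATCCTGGCTCAG"
#' r <- "TACCTTGTTACGACT"
#' tmpl <- paste0(f, strrep("ACGT", 25),
#'   as.character(Biostrings::reverseComplement(Biostrings::DNAString(r))))
#' extract_amplicon(tmpl, f, r)
#' @export
extract_amplicon <- function(seq, forward_primer, reverse_primer,
                             max_mismatch = 0L) {
  seq <- as_annotated_sequence(seq)
  forward_primer <- check_dna(forward_primer, "forward_primer",
                              allow_ambiguous = FALSE)
  reverse_primer <- check_dna(reverse_primer, "reverse_primer",
                              allow_ambiguous = FALSE)
  if (max_mismatch < 0) abort("max_mismatch must be >= 0", "invalid_input")

  mismatch_profile <- function(subject, query) {
    n <- nchar(subject); m <- nchar(query)
    if (n < m) return(integer(0))
    sub_chars <- strsplit(subject, "", fixed = TRUE)[[1]]
    q_chars <- strsplit(query, "", fixed = TRUE)[[1]]
    starts <- 1:(n - m + 1L)
    mism <- integer(length(starts))
    for (j in seq_len(m))
      mism <- mism + (sub_chars[starts + j - 1L] != q_chars[j])
    mism
  }

  s <- seq$residues
  fw <- mismatch_profile(s, forward_primer)
  rv <- mismatch_profile(s, revcomp(reverse_primer))
  fail <- function(which)
    abort(sprintf("amplification failure: %s primer not found within %d mismatch(es)",
                  which, max_mismatch),
          "amplification_failure")
  if (!length(fw) || min(fw) > max_mismatch) fail("forward")
  if (!length(rv) || min(rv) > max_mismatch) fail("reverse")
  f_start <- which(fw == min(fw))[1]                      # leftmost best
  r_starts <- which(rv == min(rv))
  r_start <- r_starts[length(r_starts)]                   # rightmost best
  r_end <- r_start + nchar(reverse_primer) - 1L
  if (r_end < f_start) fail("reverse (downstream of forward)")
  annotated_sequence(paste0(seq$id, "_amplicon"),
                     substr(s, f_start, r_end))
}

#' Filter fragments below a gel detection limit
#'
#' Models the detection limit of agarose electrophoresis: fragments shorter
#' than `min_size` are removed and the removal is recorded as a flag.
#' The default `min_size = 0` is the "sequence-predicted" mode in which
#' every fragment is kept (the AluI typing pattern includes a 5-bp band
#' that only exists on paper); a "gel" mode with `min_size` around 50 bp
#' reflects what a 2.5% agarose gel can resolve.
#'
#' @param frags A [fragment_set].
#' @param min_size Detection limit in bp.
#' @return A [fragment_set] with the same `source_length`.
#' @export
gel_observable <- function(frags, min_size = 0L) {
  stopifnot(inherits(frags, "fragment_set"))
  if (min_size < 0) abort("min_size must be >= 0", "invalid_input")
  keep <- frags$sizes >= min_size
  flags <- frags$flags
  if (any(!keep))
    flags <- c(flags, sprintf("dropped %d band(s) below %d bp: %s",
                              sum(!keep), as.integer(min_size),
                              paste(frags$sizes[!keep], collapse = "-")))
  structure(list(sizes = frags$sizes[keep],
                 source_length = frags$source_length, flags = flags),
            class = "fragment_set")
}
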