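# Internal helpers shared across modules.

IUPAC_DNA <- c("A", "C", "G", "T", "R", "Y", "S", "W", "K", "M",
               "B", "D", "H", "V", "N")

#' @noRd
abort <- function(message, class, ...) {
  stop(errorCondition(message, ..., class = c(class, "bifidotyper_error")))
}

#' Round half away from zero
#'
#' Commercial rounding (0.5 always rounds up), used for printed survey
#' percentages. Base `round()` rounds half to even, which would print 29.5%
#' as 30% or 30% depending on parity; half-up is the documented policy.
#' @noRd
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' @noRd
is_string <- function(x) is.character(x) && length(x) == 1L && !is.na(x)

#' Validate and normalise a DNA string over the IUPAC alphabet
#' @noRd
check_dna <- function(residues, what = "sequence", allow_ambiguous = TRUE) {
  if (!is_string(residues) || nchar(residues) == 0L)
    abort(sprintf("%s must be a non-empty DNA string", what), "invalid_input")
  residues <- toupper(residues)
  chars <- strsplit(residues, "", fixed = TRUE)[[1]]
  alphabet <- if (allow_ambiguous) IUPAC_DNA else c("A", "C", "G", "T")
  bad <- setdiff(unique(chars), alphabet)
  if (length(bad) > 0L)
    abort(sprintf("%s contains non-IUPAC characters: %s",
                  what, paste(bad, collapse = ", ")), "invalid_input")
  residues
}

#' Reverse complement of an IUPAC DNA string
#' @noRd
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

#' Uniform random unambiguous DNA string
#' @noRd
random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

#' A named, linear DNA sequence
#'
#' Light container used as the substrate for amplification, digestion and
#' alignment. Residues are validated against the IUPAC DNA alphabet and
#' stored upper-case; topology is always linear (the assays modelled here
#' act on PCR amplicons and sheared genomic DNA, not plasmids).
#'
#' @param id Character label for the sequence.
#' @param residues DNA string over IUPAC codes (case-insensitive).
#' @return An object of class `annotated_sequence` with fields `id`,
#'   `residues` and `topology`.
#' @examples
#' s <- annotated_sequence("amp1", "ACGTAGCTAG")
#' nchar(s)
#' @export
annotated_sequence <- function(id, residues) {
  if (!is_string(id)) abort("id must be a single string", "invalid_input")
  residues <- check_dna(residues, sprintf("sequence '%s'", id))
  structure(list(id = id, residues = residues, topology = "linear"),
            class = "annotated_sequence")
}

#' @exportS3Method base::nchar
nchar.annotated_sequence <- function(x, ...) nchar(x$residues)

#' @export
print.annotated_sequence <- function(x, ...) {
  n <- nchar(x$residues)
  head <- if (n > 60) paste0(substr(x$residues, 1, 57), "...") else x$residues
  cat(sprintf("<annotated_sequence> %s (%d bp, %s)\n  %s\n",
              x$id, n, x$topology, head))
  invisible(x)
}

#' @export
as.character.annotated_sequence <- function(x, ...) x$residues

#' Coerce to annotated_sequence, accepting plain strings
#' @noRd
as_annotated_sequence <- function(x, id = "seq") {
  if (inherits(x, "annotated_sequence")) return(x)
  annotated_sequence(id, as.character(x))
}
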