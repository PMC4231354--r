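# End-to-end pipelines chaining the modules, plus the structured-format
# I/O they need (FASTA via Biostrings, pattern libraries as JSON, CSV
# tables). Outputs are byte-reproducible for a fixed config and seed;
# timestamps are confined to the run log.

#' Read sequences from a FASTA file
#'
#' @param path FASTA path (multi-record).
#' @return List of [annotated_sequence].
#' @export
read_fasta_sequences <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  ids <- sub("\\s.*$", "", names(x))
  Map(annotated_sequence, ids, as.character(x))
}

#' Write sequences to a FASTA file
#'
#' @param seqs List of [annotated_sequence].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fasta_sequences <- function(seqs, path) {
  stopifnot(is.list(seqs), all(vapply(seqs, inherits, TRUE, "annotated_sequence")))
  x <- Biostrings::DNAStringSet(vapply(seqs, `[[`, "", "residues"))
  names(x) <- vapply(seqs, `[[`, "", "id")
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}

#' Read a pattern library from JSON
#'
#' JSON layout: `enzymes` (name, recognition_site, cut_offset), `patterns`
#' (label, enzyme_name, expected_sizes), `combinations` (one object per
#' row of the combination map, with a `taxon` field).
#'
#' @param path JSON path.
#' @return A [pattern_library].
#' @export
read_pattern_library <- function(path) {
  cfg <- jsonlite::fromJSON(path, simplifyDataFrame = TRUE)
  need <- c("enzymes", "patterns", "combinations")
  if (!all(need %in% names(cfg)))
    abort(sprintf("pattern library JSON needs fields: %s",
                  paste(need, collapse = ", ")), "invalid_input")
  enzymes <- lapply(seq_len(nrow(cfg$enzymes)), function(i)
    restriction_enzyme(cfg$enzymes$name[i], cfg$enzymes$recognition_site[i],
                       cfg$enzymes$cut_offset[i]))
  patterns <- lapply(seq_len(nrow(cfg$patterns)), function(i)
    gel_pattern(cfg$patterns$label[i], cfg$patterns$enzyme_name[i],
                unlist(cfg$patterns$expected_sizes[i])))
  pattern_library(patterns, as.data.frame(cfg$combinations), enzymes)
}

#' Write a pattern library to JSON
#'
#' @param library A [pattern_library].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_pattern_library <- function(library, path) {
  stopifnot(inherits(library, "pattern_library"))
  cfg <- list(
    enzymes = data.frame(
      name = vapply(library$enzymes, `[[`, "", "name"),
      recognition_site = vapply(library$enzymes, `[[`, "", "recognition_site"),
      cut_offset = vapply(library$enzymes, `[[`, 0L, "cut_offset")),
    patterns = data.frame(
      label = vapply(library$patterns, `[[`, "", "label"),
      enzyme_name = vapply(library$patterns, `[[`, "", "enzyme_name")),
    combinations = library$combination_map)
  cfg$patterns$expected_sizes <- I(lapply(library$patterns, `[[`, "expected_sizes"))
  jsonlite::write_json(cfg, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

validate_config <- function(config, required, optional = character(0)) {
  unknown <- setdiff(names(config), c(required, optional))
  if (length(unknown))
    abort(sprintf("unknown config key(s): %s", paste(unknown, collapse = ", ")),
          "invalid_config")
  missing_keys <- setdiff(required, names(config))
  if (length(missing_keys))
    abort(sprintf("missing config key(s): %s",
                  paste(missing_keys, collapse = ", ")), "invalid_config")
  invisible(config)
}

write_manifest <- function(out_dir, stage, params, outputs) {
  manifest <- list(
    stage = stage,
    package_version = as.character(utils::packageVersion("bifidotyper")),
    parameters = params,
    outputs = outputs)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
}

log_lines <- function(path, lines) {
  con <- file(path, open = "a")
  on.exit(close(con))
  writeLines(sprintf("[%s] %s", format(Sys.time(), "%Y-%m-%d %H:%M:%S"), lines),
             con)
}

#' Run the cheese-survey pipeline
#'
#' Chains enrichment dilution tables through count estimation and grouped
#' summaries, and (optionally) types amplicon sequences by PCR-RFLP.
#' All stage parameters are echoed into a JSON run manifest and a plain
#' text run log; data outputs (CSV) are byte-identical across re-runs of
#' the same config.
#'
#' @param config Named list:
#'   \describe{
#'     \item{dilution_csv}{path to the dilution-series CSV (required)}
#'     \item{out_dir}{output directory (required)}
#'     \item{fasta}{optional FASTA of sequences to type}
#'     \item{library}{optional pattern-library JSON (default: shipped scheme)}
#'     \item{tolerance}{pattern-match tolerance (default 0.10)}
#'     \item{min_band}{gel detection limit in bp (default 0)}
#'     \item{by}{grouping fields for the summary (default group, taxon)}
#'   }
#' @return Invisibly, a list with `summary` (survey_summary), `table`
#'   (formatted rows), `typing` (rflp_typing or NULL) and output paths.
#' @export
run_survey_pipeline <- function(config) {
  validate_config(config, required = c("dilution_csv", "out_dir"),
                  optional = c("fasta", "library", "tolerance", "min_band", "by"))
  if (!file.exists(config$dilution_csv))
    abort(sprintf("input not found: %s", config$dilution_csv), "invalid_config")
  out_dir <- config$out_dir
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  log_path <- file.path(out_dir, "run.log")
  tolerance <- config$tolerance %||% 0.10
  min_band <- config$min_band %||% 0L
  by <- config$by %||% c("group", "taxon")

  log_lines(log_path, sprintf("survey pipeline start: dilution_csv=%s tolerance=%g min_band=%d by=%s",
                              config$dilution_csv, tolerance, as.integer(min_band),
                              paste(by, collapse = ",")))
  series <- read_dilution_csv(config$dilution_csv)
  if (!length(series)) abort("empty dilution input", "invalid_input")
  estimates <- lapply(series, estimate_log_count)
  summaries <- summarize_survey(estimates, by = by)
  tab <- survey_table(summaries)

  counts_path <- file.path(out_dir, "counts.csv")
  summary_path <- file.path(out_dir, "summary.csv")
  table_path <- file.path(out_dir, "summary_table.csv")
  counts <- data.frame(
    sample_id = vapply(estimates, `[[`, "", "sample_id"),
    group = vapply(estimates, `[[`, "", "group"),
    taxon = vapply(estimates, `[[`, "", "taxon"),
    log_count = vapply(estimates, `[[`, 0, "log_count"),
    detected = vapply(estimates, `[[`, TRUE, "detected"),
    stringsAsFactors = FALSE)
  utils::write.csv(counts, counts_path, row.names = FALSE)
  utils::write.csv(as.data.frame(summaries), summary_path, row.names = FALSE)
  utils::write.csv(tab, table_path, row.names = FALSE)
  outputs <- c(counts = counts_path, summary = summary_path, table = table_path)

  typing <- NULL
  if (!is.null(config$fasta)) {
    library <- if (is.null(config$library)) default_pattern_library()
               else read_pattern_library(config$library)
    seqs <- read_fasta_sequences(config$fasta)
    if (anyDuplicated(vapply(seqs, `[[`, "", "id")))
      abort("duplicate sequence ids in FASTA", "invalid_input")
    typing <- rflp_type(seqs, library, rel_tolerance = tolerance,
                        min_band = min_band)
    typing_path <- file.path(out_dir, "typing.csv")
    utils::write.csv(as.data.frame(typing), typing_path, row.names = FALSE)
    jsonlite::write_json(attr(typing, "deviations"),
                         file.path(out_dir, "typing_deviations.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    outputs <- c(outputs, typing = typing_path)
    log_lines(log_path, sprintf("typed %d sequence(s): %d assigned",
                                nrow(typing), sum(typing$taxon_call != "unassigned")))
  }
  write_manifest(out_dir, "survey",
                 list(dilution_csv = config$dilution_csv, tolerance = tolerance,
                      min_band = as.integer(min_band), by = by),
                 as.list(outputs))
  log_lines(log_path, "survey pipeline done")
  invisible(list(summary = summaries, table = tab, typing = typing,
                 outputs = outputs))
}

#' Run the MLSA pipeline
#'
#' Assigns alleles for every strain against an allele database, registers
#' sequence types, concatenates the loci in scheme order, computes the
#' identity-based distance matrix and (for 3+ strains) the
#' neighbor-joining tree.
#'
#' @param config Named list:
#'   \describe{
#'     \item{strains}{named list: strain id -> named list of locus
#'       sequences (required)}
#'     \item{out_dir}{output directory (required)}
#'     \item{allele_dir}{optional directory of per-locus allele FASTAs;
#'       default: empty database (every allele novel)}
#'   }
#' @return Invisibly, a list with `profiles` (data frame), `st_table`,
#'   `distances`, `tree` (phylo or NULL) and output paths.
#' @export
run_mlsa_pipeline <- function(config) {
  validate_config(config, required = c("strains", "out_dir"),
                  optional = "allele_dir")
  strains <- config$strains
  if (!length(strains)) abort("no strains supplied", "invalid_input")
  if (is.null(names(strains)) || anyDuplicated(names(strains)))
    abort("strain ids must be unique and named", "invalid_input")
  out_dir <- config$out_dir
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  log_path <- file.path(out_dir, "run.log")
  db <- if (is.null(config$allele_dir)) allele_db()
        else read_allele_db(config$allele_dir)
  log_lines(log_path, sprintf("mlsa pipeline start: %d strain(s), allele db %s",
                              length(strains),
                              config$allele_dir %||% "<empty>"))

  st_table <- NULL
  rows <- list(); concat <- character(0)
  for (id in names(strains)) {
    prof <- allelic_profile(id, strains[[id]], db)
    # register any novel alleles so subsequent strains see them
    for (locus in names(prof$alleles)) {
      if (prof$novel[[locus]]) {
        db$alleles[[locus]][as.character(prof$alleles[[locus]])] <-
          as_annotated_sequence(strains[[id]][[locus]], locus)$residues
      }
    }
    st <- profile_to_st(prof, st_table, register = TRUE)
    st_table <- st$st_table
    row <- as.data.frame(as.list(prof$alleles))
    row <- cbind(data.frame(strain_id = id, stringsAsFactors = FALSE), row)
    row$st <- st$st
    rows[[id]] <- row
    concat[id] <- concatenate_loci(strains[[id]], id)$residues
  }
  profiles <- do.call(rbind, rows)
  rownames(profiles) <- NULL

  profiles_path <- file.path(out_dir, "profiles.csv")
  utils::write.csv(profiles, profiles_path, row.names = FALSE)
  dm <- distance_matrix(concat)
  dm_path <- file.path(out_dir, "distances.csv")
  utils::write.csv(as.data.frame(dm), dm_path, row.names = TRUE)
  outputs <- c(profiles = profiles_path, distances = dm_path)

  tree <- NULL
  if (length(strains) >= 3) {
    tree <- nj_tree(dm)
    tree_path <- file.path(out_dir, "tree.nwk")
    ape::write.tree(tree, tree_path)
    outputs <- c(outputs, tree = tree_path)
  } else {
    warning("fewer than 3 strains: profiles only, no tree")
    log_lines(log_path, "fewer than 3 strains: tree skipped")
  }
  write_manifest(out_dir, "mlsa",
                 list(n_strains = length(strains),
                      allele_dir = config$allele_dir %||% NA),
                 as.list(outputs))
  log_lines(log_path, "mlsa pipeline done")
  invisible(list(profiles = profiles, st_table = st_table, distances = dm,
                 tree = tree, outputs = outputs))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
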