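# In-silico digestion, amplicon extraction and pattern matching.

alu <- default_enzyme("AluI")
taq <- default_enzyme("TaqI")

test_that("recognition-site scanning finds literal top-strand sites only", {
  expect_identical(find_recognition_sites("TTAGCTTT", alu), 4L)
  expect_identical(find_recognition_sites("AAAAAA", taq), integer(0))
  expect_identical(find_recognition_sites("TCGATCGA", taq), c(1L, 5L))
  # ambiguity codes in the substrate never complete a site
  expect_identical(find_recognition_sites("TTAGNTTT", alu), integer(0))
  expect_identical(find_recognition_sites("TTRGCTTT", alu), integer(0))
  # overlapping occurrences are all reported
  ov <- restriction_enzyme("ovl", "AAAA", 2)
  expect_identical(find_recognition_sites("AAAAAA", ov), c(2L, 3L, 4L))
})

test_that("digestion yields end-to-end fragments that conserve length", {
  expect_identical(digest("TTAGCTTT", alu)$sizes, c(4L, 4L))
  # site-free sequence passes through intact
  free <- generate_sequence_with_pattern(1452, alu, seed = 7)
  expect_identical(digest(free, alu)$sizes, 1452L)
  # a cut flush with the molecule end produces no zero-length fragment
  end_cutter <- restriction_enzyme("end", "ACGT", 0)
  fr <- digest("ACGTAAAA", end_cutter)
  expect_identical(fr$sizes, 8L)
  expect_identical(fr$source_length, 8L)
})

test_that("digestion agrees with a naive quadratic scan oracle on random sequences", {
  set.seed(42)
  for (i in 1:30) {
    s <- paste(sample(c("A", "C", "G", "T"), 200, replace = TRUE), collapse = "")
    for (enz in list(alu, taq)) {
      expect_identical(digest(s, enz)$sizes,
                       as.integer(naive_digest(s, enz$recognition_site,
                                               enz$cut_offset)))
      expect_identical(sum(digest(s, enz)$sizes), 200L)
    }
  }
})

test_that("adding a recognition site never decreases the fragment count", {
  set.seed(11)
  for (i in 1:10) {
    s <- generate_sequence_with_pattern(c(60, 80, 50), taq, seed = 100 + i)
    n0 <- length(digest(s, taq)$sizes)
    # splice a fresh site into the middle of the first fragment
    res <- s$residues
    with_site <- paste0(substr(res, 1, 30), "TCGA",
                        substr(res, 31, nchar(res)))
    n1 <- length(digest(annotated_sequence("x", with_site), taq)$sizes)
    expect_gte(n1, n0)
  }
})

test_that("amplicon extraction honours primer placement and mismatches", {
  f <- "AGTTTGATCCTGGCTCAG"   # CO1
  r <- "TACCTTGTTACGACT"      # CO2
  core <- generate_sequence_with_pattern(300, alu, seed = 3)$residues
  tmpl <- paste0(f, core, revcomp(r))
  amp <- extract_amplicon(tmpl, f, r, max_mismatch = 0)
  expect_identical(amp$residues, tmpl)

  # primers absent -> amplification failure, a classed condition
  expect_error(extract_amplicon(core, f, r), class = "amplification_failure")

  # one mismatch in the forward primer is tolerated at max_mismatch = 1
  f_mut <- mutate_one(f, 5)
  tmpl_mut <- paste0(f_mut, core, revcomp(r))
  expect_error(extract_amplicon(tmpl_mut, f, r, max_mismatch = 0),
               class = "amplification_failure")
  amp1 <- extract_amplicon(tmpl_mut, f, r, max_mismatch = 1)
  expect_identical(amp1$residues, tmpl_mut)

  # flanking junk is trimmed away
  tmpl2 <- paste0("GGGGG", f, core, revcomp(r), "CCCCC")
  expect_identical(extract_amplicon(tmpl2, f, r)$residues,
                   paste0(f, core, revcomp(r)))
})

test_that("gel-observable filtering drops small bands and records a flag", {
  v <- fragment_set(c(5, 95, 152, 206, 285, 311), 1054)
  expect_identical(gel_observable(v, 0)$sizes, v$sizes)
  g <- gel_observable(v, 50)
  expect_identical(g$sizes, c(95L, 152L, 206L, 285L, 311L))
  expect_identical(g$source_length, 1054L)
  expect_match(g$flags, "below 50 bp")
  expect_identical(gel_observable(fragment_set(c(4, 4), 8), 10)$sizes, integer(0))
})

test_that("pattern matching is rank-order pairing under relative tolerance", {
  lib <- default_pattern_library()
  expect_identical(match_pattern(fragment_set(c(120, 210, 250, 470), 1050),
                                 lib, "TaqI")$label, "IX")
  expect_identical(match_pattern(fragment_set(c(132, 200, 664), 996),
                                 lib, "TaqI")$label, "X")
  # band-count mismatch -> unmatched with score 0
  m <- match_pattern(fragment_set(1000, 1000), lib, "TaqI")
  expect_identical(m$label, "unmatched")
  expect_identical(m$score, 0)
  # empty observed set -> unmatched
  empty <- gel_observable(fragment_set(c(4, 4), 8), 10)
  expect_identical(match_pattern(empty, lib, "TaqI")$label, "unmatched")
  # deviations just inside / outside the tolerance envelope
  near <- fragment_set(round(c(120, 210, 250, 470) * 1.09), 1145)
  expect_identical(match_pattern(near, lib, "TaqI", 0.10)$label, "IX")
  far <- fragment_set(round(c(120, 210, 250, 470) * 1.12), 1176)
  expect_identical(match_pattern(far, lib, "TaqI", 0.10)$label, "unmatched")
  # perfect match scores 1
  expect_equal(match_pattern(fragment_set(c(120, 210, 250, 470), 1050),
                             lib, "TaqI")$score, 1)
})

test_that("species calls are exact combination lookups", {
  lib <- default_pattern_library()
  expect_identical(call_species(c(AluI = "V", TaqI = "X"), lib),
                   "Bifidobacterium crudilactis")
  expect_identical(call_species(c(AluI = "V", TaqI = "IX"), lib),
                   "Bifidobacterium mongoliense")
  expect_identical(call_species(c(AluI = "unmatched", TaqI = "IX"), lib),
                   "unassigned")
  expect_identical(call_species(c(AluI = "V", TaqI = "V"), lib), "unassigned")
})

test_that("end-to-end typing of planted dual-pattern sequences is error-free", {
  set.seed(5)
  truth <- rep(c("Bifidobacterium crudilactis", "Bifidobacterium mongoliense"),
               each = 5)
  seqs <- c(
    lapply(1:5, function(i)
      generate_typing_sequence(c(AluI = "V", TaqI = "X"), seed = 600 + i,
                               id = paste0("crud", i))),
    lapply(1:5, function(i)
      generate_typing_sequence(c(AluI = "V", TaqI = "IX"), seed = 700 + i,
                               id = paste0("mong", i))))
  res <- rflp_type(seqs)
  expect_identical(res$taxon_call, truth)
  expect_true(all(res$AluI_score > 0.9 & res$TaqI_score > 0.9))
})

test_that("malformed enzymes and sequences are rejected", {
  expect_error(restriction_enzyme("x", "AGC", 1), class = "invalid_input")
  expect_error(restriction_enzyme("x", "AGCN", 1), class = "invalid_input")
  expect_error(restriction_enzyme("x", "AGCT", 5), class = "invalid_input")
  expect_error(annotated_sequence("x", ""), class = "invalid_input")
  expect_error(annotated_sequence("x", "ACGU"), class = "invalid_input")
})
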