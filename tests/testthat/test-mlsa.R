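# Alignment, allele assignment, sequence types, concatenation and
# neighbor-joining trees.

test_that("global alignment handles matches, indels and rejects empties", {
  al <- align_pair("ACGTACGT", "ACGTACGT")
  expect_identical(al$a_aligned, al$b_aligned)
  expect_false(grepl("-", al$a_aligned, fixed = TRUE))

  al2 <- align_pair("ACGT", "ACT")
  gaps <- sum(strsplit(paste0(al2$a_aligned, al2$b_aligned), "")[[1]] == "-")
  expect_identical(gaps, 1L)
  expect_identical(nchar(al2$a_aligned), 4L)

  expect_error(align_pair("", "ACGT"), class = "invalid_input")
})

test_that("percent identity counts gap columns in the denominator", {
  expect_equal(pairwise_identity("ACGT", "ACGT"), 100)
  # one substitution in 1000
  s <- generate_sequence_with_pattern(1000, default_enzyme("AluI"), seed = 4)$residues
  expect_equal(pairwise_identity(s, mutate_one(s, 500)), 99.9)
  # one substitution in a 600-mer locus: (L-1)/L
  set.seed(9)
  l600 <- random_dna_600 <- paste(sample(c("A","C","G","T"), 600, TRUE), collapse = "")
  expect_equal(pairwise_identity(l600, mutate_one(l600, 42)), 100 * 599 / 600)
  # symmetry
  a <- "ACGTACGTAA"; b <- "ACGTTCGTAA"
  expect_equal(pairwise_identity(a, b), pairwise_identity(b, a))
  # an indel lowers identity below 100
  expect_lt(pairwise_identity("ACGTACGT", "ACGTCGT"), 100)
})

test_that("allele assignment: exact hit, novel numbering, quality gate", {
  set.seed(14)
  gyrB46 <- paste(sample(c("A","C","G","T"), 600, TRUE), collapse = "")
  db <- allele_db(list(gyrB = c("46" = gyrB46)))
  hit <- assign_allele(gyrB46, "gyrB", db)
  expect_identical(hit$allele, 46L)
  expect_equal(hit$identity, 100)
  expect_false(hit$is_novel)

  nov <- assign_allele(mutate_one(gyrB46, 10), "gyrB", db)
  expect_identical(nov$allele, 47L)
  expect_true(nov$is_novel)
  expect_equal(nov$identity, 100 * 599 / 600)
  expect_identical(nov$nearest, 46L)

  # bootstrap: empty locus seeds allele 1
  boot <- assign_allele(paste(rep("ACGT", 150), collapse = ""), "fusA",
                        allele_db())
  expect_identical(boot$allele, 1L)
  expect_true(boot$is_novel)

  # length deviating >10% from the template is a quality failure
  expect_error(assign_allele(substr(gyrB46, 1, 500), "gyrB", db),
               class = "quality_failure")
  expect_error(assign_allele(gyrB46, "noSuchLocus", db), class = "invalid_input")
})

test_that("sequence types are a bijection on seven-allele tuples", {
  set.seed(15)
  seqs <- lapply(MLSA_LOCI, function(L)
    paste(sample(c("A","C","G","T"), L, TRUE), collapse = ""))
  db <- allele_db()
  p1 <- allelic_profile("FR41/2-like", seqs, db)
  expect_identical(unname(p1$alleles), rep(1L, 7))

  st1 <- profile_to_st(p1, NULL, register = TRUE)
  expect_identical(st1$st, 1L)
  # an identical profile maps to the same ST
  p2 <- allelic_profile("FR49/f/2-like", seqs, db)
  expect_identical(profile_to_st(p2, st1$st_table)$st, 1L)
  # differing at a single locus yields a different ST
  p3 <- p1; p3$alleles["purF"] <- 2L
  st3 <- profile_to_st(p3, st1$st_table, register = TRUE)
  expect_identical(st3$st, 2L)
  # unseen tuple against an empty table is novel
  expect_identical(profile_to_st(p1, NULL)$st, "novel")

  incomplete <- p1; incomplete$alleles <- p1$alleles[-1]
  expect_error(profile_to_st(incomplete), class = "incomplete_profile")
})

test_that("concatenation is fixed-order, additive, input-order invariant", {
  set.seed(16)
  seqs <- lapply(MLSA_LOCI, function(L)
    paste(sample(c("A","C","G","T"), L, TRUE), collapse = ""))
  cc <- concatenate_loci(seqs, "s1")
  expect_identical(nchar(cc), sum(MLSA_LOCI))
  expect_identical(nchar(cc), 3831L)
  # scheme order regardless of how the input list is ordered
  shuffled <- seqs[rev(names(seqs))]
  expect_identical(concatenate_loci(shuffled, "s1")$residues, cc$residues)
  expect_identical(substr(cc$residues, 1, 501), seqs$clpC)
  expect_error(concatenate_loci(seqs[-3], "s1"), class = "incomplete_profile")
})

test_that("NJ reproduces three-point branch lengths and rejects bad input", {
  d <- matrix(c(0, .2, .3, .2, 0, .4, .3, .4, 0), 3, 3,
              dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  tr <- nj_tree(d)
  lens <- setNames(tr$edge.length, tr$tip.label[tr$edge[, 2]])
  expect_equal(lens[c("A", "B", "C")], c(A = 0.05, B = 0.15, C = 0.25))

  bad <- d; bad[1, 2] <- 99
  expect_error(nj_tree(bad), class = "invalid_input")
  expect_error(nj_tree(d[1:2, 1:2]), class = "invalid_input")

  # identical strains: zero distances, zero-length branches
  z <- matrix(0, 3, 3, dimnames = dimnames(d))
  expect_true(all(nj_tree(z)$edge.length == 0))
})

test_that("NJ recovers the generating topology of additive matrices", {
  set.seed(17)
  for (i in 1:5) {
    gen <- random_additive_matrix(5)
    tr <- nj_tree(gen$dm[gen$tree$tip.label, gen$tree$tip.label])
    expect_equal(as.numeric(ape::dist.topo(ape::unroot(tr),
                                           ape::unroot(gen$tree))), 0)
    # branch lengths are recovered too: cophenetic distances match input
    expect_equal(ape::cophenetic.phylo(tr)[rownames(gen$dm), colnames(gen$dm)],
                 gen$dm, tolerance = 1e-8)
  }
})

test_that("identity distances between concatenates separate planted clades", {
  # two clades at depth, strains evolved along a known tree
  tree <- ape::read.tree(text = "((s1:0.01,s2:0.01):0.2,(s3:0.01,s4:0.01):0.2);")
  ev <- evolve_alleles(tree, sub_rate = 0.05, seed = 20)
  cc <- vapply(names(ev$strains), function(id)
    concatenate_loci(ev$strains[[id]], id)$residues, "")
  dm <- distance_matrix(cc)
  within <- c(dm["s1", "s2"], dm["s3", "s4"])
  across <- c(dm["s1", "s3"], dm["s1", "s4"], dm["s2", "s3"], dm["s2", "s4"])
  expect_lt(max(within), min(across))
})
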