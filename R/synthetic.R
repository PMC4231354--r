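# Synthetic-data generators. Every analysis stage gets inputs with known
# ground truth: sequences with planted digestion patterns, enrichment
# surveys with planted prevalence and counts, renaturation kinetics with
# planted relatedness, allele sets evolved along a known tree, and binary
# phenotype panels with planted cluster structure. All generators are
# deterministic for a fixed seed.

with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
      get(".Random.seed", globalenv()) else NULL
    on.exit({
      if (is.null(old)) rm(".Random.seed", envir = globalenv())
      else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(as.integer(seed))
  }
  expr
}

#' Generate a sequence whose digest yields given fragment sizes
#'
#' Builds a linear sequence that digests with `enzyme` into exactly
#' `sort(target_sizes)`. Each internal junction carries one recognition
#' site straddling the cut; the filler between junctions is random DNA in
#' which accidental recognition sites are removed by mutating one site
#' base at a time (rejection/repair), and the finished sequence is
#' verified by a round-trip digest.
#'
#' Fragments must accommodate the fixed site halves at their junction(s):
#' every interior fragment must be at least the site length; the terminal
#' fragments need only cover their single site half, which is how the
#' 5-bp band of the AluI typing pattern is representable. At most one
#' target may be shorter than the site length.
#'
#' @param target_sizes Positive integer fragment sizes.
#' @param enzyme A [restriction_enzyme].
#' @param seed Integer seed (`NULL` to use the current RNG stream).
#' @param id Sequence id.
#' @param max_tries Attempts before giving up (construction is rejected
#'   and retried if repair cannot silence accidental sites).
#' @return An [annotated_sequence] such that
#'   `digest(out, enzyme)$sizes == sort(target_sizes)`.
#' @examples
#' s <- generate_sequence_with_pattern(c(120, 210, 250, 470),
#'                                     default_enzyme("TaqI"), seed = 1)
#' digest(s, default_enzyme("TaqI"))
#' @export
generate_sequence_with_pattern <- function(target_sizes, enzyme, seed = NULL,
                                           id = "synthetic", max_tries = 100L) {
  target_sizes <- as.integer(target_sizes)
  if (!length(target_sizes) || any(is.na(target_sizes)) || any(target_sizes < 1L))
    abort("target sizes must be positive integers", "invalid_input")
  site <- enzyme$recognition_site
  k <- nchar(site)
  co <- enzyme$cut_offset
  m <- length(target_sizes)
  sizes <- sort(target_sizes)
  if (m > 1L) {
    small <- sizes[sizes < k]
    if (length(small) > 1L)
      abort("at most one target may be smaller than the site length",
            "infeasible_sizes")
    # terminal fragments only need to cover one half of a straddling site
    if (length(small) == 1L && small[1] < min(co, k - co))
      abort(sprintf("target %d bp cannot host a site half (need >= %d)",
                    small[1], min(co, k - co)), "infeasible_sizes")
    # place a small fragment at whichever end its site half fits
    order_sizes <- sizes
    if (length(small) == 1L) {
      rest <- sizes[-match(small, sizes)]
      order_sizes <- if (small >= co) c(small, rest) else c(rest, small)
    }
    sizes <- order_sizes
  }
  left_half <- substr(site, 1, co)          # suffix of fragment before a cut
  right_half <- substr(site, co + 1, k)     # prefix of fragment after a cut

  scrub_sites <- function(chars) {
    # mutate one base inside each accidental site until none remain
    repeat {
      s <- paste(chars, collapse = "")
      hits <- find_recognition_sites(annotated_sequence("f", s), enzyme)
      if (!length(hits)) return(chars)
      start <- hits[1] - co + 1L            # 1-based site start
      pos <- start + sample.int(k, 1) - 1L
      chars[pos] <- sample(setdiff(c("A", "C", "G", "T"), chars[pos]), 1)
    }
  }

  with_seed(seed, {
    for (try in seq_len(max_tries)) {
      frags <- character(m)
      for (i in seq_len(m)) {
        pre <- if (i > 1L) right_half else ""
        suf <- if (i < m) left_half else ""
        free <- sizes[i] - nchar(pre) - nchar(suf)
        if (free < 0)
          abort(sprintf("target %d bp too small for its junction context",
                        sizes[i]), "infeasible_sizes")
        mid <- if (free > 0) {
          chars <- sample(c("A", "C", "G", "T"), free, replace = TRUE)
          # scrub within the fragment including its fixed flanks
          full <- c(strsplit(pre, "")[[1]], chars, strsplit(suf, "")[[1]])
          n_pre <- nchar(pre); n_suf <- nchar(suf)
          full <- scrub_sites(full)
          # fixed flanks must survive scrubbing; if not, reject this draw
          if (paste(full[seq_len(n_pre)], collapse = "") != pre ||
              (n_suf > 0 && paste(full[(length(full) - n_suf + 1):length(full)],
                                  collapse = "") != suf)) next
          paste(full[(n_pre + 1):(length(full) - n_suf)], collapse = "")
        } else ""
        frags[i] <- paste0(pre, mid, suf)
      }
      if (any(!nzchar(frags) & sizes > 0L)) next
      out <- annotated_sequence(id, paste(frags, collapse = ""))
      got <- digest(out, enzyme)$sizes
      if (identical(got, sort(target_sizes))) return(out)
    }
    abort("could not construct a sequence for the requested sizes",
          "infeasible_sizes")
  })
}

#' Generate a sequence carrying the typing patterns of several enzymes
#'
#' Builds one amplicon-like sequence whose digest with each enzyme of a
#' typing scheme approximates a chosen pattern label. The printed band
#' sizes of different enzymes sum to different totals (they are gel
#' estimates), so no sequence can reproduce all of them exactly; instead
#' each pattern's cut positions are scaled to a common compromise length.
#' The per-band deviation this introduces (about 3% for the shipped
#' scheme) sits well inside the default 10% matching tolerance, and the
#' construction is verified by digesting and matching before returning.
#'
#' @param labels Named character vector enzyme -> pattern label, e.g.
#'   `c(AluI = "V", TaqI = "X")`.
#' @param library A [pattern_library] containing those patterns.
#' @param rel_tolerance Tolerance the result must satisfy under
#'   [match_pattern()].
#' @param seed Integer seed (`NULL` to use the current RNG stream).
#' @param id Sequence id.
#' @param max_tries Construction attempts before giving up.
#' @return An [annotated_sequence] that types as `labels` (and therefore
#'   as the taxon their combination maps to).
#' @examples
#' s <- generate_typing_sequence(c(AluI = "V", TaqI = "X"), seed = 1)
#' rflp_type(list(s))$taxon_call
#' @export
generate_typing_sequence <- function(labels, library = default_pattern_library(),
                                     rel_tolerance = 0.10, seed = NULL,
                                     id = "synthetic", max_tries = 50L) {
  stopifnot(inherits(library, "pattern_library"))
  pat <- list()
  for (e in names(labels)) {
    hit <- Filter(function(p) p$enzyme_name == e && p$label == labels[[e]],
                  library$patterns)
    if (!length(hit))
      abort(sprintf("no pattern %s for enzyme %s", labels[[e]], e),
            "invalid_input")
    pat[[e]] <- hit[[1]]$expected_sizes
  }
  totals <- vapply(pat, sum, 0)
  L <- round(mean(totals))
  enzymes <- library$enzymes[names(labels)]
  bases <- c("A", "C", "G", "T")

  with_seed(seed, {
    for (try in seq_len(max_tries)) {
      # designed cut positions per enzyme, scaled to the common length
      cuts <- lapply(names(labels), function(e) {
        s <- pat[[e]]
        round(cumsum(s[-length(s)]) / totals[[e]] * L)
      })
      names(cuts) <- names(labels)
      # site footprints; nudge later footprints right until all disjoint
      foot <- list()
      occupied <- integer(0)
      ok <- TRUE
      for (e in names(labels)) {
        enz <- enzymes[[e]]
        k <- nchar(enz$recognition_site)
        for (j in seq_along(cuts[[e]])) {
          p <- cuts[[e]][j]
          span <- function(p) (p - enz$cut_offset + 1L):(p - enz$cut_offset + k)
          shift <- 0L
          while (any(span(p + shift) %in% occupied) && shift < 20L)
            shift <- shift + 1L
          p <- p + shift
          if (any(span(p) %in% occupied) || min(span(p)) < 1L ||
              max(span(p)) > L) { ok <- FALSE; break }
          cuts[[e]][j] <- p
          occupied <- c(occupied, span(p))
          foot[[length(foot) + 1L]] <- list(enzyme = e, start = min(span(p)))
        }
        if (!ok) break
      }
      if (!ok) next
      chars <- sample(bases, L, replace = TRUE)
      for (f in foot) {
        site <- enzymes[[f$enzyme]]$recognition_site
        chars[f$start:(f$start + nchar(site) - 1L)] <-
          strsplit(site, "")[[1]]
      }
      # scrub accidental sites, never touching a designed footprint
      clean <- TRUE
      for (rep_i in seq_len(200L)) {
        s <- paste(chars, collapse = "")
        accidental <- NULL
        for (e in names(labels)) {
          enz <- enzymes[[e]]
          got <- find_recognition_sites(annotated_sequence(id, s), enz)
          extra <- setdiff(got, cuts[[e]])
          if (length(extra)) {
            accidental <- list(enzyme = e, cut = extra[1]); break
          }
        }
        if (is.null(accidental)) break
        enz <- enzymes[[accidental$enzyme]]
        k <- nchar(enz$recognition_site)
        pos <- (accidental$cut - enz$cut_offset + 1L):
               (accidental$cut - enz$cut_offset + k)
        pos <- setdiff(pos, occupied)
        if (!length(pos)) { clean <- FALSE; break }
        p <- sample(pos, 1)
        chars[p] <- sample(setdiff(bases, chars[p]), 1)
        if (rep_i == 200L) clean <- FALSE
      }
      if (!clean) next
      out <- annotated_sequence(id, paste(chars, collapse = ""))
      good <- TRUE
      for (e in names(labels)) {
        m <- match_pattern(digest(out, enzymes[[e]]), library, e, rel_tolerance)
        if (m$label != labels[[e]]) { good <- FALSE; break }
      }
      if (good) return(out)
    }
    abort("could not construct a dual-pattern sequence", "infeasible_sizes")
  })
}

#' Simulate an enrichment dilution-series survey
#'
#' Per group, each sample is positive with the group's prevalence;
#' positive samples draw a true log10 count by `count_sampler` (default:
#' a normal draw rounded and clamped to the dilution range, emulating the
#' spread of counts seen across cheese production steps), and tubes are
#' positive for every dilution exponent `d <=` true count. One tube per
#' dilution, exponents 0..6, matching the survey design.
#'
#' @param prevalence Named numeric vector: group -> detection probability.
#'   The default groups A-D are the four production steps (raw milk,
#'   after rennet, after mold removal, ripening).
#' @param n Samples per group (default 44, the survey's per-step size).
#' @param taxon Taxon label written to every series.
#' @param count_sampler Function `(n)` returning `n` true log counts for
#'   positive samples; default `round(rnorm(n, 3, 1.5))` clamped to
#'   `0..max_exponent`.
#' @param max_exponent Deepest dilution exponent (default 6).
#' @param seed Integer seed (`NULL` to use the current RNG stream).
#' @return A list of [dilution_series] with attribute `truth` (data frame
#'   of per-sample planted detection and counts).
#' @export
simulate_survey <- function(prevalence = c(A = 0.82, B = 0.77, C = 0.09, D = 0.77),
                            n = 44L, taxon = "Bifidobacterium crudilactis",
                            count_sampler = NULL, max_exponent = 6L,
                            seed = NULL) {
  if (any(prevalence < 0 | prevalence > 1))
    abort("prevalences must lie in [0, 1]", "invalid_input")
  if (is.null(count_sampler))
    count_sampler <- function(k) pmin(pmax(round(stats::rnorm(k, 3, 1.5)), 0L),
                                      max_exponent)
  with_seed(seed, {
    series <- list(); truth <- list()
    for (g in names(prevalence)) {
      pos <- stats::runif(n) < prevalence[[g]]
      counts <- integer(n)
      counts[pos] <- as.integer(count_sampler(sum(pos)))
      for (i in seq_len(n)) {
        exps <- 0:max_exponent
        tube_pos <- pos[i] & exps <= counts[i]
        series[[length(series) + 1L]] <-
          dilution_series(sprintf("%s_%02d", g, i), g, taxon, exps, tube_pos,
                          max_exponent)
      }
      truth[[g]] <- data.frame(sample_id = sprintf("%s_%02d", g, seq_len(n)),
                               group = g, positive = pos, true_log = counts,
                               stringsAsFactors = FALSE)
    }
    attr(series, "truth") <- do.call(rbind, truth)
    series
  })
}

#' Simulate renaturation kinetics with a planted relatedness
#'
#' Produces three absorbance series (organism A, organism B, equal mix)
#' whose underlying linear decline rates satisfy the De Ley relation at
#' the requested relatedness: `Vm = (p/100 * 2*sqrt(Va*Vb) + Va + Vb) / 4`.
#' Gaussian noise of standard deviation `noise_sd` (absorbance units) is
#' added independently per recorded point, so in the noise-free limit the
#' estimated percentage equals `true_percent` exactly.
#'
#' @param true_percent Planted relatedness percentage.
#' @param Va,Vb Renaturation rates for the two single-organism cuvettes
#'   (absorbance units per minute). Defaults give a realistic ~25%
#'   absorbance decline over a 24-min recording from `a0 = 1`.
#' @param noise_sd Per-point Gaussian noise SD in absorbance units
#'   (default 0.01, i.e. 1% of the initial absorbance).
#' @param a0 Initial absorbance.
#' @param times Recording times in minutes.
#' @param seed Integer seed (`NULL` to use the current RNG stream).
#' @return A list with elements `A`, `B`, `mix` ([absorbance_series]) and
#'   `truth` (the planted rates and percentage).
#' @export
simulate_renaturation <- function(true_percent, Va = 0.012, Vb = 0.010,
                                  noise_sd = 0.01, a0 = 1.0, times = 0:24,
                                  seed = NULL) {
  if (Va <= 0 || Vb <= 0) abort("Va and Vb must be positive", "invalid_input")
  Vm <- (true_percent / 100 * 2 * sqrt(Va * Vb) + Va + Vb) / 4
  if (Vm <= 0)
    abort("planted relatedness implies a non-positive mixture rate",
          "invalid_input")
  with_seed(seed, {
    mk <- function(v, label)
      absorbance_series(times,
                        a0 - v * times + stats::rnorm(length(times), 0, noise_sd),
                        label)
    list(A = mk(Va, "A"), B = mk(Vb, "B"), mix = mk(Vm, "mix"),
         truth = list(Va = Va, Vb = Vb, Vm = Vm, percent = true_percent))
  })
}

#' Simulate a sigmoidal DNA melting curve
#'
#' Logistic hyperchromic rise centred at the planted Tm, for exercising
#' [tm_from_curve()] and [gc_from_tm()].
#'
#' @param tm Planted melting midpoint in degrees C.
#' @param temperature Temperature grid.
#' @param rise Total absorbance rise (hyperchromicity).
#' @param width Logistic scale parameter in degrees C.
#' @param noise_sd Per-point Gaussian noise SD.
#' @param seed Integer seed.
#' @return A [melting_curve].
#' @export
simulate_melting_curve <- function(tm, temperature = seq(60, 110, by = 0.25),
                                   rise = 0.35, width = 1.5, noise_sd = 0,
                                   seed = NULL) {
  with_seed(seed, {
    a <- 1 + rise / (1 + exp(-(temperature - tm) / width)) +
      stats::rnorm(length(temperature), 0, noise_sd)
    melting_curve(temperature, a)
  })
}

#' Evolve MLSA allele sets along a known tree
#'
#' Starting from ancestor sequences (random at the template sizes unless
#' supplied), applies Poisson(rate x branch length x locus length) point
#' substitutions along every branch of `tree`, independently per locus.
#' Tip sequences and the generating tree are returned so tree-recovery
#' and allele/ST consistency can be checked against planted truth.
#'
#' @param tree An \pkg{ape} `phylo` with branch lengths; tip labels name
#'   the strains.
#' @param sub_rate Expected substitutions per site per unit branch length.
#' @param loci Named integer vector of locus template sizes.
#' @param ancestor Optional named list of ancestor sequences per locus.
#' @param seed Integer seed.
#' @return A list: `strains` (named list of per-locus sequence lists),
#'   `tree` (the generating tree), `ancestor`.
#' @export
evolve_alleles <- function(tree, sub_rate = 0.02, loci = MLSA_LOCI,
                           ancestor = NULL, seed = NULL) {
  stopifnot(inherits(tree, "phylo"))
  if (is.null(tree$edge.length))
    abort("tree must have branch lengths", "invalid_input")
  if (sub_rate < 0) abort("sub_rate must be >= 0", "invalid_input")
  with_seed(seed, {
    if (is.null(ancestor))
      ancestor <- lapply(loci, function(L) random_dna(L))
    mutate <- function(seq, n_sub) {
      if (n_sub == 0L) return(seq)
      chars <- strsplit(seq, "", fixed = TRUE)[[1]]
      pos <- sample.int(length(chars), min(n_sub, length(chars)))
      for (p in pos)
        chars[p] <- sample(setdiff(c("A", "C", "G", "T"), chars[p]), 1)
      paste(chars, collapse = "")
    }
    ntip <- length(tree$tip.label)
    root <- ntip + 1L
    node_seqs <- vector("list", ntip + tree$Nnode)
    node_seqs[[root]] <- ancestor
    # preorder traversal so parents are materialised before children
    edges <- ape::reorder.phylo(tree, "cladewise")$edge
    edge_len <- ape::reorder.phylo(tree, "cladewise")$edge.length
    for (k in seq_len(nrow(edges))) {
      parent <- edges[k, 1]; child <- edges[k, 2]
      ps <- node_seqs[[parent]]
      cs <- ps
      for (locus in names(loci)) {
        n_sub <- stats::rpois(1, sub_rate * edge_len[k] * loci[[locus]])
        cs[[locus]] <- mutate(ps[[locus]], n_sub)
      }
      node_seqs[[child]] <- cs
    }
    strains <- stats::setNames(node_seqs[seq_len(ntip)], tree$tip.label)
    list(strains = strains, tree = tree, ancestor = ancestor)
  })
}

#' Simulate binary phenotype panels with planted clusters
#'
#' Each cluster has an archetype of Bernoulli(0.5) test outcomes; member
#' strains flip each outcome independently with probability `flip_prob`.
#'
#' @param clusters Named integer vector: cluster -> number of strains.
#' @param n_tests Number of binary tests (default 79, the size of a
#'   combined carbohydrate + enzymatic panel).
#' @param flip_prob Per-test within-cluster flip probability.
#' @param seed Integer seed.
#' @return List of [phenotype_panel] with attribute `truth` (named
#'   cluster membership).
#' @export
simulate_phenotype_panels <- function(clusters = c(crudilactis = 5, mongoliense = 5),
                                      n_tests = 79L, flip_prob = 0.05,
                                      seed = NULL) {
  with_seed(seed, {
    tests <- paste0("test", seq_len(n_tests))
    panels <- list(); truth <- character(0)
    for (cl in names(clusters)) {
      archetype <- stats::runif(n_tests) < 0.5
      for (i in seq_len(clusters[[cl]])) {
        flips <- stats::runif(n_tests) < flip_prob
        id <- sprintf("%s_%d", cl, i)
        panels[[length(panels) + 1L]] <-
          phenotype_panel(id, stats::setNames(xor(archetype, flips), tests))
        truth[id] <- cl
      }
    }
    attr(panels, "truth") <- truth
    panels
  })
}
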