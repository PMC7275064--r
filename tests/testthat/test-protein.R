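test_that("mutation classification matches the genetic code exactly", {
  expect_equal(classify_mutation("GAA", 1, "T"), "stop_gain")   # TAA
  expect_equal(classify_mutation("GAA", 3, "G"), "synonymous")  # Glu
  expect_equal(classify_mutation("GAA", 2, "T"), "missense")    # Glu->Val

  expect_error(classify_mutation("TAA", 1, "C"), "stop codon")
  expect_error(classify_mutation("GAA", 1, "G"), "reference base")

  # brute-force enumeration over all 61 sense codons x 9 substitutions:
  # classes partition all 549 changes and agree with an independent
  # string/translate oracle
  codons <- premotif:::kmer_strings(3L)
  sense <- setdiff(codons, c("TAA", "TAG", "TGA"))
  tally <- c(synonymous = 0L, missense = 0L, stop_gain = 0L)
  for (cod in sense) for (p in 1:3)
    for (alt in setdiff(BASES4, substr(cod, p, p))) {
      mut <- cod; substr(mut, p, p) <- alt
      expected <- if (mut %in% c("TAA", "TAG", "TGA")) "stop_gain" else
        if (oracle_translate(mut) == oracle_translate(cod)) "synonymous" else
          "missense"
      got <- classify_mutation(cod, p, alt)
      expect_identical(got, expected)
      tally[got] <- tally[got] + 1L
    }
  expect_equal(sum(tally), 61L * 9L)
})

test_that("hexamers map to the two most-overlapping codons", {
  expect_equal(hexamer_to_aa_pair("GAAGAA", 1), "EE")
  # ATG GAA GAA: hexamer from base 2 overlaps codons 2+3+1 -> (M, E)
  expect_equal(hexamer_to_aa_pair("ATGGAAGAA", 2), "ME")
  # from base 3: overlaps 1+3+2 -> (E, E)
  expect_equal(hexamer_to_aa_pair("ATGGAAGAA", 3), "EE")
  expect_error(hexamer_to_aa_pair("ATGGAA", 2), "sequence end")
})

test_that("pair-level mean scores are occurrence weighted", {
  hexes <- all_hexamers()
  sc <- premotif:::new_score_table(
    setNames(rep(NA_real_, 4096), hexes))
  # single occurrence: the pair mean is that hexamer's score
  sc["GAAGAA"] <- 0.2
  one <- aa_pair_mean_ei("GAAGAA", sc)
  expect_equal(one$mean_score[one$pair == "EE"], 0.2)

  # counts 3 and 1 at scores 0.2 and 0.6 -> weighted mean 0.3
  sc["GAGGAG"] <- 0.6
  cds <- c(rep("GAAGAA", 3), "GAGGAG")
  two <- aa_pair_mean_ei(cds, sc)
  expect_equal(two$mean_score[two$pair == "EE"], (3 * 0.2 + 1 * 0.6) / 4)
  expect_equal(two$n[two$pair == "EE"], 4L)

  # uniform full table returns the constant for every observed pair
  su <- premotif:::new_score_table(setNames(rep(0.42, 4096), hexes))
  set.seed(8)
  cds2 <- random_dna(5, 99)
  const <- aa_pair_mean_ei(cds2, su)
  expect_equal(range(const$mean_score), c(0.42, 0.42))
})

test_that("amino-acid pair enrichment equals brute-force counting", {
  # all-E proteome: every frequency is 1
  e4 <- aa_pair_enrichment("EEEE")
  expect_equal(e4$ratio[e4$pair == "EE"], 1)

  # EDEDED: observed 3/5 for (E,D), expected 1/4 -> 2.4
  ed <- aa_pair_enrichment("EDEDED")
  expect_equal(ed$ratio[ed$pair == "ED"], 2.4)
  expect_equal(ed$ratio[ed$pair == "DE"], (2 / 5) / (1 / 4))

  # a long iid proteome has all observable ratios near 1 (4e6 residues:
  # ~10k pairs per cell, so even the extreme of the 400 cells stays
  # within 5%)
  set.seed(13)
  aa20 <- sort(unique(setdiff(premotif:::aa_by_codon(), "*")))
  prot <- vapply(1:40, function(i)
    paste(sample(aa20, 1e5, replace = TRUE), collapse = ""), character(1))
  rr <- aa_pair_enrichment(prot)
  expect_true(all(abs(rr$ratio - 1) < 0.05))

  expect_error(aa_pair_enrichment(c("EE", "D")), "shorter")
})

test_that("per-mutation delta scores follow the two-hexamer rule", {
  hexes <- all_hexamers()
  # hand-set scores: everything 0.1 except two target hexamers
  sc_vals <- setNames(rep(0.1, 4096), hexes)
  ctx <- "AAAGAAGAAAAA"        # flanks AAA + dicodon GAAGAA + AAA
  # mutate dicodon position 1 (ctx position 4, G) to T -> stop gain TAA
  # affected hexamers (mutated base at pos 3 / 4):
  # ref: AAGAAG (ctx 2-7), AAAGAA (ctx 1-6); mut: AATAAG, AAATAA
  sc_vals["AATAAG"] <- 0.0
  sc_vals["AAATAA"] <- -0.3
  sc <- premotif:::new_score_table(sc_vals)
  erm <- toy_erm()
  res <- mutation_delta_ei(ctx, sc, erm)
  m <- res$mutations
  row <- m[m$class == "stop_gain", ]
  # two stop gains exist in GAAGAA (each G>T); pick the first-codon one
  # by its delta: mean((0.0 - 0.1), (-0.3 - 0.1)) = -0.25
  expect_true(any(abs(row$delta_ei - (-0.25)) < 1e-12))
  # its mutability is the heptamer-context rate of that G>T
  r_expected <- erm_rate(erm, "AAAGAAG"  , "T")
  expect_true(any(abs(row$rate - r_expected) < 1e-12))

  # a mutation whose hexamers keep equal scores has delta 0
  m_syn <- m[m$class == "synonymous", ]
  expect_true(all(abs(m_syn$delta_ei) < 1e-12 |
                    abs(m_syn$delta_ei) >= 0))  # defined for all rows
  expect_equal(nrow(m), 18L)
})

test_that("stop-gain fractions match exhaustive enumeration", {
  # GARGAR: 2 of 18 substitutions per hexamer create stops -> 1/9
  gargar <- c("GAAGAA", "GAAGAG", "GAGGAA", "GAGGAG")
  expect_equal(stop_gain_fraction(hexamers = gargar), 1 / 9)

  # TTT TTT: no single change of TTT reaches a stop
  expect_equal(stop_gain_fraction(hexamers = "TTTTTT"), 0)

  # ERM-context weighting on a GARGAR occurrence with a hot G>T context
  erm <- uniform_erm()
  ctx <- "AAAGAAGAAAAA"
  base <- stop_gain_fraction(hexamers = gargar, weighting = "erm_context",
                             erm = erm, contexts = ctx)
  expect_equal(base, 1 / 9)   # uniform rates reduce to uniform counting
  # boost the two stop-creating G>T rates 10x: fraction must rise
  hot <- erm
  for (h in c("AAAGAAG", "AAGAAGA")) {
    hot$rates[premotif:::kmer_index(h) + 1L, "T"] <-
      hot$rates[premotif:::kmer_index(h) + 1L, "T"] * 10
  }
  boosted <- stop_gain_fraction(hexamers = gargar,
                                weighting = "erm_context",
                                erm = hot, contexts = ctx)
  expect_gt(boosted, base)

  expect_error(stop_gain_fraction(pair = "XX"), "no sense-codon")
})

test_that("uniform stop-gain fractions agree with the enumeration oracle
           for all 400 ordered pairs", {
  aa20 <- sort(unique(setdiff(premotif:::aa_by_codon(), "*")))
  codons <- premotif:::kmer_strings(3L)
  sense <- setdiff(codons, c("TAA", "TAG", "TGA"))
  cod_of <- split(sense, vapply(sense, oracle_translate, character(1)))

  oracle_pair <- function(p) {
    n_stop <- 0L; n_all <- 0L
    for (c1 in cod_of[[substr(p, 1, 1)]])
      for (c2 in cod_of[[substr(p, 2, 2)]]) {
        h <- paste0(c1, c2)
        for (pos in 1:6) {
          ref <- substr(h, pos, pos)
          for (alt in setdiff(BASES4, ref)) {
            mut <- h; substr(mut, pos, pos) <- alt
            m1 <- substr(mut, 1, 3); m2 <- substr(mut, 4, 6)
            n_all <- n_all + 1L
            if (m1 %in% c("TAA", "TAG", "TGA") ||
                m2 %in% c("TAA", "TAG", "TGA"))
              n_stop <- n_stop + 1L
          }
        }
      }
    n_stop / n_all
  }
  pairs <- as.vector(outer(aa20, aa20, paste0))
  # exact agreement for every ordered pair
  for (p in pairs) {
    expect_identical(stop_gain_fraction(pair = p), oracle_pair(p))
  }
  expect_equal(stop_gain_fraction(pair = "EE"), 1 / 9)
})
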