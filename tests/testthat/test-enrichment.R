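make_toy_gene <- function() {
  # one + strand gene: intron(40) exon(30) intron(40) exon(30) intron(40)
  set.seed(77)
  s <- paste(sample(BASES4, 180, replace = TRUE), collapse = "")
  models <- data.frame(
    transcript = "t1", seqname = "g1",
    start = c(40L, 110L), end = c(70L, 140L), strand = "+", rank = 1:2)
  list(seqs = Biostrings::DNAStringSet(c(g1 = s)), models = models, raw = s)
}

test_that("splice windows are oriented, truncated when short, and
           deduplicated across isoforms", {
  toy <- make_toy_gene()
  win <- splice_windows(toy$models, toy$seqs, intron_span = 50,
                        exon_span = 20)
  # one internal intron: donor of exon 1 and acceptor of exon 2
  expect_equal(sort(win$side), c("acceptor", "donor"))
  expect_equal(nrow(win), 2L)
  # intron span truncated to the 40 nt available
  expect_true(all(win$intron_len == 40))
  expect_true(all(win$truncated))

  # a duplicate isoform does not add windows
  models2 <- rbind(toy$models,
                   transform(toy$models, transcript = "t1b"))
  win2 <- splice_windows(models2, toy$seqs, intron_span = 50,
                         exon_span = 20)
  expect_equal(nrow(win2), nrow(win))
})

test_that("positional profiles equal direct per-position lookups", {
  toy <- make_toy_gene()
  u <- uniform_erm(1.5)
  win <- splice_windows(toy$models, toy$seqs, intron_span = 30,
                        exon_span = 15)
  prof <- positional_mean_rate(win, u)
  expect_equal(range(prof$profile$mean_rate), c(1.5, 1.5))

  # hand-check the acceptor window against direct site_rate on the gene:
  # offset +1 is the first exonic base of exon 2, genomic 0-based 110
  erm <- toy_erm()
  prof2 <- positional_mean_rate(win, erm)
  raw <- toy$raw
  got <- prof2$profile
  got_val <- got$mean_rate[got$side == "acceptor" & got$offset == 1]
  expect_equal(got_val, site_rate(raw, 111, erm))
  # offset -1, last intronic base before the acceptor (genomic 109)
  got_m1 <- got$mean_rate[got$side == "acceptor" & got$offset == -1]
  expect_equal(got_m1, site_rate(raw, 110, erm))

  # exon/intron means: exonic offsets only
  expect_equal(prof2$exon_mean,
               mean(got$mean_rate[got$region == "exon"] *
                      got$n[got$region == "exon"]) /
                 mean(got$n[got$region == "exon"]))
})

test_that("k-mer frequencies count overlapping windows within records
           only", {
  f <- kmer_frequencies("AAAAAAA", 6)
  expect_equal(unname(f["AAAAAA"]), 1)
  expect_equal(attr(f, "n_windows"), 2)

  f2 <- kmer_frequencies(c("ACGTACGTAC", "TTTTTT"), 6)
  expect_equal(sum(f2), 1)
  # no window spans the record boundary: concatenation changes counts
  f_cat <- kmer_frequencies(paste0("ACGTACGTAC", "TTTTTT"), 6)
  expect_false(isTRUE(all.equal(as.numeric(f2), as.numeric(f_cat))))

  # ambiguous bases are skipped, not imputed: of the 8 windows in
  # AAAAAANAAAAAA only the 2 N-free ones count
  fN <- kmer_frequencies("AAAAAANAAAAAA", 6)
  expect_equal(unname(fN["AAAAAA"]), 1)
  expect_equal(attr(fN, "n_windows"), 2)
  expect_error(kmer_frequencies("ACG", 6), "shorter")
})

test_that("exon/intron enrichment is antisymmetric and flags the
           constructed signal", {
  ex <- rep("GAAGAAGAAGAAGAAGAA", 5)
  inx <- rep("TTTTTTTTTTTTTTTTTT", 5)
  enr <- exon_intron_enrichment(ex, inx)
  expect_gt(enr$enrichment[enr$hexamer == "GAAGAA"], 2)
  expect_lt(enr$enrichment[enr$hexamer == "TTTTTT"], -2)

  # identical collections: all zero
  enr0 <- exon_intron_enrichment(ex, ex)
  expect_equal(range(enr0$enrichment), c(0, 0))

  # swapping collections flips the sign
  rev <- exon_intron_enrichment(inx, ex)
  expect_equal(rev$enrichment, -enr$enrichment)
})

test_that("score correlations behave at the fixed points and exclude CpG
           hexamers on request", {
  set.seed(3)
  enr <- data.frame(hexamer = all_hexamers(),
                    enrichment = rnorm(4096))
  self <- premotif:::new_score_table(
    setNames(enr$enrichment, enr$hexamer))
  r <- correlate_scores(enr, self)
  expect_equal(r$r, 1, tolerance = 1e-12)
  expect_equal(r$n, 4096L)

  anti <- premotif:::new_score_table(
    setNames(-enr$enrichment, enr$hexamer))
  expect_equal(correlate_scores(enr, anti)$r, -1, tolerance = 1e-12)

  # CpG exclusion keeps exactly the CG-free hexamers; their count obeys
  # the avoid-a-word recurrence a_n = 4 a_{n-1} - a_{n-2}: a_6 = 2911
  a <- c(1, 4)
  for (n in 2:6) a[n + 1] <- 4 * a[n] - a[n - 1]
  n_cpg <- sum(grepl("CG", all_hexamers(), fixed = TRUE))
  expect_equal(n_cpg, 4096L - a[7])
  expect_equal(correlate_scores(enr, self, exclude_cpg = TRUE)$n, a[7])

  expect_error(correlate_scores(enr[1:2, ], self), "fewer than 3")
})

test_that("planted score-mutability correlations are recovered", {
  hx <- hexamer_mean_rates(default_erm())
  for (rho in c(0, 0.7, 1)) {
    sc <- gen_score_table(synth_spec(seed = 5, rho = rho), hx)
    r <- cor(log(hx$mean_rate), as.numeric(sc))
    if (rho == 0) expect_lt(abs(r), 0.05) else
      expect_equal(r, rho, tolerance = 0.05)
  }
})
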