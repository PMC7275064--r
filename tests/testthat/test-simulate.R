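test_that("initialization is deterministic and uniform", {
  cfg <- sim_config(n_sequences = 200, seq_length = 999, seed = 42)
  g1 <- init_genome(cfg)
  g2 <- init_genome(cfg)
  expect_identical(g1$seqs, g2$seqs)

  comp <- table(unlist(g1$seqs))
  frac <- comp / sum(comp)
  expect_true(all(abs(frac - 0.25) < 0.005))
})

test_that("FASTA initialization validates frame and stops under constraint", {
  f <- withr::local_tempfile(fileext = ".fa")
  write_sequences(c(ok = "ATGGAAGAAGAAGAA", bad = "ATGTAAGAAGAAGAA"), f)
  cfg <- sim_config(n_sequences = 2, seq_length = 15,
                    constraint = "protein", seed = 1,
                    init = "from_fasta", init_fasta = f)
  expect_error(init_genome(cfg), "stop codon")

  write_sequences(c(ok = "ATGGAAGAAGAAGAA"), f)
  cfg2 <- sim_config(n_sequences = 1, seq_length = 15,
                     constraint = "protein", seed = 1,
                     init = "from_fasta", init_fasta = f)
  g <- init_genome(cfg2)
  expect_equal(g$ref_translation, "MEEEE")
})

test_that("the constraint acceptance rule matches the genetic code", {
  # missense rejected
  expect_false(substitution_allowed("GAA", 2, "T"))   # Glu -> Val
  # synonymous accepted
  expect_true(substitution_allowed("GAA", 3, "G"))    # Glu -> Glu
  # stop gain rejected even though some would read as "silent" at the
  # protein string level
  expect_false(substitution_allowed("TAC", 3, "A"))   # Tyr -> stop
  expect_false(substitution_allowed("GAA", 1, "T"))   # Glu -> stop (TAA)

  # exhaustive property: allowed iff same amino acid and not a stop
  codons <- premotif:::kmer_strings(3L)
  for (cod in sample(setdiff(codons, c("TAA", "TAG", "TGA")), 12)) {
    for (p in 1:3) for (alt in setdiff(BASES4, substr(cod, p, p))) {
      mut <- cod; substr(mut, p, p) <- alt
      expected <- !(mut %in% c("TAA", "TAG", "TGA")) &&
        oracle_translate(mut) == oracle_translate(cod)
      expect_identical(substitution_allowed(cod, p, alt), expected)
    }
  }
})

test_that("runs are reproducible, conserve structure, and count time as
           accepted substitutions per base", {
  erm <- default_erm()
  cfg <- sim_config(n_sequences = 20, seq_length = 99,
                    constraint = "protein", t_max = 1, seed = 9)
  r1 <- run_sim(cfg, erm)
  r2 <- run_sim(cfg, erm)
  expect_identical(r1$final, r2$final)
  expect_identical(r1$hex_counts, r2$hex_counts)

  # conservation: sequence count and lengths never change
  expect_equal(length(r1$final), 20L)
  expect_true(all(nchar(r1$final) == 99L))

  # tau grid and accounting: tau = accepted / total bases
  expect_equal(r1$tau, seq(0, 1, by = 0.2))
  expect_equal(r1$accepted, 1 * 20 * 99)
  # the stated full-scale arithmetic: 999,000 accepted on 5000 x 999 bases
  expect_equal(999000 / (5000 * 999), 0.2)

  # hexamer frequencies sum to 1 at every record
  expect_equal(unname(rowSums(r1$hex_freq)), rep(1, length(r1$tau)))

  # translation invariance at every recorded state's endpoint
  tr <- vapply(r1$final, premotif:::translate_str, character(1),
               USE.NAMES = FALSE)
  expect_identical(tr, r1$ref_translation)
})

test_that("hot motifs are depleted and cold motifs accumulate without
           constraint", {
  erm <- default_erm()
  hx <- rank_hexamers(hexamer_mean_rates(erm))
  most <- hx$hexamer[1]; least <- hx$hexamer[4096]
  deltas_hot <- deltas_cold <- numeric(10)
  for (i in 1:10) {
    cfg <- sim_config(n_sequences = 30, seq_length = 300,
                      constraint = "none", t_max = 2, seed = 100 + i)
    r <- run_sim(cfg, erm)
    deltas_hot[i] <- r$hex_freq[nrow(r$hex_freq), most] -
      r$hex_freq[1, most]
    deltas_cold[i] <- r$hex_freq[nrow(r$hex_freq), least] -
      r$hex_freq[1, least]
  }
  expect_lt(mean(deltas_hot), 0)
  expect_gt(mean(deltas_cold), 0)
})

test_that("enrichment ratios start near 1 and acquire the
           mutability-coupled signal", {
  erm <- default_erm()
  cfg_c <- sim_config(n_sequences = 60, seq_length = 300,
                      constraint = "protein", t_max = 2, seed = 21)
  cfg_u <- sim_config(n_sequences = 60, seq_length = 300,
                      constraint = "none", t_max = 2, seed = 22)
  rc <- run_sim(cfg_c, erm)
  ru <- run_sim(cfg_u, erm)
  ratio <- enrichment_ratio(rc, ru)
  # tau = 0: same initialization distribution, ratios ~ 1
  expect_lt(abs(mean(log(ratio[1, ]))), 0.05)

  # mismatched grids rejected
  cfg_s <- sim_config(n_sequences = 60, seq_length = 300,
                      constraint = "none", t_max = 1, seed = 23)
  expect_error(enrichment_ratio(rc, run_sim(cfg_s, erm)), "tau grids")
})

test_that("the incremental rate cache matches a full recomputation after
           many substitutions", {
  erm <- default_erm()
  cfg <- sim_config(n_sequences = 5, seq_length = 120,
                    constraint = "none", t_max = 2, seed = 31)
  r <- run_sim(cfg, erm)
  b <- unlist(lapply(r$final, premotif:::seq_to_int))
  recomputed <- premotif:::site_means_cpp(b, rep(120L, 5L), erm$rates)
  expect_equal(r$mean_erm[length(r$mean_erm)], mean(recomputed),
               tolerance = 1e-12)
})

test_that("a genome with no acceptable substitution deadlocks explicitly", {
  erm <- uniform_erm()
  f <- withr::local_tempfile(fileext = ".fa")
  # Met and Trp are single-codon amino acids: every change is non-
  # synonymous, so under constraint nothing can ever be accepted
  write_sequences(c(s1 = "ATGTGGATGTGGATGTGG"), f)
  cfg <- sim_config(n_sequences = 1, seq_length = 18,
                    constraint = "protein", t_max = 1,
                    record_interval = 1, seed = 1,
                    init = "from_fasta", init_fasta = f)
  expect_error(run_sim(cfg, erm, max_reject = 1000), "deadlock")
})

test_that("positional profile of simulated triples shows constrained
           middle blocks as more mutable", {
  erm <- default_erm()
  # uniform table -> flat profile
  u <- uniform_erm(2)
  cfg_c <- sim_config(n_sequences = 6, seq_length = 300,
                      constraint = "protein", t_max = 0.5, seed = 41)
  cfg_u <- sim_config(n_sequences = 12, seq_length = 300,
                      constraint = "none", t_max = 0.5, seed = 42)
  rc <- run_sim(cfg_c, u); ru <- run_sim(cfg_u, u)
  prof_u <- pseudo_positional_profile(rc, ru, u)
  expect_equal(range(prof_u$mean_rate, na.rm = TRUE), c(2, 2))
  # edge positions have no full linear context
  expect_true(all(is.na(prof_u$mean_rate[c(1:3, 898:900)])))

  # directional: constrained middle more mutable than flanks, most seeds
  wins <- 0L
  for (i in 1:10) {
    cfg_c <- sim_config(n_sequences = 10, seq_length = 300,
                        constraint = "protein", t_max = 3, seed = 500 + i)
    cfg_u <- sim_config(n_sequences = 20, seq_length = 300,
                        constraint = "none", t_max = 3, seed = 600 + i)
    prof <- pseudo_positional_profile(run_sim(cfg_c, erm),
                                      run_sim(cfg_u, erm), erm)
    ex <- mean(prof$mean_rate[prof$region == "exon"], na.rm = TRUE)
    inx <- mean(prof$mean_rate[prof$region == "intron"], na.rm = TRUE)
    if (ex > inx) wins <- wins + 1L
  }
  expect_gte(wins, 9L)
})

test_that("final-frequency variance grows with mutational bias and shrinks
           under constraint", {
  erm <- default_erm()
  hx <- rank_hexamers(hexamer_mean_rates(erm))
  # track the least mutable hexamer: it accumulates rather than vanishes,
  # so its frequency is well resolved at this genome size
  target <- hx$hexamer[4096]
  n_rep <- 20
  final_freq <- function(beta, constraint, seed) {
    cfg <- sim_config(n_sequences = 20, seq_length = 300,
                      constraint = constraint, beta = beta, t_max = 2,
                      record_interval = 2, seed = seed)
    r <- run_sim(cfg, erm)
    r$hex_freq[nrow(r$hex_freq), target]
  }
  v <- vapply(c(0.5, 1, 2), function(beta)
    var(vapply(seq_len(n_rep), function(i)
      final_freq(beta, "none", 1000 * beta + i), numeric(1))), numeric(1))
  expect_true(v[1] <= v[2] && v[2] <= v[3])

  vc <- var(vapply(seq_len(n_rep), function(i)
    final_freq(1, "protein", 7000 + i), numeric(1)))
  expect_lt(vc, v[2])
})
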