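test_that("rate-table generation is seeded, structured, and spans the
           reported dynamic range", {
  spec <- synth_spec(seed = 99)
  t1 <- gen_erm_table(spec)
  t2 <- gen_erm_table(spec)
  expect_identical(t1$rates, t2$rates)

  # degenerate spec: all multipliers 1, sigma 0 -> uniform table
  u <- gen_erm_table(synth_spec(seed = 1, sigma_log = 0, titv = 1,
                                cpg_mult = 1, gt_purine_mult = 1))
  r <- u$rates[u$rates > 0]
  expect_equal(range(r), c(1, 1))

  # the full table spans more than the reported ~400-fold context range
  r1 <- t1$rates[t1$rates > 0]
  expect_gt(max(r1) / min(r1), 400)

  # CpG boost raises the mean rate of CG-containing hexamers
  spec_cpg <- synth_spec(seed = 4, cpg_mult = 10)
  hx <- hexamer_mean_rates(gen_erm_table(spec_cpg))
  has_cg <- grepl("CG", hx$hexamer, fixed = TRUE)
  expect_gt(mean(hx$mean_rate[has_cg]), mean(hx$mean_rate[!has_cg]))

  # purine-context G>T hotspot is visible in the GARGAR stop contexts
  erm <- gen_erm_table(synth_spec(seed = 4))
  hot <- erm_rate(erm, "AAAGAAG", "T")    # purine-flanked G>T
  typ <- mean(erm$rates[, "T"][erm$rates[, "T"] > 0])
  expect_gt(hot / typ, 1)
})

test_that("gene models parse cleanly and show the constrained-exon
           mutability signal", {
  spec <- synth_spec(seed = 11, n_genes = 6)
  erm <- gen_erm_table(spec)
  genes <- gen_gene_models(spec, erm)

  # output round-trips through the package's own readers
  fa <- withr::local_tempfile(fileext = ".fa")
  bed <- withr::local_tempfile(fileext = ".bed")
  write_sequences(genes$seqs, fa)
  write_annotation(genes$models, bed)
  models <- read_annotation(bed)
  seqs <- read_sequences(fa)
  expect_silent(validate_annotation(models, seqs))
  win <- splice_windows(models, seqs)
  # 3 exons per gene -> 4 internal splice sites per gene
  expect_equal(nrow(win), 6L * 4L)

  # directional signal: exonic windows more mutable than intronic in
  # >= 9/10 replicates at the generator's evolutionary time
  wins <- 0L
  for (i in 1:10) {
    sp <- synth_spec(seed = 2000 + i, n_genes = 4)
    g <- gen_gene_models(sp, erm)
    pm <- positional_mean_rate(splice_windows(g$models, g$seqs), erm)
    if (pm$exon_mean > pm$intron_mean) wins <- wins + 1L
  }
  expect_gte(wins, 9L)

  # tau = 0: no exon/intron difference beyond sampling noise
  diffs <- vapply(1:6, function(i) {
    sp0 <- synth_spec(seed = 3000 + i, n_genes = 4, sim_tau = 0)
    g0 <- gen_gene_models(sp0, erm)
    pm0 <- positional_mean_rate(splice_windows(g0$models, g0$seqs), erm)
    pm0$exon_mean / pm0$intron_mean - 1
  }, numeric(1))
  expect_lt(abs(mean(diffs)), 0.02)
})

test_that("variant generation couples rarity to mutability only through
           the coupling parameter", {
  erm <- gen_erm_table(synth_spec(seed = 21))
  genes <- gen_gene_models(synth_spec(seed = 21, n_genes = 6), erm)

  v0 <- gen_variants(synth_spec(seed = 22, daf_coupling = 0,
                                n_variants = 400), genes, erm)
  cod0 <- v0[v0$effect != "intronic", ]
  expect_lt(abs(cor(log(cod0$rate), log10(cod0$daf))), 0.12)

  v1 <- gen_variants(synth_spec(seed = 23, daf_coupling = 2,
                                n_variants = 400), genes, erm)
  cod1 <- v1[v1$effect != "intronic", ]
  expect_lt(cor(log(cod1$rate), log10(cod1$daf)), -0.3)

  # round trip through the reader
  f <- withr::local_tempfile(fileext = ".tsv")
  df <- v1[, c("variant_id", "heptamer", "ref", "alt", "effect", "daf",
               "exon_dist")]
  write.table(df, f, sep = "\t", quote = FALSE, row.names = FALSE)
  back <- read_variant_table(f)
  expect_equal(nrow(back), nrow(v1))

  # the analysis recovers the construction: rare variants sit at more
  # mutable sites
  res <- daf_bin_mean_rate(back, erm)
  syn <- res$bins[res$bins$effect %in% c("synonymous", "missense"), ]
  agg <- tapply(syn$mean_rate * syn$n, syn$bin, sum) /
    tapply(syn$n, syn$bin, sum)
  agg <- agg[order(names(agg))]
  expect_gt(length(agg), 2)
  # mean rate decreases from the rarest to the commonest bin
  expect_gt(agg[["[5e-05,0.0001)"]], agg[["[0.1,1]"]])
})

test_that("assay counts recover planted effects exactly without noise and
           as medians with noise", {
  erm <- gen_erm_table(synth_spec(seed = 31))
  genes <- gen_gene_models(synth_spec(seed = 31, n_genes = 6), erm)
  variants <- gen_variants(synth_spec(seed = 32, n_variants = 300),
                           genes, erm)

  # noiseless: ratios equal the class effects to machine precision
  sp0 <- synth_spec(seed = 33, assay_noise_sd = 0)
  a0 <- gen_assay_counts(sp0, variants)
  mw0 <- mw_splice_ratio(a0$counts)
  expect_equal(mw0, unname(sp0$assay_effects[a0$counts$effect]),
               tolerance = 1e-12)

  # with noise: the full generate -> analyze round trip recovers the
  # planted median ordering stop_gain < missense < synonymous
  sp1 <- synth_spec(seed = 34)
  a1 <- gen_assay_counts(sp1, variants)
  expect_true(all(a1$counts$mt_i + a1$counts$mt_o +
                    a1$counts$wt_i + a1$counts$wt_o ==
                    tapply(a1$replicates$count, a1$replicates$variant_id,
                           sum)[a1$counts$variant_id]))
  mw1 <- mw_splice_ratio(a1$counts)
  res <- effect_class_comparison(mw1, a1$counts$effect)
  med <- setNames(res$summary$median, res$summary$class)
  expect_lt(med[["stop_gain"]], med[["missense"]])
  expect_lt(med[["missense"]], med[["synonymous"]])
})

test_that("score tables are pure functions of the spec", {
  hx <- hexamer_mean_rates(gen_erm_table(synth_spec(seed = 41)))
  s1 <- gen_score_table(synth_spec(seed = 41), hx)
  s2 <- gen_score_table(synth_spec(seed = 41), hx)
  expect_identical(as.numeric(s1), as.numeric(s2))
  expect_equal(attr(s1, "n_absent"), 0L)
})
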