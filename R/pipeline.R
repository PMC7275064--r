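# End-to-end orchestration of the figure-family analyses on synthetic
# inputs: motif trajectories, exon/intron mutability and enrichment,
# score correlations, amino-acid-pair statistics, and variant/assay
# statistics. Deterministic given the seed; optionally writes every stage
# table as TSV under an output prefix.

#' Run the full synthetic analysis pipeline
#'
#' Generates all inputs from a [synth_spec()], runs each analysis family,
#' and returns their summary statistics. Stage tables are written as TSVs
#' when `out_dir` is given. Default scale is reduced relative to the
#' full-study configuration (see the methods vignette); `n_sequences`,
#' `seq_length` and `t_max` control the simulation stage.
#'
#' @param seed integer seed for the whole run.
#' @param n_sequences,seq_length,t_max simulation scale (default 500 x
#'   300 nt to tau = 3).
#' @param spec optional pre-built [synth_spec()]; its seed is overridden.
#' @param out_dir optional directory for stage TSVs.
#' @return nested list with components `mutability`, `trajectories`,
#'   `genome`, `protein`, `variants`; each holds the figure-family summary
#'   statistics described in the vignette.
#' @export
run_synthetic_pipeline <- function(seed = 1L, n_sequences = 500L,
                                   seq_length = 300L, t_max = 3,
                                   spec = NULL, out_dir = NULL) {
  if (is.null(spec)) spec <- synth_spec(seed = seed)
  spec$seed <- as.integer(seed)
  if (!is.null(out_dir) && !dir.exists(out_dir))
    dir.create(out_dir, recursive = TRUE)
  emit <- function(df, name) {
    if (!is.null(out_dir))
      write.table(df, file.path(out_dir, paste0(name, ".tsv")), sep = "\t",
                  quote = FALSE, row.names = FALSE)
    invisible(df)
  }

  # -- mutability layer ----------------------------------------------------
  erm <- gen_erm_table(spec)
  hex <- rank_hexamers(hexamer_mean_rates(erm))
  scores <- gen_score_table(spec, hex)
  emit(hex, "hexamer_rates")
  most <- hex$hexamer[1]
  least <- hex$hexamer[nrow(hex)]

  # -- simulated trajectories (constraint vs none) -------------------------
  cfg_c <- sim_config(n_sequences = n_sequences, seq_length = seq_length,
                      constraint = "protein", t_max = t_max,
                      seed = seed + 11L)
  cfg_u <- sim_config(n_sequences = n_sequences, seq_length = seq_length,
                      constraint = "none", t_max = t_max, seed = seed + 12L)
  run_c <- run_sim(cfg_c, erm, scores)
  run_u <- run_sim(cfg_u, erm, scores)
  ratio <- enrichment_ratio(run_c, run_u)
  final_ratio <- ratio[nrow(ratio), ]
  sp <- cor(hex$mean_rate[match(colnames(ratio), hex$hexamer)],
            log(final_ratio), method = "spearman")
  traj <- data.frame(tau = run_c$tau,
                     most_mutable_con = run_c$hex_freq[, most],
                     most_mutable_unc = run_u$hex_freq[, most],
                     least_mutable_con = run_c$hex_freq[, least],
                     least_mutable_unc = run_u$hex_freq[, least],
                     mean_erm_con = run_c$mean_erm,
                     mean_erm_unc = run_u$mean_erm,
                     mean_ei_con = run_c$mean_ei,
                     mean_ei_unc = run_u$mean_ei)
  emit(traj, "trajectories")

  # -- genome layer: gene models, profile, enrichment, correlations --------
  genes <- gen_gene_models(spec, erm)
  win <- splice_windows(genes$models, genes$seqs)
  prof <- positional_mean_rate(win, erm)
  emit(prof$profile, "splice_profile")
  exon_seqs <- exon_sequences(genes$models, genes$seqs)
  intron_seqs <- intron_sequences(genes$models, genes$seqs)
  enr <- exon_intron_enrichment(exon_seqs, intron_seqs)
  emit(enr, "exon_intron_enrichment")
  cor_ese <- correlate_scores(enr, scores)
  anti <- new_score_table(setNames(-as.numeric(scores), names(scores)))
  cor_ise <- correlate_scores(enr, anti)
  cor_nocpg <- correlate_scores(enr, scores, exclude_cpg = TRUE)

  # -- protein layer -------------------------------------------------------
  cds <- genes$constrained$final
  pair_ei <- aa_pair_mean_ei(cds, scores)
  emit(pair_ei, "aa_pair_mean_ei")
  prot_splicing <- vapply(cds, translate_str, character(1),
                          USE.NAMES = FALSE)
  # frozen stops break proteins into separate peptides
  prot_splicing <- unlist(strsplit(prot_splicing, "*", fixed = TRUE))
  prot_splicing <- prot_splicing[nchar(prot_splicing) >= 2L]
  set.seed(seed + 21L)
  aa20 <- sort(setdiff(unique(aa_by_codon()), "*"))
  prot_plain <- vapply(seq_along(prot_splicing), function(i)
    paste(sample(aa20, nchar(prot_splicing[i]), replace = TRUE),
          collapse = ""), character(1))
  pair_enr <- aa_pair_enrichment(prot_splicing, prot_plain)
  emit(pair_enr, "aa_pair_enrichment")
  gargar <- stop_gain_fraction(hexamers = c("GAAGAA", "GAAGAG", "GAGGAA",
                                            "GAGGAG"))
  ee_ctx <- dicodon_contexts(cds, pair = "EE")
  ee_erm_frac <- if (length(ee_ctx)) {
    stop_gain_fraction(hexamers = codon_pair_hexamers("EE"),
                       weighting = "erm_context", erm = erm,
                       contexts = ee_ctx)
  } else NA_real_
  dctx <- dicodon_contexts(cds, max_n = 4000L, seed = seed + 22L)
  dei <- mutation_delta_ei(dctx, scores, erm)
  emit(dei$by_class, "delta_ei_by_class")

  # -- variant layer -------------------------------------------------------
  variants <- gen_variants(spec, genes, erm)
  emit(variants, "variants")
  assay <- gen_assay_counts(spec, variants)
  assay$counts$mw <- mw_splice_ratio(assay$counts)
  emit(assay$counts, "assay_counts")
  cls <- effect_class_comparison(assay$counts$mw, assay$counts$effect)
  daf <- daf_bin_mean_rate(variants, erm)
  emit(daf$bins, "daf_bins")

  list(
    mutability = list(most_mutable = most, least_mutable = least,
                      dynamic_range = max(hex$mean_rate) /
                        min(hex$mean_rate)),
    trajectories = list(
      table = traj, tau_max = max(run_c$tau),
      most_mutable_ratio = final_ratio[[most]],
      least_mutable_ratio = final_ratio[[least]],
      spearman_rate_vs_log_ratio = sp),
    genome = list(exon_mean = prof$exon_mean,
                  intron_mean = prof$intron_mean,
                  exon_excess_pct = 100 * (prof$exon_mean /
                                             prof$intron_mean - 1),
                  cor_ese = cor_ese, cor_ise = cor_ise,
                  cor_nocpg = cor_nocpg),
    protein = list(pair_ei = pair_ei, pair_enr = pair_enr,
                   gargar_uniform_stop_fraction = gargar,
                   ee_erm_stop_fraction = ee_erm_frac,
                   delta_ei = dei$by_class),
    variants = list(class_comparison = cls, daf = daf)
  )
}

#' Intron sequences of gene models (transcript-oriented)
#' @param models annotation data.frame.
#' @param seqs `DNAStringSet`.
#' @return character vector of intron sequences between consecutive exons.
#' @export
intron_sequences <- function(models, seqs) {
  chr <- as_seq_chr(seqs)
  names(chr) <- names(seqs)
  out <- character(0)
  for (tx in split(models, models$transcript)) {
    tx <- tx[order(tx$start), ]
    if (nrow(tx) < 2L) next
    for (i in seq_len(nrow(tx) - 1L)) {
      s <- substr(chr[[tx$seqname[1]]], tx$end[i] + 1L, tx$start[i + 1L])
      if (tx$strand[1] == "-") s <- revcomp_str(s)
      out <- c(out, s)
    }
  }
  out
}

#' Extract dicodon occurrence contexts from coding sequences
#'
#' All in-frame dicodons with 3 nt of flanking sequence on each side
#' (12-mers), optionally restricted to a given amino-acid pair and
#' down-sampled.
#'
#' @param cds character vector of in-frame coding sequences.
#' @param pair optional two-letter pair filter.
#' @param max_n optional cap (uniform subsample).
#' @param seed seed for the subsample.
#' @return character vector of 12-mers.
#' @export
dicodon_contexts <- function(cds, pair = NULL, max_n = NULL, seed = 1L) {
  aa <- aa_by_codon()
  out <- character(0)
  for (s in as_seq_chr(cds)) {
    n <- nchar(s)
    starts <- seq(4L, n - 8L, by = 3L)   # dicodon start (1-based), in frame
    starts <- starts[(starts - 1L) %% 3L == 0L]
    if (!length(starts)) next
    ctx <- substring(s, starts - 3L, starts + 8L)
    # dicodons carrying a stop codon are excluded (stop-loss out of scope)
    stops <- c("TAA", "TAG", "TGA")
    ctx <- ctx[!(substring(ctx, 4L, 6L) %in% stops |
                   substring(ctx, 7L, 9L) %in% stops)]
    if (!is.null(pair)) {
      p <- paste0(aa[vapply(substring(ctx, 4L, 6L), kmer_index,
                            integer(1)) + 1L],
                  aa[vapply(substring(ctx, 7L, 9L), kmer_index,
                            integer(1)) + 1L])
      ctx <- ctx[p == pair]
    }
    out <- c(out, ctx)
  }
  out <- out[!grepl("[^ACGT]", out)]
  if (!is.null(max_n) && length(out) > max_n) {
    set.seed(seed)
    out <- sample(out, max_n)
  }
  out
}

#' Hexamer (dicodon) encodings of an amino-acid pair
#' @param pair two-letter amino-acid pair.
#' @return character vector of 6-mers.
#' @export
codon_pair_hexamers <- function(pair) {
  a1 <- codons_for_aa(substr(pair, 1, 1))
  a2 <- codons_for_aa(substr(pair, 2, 2))
  as.vector(outer(a1, a2, paste0))
}
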