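# Synthetic-data generators emulating every input the analyses consume:
# a heavy-tailed context-dependent rate table with transition/transversion
# skew and CpG-like and purine-context G>T hotspots, activity scores
# partially coupled to mutability, gene models whose exons evolved under
# coding constraint, variant sets whose rare alleles sit at mutable
# constrained sites, and reporter-assay counts in which stop gains carry
# the largest splicing disruption. Every generator is a pure function of
# its spec (the seed is part of the spec).

#' Specification for the synthetic-data generators
#'
#' Defaults are the study conditions used throughout the package's tests
#' and analyses; see the methods vignette for the reasoning behind each.
#'
#' @param seed integer seed; with the spec it fully determines all outputs.
#' @param sigma_log log-scale (natural log) standard deviation of the
#'   base rates (0.5 spreads 49152 rates over a few-hundred-fold range
#'   before hotspot multipliers, matching the reported >400-fold context
#'   spread once they are applied).
#' @param titv transition/transversion rate multiplier (2).
#' @param cpg_mult multiplier for C>T (and G>A) deamination-like changes in
#'   CpG context (8).
#' @param gt_purine_mult multiplier for G>T changes flanked by purines on
#'   both sides (4) -- the purine-context hotspot.
#' @param rho target correlation between synthetic activity scores and log
#'   hexamer mean mutability (0.7).
#' @param n_genes,exon_len,intron_len gene-model geometry (20 three-exon
#'   genes, 240 nt exons, 300 nt introns).
#' @param sim_tau evolutionary time (mutations per base) at which exon and
#'   intron sequences are harvested (5).
#' @param sim_seq_len length of the simulated source sequences (300).
#' @param n_variants variants drawn for the population analysis (600).
#' @param daf_coupling strength of the rare-at-mutable-sites coupling for
#'   coding variants (1).
#' @param assay_effects true log2 splice-ratio effect per class.
#' @param assay_noise_sd between-variant effect noise, log2 units (0.5).
#' @param assay_depth mean input read count per replicate (1000).
#' @param n_input_reps,n_output_reps replicate counts (2 input, 4 output).
#' @return a `synth_spec` list.
#' @export
synth_spec <- function(seed = 1L, sigma_log = 0.5, titv = 2, cpg_mult = 8,
                       gt_purine_mult = 4, rho = 0.7, n_genes = 20L,
                       exon_len = 240L, intron_len = 300L, sim_tau = 5,
                       sim_seq_len = 300L, n_variants = 600L,
                       daf_coupling = 1, assay_effects = c(
                         synonymous = 0, missense = -0.5, stop_gain = -2),
                       assay_noise_sd = 0.5, assay_depth = 1000,
                       n_input_reps = 2L, n_output_reps = 4L) {
  stopifnot(sigma_log >= 0, titv > 0, cpg_mult > 0, gt_purine_mult > 0,
            rho >= -1, rho <= 1, exon_len %% 3L == 0L)
  structure(as.list(environment()), class = "synth_spec")
}

TRANSITION_OF <- c(A = "G", C = "T", G = "A", T = "C")

#' Generate a synthetic heptamer rate table
#'
#' Log-normal base rates; transitions boosted over transversions; C>T
#' boosted where the middle C is followed by G and G>A where preceded by C
#' (CpG-deamination-like, on both strands' representations); G>T boosted
#' where both immediate neighbours are purines. Rates are normalized to
#' mean 1 (they are relative rates).
#'
#' @param spec a [synth_spec()].
#' @return an `erm_table`.
#' @export
gen_erm_table <- function(spec) {
  stopifnot(inherits(spec, "synth_spec"))
  set.seed(spec$seed + 101L)
  hept <- kmer_strings(7L)
  mid <- substr(hept, 4L, 4L)
  nb_l <- substr(hept, 3L, 3L)
  nb_r <- substr(hept, 5L, 5L)
  rates <- matrix(0, N_HEPTAMERS, 4L, dimnames = list(NULL, BASES))
  for (a in BASES) {
    sel <- mid != a
    r <- exp(rnorm(sum(sel), 0, spec$sigma_log))
    is_ti <- TRANSITION_OF[mid[sel]] == a
    r[is_ti] <- r[is_ti] * spec$titv
    cpg <- (mid[sel] == "C" & a == "T" & nb_r[sel] == "G") |
      (mid[sel] == "G" & a == "A" & nb_l[sel] == "C")
    r[cpg] <- r[cpg] * spec$cpg_mult
    gt <- mid[sel] == "G" & a == "T" &
      nb_l[sel] %in% c("A", "G") & nb_r[sel] %in% c("A", "G")
    r[gt] <- r[gt] * spec$gt_purine_mult
    rates[sel, a] <- r
  }
  rates[rates > 0] <- rates[rates > 0] / mean(rates[rates > 0])
  new_erm_table(rates)
}

#' Generate an activity-score table coupled to mutability
#'
#' Additive Gaussian mixing on the log-rate scale: scores are
#' `rho * z + sqrt(1 - rho^2) * eps` with `z` the standardized log hexamer
#' mean rate, rescaled to a typical enhancer-score spread (sd 0.3).
#'
#' @param spec a [synth_spec()].
#' @param hex_rates data.frame from [hexamer_mean_rates()].
#' @return a complete `score_table` whose sample correlation with the log
#'   mean rate is within a few hundredths of `spec$rho`.
#' @export
gen_score_table <- function(spec, hex_rates) {
  stopifnot(inherits(spec, "synth_spec"))
  set.seed(spec$seed + 202L)
  z <- scale(log(hex_rates$mean_rate))[, 1]
  if (sd(z) == 0 || !is.finite(sd(z))) z <- rep(0, length(z))
  eps <- rnorm(length(z))
  raw <- spec$rho * z + sqrt(1 - spec$rho^2) * eps
  sc <- setNames(0.3 * raw, hex_rates$hexamer)
  new_score_table(sc[kmer_strings(6L)])
}

#' Generate gene models with constrained exons and neutral introns
#'
#' Runs the mutation-selection simulator twice at matched time
#' (`spec$sim_tau`): exon sequences are harvested from the
#' protein-constrained run, intron sequences from the unconstrained run.
#' Each gene is a separate sequence: intron, exon, intron, exon, intron,
#' exon, intron (three exons), with exact exon coordinates in the
#' annotation, plus strand.
#'
#' @param spec a [synth_spec()].
#' @param erm an `erm_table`.
#' @return list: `seqs` (`DNAStringSet`, one per gene), `models`
#'   (annotation data.frame), and the two `sim_run`s.
#' @export
gen_gene_models <- function(spec, erm) {
  stopifnot(inherits(spec, "synth_spec"), inherits(erm, "erm_table"))
  n_ex <- 3L
  need_ex <- spec$n_genes * n_ex
  need_in <- spec$n_genes * (n_ex + 1L)
  if (spec$sim_tau > 0) {
    con <- run_sim(sim_config(n_sequences = need_ex,
                              seq_length = spec$sim_seq_len,
                              constraint = "protein", t_max = spec$sim_tau,
                              record_interval = spec$sim_tau,
                              seed = spec$seed + 303L), erm)
    unc <- run_sim(sim_config(n_sequences = need_in,
                              seq_length = spec$sim_seq_len,
                              constraint = "none", t_max = spec$sim_tau,
                              record_interval = spec$sim_tau,
                              seed = spec$seed + 404L), erm)
    exons <- con$final
    introns <- unc$final
  } else {
    # tau = 0: unevolved random sequences on both sides
    con <- unc <- NULL
    g1 <- init_genome(sim_config(n_sequences = need_ex,
                                 seq_length = spec$sim_seq_len,
                                 constraint = "protein",
                                 seed = spec$seed + 303L))
    g2 <- init_genome(sim_config(n_sequences = need_in,
                                 seq_length = spec$sim_seq_len,
                                 constraint = "none",
                                 seed = spec$seed + 404L))
    exons <- vapply(g1$seqs, int_to_seq, character(1))
    introns <- vapply(g2$seqs, int_to_seq, character(1))
  }
  exons <- substr(exons, 1L, spec$exon_len)
  introns <- substr(introns, 1L, spec$intron_len)
  seqs <- character(spec$n_genes)
  models <- list()
  for (g in seq_len(spec$n_genes)) {
    ex <- exons[(g - 1L) * n_ex + seq_len(n_ex)]
    inx <- introns[(g - 1L) * (n_ex + 1L) + seq_len(n_ex + 1L)]
    parts <- character(2L * n_ex + 1L)
    parts[seq(1L, by = 2L, length.out = n_ex + 1L)] <- inx
    parts[seq(2L, by = 2L, length.out = n_ex)] <- ex
    seqs[g] <- paste(parts, collapse = "")
    starts <- spec$intron_len +
      (seq_len(n_ex) - 1L) * (spec$exon_len + spec$intron_len)
    models[[g]] <- data.frame(
      transcript = sprintf("tx%03d", g), seqname = sprintf("gene%03d", g),
      start = starts, end = starts + spec$exon_len, strand = "+",
      rank = seq_len(n_ex), stringsAsFactors = FALSE)
  }
  models <- do.call(rbind, models)
  names(seqs) <- sprintf("gene%03d", seq_len(spec$n_genes))
  list(seqs = Biostrings::DNAStringSet(seqs), models = models,
       constrained = con, unconstrained = unc)
}

#' Generate a variant set over synthetic gene models
#'
#' Coding variants are drawn at random exonic positions with the alternate
#' allele sampled proportional to its context rate and the effect assigned
#' by [classify_mutation()]; a configurable fraction is intronic. Derived
#' allele frequencies follow `daf = 10^(-5.5 * Phi(latent))` where for
#' coding variants `latent = daf_coupling * z(log rate) + noise`, so high-
#' mutability constrained sites skew rare; intronic variants are
#' uncoupled.
#'
#' @param spec a [synth_spec()].
#' @param genes output of [gen_gene_models()].
#' @param erm an `erm_table`.
#' @param frac_intronic fraction of intronic variants (default 0.3).
#' @return variant data.frame in the [read_variant_table()] layout plus
#'   `seqname`, `pos` (0-based), `exon_dist`.
#' @export
gen_variants <- function(spec, genes, erm, frac_intronic = 0.3) {
  stopifnot(inherits(spec, "synth_spec"))
  set.seed(spec$seed + 505L)
  chr <- as_seq_chr(genes$seqs)
  names(chr) <- names(genes$seqs)
  m <- genes$models
  n <- spec$n_variants
  n_in <- round(frac_intronic * n)
  n_cod <- n - n_in
  make_rec <- function(seqname, pos, exon_row = NA_integer_) {
    s <- chr[[seqname]]
    hept <- substr(s, pos - 2L, pos + 4L)      # middle = 0-based pos
    ref <- substr(hept, 4L, 4L)
    r3 <- erm_rate(erm, rep(hept, 3L), setdiff(BASES, ref))
    alt <- sample(setdiff(BASES, ref), 1L, prob = r3)
    rate <- erm_rate(erm, hept, alt)
    if (is.na(exon_row)) {
      eff <- "intronic"
    } else {
      off <- pos - m$start[exon_row]           # 0-based within exon
      cod0 <- off - off %% 3L
      codon <- substr(s, m$start[exon_row] + cod0 + 1L,
                      m$start[exon_row] + cod0 + 3L)
      if (codon %in% STOP_CODONS) return(NULL) # frozen stop: redraw site
      eff <- classify_mutation(codon, off %% 3L + 1L, alt)
    }
    exon_dist <- if (is.na(exon_row)) NA_integer_ else
      min(pos - m$start[exon_row], m$end[exon_row] - 1L - pos)
    data.frame(seqname = seqname, pos = pos, heptamer = hept, ref = ref,
               alt = alt, effect = eff, rate = rate, exon_dist = exon_dist,
               stringsAsFactors = FALSE)
  }
  # coding draws: random exon rows and positions within (away from edges
  # so the heptamer stays inside the gene); reference stop codons redrawn
  recs_cod <- vector("list", n_cod)
  k <- 0L
  while (k < n_cod) {
    r <- sample(nrow(m), 1L)
    pos <- sample((m$start[r] + 3L):(m$end[r] - 4L), 1L)
    rec <- make_rec(m$seqname[r], pos, r)
    if (!is.null(rec)) {
      k <- k + 1L
      recs_cod[[k]] <- rec
    }
  }
  # intronic draws: positions in the first intron of random genes
  g_in <- sample(names(chr), n_in, replace = TRUE)
  p_in <- sample(3:(spec$intron_len - 4L), n_in, replace = TRUE)
  recs <- rbind(
    do.call(rbind, recs_cod),
    do.call(rbind, lapply(seq_len(n_in), function(i)
      make_rec(g_in[i], p_in[i]))))
  z <- scale(log(recs$rate))[, 1]
  coupling <- ifelse(recs$effect == "intronic", 0, spec$daf_coupling)
  latent <- coupling * z + rnorm(nrow(recs))
  latent <- latent / sqrt(coupling^2 + 1)
  recs$daf <- 10^(-5.5 * pnorm(latent))
  recs$variant_id <- sprintf("var%05d", seq_len(nrow(recs)))
  recs[, c("variant_id", "seqname", "pos", "heptamer", "ref", "alt",
           "effect", "daf", "exon_dist", "rate")]
}

#' Generate reporter-assay counts around class-dependent true effects
#'
#' Each variant's true log2 splice effect is its class effect plus
#' Gaussian noise (`assay_noise_sd`). Input counts per replicate are
#' negative-binomial around `assay_depth`; output counts around
#' depth x odds, with mutant odds scaled by `2^effect`. With
#' `assay_noise_sd = 0` all counts are exact expectations (non-integer),
#' a degenerate mode used to verify noiseless recovery.
#'
#' @param spec a [synth_spec()].
#' @param variants data.frame with `variant_id` and `effect` (splice-region
#'   and intronic variants are skipped: the assay targets coding classes).
#' @return list: `counts` (summed table as from [read_assay_counts()],
#'   with `true_effect` and `effect` columns) and `replicates` (long
#'   table).
#' @export
gen_assay_counts <- function(spec, variants) {
  stopifnot(inherits(spec, "synth_spec"))
  set.seed(spec$seed + 606L)
  v <- variants[variants$effect %in% names(spec$assay_effects), ]
  if (!nrow(v)) stop("no variants in assayable effect classes")
  theta <- unname(spec$assay_effects[v$effect]) +
    (if (spec$assay_noise_sd > 0) rnorm(nrow(v), 0, spec$assay_noise_sd)
     else 0)
  draw <- function(mu, n) {
    if (spec$assay_noise_sd == 0) rep(mu, n) else
      rnbinom(n, mu = mu, size = 20)
  }
  long <- list()
  for (i in seq_len(nrow(v))) {
    wt_i <- draw(spec$assay_depth, spec$n_input_reps)
    mt_i <- draw(spec$assay_depth, spec$n_input_reps)
    wt_o <- draw(spec$assay_depth, spec$n_output_reps)
    mt_o <- draw(spec$assay_depth * 2^theta[i], spec$n_output_reps)
    long[[i]] <- data.frame(
      variant_id = v$variant_id[i],
      replicate = c(seq_len(spec$n_input_reps), seq_len(spec$n_input_reps),
                    seq_len(spec$n_output_reps), seq_len(spec$n_output_reps)),
      species = c(rep("wt", spec$n_input_reps), rep("mt", spec$n_input_reps),
                  rep("wt", spec$n_output_reps), rep("mt", spec$n_output_reps)),
      stage = c(rep("input", 2L * spec$n_input_reps),
                rep("output", 2L * spec$n_output_reps)),
      count = c(wt_i, mt_i, wt_o, mt_o), stringsAsFactors = FALSE)
  }
  long <- do.call(rbind, long)
  term <- paste0(long$species, "_", ifelse(long$stage == "input", "i", "o"))
  agg <- tapply(long$count, list(long$variant_id, term), sum, default = 0)
  counts <- data.frame(variant_id = rownames(agg), stringsAsFactors = FALSE)
  for (k in c("mt_i", "mt_o", "wt_i", "wt_o")) counts[[k]] <- unname(agg[, k])
  ord <- match(counts$variant_id, v$variant_id)
  counts$effect <- v$effect[ord]
  counts$true_effect <- theta[ord]
  rownames(counts) <- NULL
  list(counts = counts, replicates = long)
}
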