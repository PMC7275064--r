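#!/usr/bin/env Rscript
# Stage 4: the protein layer. Associate hexamers with the amino-acid
# pairs they encode, compare pair enrichment in a splicing-like proteome
# (translated constrained exons) against an unstructured one, score every
# possible dicodon mutation for its change in enhancer activity by class,
# and enumerate stop-gain fractions -- including the GARGAR/EE case.

suppressMessages(library(premotif))

seed <- 1L
dir.create("results", showWarnings = FALSE)
erm <- read_erm_table("results/inputs/erm.tsv")
scores <- read_score_table("results/inputs/scores.tsv")

genes <- gen_gene_models(synth_spec(seed = seed, n_genes = 30), erm)
cds <- genes$constrained$final

pair_ei <- aa_pair_mean_ei(cds, scores)
write.table(pair_ei, "results/aa_pair_mean_ei.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)

prot <- vapply(cds, premotif:::translate_str, character(1),
               USE.NAMES = FALSE)
prot <- unlist(strsplit(prot, "*", fixed = TRUE))
prot <- prot[nchar(prot) >= 2]
set.seed(seed + 21L)
aa20 <- sort(setdiff(unique(premotif:::aa_by_codon()), "*"))
prot_plain <- vapply(seq_along(prot), function(i)
  paste(sample(aa20, nchar(prot[i]), replace = TRUE), collapse = ""),
  character(1))
pair_enr <- aa_pair_enrichment(prot, prot_plain)
write.table(pair_enr, "results/aa_pair_enrichment.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)

ctx <- dicodon_contexts(cds, max_n = 8000, seed = seed + 22L)
dei <- mutation_delta_ei(ctx, scores, erm)
write.table(dei$by_class, "results/delta_ei_by_class.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)

# stop-gain fraction for every ordered pair, uniform weighting
pairs <- as.vector(outer(aa20, aa20, paste0))
sg <- data.frame(pair = pairs,
                 stop_gain_fraction = vapply(pairs, function(p)
                   stop_gain_fraction(pair = p), numeric(1)))
write.table(sg, "results/stop_gain_fractions.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)

gargar <- stop_gain_fraction(hexamers = c("GAAGAA", "GAAGAG", "GAGGAA",
                                          "GAGGAG"))
ee_ctx <- dicodon_contexts(cds, pair = "EE")
cat(sprintf("GARGAR uniform stop-gain fraction: %.4f (= 1/9)\n", gargar))
if (length(ee_ctx))
  cat(sprintf("EE rate-weighted stop-gain fraction on %d exonic occurrences: %.3f\n", length(ee_ctx),
              stop_gain_fraction(hexamers = codon_pair_hexamers("EE"),
                                 weighting = "erm_context", erm = erm,
                                 contexts = ee_ctx)))
m <- dei$mutations
cls <- tapply(m$delta_ei, m$class, mean)
cat(sprintf("mean delta-EI by class: synonymous %+.4f > missense %+.4f > stop gain %+.4f\n",
            cls[["synonymous"]], cls[["missense"]], cls[["stop_gain"]]))
cat(sprintf("top pair-enrichment contrast: %s (%+.3f)\n",
            pair_enr$pair[which.max(pair_enr$diff)],
            max(pair_enr$diff, na.rm = TRUE)))
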