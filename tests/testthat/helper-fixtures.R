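# Shared fixtures, all built in code at test time.

BASES4 <- c("A", "C", "G", "T")

# every heptamer -> same rate for all three substitutions
uniform_erm <- function(rate = 1) {
  spec <- synth_spec(seed = 1, sigma_log = 0, titv = 1, cpg_mult = 1,
                     gt_purine_mult = 1)
  erm <- gen_erm_table(spec)
  erm$rates[erm$rates > 0] <- rate
  erm
}

# the package's standard synthetic table (study conditions)
default_erm <- function(seed = 7) gen_erm_table(synth_spec(seed = seed))

# deterministic non-uniform toy: rate depends on heptamer index and alt so
# every (heptamer, alt) cell is distinct and reproducible without RNG
toy_erm <- function() {
  erm <- uniform_erm()
  r <- erm$rates
  idx <- seq_len(nrow(r)) - 1L
  for (a in 1:4) {
    pos <- r[, a] > 0
    r[pos, a] <- 0.5 + ((idx[pos] * 13L + a * 7L) %% 97L) / 97
  }
  erm$rates <- r
  erm
}

all_hexamers <- function() {
  g <- expand.grid(rev(replicate(6, BASES4, simplify = FALSE)),
                   stringsAsFactors = FALSE)
  do.call(paste0, rev(g))
}

# independent genetic-code helper for oracles (string-based, via Biostrings)
oracle_translate <- function(codon) {
  as.character(Biostrings::translate(Biostrings::DNAString(codon),
                                     no.init.codon = TRUE))
}

random_dna <- function(n, len) {
  vapply(seq_len(n), function(i)
    paste(sample(BASES4, len, replace = TRUE), collapse = ""), character(1))
}

write_tsv <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}
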