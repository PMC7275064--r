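# Protein-layer analyses: mutation classification under the standard
# genetic code, hexamer -> amino-acid-pair association, pair-level mean
# enhancer activity, proteome pair enrichment, per-class delta-EI, and
# stop-gain fraction enumeration.

MUTATION_CLASSES <- c("synonymous", "missense", "stop_gain")

#' Classify a codon substitution
#'
#' Standard genetic code. A substitution yielding TAA/TAG/TGA is a stop
#' gain; one preserving the amino acid is synonymous; anything else is
#' missense. Input stop codons are rejected (stop-loss is out of scope).
#'
#' @param codon reference 3-mer (not a stop codon); vectorized.
#' @param pos position within the codon, 1..3.
#' @param alt mutant base, different from the reference base at `pos`.
#' @return character vector over `synonymous`, `missense`, `stop_gain`.
#' @export
classify_mutation <- function(codon, pos, alt) {
  n <- max(length(codon), length(pos), length(alt))
  codon <- rep_len(toupper(codon), n)
  pos <- rep_len(as.integer(pos), n)
  alt <- rep_len(toupper(alt), n)
  if (any(!pos %in% 1:3)) stop("pos must be 1..3")
  if (any(codon %in% STOP_CODONS))
    stop("input stop codon (stop-loss out of scope)")
  if (any(substr(codon, pos, pos) == alt))
    stop("alt equals the reference base")
  aa <- aa_by_codon()
  mut <- codon
  substr(mut, pos, pos) <- alt
  out <- rep("missense", n)
  out[mut %in% STOP_CODONS] <- "stop_gain"
  same <- aa[vapply(mut, kmer_index, integer(1), USE.NAMES = FALSE) + 1L] ==
    aa[vapply(codon, kmer_index, integer(1), USE.NAMES = FALSE) + 1L]
  out[same & !(mut %in% STOP_CODONS)] <- "synonymous"
  out
}

#' Amino-acid pair associated with a hexamer occurrence
#'
#' The two codons with the largest overlap with the hexamer in the reading
#' frame. Overlap patterns are 3+3 (in-frame), 2+3+1 and 1+3+2 for the
#' three frame offsets, so the top two codons are always unique.
#'
#' @param seq in-frame coding sequence (frame 0).
#' @param offset 1-based start of the hexamer within `seq`.
#' @return two-letter amino-acid pair (may include `*` if the codons are
#'   stops).
#' @export
hexamer_to_aa_pair <- function(seq, offset) {
  seq <- toupper(seq)
  if (offset < 1L || offset + 5L > nchar(seq))
    stop("hexamer spans a sequence end")
  phase <- (offset - 1L) %% 3L
  # 1-based start of the first of the two most-overlapping codons
  c1 <- if (phase == 0L) offset else
    if (phase == 1L) offset - 1L else offset + 1L
  p1 <- translate_str(substr(seq, c1, c1 + 2L))
  p2 <- translate_str(substr(seq, c1 + 3L, c1 + 5L))
  paste0(p1, p2)
}

#' Occurrence-weighted mean score per amino-acid pair
#'
#' Every in-frame hexamer occurrence (all three frame offsets, step 1)
#' contributes its score to the amino-acid pair it encodes; the pair mean
#' is the occurrence-weighted average. Pairs never observed are absent,
#' occurrences whose hexamer lacks a score are skipped (count reported).
#'
#' @param cds character vector of in-frame coding sequences.
#' @param scores a `score_table`.
#' @return data.frame: `pair`, `mean_score`, `n`; attribute `n_unscored`.
#' @export
aa_pair_mean_ei <- function(cds, scores) {
  stopifnot(inherits(scores, "score_table"))
  cds <- as_seq_chr(cds)
  aa <- aa_by_codon()
  tot <- new.env(parent = emptyenv())
  sums <- numeric(0); cnts <- numeric(0); labels <- character(0)
  acc_sum <- list(); # accumulate per sequence then aggregate
  all_pairs <- character(0); all_scores <- numeric(0)
  n_unscored <- 0L
  for (s in cds) {
    if (nchar(s) %% 3L != 0L) stop("coding sequences must be in frame")
    b <- seq_to_int(s)
    n <- length(b)
    if (n < 6L) next
    hidx <- window_kmer_indices(b, 6L, circular = FALSE)
    offs <- seq_along(hidx)
    sc <- as.numeric(scores)[hidx + 1L]
    # codon index of the dominant pair per offset
    phase <- (offs - 1L) %% 3L
    c1 <- ifelse(phase == 0L, offs, ifelse(phase == 1L, offs - 1L,
                                           offs + 1L))
    ok <- c1 >= 1L & (c1 + 5L) <= n
    cod1 <- (c1 - 1L) %/% 3L + 1L
    codons <- matrix(b, nrow = 3L)
    cidx <- as.integer(codons[1, ] * 16L + codons[2, ] * 4L + codons[3, ])
    pair <- paste0(aa[cidx[cod1[ok]] + 1L], aa[cidx[cod1[ok] + 1L] + 1L])
    sc <- sc[ok]
    drop <- is.na(sc)
    n_unscored <- n_unscored + sum(drop)
    all_pairs <- c(all_pairs, pair[!drop])
    all_scores <- c(all_scores, sc[!drop])
  }
  if (!length(all_pairs)) stop("no scored hexamer occurrences")
  mean_by <- tapply(all_scores, all_pairs, mean)
  n_by <- tapply(all_scores, all_pairs, length)
  out <- data.frame(pair = names(mean_by),
                    mean_score = as.numeric(mean_by),
                    n = as.integer(n_by), stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "n_unscored") <- n_unscored
  out
}

#' Observed/expected enrichment of adjacent amino-acid pairs
#'
#' Ordered-pair frequencies over adjacent positions within each protein
#' (no cross-protein pairs) divided by the product of the single
#' amino-acid frequencies (over all positions). With a second proteome the
#' per-pair difference of ratios is also returned (the splicing-genome
#' versus non-splicing-genome contrast).
#'
#' @param proteome character vector of amino-acid sequences.
#' @param proteome2 optional second proteome for the contrast.
#' @return data.frame over all 400 ordered pairs: `pair`, `ratio` (and
#'   `ratio2`, `diff` with a second proteome). Pairs of amino acids absent
#'   from a proteome get ratio `NA`.
#' @export
aa_pair_enrichment <- function(proteome, proteome2 = NULL) {
  ratios <- function(prot) {
    prot <- toupper(prot)
    if (any(nchar(prot) < 2L)) stop("proteins shorter than 2 residues")
    chars <- strsplit(prot, "", fixed = TRUE)
    all_aa <- unlist(chars)
    f1 <- table(factor(all_aa, levels = LETTERS))
    f1 <- f1 / sum(f1)
    pairs <- unlist(lapply(chars, function(x)
      paste0(x[-length(x)], x[-1])))
    lv <- as.vector(outer(LETTERS, LETTERS, paste0))
    f2 <- table(factor(pairs, levels = lv))
    f2 <- f2 / sum(f2)
    exp2 <- as.numeric(outer(f1, f1))
    r <- ifelse(exp2 > 0, as.numeric(f2) / exp2, NA_real_)
    setNames(r, lv)
  }
  aa20 <- sort(setdiff(unique(aa_by_codon()), "*"))
  lv <- as.vector(outer(aa20, aa20, function(a, b) paste0(a, b)))
  r1 <- ratios(proteome)[lv]
  out <- data.frame(pair = lv, ratio = as.numeric(r1),
                    stringsAsFactors = FALSE)
  if (!is.null(proteome2)) {
    r2 <- ratios(proteome2)[lv]
    out$ratio2 <- as.numeric(r2)
    out$diff <- out$ratio - out$ratio2
  }
  out
}

# All 18 substitutions of a dicodon carried inside a 12-mer context
# (3 nt flank + 6 nt dicodon + 3 nt flank). Internal work-horse for
# mutation_delta_ei and stop_gain_fraction.
dicodon_substitutions <- function(ctx) {
  ctx <- toupper(ctx)
  stopifnot(nchar(ctx) == 12L)
  subs <- list()
  for (i in 4:9) {                        # dicodon positions within ctx
    ref <- substr(ctx, i, i)
    for (alt in setdiff(BASES, ref)) {
      subs[[length(subs) + 1L]] <- list(i = i, ref = ref, alt = alt)
    }
  }
  subs
}

#' Per-mutation change in enhancer score, aggregated by pair and class
#'
#' Each dicodon occurrence is a 12-mer: 3 nt of flanking sequence, the
#' 6 nt dicodon, 3 nt of flank. For each of the 18 possible substitutions
#' the mutation is classified under the genetic code, assigned the two
#' hexamers in which the mutated base sits at position 3 and position 4,
#' and scored as the mean over those two hexamers of (score_mut -
#' score_ref). Its mutability is the ERM rate of the substitution in its
#' heptamer context. Aggregation is the mean over all occurrences per
#' (pair, class).
#'
#' @param contexts character vector of 12-mers whose middle 6 nt are an
#'   in-frame dicodon.
#' @param scores a `score_table` (occurrences hitting unscored hexamers are
#'   skipped; count reported).
#' @param erm an `erm_table`.
#' @return list with `mutations` (one row per context x substitution:
#'   `pair`, `class`, `delta_ei`, `rate`) and `by_class` (mean delta_ei and
#'   mean rate per pair x class); attribute `n_unscored`.
#' @export
mutation_delta_ei <- function(contexts, scores, erm) {
  stopifnot(inherits(scores, "score_table"), inherits(erm, "erm_table"))
  aa <- aa_by_codon()
  sc <- as.numeric(scores)
  rows <- list()
  n_unscored <- 0L
  for (ctx in toupper(contexts)) {
    dic <- substr(ctx, 4L, 9L)
    pair <- paste0(aa[kmer_index(substr(dic, 1, 3)) + 1L],
                   aa[kmer_index(substr(dic, 4, 6)) + 1L])
    for (s in dicodon_substitutions(ctx)) {
      codon_no <- (s$i - 4L) %/% 3L             # 0 or 1
      cod <- substr(ctx, 4L + 3L * codon_no, 6L + 3L * codon_no)
      cls <- classify_mutation(cod, (s$i - 4L) %% 3L + 1L, s$alt)
      mut <- ctx
      substr(mut, s$i, s$i) <- s$alt
      # hexamers with the mutated base at positions 3 and 4
      h3 <- c(substr(ctx, s$i - 2L, s$i + 3L), substr(ctx, s$i - 3L, s$i + 2L))
      h3m <- c(substr(mut, s$i - 2L, s$i + 3L), substr(mut, s$i - 3L, s$i + 2L))
      ei_ref <- sc[vapply(h3, kmer_index, integer(1)) + 1L]
      ei_mut <- sc[vapply(h3m, kmer_index, integer(1)) + 1L]
      if (anyNA(c(ei_ref, ei_mut))) {
        n_unscored <- n_unscored + 1L
        next
      }
      hept <- substr(ctx, s$i - 3L, s$i + 3L)
      rows[[length(rows) + 1L]] <- data.frame(
        pair = pair, class = cls,
        delta_ei = mean(ei_mut - ei_ref),
        rate = erm_rate(erm, hept, s$alt), stringsAsFactors = FALSE)
    }
  }
  if (!length(rows)) stop("no scorable substitutions")
  mut_df <- do.call(rbind, rows)
  key <- interaction(mut_df$pair, mut_df$class, drop = TRUE)
  by_class <- data.frame(
    pair = tapply(mut_df$pair, key, `[`, 1),
    class = tapply(mut_df$class, key, `[`, 1),
    mean_delta_ei = as.numeric(tapply(mut_df$delta_ei, key, mean)),
    mean_rate = as.numeric(tapply(mut_df$rate, key, mean)),
    n = as.integer(tapply(mut_df$rate, key, length)),
    stringsAsFactors = FALSE)
  rownames(by_class) <- NULL
  structure(list(mutations = mut_df, by_class = by_class),
            n_unscored = n_unscored)
}

# sense-codon encodings (as strings) of a single amino acid letter
codons_for_aa <- function(a) {
  aa <- aa_by_codon()
  kmer_strings(3L)[aa == a & aa != "*"]
}

#' Fraction of substitutions in an amino-acid pair that create a stop
#'
#' Uniform weighting counts stop-creating substitutions over all 18
#' substitutions of every codon-pair encoding of the pair (or of a stated
#' hexamer subset such as the GARGAR set). ERM-context weighting uses
#' genomic occurrences with flanking context: per occurrence the rate-
#' weighted stop fraction is computed, then occurrences are averaged
#' equally.
#'
#' @param pair two-letter amino-acid pair (uniform mode; ignored when
#'   `hexamers` given).
#' @param hexamers optional explicit hexamer (dicodon) subset.
#' @param weighting `"uniform"` or `"erm_context"`.
#' @param erm `erm_table`, required for `erm_context`.
#' @param contexts 12-mer occurrence contexts, required for `erm_context`.
#' @return fraction in `[0, 1]`.
#' @export
stop_gain_fraction <- function(pair = NULL, hexamers = NULL,
                               weighting = c("uniform", "erm_context"),
                               erm = NULL, contexts = NULL) {
  weighting <- match.arg(weighting)
  if (is.null(hexamers)) {
    if (is.null(pair)) stop("give a pair or a hexamer set")
    a1 <- codons_for_aa(substr(pair, 1, 1))
    a2 <- codons_for_aa(substr(pair, 2, 2))
    if (!length(a1) || !length(a2))
      stop("pair has no sense-codon encoding: ", pair)
    hexamers <- as.vector(outer(a1, a2, paste0))
  }
  hexamers <- toupper(hexamers)
  if (weighting == "uniform") {
    grid <- expand.grid(h = hexamers, p = 1:6, a = BASES,
                        stringsAsFactors = FALSE)
    grid$ref <- substr(grid$h, grid$p, grid$p)
    grid <- grid[grid$ref != grid$a, ]
    cod <- ifelse(grid$p <= 3, substr(grid$h, 1, 3), substr(grid$h, 4, 6))
    cls <- classify_mutation(cod, (grid$p - 1L) %% 3L + 1L, grid$a)
    return(sum(cls == "stop_gain") / length(cls))
  }
  if (is.null(erm) || is.null(contexts))
    stop("erm_context weighting needs erm and occurrence contexts")
  keep <- substr(toupper(contexts), 4L, 9L) %in% hexamers
  contexts <- contexts[keep]
  if (!length(contexts)) stop("no occurrences of the given hexamer set")
  fracs <- vapply(toupper(contexts), function(ctx) {
    w_stop <- 0; w_all <- 0
    for (s in dicodon_substitutions(ctx)) {
      codon_no <- (s$i - 4L) %/% 3L
      cod <- substr(ctx, 4L + 3L * codon_no, 6L + 3L * codon_no)
      cls <- classify_mutation(cod, (s$i - 4L) %% 3L + 1L, s$alt)
      r <- erm_rate(erm, substr(ctx, s$i - 3L, s$i + 3L), s$alt)
      w_all <- w_all + r
      if (cls == "stop_gain") w_stop <- w_stop + r
    }
    w_stop / w_all
  }, numeric(1), USE.NAMES = FALSE)
  mean(fracs)
}
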