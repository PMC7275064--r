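# Gene-model analytics: splice-site-relative mutability profiles, hexamer
# exon/intron enrichment, and correlation of enrichment with activity-score
# tables.

#' Extract splice-site windows from gene models
#'
#' For every internal splice site, a window reaching `intron_span` nt into
#' the intron and `exon_span` nt into the exon, oriented in transcript
#' direction and carrying 3 nt of genuine genomic context on each side so
#' heptamer contexts at the junction extend into the neighbouring feature.
#' Windows truncated by short exons or introns are kept with their actual
#' spans recorded; duplicate sites shared across isoforms are deduplicated
#' by genomic coordinate.
#'
#' @param models annotation data.frame (see [read_annotation()]).
#' @param seqs `DNAStringSet` of the underlying sequences.
#' @param intron_span nt into the intron (default 300).
#' @param exon_span nt into the exon (default 150).
#' @return data.frame: `transcript`, `side` (`acceptor`/`donor`), genomic
#'   `site` coordinate, actual `intron_len`/`exon_len`, `truncated`, and the
#'   oriented window sequence `seq` (3 nt pad + intron + exon + 3 nt pad for
#'   acceptors; pads swapped for donors).
#' @export
splice_windows <- function(models, seqs, intron_span = 300L,
                           exon_span = 150L) {
  validate_annotation(models, seqs)
  chr <- as_seq_chr(seqs)
  names(chr) <- names(seqs)
  out <- list()
  for (tx in split(models, models$transcript)) {
    tx <- tx[order(tx$rank), ]
    if (nrow(tx) < 2L) next
    strand <- tx$strand[1]
    len_chr <- nchar(chr[[tx$seqname[1]]])
    for (i in seq_len(nrow(tx))) {
      # acceptor: upstream intron -> this exon (skip first exon)
      if (i > 1L) {
        prev <- tx[i - 1L, ]
        intron_len <- if (strand == "+") tx$start[i] - prev$end else
          prev$start - tx$end[i]
        out[[length(out) + 1L]] <- window_row(
          tx[i, ], side = "acceptor", strand = strand,
          intron_len = min(intron_len, intron_span),
          exon_len = min(tx$end[i] - tx$start[i], exon_span),
          intron_span = intron_span, exon_span = exon_span,
          chr = chr[[tx$seqname[1]]], len_chr = len_chr)
      }
      # donor: this exon -> downstream intron (skip last exon)
      if (i < nrow(tx)) {
        nxt <- tx[i + 1L, ]
        intron_len <- if (strand == "+") nxt$start - tx$end[i] else
          tx$start[i] - nxt$end
        out[[length(out) + 1L]] <- window_row(
          tx[i, ], side = "donor", strand = strand,
          intron_len = min(intron_len, intron_span),
          exon_len = min(tx$end[i] - tx$start[i], exon_span),
          intron_span = intron_span, exon_span = exon_span,
          chr = chr[[tx$seqname[1]]], len_chr = len_chr)
      }
    }
  }
  if (!length(out)) stop("no internal splice sites in the annotation")
  df <- do.call(rbind, out)
  df <- df[!duplicated(df[, c("seqname", "strand", "side", "site")]), ]
  rownames(df) <- NULL
  df
}

# Build one splice-window record in transcript orientation.
window_row <- function(exon, side, strand, intron_len, exon_len,
                       intron_span, exon_span, chr, len_chr) {
  # genomic coordinate of the splice site (0-based boundary position)
  fivep <- (side == "acceptor") == (strand == "+")
  site <- if (fivep) {
    if (strand == "+") exon$start else exon$end
  } else {
    if (strand == "+") exon$end else exon$start
  }
  # span in genome coordinates: [site - left, site + right)
  if (strand == "+") {
    left <- if (side == "acceptor") intron_len else exon_len
    right <- if (side == "acceptor") exon_len else intron_len
  } else {
    left <- if (side == "acceptor") exon_len else intron_len
    right <- if (side == "acceptor") intron_len else exon_len
  }
  a <- max(0L, site - left - 3L)
  b <- min(len_chr, site + right + 3L)
  pad_l <- site - left - a          # realized left pad (<= 3)
  pad_r <- b - (site + right)
  s <- substr(chr, a + 1L, b)
  if (strand == "-") {
    s <- revcomp_str(s)
    tmp <- pad_l; pad_l <- pad_r; pad_r <- tmp
  }
  data.frame(transcript = exon$transcript, seqname = exon$seqname,
             strand = strand, side = side, site = site,
             intron_len = intron_len, exon_len = exon_len,
             truncated = intron_len < intron_span | exon_len < exon_span,
             pad_left = pad_l, pad_right = pad_r, seq = s,
             stringsAsFactors = FALSE)
}

#' Mean mutability as a function of distance from the splice site
#'
#' Every window position is assigned the mean rate of its three possible
#' substitutions from the heptamer spanning +/-3 nt (contexts within 3 nt
#' of the junction extend into the neighbouring exon/intron; contexts
#' falling off a window's padded end are dropped). Offsets are negative
#' upstream and positive downstream of the splice site in transcript
#' orientation, with no offset 0: for acceptors, -intron_span..-1 is
#' intronic and 1..exon_span exonic; for donors, -exon_span..-1 exonic and
#' 1..intron_span intronic.
#'
#' @param windows data.frame from [splice_windows()].
#' @param erm an `erm_table`.
#' @return list with `profile` (data.frame side, offset, region,
#'   mean_rate, n) and overall `exon_mean` / `intron_mean` across all
#'   profiled positions.
#' @export
positional_mean_rate <- function(windows, erm) {
  stopifnot(inherits(erm, "erm_table"))
  if (!nrow(windows)) stop("empty window set")
  recs <- vector("list", nrow(windows))
  for (i in seq_len(nrow(windows))) {
    w <- windows[i, ]
    r <- site_rates_all(w$seq, erm, circular = FALSE)
    # strip pads; remaining positions are 1..(left+right) around the site
    body <- r[(w$pad_left + 1L):(length(r) - w$pad_right)]
    left <- if (w$side == "acceptor") w$intron_len else w$exon_len
    right <- if (w$side == "acceptor") w$exon_len else w$intron_len
    offset <- c(seq(-left, -1L), seq_len(right))
    region <- if (w$side == "acceptor")
      rep(c("intron", "exon"), c(left, right)) else
      rep(c("exon", "intron"), c(left, right))
    recs[[i]] <- data.frame(side = w$side, offset = offset, region = region,
                            rate = body, stringsAsFactors = FALSE)
  }
  all <- do.call(rbind, recs)
  all <- all[!is.na(all$rate), ]
  key <- interaction(all$side, all$offset, drop = TRUE)
  prof <- data.frame(
    side = tapply(all$side, key, `[`, 1),
    offset = as.integer(tapply(all$offset, key, `[`, 1)),
    region = tapply(all$region, key, `[`, 1),
    mean_rate = as.numeric(tapply(all$rate, key, mean)),
    n = as.integer(tapply(all$rate, key, length)),
    stringsAsFactors = FALSE)
  prof <- prof[order(prof$side, prof$offset), ]
  rownames(prof) <- NULL
  list(profile = prof,
       exon_mean = mean(all$rate[all$region == "exon"]),
       intron_mean = mean(all$rate[all$region == "intron"]))
}

#' Overlapping k-mer frequencies of a sequence collection
#'
#' Windows step by 1 within each sequence and never span record boundaries;
#' k-mers containing ambiguous bases are skipped. Frequencies are
#' normalized to sum to 1 over the 4^k k-mers.
#'
#' @param seqs `DNAStringSet` or character vector.
#' @param k k-mer width (default 6).
#' @return named numeric vector of length 4^k; attribute `n_windows` gives
#'   the number of counted windows.
#' @export
kmer_frequencies <- function(seqs, k = 6L) {
  if (!methods::is(seqs, "DNAStringSet"))
    seqs <- Biostrings::DNAStringSet(as_seq_chr(seqs))
  if (all(Biostrings::width(seqs) < k))
    stop("all sequences shorter than k = ", k)
  cnt <- colSums(Biostrings::oligonucleotideFrequency(seqs, width = k))
  if (sum(cnt) == 0) stop("no countable ", k, "-mers")
  structure(cnt / sum(cnt), n_windows = sum(cnt))
}

#' Hexamer exon-versus-intron enrichment
#'
#' log2 of the exon frequency over the intron frequency of each hexamer,
#' each frequency shifted by a pseudo-frequency (default: one pseudo-window
#' per collection, i.e. 1 / number of counted windows) so enrichments stay
#' finite. Positive values mark exon-enriched (ESE-like), negative
#' intron-enriched (ISE-like) motifs.
#'
#' @param exon_seqs,intron_seqs sequence collections.
#' @param pseudo pseudo-frequency; `NULL` (default) uses 1/n_windows of the
#'   respective collection.
#' @return data.frame: `hexamer`, `f_exon`, `f_intron`, `enrichment`
#'   (log2).
#' @export
exon_intron_enrichment <- function(exon_seqs, intron_seqs, pseudo = NULL) {
  fe <- kmer_frequencies(exon_seqs, 6L)
  fi <- kmer_frequencies(intron_seqs, 6L)
  pe <- if (is.null(pseudo)) 1 / attr(fe, "n_windows") else pseudo
  pi_ <- if (is.null(pseudo)) 1 / attr(fi, "n_windows") else pseudo
  data.frame(hexamer = names(fe), f_exon = as.numeric(fe),
             f_intron = as.numeric(fi),
             enrichment = log2((as.numeric(fe) + pe) /
                                 (as.numeric(fi) + pi_)),
             stringsAsFactors = FALSE)
}

#' Correlate motif enrichment with an activity-score table
#'
#' Pearson correlation across the hexamers present in both tables, with an
#' option to exclude the 1023 hexamers containing a CG dinucleotide (the
#' CpG-free reanalysis).
#'
#' @param enrich data.frame from [exon_intron_enrichment()] (or any with
#'   `hexamer` and `enrichment` columns).
#' @param scores a `score_table`.
#' @param exclude_cpg drop hexamers containing "CG".
#' @return list: `r`, `r2`, `slope_sign`, `n`, `p_value`.
#' @export
correlate_scores <- function(enrich, scores, exclude_cpg = FALSE) {
  stopifnot(inherits(scores, "score_table"))
  s <- scores[enrich$hexamer]
  keep <- !is.na(s) & is.finite(enrich$enrichment)
  if (exclude_cpg) keep <- keep & !grepl("CG", enrich$hexamer, fixed = TRUE)
  x <- as.numeric(s[keep]); y <- enrich$enrichment[keep]
  if (sum(keep) < 3L) stop("fewer than 3 common hexamers")
  if (sd(x) == 0 || sd(y) == 0) stop("degenerate (constant) input")
  ct <- cor.test(x, y)
  list(r = unname(ct$estimate), r2 = unname(ct$estimate)^2,
       slope_sign = sign(unname(ct$estimate)), n = sum(keep),
       p_value = ct$p.value)
}
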