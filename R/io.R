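# Readers and writers for every on-disk format the analyses touch.
#
# Conventions: all tables are tab-delimited with a header row and '.' for
# missing values; coordinates are normalized at the I/O edge to 0-based
# half-open intervals in transcript orientation and stay that way everywhere
# downstream; rates and scores round-trip bit-exactly (written with 17
# significant digits).

N_HEPTAMERS <- 16384L
N_HEXAMERS  <- 4096L

#' Read a heptamer relative-mutation-rate (ERM) table
#'
#' The table maps each of the 16384 heptamers to three relative rates, one
#' per possible substitution of the middle base. A complete table is
#' required: every heptamer must carry exactly its three alternate alleles.
#'
#' @param path TSV with columns `heptamer` (7-mer over ACGT), `alt`
#'   (single base, different from the heptamer's middle base) and `rate`
#'   (positive real).
#' @return An `erm_table`: a 16384 x 4 numeric matrix of rates indexed by
#'   heptamer index and alternate base, zero on the reference-base column.
#' @export
read_erm_table <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE, na.strings = c(".", "NA"))
  need <- c("heptamer", "alt", "rate")
  if (!all(need %in% names(df)))
    stop("ERM table must have columns: ", paste(need, collapse = ", "))
  df$heptamer <- toupper(df$heptamer)
  df$alt <- toupper(df$alt)
  if (any(nchar(df$heptamer) != 7L) || any(grepl("[^ACGT]", df$heptamer)))
    stop("heptamers must be 7-mers over ACGT")
  if (any(!df$alt %in% BASES))
    stop("alt must be a single base over ACGT")
  mid <- substr(df$heptamer, 4L, 4L)
  bad <- df$alt == mid
  if (any(bad))
    stop("alt equals the middle reference base for ",
         sum(bad), " rows (first: ", df$heptamer[which(bad)[1]], ">",
         df$alt[which(bad)[1]], "); a substitution to self is invalid")
  if (!is.numeric(df$rate) || anyNA(df$rate) || any(df$rate <= 0))
    stop("rates must be positive reals with no missing entries")
  key <- paste(df$heptamer, df$alt)
  if (anyDuplicated(key))
    stop("duplicate (heptamer, alt) rows: ",
         paste(head(unique(key[duplicated(key)]), 5), collapse = ", "))
  hidx <- vapply(df$heptamer, kmer_index, integer(1), USE.NAMES = FALSE)
  aidx <- match(df$alt, BASES)
  rates <- matrix(0, nrow = N_HEPTAMERS, ncol = 4L,
                  dimnames = list(NULL, BASES))
  rates[cbind(hidx + 1L, aidx)] <- df$rate
  tab <- new_erm_table(rates)
  missing <- erm_missing_keys(tab)
  if (length(missing))
    stop("incomplete ERM table: ", length(missing),
         " (heptamer, alt) keys absent (first: ",
         paste(head(missing, 5), collapse = ", "), ")")
  tab
}

new_erm_table <- function(rates) {
  structure(list(rates = rates), class = "erm_table")
}

# Keys whose rate is unset (== 0) excluding the reference-base cells.
erm_missing_keys <- function(erm) {
  rates <- erm$rates
  hept <- kmer_strings(7L)
  mid <- match(substr(hept, 4L, 4L), BASES)
  out <- character(0)
  for (a in 1:4) {
    miss <- which(rates[, a] == 0 & mid != a)
    if (length(miss))
      out <- c(out, paste(hept[miss], BASES[a]))
  }
  out
}

#' Write an ERM table (bit-exact round trip with [read_erm_table()])
#' @param erm an `erm_table`.
#' @param path output TSV path.
#' @export
write_erm_table <- function(erm, path) {
  stopifnot(inherits(erm, "erm_table"))
  hept <- kmer_strings(7L)
  mid <- match(substr(hept, 4L, 4L), BASES)
  rows <- lapply(1:4, function(a) {
    keep <- mid != a
    data.frame(heptamer = hept[keep], alt = BASES[a],
               rate = erm$rates[keep, a], stringsAsFactors = FALSE)
  })
  df <- do.call(rbind, rows)
  df <- df[order(df$heptamer, df$alt), ]
  df$rate <- sprintf("%.17g", df$rate)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Look up ERM rates for (heptamer, alt) pairs
#' @param erm an `erm_table`.
#' @param heptamer character vector of 7-mers.
#' @param alt character vector of single bases (recycled), each different
#'   from the corresponding middle base.
#' @return numeric vector of rates.
#' @export
erm_rate <- function(erm, heptamer, alt) {
  stopifnot(inherits(erm, "erm_table"))
  n <- max(length(heptamer), length(alt))
  heptamer <- rep_len(toupper(heptamer), n)
  alt <- rep_len(toupper(alt), n)
  if (any(alt == substr(heptamer, 4L, 4L)))
    stop("alt equals the middle reference base")
  hidx <- vapply(heptamer, kmer_index, integer(1), USE.NAMES = FALSE)
  erm$rates[cbind(hidx + 1L, match(alt, BASES))]
}

#' @export
print.erm_table <- function(x, ...) {
  r <- x$rates[x$rates > 0]
  cat("erm_table: 16384 heptamers x 3 substitutions\n")
  cat(sprintf("  rate range: %.4g .. %.4g (%.0f-fold)\n",
              min(r), max(r), max(r) / min(r)))
  invisible(x)
}

#' Read a hexamer score table (e.g. splicing-enhancer activity scores)
#'
#' Partial tables are allowed; hexamers absent from the file are explicit
#' `NA`s in the returned vector and their count is attached as an attribute.
#'
#' @param path TSV with columns `hexamer` and `score`.
#' @return A `score_table`: named numeric vector of length 4096 in hexamer
#'   index order, `NA` where absent, with attribute `n_absent`.
#' @export
read_score_table <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE, na.strings = c(".", "NA"),
                   colClasses = "character")
  if (!all(c("hexamer", "score") %in% names(df)))
    stop("score table must have columns: hexamer, score")
  df$hexamer <- toupper(df$hexamer)
  if (any(nchar(df$hexamer) != 6L) || any(grepl("[^ACGT]", df$hexamer)))
    stop("hexamers must be 6-mers over ACGT")
  if (anyDuplicated(df$hexamer))
    stop("duplicate hexamers: ",
         paste(head(unique(df$hexamer[duplicated(df$hexamer)]), 5),
               collapse = ", "))
  sc <- suppressWarnings(as.numeric(df$score))
  bad <- which(is.na(sc) & !is.na(df$score))
  if (length(bad))
    stop("non-numeric score at row ", bad[1],
         " (hexamer ", df$hexamer[bad[1]], ": '", df$score[bad[1]], "')")
  out <- setNames(rep(NA_real_, N_HEXAMERS), kmer_strings(6L))
  out[df$hexamer] <- sc
  new_score_table(out)
}

new_score_table <- function(x) {
  stopifnot(length(x) == N_HEXAMERS)
  structure(x, n_absent = sum(is.na(x)), class = "score_table")
}

#' Write a score table (bit-exact round trip); absent hexamers are omitted
#' @param scores a `score_table`.
#' @param path output TSV path.
#' @export
write_score_table <- function(scores, path) {
  stopifnot(inherits(scores, "score_table"))
  keep <- !is.na(scores)
  df <- data.frame(hexamer = names(scores)[keep],
                   score = sprintf("%.17g", scores[keep]))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @export
print.score_table <- function(x, ...) {
  cat(sprintf("score_table: %d of 4096 hexamers scored (%d absent)\n",
              sum(!is.na(x)), attr(x, "n_absent")))
  invisible(x)
}

#' Read sequences from FASTA
#' @param path FASTA file.
#' @return `DNAStringSet`.
#' @export
read_sequences <- function(path) Biostrings::readDNAStringSet(path)

#' Write sequences to FASTA
#' @param seqs `DNAStringSet` or named character vector.
#' @param path output path.
#' @export
write_sequences <- function(seqs, path) {
  if (!methods::is(seqs, "DNAStringSet"))
    seqs <- Biostrings::DNAStringSet(seqs)
  Biostrings::writeXStringSet(seqs, path)
  invisible(path)
}

#' Read exon annotation from GTF or BED
#'
#' GTF exon rows (1-based closed) and BED rows (0-based half-open; the
#' `name` column is taken as the transcript id) are both normalized to the
#' internal convention: 0-based half-open genomic intervals plus an exon
#' rank in transcript orientation (rank 1 is the 5'-most exon of the
#' transcript, so minus-strand transcripts rank right-to-left).
#'
#' @param path file ending in `.gtf` or `.bed`.
#' @return data.frame with columns `transcript`, `seqname`, `start`, `end`
#'   (0-based half-open), `strand`, `rank`.
#' @export
read_annotation <- function(path) {
  fmt <- tolower(tools::file_ext(path))
  if (!fmt %in% c("gtf", "bed"))
    stop("annotation must be .gtf or .bed, got: ", path)
  gr <- rtracklayer::import(path, format = fmt)
  if (fmt == "gtf") {
    gr <- gr[!is.na(gr$type) & gr$type == "exon"]
    tx <- as.character(gr$transcript_id)
  } else {
    tx <- as.character(gr$name)
  }
  if (length(gr) == 0) stop("no exon records in ", path)
  df <- data.frame(
    transcript = tx,
    seqname = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,  # to 0-based half-open
    end = GenomicRanges::end(gr),
    strand = as.character(GenomicRanges::strand(gr)),
    stringsAsFactors = FALSE
  )
  if (any(!df$strand %in% c("+", "-")))
    stop("exons must have explicit strand")
  df <- df[order(df$transcript, df$start), ]
  # overlap check within transcript (sorted by start: overlap iff a start
  # precedes the previous end)
  by_tx <- split(df, df$transcript)
  for (tx1 in by_tx) {
    if (nrow(tx1) > 1 && any(tx1$start[-1] < tx1$end[-nrow(tx1)]))
      stop("overlapping exons within transcript ", tx1$transcript[1])
  }
  df <- do.call(rbind, lapply(by_tx, function(tx1) {
    tx1$rank <- if (tx1$strand[1] == "+") seq_len(nrow(tx1)) else
      rev(seq_len(nrow(tx1)))
    tx1
  }))
  rownames(df) <- NULL
  df[order(df$transcript, df$rank), ]
}

#' Write exon annotation as BED (0-based half-open; name = transcript)
#' @param models annotation data.frame as from [read_annotation()].
#' @param path output `.bed` path.
#' @export
write_annotation <- function(models, path) {
  df <- models[order(models$seqname, models$start), ]
  out <- data.frame(df$seqname, df$start, df$end, df$transcript, 0L,
                    df$strand)
  write.table(out, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Check that annotated exons fall inside their sequences
#' @param models annotation data.frame.
#' @param seqs `DNAStringSet` (names matching `seqname`).
#' @export
validate_annotation <- function(models, seqs) {
  lens <- setNames(Biostrings::width(seqs), names(seqs))
  if (any(!models$seqname %in% names(lens)))
    stop("annotation references sequences absent from FASTA: ",
         paste(head(setdiff(models$seqname, names(lens)), 3), collapse = ", "))
  bad <- models$start < 0 | models$end > lens[models$seqname]
  if (any(bad))
    stop("exons outside sequence bounds: ",
         paste(head(models$transcript[bad], 3), collapse = ", "))
  invisible(TRUE)
}

#' Extract transcript-oriented exon sequence
#'
#' Minus-strand exons are reverse-complemented so all downstream k-mer work
#' is in transcript orientation.
#' @param models annotation data.frame.
#' @param seqs `DNAStringSet`.
#' @return character vector of exon sequences, one per annotation row.
#' @export
exon_sequences <- function(models, seqs) {
  validate_annotation(models, seqs)
  chr <- as_seq_chr(seqs)
  names(chr) <- names(seqs)
  out <- substr(rep(chr[models$seqname], 1L),
                models$start + 1L, models$end)
  flip <- models$strand == "-"
  out[flip] <- vapply(out[flip], revcomp_str, character(1), USE.NAMES = FALSE)
  unname(out)
}

VARIANT_EFFECTS <- c("intronic", "synonymous", "missense", "stop_gain",
                     "splice_region")

#' Read a variant table
#'
#' @param path TSV with columns `variant_id`, `heptamer` (reference-oriented
#'   context, middle base = ref), `ref`, `alt`, `effect` (one of intronic,
#'   synonymous, missense, stop_gain, splice_region), `daf` (derived allele
#'   frequency, '.' when absent) and optional `exon_dist` (0-based distance
#'   to the nearest exon boundary, '.' when not applicable).
#' @return data.frame of validated variant records.
#' @export
read_variant_table <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE, na.strings = c(".", "NA"))
  need <- c("variant_id", "heptamer", "ref", "alt", "effect", "daf")
  if (!all(need %in% names(df)))
    stop("variant table must have columns: ", paste(need, collapse = ", "))
  df$heptamer <- toupper(df$heptamer)
  df$ref <- toupper(df$ref); df$alt <- toupper(df$alt)
  if (any(df$alt == df$ref)) stop("alt must differ from ref")
  if (any(substr(df$heptamer, 4L, 4L) != df$ref))
    stop("heptamer middle base must equal ref")
  if (any(!df$effect %in% VARIANT_EFFECTS))
    stop("unknown effect class: ",
         paste(head(setdiff(df$effect, VARIANT_EFFECTS), 3), collapse = ", "))
  if (any(!is.na(df$daf) & (df$daf < 0 | df$daf > 1)))
    stop("daf must lie in [0, 1]")
  if (!"exon_dist" %in% names(df)) df$exon_dist <- NA_integer_
  df
}

#' Read a splicing-assay count table
#'
#' Long format, one row per (variant, replicate, species, stage); counts are
#' summed over replicates per species/stage into the four terms of the M/W
#' splice ratio, with the per-replicate breakdown retained as an attribute.
#'
#' @param path TSV with columns `variant_id`, `replicate`, `species`
#'   (`mt`/`wt`), `stage` (`input`/`output`), `count`.
#' @return data.frame with columns `variant_id`, `mt_i`, `mt_o`, `wt_i`,
#'   `wt_o`; attribute `replicates` holds the long table.
#' @export
read_assay_counts <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE, na.strings = c(".", "NA"))
  need <- c("variant_id", "replicate", "species", "stage", "count")
  if (!all(need %in% names(df)))
    stop("count table must have columns: ", paste(need, collapse = ", "))
  if (any(!df$species %in% c("mt", "wt"))) stop("species must be mt or wt")
  if (any(!df$stage %in% c("input", "output")))
    stop("stage must be input or output")
  if (any(df$count < 0)) stop("counts must be nonnegative")
  term <- paste0(df$species, "_", ifelse(df$stage == "input", "i", "o"))
  agg <- tapply(df$count, list(df$variant_id, term), sum, default = 0)
  out <- data.frame(variant_id = rownames(agg), stringsAsFactors = FALSE)
  for (k in c("mt_i", "mt_o", "wt_i", "wt_o"))
    out[[k]] <- if (k %in% colnames(agg)) unname(agg[, k]) else 0
  rownames(out) <- NULL
  attr(out, "replicates") <- df
  out
}

#' Read a YAML run configuration
#'
#' A `seed` is mandatory so that every stochastic run is fully determined;
#' optional inputs stay `NULL` explicitly rather than being silently
#' defaulted.
#' @param path YAML file.
#' @return named list with class `run_config`.
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg$seed)) stop("run configuration must set a seed")
  cfg$seed <- as.integer(cfg$seed)
  known <- c("seed", "erm", "scores", "fasta", "annotation", "variants",
             "counts", "out_prefix", "log_level")
  for (k in setdiff(known, names(cfg))) cfg[k] <- list(NULL)
  if (is.null(cfg$log_level)) cfg$log_level <- "info"
  structure(cfg, class = "run_config")
}
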