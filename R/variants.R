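# Variant-level statistics: allelic splice ratios from pooled reporter
# assays, splice-region classification, group comparisons, and mean
# mutability by effect class and derived-allele-frequency bin.

#' Mutant/wild-type splice ratio
#'
#' `log2((mt_o/mt_i) / (wt_o/wt_i))`: the mutant output/input odds over
#' the wild-type output/input odds, counts summed over replicates.
#' Negative values mean the mutation disrupts splicing. With the default
#' pseudocount of 0 a zero term is an error (replicate sums make zeros
#' rare in practice); a small pseudocount (e.g. 0.5) is added to all four
#' terms when requested.
#'
#' @param counts data.frame with columns `mt_o`, `mt_i`, `wt_o`, `wt_i`
#'   (as from [read_assay_counts()]); extra columns are carried through.
#' @param pseudocount nonnegative value added to each term (default 0).
#' @return numeric vector of log2 ratios (one per row).
#' @export
mw_splice_ratio <- function(counts, pseudocount = 0) {
  stopifnot(pseudocount >= 0)
  need <- c("mt_o", "mt_i", "wt_o", "wt_i")
  if (is.numeric(counts) && length(counts) == 4L && !is.null(names(counts)))
    counts <- as.data.frame(as.list(counts))
  if (!all(need %in% names(counts)))
    stop("counts must have columns ", paste(need, collapse = ", "))
  m <- as.matrix(counts[, need]) + pseudocount
  if (any(m <= 0))
    stop("zero count term with pseudocount ", pseudocount,
         "; ratio undefined for row(s) ",
         paste(head(which(apply(m <= 0, 1, any)), 5), collapse = ", "))
  unname(log2((m[, "mt_o"] / m[, "mt_i"]) / (m[, "wt_o"] / m[, "wt_i"])))
}

#' Is a variant in the exonic splice-site region?
#'
#' TRUE iff the variant lies within the first or final 3 nucleotides of
#' its exon.
#'
#' @param pos 0-based genomic position(s) of the variant.
#' @param exon_start,exon_end exon interval, 0-based half-open.
#' @return logical vector.
#' @export
classify_splice_region <- function(pos, exon_start, exon_end) {
  if (any(pos < exon_start | pos >= exon_end))
    stop("variant outside the exon; flag intronic variants separately")
  (pos - exon_start < 3L) | (exon_end - pos <= 3L)
}

#' Compare splice-disruption measures across mutation-effect classes
#'
#' Group medians and quartiles plus pairwise two-sided Mann-Whitney
#' (Wilcoxon rank-sum) tests between all nonempty class pairs.
#'
#' @param values per-variant splice measures (e.g. log2 M/W ratios).
#' @param classes parallel vector of effect classes.
#' @return list with `summary` (class, n, median, q1, q3) and `pairwise`
#'   (class_a, class_b, p_value).
#' @export
effect_class_comparison <- function(values, classes) {
  stopifnot(length(values) == length(classes))
  keep <- !is.na(values) & !is.na(classes)
  values <- values[keep]; classes <- as.character(classes[keep])
  groups <- split(values, classes)
  groups <- groups[lengths(groups) > 0]
  if (length(groups) < 2L)
    stop("need at least two nonempty effect classes")
  summ <- data.frame(
    class = names(groups), n = lengths(groups),
    median = vapply(groups, median, numeric(1)),
    q1 = vapply(groups, function(g) unname(quantile(g, 0.25)), numeric(1)),
    q3 = vapply(groups, function(g) unname(quantile(g, 0.75)), numeric(1)),
    stringsAsFactors = FALSE)
  rownames(summ) <- NULL
  cmb <- utils::combn(names(groups), 2)
  pw <- data.frame(
    class_a = cmb[1, ], class_b = cmb[2, ],
    p_value = apply(cmb, 2, function(ab)
      suppressWarnings(wilcox.test(groups[[ab[1]]], groups[[ab[2]]],
                                   alternative = "two.sided")$p.value)),
    stringsAsFactors = FALSE)
  list(summary = summ, pairwise = pw)
}

#' Mean mutability of variants by effect class and DAF bin
#'
#' Variants with missing derived-allele frequency, extremely rare variants
#' (DAF below `min_daf`, whose frequency spectrum is dominated by
#' recurrent mutation), and effects outside
#' intronic/synonymous/missense/stop_gain are removed; removal counts are
#' reported. Each remaining variant gets the ERM rate of its ancestral to
#' derived change in its heptamer context, and means are taken per effect
#' class x DAF bin.
#'
#' @param variants data.frame from [read_variant_table()].
#' @param erm an `erm_table`.
#' @param breaks DAF bin edges (default log10-spaced
#'   5e-5, 1e-4, 1e-3, 1e-2, 1e-1, 1).
#' @param min_daf lower DAF cutoff (default 5e-5).
#' @return list with `bins` (effect, bin, n, mean_rate; empty bins absent)
#'   and `removed` (named counts: missing_daf, rare, effect).
#' @export
daf_bin_mean_rate <- function(variants, erm,
                              breaks = c(5e-5, 1e-4, 1e-3, 1e-2, 1e-1, 1),
                              min_daf = 5e-5) {
  stopifnot(inherits(erm, "erm_table"))
  v <- variants
  removed <- c(missing_daf = sum(is.na(v$daf)))
  v <- v[!is.na(v$daf), ]
  removed["rare"] <- sum(v$daf < min_daf)
  v <- v[v$daf >= min_daf, ]
  in_scope <- v$effect %in% c("intronic", "synonymous", "missense",
                              "stop_gain")
  removed["effect"] <- sum(!in_scope)
  v <- v[in_scope, ]
  if (!nrow(v)) stop("no variants left after filtering")
  v$rate <- erm_rate(erm, v$heptamer, v$alt)
  v$bin <- cut(v$daf, breaks, include.lowest = TRUE, right = FALSE)
  key <- interaction(v$effect, v$bin, drop = TRUE)
  bins <- data.frame(
    effect = tapply(v$effect, key, `[`, 1),
    bin = tapply(as.character(v$bin), key, `[`, 1),
    n = as.integer(tapply(v$rate, key, length)),
    mean_rate = as.numeric(tapply(v$rate, key, mean)),
    stringsAsFactors = FALSE)
  rownames(bins) <- NULL
  bins <- bins[order(bins$effect, bins$bin), ]
  list(bins = bins, removed = removed)
}
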