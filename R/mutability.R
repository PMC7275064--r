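# ERM-rate arithmetic: site-level rates, hexamer-level mean rates, bias
# rescaling, rankings and quintiles.

#' Mean relative mutation rate at sequence positions
#'
#' Each position is assigned the arithmetic mean of the three possible
#' single-nucleotide change rates given its current heptamer (+/-3 nt)
#' context. On a circular sequence the context wraps; on a linear sequence
#' positions within 3 nt of either end have no full context and raise an
#' error (callers that have flanking sequence should pass it in).
#'
#' @param seq single DNA string over ACGT (may contain N; such contexts
#'   yield `NA`).
#' @param pos 1-based position(s).
#' @param erm an `erm_table`.
#' @param circular treat `seq` as circular.
#' @return numeric vector of per-position mean rates.
#' @export
site_rate <- function(seq, pos, erm, circular = FALSE) {
  stopifnot(inherits(erm, "erm_table"))
  b <- seq_to_int(seq)
  n <- length(b)
  if (n < 7L && !circular)
    stop("sequence too short (", n, " nt) for heptamer context")
  if (!circular && any(pos < 4L | pos > n - 3L))
    stop("no full heptamer context at positions within 3 nt of a linear ",
         "sequence end")
  rs <- rowSums(erm$rates)
  vapply(pos, function(p) {
    off <- (p - 4L):(p + 2L)        # 0-based positions of the heptamer
    if (circular) off <- off %% n
    h <- b[off + 1L]
    if (anyNA(h)) return(NA_real_)
    idx <- sum(h * 4L^(6:0)) + 1L
    rs[idx] / 3
  }, numeric(1))
}

# Vectorized site rates along one sequence; NA where no full context or an
# ambiguous base intrudes. Positions are 1..nchar(seq).
site_rates_all <- function(seq, erm, circular = FALSE) {
  b <- seq_to_int(seq)
  n <- length(b)
  idx <- window_kmer_indices(b, 7L, circular = circular)
  rs <- rowSums(erm$rates) / 3
  r <- rep(NA_real_, n)
  val <- ifelse(is.na(idx), NA_real_, rs[idx + 1L])
  if (circular) {
    # window j covers middle position j+3 (wrapped)
    r[((seq_len(n) + 2L) %% n) + 1L] <- val
  } else {
    r[4:(n - 3L)] <- val
  }
  r
}

#' Hexamer-level mean rates under uniform flanking contexts
#'
#' For each hexamer, the mean of the heptamer-level rates over all 18
#' possible single-nucleotide changes (3 per position), averaging uniformly
#' over the unknown flanking bases needed to complete each heptamer
#' (NNN\[hexamer\]NNN with each N worth 1/4 per base).
#'
#' @param erm a complete `erm_table`.
#' @return data.frame with columns `hexamer` and `mean_rate` for all 4096
#'   hexamers in index order.
#' @export
hexamer_mean_rates <- function(erm) {
  stopifnot(inherits(erm, "erm_table"))
  rs <- rowSums(erm$rates)             # sum of the 3 alternate rates
  hex <- 0:(N_HEXAMERS - 1L)
  digits <- sapply(0:5, function(p) (hex %/% 4L^(5L - p)) %% 4L)  # 4096 x 6
  total <- numeric(N_HEXAMERS)
  for (p in 0:5) {                     # mutated hexamer position
    span <- (p - 3L):(p + 3L)          # hexamer coordinates of the heptamer
    known <- span >= 0L & span <= 5L
    w7 <- 4L^(6:0)
    base_idx <- as.numeric(digits[, span[known] + 1L, drop = FALSE] %*%
                             w7[known])
    m <- sum(!known)                   # flanking bases to enumerate
    flank_pos <- which(!known)
    acc <- numeric(N_HEXAMERS)
    for (u in 0:(4L^m - 1L)) {
      fi <- 0
      uu <- u
      for (j in seq_len(m)) {
        fi <- fi + (uu %% 4L) * w7[flank_pos[j]]
        uu <- uu %/% 4L
      }
      acc <- acc + rs[base_idx + fi + 1L]
    }
    total <- total + acc / 4L^m
  }
  data.frame(hexamer = kmer_strings(6L), mean_rate = total / 18,
             stringsAsFactors = FALSE)
}

#' Rescale mutational bias
#'
#' Log-transforms every rate, multiplies by `beta`, and inverse-transforms:
#' each rate r becomes r^beta. `beta = 1` returns the original spectrum,
#' `beta = 0` uniform rates; rank order is preserved for `beta > 0` and the
#' dynamic range is tuned by the single parameter.
#'
#' @param erm an `erm_table`.
#' @param beta nonnegative bias parameter.
#' @return rescaled `erm_table`.
#' @export
rescale_bias <- function(erm, beta) {
  stopifnot(inherits(erm, "erm_table"))
  if (!is.numeric(beta) || length(beta) != 1L || beta < 0)
    stop("beta must be a single nonnegative number")
  rates <- erm$rates
  pos <- rates > 0
  rates[pos] <- rates[pos]^beta
  new_erm_table(rates)
}

#' Rank hexamers by mean mutability and assign quintiles
#'
#' Descending mean-rate order with lexicographic tie-break; quintile 5 is
#' the most mutable fifth. 4096 hexamers split into groups of 820, 819,
#' 819, 819, 819 (boundaries after ranks 820/1639/2458/3277).
#'
#' @param hex_rates data.frame from [hexamer_mean_rates()].
#' @return the input ordered by descending rate with added `rank` (1 = most
#'   mutable) and `quintile` (5 = most mutable fifth) columns.
#' @export
rank_hexamers <- function(hex_rates) {
  stopifnot(all(c("hexamer", "mean_rate") %in% names(hex_rates)))
  o <- order(-hex_rates$mean_rate, hex_rates$hexamer)
  out <- hex_rates[o, , drop = FALSE]
  out$rank <- seq_len(nrow(out))
  n <- nrow(out)
  edges <- if (n == N_HEXAMERS) c(0, 820, 1639, 2458, 3277, n) else
    round(seq(0, n, length.out = 6))
  out$quintile <- 6L - as.integer(cut(out$rank, edges, right = TRUE))
  rownames(out) <- NULL
  out
}
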