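# Mutation-selection simulator: circular sequences evolved one substitution
# at a time, position and allele drawn proportional to context-dependent
# rates, optionally constrained to preserve the encoded protein. Time is
# measured in accepted substitutions per base (tau).

#' Simulation configuration
#'
#' @param n_sequences number of circular sequences (study default 5000).
#' @param seq_length length of each sequence in nt (study default 999;
#'   must be a multiple of 3 under protein constraint so the fixed frame-0
#'   reading frame tiles the circle).
#' @param constraint `"none"` (neutral drift) or `"protein"` (any proposal
#'   that changes the translation or creates a stop codon is rejected and
#'   redrawn).
#' @param beta mutational bias exponent applied to the rate table (see
#'   [rescale_bias()]).
#' @param record_interval recording cadence in mutations per base (default
#'   0.2).
#' @param t_max end time in mutations per base (study default 10).
#' @param seed integer seed; fully determines the run.
#' @param init `"random_uniform"` or `"from_fasta"`.
#' @param init_fasta FASTA path when `init = "from_fasta"`.
#' @return a `sim_config` list.
#' @export
sim_config <- function(n_sequences = 5000L, seq_length = 999L,
                       constraint = c("none", "protein"), beta = 1,
                       record_interval = 0.2, t_max = 10, seed = 1L,
                       init = c("random_uniform", "from_fasta"),
                       init_fasta = NULL) {
  constraint <- match.arg(constraint)
  init <- match.arg(init)
  if (constraint == "protein" && seq_length %% 3L != 0L)
    stop("seq_length must be a multiple of 3 under protein constraint")
  if (!(t_max >= record_interval && record_interval > 0))
    stop("need t_max >= record_interval > 0")
  if (init == "from_fasta" && is.null(init_fasta))
    stop("init = 'from_fasta' needs init_fasta")
  structure(list(n_sequences = as.integer(n_sequences),
                 seq_length = as.integer(seq_length),
                 constraint = constraint, beta = beta,
                 record_interval = record_interval, t_max = t_max,
                 seed = as.integer(seed), init = init,
                 init_fasta = init_fasta),
            class = "sim_config")
}

# amino-acid ids per codon index (0..63); stop = -1
aa_codes <- function() {
  aa <- aa_by_codon()
  ifelse(aa == "*", -1L, match(aa, LETTERS))
}

#' Initialize a simulation genome
#'
#' Random initialization draws iid uniform ACGT bases. FASTA initialization
#' trims each sequence to a multiple of 3 and, under protein constraint,
#' rejects sequences containing a stop codon in frame 0. The reference
#' translation is stored for the constraint invariant.
#'
#' @param config a [sim_config()].
#' @return a `sim_genome`: list with integer-coded `seqs`, `lengths`, and
#'   `ref_translation` (frame 0, `*` = stop).
#' @export
init_genome <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  if (config$init == "random_uniform") {
    set.seed(config$seed)
    seqs <- lapply(seq_len(config$n_sequences), function(i)
      sample.int(4L, config$seq_length, replace = TRUE) - 1L)
  } else {
    fa <- as_seq_chr(read_sequences(config$init_fasta))
    if (any(grepl("[^ACGT]", fa)))
      stop("FASTA initialization requires pure ACGT sequences")
    fa <- substr(fa, 1L, nchar(fa) - nchar(fa) %% 3L)
    if (any(nchar(fa) < 6L)) stop("initial sequences shorter than 6 nt")
    if (config$constraint == "protein") {
      has_stop <- vapply(fa, function(s) grepl("*", translate_str(s),
                                               fixed = TRUE), logical(1))
      if (any(has_stop))
        stop("sequence(s) with internal stop codon under protein ",
             "constraint: ", paste(head(which(has_stop), 3), collapse = ", "))
    }
    seqs <- lapply(fa, seq_to_int)
  }
  trans <- vapply(seqs, function(b) translate_str(int_to_seq(b)), character(1),
                  USE.NAMES = FALSE)
  structure(list(seqs = seqs, lengths = lengths(seqs),
                 ref_translation = trans), class = "sim_genome")
}

#' Is a single-base substitution acceptable under protein constraint?
#'
#' The rule applied at every simulation step: a mutant allele is introduced
#' only if it leaves the amino acid unchanged and the mutated codon is not
#' a stop. (A codon that is already a stop therefore admits no change.)
#'
#' @param codon 3-mer reference codon.
#' @param pos position within the codon, 1..3.
#' @param alt mutant base.
#' @return logical.
#' @export
substitution_allowed <- function(codon, pos, alt) {
  stopifnot(pos %in% 1:3)
  codon <- toupper(codon); alt <- toupper(alt)
  aa <- aa_by_codon()
  mut <- codon
  substr(mut, pos, pos) <- alt
  if (mut %in% STOP_CODONS) return(FALSE)
  aa[kmer_index(mut) + 1L] == aa[kmer_index(codon) + 1L]
}

#' Run the mutation-selection simulation
#'
#' @param config a [sim_config()].
#' @param erm an `erm_table` (bias `config$beta` is applied internally).
#' @param ei optional `score_table` for mean-score tracking.
#' @param max_reject bound on consecutive rejected proposals before a
#'   deadlock error (protein constraint only).
#' @return a `sim_run`: `tau` grid (0, interval, ..., t_max), per-record
#'   hexamer counts and frequencies (4096 columns, circular overlapping
#'   windows pooled over sequences), `mean_erm`, `mean_ei`, final sequences
#'   and the genome's reference translation.
#' @export
run_sim <- function(config, erm, ei = NULL, max_reject = 1e7) {
  stopifnot(inherits(config, "sim_config"), inherits(erm, "erm_table"))
  genome <- init_genome(config)
  total <- sum(genome$lengths)
  steps_per_record <- as.integer(round(config$record_interval * total))
  if (steps_per_record < 1L)
    stop("record_interval smaller than one substitution on this genome")
  n_records <- as.integer(round(config$t_max / config$record_interval))
  rates <- rescale_bias(erm, config$beta)$rates
  set.seed(config$seed + 1L)  # init consumed config$seed
  res <- sim_run_cpp(unlist(genome$seqs), genome$lengths, rates, aa_codes(),
                     config$constraint == "protein", n_records,
                     steps_per_record, max_reject)
  hex_counts <- res$hex_counts
  colnames(hex_counts) <- kmer_strings(6L)
  hex_freq <- hex_counts / rowSums(hex_counts)
  tau <- res$accepted / total
  mean_ei <- if (is.null(ei)) rep(NA_real_, length(tau)) else
    mean_score_from_freq(hex_freq, ei)
  final <- split_final(res$final_seq, genome$lengths)
  structure(list(config = config, tau = tau, hex_counts = hex_counts,
                 hex_freq = hex_freq, mean_erm = res$mean_erm,
                 mean_ei = mean_ei, final = final,
                 ref_translation = genome$ref_translation,
                 accepted = res$accepted[length(res$accepted)],
                 rejected = res$rejected, total_bases = total),
            class = "sim_run")
}

mean_score_from_freq <- function(hex_freq, scores) {
  stopifnot(inherits(scores, "score_table"))
  ok <- !is.na(scores)
  as.numeric(hex_freq[, ok, drop = FALSE] %*% scores[ok]) /
    rowSums(hex_freq[, ok, drop = FALSE])
}

split_final <- function(flat, lengths) {
  ends <- cumsum(lengths)
  starts <- c(1L, head(ends, -1L) + 1L)
  vapply(seq_along(lengths),
         function(i) int_to_seq(flat[starts[i]:ends[i]]), character(1))
}

#' @export
print.sim_run <- function(x, ...) {
  cat(sprintf(
    "sim_run: %d x %d nt, constraint=%s, beta=%g, tau 0..%g (%d records)\n",
    x$config$n_sequences, x$config$seq_length, x$config$constraint,
    x$config$beta, max(x$tau), length(x$tau)))
  cat(sprintf("  accepted %d substitutions (%.3g rejected proposals)\n",
              as.integer(x$accepted), x$rejected))
  invisible(x)
}

#' Constrained-versus-unconstrained motif frequency ratios
#'
#' The per-hexamer frequency ratio of a protein-constrained run over a
#' matched unconstrained run at each recorded time point -- the simulated
#' analogue of exon-versus-intron enrichment. One pseudocount is added to
#' each hexamer count in numerator and denominator before normalizing, so
#' ratios stay finite when a motif is absent.
#'
#' @param run_constrained,run_unconstrained `sim_run` objects on matching
#'   tau grids.
#' @param pseudocount added to every hexamer count (default 1).
#' @return matrix (records x 4096) of ratios; rownames are tau values.
#' @export
enrichment_ratio <- function(run_constrained, run_unconstrained,
                             pseudocount = 1) {
  stopifnot(inherits(run_constrained, "sim_run"),
            inherits(run_unconstrained, "sim_run"))
  if (!isTRUE(all.equal(run_constrained$tau, run_unconstrained$tau)))
    stop("tau grids differ between the two runs")
  fr <- function(cnt) (cnt + pseudocount) /
    (rowSums(cnt) + pseudocount * ncol(cnt))
  out <- fr(run_constrained$hex_counts) / fr(run_unconstrained$hex_counts)
  rownames(out) <- format(run_constrained$tau)
  out
}

#' Positional mutability profile over simulated exon/intron triples
#'
#' Builds 900-nt pseudo-genes: positions 1-300 and 601-900 from
#' unconstrained ("intron") sequences, 301-600 from constrained ("exon")
#' sequences, assigned deterministically round-robin by sequence index
#' (exon i flanked by unconstrained sequences 2i-1 and 2i), each trimmed to
#' its first `trim` nt. Heptamer contexts at the junctions span the
#' concatenated neighbours; the first and last 3 positions of the linear
#' 900-mer have no full context and are NA.
#'
#' @param constrained,unconstrained `sim_run` objects or character vectors
#'   of sequences.
#' @param erm an `erm_table`.
#' @param trim nt taken from the start of each sequence (default 300).
#' @return data.frame: `position` (1..3*trim), `region`
#'   (intron/exon/intron), `mean_rate` over triples.
#' @export
pseudo_positional_profile <- function(constrained, unconstrained, erm,
                                      trim = 300L) {
  get_seqs <- function(x) if (inherits(x, "sim_run")) x$final else
    as_seq_chr(x)
  ex <- get_seqs(constrained)
  inx <- get_seqs(unconstrained)
  if (any(nchar(c(ex, inx)) < trim))
    stop("sequences shorter than trim = ", trim)
  n_triples <- min(length(ex), length(inx) %/% 2L)
  if (n_triples < 1L)
    stop("not enough sequences to form distinct intron-exon-intron triples")
  acc <- matrix(NA_real_, n_triples, 3L * trim)
  for (t in seq_len(n_triples)) {
    s <- paste0(substr(inx[2L * t - 1L], 1L, trim),
                substr(ex[t], 1L, trim),
                substr(inx[2L * t], 1L, trim))
    acc[t, ] <- site_rates_all(s, erm, circular = FALSE)
  }
  data.frame(
    position = seq_len(3L * trim),
    region = rep(c("intron", "exon", "intron"), each = trim),
    mean_rate = colMeans(acc),
    stringsAsFactors = FALSE)
}

#' Exact stationary distribution of the substitution jump chain
#'
#' Brute-force oracle for the simulator's long-run behaviour on a single
#' short circular sequence. The embedded jump chain moves between the 4^L
#' sequence states with probability proportional to the per-substitution
#' rate, restricted to accepted moves under protein constraint (amino acid
#' unchanged, no stop created, reference translation that of `start`).
#' Solved by damped power iteration to 1e-12.
#'
#' @param erm an `erm_table`.
#' @param length circular sequence length, <= 6 (multiple of 3 under
#'   constraint).
#' @param constraint `"none"` or `"protein"`.
#' @param start starting sequence (required under constraint; fixes the
#'   reference translation and the reachable state class).
#' @return named numeric vector over all 4^L sequences summing to 1 (zero
#'   outside the reachable class); attribute `states` lists the class.
#' @export
exact_stationary <- function(erm, length, constraint = c("none", "protein"),
                             start = NULL) {
  stopifnot(inherits(erm, "erm_table"))
  constraint <- match.arg(constraint)
  L <- as.integer(length)
  if (L > 6L || L < 1L) stop("length must be between 1 and 6")
  if (constraint == "protein") {
    if (L %% 3L != 0L) stop("length must be a multiple of 3 under constraint")
    if (is.null(start)) stop("start sequence required under constraint")
  }
  nS <- 4L^L
  states <- 0:(nS - 1L)
  digits <- sapply(0:(L - 1L), function(p) (states %/% 4L^(L - 1L - p)) %% 4L)
  digits <- matrix(digits, nrow = nS)

  aa64 <- aa_codes()
  if (constraint == "protein") {
    n_cod <- L %/% 3L
    cod_idx <- sapply(seq_len(n_cod), function(c)
      digits[, 3L * c - 2L] * 16L + digits[, 3L * c - 1L] * 4L +
        digits[, 3L * c])
    cod_idx <- matrix(cod_idx, nrow = nS)
  }

  from <- integer(0); to <- integer(0); rate <- numeric(0)
  for (p in 0:(L - 1L)) {
    span <- ((p - 3L):(p + 3L)) %% L
    hept <- as.numeric(digits[, span + 1L, drop = FALSE] %*% 4L^(6:0))
    ref <- digits[, p + 1L]
    for (b in 0:3) {
      ok <- ref != b
      if (constraint == "protein") {
        c <- p %/% 3L
        within <- p %% 3L
        old_cod <- cod_idx[, c + 1L]
        new_cod <- old_cod + (b - ref) * 4L^(2L - within)
        ok <- ok & aa64[new_cod + 1L] >= 0 &
          aa64[new_cod + 1L] == aa64[old_cod + 1L]
      }
      if (!any(ok)) next
      from <- c(from, states[ok])
      to <- c(to, states[ok] + (b - ref[ok]) * 4L^(L - 1L - p))
      rate <- c(rate, erm$rates[hept[ok] + 1L, b + 1L])
    }
  }

  # reachable class from the start state (constraint) or all states
  if (constraint == "protein") {
    s0 <- kmer_index(toupper(start))
    A <- Matrix::sparseMatrix(i = from + 1L, j = to + 1L, x = 1,
                              dims = c(nS, nS))
    reach <- rep(FALSE, nS); reach[s0 + 1L] <- TRUE
    repeat {
      nxt <- reach | (as.numeric(reach %*% A) > 0)
      if (identical(nxt, reach)) break
      reach <- nxt
    }
    keep <- (from %in% (which(reach) - 1L)) & (to %in% (which(reach) - 1L))
    # stranded: reachable states with no outgoing accepted move
    outdeg <- tabulate(from + 1L, nbins = nS)
    stranded <- which(reach & outdeg == 0)
    if (length(stranded))
      stop("reducible chain: no acceptable moves from state(s) ",
           paste(kmer_strings(L)[stranded], collapse = ", "))
    from <- from[keep]; to <- to[keep]; rate <- rate[keep]
    class_states <- which(reach)
  } else {
    class_states <- seq_len(nS)
  }

  P <- Matrix::sparseMatrix(i = from + 1L, j = to + 1L, x = rate,
                            dims = c(nS, nS))
  rs <- Matrix::rowSums(P)
  rs[rs == 0] <- 1
  P <- P / rs
  pi0 <- numeric(nS)
  pi0[class_states] <- 1 / length(class_states)
  for (it in seq_len(200000L)) {
    pi1 <- 0.5 * pi0 + 0.5 * as.numeric(pi0 %*% P)
    if (max(abs(pi1 - pi0)) < 1e-12) { pi0 <- pi1; break }
    pi0 <- pi1
  }
  out <- setNames(pi0 / sum(pi0), kmer_strings(L))
  attr(out, "states") <- kmer_strings(L)[class_states]
  out
}

#' Empirical jump-chain occupancy of the simulator
#'
#' Runs the compiled simulator on a single short circular sequence and
#' tallies the state after every accepted substitution past a burn-in;
#' the companion of [exact_stationary()].
#'
#' @param erm an `erm_table`.
#' @param start starting sequence (its length fixes the state space).
#' @param constraint `"none"` or `"protein"`.
#' @param burn_in substitutions discarded before tallying.
#' @param n_steps substitutions tallied.
#' @param seed integer seed.
#' @return named numeric vector over 4^L states summing to 1.
#' @export
sim_occupancy <- function(erm, start, constraint = c("none", "protein"),
                          burn_in = 1e4, n_steps = 1e6, seed = 1L) {
  stopifnot(inherits(erm, "erm_table"))
  constraint <- match.arg(constraint)
  b <- seq_to_int(start)
  set.seed(seed)
  cnt <- sim_occupancy_cpp(b, erm$rates, aa_codes(),
                           constraint == "protein", burn_in, n_steps, 1e7)
  setNames(cnt / sum(cnt), kmer_strings(length(b)))
}

#' Total-variation distance between two distributions
#' @param p,q numeric vectors on the same support.
#' @return sum of absolute differences / 2.
#' @export
total_variation <- function(p, q) sum(abs(p - q)) / 2
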