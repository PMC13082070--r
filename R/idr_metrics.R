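# Sequence analytics for disordered regions: charge patterning, hydropathy
# decoration, compositional complexity, distribution distances, motif scans.

#' Per-residue charge assignment
#'
#' Lysine and arginine are +1, aspartate and glutamate are -1, everything
#' else (including histidine and cysteine, pH 7 convention) is 0.
#' @param seq amino-acid string.
#' @param positive,negative residue sets carrying +1 / -1.
#' @return integer vector of charges, one per residue.
#' @export
residue_charges <- function(seq, positive = c("K", "R"),
                            negative = c("D", "E")) {
  chars <- strsplit(seq, "", fixed = TRUE)[[1]]
  ifelse(chars %in% positive, 1L, ifelse(chars %in% negative, -1L, 0L))
}

#' Fraction of charged residues (FCR)
#'
#' Count of D, E, K, R divided by sequence length.
#' @param seq amino-acid string.
#' @export
fcr <- function(seq) {
  if (!nzchar(seq)) stop("empty sequence")
  mean(residue_charges(seq) != 0L)
}

#' Net charge per residue (NCPR) profile
#'
#' Sliding-window mean of per-residue charges; windows are truncated at the
#' termini so the profile has one value per residue, each in [-1, 1].
#' @param seq amino-acid string.
#' @param window window width (default 5).
#' @export
ncpr_profile <- function(seq, window = 5L) {
  ch <- residue_charges(seq)
  n <- length(ch)
  if (window > n) stop("window exceeds sequence length")
  h_lo <- (window - 1L) %/% 2L
  h_hi <- window - 1L - h_lo
  cs <- cumsum(c(0, ch))
  lo <- pmax(seq_len(n) - h_lo, 1L)
  hi <- pmin(seq_len(n) + h_hi, n)
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}

# Charge asymmetry sigma = (f+ - f-)^2 / (f+ + f-); 0 when no charges.
charge_sigma <- function(ch) {
  fp <- mean(ch > 0L); fm <- mean(ch < 0L)
  if (fp + fm == 0) 0 else (fp - fm)^2 / (fp + fm)
}

# delta(g): mean squared deviation of sliding-window sigma from whole-seq
# sigma; windows computed by cumulative sums so the whole profile is O(n).
charge_delta <- function(ch, g) {
  n <- length(ch)
  csp <- cumsum(c(0, ch > 0L))
  csm <- cumsum(c(0, ch < 0L))
  i <- seq_len(n - g + 1L)
  fp <- (csp[i + g] - csp[i]) / g
  fm <- (csm[i + g] - csm[i]) / g
  tot <- fp + fm
  sig_win <- ifelse(tot == 0, 0, (fp - fm)^2 / tot)
  mean((sig_win - charge_sigma(ch))^2)
}

# Delta of the maximally charge-segregated arrangement with the same
# composition.  The maximizing arrangement keeps each charge type in one
# contiguous block, separated and flanked by neutral buffers:
#   0^a (+)^np 0^b (-)^nm 0^c .
# Only buffer widths up to g-1 change the window overlap profile, so the
# exact maximum is found by enumerating a, b in 0..g-1 (c takes the
# remaining neutrals).  The classic blocks-at-the-ends variant is the
# a = c = 0 member of this family; for sparse charges interior blocks give a
# strictly larger delta, and stopping at the ends variant would let kappa
# exceed 1.
max_segregated_delta <- function(ch, g) {
  np <- sum(ch > 0L); nm <- sum(ch < 0L); n0 <- sum(ch == 0L)
  best <- -Inf
  for (a in 0:min(g - 1L, n0)) {
    for (b in 0:min(g - 1L, n0 - a)) {
      arr <- c(rep(0L, a), rep(1L, np), rep(0L, b), rep(-1L, nm),
               rep(0L, n0 - a - b))
      best <- max(best, charge_delta(arr, g))
    }
  }
  best
}

#' Charge-patterning parameter kappa
#'
#' Quantifies linear segregation of opposite charges: for each blob size
#' \code{g}, the mean squared deviation of windowed charge asymmetry from the
#' whole-sequence asymmetry (delta) is normalized by the delta of the
#' maximally segregated permutation of the same composition; kappa is the
#' mean of the normalized values over blob sizes.  kappa near 0 means
#' well-mixed opposite charges; kappa = 1 means fully blocky.  The
#' maximally segregated permutation is found exactly within the family of
#' neutral-buffered two-block arrangements (see the methods vignette), which
#' keeps kappa in [0, 1] even for sparsely charged sequences.
#'
#' Undefined (returns \code{NA}) for sequences with no charged residues, or
#' when the maximally segregated delta is zero (e.g. charges of one sign
#' only, uniformly spread); such sequences have no meaningful patterning
#' contrast.
#'
#' @param seq amino-acid string, at least as long as the largest window.
#' @param windows blob sizes averaged over (default \code{c(5, 6)}).
#' @return numeric in [0, 1], or \code{NA_real_} when undefined.
#' @export
kappa <- function(seq, windows = c(5L, 6L)) {
  ch <- residue_charges(seq)
  if (length(ch) < max(windows)) stop("sequence shorter than largest window")
  if (all(ch == 0L)) return(NA_real_)
  ratios <- vapply(windows, function(g) {
    dmax <- max_segregated_delta(ch, g)
    if (dmax == 0) return(NA_real_)
    charge_delta(ch, g) / dmax
  }, numeric(1))
  if (all(is.na(ratios))) return(NA_real_)
  mean(ratios, na.rm = TRUE)
}

# Kyte-Doolittle hydropathy, linearly rescaled to [0, 1].
KD_HYDROPATHY <- c(
  A = 1.8, C = 2.5, D = -3.5, E = -3.5, F = 2.8, G = -0.4, H = -3.2,
  I = 4.5, K = -3.9, L = 3.8, M = 1.9, N = -3.5, P = -1.6, Q = -3.5,
  R = -4.5, S = -0.8, T = -0.7, V = 4.2, W = -0.9, Y = -1.3)
KD_SCALED <- (KD_HYDROPATHY + 4.5) / 9

#' Sequence hydropathy decoration (SHD)
#'
#' Distance-weighted pairwise hydropathy sum quantifying linear clustering of
#' hydrophobic residues: \code{SHD = (1/N) * sum_{i<j} (h_i + h_j) / (j - i)}
#' with \code{h} the per-residue hydropathy.
#'
#' @param seq amino-acid string of length >= 2.
#' @param scale named hydropathy table; default Kyte-Doolittle rescaled to
#'   [0, 1] so that all terms are nonnegative.
#' @export
shd <- function(seq, scale = KD_SCALED) {
  chars <- strsplit(seq, "", fixed = TRUE)[[1]]
  n <- length(chars)
  if (n < 2L) stop("sequence must have at least 2 residues")
  h <- unname(scale[chars])
  if (any(is.na(h))) stop("residue missing from hydropathy scale")
  total <- 0
  # O(n^2) pair sum arranged by offset so each offset is one vector op
  for (d in 1:(n - 1L)) {
    i <- 1:(n - d)
    total <- total + sum(h[i] + h[i + d]) / d
  }
  total / n
}

#' Windowed compositional entropy (SEG-style complexity)
#'
#' Mean over sliding windows of the Shannon entropy (base 2) of the
#' within-window residue frequencies.  Sequences shorter than the window are
#' scored with a single whole-sequence window.  Low values mark
#' low-complexity regions.
#'
#' @param seq amino-acid string.
#' @param window window width (default 12).
#' @return entropy in bits.
#' @export
seg_complexity <- function(seq, window = 12L) {
  chars <- strsplit(seq, "", fixed = TRUE)[[1]]
  n <- length(chars)
  if (n == 0L) stop("empty sequence")
  win_entropy <- function(v) {
    p <- table(v) / length(v)
    -sum(p * log2(p))
  }
  if (n < window) return(win_entropy(chars))
  mean(vapply(seq_len(n - window + 1L),
              function(i) win_entropy(chars[i:(i + window - 1L)]),
              numeric(1)))
}

#' Per-sequence amino-acid composition
#'
#' @param seq amino-acid string.
#' @return numeric vector of 20 frequencies (named by residue), summing to 1.
#' @export
aa_composition <- function(seq) {
  chars <- strsplit(seq, "", fixed = TRUE)[[1]]
  counts <- table(factor(chars, levels = AA20))
  stats::setNames(as.numeric(counts) / length(chars), AA20)
}

#' Compositional enrichment of one sequence set over a reference
#'
#' Pooled residue frequency in \code{seqs} divided by pooled frequency in
#' \code{reference_seqs} (counts are pooled over sequences, not averaged per
#' sequence).  A residue absent from the reference but present in
#' \code{seqs} yields \code{Inf}.
#'
#' @param seqs,reference_seqs character vectors of sequences.
#' @return named numeric vector of 20 ratios; 1 means parity with reference.
#' @export
composition_enrichment <- function(seqs, reference_seqs) {
  pool <- function(ss) {
    chars <- unlist(strsplit(paste(ss, collapse = ""), "", fixed = TRUE))
    counts <- table(factor(chars, levels = AA20))
    as.numeric(counts) / length(chars)
  }
  if (length(seqs) == 0L || length(reference_seqs) == 0L)
    stop("both sequence sets must be non-empty")
  f <- pool(seqs); g <- pool(reference_seqs)
  ratio <- ifelse(g == 0, ifelse(f == 0, NaN, Inf), f / g)
  stats::setNames(ratio, AA20)
}

#' Normalized empirical Wasserstein-1 distance
#'
#' 1-Wasserstein distance between two empirical samples (the area between
#' their empirical CDFs), divided by a normalizer.  The default normalizer is
#' the standard deviation of the reference sample \code{samples_b} so that
#' distances are comparable across metrics with different units.
#'
#' @param samples_a,samples_b numeric samples.
#' @param normalizer positive scalar; default \code{sd(samples_b)}.  Use 1
#'   for the raw (unnormalized) distance.
#' @export
wasserstein1 <- function(samples_a, samples_b,
                         normalizer = stats::sd(samples_b)) {
  if (!length(samples_a) || !length(samples_b)) stop("empty sample")
  if (!is.finite(normalizer) || normalizer == 0) stop("zero normalizer")
  a <- sort(samples_a); b <- sort(samples_b)
  na <- length(a); nb <- length(b)
  if (na == nb) {
    w <- mean(abs(a - b))
  } else {
    # integral of |F_a - F_b| over the pooled grid
    grid <- sort(unique(c(a, b)))
    Fa <- stats::ecdf(a)(grid); Fb <- stats::ecdf(b)(grid)
    k <- length(grid)
    w <- sum(abs(Fa[-k] - Fb[-k]) * diff(grid))
  }
  w / normalizer
}

#' Load short-linear-motif patterns
#'
#' Reads a TSV with columns \code{name}, \code{class}
#' (\code{NLS}/\code{MOD}/\code{RNA}), \code{regex}.  The package ships a
#' default, editable set (classic monopartite and bipartite NLS patterns, a
#' subset of PTM/MOD site patterns, and RG/RGG, [FY]GG, SYG RNA-interaction
#' elements); these defaults are approximate stand-ins for the full ELM
#' resource lists and are data, not code.
#'
#' @param path TSV path; default the bundled table.
#' @return data.frame with columns \code{name}, \code{class}, \code{regex}.
#' @export
load_motif_patterns <- function(path = system.file("extdata",
                                                   "motif_patterns.tsv",
                                                   package = "idrlm")) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE, comment.char = "#")
  stopifnot(all(c("name", "class", "regex") %in% names(df)))
  if (anyDuplicated(df$name)) stop("duplicate motif names")
  for (rx in df$regex) {
    ok <- tryCatch({ grepl(rx, "A", perl = TRUE); TRUE },
                   error = function(e) FALSE)
    if (!ok) stop("invalid regex: ", rx)
  }
  df
}

#' Scan a sequence for motif matches
#'
#' Reports all (including overlapping) matches of each pattern; overlapping
#' occurrences are found with a zero-width lookahead so every start position
#' is tested.  Coordinates are 1-based inclusive.
#'
#' @param seq amino-acid string.
#' @param patterns data.frame from [load_motif_patterns()] (or any frame with
#'   \code{name} and \code{regex} columns).
#' @return data.frame with columns \code{name}, \code{start}, \code{end};
#'   zero rows when nothing matches.
#' @export
motif_scan <- function(seq, patterns) {
  out <- list()
  for (i in seq_len(nrow(patterns))) {
    rx <- paste0("(?=(", patterns$regex[i], "))")
    m <- gregexpr(rx, seq, perl = TRUE)[[1]]
    if (m[1] == -1L) next
    starts <- as.integer(m)
    lens <- attr(m, "capture.length")[, 1L]
    out[[length(out) + 1L]] <- data.frame(
      name = patterns$name[i], start = starts, end = starts + lens - 1L,
      stringsAsFactors = FALSE)
  }
  if (!length(out))
    return(data.frame(name = character(0), start = integer(0),
                      end = integer(0), stringsAsFactors = FALSE))
  do.call(rbind, out)
}

#' Mean unique PTM-motif density over sequences
#'
#' For each sequence, counts distinct (pattern, start) sites matched by the
#' MOD-class patterns and reports the mean count per sequence.
#' @param seqs character vector of sequences.
#' @param mod_patterns pattern data.frame (typically the MOD-class subset).
#' @export
ptm_density <- function(seqs, mod_patterns) {
  counts <- vapply(seqs, function(s) {
    hits <- motif_scan(s, mod_patterns)
    nrow(unique(hits[, c("name", "start")]))
  }, numeric(1))
  mean(counts)
}

#' Motif presence and co-occurrence within a span
#'
#' @param seq amino-acid string.
#' @param patterns pattern data.frame.
#' @param span co-occurrence window in residues (default 30): the second
#'   flag is true iff two matches (any patterns in the set) have start
#'   positions differing by at most \code{span}.
#' @return logical vector \code{c(any = ., pair_within_span = .)}.
#' @export
motif_cooccurrence <- function(seq, patterns, span = 30L) {
  if (span < 1L) stop("span must be >= 1")
  hits <- motif_scan(seq, patterns)
  if (nrow(hits) == 0L)
    return(c(any = FALSE, pair_within_span = FALSE))
  pair <- nrow(hits) >= 2L && any(diff(sort(hits$start)) <= span)
  c(any = TRUE, pair_within_span = pair)
}

#' Per-sequence metric table
#'
#' Computes the full analytics row for each sequence: length, FCR, kappa,
#' SHD, SEG complexity, and the 20-component composition vector.
#'
#' @param seqs named character vector (or list) of sequences.
#' @param kappa_windows blob sizes for [kappa()].
#' @param seg_window window for [seg_complexity()].
#' @return data.frame with one row per sequence; composition columns are
#'   named \code{comp_A} .. \code{comp_Y} and sum to 1 per row.
#' @export
metric_table <- function(seqs, kappa_windows = c(5L, 6L), seg_window = 12L) {
  seqs <- unlist(seqs)
  ids <- names(seqs)
  if (is.null(ids)) ids <- paste0("seq", seq_along(seqs))
  rows <- lapply(seq_along(seqs), function(i) {
    s <- seqs[[i]]
    comp <- aa_composition(s)
    k <- if (nchar(s) >= max(kappa_windows)) kappa(s, kappa_windows) else NA_real_
    data.frame(id = ids[i], length = nchar(s), fcr = fcr(s), kappa = k,
               shd = if (nchar(s) >= 2) shd(s) else NA_real_,
               seg = seg_complexity(s, seg_window),
               t(stats::setNames(as.numeric(comp), paste0("comp_", AA20))),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
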