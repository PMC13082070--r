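# Seeded synthetic-data generators: proteins with segment-structured pLDDT
# traces (curation ground truth), IDR corpora with controllable composition
# and charge blockiness, and the scrambled-sequence null.

# Residue pool used when drawing synthetic residues for folded segments.
folded_composition <- function() {
  p <- rep(1, 20); names(p) <- AA20
  p[c("L", "I", "V", "F", "A", "W", "Y", "M")] <- 2.5
  p / sum(p)
}

#' Disorder-biased residue composition
#'
#' Default composition for synthetic IDR corpora: proline, serine, glycine,
#' glutamate and lysine enriched; order-promoting aliphatics and aromatics
#' (L, I, V, F, W, Y) depleted.  Encodes the directionality of known
#' disorder compositional biases without claiming real magnitudes.
#' @return named numeric vector of 20 frequencies summing to 1.
#' @export
disorder_composition <- function() {
  p <- rep(1, 20); names(p) <- AA20
  p[c("P", "S", "G", "E", "K")] <- 4
  p[c("Q", "A", "D", "R", "T", "N")] <- 1.6
  p[c("L", "I", "V", "F", "W", "Y", "C", "M")] <- 0.35
  p / sum(p)
}

#' Low-entropy residue composition
#'
#' A deliberately skewed composition (mean single-sequence compositional
#' entropy near 2.2 nats) for experiments that start from a low-diversity
#' corpus, e.g. entropy-targeted reward shaping.
#' @return named numeric vector of 20 frequencies summing to 1.
#' @export
low_entropy_composition <- function() {
  p <- rep(0.01, 20); names(p) <- AA20
  p[c("P", "S", "G", "E", "K")] <- 0.17
  p / sum(p)
}

#' Segment layout for a synthetic protein
#'
#' @param labels character vector in \code{c("FOLDED","DISORDERED")}.
#' @param lengths integer segment lengths (same length as \code{labels}).
#' @param folded_mean,folded_sd pLDDT distribution for folded segments
#'   (defaults 92, 3).
#' @param disordered_mean,disordered_sd for disordered segments (55, 6).
#' @param ramp boundary ramp width in residues (default 4): pLDDT means are
#'   linearly interpolated across each internal boundary.
#' @export
segment_layout <- function(labels, lengths, folded_mean = 92, folded_sd = 3,
                           disordered_mean = 55, disordered_sd = 6,
                           ramp = 4L) {
  stopifnot(length(labels) == length(lengths), all(lengths >= 1L),
            all(labels %in% c("FOLDED", "DISORDERED")))
  structure(list(labels = labels, lengths = as.integer(lengths),
                 folded_mean = folded_mean, folded_sd = folded_sd,
                 disordered_mean = disordered_mean,
                 disordered_sd = disordered_sd, ramp = as.integer(ramp)),
            class = "segment_layout")
}

#' Synthesize a protein with a segment-structured pLDDT trace
#'
#' Residues are drawn from a label-appropriate composition (hydrophobic-
#' enriched for folded segments, disorder-biased otherwise); per-residue
#' pLDDT is Gaussian around the label mean, clipped to [0, 100], with linear
#' mean ramps of width \code{ramp} across internal boundaries.  The returned
#' ground-truth segments make parameter-recovery tests possible.
#'
#' @param layout a [segment_layout()].
#' @param protein_id identifier for the trace.
#' @param seed integer seed (all randomness is derived from it).
#' @return list with \code{trace} (a \code{plddt_trace}) and \code{truth}
#'   (data.frame of segments: \code{start} 0-based inclusive, \code{end}
#'   exclusive, \code{label}).
#' @export
synth_protein_with_plddt <- function(layout, protein_id = "synthetic",
                                     seed = 1L) {
  set.seed(seed)
  L <- sum(layout$lengths)
  lab_per_res <- rep(layout$labels, layout$lengths)
  mu <- ifelse(lab_per_res == "FOLDED", layout$folded_mean,
               layout$disordered_mean)
  # linear ramps across internal boundaries
  if (layout$ramp > 0L && length(layout$lengths) > 1L) {
    bounds <- cumsum(layout$lengths)
    bounds <- bounds[-length(bounds)]
    half <- layout$ramp / 2
    base_mu <- mu
    for (b in bounds) {
      left_mu <- base_mu[b]; right_mu <- base_mu[b + 1L]
      idx <- seq(max(1L, b - ceiling(half) + 1L), min(L, b + ceiling(half)))
      frac <- (idx - (b + 0.5)) / layout$ramp + 0.5
      frac <- pmin(pmax(frac, 0), 1)
      mu[idx] <- left_mu + frac * (right_mu - left_mu)
    }
  }
  sdv <- ifelse(lab_per_res == "FOLDED", layout$folded_sd,
                layout$disordered_sd)
  plddt <- pmin(pmax(stats::rnorm(L, mu, sdv), 0), 100)
  seq_chars <- character(L)
  for (lab in c("FOLDED", "DISORDERED")) {
    idx <- which(lab_per_res == lab)
    if (!length(idx)) next
    comp <- if (lab == "FOLDED") folded_composition() else disorder_composition()
    seq_chars[idx] <- sample(AA20, length(idx), replace = TRUE, prob = comp)
  }
  truth <- labels_to_runs(rep(layout$labels, layout$lengths))
  list(trace = plddt_trace(protein_id, paste(seq_chars, collapse = ""), plddt),
       truth = truth)
}

#' Corpus specification for synthetic IDR sequences
#'
#' Lengths are log-normal with configurable median, clipped to a range;
#' residues are drawn i.i.d. from a composition vector; the placement of
#' charged residues along the chain interpolates between strictly
#' alternating (+/-/+/-, \code{charge_block = 0}) and fully segregated
#' blocks (\code{charge_block = 1}).
#'
#' @param n_sequences number of sequences.
#' @param median_length median of the log-normal length distribution
#'   (default 80, matching the bulk of natural IDR lengths below 100
#'   residues with a tail toward ~300).
#' @param length_sdlog log-scale sd (default 0.45).
#' @param length_range clip range (default \code{c(30, 300)}).
#' @param composition residue frequency vector (default
#'   [disorder_composition()]).
#' @param charge_block blockiness parameter in [0, 1].
#' @export
corpus_spec <- function(n_sequences, median_length = 80,
                        length_sdlog = 0.45, length_range = c(30L, 300L),
                        composition = disorder_composition(),
                        charge_block = 0.5) {
  stopifnot(n_sequences >= 1L, abs(sum(composition) - 1) < 1e-8,
            charge_block >= 0, charge_block <= 1)
  structure(list(n_sequences = as.integer(n_sequences),
                 median_length = median_length, length_sdlog = length_sdlog,
                 length_range = as.integer(length_range),
                 composition = composition, charge_block = charge_block),
            class = "corpus_spec")
}

# Arrange a multiset of charges: b = 0 alternating, b = 1 fully segregated.
# Intermediate b: start from the segregated order and randomly reshuffle a
# fraction (1 - b) of the charge slots.
arrange_charges <- function(charges, b) {
  np <- sum(charges > 0L); nm <- sum(charges < 0L)
  nc <- np + nm
  if (nc <= 1L) return(charges[charges != 0L])
  seg <- c(rep(1L, np), rep(-1L, nm))
  # alternating layout: spread each sign evenly along the charge slots
  ranks <- c((seq_len(np) - 0.5) / max(np, 1L), (seq_len(nm) - 0.5) / max(nm, 1L))
  alt <- seg[order(ranks)]
  if (b >= 1) return(seg)
  if (b <= 0) return(alt)
  out <- seg
  k <- round((1 - b) * nc)
  if (k >= 2L) {
    idx <- sample.int(nc, k)
    out[idx] <- sample(out[idx])
  }
  out
}

#' Generate a synthetic IDR corpus
#'
#' @param spec a [corpus_spec()].
#' @param seed integer seed.
#' @return named character vector of sequences (FASTA-ready).
#' @export
synth_idr_corpus <- function(spec, seed = 1L) {
  set.seed(seed)
  n <- spec$n_sequences
  lens <- round(stats::rlnorm(n, log(spec$median_length), spec$length_sdlog))
  lens <- pmin(pmax(lens, spec$length_range[1]), spec$length_range[2])
  pos_set <- c("K", "R"); neg_set <- c("D", "E")
  seqs <- character(n)
  for (i in seq_len(n)) {
    chars <- sample(names(spec$composition), lens[i], replace = TRUE,
                    prob = spec$composition)
    chg <- ifelse(chars %in% pos_set, 1L, ifelse(chars %in% neg_set, -1L, 0L))
    slots <- which(chg != 0L)
    if (length(slots) > 1L) {
      arranged <- arrange_charges(chg, spec$charge_block)
      pos_pool <- chars[chars %in% pos_set]
      neg_pool <- chars[chars %in% neg_set]
      ipos <- 0L; ineg <- 0L
      for (j in seq_along(slots)) {
        if (arranged[j] > 0L) {
          ipos <- ipos + 1L; chars[slots[j]] <- pos_pool[ipos]
        } else {
          ineg <- ineg + 1L; chars[slots[j]] <- neg_pool[ineg]
        }
      }
    }
    seqs[i] <- paste(chars, collapse = "")
  }
  stats::setNames(seqs, sprintf("synth%05d", seq_len(n)))
}

#' Randomly scramble a sequence
#'
#' Uniform random permutation of the residues: composition (hence FCR and
#' compositional entropy) is exactly preserved while order-dependent metrics
#' (kappa, SHD) generally change.  This is the null model used to test
#' whether generated charge patterning exceeds what composition alone gives.
#'
#' @param seq amino-acid string.
#' @param seed integer seed.
#' @export
scramble <- function(seq, seed = 1L) {
  if (!nzchar(seq)) stop("empty sequence")
  set.seed(seed)
  paste(sample(strsplit(seq, "", fixed = TRUE)[[1]]), collapse = "")
}

#' Plant motifs into background sequences
#'
#' Test helper producing sequences with known motif instances at known
#' offsets, plus the planting manifest that a scanner must reproduce.
#'
#' @param n number of sequences.
#' @param length sequence length.
#' @param motif literal motif string to plant.
#' @param sites_per_seq number of planted sites per sequence (vectorized).
#' @param background composition for non-motif positions; defaults to a
#'   motif-free alphabet (letters not occurring in \code{motif}).
#' @param seed integer seed.
#' @return list with \code{seqs} (named character) and \code{manifest}
#'   (data.frame: \code{seq}, \code{start}, \code{end}).
#' @export
plant_motifs <- function(n, length = 60L, motif = "RGG", sites_per_seq = 1L,
                         background = NULL, seed = 1L) {
  set.seed(seed)
  mchars <- strsplit(motif, "", fixed = TRUE)[[1]]
  if (is.null(background)) background <- setdiff(AA20, mchars)
  sites_per_seq <- rep_len(sites_per_seq, n)
  seqs <- character(n); manifest <- list()
  for (i in seq_len(n)) {
    chars <- sample(background, length, replace = TRUE)
    k <- sites_per_seq[i]
    if (k > 0L) {
      # non-overlapping slots
      slot_w <- nchar(motif) + 1L
      avail <- seq(1L, length - nchar(motif) + 1L)
      starts <- integer(0)
      for (s in sample(avail)) {
        if (all(abs(s - starts) >= slot_w)) starts <- c(starts, s)
        if (length(starts) == k) break
      }
      for (s in starts)
        chars[s:(s + nchar(motif) - 1L)] <- mchars
      if (length(starts))
        manifest[[length(manifest) + 1L]] <- data.frame(
          seq = sprintf("plant%04d", i), start = sort(starts),
          end = sort(starts) + nchar(motif) - 1L)
    }
    seqs[i] <- paste(chars, collapse = "")
  }
  manifest <- if (length(manifest)) do.call(rbind, manifest) else
    data.frame(seq = character(0), start = integer(0), end = integer(0))
  list(seqs = stats::setNames(seqs, sprintf("plant%04d", seq_len(n))),
       manifest = manifest)
}
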