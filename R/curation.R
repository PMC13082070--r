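# IDR curation from per-residue pLDDT traces: windowed smoothing, three-state
# classification, region relabeling, record extraction.

#' Segmentation parameters for pLDDT-based IDR curation
#'
#' @param window odd width (residues) of the centered averaging filter
#'   applied to the raw pLDDT trace (default 15).
#' @param fold_threshold smoothed pLDDT above which a residue is folded
#'   (default 80; strict inequality).
#' @param disorder_threshold smoothed pLDDT below which a residue is
#'   disordered (default 70; strict inequality).  Scores between the two
#'   thresholds (inclusive at both ends) are gaps.
#' @param min_run minimum run length (residues) for a folded or disordered
#'   region to survive; shorter runs are reclassified as gaps (default 10).
#' @param min_idr_len minimum IDR length kept in the output (default 30).
#' @param max_protein_len proteins longer than this are discarded entirely
#'   (default 512).
#' @return list of class \code{segmentation_params}.
#' @export
segmentation_params <- function(window = 15L, fold_threshold = 80,
                                disorder_threshold = 70, min_run = 10L,
                                min_idr_len = 30L, max_protein_len = 512L) {
  window <- as.integer(window)
  if (window < 1L || window %% 2L == 0L) stop("window must be odd and >= 1")
  if (disorder_threshold >= fold_threshold)
    stop("disorder_threshold must be below fold_threshold")
  if (min_run < 1L) stop("min_run must be >= 1")
  structure(list(window = window, fold_threshold = fold_threshold,
                 disorder_threshold = disorder_threshold,
                 min_run = as.integer(min_run),
                 min_idr_len = as.integer(min_idr_len),
                 max_protein_len = as.integer(max_protein_len)),
            class = "segmentation_params")
}

#' A protein with its per-residue pLDDT trace
#'
#' @param protein_id identifier.
#' @param sequence amino-acid string.
#' @param plddt numeric vector in [0, 100], one score per residue.
#' @export
plddt_trace <- function(protein_id, sequence, plddt) {
  if (!nzchar(sequence)) stop("empty sequence")
  if (length(plddt) != nchar(sequence))
    stop("plddt length does not match sequence length")
  if (any(!is.finite(plddt)) || any(plddt < 0 | plddt > 100))
    stop("plddt scores must lie in [0, 100]")
  structure(list(protein_id = protein_id, sequence = sequence,
                 plddt = as.numeric(plddt)),
            class = "plddt_trace")
}

#' Windowed smoothing of a pLDDT trace
#'
#' Centered moving average of width \code{window}; at the termini the window
#' shrinks to the residues actually present (no pad values are invented), so
#' the output always has the same length as the input.
#'
#' @param trace a \code{plddt_trace} or a bare numeric vector.
#' @param window odd positive width.
#' @return numeric vector of smoothed scores, same length as the input.
#' @export
smooth_plddt <- function(trace, window = 15L) {
  x <- if (inherits(trace, "plddt_trace")) trace$plddt else as.numeric(trace)
  if (length(x) == 0L) stop("empty trace")
  window <- as.integer(window)
  if (window < 1L || window %% 2L == 0L) stop("window must be odd and >= 1")
  n <- length(x)
  h <- (window - 1L) %/% 2L
  cs <- cumsum(c(0, x))
  lo <- pmax(seq_len(n) - h, 1L)
  hi <- pmin(seq_len(n) + h, n)
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}

#' Three-state residue classification
#'
#' Residues with smoothed pLDDT strictly above \code{fold_threshold} are
#' FOLDED, strictly below \code{disorder_threshold} DISORDERED, and
#' everything between (including exact equality with either threshold) GAP.
#'
#' @param smoothed numeric scores in [0, 100].
#' @param params a \code{segmentation_params}.
#' @return character vector of labels in \code{c("FOLDED","DISORDERED","GAP")}.
#' @export
classify_residues <- function(smoothed, params = segmentation_params()) {
  if (any(smoothed < 0 | smoothed > 100)) stop("scores must lie in [0, 100]")
  labels <- rep("GAP", length(smoothed))
  labels[smoothed > params$fold_threshold] <- "FOLDED"
  labels[smoothed < params$disorder_threshold] <- "DISORDERED"
  labels
}

# Run-length view of labels -> data.frame(start [0-based incl], end [excl], label)
labels_to_runs <- function(labels) {
  r <- rle(labels)
  end <- cumsum(r$lengths)
  data.frame(start = c(0L, end[-length(end)]), end = end,
             label = r$values, stringsAsFactors = FALSE)
}

merge_adjacent_runs <- function(runs) {
  if (nrow(runs) <= 1L) return(runs)
  keep <- c(TRUE, runs$label[-1L] != runs$label[-nrow(runs)])
  grp <- cumsum(keep)
  out <- data.frame(
    start = tapply(runs$start, grp, min),
    end = tapply(runs$end, grp, max),
    label = tapply(runs$label, grp, function(v) v[1L]),
    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out$start <- as.integer(out$start); out$end <- as.integer(out$end)
  out
}

#' Refine per-residue labels into final folded/disordered segments
#'
#' Applies the region-relabeling rules, in order: (1) form maximal runs;
#' (2) FOLDED or DISORDERED runs shorter than \code{min_run} become GAP;
#' (3) adjacent GAP runs merge; (4) a GAP run flanked by two DISORDERED runs,
#' or terminal and adjacent to a DISORDERED run, becomes DISORDERED; (5) all
#' remaining GAP runs become FOLDED; (6) adjacent same-label runs merge.
#' The single pass is a fixed point: re-running on the output changes nothing.
#'
#' @param labels per-residue labels from [classify_residues()].
#' @param params a \code{segmentation_params}.
#' @return data.frame of segments with columns \code{start} (0-based
#'   inclusive), \code{end} (exclusive), \code{label} in
#'   \code{c("FOLDED","DISORDERED")}; segments tile \code{[0, L)}.
#' @export
refine_segments <- function(labels, params = segmentation_params()) {
  if (length(labels) == 0L) stop("labels must be non-empty")
  runs <- labels_to_runs(labels)
  # (2) short folded/disordered runs -> GAP
  short <- runs$label != "GAP" & (runs$end - runs$start) < params$min_run
  runs$label[short] <- "GAP"
  # (3) merge adjacent gaps (and any adjacent same labels created above)
  runs <- merge_adjacent_runs(runs)
  # (4)/(5) relabel gap runs
  n <- nrow(runs)
  for (i in seq_len(n)) {
    if (runs$label[i] != "GAP") next
    left  <- if (i > 1L) runs$label[i - 1L] else NA_character_
    right <- if (i < n)  runs$label[i + 1L] else NA_character_
    flanked_dd <- identical(left, "DISORDERED") && identical(right, "DISORDERED")
    terminal_d <- (is.na(left) && identical(right, "DISORDERED")) ||
                  (is.na(right) && identical(left, "DISORDERED"))
    runs$label[i] <- if (flanked_dd || terminal_d) "DISORDERED" else "FOLDED"
  }
  merge_adjacent_runs(runs)
}

#' Extract IDR records from refined segments
#'
#' One record per DISORDERED segment, with everything before the segment as
#' the N-terminal context and everything after as the C-terminal context
#' (other IDRs in the flanks are left as plain sequence).  Records are
#' dropped when the IDR is shorter than \code{min_idr_len}; no records are
#' produced when the protein exceeds \code{max_protein_len}, is entirely
#' disordered, or contains non-canonical residues (X, B, Z, U, O, J).
#' Coordinates are serialized 1-based inclusive.
#'
#' @param trace a \code{plddt_trace}.
#' @param segments segment data.frame from [refine_segments()].
#' @param params a \code{segmentation_params}.
#' @return list of \code{idr_record}s (possibly empty).
#' @export
extract_idr_records <- function(trace, segments,
                                params = segmentation_params()) {
  L <- nchar(trace$sequence)
  if (length(trace$plddt) != L) stop("sequence/plddt length mismatch")
  if (nrow(segments) == 0L || segments$start[1L] != 0L ||
      segments$end[nrow(segments)] != L)
    stop("segments must tile the protein")
  if (L > params$max_protein_len) return(list())
  if (all(segments$label == "DISORDERED")) return(list())
  chars <- strsplit(trace$sequence, "", fixed = TRUE)[[1]]
  if (any(chars %in% NONCANONICAL_AA) || any(!chars %in% AA20)) return(list())
  out <- list()
  for (i in seq_len(nrow(segments))) {
    if (segments$label[i] != "DISORDERED") next
    s <- segments$start[i]; e <- segments$end[i]
    if (e - s < params$min_idr_len) next
    out[[length(out) + 1L]] <- idr_record(
      trace$protein_id,
      n_context = substr(trace$sequence, 1L, s),
      idr       = substr(trace$sequence, s + 1L, e),
      c_context = substr(trace$sequence, e + 1L, L),
      idr_start = s + 1L, idr_end = e)
  }
  out
}

#' Curate IDRs from one pLDDT trace
#'
#' Convenience pipeline: smooth, classify, refine, extract.
#' @inheritParams extract_idr_records
#' @return list of \code{idr_record}s.
#' @export
curate_trace <- function(trace, params = segmentation_params()) {
  sm <- smooth_plddt(trace, params$window)
  labels <- classify_residues(sm, params)
  segs <- refine_segments(labels, params)
  extract_idr_records(trace, segs, params)
}

#' Read a pLDDT trace file
#'
#' Supports the AFDB-style confidence JSON dialect (an object with a
#' per-residue score array under \code{plddt}, or a bare JSON array) and
#' two-column CSV (\code{index,score} or a single score column).
#' @param path file ending in \code{.json} or \code{.csv}.
#' @return numeric vector of per-residue scores.
#' @export
read_plddt <- function(path) {
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    x <- jsonlite::fromJSON(path)
    scores <- if (is.list(x) && !is.null(x$plddt)) x$plddt else x
    return(as.numeric(unlist(scores)))
  }
  if (grepl("\\.csv$", path, ignore.case = TRUE)) {
    df <- utils::read.csv(path)
    return(as.numeric(df[[ncol(df)]]))
  }
  stop("unsupported pLDDT file format: ", path)
}

#' Curate a FASTA + pLDDT directory into IDR records
#'
#' Pairs each FASTA entry with \code{<plddt_dir>/<protein_id>.json} or
#' \code{.csv} and runs [curate_trace()] on each protein.
#' @param fasta path to a FASTA of protein sequences.
#' @param plddt_dir directory of per-protein trace files named by id.
#' @param params a \code{segmentation_params}.
#' @return list of \code{idr_record}s pooled over proteins.
#' @export
curate_fasta <- function(fasta, plddt_dir, params = segmentation_params()) {
  seqs <- read_fasta(fasta)
  out <- list()
  for (id in names(seqs)) {
    f <- file.path(plddt_dir, paste0(id, c(".json", ".csv")))
    f <- f[file.exists(f)][1]
    if (is.na(f)) {
      warning("no pLDDT file for ", id, "; skipped")
      next
    }
    tr <- plddt_trace(id, seqs[[id]], read_plddt(f))
    out <- c(out, curate_trace(tr, params))
  }
  out
}
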