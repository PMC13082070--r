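# Fill-in-the-middle codec: IdrRecord -> token string -> padded id sequence.

#' Construct a curated IDR record
#'
#' An \code{idr_record} holds one intrinsically disordered region together
#' with its N- and C-terminal flanking contexts and its 1-based inclusive
#' coordinates within the full protein.  \code{n_context + idr + c_context}
#' always reconstructs the full protein sequence.
#'
#' @param protein_id identifier string.
#' @param n_context,idr,c_context amino-acid strings (contexts may be empty).
#' @param idr_start,idr_end 1-based inclusive residue coordinates of the IDR
#'   within the protein.  Defaults are derived from the context lengths.
#' @return A list of class \code{idr_record}.
#' @export
idr_record <- function(protein_id, n_context, idr, c_context,
                       idr_start = nchar(n_context) + 1L,
                       idr_end   = nchar(n_context) + nchar(idr)) {
  stopifnot(is.character(protein_id), nzchar(idr))
  rec <- list(protein_id = protein_id,
              n_context = n_context, idr = idr, c_context = c_context,
              idr_start = as.integer(idr_start), idr_end = as.integer(idr_end))
  if (rec$idr_end - rec$idr_start + 1L != nchar(idr))
    stop("idr coordinates inconsistent with idr length")
  class(rec) <- "idr_record"
  rec
}

#' Fill-in-the-middle transformation
#'
#' Rearranges an IDR record into the token order
#' \code{<N>} n-context \code{<C>} c-context \code{<I>} IDR, so that a causal
#' language model conditioned on both flanking contexts generates the
#' disordered span last.
#'
#' @param record an \code{idr_record}.
#' @return A single token string, e.g. \code{"<N>MEDS<C>RKSL<I>VEED"}.
#' @export
fim_transform <- function(record) {
  check_canonical(record$n_context, "n_context")
  check_canonical(record$c_context, "c_context")
  check_canonical(record$idr, "idr")
  paste0("<N>", record$n_context, "<C>", record$c_context, "<I>", record$idr)
}

#' Invert the fill-in-the-middle transformation
#'
#' Splits a FIM token string at the \code{<N>}, \code{<C>}, \code{<I>}
#' sentinels, recovering \code{(n_context, c_context, idr)} exactly.
#' @param text a FIM token string as produced by [fim_transform()].
#' @return list with \code{n_context}, \code{c_context}, \code{idr}.
#' @export
fim_invert <- function(text) {
  m <- regmatches(text, regexec("^<N>([A-Z]*)<C>([A-Z]*)<I>([A-Z]*)$", text))[[1]]
  if (length(m) != 4L) stop("not a well-formed FIM token string")
  list(n_context = m[2], c_context = m[3], idr = m[4])
}

#' Context-deletion augmentation (IDP records)
#'
#' Returns a copy of the record with both flanking contexts removed, turning a
#' contextual IDR into a standalone intrinsically disordered protein (IDP).
#' Applied to a whole corpus this doubles the record count (each IDR
#' contributes one IDR record and one IDP record).  Idempotent.
#'
#' @param record an \code{idr_record}.
#' @export
idp_augment <- function(record) {
  idr_record(record$protein_id, "", record$idr, "",
             idr_start = 1L, idr_end = nchar(record$idr))
}

#' Augment a corpus with context-free duplicates
#'
#' @param records list of \code{idr_record}s.
#' @return list of length \code{2 * length(records)}: the originals followed
#'   by their context-deleted duplicates.
#' @export
augment_corpus <- function(records) {
  c(records, lapply(records, idp_augment))
}

#' Encode a token string to padded ids
#'
#' Prepends \code{<bos>}, appends \code{<eos>}, and right-pads with
#' \code{<pad>} to \code{max_len}.  Token strings whose encoded length
#' exceeds \code{max_len} are rejected (a truncated record would destroy the
#' \code{<I>} span), so corpora are built with an effective residue budget of
#' \code{max_len - 5} (bos, eos, and the three sentinels).
#'
#' @param text token string (see [tokenize_text] conventions: angle-bracketed
#'   names are single tokens, all other characters one token each).
#' @param max_len pad/limit length in tokens (default 512).
#' @param vocab vocabulary, defaults to [idr_vocab()].
#' @return list of class \code{token_sequence} with 0-based \code{ids}
#'   (length \code{max_len}), \code{n_real} (token count before padding), and
#'   \code{prompt_len} (number of tokens up to and including \code{<I>}, the
#'   index one past which completion tokens start; \code{NA} if no \code{<I>}).
#' @export
encode_tokens <- function(text, max_len = 512L, vocab = idr_vocab()) {
  toks <- tokenize_text(text)
  unknown <- setdiff(unique(toks), vocab$tokens)
  if (length(unknown))
    stop("unknown tokens: ", paste(unknown, collapse = ", "))
  ids <- unname(vocab$id[toks])
  ids <- c(vocab$bos, ids, vocab$eos)
  if (length(ids) > max_len)
    stop(sprintf("encoded length %d exceeds max_len %d", length(ids), max_len))
  n_real <- length(ids)
  i_pos <- which(ids == vocab$idr_tok)
  if (length(i_pos) > 1L) stop("<I> occurs more than once")
  prompt_len <- if (length(i_pos) == 1L) i_pos else NA_integer_
  ids <- c(ids, rep(vocab$pad, max_len - n_real))
  structure(list(ids = ids, n_real = n_real, prompt_len = prompt_len),
            class = "token_sequence")
}

#' Decode token ids back to a token string
#'
#' Inverse of [encode_tokens()] on the non-pad region: strips \code{<bos>},
#' \code{<eos>} and padding and concatenates the remaining tokens.
#' @param ids 0-based token ids (vector or \code{token_sequence}).
#' @param vocab vocabulary.
#' @export
decode_tokens <- function(ids, vocab = idr_vocab()) {
  if (inherits(ids, "token_sequence")) ids <- ids$ids
  ids <- ids[ids != vocab$pad]
  toks <- vocab$tokens[ids + 1L]
  toks <- toks[!toks %in% c("<bos>", "<eos>")]
  paste(toks, collapse = "")
}

#' Encode a corpus of IDR records
#'
#' Applies [fim_transform()] (optionally after [augment_corpus()]) and
#' encodes each record, dropping records whose token length exceeds
#' \code{max_len}.
#'
#' @param records list of \code{idr_record}s.
#' @param max_len token budget per sequence.
#' @param idp_augment add context-deleted duplicates before encoding.
#' @param pad keep per-sequence padding (\code{FALSE} returns ragged id
#'   vectors, the form the trainer consumes).
#' @return list of 0-based integer id vectors; attribute \code{n_dropped}
#'   counts over-length records.
#' @export
encode_corpus <- function(records, max_len = 512L, idp_augment = FALSE,
                          pad = FALSE) {
  vocab <- idr_vocab()
  if (idp_augment) records <- augment_corpus(records)
  out <- vector("list", length(records))
  dropped <- 0L
  for (i in seq_along(records)) {
    text <- fim_transform(records[[i]])
    enc <- tryCatch(encode_tokens(text, max_len = max_len, vocab = vocab),
                    error = function(e) NULL)
    if (is.null(enc)) { dropped <- dropped + 1L; next }
    out[[i]] <- if (pad) enc$ids else enc$ids[seq_len(enc$n_real)]
  }
  out <- out[!vapply(out, is.null, logical(1))]
  attr(out, "n_dropped") <- dropped
  out
}

#' Read / write IDR records as JSONL
#'
#' One JSON object per line with keys \code{protein_id}, \code{n_context},
#' \code{idr}, \code{c_context}, \code{idr_start}, \code{idr_end}.
#' @param records list of \code{idr_record}s.
#' @param path file path.
#' @export
write_idr_records <- function(records, path) {
  lines <- vapply(records, function(r) {
    jsonlite::toJSON(unclass(r), auto_unbox = TRUE)
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_idr_records
#' @export
read_idr_records <- function(path) {
  lines <- readLines(path)
  lapply(lines, function(l) {
    x <- jsonlite::fromJSON(l)
    idr_record(x$protein_id, x$n_context, x$idr, x$c_context,
               x$idr_start, x$idr_end)
  })
}

#' Write token-id corpora as JSONL
#'
#' Each line is a JSON array of 0-based token ids (unpadded).
#' @param corpus list of integer vectors from [encode_corpus()].
#' @param path file path.
#' @export
write_token_corpus <- function(corpus, path) {
  lines <- vapply(corpus, function(ids) {
    as.character(jsonlite::toJSON(as.integer(ids)))
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_token_corpus
#' @export
read_token_corpus <- function(path) {
  lapply(readLines(path), function(l) as.integer(jsonlite::fromJSON(l)))
}
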