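# Canonical 20-letter amino-acid alphabet, alphabetical by one-letter code.
AA20 <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
          "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

NONCANONICAL_AA <- c("X", "B", "Z", "U", "O", "J")

#' The 27-token alphabet
#'
#' Builds the fixed vocabulary used throughout the package: the 20 canonical
#' amino acids, the fill-in-the-middle sentinels \code{<N>} (N-terminal
#' context), \code{<C>} (C-terminal context) and \code{<I>} (IDR span), and
#' the control tokens \code{<bos>}, \code{<eos>}, \code{<pad>} and
#' \code{<mask>}.  \code{<mask>} is reserved: it is a member of the alphabet
#' but is never emitted by any encoder in this package (training is purely
#' causal).
#'
#' Token ids are dense and 0-based (0..26) so that serialized corpora are
#' portable; R-side code converts to 1-based indices where needed.
#'
#' @return A list of class \code{idrlm_vocab} with elements \code{tokens}
#'   (character vector of length 27), \code{id} (named integer vector mapping
#'   token to 0-based id), and the special-token ids \code{bos}, \code{eos},
#'   \code{pad}, \code{mask}, \code{n_ctx}, \code{c_ctx}, \code{idr_tok},
#'   plus \code{aa_ids} (0-based ids of the 20 amino acids).
#' @examples
#' v <- idr_vocab()
#' length(v$tokens)  # 27
#' @export
idr_vocab <- function() {
  tokens <- c(AA20, "<N>", "<C>", "<I>", "<bos>", "<eos>", "<pad>", "<mask>")
  stopifnot(length(tokens) == 27L)
  id <- stats::setNames(seq_along(tokens) - 1L, tokens)
  structure(list(
    tokens  = tokens,
    id      = id,
    size    = length(tokens),
    aa_ids  = unname(id[AA20]),
    n_ctx   = unname(id[["<N>"]]),
    c_ctx   = unname(id[["<C>"]]),
    idr_tok = unname(id[["<I>"]]),
    bos     = unname(id[["<bos>"]]),
    eos     = unname(id[["<eos>"]]),
    pad     = unname(id[["<pad>"]]),
    mask    = unname(id[["<mask>"]])
  ), class = "idrlm_vocab")
}

#' @export
print.idrlm_vocab <- function(x, ...) {
  cat("idrlm vocabulary:", x$size, "tokens\n")
  cat(" ", paste(x$tokens, collapse = " "), "\n")
  invisible(x)
}

#' Serialize / restore a vocabulary
#'
#' The token list is written as a JSON array so ids are fixed across runs and
#' languages.
#' @param vocab an \code{idrlm_vocab}.
#' @param path file path.
#' @export
write_vocab <- function(vocab, path) {
  jsonlite::write_json(vocab$tokens, path)
  invisible(path)
}

#' @rdname write_vocab
#' @export
read_vocab <- function(path) {
  tokens <- unlist(jsonlite::read_json(path))
  v <- idr_vocab()
  if (!identical(tokens, v$tokens))
    stop("vocabulary file does not match the fixed 27-token alphabet")
  v
}

# Split a token string such as "<N>MED<C>SVE<I>VEED" into individual tokens.
# Angle-bracketed names are single tokens; every other character is one token.
tokenize_text <- function(text) {
  if (!nzchar(text)) return(character(0))
  out <- character(0)
  chars <- strsplit(text, "", fixed = TRUE)[[1]]
  i <- 1L
  n <- length(chars)
  while (i <= n) {
    if (chars[i] == "<") {
      j <- i
      while (j <= n && chars[j] != ">") j <- j + 1L
      if (j > n) stop("unterminated '<' in token string")
      out <- c(out, paste(chars[i:j], collapse = ""))
      i <- j + 1L
    } else {
      out <- c(out, chars[i])
      i <- i + 1L
    }
  }
  out
}

check_canonical <- function(seq, what = "sequence") {
  if (!nzchar(seq)) return(invisible(TRUE))
  bad <- setdiff(unique(strsplit(seq, "", fixed = TRUE)[[1]]), AA20)
  if (length(bad))
    stop(sprintf("%s contains non-canonical residues: %s",
                 what, paste(bad, collapse = ", ")))
  invisible(TRUE)
}
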