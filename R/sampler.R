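# Autoregressive decoding: prompted (fill-in-the-middle) and unprompted
# modes, temperature sampling over the full categorical distribution, with a
# per-layer key/value cache so generation cost is linear per token.

#' Generation request
#'
#' @param mode \code{"prompted"} (condition on flanking contexts) or
#'   \code{"unprompted"} (bare \code{<N><C><I>} prompt for IDP generation).
#' @param n_context,c_context amino-acid context strings (prompted mode).
#' @param temperature softmax temperature T > 0 (default 1.0).
#' @param max_len cap on the total token count including the prompt
#'   (default 512).
#' @param seed integer seed for the sampling RNG.
#' @export
generation_request <- function(mode = c("unprompted", "prompted"),
                               n_context = "", c_context = "",
                               temperature = 1.0, max_len = 512L,
                               seed = 1L) {
  mode <- match.arg(mode)
  if (temperature <= 0) stop("temperature must be > 0")
  if (mode == "prompted") {
    check_canonical(n_context, "n_context")
    check_canonical(c_context, "c_context")
  }
  structure(list(mode = mode, n_context = n_context, c_context = c_context,
                 temperature = temperature, max_len = as.integer(max_len),
                 seed = as.integer(seed)),
            class = "generation_request")
}

#' Build the prompt token ids for a request
#'
#' Prompted mode yields \code{<bos><N>{n_ctx}<C>{c_ctx}<I>}; unprompted mode
#' yields \code{<bos><N><C><I>}.
#' @param req a [generation_request()].
#' @param vocab vocabulary.
#' @return integer vector of 0-based token ids.
#' @export
build_prompt <- function(req, vocab = idr_vocab()) {
  ctx_ids <- function(s) if (nzchar(s))
    unname(vocab$id[strsplit(s, "", fixed = TRUE)[[1]]]) else integer(0)
  ids <- c(vocab$bos, vocab$n_ctx,
           if (req$mode == "prompted") ctx_ids(req$n_context),
           vocab$c_ctx,
           if (req$mode == "prompted") ctx_ids(req$c_context),
           vocab$idr_tok)
  if (length(ids) >= req$max_len) stop("prompt alone reaches max_len")
  ids
}

# ---- incremental forward with KV cache -------------------------------------

# Cache: one environment per layer holding per-position key/value matrices,
# each (d x B) with the position's keys/values for the whole batch.
# Appending a position only copies the list spine (pointers), never the
# stored matrices, so per-token cost stays linear.
kv_cache_new <- function(cfg, B, max_len) {
  lapply(seq_len(cfg$n_layers), function(k) {
    e <- new.env(parent = emptyenv())
    e$K <- vector("list", max_len)
    e$V <- vector("list", max_len)
    e
  })
}

# Drop finished rows from a cache: keep_rows indexes the current batch.
kv_cache_compact <- function(cache, keep_rows, pos) {
  for (env in cache) {
    for (t in seq_len(pos)) {
      env$K[[t]] <- env$K[[t]][, keep_rows, drop = FALSE]
      env$V[[t]] <- env$V[[t]][, keep_rows, drop = FALSE]
    }
  }
  cache
}

# One decoding step, vectorized over the batch: new_ids is an integer vector
# of length B (0-based ids placed at position `pos`, 1-based).  Mutates the
# cache in place; returns logits (B x V) for the next token.
decode_step <- function(model, cache, new_ids, pos, rope) {
  cfg <- model$config; par <- model$params
  B <- length(new_ids)
  d <- cfg$d_model; nh <- cfg$n_heads; hd <- cfg$head_dim
  half <- hd %/% 2L
  scale <- 1 / sqrt(hd)
  COS <- matrix(rope$cos[pos, ], B, half, byrow = TRUE)
  SIN <- matrix(rope$sin[pos, ], B, half, byrow = TRUE)
  head_of_col <- rep(seq_len(nh), each = hd)
  Hmap <- outer(head_of_col, seq_len(nh), `==`) * scale
  # row picks turning per-(head,batch) softmax weights into per-column weights
  row_idx <- as.vector(outer(head_of_col, (seq_len(B) - 1L) * nh, `+`))
  nBP <- B * pos
  x <- par$tok_emb[new_ids + 1L, , drop = FALSE]
  for (k in seq_len(cfg$n_layers)) {
    p <- paste0("l", k, ".")
    a <- ln_forward(x, par[[paste0(p, "ln1_g")]], par[[paste0(p, "ln1_b")]],
                    cfg$ln_eps)$y
    qkv <- a %*% par[[paste0(p, "w_qkv")]]
    q <- qkv[, 1:d, drop = FALSE]
    kk <- qkv[, (d + 1):(2 * d), drop = FALSE]
    vv <- qkv[, (2 * d + 1):(3 * d), drop = FALSE]
    for (hh in seq_len(nh)) {
      colsh <- ((hh - 1L) * hd + 1L):(hh * hd)
      q[, colsh] <- rope_apply(q[, colsh, drop = FALSE], COS, SIN)
      kk[, colsh] <- rope_apply(kk[, colsh, drop = FALSE], COS, SIN)
    }
    env <- cache[[k]]
    env$K[[pos]] <- t(kk)
    env$V[[pos]] <- t(vv)
    KT <- matrix(unlist(env$K[seq_len(pos)], use.names = FALSE), d)  # (d, B*pos)
    E <- KT * as.vector(t(q))                  # query recycled over positions
    M3 <- crossprod(Hmap, E)                   # (nh, B*pos)
    dim(M3) <- c(nh * B, pos)                  # rows: head fastest, then batch
    mx <- M3[cbind(seq_len(nh * B), max.col(M3, ties.method = "first"))]
    W2 <- exp(M3 - mx)
    W2 <- W2 / rowSums(W2)
    WexpT <- W2[row_idx, , drop = FALSE]
    dim(WexpT) <- c(d, nBP)
    VT <- matrix(unlist(env$V[seq_len(pos)], use.names = FALSE), d)
    X <- VT * WexpT
    dim(X) <- c(d, B, pos)
    o <- t(rowSums(X, dims = 2))               # (B, d)
    x <- x + o %*% par[[paste0(p, "w_o")]]
    a2 <- ln_forward(x, par[[paste0(p, "ln2_g")]], par[[paste0(p, "ln2_b")]],
                     cfg$ln_eps)$y
    G <- a2 %*% par[[paste0(p, "w_gate")]]
    U <- a2 %*% par[[paste0(p, "w_up")]]
    x <- x + ((G * sigmoid(G)) * U) %*% par[[paste0(p, "w_down")]]
  }
  hfin <- ln_forward(x, par$lnf_g, par$lnf_b, cfg$ln_eps)$y
  w_head <- if (cfg$tie_embeddings) t(par$tok_emb) else par$w_head
  hfin %*% w_head
}

# sample one id per row from softmax(logits/T) with given forbidden ids
sample_rows <- function(logits, temperature, forbid_ids) {
  z <- logits / temperature
  if (length(forbid_ids)) z[, forbid_ids + 1L] <- -Inf
  z <- z - apply(z, 1L, max)
  p <- exp(z)
  p <- p / rowSums(p)
  cp <- t(apply(p, 1L, cumsum))
  u <- stats::runif(nrow(p))
  hit <- cp >= u
  ids0 <- max.col(hit, ties.method = "first") - 1L
  none <- rowSums(hit) == 0L          # float edge: u beyond last cumsum
  if (any(none))
    ids0[none] <- max.col(p[none, , drop = FALSE],
                          ties.method = "first") - 1L
  list(ids = ids0, probs = p)
}

#' Generate sequences by temperature sampling
#'
#' At each step the next token is drawn from
#' \code{softmax(logits / T)} over the vocabulary; generation stops on
#' \code{<eos>} or when the total token count (prompt included) reaches
#' \code{max_len}.  Sentinel and control tokens other than \code{<eos>} are
#' masked to \code{-Inf} during decoding so that outputs are pure residue
#' strings.  Deterministic under the request seed.
#'
#' @param model an \code{idrlm_model}.
#' @param req a [generation_request()].
#' @param n number of sequences to draw (batched).
#' @param greedy take the argmax instead of sampling (T to 0 limit).
#' @param return_logp also return the per-token log-probabilities of the
#'   sampled tokens under the (special-masked, temperature-scaled) sampling
#'   distribution actually used; the RL aligner consumes these as the
#'   old-policy log-probabilities.
#' @param backend \code{"compiled"} (C++ decoding loop, default) or
#'   \code{"reference"} (R loop); both are deterministic under the seed but
#'   consume the RNG stream differently, so their draws are not identical.
#' @return character vector of amino-acid strings; when \code{return_logp},
#'   a list with \code{seqs}, \code{ids} (list of completion id vectors,
#'   including the terminal \code{<eos>} when emitted), and \code{logp}
#'   (list of numeric vectors aligned with \code{ids}).
#' @export
generate <- function(model, req = generation_request(), n = 1L,
                     greedy = FALSE, return_logp = FALSE,
                     backend = c("compiled", "reference")) {
  backend <- match.arg(backend)
  vocab <- idr_vocab()
  if (model$config$vocab_size != vocab$size)
    stop("model vocabulary does not match the codec")
  set.seed(req$seed)
  prompt <- build_prompt(req, vocab)
  max_len <- min(req$max_len, model$config$max_len)
  forbid <- c(vocab$n_ctx, vocab$c_ctx, vocab$idr_tok, vocab$bos,
              vocab$pad, vocab$mask)
  if (backend == "compiled") {
    res <- .cpp_generate(model$params, unclass(model$config),
                         as.integer(prompt), as.integer(n),
                         as.integer(max_len), req$temperature,
                         as.integer(forbid), vocab$eos, isTRUE(greedy))
    seqs <- vapply(res$ids, function(ids) {
      ids <- ids[ids != vocab$eos]
      paste(vocab$tokens[ids + 1L], collapse = "")
    }, character(1))
    if (!return_logp) return(seqs)
    return(list(seqs = seqs, ids = res$ids, logp = res$logp,
                prompt = prompt))
  }
  rope <- rope_tables(max_len, model$config$head_dim, model$config$rope_base)
  cache <- kv_cache_new(model$config, n, max_len)
  # feed the prompt
  for (t in seq_along(prompt))
    logits <- decode_step(model, cache, rep(prompt[t], n), t, rope)
  out_ids <- vector("list", n)
  out_logp <- vector("list", n)
  active <- seq_len(n)       # original index of each current batch row
  alive <- rep(TRUE, n)      # rows of the current batch still generating
  pos <- length(prompt)
  while (pos < max_len && any(alive)) {
    nb <- length(active)
    if (greedy) {
      zmask <- logits
      zmask[, forbid + 1L] <- -Inf
      ids0 <- max.col(zmask, ties.method = "first") - 1L
      lp <- rep(0, nb)
    } else {
      sm <- sample_rows(logits, req$temperature, forbid)
      ids0 <- sm$ids
      lp <- if (return_logp)
        log(sm$probs[cbind(seq_len(nb), ids0 + 1L)]) else rep(0, nb)
    }
    for (j in which(alive)) {
      b <- active[j]
      out_ids[[b]] <- c(out_ids[[b]], ids0[j])
      if (return_logp) out_logp[[b]] <- c(out_logp[[b]], lp[j])
      if (ids0[j] == vocab$eos) alive[j] <- FALSE
    }
    if (!any(alive)) break
    # drop finished rows from the cache once enough have accumulated
    n_dead <- sum(!alive)
    if (n_dead >= 4L && n_dead >= 0.25 * nb) {
      keep <- which(alive)
      cache <- kv_cache_compact(cache, keep, pos)
      active <- active[keep]
      ids0 <- ids0[keep]
      alive <- rep(TRUE, length(active))
    }
    pos <- pos + 1L
    # rows finished but not yet compacted keep feeding <eos>; ignored above
    feed <- ifelse(alive, ids0, vocab$eos)
    logits <- decode_step(model, cache, feed, pos, rope)
  }
  seqs <- vapply(out_ids, function(ids) {
    ids <- ids[ids != vocab$eos]
    paste(vocab$tokens[ids + 1L], collapse = "")
  }, character(1))
  if (!return_logp) return(seqs)
  list(seqs = seqs, ids = out_ids, logp = out_logp, prompt = prompt)
}

#' First-token distribution of a request
#'
#' Returns the model's next-token probabilities immediately after the prompt
#' (specials masked as in [generate()]); used for sampling-correctness and
#' temperature-monotonicity checks.
#' @inheritParams generate
#' @return named probability vector over the vocabulary.
#' @export
first_token_probs <- function(model, req = generation_request()) {
  vocab <- idr_vocab()
  prompt <- build_prompt(req, vocab)
  logits <- model_forward(model, matrix(prompt, nrow = 1L))
  z <- logits[1, length(prompt), ] / req$temperature
  forbid <- c(vocab$n_ctx, vocab$c_ctx, vocab$idr_tok, vocab$bos,
              vocab$pad, vocab$mask)
  z[forbid + 1L] <- -Inf
  z <- z - max(z)
  p <- exp(z) / sum(exp(z))
  stats::setNames(p, vocab$tokens)
}
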