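# Decoder-only transformer: pre-LayerNorm, SwiGLU feedforward, rotary
# position embeddings, causal attention.  Forward and backward passes are
# written directly on base-R matrices (BLAS does the heavy lifting); the
# activations needed for the backward pass are cached by the forward pass.
#
# Parameters live in a flat named list of matrices/vectors:
#   tok_emb (V x d), l<k>.ln1_g/.ln1_b, l<k>.w_qkv (d x 3d), l<k>.w_o (d x d),
#   l<k>.ln2_g/.ln2_b, l<k>.w_gate/.w_up (d x h), l<k>.w_down (h x d),
#   lnf_g, lnf_b, w_head (d x V).
# No biases on projections; LayerNorm has scale + shift.

#' Transformer model configuration
#'
#' The default values are the full-scale architecture: 12 layers, 14 heads,
#' width 896, SwiGLU feedforward with expansion ratio 8/3, vocabulary 27,
#' context 512, untied output head.  The SwiGLU hidden width is
#' \code{ffn_ratio * d_model} rounded to the nearest multiple of 64.
#'
#' @param n_layers,n_heads,d_model architecture sizes.
#' @param ffn_ratio feedforward expansion ratio (default 8/3).
#' @param vocab_size alphabet size (default 27).
#' @param max_len context length in tokens (default 512).
#' @param tie_embeddings share input embedding and output head (default
#'   \code{FALSE}).
#' @param rope_base rotary embedding base frequency (default 10000).
#' @return list of class \code{model_config} with the derived fields
#'   \code{head_dim} and \code{ffn_hidden}.
#' @export
model_config <- function(n_layers = 12L, n_heads = 14L, d_model = 896L,
                         ffn_ratio = 8 / 3, vocab_size = 27L,
                         max_len = 512L, tie_embeddings = FALSE,
                         rope_base = 10000) {
  if (d_model %% n_heads != 0L)
    stop("d_model must be divisible by n_heads")
  head_dim <- d_model %/% n_heads
  if (head_dim %% 2L != 0L)
    stop("head dimension must be even for rotary embeddings")
  ffn_hidden <- max(64L, as.integer(round(ffn_ratio * d_model / 64) * 64))
  if (ffn_hidden < d_model) ffn_hidden <- as.integer(d_model)
  structure(list(n_layers = as.integer(n_layers),
                 n_heads = as.integer(n_heads),
                 d_model = as.integer(d_model),
                 ffn_ratio = ffn_ratio, vocab_size = as.integer(vocab_size),
                 max_len = as.integer(max_len), head_dim = head_dim,
                 ffn_hidden = ffn_hidden, tie_embeddings = tie_embeddings,
                 rope_base = rope_base, ln_eps = 1e-5),
            class = "model_config")
}

#' Build (initialize) a model
#'
#' Deterministic Gaussian initialization under the given seed: embeddings and
#' projections sd 0.02, residual output projections scaled by
#' \code{1/sqrt(2 * n_layers)}, LayerNorm at identity.
#'
#' @param config a [model_config()].
#' @param seed integer seed.
#' @return list of class \code{idrlm_model} with elements \code{config} and
#'   \code{params} (flat named list).
#' @export
build_model <- function(config = model_config(), seed = 1L) {
  set.seed(seed)
  d <- config$d_model; h <- config$ffn_hidden; V <- config$vocab_size
  sd0 <- 0.02
  sd_res <- sd0 / sqrt(2 * config$n_layers)
  rmat <- function(nr, nc, s) matrix(stats::rnorm(nr * nc, 0, s), nr, nc)
  params <- list(tok_emb = rmat(V, d, sd0))
  for (k in seq_len(config$n_layers)) {
    p <- paste0("l", k, ".")
    params[[paste0(p, "ln1_g")]] <- rep(1, d)
    params[[paste0(p, "ln1_b")]] <- rep(0, d)
    params[[paste0(p, "w_qkv")]] <- rmat(d, 3L * d, sd0)
    params[[paste0(p, "w_o")]]   <- rmat(d, d, sd_res)
    params[[paste0(p, "ln2_g")]] <- rep(1, d)
    params[[paste0(p, "ln2_b")]] <- rep(0, d)
    params[[paste0(p, "w_gate")]] <- rmat(d, h, sd0)
    params[[paste0(p, "w_up")]]   <- rmat(d, h, sd0)
    params[[paste0(p, "w_down")]] <- rmat(h, d, sd_res)
  }
  params$lnf_g <- rep(1, d)
  params$lnf_b <- rep(0, d)
  if (!config$tie_embeddings) params$w_head <- rmat(d, V, sd0)
  structure(list(config = config, params = params), class = "idrlm_model")
}

#' @export
print.idrlm_model <- function(x, ...) {
  cfg <- x$config
  cat(sprintf(
    "decoder-only transformer: %d layers, %d heads, d_model %d, ffn %d, vocab %d\n",
    cfg$n_layers, cfg$n_heads, cfg$d_model, cfg$ffn_hidden, cfg$vocab_size))
  cat(sprintf("  %s parameters (%s)\n",
              format(count_parameters(x), big.mark = ","),
              if (cfg$tie_embeddings) "tied head" else "untied head"))
  invisible(x)
}

#' Count trainable parameters
#'
#' Exact sum of trainable scalars over all weights.  With the full-scale
#' configuration this evaluates to about 115.2M; see the methods vignette for
#' the per-component breakdown.
#' @param model an \code{idrlm_model}.
#' @return integer count.
#' @export
count_parameters <- function(model) {
  sum(vapply(model$params, length, numeric(1)))
}

#' Per-component parameter breakdown
#'
#' @param model an \code{idrlm_model}.
#' @return data.frame with columns \code{component}, \code{count}.
#' @export
parameter_breakdown <- function(model) {
  n <- vapply(model$params, length, numeric(1))
  comp <- sub("^l[0-9]+\\.", "layer.", names(n))
  agg <- tapply(n, comp, sum)
  data.frame(component = names(agg), count = as.numeric(agg),
             row.names = NULL, stringsAsFactors = FALSE)
}

# ---- numerics helpers -------------------------------------------------------

sigmoid <- function(x) 1 / (1 + exp(-x))

# rowwise layer norm; returns y plus the cache needed for backward
ln_forward <- function(x, g, b, eps) {
  mu <- rowMeans(x)
  xc <- x - mu
  v <- rowMeans(xc * xc)
  inv_sd <- 1 / sqrt(v + eps)
  xhat <- xc * inv_sd
  y <- sweep(xhat, 2L, g, `*`)
  y <- sweep(y, 2L, b, `+`)
  list(y = y, xhat = xhat, inv_sd = inv_sd)
}

ln_backward <- function(dy, cache, g) {
  xhat <- cache$xhat
  dg <- colSums(dy * xhat)
  db <- colSums(dy)
  dxhat <- sweep(dy, 2L, g, `*`)
  m1 <- rowMeans(dxhat)
  m2 <- rowMeans(dxhat * xhat)
  dx <- cache$inv_sd * (dxhat - m1 - xhat * m2)
  list(dx = dx, dg = dg, db = db)
}

# rotary tables for positions 1..T (cos/sin matrices T x head_dim/2)
rope_tables <- function(max_pos, head_dim, base) {
  half <- head_dim %/% 2L
  inv_freq <- base^(-(2 * (seq_len(half) - 1)) / head_dim)
  ang <- outer(seq_len(max_pos) - 1, inv_freq)
  list(cos = cos(ang), sin = sin(ang))
}

# apply rotary rotation to one head's block (rows = flattened positions).
# COS/SIN are (nrow x half) aligned with the rows.
rope_apply <- function(xh, COS, SIN) {
  half <- ncol(xh) %/% 2L
  x1 <- xh[, 1:half, drop = FALSE]
  x2 <- xh[, (half + 1):(2 * half), drop = FALSE]
  cbind(x1 * COS - x2 * SIN, x1 * SIN + x2 * COS)
}

rope_apply_inv <- function(dxh, COS, SIN) {
  half <- ncol(dxh) %/% 2L
  d1 <- dxh[, 1:half, drop = FALSE]
  d2 <- dxh[, (half + 1):(2 * half), drop = FALSE]
  cbind(d1 * COS + d2 * SIN, -d1 * SIN + d2 * COS)
}

# ---- forward ---------------------------------------------------------------

#' Forward pass: per-position next-token logits
#'
#' Runs the model over a batch of token sequences and returns the logits at
#' every position.  Causality holds exactly: the logits at position t depend
#' only on tokens at positions <= t.
#'
#' Two numerically equivalent backends exist: \code{"compiled"} (C++ kernels,
#' the default) and \code{"reference"} (plain R matrix code).  The contract
#' is the math, not the kernel; tests assert agreement between the two.
#'
#' @param model an \code{idrlm_model}.
#' @param ids integer matrix (batch x time) of 0-based token ids, or a single
#'   integer vector.
#' @param want_cache keep activations for a subsequent [model_backward()]
#'   (reference backend only).
#' @param backend \code{"compiled"} or \code{"reference"}.
#' @return array (batch x time x vocab) of logits; when \code{want_cache} the
#'   cache is attached as attribute \code{"cache"}.
#' @export
model_forward <- function(model, ids, want_cache = FALSE,
                          backend = c("compiled", "reference")) {
  backend <- match.arg(backend)
  if (is.vector(ids)) ids <- matrix(as.integer(ids), nrow = 1L)
  if (backend == "compiled" && !want_cache) {
    storage.mode(ids) <- "integer"
    if (ncol(ids) > model$config$max_len) stop("sequence longer than max_len")
    return(.cpp_forward(model$params, unclass(model$config), ids))
  }
  cfg <- model$config; par <- model$params
  B <- nrow(ids); Tn <- ncol(ids)
  if (Tn > cfg$max_len) stop("sequence longer than max_len")
  d <- cfg$d_model; nh <- cfg$n_heads; hd <- cfg$head_dim
  half <- hd %/% 2L
  scale <- 1 / sqrt(hd)
  rope <- rope_tables(Tn, hd, cfg$rope_base)
  # rows grouped by sequence: row (b-1)*Tn + t
  pos_of_row <- rep(seq_len(Tn), times = B)
  COS <- rope$cos[pos_of_row, , drop = FALSE]
  SIN <- rope$sin[pos_of_row, , drop = FALSE]
  ids_vec <- as.vector(t(ids)) + 1L
  x <- par$tok_emb[ids_vec, , drop = FALSE]
  cache <- if (want_cache) list(ids = ids, ids_vec = ids_vec,
                                COS = COS, SIN = SIN, layers = vector("list", cfg$n_layers))
  mask_idx <- which(upper.tri(matrix(TRUE, Tn, Tn)))
  for (k in seq_len(cfg$n_layers)) {
    p <- paste0("l", k, ".")
    ln1 <- ln_forward(x, par[[paste0(p, "ln1_g")]], par[[paste0(p, "ln1_b")]],
                      cfg$ln_eps)
    qkv <- ln1$y %*% par[[paste0(p, "w_qkv")]]
    Q <- qkv[, 1:d, drop = FALSE]
    K <- qkv[, (d + 1):(2 * d), drop = FALSE]
    Vv <- qkv[, (2 * d + 1):(3 * d), drop = FALSE]
    for (hh in seq_len(nh)) {
      colsh <- ((hh - 1L) * hd + 1L):(hh * hd)
      Q[, colsh] <- rope_apply(Q[, colsh, drop = FALSE], COS, SIN)
      K[, colsh] <- rope_apply(K[, colsh, drop = FALSE], COS, SIN)
    }
    O <- matrix(0, B * Tn, d)
    Plist <- if (want_cache) vector("list", B * nh)
    for (b in seq_len(B)) {
      rows <- ((b - 1L) * Tn + 1L):(b * Tn)
      for (hh in seq_len(nh)) {
        colsh <- ((hh - 1L) * hd + 1L):(hh * hd)
        S <- tcrossprod(Q[rows, colsh, drop = FALSE],
                        K[rows, colsh, drop = FALSE]) * scale
        S[mask_idx] <- -Inf
        mx <- S[cbind(seq_len(Tn), max.col(S, ties.method = "first"))]
        E <- exp(S - mx)
        P <- E / rowSums(E)
        O[rows, colsh] <- P %*% Vv[rows, colsh, drop = FALSE]
        if (want_cache) Plist[[(b - 1L) * nh + hh]] <- P
      }
    }
    attn <- O %*% par[[paste0(p, "w_o")]]
    x_mid <- x + attn
    ln2 <- ln_forward(x_mid, par[[paste0(p, "ln2_g")]],
                      par[[paste0(p, "ln2_b")]], cfg$ln_eps)
    G <- ln2$y %*% par[[paste0(p, "w_gate")]]
    U <- ln2$y %*% par[[paste0(p, "w_up")]]
    sigG <- sigmoid(G)
    S_act <- G * sigG
    SU <- S_act * U
    ffn <- SU %*% par[[paste0(p, "w_down")]]
    x_out <- x_mid + ffn
    if (want_cache) {
      cache$layers[[k]] <- list(x_in = x, ln1 = ln1, Q = Q, K = K, V = Vv,
                                Plist = Plist, O = O, x_mid = x_mid,
                                ln2 = ln2, G = G, U = U, sigG = sigG,
                                SU = SU)
    }
    x <- x_out
  }
  lnf <- ln_forward(x, par$lnf_g, par$lnf_b, cfg$ln_eps)
  w_head <- if (cfg$tie_embeddings) t(par$tok_emb) else par$w_head
  logits_flat <- lnf$y %*% w_head
  logits <- aperm(array(logits_flat, c(Tn, B, cfg$vocab_size)), c(2, 1, 3))
  if (want_cache) {
    cache$x_final_in <- x
    cache$lnf <- lnf
    cache$B <- B; cache$Tn <- Tn
    attr(logits, "cache") <- cache
  }
  logits
}

# ---- backward --------------------------------------------------------------

# Parameter gradients for an arbitrary logit gradient: the workhorse behind
# both the pre-training loss and the GRPO surrogate.  The compiled backend
# recomputes the forward pass internally.
model_grads <- function(model, ids, dlogits,
                        backend = c("compiled", "reference")) {
  backend <- match.arg(backend)
  if (is.vector(ids)) ids <- matrix(as.integer(ids), nrow = 1L)
  if (backend == "compiled") {
    storage.mode(ids) <- "integer"
    g <- .cpp_backward(model$params, unclass(model$config), ids, dlogits)
    return(g[names(model$params)])
  }
  logits <- model_forward(model, ids, want_cache = TRUE,
                          backend = "reference")
  g <- model_backward(model, attr(logits, "cache"), dlogits)
  g[names(model$params)]
}

# dlogits: array (B x T x V).  Returns flat named list of parameter grads.
model_backward <- function(model, cache, dlogits) {
  cfg <- model$config; par <- model$params
  B <- cache$B; Tn <- cache$Tn
  d <- cfg$d_model; nh <- cfg$n_heads; hd <- cfg$head_dim
  scale <- 1 / sqrt(hd)
  COS <- cache$COS; SIN <- cache$SIN
  grads <- list()
  dl_flat <- matrix(aperm(dlogits, c(2, 1, 3)), B * Tn, cfg$vocab_size)
  w_head <- if (cfg$tie_embeddings) t(par$tok_emb) else par$w_head
  grads$w_head <- crossprod(cache$lnf$y, dl_flat)
  dy <- tcrossprod(dl_flat, w_head)
  lb <- ln_backward(dy, cache$lnf, par$lnf_g)
  grads$lnf_g <- lb$dg; grads$lnf_b <- lb$db
  dx <- lb$dx
  for (k in rev(seq_len(cfg$n_layers))) {
    p <- paste0("l", k, ".")
    cl <- cache$layers[[k]]
    # FFN branch
    dffn <- dx
    grads[[paste0(p, "w_down")]] <- crossprod(cl$SU, dffn)
    dSU <- tcrossprod(dffn, par[[paste0(p, "w_down")]])
    dS_act <- dSU * cl$U
    dU <- dSU * (cl$G * cl$sigG)
    dG <- dS_act * (cl$sigG * (1 + cl$G * (1 - cl$sigG)))
    grads[[paste0(p, "w_gate")]] <- crossprod(cl$ln2$y, dG)
    grads[[paste0(p, "w_up")]]   <- crossprod(cl$ln2$y, dU)
    dA2 <- tcrossprod(dG, par[[paste0(p, "w_gate")]]) +
           tcrossprod(dU, par[[paste0(p, "w_up")]])
    lb2 <- ln_backward(dA2, cl$ln2, par[[paste0(p, "ln2_g")]])
    grads[[paste0(p, "ln2_g")]] <- lb2$dg
    grads[[paste0(p, "ln2_b")]] <- lb2$db
    dx_mid <- dx + lb2$dx
    # attention branch
    grads[[paste0(p, "w_o")]] <- crossprod(cl$O, dx_mid)
    dO <- tcrossprod(dx_mid, par[[paste0(p, "w_o")]])
    dQ <- matrix(0, B * Tn, d)
    dK <- matrix(0, B * Tn, d)
    dV <- matrix(0, B * Tn, d)
    for (b in seq_len(B)) {
      rows <- ((b - 1L) * Tn + 1L):(b * Tn)
      for (hh in seq_len(nh)) {
        colsh <- ((hh - 1L) * hd + 1L):(hh * hd)
        P <- cl$Plist[[(b - 1L) * nh + hh]]
        dOb <- dO[rows, colsh, drop = FALSE]
        Vb <- cl$V[rows, colsh, drop = FALSE]
        dP <- tcrossprod(dOb, Vb)
        dV[rows, colsh] <- crossprod(P, dOb)
        dS <- P * (dP - rowSums(dP * P))
        dQ[rows, colsh] <- dS %*% cl$K[rows, colsh, drop = FALSE] * scale
        dK[rows, colsh] <- crossprod(dS, cl$Q[rows, colsh, drop = FALSE]) * scale
      }
    }
    for (hh in seq_len(nh)) {
      colsh <- ((hh - 1L) * hd + 1L):(hh * hd)
      dQ[, colsh] <- rope_apply_inv(dQ[, colsh, drop = FALSE], COS, SIN)
      dK[, colsh] <- rope_apply_inv(dK[, colsh, drop = FALSE], COS, SIN)
    }
    dQKV <- cbind(dQ, dK, dV)
    grads[[paste0(p, "w_qkv")]] <- crossprod(cl$ln1$y, dQKV)
    dA1 <- tcrossprod(dQKV, par[[paste0(p, "w_qkv")]])
    lb1 <- ln_backward(dA1, cl$ln1, par[[paste0(p, "ln1_g")]])
    grads[[paste0(p, "ln1_g")]] <- lb1$dg
    grads[[paste0(p, "ln1_b")]] <- lb1$db
    dx <- dx_mid + lb1$dx
  }
  # embedding scatter-add
  demb <- matrix(0, cfg$vocab_size, d)
  agg <- rowsum(dx, group = cache$ids_vec)
  demb[as.integer(rownames(agg)), ] <- agg
  if (cfg$tie_embeddings) {
    grads$tok_emb <- demb + t(grads$w_head)
    grads$w_head <- NULL
  } else {
    grads$tok_emb <- demb
  }
  grads
}

# ---- loss ------------------------------------------------------------------

log_softmax_rows <- function(z) {
  m <- z[cbind(seq_len(nrow(z)), max.col(z, ties.method = "first"))]
  zc <- z - m
  zc - log(rowSums(exp(zc)))
}

#' Next-token cross-entropy loss
#'
#' Mean cross-entropy in nats over non-ignored target positions.  The logit
#' row at position t scores the target at position t+1; positions whose
#' target token is in \code{ignore} (by default pad and the reserved mask
#' token) contribute nothing and are excluded from the mean.
#'
#' @param logits array (batch x time x vocab) from [model_forward()].
#' @param targets integer matrix (batch x time) of 0-based ids; column t is
#'   the target for logit position t (i.e. already shifted by one).
#' @param ignore 0-based token ids to exclude (default pad and mask).
#' @param want_grad also return the gradient with respect to the logits
#'   (used by the trainer).
#' @return scalar loss, or when \code{want_grad} a list
#'   \code{(loss, dlogits, n_tokens)}.
#' @export
next_token_loss <- function(logits, targets,
                            ignore = c(idr_vocab()$pad, idr_vocab()$mask),
                            want_grad = FALSE) {
  B <- dim(logits)[1]; Tn <- dim(logits)[2]; V <- dim(logits)[3]
  if (is.vector(targets)) targets <- matrix(as.integer(targets), nrow = 1L)
  stopifnot(nrow(targets) == B, ncol(targets) == Tn)
  z <- matrix(aperm(logits, c(2, 1, 3)), B * Tn, V)
  tg <- as.vector(t(targets))
  keep <- !(tg %in% ignore)
  if (!any(keep)) stop("all targets are ignored; loss undefined")
  lsm <- log_softmax_rows(z[keep, , drop = FALSE])
  picked <- lsm[cbind(seq_len(sum(keep)), tg[keep] + 1L)]
  loss <- -mean(picked)
  if (!want_grad) return(loss)
  n <- sum(keep)
  dflat <- matrix(0, B * Tn, V)
  probs <- exp(lsm)
  probs[cbind(seq_len(n), tg[keep] + 1L)] <-
    probs[cbind(seq_len(n), tg[keep] + 1L)] - 1
  dflat[keep, ] <- probs / n
  dlogits <- aperm(array(dflat, c(Tn, B, V)), c(2, 1, 3))
  list(loss = loss, dlogits = dlogits, n_tokens = n)
}

#' Read a model or training configuration from YAML
#'
#' Fields in the YAML file override the corresponding defaults of
#' [model_config()] / [train_config()].
#' @param path YAML file.
#' @export
model_config_from_yaml <- function(path) {
  x <- yaml::read_yaml(path)
  do.call(model_config, x[intersect(names(x), names(formals(model_config)))])
}

#' @rdname model_config_from_yaml
#' @export
train_config_from_yaml <- function(path) {
  x <- yaml::read_yaml(path)
  do.call(train_config, x[intersect(names(x), names(formals(train_config)))])
}

#' Save / load model checkpoints
#'
#' Weights are written as a flat JSON object (numeric arrays with dims) with
#' the config as a side-car field, so checkpoints are plain text.
#' @param model an \code{idrlm_model}.
#' @param path file path (.json).
#' @export
save_checkpoint <- function(model, path) {
  obj <- list(
    config = unclass(model$config),
    params = lapply(model$params, function(w) {
      if (is.matrix(w)) list(dim = dim(w), data = as.numeric(w))
      else list(dim = length(w), data = as.numeric(w))
    }))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  obj <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  cfg <- do.call(model_config, obj$config[c("n_layers", "n_heads", "d_model",
                                            "ffn_ratio", "vocab_size",
                                            "max_len", "tie_embeddings",
                                            "rope_base")])
  params <- lapply(obj$params, function(w) {
    if (length(w$dim) == 2L) matrix(w$data, w$dim[1], w$dim[2]) else w$data
  })
  structure(list(config = cfg, params = params), class = "idrlm_model")
}
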