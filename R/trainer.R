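# Pre-training: dataset splitting, warmup + cosine learning-rate schedule,
# AdamW, and the training loop with periodic validation.

#' Training configuration
#'
#' Defaults are the full-scale recipe: AdamW at peak learning rate 4.0e-4
#' decaying cosine-wise to 4.0e-5 (10 percent of peak) over 250,000 steps
#' after a 3,000-step linear warmup, no weight decay, no gradient clipping,
#' batch 1024, validation every 25,000 steps, 99/0.5/0.5 splits.  Tests and
#' examples override to desk-scale values via [desk_train_config()].
#'
#' @param peak_lr,min_lr learning-rate extremes.
#' @param warmup_steps,total_steps schedule lengths (optimizer steps).
#' @param batch_size sequences per step.
#' @param weight_decay AdamW decoupled weight decay (default 0).
#' @param val_every validation cadence in steps.
#' @param split_fracs train/validation/test fractions (sum to 1).
#' @param seed integer seed governing splits and data order.
#' @export
train_config <- function(peak_lr = 4.0e-4, min_lr = 4.0e-5,
                         warmup_steps = 3000L, total_steps = 250000L,
                         batch_size = 1024L, weight_decay = 0,
                         val_every = 25000L,
                         split_fracs = c(0.99, 0.005, 0.005), seed = 1L) {
  if (min_lr > peak_lr) stop("min_lr must not exceed peak_lr")
  if (warmup_steps >= total_steps) stop("warmup_steps must be < total_steps")
  if (abs(sum(split_fracs) - 1) > 1e-8) stop("split fractions must sum to 1")
  structure(list(peak_lr = peak_lr, min_lr = min_lr,
                 warmup_steps = as.integer(warmup_steps),
                 total_steps = as.integer(total_steps),
                 batch_size = as.integer(batch_size),
                 weight_decay = weight_decay,
                 val_every = as.integer(val_every),
                 split_fracs = split_fracs, seed = as.integer(seed)),
            class = "train_config")
}

#' Desk-scale training profile
#'
#' A named profile for laptop-scale experiments: the same schedule shape at
#' small sizes (tiny batches, short runs).  Tests never need the full-scale
#' profile.
#' @param total_steps,batch_size,peak_lr,... overrides passed to
#'   [train_config()].
#' @export
desk_train_config <- function(total_steps = 500L, batch_size = 32L,
                              peak_lr = 3e-3, warmup_steps = 50L,
                              min_lr = peak_lr / 10, val_every = 250L, ...) {
  train_config(peak_lr = peak_lr, min_lr = min_lr,
               warmup_steps = warmup_steps, total_steps = total_steps,
               batch_size = batch_size, val_every = val_every, ...)
}

#' Random train/validation/test split
#'
#' Disjoint, exhaustive index sets with sizes within one of
#' \code{n * frac}, deterministic under the seed.
#' @param n_records number of records.
#' @param fracs three fractions summing to 1.
#' @param seed integer seed.
#' @return list with integer vectors \code{train}, \code{val}, \code{test}.
#' @export
split_dataset <- function(n_records, fracs = c(0.99, 0.005, 0.005),
                          seed = 1L) {
  if (abs(sum(fracs) - 1) > 1e-8) stop("fractions must sum to 1")
  if (n_records < 3L) stop("need at least 3 records")
  sizes <- floor(n_records * fracs)
  rem <- n_records - sum(sizes)
  if (rem > 0L) {
    fr <- n_records * fracs - sizes
    add <- order(fr, decreasing = TRUE)[seq_len(rem)]
    sizes[add] <- sizes[add] + 1L
  }
  set.seed(seed)
  perm <- sample.int(n_records)
  list(train = sort(perm[seq_len(sizes[1])]),
       val   = sort(perm[sizes[1] + seq_len(sizes[2])]),
       test  = sort(perm[sizes[1] + sizes[2] + seq_len(sizes[3])]))
}

#' Learning-rate schedule: linear warmup then cosine decay
#'
#' Ramps linearly from 0 to \code{peak_lr} over \code{warmup_steps}, then
#' follows a half-period cosine from \code{peak_lr} down to \code{min_lr} at
#' \code{total_steps}, constant \code{min_lr} afterwards.  Continuous at the
#' warmup boundary and monotone nonincreasing after it.
#'
#' @param step optimizer step (0-based; vectorized).
#' @param cfg a [train_config()].
#' @export
lr_schedule <- function(step, cfg = train_config()) {
  w <- cfg$warmup_steps; Tt <- cfg$total_steps
  ifelse(step <= w,
         cfg$peak_lr * (step / w),
         ifelse(step >= Tt,
                cfg$min_lr,
                cfg$min_lr + 0.5 * (cfg$peak_lr - cfg$min_lr) *
                  (1 + cos(pi * (step - w) / (Tt - w)))))
}

# ---- AdamW -----------------------------------------------------------------

adamw_init <- function(params) {
  list(m = lapply(params, function(w) w * 0),
       v = lapply(params, function(w) w * 0),
       t = 0L, beta1 = 0.9, beta2 = 0.999, eps = 1e-8)
}

adamw_step <- function(params, grads, state, lr, weight_decay = 0) {
  state$t <- state$t + 1L
  b1 <- state$beta1; b2 <- state$beta2
  bc1 <- 1 - b1^state$t; bc2 <- 1 - b2^state$t
  for (nm in names(grads)) {
    g <- grads[[nm]]
    state$m[[nm]] <- b1 * state$m[[nm]] + (1 - b1) * g
    state$v[[nm]] <- b2 * state$v[[nm]] + (1 - b2) * g * g
    mhat <- state$m[[nm]] / bc1
    vhat <- state$v[[nm]] / bc2
    upd <- mhat / (sqrt(vhat) + state$eps)
    if (weight_decay > 0) upd <- upd + weight_decay * params[[nm]]
    params[[nm]] <- params[[nm]] - lr * upd
  }
  list(params = params, state = state)
}

# pad a list of id vectors to a (B x Tmax) matrix of 0-based ids
pad_batch <- function(seq_list, pad_id) {
  Tmax <- max(vapply(seq_list, length, integer(1)))
  ids <- matrix(pad_id, length(seq_list), Tmax)
  for (i in seq_along(seq_list))
    ids[i, seq_along(seq_list[[i]])] <- seq_list[[i]]
  ids
}

# loss over a batch of ragged id vectors (inputs = ids[, -T], targets = ids[, -1])
batch_loss <- function(model, seq_list, vocab, want_grad = FALSE) {
  ids <- pad_batch(seq_list, vocab$pad)
  inputs <- ids[, -ncol(ids), drop = FALSE]
  targets <- ids[, -1L, drop = FALSE]
  storage.mode(inputs) <- "integer"
  if (!want_grad) {
    logits <- model_forward(model, inputs)
    return(next_token_loss(logits, targets,
                           ignore = c(vocab$pad, vocab$mask)))
  }
  fc <- .cpp_forward_cache(model$params, unclass(model$config), inputs)
  res <- next_token_loss(fc$logits, targets,
                         ignore = c(vocab$pad, vocab$mask), want_grad = TRUE)
  grads <- .cpp_backward_cached(model$params, unclass(model$config), inputs,
                                res$dlogits, fc$cache)
  list(loss = res$loss, grads = grads[names(model$params)])
}

#' Pre-train a model on an encoded corpus
#'
#' Autoregressive next-token training with AdamW, the warmup + cosine
#' schedule, shuffled (seeded) data order, pad-masked cross-entropy, and
#' periodic validation on a held-out split.
#'
#' @param model an \code{idrlm_model} (freshly built or resumed).
#' @param corpus list of 0-based token-id vectors from [encode_corpus()].
#' @param cfg a [train_config()] (use [desk_train_config()] at desk scale).
#' @param verbose print a progress line at each validation point.
#' @return list with \code{model} (trained), \code{history} (data.frame of
#'   step, lr, train_loss) and \code{val_history} (step, val_loss).
#' @export
pretrain <- function(model, corpus, cfg = desk_train_config(),
                     verbose = FALSE) {
  if (!length(corpus)) stop("empty corpus")
  vocab <- idr_vocab()
  split <- split_dataset(length(corpus), cfg$split_fracs, cfg$seed)
  train_idx <- split$train; val_idx <- split$val
  if (!length(train_idx)) stop("empty training split")
  set.seed(cfg$seed + 1L)
  state <- adamw_init(model$params)
  history <- data.frame(step = integer(0), lr = numeric(0),
                        train_loss = numeric(0))
  val_history <- data.frame(step = integer(0), val_loss = numeric(0))
  order_pool <- sample(train_idx)
  pool_pos <- 1L
  for (step in seq_len(cfg$total_steps)) {
    bs <- min(cfg$batch_size, length(train_idx))
    if (pool_pos + bs - 1L > length(order_pool)) {
      order_pool <- sample(train_idx)
      pool_pos <- 1L
    }
    batch_idx <- order_pool[pool_pos:(pool_pos + bs - 1L)]
    pool_pos <- pool_pos + bs
    res <- batch_loss(model, corpus[batch_idx], vocab, want_grad = TRUE)
    lr <- lr_schedule(step, cfg)
    upd <- adamw_step(model$params, res$grads, state, lr, cfg$weight_decay)
    model$params <- upd$params
    state <- upd$state
    history <- rbind(history,
                     data.frame(step = step, lr = lr, train_loss = res$loss))
    if (length(val_idx) && (step %% cfg$val_every == 0L ||
                            step == cfg$total_steps)) {
      vl <- batch_loss(model, corpus[val_idx], vocab)
      val_history <- rbind(val_history,
                           data.frame(step = step, val_loss = vl))
      if (verbose)
        message(sprintf("step %d  lr %.2e  train %.4f  val %.4f",
                        step, lr, res$loss, vl))
    }
  }
  list(model = model, history = history, val_history = val_history)
}
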