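# GRPO post-training: group-relative advantages, PPO-style clipping, a
# KL-to-reference penalty, prompt masking, and the composite quadratic reward
# (pluggable score model; a toy localization reward ships with the package).

#' Reward specification for post-training
#'
#' The composite reward is a sum of quadratic penalties around three targets:
#' a score-model output of 0.9, a sequence length of 100 residues, and a
#' per-sequence Shannon composition entropy of 2.7 nats.  The maximum reward
#' (zero) is attained exactly when all three targets are met.  Lengths are
#' normalized by \code{length_scale} so the three terms are comparable.
#'
#' @param target_score score-model target in [0, 1] (default 0.9).
#' @param target_length length target in residues (default 100).
#' @param target_entropy Shannon entropy target in nats (default 2.7; must
#'   lie in (0, ln 20]).
#' @param w_score,w_length,w_entropy nonnegative penalty weights (default 1
#'   each; set a weight to 0 to drop that term).
#' @param length_scale residues per unit of the length penalty (default 100).
#' @export
reward_spec <- function(target_score = 0.9, target_length = 100,
                        target_entropy = 2.7, w_score = 1, w_length = 1,
                        w_entropy = 1, length_scale = 100) {
  stopifnot(w_score >= 0, w_length >= 0, w_entropy >= 0,
            target_entropy > 0, target_entropy <= log(20) + 1e-12)
  structure(list(target_score = target_score, target_length = target_length,
                 target_entropy = target_entropy, w_score = w_score,
                 w_length = w_length, w_entropy = w_entropy,
                 length_scale = length_scale),
            class = "reward_spec")
}

#' GRPO configuration
#'
#' Defaults follow the full-scale recipe (group size 8, clip 0.2, KL weight
#' 0.02, learning rate 5e-6, 1500 steps); desk-scale runs override the
#' learning rate and step count via [desk_grpo_config()].
#'
#' @param group_size completions per prompt G (>= 2).
#' @param clip PPO clipping width epsilon in (0, 1).
#' @param kl_weight KL penalty strength beta.
#' @param lr AdamW learning rate.
#' @param batch_prompts prompts per optimizer step.
#' @param steps optimizer steps.
#' @param gen_max_len token cap during completion sampling.
#' @param kl_direction \code{"reference_policy"} penalizes
#'   KL(reference || policy) as printed in the training objective;
#'   \code{"policy_reference"} is the conventional alternative.
#' @param kl_estimator \code{"exact"} computes the per-position KL over the
#'   full 27-token vocabulary (cheap at this alphabet size, zero variance);
#'   \code{"k3"} uses the sampled-token k3 estimator.
#' @param token_level_loss DAPO-style aggregation: normalize the loss by the
#'   total completion-token count across the batch rather than per sequence.
#' @export
grpo_config <- function(group_size = 8L, clip = 0.2, kl_weight = 0.02,
                        lr = 5e-6, batch_prompts = 8L, steps = 1500L,
                        gen_max_len = 512L,
                        kl_direction = c("reference_policy",
                                         "policy_reference"),
                        kl_estimator = c("exact", "k3"),
                        token_level_loss = TRUE) {
  stopifnot(group_size >= 2L, clip > 0, clip < 1, kl_weight >= 0)
  structure(list(group_size = as.integer(group_size), clip = clip,
                 kl_weight = kl_weight, lr = lr,
                 batch_prompts = as.integer(batch_prompts),
                 steps = as.integer(steps),
                 gen_max_len = as.integer(gen_max_len),
                 kl_direction = match.arg(kl_direction),
                 kl_estimator = match.arg(kl_estimator),
                 token_level_loss = token_level_loss),
            class = "grpo_config")
}

#' Desk-scale GRPO profile
#'
#' Same algorithm at desk scale: the learning rate is raised to 1e-3 because
#' the tiny models used here have ~1e5 parameters rather than ~1e8 (policy
#' updates scale with model size under Adam), and completion sampling is
#' capped at 256 tokens.
#' @param steps,lr,batch_prompts,gen_max_len,... overrides for
#'   [grpo_config()].
#' @export
desk_grpo_config <- function(steps = 400L, lr = 1e-3, batch_prompts = 4L,
                             gen_max_len = 256L, ...) {
  grpo_config(steps = steps, lr = lr, batch_prompts = batch_prompts,
              gen_max_len = gen_max_len, ...)
}

#' Shannon entropy of a sequence's residue composition
#'
#' \code{H = -sum_a p_a ln p_a} over the 20 canonical residues, with
#' \code{p_a} the within-sequence frequency.  Reported in nats; ranges from
#' 0 (homopolymer) to ln 20 (uniform composition).
#' @param seq non-empty amino-acid string.
#' @export
sequence_entropy <- function(seq) {
  if (!nzchar(seq)) stop("empty sequence")
  p <- aa_composition(seq)
  p <- p[p > 0]
  -sum(p * log(p))
}

#' Composite quadratic reward
#'
#' \code{r = -w_s (score - s*)^2 - w_L ((len - L*) / scale)^2
#'        - w_H (H - H*)^2}; zero exactly at the three targets.  Empty
#' sequences are scored with entropy 0.
#'
#' @param seq amino-acid string (may be empty).
#' @param score score-model output in [0, 1].
#' @param spec a [reward_spec()].
#' @export
composite_reward <- function(seq, score, spec = reward_spec()) {
  if (!is.na(score) && (score < 0 || score > 1)) stop("score must be in [0,1]")
  H <- if (nzchar(seq)) sequence_entropy(seq) else 0
  r <- -spec$w_length * ((nchar(seq) - spec$target_length) /
                           spec$length_scale)^2 -
       spec$w_entropy * (H - spec$target_entropy)^2
  if (spec$w_score > 0)
    r <- r - spec$w_score * (score - spec$target_score)^2
  r
}

#' Group-relative advantages
#'
#' \code{A_i = (r_i - mean(r)) / (sd_pop(r) + 1e-8)} with the population
#' standard deviation; a group of identical rewards yields all-zero
#' advantages (never NaN).  Advantages always sum to zero.
#' @param rewards numeric vector of G >= 2 rewards.
#' @export
group_advantages <- function(rewards) {
  G <- length(rewards)
  if (G < 2L) stop("group size must be >= 2")
  mu <- mean(rewards)
  sd_pop <- sqrt(mean((rewards - mu)^2))
  (rewards - mu) / (sd_pop + 1e-8)
}

#' Toy localization reward
#'
#' A deterministic logistic score over interpretable composition features,
#' standing in for a neural localization predictor so that desk-scale RL is
#' runnable end to end.  The score is
#' \code{plogis(-2 + 6 f_KR + 3 f_G + 0.8 n_RGG / (len/100))} where
#' \code{f_KR} is the K+R fraction, \code{f_G} the glycine fraction and
#' \code{n_RGG} the RGG-tract count -- features associated with nucleolar /
#' RNA-granule targeting.  Output is always in [0, 1] and monotone in the
#' K+R fraction.  This is a synthetic stand-in, not a trained predictor.
#'
#' @param seq non-empty amino-acid string.
#' @export
toy_localization_reward <- function(seq) {
  if (!nzchar(seq)) stop("empty sequence")
  chars <- strsplit(seq, "", fixed = TRUE)[[1]]
  f_kr <- mean(chars %in% c("K", "R"))
  f_g <- mean(chars == "G")
  n_rgg <- nrow(motif_scan(seq, data.frame(name = "RGG", regex = "RGG")))
  stats::plogis(-2 + 6 * f_kr + 3 * f_g + 0.8 * n_rgg / (nchar(seq) / 100))
}

#' Wrap an external reward executable
#'
#' Returns a score-model function that pipes one sequence per line to the
#' executable and reads one probability per line back, so an external neural
#' reward model can be plugged in without code changes.
#' @param cmd path to an executable implementing the line protocol.
#' @export
command_score_model <- function(cmd) {
  force(cmd)
  function(seq) {
    out <- system2(cmd, input = seq, stdout = TRUE)
    p <- as.numeric(out[length(out)])
    if (!is.finite(p) || p < 0 || p > 1)
      stop("external reward model returned invalid probability: ", out)
    p
  }
}

# ---- GRPO update -----------------------------------------------------------

# deterministic seed mixing kept within 32-bit integer range
mix_seed <- function(a, b) {
  as.integer((as.numeric(a) * 7919 + as.numeric(b)) %% 2147483562)
}

# log-softmax with the sampler's special-token mask applied, so the policy
# that is optimized is exactly the policy that sampled.
masked_log_softmax <- function(z, forbid_cols) {
  z[, forbid_cols] <- -Inf
  log_softmax_rows(z)
}

# Build the padded batch (prompt + completion ids) and index bookkeeping for
# one update: returns inputs, target ids, completion-position masks.
assemble_rollouts <- function(prompt, completions, pad_id) {
  B <- length(completions)
  full <- lapply(completions, function(ids) c(prompt, ids))
  Tmax <- max(vapply(full, length, integer(1)))
  inputs <- matrix(pad_id, B, Tmax - 1L)
  targets <- matrix(pad_id, B, Tmax - 1L)
  comp_mask <- matrix(FALSE, B, Tmax - 1L)
  for (b in seq_len(B)) {
    ids <- full[[b]]
    L <- length(ids)
    inputs[b, seq_len(L - 1L)] <- ids[-L]
    targets[b, seq_len(L - 1L)] <- ids[-1L]
    # completion targets: positions whose target is a sampled token
    comp_mask[b, seq(length(prompt), L - 1L)] <- TRUE
  }
  list(inputs = inputs, targets = targets, comp_mask = comp_mask)
}

#' One GRPO optimizer step
#'
#' Samples \code{G} completions per prompt from the current policy, scores
#' them with the composite reward, computes group-relative advantages, and
#' takes one AdamW step on the clipped surrogate objective plus the KL
#' penalty to the frozen reference.  Prompt tokens are masked from the loss.
#'
#' The objective per completion token is
#' \code{min(rho_t A, clip(rho_t, 1 - eps, 1 + eps) A)} with
#' \code{rho_t} the probability ratio to the old (sampling-time) policy;
#' with a single inner epoch the ratios start at 1, making the update the
#' group-normalized policy gradient while the clip guards pathological
#' ratios.  The KL penalty uses the exact per-position divergence over the
#' vocabulary by default (see [grpo_config()]).
#'
#' @param policy current policy model.
#' @param reference frozen reference model (pre-trained checkpoint).
#' @param prompts list of [generation_request()]s (one per prompt slot).
#' @param cfg a [grpo_config()].
#' @param spec a [reward_spec()].
#' @param score_model function(sequence) -> probability in [0, 1], or
#'   \code{NULL} when \code{spec$w_score == 0}.
#' @param opt_state AdamW state (created on first call).
#' @param step_seed integer seed for this step's sampling.
#' @return list with updated \code{policy}, \code{opt_state}, and
#'   \code{metrics} (mean_reward, mean_length, kl, mean_entropy,
#'   grad_norm, max_ratio_term).
#' @export
grpo_update <- function(policy, reference, prompts, cfg = grpo_config(),
                        spec = reward_spec(), score_model = NULL,
                        opt_state = NULL, step_seed = 1L) {
  vocab <- idr_vocab()
  forbid_cols <- c(vocab$n_ctx, vocab$c_ctx, vocab$idr_tok, vocab$bos,
                   vocab$pad, vocab$mask) + 1L
  G <- cfg$group_size
  all_ids <- list(); all_logp_old <- list(); groups <- list()
  seqs <- character(0)
  prompt_ids <- NULL
  for (ip in seq_along(prompts)) {
    req <- prompts[[ip]]
    req$seed <- mix_seed(step_seed, ip)
    req$max_len <- min(req$max_len, cfg$gen_max_len)
    roll <- generate(policy, req, n = G, return_logp = TRUE)
    if (is.null(prompt_ids)) prompt_ids <- roll$prompt
    if (!identical(roll$prompt, prompt_ids))
      stop("all prompts in one update must share a prompt template")
    all_ids <- c(all_ids, roll$ids)
    all_logp_old <- c(all_logp_old, roll$logp)
    seqs <- c(seqs, roll$seqs)
    groups[[ip]] <- (ip - 1L) * G + seq_len(G)
  }
  B <- length(all_ids)
  # rewards and advantages
  scores <- if (spec$w_score > 0) {
    vapply(seqs, function(s) {
      sc <- tryCatch(score_model(s), error = function(e)
        stop("score model failed: ", conditionMessage(e)))
      sc
    }, numeric(1))
  } else rep(NA_real_, B)
  rewards <- vapply(seq_len(B), function(i)
    composite_reward(seqs[i], scores[i], spec), numeric(1))
  adv <- numeric(B)
  for (g in groups) adv[g] <- group_advantages(rewards[g])
  # forward over the padded rollouts
  ro <- assemble_rollouts(prompt_ids, all_ids, vocab$pad)
  storage.mode(ro$inputs) <- "integer"
  fc <- .cpp_forward_cache(policy$params, unclass(policy$config), ro$inputs)
  logits <- fc$logits
  ref_logits <- model_forward(reference, ro$inputs)
  Tn <- ncol(ro$inputs); V <- vocab$size
  zP <- matrix(aperm(logits, c(2, 1, 3)), B * Tn, V)
  zR <- matrix(aperm(ref_logits, c(2, 1, 3)), B * Tn, V)
  keep <- as.vector(t(ro$comp_mask))
  tg <- as.vector(t(ro$targets))
  rows <- which(keep)
  lpP <- masked_log_softmax(zP[rows, , drop = FALSE], forbid_cols)
  lpR <- masked_log_softmax(zR[rows, , drop = FALSE], forbid_cols)
  pick <- cbind(seq_along(rows), tg[rows] + 1L)
  logp_new <- lpP[pick]
  logp_old <- unlist(all_logp_old)
  stopifnot(length(logp_old) == length(rows))
  adv_tok <- rep(adv, times = vapply(all_ids, length, integer(1)))
  rho <- exp(logp_new - logp_old)
  # clipped surrogate; gradient flows only where the unclipped branch is active
  unclipped <- rho * adv_tok
  clipped <- pmin(pmax(rho, 1 - cfg$clip), 1 + cfg$clip) * adv_tok
  surrogate <- pmin(unclipped, clipped)
  active <- unclipped <= clipped + 1e-12
  # per-token contribution weights (token-level normalization by default;
  # otherwise 1/(B * len_b) per sequence)
  wtok <- if (cfg$token_level_loss) rep(1 / length(rows), length(rows))
          else {
            lens <- vapply(all_ids, length, integer(1))
            rep(1 / (B * lens), times = lens)
          }
  pP <- exp(lpP)
  pR <- exp(lpR)
  # KL estimate on completion tokens
  kl_exact_rp <- rowSums(ifelse(pR > 0, pR * (lpR - lpP), 0))
  kl_exact_pr <- rowSums(ifelse(pP > 0, pP * (lpP - lpR), 0))
  kl_value <- if (cfg$kl_estimator == "exact") {
    if (cfg$kl_direction == "reference_policy") mean(kl_exact_rp)
    else mean(kl_exact_pr)
  } else {
    r3 <- exp(lpR[pick] - logp_new)          # k3 on sampled tokens
    mean(r3 - 1 - log(r3))
  }
  # gradient wrt policy logits
  onehot_minus_p <- -pP
  onehot_minus_p[pick] <- onehot_minus_p[pick] + 1
  g_policy <- -(active * rho * adv_tok * wtok) * onehot_minus_p
  if (cfg$kl_weight > 0) {
    g_kl <- if (cfg$kl_direction == "reference_policy") (pP - pR)
            else {
              # d/dz of exact KL(policy || ref) = p * (log p - log r - KL)
              ifelse(pP > 0, pP * ((lpP - lpR) - kl_exact_pr), 0)
            }
    g_policy <- g_policy + cfg$kl_weight * g_kl / length(rows)
  }
  dflat <- matrix(0, B * Tn, V)
  dflat[rows, ] <- g_policy
  dflat[, forbid_cols] <- 0                   # masked logits get no gradient
  dlogits <- aperm(array(dflat, c(Tn, B, V)), c(2, 1, 3))
  grads <- .cpp_backward_cached(policy$params, unclass(policy$config),
                                ro$inputs, dlogits, fc$cache)
  grads <- grads[names(policy$params)]
  if (is.null(opt_state)) opt_state <- adamw_init(policy$params)
  upd <- adamw_step(policy$params, grads, opt_state, cfg$lr)
  policy$params <- upd$params
  gn <- sqrt(sum(vapply(grads, function(g) sum(g * g), numeric(1))))
  lens <- nchar(seqs)
  ents <- vapply(seqs, function(s) if (nzchar(s)) sequence_entropy(s) else 0,
                 numeric(1))
  list(policy = policy, opt_state = upd$state,
       metrics = data.frame(
         mean_reward = mean(rewards), mean_length = mean(lens),
         kl = kl_value, mean_entropy = mean(ents), grad_norm = gn,
         max_ratio_term = max(abs(surrogate)),
         clip_ok = all(abs(surrogate) <=
                         (1 + cfg$clip) * abs(adv_tok) + 1e-9)))
}

#' Run a GRPO alignment loop
#'
#' Repeats [grpo_update()] for \code{cfg$steps} optimizer steps against a
#' frozen copy of the starting policy and collects per-step metrics
#' (mean reward, mean generated length, KL estimate, mean entropy).
#'
#' @param model pre-trained \code{idrlm_model}; a frozen copy becomes the
#'   reference.
#' @param cfg a [grpo_config()] (use [desk_grpo_config()] at desk scale).
#' @param spec a [reward_spec()].
#' @param score_model scoring function, or \code{NULL} when the score weight
#'   is zero.
#' @param prompt_request template [generation_request()] (default
#'   unprompted IDP generation, as used for all post-training runs).
#' @param seed integer seed.
#' @param verbose print a metrics line every 50 steps.
#' @return list with \code{policy} (aligned model), \code{reference}, and
#'   \code{metrics} (one row per step).
#' @export
grpo_train <- function(model, cfg = desk_grpo_config(), spec = reward_spec(),
                       score_model = NULL,
                       prompt_request = generation_request("unprompted"),
                       seed = 1L, verbose = FALSE) {
  reference <- model
  policy <- model
  opt_state <- NULL
  metrics <- NULL
  prompts <- rep(list(prompt_request), cfg$batch_prompts)
  for (step in seq_len(cfg$steps)) {
    res <- grpo_update(policy, reference, prompts, cfg, spec, score_model,
                       opt_state, step_seed = mix_seed(seed, step))
    policy <- res$policy
    opt_state <- res$opt_state
    row <- cbind(step = step, res$metrics)
    metrics <- if (is.null(metrics)) row else rbind(metrics, row)
    if (verbose && step %% 50L == 0L)
      message(sprintf("step %d  reward %.4f  len %.1f  KL %.4f  H %.3f",
                      step, row$mean_reward, row$mean_length, row$kl,
                      row$mean_entropy))
  }
  list(policy = policy, reference = reference, metrics = metrics)
}
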