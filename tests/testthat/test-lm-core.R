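# Transformer core: configuration, parameter counting, causality, loss, and
# agreement between the compiled and reference backends.

test_that("config validation and derived fields", {
  cfg <- model_config()
  expect_equal(cfg$head_dim, 64L)
  expect_equal(cfg$ffn_hidden, 2368L)   # 8/3 * 896 rounded to multiple of 64
  expect_error(model_config(n_heads = 13L, d_model = 896L), "divisible")
})

test_that("initialization is deterministic under the seed", {
  cfg <- micro_config()
  m1 <- build_model(cfg, seed = 3L)
  m2 <- build_model(cfg, seed = 3L)
  ids <- matrix(sample(0:26, 10), 1)
  expect_identical(model_forward(m1, ids), model_forward(m2, ids))
  m3 <- build_model(cfg, seed = 4L)
  expect_gt(max(abs(model_forward(m1, ids) - model_forward(m3, ids))), 0)
})

test_that("parameter count matches a shape-sum oracle on a toy config", {
  cfg <- model_config(n_layers = 2L, n_heads = 4L, d_model = 64L,
                      vocab_size = 27L)
  m <- build_model(cfg, seed = 1L)
  d <- 64; h <- cfg$ffn_hidden; V <- 27
  per_layer <- (d * 3 * d) + (d * d) +      # qkv + output projection
               3 * d * h +                  # swiglu gate/up/down
               2 * (2 * d)                  # two layer norms (scale+shift)
  oracle <- V * d +                         # embedding
            2 * per_layer +
            2 * d +                         # final layer norm
            d * V                           # untied head
  expect_identical(count_parameters(m), oracle)
  # adding one vocabulary token adds one embedding row and one head column
  cfg2 <- model_config(n_layers = 2L, n_heads = 4L, d_model = 64L,
                       vocab_size = 28L)
  expect_identical(count_parameters(build_model(cfg2, seed = 1L)),
                   oracle + 2L * 64L)
  bd <- parameter_breakdown(m)
  expect_equal(sum(bd$count), oracle)
})

test_that("logits are causal: future tokens never affect earlier positions", {
  m <- build_model(micro_config(), seed = 11L)
  set.seed(2)
  for (i in 1:50) {
    Tn <- sample(6:16, 1)
    ids <- sample(0:26, Tn, replace = TRUE)
    pos <- sample(2:(Tn - 1), 1)
    ids2 <- ids
    ids2[pos + 1] <- (ids[pos + 1] + sample(1:26, 1)) %% 27
    l1 <- model_forward(m, ids)
    l2 <- model_forward(m, ids2)
    expect_identical(l1[1, 1:pos, ], l2[1, 1:pos, ])
    expect_gt(max(abs(l1[1, (pos + 1):Tn, ] - l2[1, (pos + 1):Tn, ])), 0)
  }
})

test_that("rotary embeddings make logits order-sensitive", {
  m <- build_model(micro_config(), seed = 13L)
  ids <- c(3L, 3L, 7L, 7L, 12L, 12L)
  perm <- c(12L, 7L, 3L, 7L, 3L, 12L)
  l1 <- model_forward(m, ids)
  l2 <- model_forward(m, perm)
  # last-position logits differ although the token multiset is identical
  expect_gt(max(abs(l1[1, 6, ] - l2[1, 6, ])), 1e-8)
})

test_that("next-token loss handles uniform, near-one-hot, and random cases", {
  V <- 27L
  B <- 2L; Tn <- 5L
  v <- idr_vocab()
  unif <- array(0, c(B, Tn, V))
  targets <- matrix(sample(0:19, B * Tn, replace = TRUE), B, Tn)
  expect_equal(next_token_loss(unif, targets), log(27), tolerance = 1e-12)
  # strongly peaked logits on the correct class drive the loss to zero
  onehot <- array(-50, c(B, Tn, V))
  for (b in 1:B) for (t in 1:Tn) onehot[b, t, targets[b, t] + 1] <- 50
  expect_lt(next_token_loss(onehot, targets), 1e-6)
  # random logits match a direct softmax/log-pick oracle
  set.seed(21)
  z <- array(rnorm(B * Tn * V), c(B, Tn, V))
  targets[1, 4:5] <- c(v$pad, v$mask)   # ignored positions
  oracle <- local({
    tot <- 0; n <- 0
    for (b in 1:B) for (t in 1:Tn) {
      tg <- targets[b, t]
      if (tg %in% c(v$pad, v$mask)) next
      p <- exp(z[b, t, ]) / sum(exp(z[b, t, ]))
      tot <- tot - log(p[tg + 1]); n <- n + 1
    }
    tot / n
  })
  expect_equal(next_token_loss(z, targets), oracle, tolerance = 1e-6)
  expect_error(next_token_loss(z, matrix(v$pad, B, Tn)), "ignored")
})

test_that("appending pad-target positions never changes the loss", {
  m <- build_model(micro_config(), seed = 5L)
  v <- idr_vocab()
  ids <- matrix(sample(0:19, 8), 1)
  targets <- matrix(sample(0:19, 8), 1)
  l1 <- next_token_loss(model_forward(m, ids), targets)
  ids_p <- cbind(ids, matrix(v$pad, 1, 4))
  targets_p <- cbind(targets, matrix(v$pad, 1, 4))
  l2 <- next_token_loss(model_forward(m, ids_p), targets_p)
  expect_equal(l1, l2, tolerance = 1e-12)
})

test_that("compiled and reference backends agree on forward and gradients", {
  m <- build_model(tiny_config(max_len = 64L), seed = 17L)
  ids <- matrix(sample(0:26, 3 * 24, replace = TRUE), 3, 24)
  lr <- model_forward(m, ids, backend = "reference")
  lc <- model_forward(m, ids, backend = "compiled")
  expect_lt(max(abs(lr - lc)), 1e-10)
  targets <- matrix(sample(0:19, 3 * 24, replace = TRUE), 3, 24)
  res <- next_token_loss(lr, targets, want_grad = TRUE)
  gr <- idrlm:::model_grads(m, ids, res$dlogits, backend = "reference")
  gc <- idrlm:::model_grads(m, ids, res$dlogits, backend = "compiled")
  expect_identical(names(gr), names(gc))
  expect_lt(max(unlist(Map(function(a, b) max(abs(a - b)), gr, gc))), 1e-10)
})

test_that("analytic gradients match central finite differences", {
  m <- build_model(micro_config(), seed = 23L)
  v <- idr_vocab()
  ids <- matrix(sample(0:26, 2 * 6, replace = TRUE), 2, 6)
  targets <- matrix(sample(0:19, 2 * 6, replace = TRUE), 2, 6)
  targets[1, 6] <- v$pad
  lossfun <- function(model)
    next_token_loss(model_forward(model, ids, backend = "reference"), targets)
  res <- next_token_loss(model_forward(m, ids), targets, want_grad = TRUE)
  grads <- idrlm:::model_grads(m, ids, res$dlogits)
  eps <- 1e-5
  set.seed(31)
  for (nm in c("tok_emb", "l1.w_qkv", "l1.w_o", "l2.w_gate", "l2.w_down",
               "l1.ln1_g", "lnf_b", "w_head")) {
    for (i in sample(length(m$params[[nm]]), 3)) {
      mp <- m; mp$params[[nm]][i] <- mp$params[[nm]][i] + eps
      mm <- m; mm$params[[nm]][i] <- mm$params[[nm]][i] - eps
      fd <- (lossfun(mp) - lossfun(mm)) / (2 * eps)
      expect_equal(grads[[nm]][i], fd, tolerance = 1e-4)
    }
  }
})

test_that("configurations load from YAML with defaults for absent fields", {
  tmp <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c("n_layers: 2", "n_heads: 4", "d_model: 64"), tmp)
  cfg <- model_config_from_yaml(tmp)
  expect_equal(cfg$n_layers, 2L)
  expect_equal(cfg$d_model, 64L)
  expect_equal(cfg$vocab_size, 27L)      # default preserved
  tmp2 <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c("total_steps: 100", "warmup_steps: 10", "batch_size: 8"), tmp2)
  tcfg <- train_config_from_yaml(tmp2)
  expect_equal(tcfg$total_steps, 100L)
  expect_equal(tcfg$peak_lr, 4e-4)       # default preserved
})

test_that("checkpoints roundtrip through plain-text JSON", {
  m <- build_model(micro_config(), seed = 41L)
  tmp <- withr::local_tempfile(fileext = ".json")
  save_checkpoint(m, tmp)
  m2 <- load_checkpoint(tmp)
  ids <- matrix(sample(0:26, 12), 1)
  expect_equal(model_forward(m, ids), model_forward(m2, ids),
               tolerance = 1e-12)
})
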