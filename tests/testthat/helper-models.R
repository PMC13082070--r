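# Shared fixtures: tiny model configurations and lazily pre-trained models,
# built once per test run and reused across files.

tiny_config <- function(n_layers = 2L, n_heads = 4L, d_model = 64L,
                        max_len = 512L) {
  model_config(n_layers = n_layers, n_heads = n_heads, d_model = d_model,
               vocab_size = 27L, max_len = max_len)
}

micro_config <- function() {
  # smallest config that still exercises multi-head attention
  model_config(n_layers = 2L, n_heads = 2L, d_model = 8L, vocab_size = 27L,
               max_len = 512L)
}

# build an IDP-only corpus (no flanking contexts) from synthetic sequences
idp_corpus <- function(n = 800L, median_length = 60, seed = 101L,
                       composition = disorder_composition()) {
  seqs <- synth_idr_corpus(
    corpus_spec(n, median_length = median_length, length_sdlog = 0.35,
                length_range = c(20L, 200L), composition = composition),
    seed = seed)
  recs <- lapply(seq_along(seqs), function(i)
    idr_record(names(seqs)[i], "", seqs[[i]], ""))
  encode_corpus(recs, max_len = 512L)
}

.model_store <- new.env(parent = emptyenv())

# tiny model pre-trained on a disorder-biased IDP corpus (median length 60);
# cached so the RL tests share one pre-training run
tiny_pretrained <- function(composition = c("disorder", "low_entropy")) {
  composition <- match.arg(composition)
  key <- paste0("pt_", composition)
  if (!is.null(.model_store[[key]])) return(.model_store[[key]])
  comp <- if (composition == "disorder") disorder_composition()
          else low_entropy_composition()
  corpus <- idp_corpus(800L, 60, seed = 101L, composition = comp)
  model <- build_model(tiny_config(), seed = 901L)
  pt <- pretrain(model, corpus,
                 desk_train_config(total_steps = 300L, batch_size = 16L,
                                   peak_lr = 3e-3, warmup_steps = 30L,
                                   val_every = 150L, seed = 55L))
  .model_store[[key]] <- pt$model
  pt$model
}

random_aa_seq <- function(n, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  paste(sample(c("A","C","D","E","F","G","H","I","K","L","M","N","P","Q",
                 "R","S","T","V","W","Y"), n, replace = TRUE), collapse = "")
}
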