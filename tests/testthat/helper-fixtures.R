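# Shared fixtures. Model/provider sizes here are deliberately small so the
# suite exercises the full code paths quickly; full-scale dimensions are
# checked once in the architecture tests.

flank_seq <- function(base = "A", center = "C") {
  paste0(strrep(base, 20), center, strrep(base, 20))
}

# A tiny hand-built set: all-A flanks except one G/U accent, labels mixed.
toy_set <- function() {
  sample_set(
    id = sprintf("s%d", 1:4),
    sequence = c(flank_seq("A"), flank_seq("G"), flank_seq("U"),
                 paste0(strrep("A", 19), "G", "C", "U", strrep("A", 19))),
    label = c(1L, 0L, 1L, 0L)
  )
}

random_valid_seq <- function(seed = 1L) {
  set.seed(seed)
  chars <- sample(c("A", "C", "G", "U"), 41, replace = TRUE)
  chars[21] <- "C"
  paste(chars, collapse = "")
}

small_cfg <- function(...) {
  model_config(embed_dim = 16L, transformer_heads = 2L,
               transformer_ffn_dim = 32L, transformer_layers = 2L,
               rnn_hidden = 12L, ...)
}

# Reduced-width configuration used for the end-to-end studies: the published
# recipe (6 encoder layers, 3 inception modules, 18 epochs, lr 1e-5, batch
# 500, dropout 0.5/0.3, grad-norm clip 1) at a narrower embedding width so
# training is tractable on one CPU.
e2e_cfg <- function(...) {
  model_config(embed_dim = 16L, transformer_heads = 2L,
               transformer_ffn_dim = 32L, ...)
}

small_provider <- function(dim = 16L, seed = 7L) {
  synthetic_provider(provider_spec("synthetic", dim = dim, seed = seed))
}

planted_bundle <- function(n = 100L, a_delta = 0.4, g_delta = 0.2,
                           seed = 11L, fraction = 0.8) {
  generate_split_bundle(
    generator_config(n, n, seed = seed,
                     motif = motif_spec(a_delta, g_delta)),
    fraction, seed = seed)
}
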