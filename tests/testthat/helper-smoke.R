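# Desk-scale training configurations shared by the heavier end-to-end
# tests. The encoder keeps the framework constants (148-token vocabulary,
# 116-wide embedding, 262-wide representation) with a compact convolution
# stack and a 48-token window, which covers every fixture SMILES.

smoke_encoder_config <- function() {
  encoder_config(conv_channels = c(64L, 96L, 128L),
                 kernel_sizes = c(5L, 5L, 3L), max_len = 48L)
}

full_library <- function() {
  if (is.null(.fixture_cache$full_lib)) {
    .fixture_cache$full_lib <- generate_molecule_library(fixture_config(seed = 1L))
  }
  .fixture_cache$full_lib
}

# 200-molecule smoke pre-training with 64 molecules held out by MaxMin;
# memoized because several tests probe the same trained state.
smoke_pretrain <- function() {
  if (is.null(.fixture_cache$smoke_state)) {
    .fixture_cache$smoke_state <- pretrain(
      full_library(), smoke_encoder_config(), epochs = 30L, batch_size = 32L,
      seed = 2024L, val_fraction = 0.32, pool_size = 20L)
  }
  .fixture_cache$smoke_state
}
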