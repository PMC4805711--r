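# The frozen default synthetic dataset (8 classes x 20+20 patches, 128x128,
# seed 20), generated once and shared across test files.
frozen_dataset <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- generate_texture_dataset(texture_dataset_spec())
    cache
  }
})
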