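# Shared simulated fixtures, built once per test run and cached, since a
# full-size simulated level is the most expensive object the suite needs.
.fixture_cache <- new.env(parent = emptyenv())

cached_recording <- function(level, seed = 101, noise = 2,
                             templates = default_templates()) {
  key <- paste(level, seed, noise, sep = "|")
  if (is.null(.fixture_cache[[key]])) {
    sch <- generate_level(level, seed = seed)
    .fixture_cache[[key]] <- simulate_recording(
      sch, profile = default_profile(noise_uV = noise),
      templates = templates, seed = seed + 1)
  }
  .fixture_cache[[key]]
}

cached_filtered <- function(level, seed = 101, noise = 2) {
  key <- paste("filt", level, seed, noise, sep = "|")
  if (is.null(.fixture_cache[[key]])) {
    .fixture_cache[[key]] <-
      average_reference(filter_band(cached_recording(level, seed, noise)))
  }
  .fixture_cache[[key]]
}

# a light config (4 blocks) for tests that only need structure, not power
small_config <- function() paradigm_config(blocks_per_level = 4)

# hand-built epoch container with known content
synthetic_epochs <- function(data, srate = 250, channels = NULL,
                             labels = NULL, t0_ms = -200) {
  d <- dim(data)
  channels <- channels %||% paste0("ch", seq_len(d[2]))
  times_ms <- t0_ms + (seq_len(d[3]) - 1) * 1000 / srate
  labels <- labels %||% data.frame(epoch = seq_len(d[1]))
  structure(list(data = data, times_ms = times_ms, srate = srate,
                 channels = channels, labels = labels, lock = "stimulus",
                 baseline_ms = NULL),
            class = "erp_epochs")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# stack two epoch arrays along the epoch dimension
abind2 <- function(a, b) {
  out <- array(0, dim = c(dim(a)[1] + dim(b)[1], dim(a)[2], dim(a)[3]))
  out[seq_len(dim(a)[1]), , ] <- a
  out[dim(a)[1] + seq_len(dim(b)[1]), , ] <- b
  out
}
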