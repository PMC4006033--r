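# Shared fixtures, memoized per test run: synthetic DTF generation is fast
# but used by many tests.

.fix_cache <- new.env(parent = emptyenv())

fix_listener_dtf <- function(cue_quality = 1, seed = 1) {
  key <- sprintf("dtf_%g_%d", cue_quality, seed)
  if (is.null(.fix_cache[[key]]))
    .fix_cache[[key]] <- generate_listener_dtfs(
      synthetic_listener_params(cue_quality = cue_quality, seed = seed,
                                listener_id = sprintf("VL%02d", seed)))
  .fix_cache[[key]]
}

fix_config <- function() model_config()

# tiny 3-template world on the median plane, for hand-composed oracles
toy_config <- function() model_config(polar_grid = c(-30, 0, 30),
                                      lateral_segments = 0)

toy_dtf <- function(seed = 4) {
  freq <- default_freq_grid(129)
  rng_state <- seed
  nxt <- function() {
    rng_state <<- (rng_state * 48271) %% 2147483647
    rng_state / 2147483647
  }
  dirs <- direction(0, c(-30, 0, 30))
  mk <- function() {
    m <- sapply(1:3, function(j)
      10 * sin(2 * pi * (1 + j) * seq(0, 1, length.out = 129) + 2 * pi * nxt()))
    m
  }
  dtf_set("TOY", dirs, freq, list(left = mk(), right = mk()))
}
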