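## Deterministic sub-stream seeds.
##
## Patient characteristics draw from stream 0 keyed by (seed, id); each
## strategy arm draws its preoperative and episode events from its own
## stream keyed by (seed, id, arm). Characteristics are therefore common
## random numbers across arms and scenarios run at the same master seed,
## while event noise stays independent between arms.

STREAM_PROFILE <- 0L
STREAM_ARM <- c(ABT = 1L, PAD = 2L, EPO = 3L)

## mix into [1, 2^31 - 2]; all intermediates stay below 2^53
derive_stream_seed <- function(seed, id, stream) {
  m <- 2147483629
  s <- ((seed %% m) * 1299709 + id * 9973 + stream * 104729) %% m
  as.integer(s + 1)
}
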