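# internal helpers shared across modules

# Round half away from zero. base::round() rounds half to even, which makes
# counts like round(0.5 * 5) platform-stable but surprising in a sampling
# design; the experiment contracts use the away-from-zero convention.
round_half_away <- function(x) {
  sign(x) * floor(abs(x) + 0.5)
}

# Deterministic child-seed derivation: one master seed per experiment, one
# child per (stream, counter) pair so any replicate can be regenerated in
# isolation. Linear-congruential mix kept below 2^31 - 1.
child_seed <- function(master, stream, counter = 0L) {
  stopifnot(is.numeric(master), length(master) == 1L)
  stream_id <- sum(utf8ToInt(as.character(stream))) %% 1000L
  x <- (as.double(master) %% 2147483647) + 1
  x <- (x * 48271 + stream_id * 69621 + as.double(counter) * 16807) %% 2147483647
  as.integer(x)
}

# Evaluate `expr` under a fixed seed when one is supplied, leaving the
# caller's RNG state untouched; with seed = NULL the global stream is used.
with_seed_opt <- function(seed, expr) {
  if (is.null(seed)) expr else withr::with_seed(as.integer(seed), expr)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
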