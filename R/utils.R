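# Internal helpers shared across modules.

# Deterministic 31-bit sub-seed for a named random stream. Populations and
# pipeline stages each get an independent substream of the master seed so
# that adding a stage never perturbs another stage's draws.
substream_seed <- function(seed, stream) {
  h <- sum(utf8ToInt(as.character(stream)) * seq_along(utf8ToInt(as.character(stream))))
  as.integer((as.numeric(seed) * 48271 + h * 16807) %% 2147483647)
}

# round() uses banker's rounding; allele-pool reconstruction needs ties up.
round_half_up <- function(x) floor(x + 0.5)

with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  set.seed(seed)
  on.exit({
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, envir = globalenv())
  })
  expr
}
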