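# small internal helpers

# evaluate `code` under a temporary RNG state seeded with `seed`, restoring
# the caller's RNG state afterwards
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(as.integer(seed))
  }
  force(code)
}

# derive a sub-seed for a named stage from a master seed (kept < 2^31)
stage_seed <- function(seed, stage) {
  offs <- c(scene = 101L, scan = 211L, nmea = 307L, filter = 401L,
            alpha = 503L, stats = 601L)
  o <- offs[[stage]]
  if (is.null(o)) o <- sum(utf8ToInt(stage))
  as.integer((as.numeric(seed) * 2654435761 + o) %% 2147483647)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
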