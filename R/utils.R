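## Seed plumbing and small numeric helpers.

#' Derive a stage seed from a master seed
#'
#' One master seed drives the whole pipeline; each stage (scene drawing,
#' waveform noise, speed channel, ...) gets a stable derived seed so
#' stages are individually reproducible. The derivation is a Lehmer-type
#' mixing step kept below 2^31 - 1.
#'
#' @param seed master seed (integer)
#' @param stage small integer identifying the stage
#' @return an integer seed in [1, 2^31 - 2]
#' @export
deriveSeed <- function(seed, stage) {
  m <- 2^31 - 1
  s <- ((abs(as.numeric(seed)) %% m) * 48271 + as.numeric(stage) * 9973) %% m
  as.integer(max(1, s))
}

## A private RNG stream: draws are seeded and do not disturb the caller's
## .Random.seed.
localRNG <- function(seed) {
  env <- new.env(parent = emptyenv())
  env$state <- NULL
  wrap <- function(f) {
    force(f)
    function(...) {
      glob <- globalenv()
      had <- exists(".Random.seed", envir = glob, inherits = FALSE)
      old <- if (had) get(".Random.seed", envir = glob) else NULL
      if (is.null(env$state)) set.seed(seed) else
        assign(".Random.seed", env$state, envir = glob)
      on.exit({
        env$state <- get(".Random.seed", envir = glob)
        if (had) assign(".Random.seed", old, envir = glob) else
          rm(".Random.seed", envir = glob)
      })
      f(...)
    }
  }
  list(
    runif = wrap(stats::runif),
    rnorm = wrap(stats::rnorm),
    sample = wrap(function(n, size = n, replace = FALSE) {
      sample.int(n, size, replace = replace)
    })
  )
}

## Column minima of a matrix without apply() overhead
fastColMins <- function(m) {
  out <- m[1L, ]
  for (r in seq_len(nrow(m))[-1L]) out <- pmin(out, m[r, ])
  out
}

## 32-bit FNV-1a hash of a character scalar, as 8 hex digits
fnv1a32 <- function(x) {
  bytes <- utf8ToInt(x)
  h <- 2166136261
  for (b in bytes) {
    h <- bitwXor(as.integer(h %% 2^31 - 2^30), as.integer(b))
    ## keep arithmetic in double to avoid integer overflow
    h <- (as.numeric(h) %% 2^32 + 2^31) %% 2^32
    h <- (h * 16777619) %% 2^32
  }
  sprintf("%08x", as.integer(h %% 2^31))
}

## Hash of an R object (used to stamp outputs with their config)
objectHash <- function(x) {
  fnv1a32(paste(deparse(x), collapse = "\n"))
}
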