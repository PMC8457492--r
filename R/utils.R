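# Internal helpers shared across modules.

# Evaluate `expr` with the RNG seeded at `seed`, restoring the caller's RNG
# state afterwards so that seeded stages never perturb the global stream.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else {
      NULL
    }
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
          rm(".Random.seed", envir = globalenv())
        }
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    }, add = TRUE)
    set.seed(seed)
  }
  force(expr)
}

# Deterministic fan-out of one user-facing seed into per-stage seeds.
# Kept well below 2^31 so the result is always a valid integer seed.
stage_seed <- function(seed, k) {
  as.integer((as.numeric(seed) %% 1000003) * 1009 + k)
}

# Tiny FNV-1a hash of a deparsed object, used to stamp output files with the
# configuration that produced them.
config_hash <- function(x) {
  bytes <- utf8ToInt(paste(deparse(x), collapse = "\n"))
  h <- 2166136261
  for (b in bytes) {
    h <- bitwXor(as.integer(h %% 2^31), b)
    h <- (h * 16777619) %% 2^31
  }
  sprintf("%08x", as.integer(h))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_audspeed <- function(msg, class) {
  stop(structure(class = c(class, "audspeed_error", "error", "condition"),
                 list(message = msg, call = sys.call(-1))))
}
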