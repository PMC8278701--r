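#' Derive a reproducible sub-seed from a master seed
#'
#' A single user-facing seed fans out deterministically to every stage
#' (simulation of each repetition, each rater panel, each training restart).
#' The scheme is a 32-bit FNV-1a style hash carried out in double precision
#' (exact below 2^53) and reduced modulo 2^31 - 1, so derived seeds are always
#' valid R integer seeds regardless of the master seed's magnitude.
#'
#' @param seed master seed (single number).
#' @param ... any mix of strings and integers naming the stream, e.g.
#'   `derive_seed(1, "rep", 12)`.
#' @return an integer in `[1, 2^31 - 2]`.
#' @export
derive_seed <- function(seed, ...) {
  tokens <- unlist(lapply(list(...), as.character), use.names = FALSE)
  bytes <- utf8ToInt(paste(c(as.character(seed), tokens), collapse = "/"))
  # 32-bit modular multiply, exact in doubles: split the multiplicand into
  # 16-bit halves so every intermediate stays below 2^53
  mulmod32 <- function(a, b) {
    (((a %/% 65536 * b) %% 65536) * 65536 + (a %% 65536) * b) %% 4294967296
  }
  h <- 2166136261
  for (b in bytes) {
    h <- mulmod32(bitwXor(as.integer(h %% 2^31), b) + (h >= 2^31) * 2^31, 16777619)
  }
  as.integer(h %% (2^31 - 2)) + 1L
}

#' Evaluate an expression under a temporary RNG seed
#'
#' Saves and restores `.Random.seed` so seeded internals never perturb the
#' caller's RNG stream.
#'
#' @param seed integer seed.
#' @param code expression to evaluate.
#' @keywords internal
with_seed <- function(seed, code) {
  env <- globalenv()
  had <- exists(".Random.seed", envir = env, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = env) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = env)
    else if (exists(".Random.seed", envir = env, inherits = FALSE))
      rm(".Random.seed", envir = env)
  })
  set.seed(as.integer(seed))
  code
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_domain <- function(...) stop(sprintf(...), call. = FALSE)
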