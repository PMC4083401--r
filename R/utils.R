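# Internal helpers: error signalling, seed derivation, local RNG scope.

abort_coscore <- function(message, class, call. = FALSE) {
  stop(errorCondition(message, class = c(class, "coscore_error")))
}

warn_coscore <- function(message, class) {
  warning(warningCondition(paste0(message, "\n"), class = c(class, "coscore_warning")))
}

#' @noRd
is_count <- function(x) {
  is.numeric(x) && length(x) == 1L && is.finite(x) && x >= 1 && x == floor(x)
}

# Deterministic 31-bit string hash (polynomial rolling hash mod 2^31 - 1).
# Used to derive per-feature / per-endpoint RNG sub-streams so that results
# do not depend on feature order or on the total number of features.
hash_string <- function(x) {
  h <- 0
  for (b in utf8ToInt(as.character(x))) h <- (h * 31 + b) %% 2147483647
  h
}

#' Derive a reproducible sub-seed from a master seed and string keys
#'
#' @param master integer master seed.
#' @param ... character scalars (e.g. feature id, endpoint) hashed into the
#'   sub-stream key.
#' @return an integer seed in `[0, 2^31 - 1)`.
#' @keywords internal
derive_seed <- function(master, ...) {
  h <- 0
  for (p in list(...)) h <- (h * 131 + hash_string(p)) %% 2147483647
  as.integer((abs(as.numeric(master)) %% 2147483647 + h) %% 2147483647)
}

# Evaluate `code` under `set.seed(seed)` and restore the caller's RNG state.
with_seed <- function(seed, code) {
  env <- globalenv()
  old <- if (exists(".Random.seed", envir = env, inherits = FALSE)) {
    get(".Random.seed", envir = env, inherits = FALSE)
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = env, inherits = FALSE)) {
        rm(".Random.seed", envir = env)
      }
    } else {
      assign(".Random.seed", old, envir = env)
    }
  })
  set.seed(seed)
  code
}
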