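#' Derive a reproducible child seed from a master seed and a label path
#'
#' All randomness in firtest flows from one master seed. Every machine, fold,
#' repetition and injection draws its own seed deterministically from the
#' master seed plus a descriptive label path, so that sub-computations are
#' reproducible in isolation and independent of evaluation order (pairs may be
#' computed in parallel without changing results).
#'
#' Uses a 32-bit FNV-1a hash of the concatenated labels, folded into the
#' positive integer range.
#'
#' @param master integer master seed.
#' @param ... further labels (coerced to character) identifying the consumer,
#'   e.g. the pair, the machine, the repetition index.
#' @return a single integer in `[1, .Machine$integer.max]`.
#' @export
#' @examples
#' derive_seed(1, "X1", "X2", "reduced")
derive_seed <- function(master, ...) {
  stopifnot(length(master) == 1L, is.finite(master))
  key <- paste(c(format(as.integer(master)), as.character(unlist(list(...)))),
               collapse = "|")
  bytes <- utf8ToInt(key)
  h <- 2166136261
  for (b in bytes) {
    h <- bitwXor(as.integer(h %% 2^31), as.integer(b))
    # 32-bit FNV prime multiply, done in double precision mod 2^31 to stay
    # inside R's integer range
    h <- (h * 16777619) %% 2147483647
  }
  as.integer(h %% 2147483646) + 1L
}

# Evaluate expr with a local RNG state: seeds deterministically, restores the
# caller's .Random.seed afterwards.
with_seed <- function(seed, expr) {
  env <- globalenv()
  had <- exists(".Random.seed", envir = env, inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = env)
  on.exit({
    if (had) assign(".Random.seed", old, envir = env)
    else if (exists(".Random.seed", envir = env, inherits = FALSE))
      rm(".Random.seed", envir = env)
  })
  set.seed(as.integer(seed))
  expr
}
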