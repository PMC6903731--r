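# Deterministic seeding helpers. A single run seed is fanned out to
# independent sub-streams by hashing a text label (e.g. a deployment id)
# and XOR-ing it into the seed, so per-deployment results do not depend on
# processing order.

#' Derive a sub-seed from a run seed and a label
#'
#' Stable 31-bit polynomial hash of the label, XOR-ed with the seed.
#' The result is a valid, non-negative integer seed below 2^31.
#'
#' @param seed integer run seed.
#' @param label character scalar naming the sub-stream.
#' @return an integer seed.
#' @export
derive_seed <- function(seed, label) {
  h <- 0
  for (c in utf8ToInt(as.character(label)))
    h <- (h * 31 + c) %% 2147483647
  bitwXor(as.integer(h), as.integer(abs(seed) %% 2147483647))
}

# set the RNG to `seed`, returning the previous state for restore_rng();
# keeps package randomness from disturbing the caller's RNG stream
local_rng <- function(seed) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  set.seed(seed)
  old
}

restore_rng <- function(state) {
  if (is.null(state)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else {
    assign(".Random.seed", state, envir = globalenv())
  }
  invisible(NULL)
}

# run `expr` under a private RNG stream seeded with `seed`
with_seed <- function(seed, expr) {
  st <- local_rng(seed)
  on.exit(restore_rng(st))
  expr
}
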