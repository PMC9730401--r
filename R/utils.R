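# Internal helpers shared across modules.

sigmoid <- function(x) 1 / (1 + exp(-x))

relu <- function(x) pmax(x, 0)

#' Evaluate an expression under a temporary RNG seed
#'
#' Runs `expr` with the global RNG seeded to `seed` and restores the previous
#' RNG state afterwards, so seeded generation does not perturb the caller's
#' random stream.
#'
#' @param seed integer seed.
#' @param expr expression to evaluate.
#' @return the value of `expr`.
#' @keywords internal
with_local_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}

# Per-channel sums over a (H, W, C, N) tensor -> length-C vector.
channel_sums <- function(a) {
  d <- dim(a)
  m <- matrix(a, d[1L] * d[2L], d[3L] * d[4L])
  rowSums(matrix(colSums(m), d[3L], d[4L]))
}

# Broadcast a length-C vector over (H, W, C, N): returns a vector that
# recycles correctly against the tensor in elementwise arithmetic.
bc_channel <- function(v, hw) rep(v, each = hw)

# Concatenate two (H, W, C, N) tensors along the channel axis.
concat_channels <- function(a, b) {
  da <- dim(a); db <- dim(b)
  stopifnot(da[c(1L, 2L, 4L)] == db[c(1L, 2L, 4L)])
  out <- array(0, c(da[1L], da[2L], da[3L] + db[3L], da[4L]))
  out[, , seq_len(da[3L]), ] <- a
  out[, , da[3L] + seq_len(db[3L]), ] <- b
  out
}

split_channels <- function(x, n_first) {
  d <- dim(x)
  list(first = x[, , seq_len(n_first), , drop = FALSE],
       second = x[, , (n_first + 1L):d[3L], , drop = FALSE])
}

`%||%` <- function(a, b) if (is.null(a)) b else a
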