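# Internal numerical helpers shared across modules.

# Rolling minimum over a centred window of +/- `half` points (van
# Herk/Gil-Werman, O(n)).  Out-of-range positions behave as +Inf, i.e. the
# window shrinks at the edges.
roll_min <- function(x, half) {
  stopifnot(half >= 1)
  n <- length(x)
  k <- 2L * half + 1L
  pad <- c(rep(Inf, half), x, rep(Inf, half))
  m <- length(pad)
  nblock <- ceiling(m / k)
  pad <- c(pad, rep(Inf, nblock * k - m))
  blocks <- matrix(pad, nrow = k)
  fwd <- apply(blocks, 2L, cummin)                        # prefix minima
  bwd <- apply(blocks[k:1L, , drop = FALSE], 2L, cummin)[k:1L, , drop = FALSE]
  fwd <- as.vector(fwd)
  bwd <- as.vector(bwd)
  # window for original index i spans padded indices [i, i + 2*half]
  pmin(bwd[seq_len(n)], fwd[seq_len(n) + 2L * half])
}

roll_max <- function(x, half) -roll_min(-x, half)

# Rolling mean over +/- `half` points; the window shrinks at the edges.
roll_mean <- function(x, half) {
  n <- length(x)
  cs <- cumsum(c(0, x))
  lo <- pmax(seq_len(n) - half, 1L)
  hi <- pmin(seq_len(n) + half, n)
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}

# Evaluate `code` under a fixed RNG seed without disturbing the caller's
# RNG stream.
with_seed <- function(seed, code) {
  withr::with_seed(as.integer(seed), code)
}

# Deterministic sub-seed derivation; keeps results < 2^31.
derive_seed <- function(seed, k) {
  (as.integer(seed) %% 1000003L) * 1009L + as.integer(k) * 7919L + 17L
}

make_odd <- function(k) {
  k <- as.integer(k)
  if (k %% 2L == 0L) k + 1L else k
}

`%||%` <- function(a, b) if (is.null(a)) b else a
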