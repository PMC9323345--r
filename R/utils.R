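# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Evaluate an expression under a temporary RNG seed
#'
#' Saves and restores the global RNG state so that library code never
#' clobbers the caller's random stream.
#' @noRd
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  set.seed(as.integer(seed))
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  force(code)
}

# Deterministic child-seed derivation: keeps every derived seed a positive
# 32-bit integer so stages and runs are independently rerunnable.
derive_seed <- function(master, offset) {
  as.integer((as.numeric(master) %% 2147483629L * 48271 + offset * 7919) %%
               2147483629 + 1)
}

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

# ITU-R BT.601 luma, rounded half-up to an 8-bit integer matrix.
rgb_to_gray_int <- function(arr) {
  stopifnot(length(dim(arr)) == 3L, dim(arr)[3] == 3L)
  g <- 0.2989 * arr[, , 1] + 0.5870 * arr[, , 2] + 0.1140 * arr[, , 3]
  m <- floor(g + 0.5)
  storage.mode(m) <- "integer"
  clamp(m, 0L, 255L)
}

# 2-D cumulative sum (integral image).
cumsum2 <- function(m) {
  m <- apply(m, 2, cumsum)
  t(apply(m, 1, cumsum))
}

# Edge-aware box mean with half-window `half` (window = 2*half + 1).
box_mean <- function(m, half) {
  h <- nrow(m); w <- ncol(m)
  S <- matrix(0, h + 1, w + 1)
  S[-1, -1] <- cumsum2(m)
  r1 <- pmax(seq_len(h) - half, 1L); r2 <- pmin(seq_len(h) + half, h)
  c1 <- pmax(seq_len(w) - half, 1L); c2 <- pmin(seq_len(w) + half, w)
  sums <- S[r2 + 1, c2 + 1, drop = FALSE] - S[r1, c2 + 1, drop = FALSE] -
    S[r2 + 1, c1, drop = FALSE] + S[r1, c1, drop = FALSE]
  counts <- outer(r2 - r1 + 1L, c2 - c1 + 1L)
  sums / counts
}

# x * log(x) with the 0 * log 0 = 0 convention (natural log).
xlogx <- function(x) {
  out <- numeric(length(x))
  pos <- x > 0
  out[pos] <- x[pos] * log(x[pos])
  out
}

is_count <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x) &&
  x > 0 && x == round(x)
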