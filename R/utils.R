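#' @keywords internal
"_PACKAGE"

# Run `expr` under a fixed RNG seed, restoring the caller's RNG state after.
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(as.integer(seed))
  expr
}

# Derive a reproducible 31-bit sub-seed from a parent seed and a string tag.
# Keeps every stage's randomness on an independent stream while all flowing
# from one user-facing integer.
derive_seed <- function(seed, tag) {
  h <- 0
  for (ch in utf8ToInt(paste0(tag))) h <- (h * 31 + ch) %% 2147483647
  as.integer((as.numeric(seed) * 48271 + h) %% 2147483647)
}

stop_radfuse <- function(...) stop(..., call. = FALSE)

`%||%` <- function(a, b) if (is.null(a)) b else a

# Bounding box (with optional margin) of a logical 3D array; NULL if empty.
mask_bbox <- function(mask, margin = 0L) {
  idx <- which(mask, arr.ind = TRUE)
  if (nrow(idx) == 0L) return(NULL)
  d <- dim(mask)
  lo <- pmax(apply(idx, 2, min) - margin, 1L)
  hi <- pmin(apply(idx, 2, max) + margin, d)
  list(lo = lo, hi = hi)
}

crop_bbox <- function(arr, bb) {
  arr[bb$lo[1]:bb$hi[1], bb$lo[2]:bb$hi[2], bb$lo[3]:bb$hi[3], drop = FALSE]
}

# Shift a 3D array by integer offset (dx, dy, dz), padding with `fill`.
shift3d <- function(arr, off, fill = NA) {
  d <- dim(arr)
  out <- array(fill, dim = d)
  src <- dst <- vector("list", 3)
  for (a in 1:3) {
    o <- off[a]
    if (o >= 0) {
      if (o >= d[a]) return(out)
      src[[a]] <- 1:(d[a] - o); dst[[a]] <- (1 + o):d[a]
    } else {
      if (-o >= d[a]) return(out)
      src[[a]] <- (1 - o):d[a]; dst[[a]] <- 1:(d[a] + o)
    }
  }
  out[dst[[1]], dst[[2]], dst[[3]]] <- arr[src[[1]], src[[2]], src[[3]]]
  out
}

# The 13 unique 3D direction offsets at Chebyshev distance 1 (half of the 26
# neighbours; the other half are their negations).
glcm_offsets <- function() {
  offs <- expand.grid(dx = -1:1, dy = -1:1, dz = -1:1)
  offs <- offs[!(offs$dx == 0 & offs$dy == 0 & offs$dz == 0), ]
  keep <- offs$dz > 0 | (offs$dz == 0 & offs$dy > 0) |
    (offs$dz == 0 & offs$dy == 0 & offs$dx > 0)
  as.matrix(offs[keep, , drop = FALSE])
}
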