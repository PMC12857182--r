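# Internal helpers shared across modules.

# Run expr with a local RNG seeded at `seed`, restoring the caller's RNG state.
with_local_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed %% .Machine$integer.max))
  expr
}

# 8- and 4-neighbourhood offsets as (dr, dc) rows.
neighbor_offsets <- function(connectivity = 8L) {
  if (connectivity == 4L) {
    cbind(dr = c(-1L, 1L, 0L, 0L), dc = c(0L, 0L, -1L, 1L))
  } else {
    cbind(
      dr = c(-1L, -1L, -1L, 0L, 0L, 1L, 1L, 1L),
      dc = c(-1L, 0L, 1L, -1L, 1L, -1L, 0L, 1L)
    )
  }
}

# Pixel coordinates (row, col) of a filled disc of radius r centred at (r0, c0),
# clipped to an nr x nc grid.
disc_pixels <- function(r0, c0, radius, nr, nc) {
  rr <- max(1L, floor(r0 - radius)):min(nr, ceiling(r0 + radius))
  cc <- max(1L, floor(c0 - radius)):min(nc, ceiling(c0 + radius))
  g <- expand.grid(row = rr, col = cc)
  keep <- (g$row - r0)^2 + (g$col - c0)^2 <= radius^2
  as.matrix(g[keep, , drop = FALSE])
}

# Pixel coordinates of a capsule (rectangle with semicircular caps) from
# (r0,c0) to (r1,c1) with half-width w, clipped to the grid. Used to draw
# elongated chromosome bodies.
capsule_pixels <- function(r0, c0, r1, c1, w, nr, nc) {
  rr <- max(1L, floor(min(r0, r1) - w)):min(nr, ceiling(max(r0, r1) + w))
  cc <- max(1L, floor(min(c0, c1) - w)):min(nc, ceiling(max(c0, c1) + w))
  g <- expand.grid(row = rr, col = cc)
  vx <- r1 - r0
  vy <- c1 - c0
  len2 <- vx^2 + vy^2
  t <- if (len2 == 0) 0 else pmin(1, pmax(0, ((g$row - r0) * vx + (g$col - c0) * vy) / len2))
  d2 <- (g$row - (r0 + t * vx))^2 + (g$col - (c0 + t * vy))^2
  as.matrix(g[d2 <= w^2, , drop = FALSE])
}

# linear index <-> (row, col)
px_index <- function(px, nr) (px[, 2L] - 1L) * nr + px[, 1L]

# row-major scan order key (for deterministic component ids)
row_major_key <- function(row, col, nc) (row - 1) * nc + col

# Grow a connected blob of exactly `size` pixels inside `allowed` (logical
# matrix), starting from a seed index drawn from `seeds`. Returns a (row,col)
# matrix or NULL if the region cannot host the blob.
grow_blob <- function(allowed, size, seeds) {
  nr <- nrow(allowed)
  nc <- ncol(allowed)
  if (length(seeds) == 0L) return(NULL)
  seed <- seeds[sample.int(length(seeds), 1L)]
  off <- neighbor_offsets(8L)
  in_blob <- logical(nr * nc)
  blob <- integer(0)
  frontier <- seed
  while (length(blob) < size && length(frontier) > 0L) {
    # pull one frontier pixel (closest-first keeps blobs compact)
    i <- frontier[1L]
    frontier <- frontier[-1L]
    if (in_blob[i]) next
    in_blob[i] <- TRUE
    blob <- c(blob, i)
    r <- ((i - 1L) %% nr) + 1L
    c <- ((i - 1L) %/% nr) + 1L
    nb_r <- r + off[, 1L]
    nb_c <- c + off[, 2L]
    ok <- nb_r >= 1L & nb_r <= nr & nb_c >= 1L & nb_c <= nc
    nb <- (nb_c[ok] - 1L) * nr + nb_r[ok]
    nb <- nb[allowed[nb] & !in_blob[nb]]
    frontier <- c(frontier, nb)
  }
  if (length(blob) < size) return(NULL)
  blob <- blob[seq_len(size)]
  cbind(row = ((blob - 1L) %% nr) + 1L, col = ((blob - 1L) %/% nr) + 1L)
}

round_half_up <- function(x) floor(x + 0.5)
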