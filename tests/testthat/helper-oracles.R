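# Independent brute-force oracles. These deliberately use plain loops and
# direct formulas, never the package's own code paths, so that agreement is
# evidence and not tautology.

# population variance of the 3x3 Laplacian with reflect-101 borders, by
# explicit loops
oracle_lapvar <- function(m) {
  nr <- nrow(m)
  nc <- ncol(m)
  at <- function(r, c) {
    if (r < 1) r <- min(2 - r, nr)
    if (r > nr) r <- max(2 * nr - r, 1)
    if (c < 1) c <- min(2 - c, nc)
    if (c > nc) c <- max(2 * nc - c, 1)
    m[r, c]
  }
  resp <- matrix(0, nr, nc)
  for (r in seq_len(nr)) {
    for (c in seq_len(nc)) {
      resp[r, c] <- at(r - 1, c) + at(r + 1, c) + at(r, c - 1) + at(r, c + 1) -
        4 * at(r, c)
    }
  }
  mean((resp - mean(resp))^2)
}

# stack-based flood fill, 8-connectivity; returns an integer label matrix
oracle_flood_fill <- function(fg) {
  nr <- nrow(fg)
  nc <- ncol(fg)
  lab <- matrix(0L, nr, nc)
  nid <- 0L
  for (r0 in seq_len(nr)) {
    for (c0 in seq_len(nc)) {
      if (!fg[r0, c0] || lab[r0, c0] != 0L) next
      nid <- nid + 1L
      stack <- list(c(r0, c0))
      lab[r0, c0] <- nid
      while (length(stack) > 0) {
        p <- stack[[length(stack)]]
        stack[[length(stack)]] <- NULL
        for (dr in -1:1) {
          for (dc in -1:1) {
            r <- p[1] + dr
            c <- p[2] + dc
            if (r >= 1 && r <= nr && c >= 1 && c <= nc &&
              fg[r, c] && lab[r, c] == 0L) {
              lab[r, c] <- nid
              stack[[length(stack) + 1L]] <- c(r, c)
            }
          }
        }
      }
    }
  }
  lab
}

# component partitions as canonical sets (sorted pixel-index strings)
partition_signature <- function(lab) {
  ids <- setdiff(unique(as.vector(lab)), 0L)
  sort(vapply(ids, function(i) {
    paste(sort(which(lab == i)), collapse = ",")
  }, character(1)))
}

# perimeter-adjacency fraction by explicit neighbour enumeration
oracle_adjacency <- function(px, lab, chrom_code = 1L) {
  nr <- nrow(lab)
  nc <- ncol(lab)
  comp <- matrix(FALSE, nr, nc)
  comp[px] <- TRUE
  boundary <- 0L
  adj <- 0L
  for (i in seq_len(nrow(px))) {
    r <- px[i, 1]
    c <- px[i, 2]
    is_b <- FALSE
    is_a <- FALSE
    for (dr in -1:1) {
      for (dc in -1:1) {
        if (dr == 0 && dc == 0) next
        rr <- r + dr
        cc <- c + dc
        if (rr < 1 || rr > nr || cc < 1 || cc > nc) {
          is_b <- TRUE # out-of-image side counts as outside the component
        } else {
          if (!comp[rr, cc]) is_b <- TRUE
          if (lab[rr, cc] == chrom_code) is_a <- TRUE
        }
      }
    }
    if (is_b) {
      boundary <- boundary + 1L
      if (is_a) adj <- adj + 1L
    }
  }
  list(frac = if (boundary > 0) adj / boundary else 0, boundary = boundary, adj = adj)
}

# tether class straight from the stated cutoffs
oracle_tether <- function(frac) {
  if (frac < 0.25) "untethered" else if (frac < 1) "tethered" else "surrounded"
}

# exhaustive 3-class Otsu over a binned histogram: full between-class
# variance sum over all threshold pairs, loops only
oracle_otsu3_cuts <- function(v, nbins) {
  rng <- range(v)
  width <- (rng[2] - rng[1]) / nbins
  bin <- pmin(nbins, floor((v - rng[1]) / width) + 1)
  counts <- tabulate(bin, nbins)
  centers <- rng[1] + (seq_len(nbins) - 0.5) * width
  p <- counts / sum(counts)
  grand <- sum(p * centers)
  best <- -Inf
  best_cut <- NULL
  for (t1 in 1:(nbins - 2)) {
    for (t2 in (t1 + 1):(nbins - 1)) {
      sc <- 0
      for (seg in list(1:t1, (t1 + 1):t2, (t2 + 1):nbins)) {
        w <- sum(p[seg])
        if (w > 0) {
          mu <- sum(p[seg] * centers[seg]) / w
          sc <- sc + w * (mu - grand)^2
        }
      }
      if (sc > best + 1e-12) {
        best <- sc
        best_cut <- c(t1, t2)
      }
    }
  }
  list(cuts = best_cut, thresholds = rng[1] + best_cut * width, score = best)
}

# classical one-way ANOVA by direct sums of squares
oracle_anova <- function(values, group) {
  group <- factor(group)
  grand <- mean(values)
  ssb <- 0
  ssw <- 0
  for (g in levels(group)) {
    v <- values[group == g]
    ssb <- ssb + length(v) * (mean(v) - grand)^2
    ssw <- ssw + sum((v - mean(v))^2)
  }
  dfb <- nlevels(group) - 1
  dfw <- length(values) - nlevels(group)
  f <- (ssb / dfb) / (ssw / dfw)
  list(F = f, p = pf(f, dfb, dfw, lower.tail = FALSE))
}

# Pearson chi-squared by direct expectation formula
oracle_chisq <- function(tab, yates = FALSE) {
  exp <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  d <- abs(tab - exp)
  if (yates) d <- pmax(0, d - 0.5)
  sum(d^2 / exp)
}

# least squares line by normal equations
oracle_linfit <- function(x, y) {
  sx <- sum(x)
  sy <- sum(y)
  sxx <- sum(x^2)
  sxy <- sum(x * y)
  n <- length(x)
  slope <- (n * sxy - sx * sy) / (n * sxx - sx^2)
  list(slope = slope, intercept = (sy - slope * sx) / n)
}

# point-in-convex-hull area by shoelace comparison: a lattice point is inside
# conv(S) iff adding it leaves the hull area (and degenerate diameter)
# unchanged
oracle_hull_area <- function(pts, nr, nc) {
  shoelace <- function(p) {
    h <- grDevices::chull(p)
    v <- p[h, , drop = FALSE]
    n <- nrow(v)
    if (n < 3) return(0)
    s <- 0
    for (i in seq_len(n)) {
      j <- if (i == n) 1 else i + 1
      s <- s + v[i, 1] * v[j, 2] - v[j, 1] * v[i, 2]
    }
    abs(s) / 2
  }
  diam <- function(p) max(dist(p))
  base_area <- shoelace(pts)
  base_diam <- if (nrow(pts) > 1) diam(pts) else 0
  count <- 0L
  for (r in seq_len(nr)) {
    for (c in seq_len(nc)) {
      aug <- rbind(pts, c(r, c))
      inside <- if (base_area > 0) {
        abs(shoelace(aug) - base_area) < 1e-9
      } else {
        # degenerate (point or segment) hull: inside iff diameter unchanged
        # and the point is collinear with the set (area still 0)
        abs(shoelace(aug)) < 1e-9 && abs(diam(aug) - max(base_diam, 0)) < 1e-9
      }
      if (inside) count <- count + 1L
    }
  }
  count
}

# shared default parameter bundles
seg_lower <- seg_params(threshold_rule = "lower")
seg_higher <- seg_params(threshold_rule = "higher")

# random small spread-context label mask with blob structure
random_label_mask <- function(seed, nr = 20, nc = 20) {
  set.seed(seed)
  m <- matrix(0L, nr, nc)
  for (k in seq_len(sample(1:3, 1))) { # chromosome blocks
    r <- sample(nr - 5, 1)
    c <- sample(nc - 5, 1)
    m[r:(r + sample(2:5, 1)), c:(c + sample(2:5, 1))] <- 1L
  }
  for (k in seq_len(sample(1:4, 1))) { # ecDNA blobs
    r <- sample(nr - 2, 1)
    c <- sample(nc - 2, 1)
    m[r:(r + sample(0:2, 1)), c:(c + sample(0:2, 1))] <- 2L
  }
  label_mask(m, context = "spread", provenance = "ground_truth")
}
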