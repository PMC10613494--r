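# Independent brute-force oracles used to freeze expected values. These
# deliberately share no code with the implementation paths they check.

# queue-based 6-connected flood fill over an eligibility array;
# seeds are 1-based linear indices
flood_oracle <- function(eligible, seeds) {
  dims <- dim(eligible)
  visited <- array(FALSE, dims)
  q <- seeds[eligible[seeds]]
  visited[q] <- TRUE
  offs <- rbind(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0),
                c(0, -1, 0), c(0, 0, 1), c(0, 0, -1))
  while (length(q)) {
    v <- q[1]; q <- q[-1]
    i0 <- v - 1
    x <- i0 %% dims[1]
    y <- (i0 %/% dims[1]) %% dims[2]
    z <- i0 %/% (dims[1] * dims[2])
    for (k in 1:6) {
      nx <- x + offs[k, 1]; ny <- y + offs[k, 2]; nz <- z + offs[k, 3]
      if (nx < 0 || ny < 0 || nz < 0 ||
          nx >= dims[1] || ny >= dims[2] || nz >= dims[3]) next
      w <- nx + dims[1] * (ny + dims[2] * nz) + 1
      if (eligible[w] && !visited[w]) { visited[w] <- TRUE; q <- c(q, w) }
    }
  }
  visited
}

# exhaustive surface extraction: foreground voxels with a 6-neighbor that is
# background or outside the volume
surface_oracle <- function(values) {
  dims <- dim(values)
  out <- array(FALSE, dims)
  idx <- which(values, arr.ind = TRUE)
  offs <- rbind(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0),
                c(0, -1, 0), c(0, 0, 1), c(0, 0, -1))
  for (r in seq_len(nrow(idx))) {
    p <- idx[r, ]
    for (k in 1:6) {
      q <- p + offs[k, ]
      if (any(q < 1) || any(q > dims) || !values[q[1], q[2], q[3]]) {
        out[p[1], p[2], p[3]] <- TRUE
        break
      }
    }
  }
  out
}

# O(n^2) average symmetric surface distance through the full pairwise
# distance matrix on world coordinates
assd_oracle <- function(mask_a, mask_b) {
  sa <- surface_oracle(mask_a$values)
  sb <- surface_oracle(mask_b$values)
  ca <- voxel_centers(mask_a$grid)
  pa <- ca[as.logical(sa), , drop = FALSE]
  pb <- ca[as.logical(sb), , drop = FALSE]
  tb <- t(pb); ta <- t(pa)
  dmin_a <- vapply(seq_len(nrow(pa)), function(i)
    min(sqrt(colSums((tb - pa[i, ])^2))), numeric(1))
  dmin_b <- vapply(seq_len(nrow(pb)), function(j)
    min(sqrt(colSums((ta - pb[j, ])^2))), numeric(1))
  (sum(dmin_a) + sum(dmin_b)) / (nrow(pa) + nrow(pb))
}

# marginal histogram entropy (nats) with percentile-clipped linear binning
entropy_oracle <- function(values, bins = 32) {
  q <- quantile(values, c(0.005, 0.995), names = FALSE, type = 7)
  breaks <- seq(q[1], q[2], length.out = bins + 1)
  bi <- findInterval(values, breaks, rightmost.closed = FALSE)
  bi <- pmin(pmax(bi, 1L), bins)
  p <- as.numeric(table(bi))
  p <- p / sum(p)
  -sum(p * log(p))
}

# loop-based evaluation of the time-averaged magnitude-times-speed angiogram
pcmra_oracle <- function(series) {
  d <- series$grid$shape
  out <- array(0, d)
  for (x in 1:d[1]) for (y in 1:d[2]) for (z in 1:d[3]) {
    acc <- 0
    for (i in seq_len(series$n_frames)) {
      sp <- sqrt(series$velocity[x, y, z, 1, i]^2 +
                 series$velocity[x, y, z, 2, i]^2 +
                 series$velocity[x, y, z, 3, i]^2)
      acc <- acc + series$magnitude[x, y, z, i] * sp
    }
    out[x, y, z] <- acc / series$n_frames
  }
  out
}
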