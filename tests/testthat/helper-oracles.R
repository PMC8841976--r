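# Independent brute-force oracles used to cross-check the implementation.

# voxel centres of a (z,y,x) grid in nm
oracle_centers <- function(shape, voxel_size, origin = c(0, 0, 0)) {
  voxel_size <- rep_len(voxel_size, 3)
  g <- expand.grid(z = seq_len(shape[1]), y = seq_len(shape[2]),
                   x = seq_len(shape[3]))
  cbind((g$z - 0.5) * voxel_size[1] + origin[1],
        (g$y - 0.5) * voxel_size[2] + origin[2],
        (g$x - 0.5) * voxel_size[3] + origin[3])
}

# all-pairs k-truncated range count: D(x) = min(#particles within R, k)
oracle_density <- function(coords, shape, voxel_size, radius, k,
                           origin = c(0, 0, 0)) {
  ctr <- oracle_centers(shape, voxel_size, origin)
  out <- numeric(nrow(ctr))
  for (i in seq_len(nrow(ctr))) {
    d2 <- (coords[, 1] - ctr[i, 1])^2 + (coords[, 2] - ctr[i, 2])^2 +
          (coords[, 3] - ctr[i, 3])^2
    out[i] <- min(sum(d2 <= radius^2), k)
  }
  array(out, shape)
}

# BFS flood-fill connected-component labeling
oracle_label <- function(mask, connectivity = 26) {
  d <- dim(mask)
  offs <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  s <- rowSums(abs(offs))
  offs <- offs[s > 0 & s <= switch(as.character(connectivity),
                                   "6" = 1, "18" = 2, "26" = 3), ,
               drop = FALSE]
  lab <- array(0L, d)
  nxt <- 0L
  for (i in which(mask)) {
    if (lab[i] != 0L) next
    nxt <- nxt + 1L
    queue <- i
    lab[i] <- nxt
    while (length(queue)) {
      cur <- queue[1]
      queue <- queue[-1]
      z <- ((cur - 1) %% d[1]) + 1
      y <- (((cur - 1) %/% d[1]) %% d[2]) + 1
      x <- ((cur - 1) %/% (d[1] * d[2])) + 1
      for (o in seq_len(nrow(offs))) {
        zz <- z + offs[o, 1]; yy <- y + offs[o, 2]; xx <- x + offs[o, 3]
        if (zz < 1 || zz > d[1] || yy < 1 || yy > d[2] || xx < 1 ||
            xx > d[3]) next
        j <- (xx - 1) * d[1] * d[2] + (yy - 1) * d[1] + zz
        if (mask[j] && lab[j] == 0L) {
          lab[j] <- nxt
          queue <- c(queue, j)
        }
      }
    }
  }
  lab
}

# all-pairs foreground-to-background distance, faces count as background
oracle_distance <- function(mask, voxel_size) {
  voxel_size <- rep_len(voxel_size, 3)
  d <- dim(mask)
  pad <- array(FALSE, d + 2L)
  pad[2:(d[1] + 1), 2:(d[2] + 1), 2:(d[3] + 1)] <- mask
  bg <- which(!pad, arr.ind = TRUE)
  bg_nm <- sweep(sweep(bg - 0.5, 2, voxel_size, "*"), 2,
                 voxel_size, "-") # centre of padded voxel minus one pad layer
  out <- array(0, d)
  fg <- which(mask, arr.ind = TRUE)
  if (nrow(fg) == 0) return(out)
  fg_nm <- sweep(fg - 0.5, 2, voxel_size, "*")
  for (i in seq_len(nrow(fg))) {
    d2 <- (bg_nm[, 1] - fg_nm[i, 1])^2 + (bg_nm[, 2] - fg_nm[i, 2])^2 +
          (bg_nm[, 3] - fg_nm[i, 3])^2
    out[fg[i, 1], fg[i, 2], fg[i, 3]] <- sqrt(min(d2))
  }
  out
}

# exhaustive intermeans (IsoData) threshold over the 256-bin histogram:
# smallest bin index g that is a fixed point of g -> round((m_lo + m_hi)/2)
oracle_isodata <- function(x, n_bins = 256) {
  rng <- range(x)
  bw <- diff(rng) / n_bins
  idx <- pmin(floor((x - rng[1]) / bw) + 1, n_bins)
  counts <- tabulate(idx, nbins = n_bins)
  for (g in seq_len(n_bins - 1)) {
    lo <- counts[1:g]
    hi <- counts[(g + 1):n_bins]
    if (sum(lo) == 0 || sum(hi) == 0) next
    m_lo <- sum(lo * (1:g)) / sum(lo)
    m_hi <- sum(hi * ((g + 1):n_bins)) / sum(hi)
    if (as.integer(round((m_lo + m_hi) / 2)) == g)
      return(rng[1] + g * bw)
  }
  NA_real_
}

# small random particle sets on a grid
random_instance <- function(seed, shape = c(16, 16, 16), n = 150,
                            voxel_size = 2) {
  set.seed(seed)
  ext <- shape * voxel_size
  list(coords = cbind(runif(n, 0, ext[1]), runif(n, 0, ext[2]),
                      runif(n, 0, ext[3])),
       shape = shape, voxel_size = voxel_size)
}
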