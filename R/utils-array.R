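# Low-level 3D array helpers shared by the image-processing and morphometry
# modules. All operate on plain 3D arrays in (slice, row, col) order.

# Shift a 3D array by integer offsets, filling exposed planes.
shift3d <- function(a, off, fill = 0) {
  d <- dim(a)
  out <- array(fill, d)
  src <- dst <- vector("list", 3)
  for (ax in 1:3) {
    o <- off[ax]
    if (abs(o) >= d[ax]) return(out)
    if (o >= 0) { src[[ax]] <- 1:(d[ax] - o); dst[[ax]] <- (1 + o):d[ax] }
    else { src[[ax]] <- (1 - o):d[ax]; dst[[ax]] <- 1:(d[ax] + o) }
  }
  out[dst[[1]], dst[[2]], dst[[3]]] <- a[src[[1]], src[[2]], src[[3]]]
  out
}

offsets6 <- rbind(c(1,0,0), c(-1,0,0), c(0,1,0), c(0,-1,0), c(0,0,1), c(0,0,-1))

# Binary dilation/erosion with the 6-neighborhood cross, iterated.
dilate6 <- function(mask, iter = 1L) {
  m <- mask
  for (i in seq_len(iter)) {
    acc <- m
    for (k in 1:6) acc <- acc | shift3d(m, offsets6[k, ], fill = FALSE)
    m <- acc
  }
  m
}

erode6 <- function(mask, iter = 1L) {
  m <- mask
  for (i in seq_len(iter)) {
    acc <- m
    for (k in 1:6) acc <- acc & shift3d(m, offsets6[k, ], fill = FALSE)
    m <- acc
  }
  m
}

close6 <- function(mask, iter = 1L) {
  if (iter < 1L) return(mask)
  erode6(dilate6(mask, iter), iter)
}

# 6-connected component labeling via igraph on the voxel adjacency graph.
# Returns an integer array; components numbered in decreasing size order.
label6 <- function(mask) {
  d <- dim(mask)
  lab <- array(0L, d)
  idx <- which(mask)
  if (!length(idx)) return(lab)
  pos <- arrayInd(idx, d)
  id <- array(0L, d)
  id[idx] <- seq_along(idx)
  edges <- NULL
  el <- vector("list", 3)
  for (ax in 1:3) {
    p2 <- pos
    p2[, ax] <- p2[, ax] + 1L
    ok <- p2[, ax] <= d[ax]
    j <- id[p2[ok, , drop = FALSE]]
    keep <- j > 0L
    el[[ax]] <- cbind(which(ok)[keep], j[keep])
  }
  edges <- do.call(rbind, el)
  g <- igraph::graph_from_edgelist(edges, directed = FALSE)
  nv <- length(idx)
  g <- igraph::add_vertices(g, max(0L, nv - igraph::vcount(g)))
  comp <- igraph::components(g)
  ord <- order(comp$csize, decreasing = TRUE)
  remap <- integer(comp$no)
  remap[ord] <- seq_len(comp$no)
  lab[idx] <- remap[comp$membership]
  lab
}

# Separable Gaussian smoothing (sigma in voxels, may differ per axis).
gauss3d <- function(a, sigma = 0.8) {
  sigma <- rep(sigma, length.out = 3)
  out <- a
  for (ax in 1:3) {
    s <- sigma[ax]
    if (s <= 0) next
    m <- max(1L, ceiling(3 * s))
    k <- exp(-((-m:m)^2) / (2 * s^2))
    k <- k / sum(k)
    acc <- array(0, dim(a))
    wsum <- array(0, dim(a))
    one <- array(1, dim(a))
    for (j in seq_along(k)) {
      off <- c(0L, 0L, 0L)
      off[ax] <- j - m - 1L
      acc <- acc + k[j] * shift3d(out, off, fill = 0)
      wsum <- wsum + k[j] * shift3d(one, off, fill = 0)
    }
    out <- acc / wsum   # renormalized at borders (zero-flux-like)
  }
  out
}

# 1D squared-distance lower envelope (Felzenszwalb & Huttenlocher).
# f: sampled function (Inf allowed); h: sample spacing. Returns min_j
# (f[j] + h^2 (i-j)^2) for each i.
dt1d <- function(f, h = 1) {
  n <- length(f)
  if (n == 1L) return(f)
  d <- numeric(n)
  v <- integer(n); z <- numeric(n + 1)
  h2 <- h * h
  sect <- function(q, p)
    ((f[q] + h2 * q * q) - (f[p] + h2 * p * p)) / (2 * h2 * (q - p))
  k <- 1L; v[1] <- 1L; z[1] <- -Inf; z[2] <- Inf
  for (q in 2:n) {
    s <- sect(q, v[k])
    while (is.nan(s) || s <= z[k]) {
      k <- k - 1L
      if (k == 0L) break
      s <- sect(q, v[k])
    }
    if (k == 0L) {
      k <- 1L; v[1] <- q; z[1] <- -Inf; z[2] <- Inf
    } else {
      k <- k + 1L; v[k] <- q; z[k] <- s; z[k + 1] <- Inf
    }
  }
  k <- 1L
  for (q in 1:n) {
    while (z[k + 1] < q) k <- k + 1L
    d[q] <- h2 * (q - v[k])^2 + f[v[k]]
  }
  d
}

# Exact 3D Euclidean distance transform: for every TRUE voxel, distance (in
# physical units given by spacing) to the nearest FALSE voxel; 0 outside.
# Voxels on the domain border are bounded by the border distance, so tubes
# touching the grid edge do not leak to infinity.
edt3d <- function(mask, spacing = c(1, 1, 1)) {
  d <- dim(mask)
  f <- array(ifelse(mask, Inf, 0), d)
  # pass along each axis
  for (ax in 1:3) {
    h <- spacing[ax]
    perm <- switch(ax, c(1, 2, 3), c(2, 1, 3), c(3, 1, 2))
    fp <- aperm(f, perm)
    dp <- dim(fp)
    m <- matrix(fp, nrow = dp[1])
    todo <- which(colSums(is.finite(m)) > 0 & colSums(m) != 0)
    for (j in todo) m[, j] <- dt1d(m[, j], h)
    fp <- array(m, dp)
    f <- aperm(fp, order(perm))
  }
  # border clamp: distance cannot exceed distance to the domain boundary + h/2
  idx <- which(mask)
  if (length(idx)) {
    pos <- arrayInd(idx, d)
    bd <- pmin((pos[, 1] - 0.5) * spacing[1], (d[1] - pos[, 1] + 0.5) * spacing[1])
    bd <- pmin(bd, (pos[, 2] - 0.5) * spacing[2], (d[2] - pos[, 2] + 0.5) * spacing[2])
    bd <- pmin(bd, (pos[, 3] - 0.5) * spacing[3], (d[3] - pos[, 3] + 0.5) * spacing[3])
    f[idx] <- pmin(sqrt(f[idx]), bd)
  }
  f[!mask] <- 0
  f
}

# Physical coordinates (mm) of voxel centers for 0-based index * spacing (um).
voxelCoords <- function(dimv, spacing, idx) {
  pos <- arrayInd(idx, dimv)
  cbind((pos[, 1] - 1) * spacing[1], (pos[, 2] - 1) * spacing[2],
        (pos[, 3] - 1) * spacing[3]) / 1000
}

unitize <- function(v) {
  n <- sqrt(sum(v^2))
  if (n < .Machine$double.eps) stop("cannot normalize zero vector")
  v / n
}

rowUnitize <- function(m) {
  n <- sqrt(rowSums(m^2))
  n[n < .Machine$double.eps] <- 1
  m / n
}
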