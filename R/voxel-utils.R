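# Low-level voxel operations shared by the morphometry and generator code.

# Euclidean distance (in `spacing` units) from every voxel to the nearest
# TRUE voxel of `mask`.  Voxels inside the set get 0.
dist_to_set <- function(mask, spacing = c(1, 1, 1)) {
  d <- dim(mask)
  out <- cpp_dist_to_set(as.logical(mask), as.integer(d), as.numeric(spacing))
  array(out, dim = d)
}

# distance from inside a mask to the nearest background voxel (the
# anisotropy-aware "inscribed radius" field); 0 outside the mask
edt_inside <- function(mask, spacing = c(1, 1, 1)) {
  d <- dist_to_set(!mask, spacing)
  d[!mask] <- 0
  d
}

label_components <- function(mask, connectivity = 26L) {
  d <- dim(mask)
  array(cpp_label3d(as.logical(mask), as.integer(d), as.integer(connectivity)),
        dim = d)
}

# separable Gaussian smoothing of a 3-D array; sigma per axis in voxels
gauss_smooth3 <- function(a, sigma_vox) {
  d <- dim(a)
  for (ax in 1:3) {
    s <- sigma_vox[ax]
    if (s < 0.05) next
    half <- max(1L, ceiling(3 * s))
    kern <- exp(-0.5 * ((-half:half) / s)^2)
    kern <- kern / sum(kern)
    n <- d[ax]
    # band matrix with truncated-kernel renormalisation at the edges
    K <- matrix(0, n, n)
    for (t in -half:half) {
      idx <- seq_len(n)
      src <- idx + t
      ok <- src >= 1 & src <= n
      K[cbind(idx[ok], src[ok])] <- K[cbind(idx[ok], src[ok])] +
        kern[t + half + 1]
    }
    K <- K / rowSums(K)
    perm <- c(ax, setdiff(1:3, ax))
    ap <- aperm(a, perm)
    dp <- dim(ap)
    ap <- K %*% matrix(ap, nrow = dp[1])
    dim(ap) <- dp
    a <- aperm(ap, order(perm))
  }
  a
}

# voxel coordinates (1-based indices) of TRUE voxels as an n x 3 matrix
mask_coords <- function(mask) {
  idx <- which(mask)
  d <- dim(mask)
  cbind((idx - 1L) %% d[1] + 1L,
        ((idx - 1L) %/% d[1]) %% d[2] + 1L,
        (idx - 1L) %/% (d[1] * d[2]) + 1L)
}

# 26-connectivity adjacency graph over the TRUE voxels of a mask.
# Edge attribute `len` is the physical step length; `weight` is `len`
# optionally scaled by the mean of a per-voxel traversal cost, which lets
# shortest paths prefer central (high-EDT) voxels while `len` still sums
# to the physical path length.
voxel_graph <- function(mask, spacing, cost = NULL) {
  d <- dim(mask)
  id <- array(0L, dim = d)
  nvox <- sum(mask)
  id[mask] <- seq_len(nvox)
  cv <- if (!is.null(cost)) cost[mask] else NULL
  offs <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  offs <- offs[rowSums(abs(offs)) > 0, , drop = FALSE]
  keep <- offs[, 3] > 0 | (offs[, 3] == 0 &
          (offs[, 2] > 0 | (offs[, 2] == 0 & offs[, 1] > 0)))
  offs <- offs[keep, , drop = FALSE]
  from <- integer(0); to <- integer(0); len <- numeric(0); w <- numeric(0)
  for (r in seq_len(nrow(offs))) {
    o <- offs[r, ]
    xs <- seq(max(1, 1 + o[1]), min(d[1], d[1] + o[1]))
    ys <- seq(max(1, 1 + o[2]), min(d[2], d[2] + o[2]))
    zs <- seq(max(1, 1 + o[3]), min(d[3], d[3] + o[3]))
    sub <- id[xs, ys, zs, drop = FALSE]
    nb <- id[xs - o[1], ys - o[2], zs - o[3], drop = FALSE]
    ok <- sub > 0L & nb > 0L
    if (!any(ok)) next
    l <- sqrt(sum((o * spacing)^2))
    f <- sub[ok]; t <- nb[ok]
    from <- c(from, f); to <- c(to, t)
    len <- c(len, rep(l, length(f)))
    w <- c(w, if (is.null(cv)) rep(l, length(f))
           else l * 0.5 * (cv[f] + cv[t]))
  }
  g <- igraph::make_empty_graph(n = nvox, directed = FALSE)
  g <- igraph::add_edges(g, rbind(from, to))
  igraph::E(g)$weight <- w
  igraph::E(g)$len <- len
  list(graph = g, id = id, n = nvox)
}

# physical length of a path given as a vertex-id sequence
path_length <- function(vg, vpath) {
  if (length(vpath) < 2L) return(0)
  eids <- igraph::get.edge.ids(
    vg$graph, as.vector(rbind(vpath[-length(vpath)], vpath[-1])))
  sum(igraph::E(vg$graph)$len[eids])
}
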