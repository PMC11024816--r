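# Shared fixtures and independent oracles. Everything is generated in code;
# no binary fixtures.

# cached small template so multiple files can reuse it
small_template <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- build_template_tract_mesh(template_config(4, 4, 10))
    cache
  }
})

# axis-aligned structured box mesh: nx x ny x nz unit cells, corner at origin
box_mesh <- function(nx, ny, nz, origin = c(0, 0, 0), spacing = c(1, 1, 1)) {
  g <- expand.grid(i = 0:nx, j = 0:ny, k = 0:nz)
  nodes <- cbind(origin[1] + g$i * spacing[1],
                 origin[2] + g$j * spacing[2],
                 origin[3] + g$k * spacing[3])
  nid <- function(i, j, k) i + j * (nx + 1) + k * (nx + 1) * (ny + 1) + 1L
  i <- rep(0:(nx - 1), times = ny * nz)
  j <- rep(rep(0:(ny - 1), each = nx), times = nz)
  k <- rep(0:(nz - 1), each = nx * ny)
  el <- cbind(nid(i, j, k),         nid(i + 1, j, k),
              nid(i + 1, j + 1, k), nid(i, j + 1, k),
              nid(i, j, k + 1),     nid(i + 1, j, k + 1),
              nid(i + 1, j + 1, k + 1), nid(i, j + 1, k + 1))
  hex_mesh(nodes, el, structure = list(n_u = nx, n_v = ny, n_w = nz))
}

unit_hex_mesh <- function() box_mesh(1, 1, 1)

# brute-force nearest neighbour oracle, smallest-index tie-break; the
# distance arithmetic matches the package accumulation order
nn_oracle <- function(query, ref) {
  idx <- integer(nrow(query)); dist <- numeric(nrow(query))
  for (i in seq_len(nrow(query))) {
    best <- Inf; bj <- -1L
    for (j in seq_len(nrow(ref))) {
      dx <- query[i, 1] - ref[j, 1]; dy <- query[i, 2] - ref[j, 2]
      dz <- query[i, 3] - ref[j, 3]
      d2 <- dx * dx + dy * dy + dz * dz
      if (d2 < best) { best <- d2; bj <- j }
    }
    idx[i] <- bj; dist[i] <- sqrt(best)
  }
  list(index = idx, distance = dist)
}

# independent surface-node oracle: count 4-node faces by canonical string key
surface_oracle <- function(mesh) {
  faces6 <- rbind(c(1, 2, 3, 4), c(5, 6, 7, 8), c(1, 2, 6, 5),
                  c(2, 3, 7, 6), c(3, 4, 8, 7), c(4, 1, 5, 8))
  faces <- do.call(rbind, lapply(1:6, function(f)
    mesh$elements[, faces6[f, ], drop = FALSE]))
  key <- apply(faces, 1, function(r) paste(sort(r), collapse = "-"))
  once <- names(which(table(key) == 1))
  sort(unique(as.vector(faces[key %in% once, , drop = FALSE])))
}

# point-in-hex oracle by 6-tetrahedra decomposition; exact for hexes with
# planar faces (affine images of the cube), used on box meshes only
point_in_hex_oracle <- function(p, corners, tol = 1e-9) {
  tets <- rbind(c(1, 2, 3, 7), c(1, 3, 4, 7), c(1, 4, 8, 7),
                c(1, 8, 5, 7), c(1, 5, 6, 7), c(1, 6, 2, 7))
  for (t in seq_len(6)) {
    a <- corners[tets[t, 1], ]; b <- corners[tets[t, 2], ]
    c_ <- corners[tets[t, 3], ]; d <- corners[tets[t, 4], ]
    M <- cbind(b - a, c_ - a, d - a)
    if (abs(det(M)) < 1e-14) next
    lam <- solve(M, p - a)
    if (all(lam >= -tol) && sum(lam) <= 1 + tol) return(TRUE)
  }
  FALSE
}

# brute-force per-element nearest-masked-voxel assignment oracle
assign_oracle <- function(mesh, vol, max_dist) {
  cen <- element_centroids(mesh)
  lin <- which(vol$mask)
  idx0 <- arrayInd(lin, dim(vol$data)) - 1L
  pts <- cbind(idx0, 1) %*% t(vol$affine)
  pts <- pts[, 1:3, drop = FALSE]
  vals <- rep(NA_real_, nrow(cen)); far <- logical(nrow(cen))
  for (e in seq_len(nrow(cen))) {
    best <- Inf; bj <- -1L
    for (j in seq_len(nrow(pts))) {
      dx <- cen[e, 1] - pts[j, 1]; dy <- cen[e, 2] - pts[j, 2]
      dz <- cen[e, 3] - pts[j, 3]
      d2 <- dx * dx + dy * dy + dz * dz
      if (d2 < best) { best <- d2; bj <- j }   # lin already sorted ascending
    }
    if (sqrt(best) > max_dist) far[e] <- TRUE
    else vals[e] <- vol$data[lin[bj]]
  }
  list(values = vals, unassigned = far)
}

# pooled two-sample t oracle via stats::t.test
ttest_oracle <- function(a, b) {
  tt <- stats::t.test(a, b, var.equal = TRUE)
  list(t = unname(tt$statistic), p = tt$p.value)
}

rotation_matrix <- function(ax, ay, az) {
  Rx <- rbind(c(1, 0, 0), c(0, cos(ax), -sin(ax)), c(0, sin(ax), cos(ax)))
  Ry <- rbind(c(cos(ay), 0, sin(ay)), c(0, 1, 0), c(-sin(ay), 0, cos(ay)))
  Rz <- rbind(c(cos(az), -sin(az), 0), c(sin(az), cos(az), 0), c(0, 0, 1))
  Rz %*% Ry %*% Rx
}
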