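# Host-lattice free-form deformation. The template mesh is embedded in a
# regular wrapper lattice with a trilinear per-cell basis; fitting moves the
# lattice control points so that surface nodes match a subject point cloud,
# and every node (internal ones included) rides along through its fixed
# material coordinates.

#' Build a regular host lattice around a point set
#'
#' Axis-aligned lattice whose box is the point bounding box expanded by
#' `margin` on every side; control points start on the undeformed grid.
#'
#' @param points numeric matrix n x 3 the lattice must enclose
#' @param dims integer cell counts per axis (default 4 x 4 x 4)
#' @param margin positive expansion (mm) added on each side; also rescues
#'   degenerate (flat or single-point) bounding boxes
#' @return an object of class `host_lattice` with fields `origin`, `spacing`,
#'   `dims`, `control_points` (one row per control point, x-fastest order)
#' @export
build_host_lattice <- function(points, dims = c(4L, 4L, 4L), margin) {
  points <- as_points(points)
  if (nrow(points) == 0) stop("cannot build a host lattice around an empty point set")
  dims <- as.integer(dims)
  if (length(dims) != 3 || any(dims < 1L)) stop("dims must be 3 cell counts >= 1")
  if (!is.numeric(margin) || length(margin) != 1 || margin <= 0)
    stop("margin must be a positive scalar (mm)")
  lo <- apply(points, 2, min); hi <- apply(points, 2, max)
  origin <- lo - margin
  spacing <- (hi - lo + 2 * margin) / dims
  lat <- list(origin = origin, spacing = spacing, dims = dims,
              control_points = lattice_grid_points(origin, spacing, dims))
  class(lat) <- "host_lattice"
  lat
}

lattice_grid_points <- function(origin, spacing, dims) {
  g <- expand.grid(i = 0:dims[1], j = 0:dims[2], k = 0:dims[3])
  cbind(origin[1] + g$i * spacing[1],
        origin[2] + g$j * spacing[2],
        origin[3] + g$k * spacing[3])
}

# default wrapper margin: 10% of the largest bounding-box extent
default_lattice_margin <- function(points) {
  ext <- apply(points, 2, function(x) diff(range(x)))
  m <- 0.1 * max(ext)
  if (m <= 0) 1 else m
}

#' Embed points in a host lattice (material coordinates)
#'
#' Closed-form cell index and local coordinates in the undeformed regular
#' grid. Evaluating the undeformed lattice at the result reproduces the
#' points to floating-point round-off.
#'
#' @param lattice a `host_lattice`
#' @param points numeric matrix n x 3, all inside the lattice box
#' @param tol containment slack (lattice units) before a point is rejected
#' @return an object of class `embedded_coords`: integer cell matrix (0-based)
#'   and local coordinate matrix with entries in the unit interval
#' @export
embed_points <- function(lattice, points, tol = 1e-9) {
  points <- as_points(points)
  t <- sweep(sweep(points, 2, lattice$origin), 2, lattice$spacing, `/`)
  out_lo <- t < -tol
  out_hi <- sweep(t, 2, lattice$dims + tol) > 0
  bad <- which(rowSums(out_lo | out_hi) > 0)
  if (length(bad))
    stop(sprintf("point %d (%.4g, %.4g, %.4g) lies outside the host lattice",
                 bad[1], points[bad[1], 1], points[bad[1], 2], points[bad[1], 3]))
  cell <- pmin(pmax(floor(t), 0), matrix(rep(lattice$dims - 1L, each = nrow(t)),
                                         ncol = 3))
  uvw <- pmin(pmax(t - cell, 0), 1)
  structure(list(cell = matrix(as.integer(cell), ncol = 3), uvw = uvw,
                 dims = lattice$dims),
            class = "embedded_coords")
}

# sparse trilinear weight matrix: n points x (dims+1)^3 control points
lattice_weight_matrix <- function(coords) {
  dims <- coords$dims
  n <- nrow(coords$uvw)
  np <- dims + 1L
  ncp <- prod(np)
  u <- coords$uvw[, 1]; v <- coords$uvw[, 2]; w <- coords$uvw[, 3]
  ii <- rep(seq_len(n), 8)
  jj <- numeric(0); xx <- numeric(0)
  jlist <- vector("list", 8); xlist <- vector("list", 8)
  c8 <- expand.grid(di = 0:1, dj = 0:1, dk = 0:1)
  for (r in seq_len(8)) {
    di <- c8$di[r]; dj <- c8$dj[r]; dk <- c8$dk[r]
    jlist[[r]] <- (coords$cell[, 1] + di) +
      (coords$cell[, 2] + dj) * np[1] +
      (coords$cell[, 3] + dk) * np[1] * np[2] + 1
    xlist[[r]] <- (if (di) u else 1 - u) * (if (dj) v else 1 - v) *
      (if (dk) w else 1 - w)
  }
  Matrix::sparseMatrix(i = ii, j = unlist(jlist), x = unlist(xlist),
                       dims = c(n, ncp))
}

#' Evaluate a (possibly deformed) lattice at embedded coordinates
#'
#' Trilinear combination of each point's 8 cell control points. With
#' undeformed control points this is the identity map; an affine map of the
#' control points is reproduced exactly on every embedded point (linear
#' precision of the trilinear basis).
#'
#' @param lattice a `host_lattice`
#' @param coords an `embedded_coords` for this lattice's dims
#' @return numeric matrix n x 3 of deformed positions
#' @export
evaluate_lattice <- function(lattice, coords) {
  if (!identical(as.integer(coords$dims), as.integer(lattice$dims)))
    stop("embedded coordinates were computed for a lattice with different dims")
  if (any(coords$cell < 0L) ||
      any(sweep(coords$cell, 2, lattice$dims - 1L) > 0L))
    stop("cell index out of range for this lattice")
  W <- lattice_weight_matrix(coords)
  as.matrix(W %*% lattice$control_points)
}

# graph Laplacian on the control grid: row = displacement minus the mean of
# axis neighbours; constant and affine displacement fields are annihilated
# only up to boundary effects, constants exactly (rows sum to zero)
lattice_laplacian <- function(dims) {
  np <- dims + 1L
  ncp <- prod(np)
  g <- expand.grid(i = 0:dims[1], j = 0:dims[2], k = 0:dims[3])
  id <- function(i, j, k) i + j * np[1] + k * np[1] * np[2] + 1
  ii <- jj <- xx <- vector("list", 7)
  nb <- matrix(0L, ncp, 6)
  cnt <- integer(ncp)
  offs <- rbind(c(-1, 0, 0), c(1, 0, 0), c(0, -1, 0), c(0, 1, 0),
                c(0, 0, -1), c(0, 0, 1))
  trip_i <- list(); trip_j <- list(); trip_x <- list()
  self <- id(g$i, g$j, g$k)
  for (o in seq_len(6)) {
    i2 <- g$i + offs[o, 1]; j2 <- g$j + offs[o, 2]; k2 <- g$k + offs[o, 3]
    ok <- i2 >= 0 & i2 <= dims[1] & j2 >= 0 & j2 <= dims[2] & k2 >= 0 & k2 <= dims[3]
    cnt <- cnt + ok
    trip_i[[o]] <- self[ok]
    trip_j[[o]] <- id(i2[ok], j2[ok], k2[ok])
  }
  for (o in seq_len(6)) trip_x[[o]] <- -1 / cnt[trip_i[[o]]]
  Matrix::sparseMatrix(i = c(seq_len(ncp), unlist(trip_i)),
                       j = c(seq_len(ncp), unlist(trip_j)),
                       x = c(rep(1, ncp), unlist(trip_x)),
                       dims = c(ncp, ncp))
}

#' Fitting parameters for the free-form deformation
#'
#' @param smoothing_weight nonnegative Laplacian penalty weight lambda; the
#'   effective penalty is `lambda * mean(spacing^2)` so the default behaves
#'   consistently across lattice scales
#' @param max_outer_iters maximum correspondence/solve iterations
#' @param rmse_tol stop when the surface RMSE changes by less than this (mm)
#' @param correspondence_mode `"nearest"` (surface node to nearest cloud
#'   point, cloud assumed dense) or `"symmetric"` (adds cloud-point to
#'   nearest-node residuals)
#' @return a `fit_params` list
#' @export
fit_params <- function(smoothing_weight = 0.01, max_outer_iters = 30L,
                       rmse_tol = 1e-3,
                       correspondence_mode = c("nearest", "symmetric")) {
  if (smoothing_weight < 0) stop("smoothing_weight must be >= 0")
  if (max_outer_iters < 1) stop("max_outer_iters must be positive")
  if (rmse_tol <= 0) stop("rmse_tol must be positive")
  structure(list(smoothing_weight = smoothing_weight,
                 max_outer_iters = as.integer(max_outer_iters),
                 rmse_tol = rmse_tol,
                 correspondence_mode = match.arg(correspondence_mode)),
            class = "fit_params")
}

#' @rdname fit_params
#' @param path YAML file with any subset of the parameter fields
#' @export
read_fit_params <- function(path) {
  y <- yaml::read_yaml(path)
  do.call(fit_params, y[intersect(names(y), names(formals(fit_params)))])
}

#' Surface RMSE of a mesh against a point cloud
#'
#' Root mean square, over surface nodes, of the distance to the nearest
#' cloud point — the fit-quality measure of the pipeline.
#'
#' @param mesh a `hex_mesh`
#' @param cloud numeric matrix n x 3
#' @return scalar RMSE in mm
#' @export
rms_error <- function(mesh, cloud) {
  cloud <- as_points(cloud, "cloud")
  if (nrow(cloud) == 0) stop("point cloud is empty")
  nn <- cpp_nn(mesh$nodes[mesh$surface_nodes, , drop = FALSE], cloud)
  sqrt(mean(nn$distance^2))
}

#' Fit the template mesh to a subject point cloud by FFD
#'
#' Iterates: (a) correspond each surface node of the currently deformed mesh
#' to its nearest cloud point; (b) solve the regularised linear least-squares
#' problem over control-point displacements; (c) move all mesh nodes through
#' the updated lattice. Stops when the surface RMSE change drops below
#' `rmse_tol` or after `max_outer_iters`. The correspondence step can only
#' lower the objective and the inner solve is exact, so the objective trace
#' is non-increasing.
#'
#' @param template a `hex_mesh` (topology is preserved exactly)
#' @param cloud subject surface point cloud, n x 3, n >= 10
#' @param lattice_dims host lattice cell counts (default 4 x 4 x 4)
#' @param params a `fit_params`
#' @param margin wrapper margin (mm); default 10% of the largest template
#'   bounding-box extent
#' @return an object of class `ffd_fit`: `lattice` (fitted), `mesh`
#'   (morphed), `rmse` (mm), `objective` and `rmse_trace` per outer
#'   iteration, `converged`, plus the node embedding used
#' @export
fit_to_point_cloud <- function(template, cloud, lattice_dims = c(4L, 4L, 4L),
                               params = fit_params(), margin = NULL) {
  stopifnot(inherits(template, "hex_mesh"))
  cloud <- as_points(cloud, "cloud")
  if (nrow(cloud) < 10) stop("point cloud too small: need at least 10 points")
  margin <- margin %||% default_lattice_margin(template$nodes)
  lattice <- build_host_lattice(template$nodes, lattice_dims, margin)
  emb <- embed_points(lattice, template$nodes)
  Wall <- lattice_weight_matrix(emb)
  surf <- template$surface_nodes
  A <- Wall[surf, , drop = FALSE]
  ns <- length(surf)
  L <- lattice_laplacian(lattice$dims)
  lambda <- params$smoothing_weight * mean(lattice$spacing^2)
  C0 <- lattice$control_points
  LtL <- Matrix::crossprod(L)
  symmetric <- params$correspondence_mode == "symmetric"
  wsym <- if (symmetric) ns / nrow(cloud) else 0

  chol_or_fail <- function(M) {
    R <- tryCatch(chol(as.matrix(M)), error = function(e) NULL)
    if (is.null(R))
      stop("singular normal system in FFD fit; set smoothing_weight > 0")
    R
  }
  if (!symmetric) {
    M <- Matrix::crossprod(A) + lambda * LtL
    Rch <- chol_or_fail(M)
  }

  Cp <- C0
  nodes <- as.matrix(Wall %*% Cp)
  objective <- numeric(0)
  rmse_trace <- numeric(0)
  rmse_prev <- Inf
  converged <- FALSE
  D <- matrix(0, nrow(C0), 3)
  for (it in seq_len(params$max_outer_iters)) {
    nnq <- cpp_nn(nodes[surf, , drop = FALSE], cloud)
    Y <- cloud[nnq$index, , drop = FALSE]
    if (symmetric) {
      nnr <- cpp_nn(cloud, nodes[surf, , drop = FALSE])
      A2 <- A[nnr$index, , drop = FALSE] * sqrt(wsym)
      Ait <- rbind(A, A2)
      Yit <- rbind(Y, cloud * sqrt(wsym))
      M <- Matrix::crossprod(Ait) + lambda * LtL
      Rch <- chol_or_fail(M)
    } else {
      Ait <- A; Yit <- Y
    }
    rhs <- as.matrix(Matrix::crossprod(Ait, Yit - Ait %*% C0))
    D <- backsolve(Rch, forwardsolve(t(Rch), rhs))
    Cp <- C0 + D
    nodes <- as.matrix(Wall %*% Cp)
    obj <- sum((as.matrix(Ait %*% Cp) - Yit)^2) +
      lambda * sum(as.matrix(L %*% D)^2)
    objective <- c(objective, obj)
    nnp <- cpp_nn(nodes[surf, , drop = FALSE], cloud)
    rmse <- sqrt(mean(nnp$distance^2))
    rmse_trace <- c(rmse_trace, rmse)
    if (abs(rmse_prev - rmse) < params$rmse_tol) { converged <- TRUE; break }
    rmse_prev <- rmse
  }
  lattice$control_points <- Cp
  morphed <- hex_mesh(nodes, template$elements, fields = template$fields,
                      structure = template$structure,
                      surface_nodes = template$surface_nodes, validate = FALSE)
  structure(list(lattice = lattice, mesh = morphed, rmse = rmse,
                 objective = objective, rmse_trace = rmse_trace,
                 converged = converged, iterations = length(objective),
                 embedding = emb, params = params),
            class = "ffd_fit")
}

#' @export
print.ffd_fit <- function(x, ...) {
  cat(sprintf("ffd_fit: rmse %.4g mm after %d iteration(s)%s\n",
              x$rmse, x$iterations,
              if (x$converged) " (converged)" else " (max iterations)"))
  invisible(x)
}
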