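# Hexahedral tract meshes: data structure, template generator, surface
# extraction. Corner ordering follows the VTK hexahedron convention:
# bottom face (0,0,0),(1,0,0),(1,1,0),(0,1,0) then the same cycle at w=1.

HEX_FACES <- rbind(
  c(1L, 2L, 3L, 4L),  # bottom
  c(5L, 6L, 7L, 8L),  # top
  c(1L, 2L, 6L, 5L),
  c(2L, 3L, 7L, 6L),
  c(3L, 4L, 8L, 7L),
  c(4L, 1L, 5L, 8L)
)

#' Construct a hexahedral mesh
#'
#' @param nodes numeric matrix, n x 3, node coordinates in world millimetres
#' @param elements integer matrix, m x 8, 1-based node indices per hexahedron
#'   in VTK corner order
#' @param fields named list of per-element numeric vectors (length m)
#' @param structure optional list describing a structured-tube layout
#'   (`n_u`, `n_v`, `n_w`), carried by the template generator so material
#'   coordinates of elements are recoverable after morphing
#' @param surface_nodes optional precomputed surface-node index vector; when
#'   omitted it is derived from face multiplicities
#' @param validate verify invariants (indices in range, 8 distinct corners,
#'   field lengths)
#' @return an object of class `hex_mesh`
#' @export
hex_mesh <- function(nodes, elements, fields = list(), structure = NULL,
                     surface_nodes = NULL, validate = TRUE) {
  nodes <- as_points(nodes, "nodes")
  elements <- as.matrix(elements)
  storage.mode(elements) <- "integer"
  if (ncol(elements) != 8) stop("elements must have 8 columns")
  m <- list(nodes = nodes, elements = elements, fields = fields,
            structure = structure, surface_nodes = surface_nodes)
  class(m) <- "hex_mesh"
  if (validate) validate_hex_mesh(m)
  if (is.null(m$surface_nodes)) m$surface_nodes <- extract_surface_nodes(m)
  m
}

validate_hex_mesh <- function(mesh) {
  n <- nrow(mesh$nodes); el <- mesh$elements
  if (nrow(el) < 1) stop("mesh has no elements")
  if (any(el < 1L) || any(el > n)) stop("element index out of node range")
  distinct <- apply(el, 1, function(r) length(unique(r)) == 8L)
  if (!all(distinct))
    stop(sprintf("element %d has repeated corner nodes", which(!distinct)[1]))
  for (nm in names(mesh$fields)) {
    if (length(mesh$fields[[nm]]) != nrow(el))
      stop(sprintf("field '%s' has length %d, expected %d",
                   nm, length(mesh$fields[[nm]]), nrow(el)))
  }
  invisible(TRUE)
}

#' @export
print.hex_mesh <- function(x, ...) {
  cat(sprintf("hex_mesh: %d nodes, %d elements, %d surface nodes\n",
              nrow(x$nodes), nrow(x$elements), length(x$surface_nodes)))
  if (length(x$fields))
    cat("fields:", paste(names(x$fields), collapse = ", "), "\n")
  invisible(x)
}

# canonical key per face: corner ids sorted by a 4-element sorting network,
# fully vectorised (the face table of the default template has ~123k rows)
face_keys <- function(faces) {
  a <- faces[, 1]; b <- faces[, 2]; c <- faces[, 3]; d <- faces[, 4]
  s <- function(x, y) list(lo = pmin(x, y), hi = pmax(x, y))
  p1 <- s(a, b); p2 <- s(c, d)
  q1 <- s(p1$lo, p2$lo); q2 <- s(p1$hi, p2$hi)
  mid <- s(q1$hi, q2$lo)
  cbind(q1$lo, mid$lo, mid$hi, q2$hi)
}

#' Extract surface (boundary) node indices
#'
#' Nodes that lie on faces shared by exactly one element.
#'
#' @param mesh a `hex_mesh`
#' @return sorted integer vector of node indices
#' @export
extract_surface_nodes <- function(mesh) {
  el <- mesh$elements
  faces <- do.call(rbind, lapply(seq_len(6), function(f)
    el[, HEX_FACES[f, ], drop = FALSE]))
  key <- face_keys(faces)
  o <- order(key[, 1], key[, 2], key[, 3], key[, 4])
  k <- key[o, , drop = FALSE]
  nf <- nrow(k)
  same_next <- c(rowSums(k[-nf, , drop = FALSE] == k[-1, , drop = FALSE]) == 4, FALSE)
  same_prev <- c(FALSE, same_next[-nf])
  boundary <- o[!(same_next | same_prev)]
  sort(unique(as.vector(faces[boundary, , drop = FALSE])))
}

#' Element centroids
#'
#' Arithmetic mean of each element's 8 corner coordinates, in element order.
#'
#' @param mesh a `hex_mesh`
#' @return numeric matrix, m x 3
#' @export
element_centroids <- function(mesh) {
  acc <- matrix(0, nrow(mesh$elements), 3)
  for (c in seq_len(8))
    acc <- acc + mesh$nodes[mesh$elements[, c], , drop = FALSE]
  acc / 8
}

# signed trilinear Jacobian determinant at element centres (vectorised);
# used to reject inverted elements from the template generator
centroid_jacobians <- function(mesh) {
  nd <- mesh$nodes; el <- mesh$elements
  g <- function(cols) {
    acc <- matrix(0, nrow(el), 3)
    for (c in cols) acc <- acc + nd[el[, c], , drop = FALSE]
    acc / 4
  }
  du <- g(c(2, 3, 6, 7)) - g(c(1, 4, 5, 8))
  dv <- g(c(3, 4, 7, 8)) - g(c(1, 2, 5, 6))
  dw <- g(c(5, 6, 7, 8)) - g(c(1, 2, 3, 4))
  du[, 1] * (dv[, 2] * dw[, 3] - dv[, 3] * dw[, 2]) -
    du[, 2] * (dv[, 1] * dw[, 3] - dv[, 3] * dw[, 1]) +
    du[, 3] * (dv[, 1] * dw[, 2] - dv[, 2] * dw[, 1])
}

# ---- template configuration ----

default_centerline <- function() {
  # gentle S-curve evocative of the corticospinal tract course, in mm
  rbind(c(0, 0, 0),
        c(3, 1, 25),
        c(0, 2, 50),
        c(-3, 1, 75),
        c(0, 0, 100))
}

default_radii_profile <- function() {
  # cross-section semi-axes (mm) at equally spaced axial stations
  rbind(c(5.0, 3.5),
        c(7.0, 5.0),
        c(5.0, 3.5))
}

#' Template mesh configuration
#'
#' The default resolution is 16 x 16 x 80, giving the canonical 20 480-element
#' feature dimension; the factorisation (cross-section vs. axial granularity)
#' is a package choice, configurable here.
#'
#' @param n_u,n_v element counts across the two cross-section axes
#' @param n_w element count along the tract axis
#' @param centerline ordered matrix of 3D control vertices (mm) defining the
#'   tract course; at least 2 rows
#' @param radii_profile matrix of per-station cross-section semi-axes (mm),
#'   stations equally spaced along the tract and spline-interpolated; a single
#'   row gives a constant profile
#' @return an object of class `template_config`
#' @export
template_config <- function(n_u = 16L, n_v = 16L, n_w = 80L,
                            centerline = default_centerline(),
                            radii_profile = default_radii_profile()) {
  cfg <- list(n_u = as.integer(n_u), n_v = as.integer(n_v),
              n_w = as.integer(n_w),
              centerline = as_points(as.matrix(centerline), "centerline"),
              radii_profile = as.matrix(radii_profile))
  class(cfg) <- "template_config"
  validate_template_config(cfg)
  cfg
}

validate_template_config <- function(cfg) {
  for (f in c("n_u", "n_v", "n_w")) {
    v <- cfg[[f]]
    if (length(v) != 1 || is.na(v) || v < 1L)
      stop(sprintf("invalid template config: %s must be a positive integer", f))
  }
  if (nrow(cfg$centerline) < 2)
    stop("invalid template config: centerline needs at least 2 vertices")
  rp <- cfg$radii_profile
  if (ncol(rp) != 2) stop("invalid template config: radii_profile needs 2 columns")
  if (any(!is.finite(rp)) || any(rp <= 0))
    stop("invalid template config: radii_profile must be strictly positive")
  invisible(TRUE)
}

# interpolate centerline and transport an orthonormal frame along it
centerline_frames <- function(centerline, t_out) {
  seg <- sqrt(rowSums(diff(centerline)^2))
  s <- c(0, cumsum(seg)); s <- s / s[length(s)]
  if (any(diff(s) <= 0)) stop("invalid template config: centerline vertices coincide")
  method <- if (nrow(centerline) < 4) "fmm" else "natural"
  fx <- splinefun(s, centerline[, 1], method = method)
  fy <- splinefun(s, centerline[, 2], method = method)
  fz <- splinefun(s, centerline[, 3], method = method)
  centres <- cbind(fx(t_out), fy(t_out), fz(t_out))
  tang <- cbind(fx(t_out, deriv = 1), fy(t_out, deriv = 1), fz(t_out, deriv = 1))
  tang <- tang / sqrt(rowSums(tang^2))
  nk <- nrow(centres)
  Nrm <- matrix(0, nk, 3); Bin <- matrix(0, nk, 3)
  e <- if (abs(tang[1, 1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  prev <- e - sum(e * tang[1, ]) * tang[1, ]
  for (k in seq_len(nk)) {
    v <- prev - sum(prev * tang[k, ]) * tang[k, ]
    v <- v / sqrt(sum(v^2))
    Nrm[k, ] <- v
    Bin[k, ] <- c(tang[k, 2] * v[3] - tang[k, 3] * v[2],
                  tang[k, 3] * v[1] - tang[k, 1] * v[3],
                  tang[k, 1] * v[2] - tang[k, 2] * v[1])
    prev <- v
  }
  list(centres = centres, normal = Nrm, binormal = Bin)
}

#' Build the template tract mesh
#'
#' A solid tube-like structured hexahedral mesh: `n_w + 1` elliptical
#' cross-sections swept along a smooth interpolation of the centerline. The
#' square-to-ellipse cross-section map is a smooth radial ("squircle") map so
#' corner elements stay non-degenerate; Jacobians are checked at element
#' centres.
#'
#' @param config a `template_config`
#' @return a `hex_mesh` with `n_u * n_v * n_w` elements
#' @examples
#' mesh <- build_template_tract_mesh(template_config(2, 2, 2))
#' nrow(mesh$elements)  # 8
#' @export
build_template_tract_mesh <- function(config = template_config()) {
  if (!inherits(config, "template_config")) config <- do.call(template_config, config)
  validate_template_config(config)
  nu <- config$n_u; nv <- config$n_v; nw <- config$n_w
  t_out <- seq(0, 1, length.out = nw + 1)
  fr <- centerline_frames(config$centerline, t_out)

  rp <- config$radii_profile
  if (nrow(rp) == 1) {
    ra <- rep(rp[1, 1], nw + 1); rb <- rep(rp[1, 2], nw + 1)
  } else {
    ts <- seq(0, 1, length.out = nrow(rp))
    method <- if (nrow(rp) < 4) "fmm" else "natural"
    ra <- splinefun(ts, rp[, 1], method = method)(t_out)
    rb <- splinefun(ts, rp[, 2], method = method)(t_out)
    if (any(ra <= 0) || any(rb <= 0))
      stop("invalid template config: interpolated radii_profile not positive")
  }

  a <- rep(2 * (0:nu) / nu - 1, times = nv + 1)
  b <- rep(2 * (0:nv) / nv - 1, each = nu + 1)
  sx <- a * sqrt(1 - b^2 / 2)  # squircle square-to-disc map
  sy <- b * sqrt(1 - a^2 / 2)
  npersec <- (nu + 1) * (nv + 1)
  nodes <- matrix(0, npersec * (nw + 1), 3)
  for (k in 0:nw) {
    sec <- outer(ra[k + 1] * sx, fr$normal[k + 1, ]) +
           outer(rb[k + 1] * sy, fr$binormal[k + 1, ])
    sec <- sweep(sec, 2, fr$centres[k + 1, ], `+`)
    nodes[k * npersec + seq_len(npersec), ] <- sec
  }

  nid <- function(p, q, k) k * npersec + q * (nu + 1) + p + 1L
  i <- rep(0:(nu - 1), times = nv * nw)
  j <- rep(rep(0:(nv - 1), each = nu), times = nw)
  k <- rep(0:(nw - 1), each = nu * nv)
  elements <- cbind(nid(i,     j,     k),     nid(i + 1, j,     k),
                    nid(i + 1, j + 1, k),     nid(i,     j + 1, k),
                    nid(i,     j,     k + 1), nid(i + 1, j,     k + 1),
                    nid(i + 1, j + 1, k + 1), nid(i,     j + 1, k + 1))
  mesh <- hex_mesh(nodes, elements,
                   structure = list(n_u = nu, n_v = nv, n_w = nw))
  jac <- centroid_jacobians(mesh)
  if (any(jac <= 0))
    stop(sprintf("template generation produced %d inverted element(s); use a smoother centerline or smaller radii", sum(jac <= 0)))
  mesh
}

#' Material coordinates of element centres for a structured tube mesh
#'
#' @param mesh a `hex_mesh` carrying a `structure` entry
#' @return matrix m x 3 of (U, V, W) in the unit cube; W is the axial station
#' @export
element_material_coords <- function(mesh) {
  st <- mesh$structure
  if (is.null(st)) stop("mesh has no structured-template layout information")
  nu <- st$n_u; nv <- st$n_v; nw <- st$n_w
  idx <- seq_len(nrow(mesh$elements)) - 1L
  i <- idx %% nu
  j <- (idx %/% nu) %% nv
  k <- idx %/% (nu * nv)
  cbind((i + 0.5) / nu, (j + 0.5) / nv, (k + 0.5) / nw)
}

# read/write TemplateConfig as YAML
#' @rdname template_config
#' @param path YAML file path
#' @export
read_template_config <- function(path) {
  y <- yaml::read_yaml(path)
  template_config(n_u = y$n_u, n_v = y$n_v, n_w = y$n_w,
                  centerline = do.call(rbind, y$centerline),
                  radii_profile = do.call(rbind, y$radii_profile))
}

#' @rdname template_config
#' @param config a `template_config` to serialise
#' @export
write_template_config <- function(config, path) {
  y <- list(n_u = config$n_u, n_v = config$n_v, n_w = config$n_w,
            centerline = lapply(seq_len(nrow(config$centerline)),
                                function(i) as.numeric(config$centerline[i, ])),
            radii_profile = lapply(seq_len(nrow(config$radii_profile)),
                                   function(i) as.numeric(config$radii_profile[i, ])))
  yaml::write_yaml(y, path)
  invisible(path)
}
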