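# Metric embedding: read scalar diffusion-metric volumes and assign each
# corresponded mesh element the value of its nearest masked voxel (pure
# nearest neighbour, no interpolation), producing the SubjectModel.

METRICS <- c("FA", "MD", "AD", "RD")

#' Construct a scalar metric volume
#'
#' @param data 3D numeric array of metric values
#' @param affine 4 x 4 voxel-index (0-based, voxel centre) to world-mm
#'   transform
#' @param metric_name one of FA, MD, AD, RD
#' @param mask logical 3D array of in-tract voxels; default: finite, nonzero
#'   voxels
#' @return an object of class `scalar_volume`
#' @export
scalar_volume <- function(data, affine, metric_name, mask = NULL) {
  if (length(dim(data)) != 3) stop("data must be a 3D array")
  metric_name <- match.arg(metric_name, METRICS)
  affine <- as.matrix(affine)
  if (!all(dim(affine) == c(4, 4)) || abs(det(affine[1:3, 1:3])) < 1e-12)
    stop("affine must be an invertible 4 x 4 matrix")
  if (is.null(mask)) {
    mask <- is.finite(data) & data != 0
  } else {
    if (!all(dim(mask) == dim(data)))
      stop(sprintf("mask shape (%s) does not match data shape (%s)",
                   paste(dim(mask), collapse = "x"),
                   paste(dim(data), collapse = "x")))
    mask <- array(as.logical(mask), dim = dim(data)) & is.finite(data)
  }
  mv <- data[mask]
  if (length(mv)) {
    if (metric_name == "FA" && (min(mv) < 0 || max(mv) > 1))
      warning("FA values outside [0, 1] inside the mask")
    if (metric_name != "FA" && min(mv) < 0)
      warning(sprintf("negative %s values inside the mask", metric_name))
  }
  structure(list(data = data, affine = affine, metric_name = metric_name,
                 mask = mask),
            class = "scalar_volume")
}

#' Read a scalar metric volume from NIfTI
#'
#' @param path NIfTI file of one diffusion metric
#' @param metric_name one of FA, MD, AD, RD
#' @param mask_path optional NIfTI mask volume (same shape, voxels > 0 kept)
#' @return a `scalar_volume`
#' @export
read_scalar_volume <- function(path, metric_name, mask_path = NULL) {
  nf <- read_nifti(path)
  mask <- NULL
  if (!is.null(mask_path)) {
    mk <- read_nifti(mask_path)
    if (!all(dim(mk$data) == dim(nf$data)))
      stop(sprintf("mask '%s' shape (%s) does not match volume shape (%s)",
                   mask_path, paste(dim(mk$data), collapse = "x"),
                   paste(dim(nf$data), collapse = "x")))
    mask <- mk$data > 0
  }
  scalar_volume(nf$data, nf$affine, metric_name, mask)
}

#' World coordinates and values of masked voxel centres
#'
#' The affine is applied to 0-based integer voxel indices (centre-of-voxel
#' convention). Points come out ordered by voxel linear index, which is the
#' tie-break order for nearest-neighbour assignment.
#'
#' @param volume a `scalar_volume`
#' @return list with `points` (n x 3 world mm), `values`, `linear_index`
#' @export
masked_voxel_centres <- function(volume) {
  lin <- which(volume$mask)
  if (!length(lin)) stop("volume mask is empty")
  idx0 <- arrayInd(lin, dim(volume$data)) - 1L
  pts <- cbind(idx0, 1) %*% t(volume$affine)
  list(points = pts[, 1:3, drop = FALSE], values = volume$data[lin],
       linear_index = lin)
}

#' Construct a subject model
#'
#' @param mesh morphed `hex_mesh`
#' @param fields named list of per-element metric vectors
#' @param subject_id,group_label identifiers carried into cohort analyses
#' @param unassigned per-element flag: nearest masked voxel beyond the
#'   distance cap for at least one metric
#' @export
subject_model <- function(mesh, fields, subject_id = NA_character_,
                          group_label = NA_character_, unassigned = NULL) {
  m <- nrow(mesh$elements)
  for (nm in names(fields))
    if (length(fields[[nm]]) != m)
      stop(sprintf("field '%s' length %d != element count %d",
                   nm, length(fields[[nm]]), m))
  unassigned <- unassigned %||% rep(FALSE, m)
  structure(list(mesh = mesh, fields = fields, subject_id = subject_id,
                 group_label = group_label, unassigned = unassigned),
            class = "subject_model")
}

#' @export
print.subject_model <- function(x, ...) {
  cat(sprintf("subject_model '%s' (group %s): %d elements, metrics %s, %d unassigned\n",
              x$subject_id, x$group_label, nrow(x$mesh$elements),
              paste(names(x$fields), collapse = "/"), sum(x$unassigned)))
  invisible(x)
}

#' Assign metric values to mesh elements by nearest masked voxel
#'
#' Per element and metric, the value of the masked voxel centre nearest to
#' the element centroid (ties broken by smallest voxel linear index; no
#' interpolation). Elements whose nearest masked voxel lies farther than
#' `max_dist` are flagged unassigned and get NA, to be excluded downstream.
#'
#' @param mesh morphed `hex_mesh` in the subject's world space
#' @param volumes named list of `scalar_volume`s (any declared subset of
#'   FA/MD/AD/RD; names default to each volume's metric)
#' @param max_dist distance cap in mm; default twice the largest voxel
#'   spacing of the supplied volumes
#' @param at `"element"`: sample at element centroids (default, the analysis
#'   feature dimension); `"node"`: sample at nodes, then average the 8 corner
#'   values per element
#' @param subject_id,group_label identifiers stored on the result
#' @return a `subject_model`
#' @export
assign_fields <- function(mesh, volumes, max_dist = NULL,
                          at = c("element", "node"),
                          subject_id = NA_character_,
                          group_label = NA_character_) {
  at <- match.arg(at)
  stopifnot(inherits(mesh, "hex_mesh"))
  if (inherits(volumes, "scalar_volume")) volumes <- list(volumes)
  if (is.null(names(volumes)) || any(!nzchar(names(volumes))))
    names(volumes) <- vapply(volumes, function(v) v$metric_name, "")
  spacings <- vapply(volumes, function(v)
    max(sqrt(colSums(v$affine[1:3, 1:3]^2))), 0)
  max_dist <- max_dist %||% (2 * max(spacings))
  pts <- if (at == "element") element_centroids(mesh) else mesh$nodes
  m <- nrow(mesh$elements)
  fields <- list()
  unassigned <- rep(FALSE, m)
  counts <- integer(length(volumes))
  for (vi in seq_along(volumes)) {
    vol <- volumes[[vi]]
    mvc <- masked_voxel_centres(vol)   # errors if the mask is empty
    nn <- cpp_nn(pts, mvc$points)
    vals <- mvc$values[nn$index]
    far <- nn$distance > max_dist
    vals[far] <- NA_real_
    if (at == "node") {
      acc <- matrix(vals[mesh$elements], nrow = m)
      evals <- rowMeans(acc)           # NA if any corner unassigned
      efar <- !is.finite(evals)
      evals[efar] <- NA_real_
    } else {
      evals <- vals; efar <- far
    }
    fields[[names(volumes)[vi]]] <- evals
    unassigned <- unassigned | efar
    counts[vi] <- sum(efar)
  }
  if (length(unique(counts)) > 1)
    warning(sprintf("metric volumes have inconsistent world coverage: unassigned counts %s",
                    paste(sprintf("%s=%d", names(volumes), counts), collapse = ", ")))
  subject_model(mesh, fields, subject_id, group_label, unassigned)
}

#' Write / read a subject model (VTK mesh + JSON sidecar)
#'
#' @param model a `subject_model`
#' @param prefix output path prefix; writes `<prefix>.vtk` and
#'   `<prefix>.json`
#' @export
write_subject_model <- function(model, prefix) {
  mesh <- model$mesh
  mesh$fields <- c(model$fields,
                   list(unassigned = as.numeric(model$unassigned)))
  # VTK fields cannot hold NA: store a sentinel, restore via unassigned flags
  for (nm in names(model$fields))
    mesh$fields[[nm]][is.na(mesh$fields[[nm]])] <- -1
  write_mesh(mesh, paste0(prefix, ".vtk"))
  jsonlite::write_json(list(subject_id = model$subject_id,
                            group_label = model$group_label,
                            metrics = names(model$fields),
                            unassigned_count = sum(model$unassigned)),
                       paste0(prefix, ".json"), auto_unbox = TRUE)
  invisible(prefix)
}

#' @rdname write_subject_model
#' @export
read_subject_model <- function(prefix) {
  mesh <- read_mesh(paste0(prefix, ".vtk"))
  meta <- jsonlite::read_json(paste0(prefix, ".json"), simplifyVector = TRUE)
  unassigned <- as.logical(mesh$fields$unassigned %||% rep(0, nrow(mesh$elements)))
  fields <- mesh$fields[setdiff(names(mesh$fields), "unassigned")]
  fields <- fields[intersect(meta$metrics, names(fields))]
  for (nm in names(fields)) fields[[nm]][unassigned] <- NA_real_
  mesh$fields <- list()
  subject_model(mesh, fields, meta$subject_id, meta$group_label, unassigned)
}
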