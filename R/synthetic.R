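# Fully synthetic cohorts: smoothly warped tract shapes, voxelized metric
# volumes with a known group-effect region, and ground truth. The generator
# emulates the pipeline's real inputs (surface clouds from segmentations,
# DTIFIT-style metric maps) at desk scale; its defaults are the stated study
# world (20 cases, 12 controls, 2 mm voxels, 2 mm-scale shape warps).

#' Group-effect specification
#'
#' An additive group effect confined to an axial interval of the tract in
#' material coordinates: case-group voxels whose axial station W lies in
#' `region` get `delta` added for each affected metric. The per-element truth
#' mask marks elements whose centroid station falls inside the region.
#'
#' @param affected_metrics subset of FA/MD/AD/RD
#' @param region axial interval (w1, w2), 0 <= w1 < w2 <= 1
#' @param delta named additive effects (metric units) for the affected
#'   metrics
#' @export
effect_spec <- function(affected_metrics = c("MD", "AD"),
                        region = c(0.35, 0.65),
                        delta = c(MD = 0.10e-3, AD = 0.12e-3)) {
  affected_metrics <- match.arg(affected_metrics, METRICS, several.ok = TRUE)
  if (length(region) != 2 || !(region[1] >= 0 && region[1] < region[2] && region[2] <= 1))
    stop("effect region must satisfy 0 <= w1 < w2 <= 1")
  missing <- setdiff(affected_metrics, names(delta))
  if (length(missing))
    stop(sprintf("delta missing for affected metric(s): %s",
                 paste(missing, collapse = ", ")))
  structure(list(affected_metrics = affected_metrics, region = region,
                 delta = delta),
            class = "effect_spec")
}

#' Per-element ground-truth effect mask
#'
#' @param mesh template (or morphed template) `hex_mesh` with structure info
#' @param effect an `effect_spec`
#' @return logical vector over elements
#' @export
element_truth_mask <- function(mesh, effect) {
  W <- element_material_coords(mesh)[, 3]
  W >= effect$region[1] & W <= effect$region[2]
}

#' Simulation configuration
#'
#' Defaults encode the emulated study: 20 cases and 12 controls, 2 mm
#' isotropic voxels, smooth 2 mm-scale shape warps, and physiological
#' baseline metric fields (FA falling from 0.65 at the tract core to 0.35 at
#' the rim; MD/AD/RD constant at 0.80/1.20/0.60 x 10^-3 mm^2/s) with
#' additive voxel noise and per-subject intercepts.
#'
#' @param n_case,n_control subject counts (>= 2)
#' @param shape_warp_scale SD (mm) of the smooth lattice control-point
#'   perturbations generating per-subject shapes
#' @param voxel_size isotropic voxel size in mm
#' @param noise_sd named per-metric additive voxel noise SD
#' @param baselines per-metric baseline parameters
#' @param subject_intercept_sd named per-metric between-subject SD
#' @param seed master seed; all per-subject, per-stage seeds derive from it
#' @export
sim_config <- function(n_case = 20L, n_control = 12L, shape_warp_scale = 2,
                       voxel_size = 2,
                       noise_sd = c(FA = 0.03, MD = 0.04e-3,
                                    AD = 0.06e-3, RD = 0.04e-3),
                       baselines = list(FA = c(core = 0.65, rim = 0.35),
                                        MD = 0.80e-3, AD = 1.20e-3,
                                        RD = 0.60e-3),
                       subject_intercept_sd = c(FA = 0.02, MD = 0.02e-3,
                                                AD = 0.03e-3, RD = 0.02e-3),
                       seed = 1L) {
  if (n_case < 2 || n_control < 2) stop("subject counts must be >= 2")
  if (voxel_size <= 0) stop("voxel_size must be positive")
  if (shape_warp_scale < 0 || any(noise_sd < 0) || any(subject_intercept_sd < 0))
    stop("all SDs must be >= 0")
  structure(list(n_case = as.integer(n_case), n_control = as.integer(n_control),
                 shape_warp_scale = shape_warp_scale, voxel_size = voxel_size,
                 noise_sd = noise_sd, baselines = baselines,
                 subject_intercept_sd = subject_intercept_sd,
                 seed = as.integer(seed)),
            class = "sim_config")
}

#' Generate one subject's tract shape and surface point cloud
#'
#' Perturbs the control points of a coarse wrapper lattice with seeded
#' Gaussian displacements (SD `warp_scale`), maps the template through it,
#' and samples the warped boundary surface densely. The coarse 2x2x2 lattice
#' keeps warps smooth and large-scale; its knots are nested in the default
#' 4x4x4 fitting lattice, so the fitted RMSE measures correspondence error
#' rather than basis mismatch.
#'
#' @param template template `hex_mesh`
#' @param warp_scale perturbation SD in mm (0 returns the template unchanged)
#' @param seed integer seed; identical seeds give bit-identical output
#' @param cloud_factor cloud density as a multiple of the surface node count
#' @param lattice_dims perturbation lattice cell counts
#' @return list with `mesh` (warped), `cloud` (n x 3), `lattice`
#' @export
generate_subject_shape <- function(template, warp_scale, seed,
                                   cloud_factor = 10,
                                   lattice_dims = c(2L, 2L, 2L)) {
  stopifnot(inherits(template, "hex_mesh"), warp_scale >= 0)
  lattice <- build_host_lattice(template$nodes, lattice_dims,
                                default_lattice_margin(template$nodes))
  ncp <- nrow(lattice$control_points)
  surf <- template$surface_nodes
  faces <- boundary_faces(template)
  per_face <- ceiling(cloud_factor * length(surf) / nrow(faces))
  n_cloud <- per_face * nrow(faces)
  rand <- withr::with_seed(seed, list(
    pert = matrix(rnorm(ncp * 3, 0, warp_scale), ncp, 3),
    ab = matrix(runif(2 * n_cloud), ncol = 2)))
  lattice$control_points <- lattice$control_points + rand$pert

  emb_nodes <- embed_points(lattice, template$nodes)
  warped_nodes <- evaluate_lattice(lattice, emb_nodes)
  mesh <- hex_mesh(warped_nodes, template$elements, fields = template$fields,
                   structure = template$structure,
                   surface_nodes = surf, validate = FALSE)

  fi <- rep(seq_len(nrow(faces)), each = per_face)
  a <- rand$ab[, 1]; b <- rand$ab[, 2]
  c1 <- template$nodes[faces[fi, 1], , drop = FALSE]
  c2 <- template$nodes[faces[fi, 2], , drop = FALSE]
  c3 <- template$nodes[faces[fi, 3], , drop = FALSE]
  c4 <- template$nodes[faces[fi, 4], , drop = FALSE]
  pts <- (1 - a) * (1 - b) * c1 + a * (1 - b) * c2 + a * b * c3 + (1 - a) * b * c4
  cloud <- evaluate_lattice(lattice, embed_points(lattice, pts))
  list(mesh = mesh, cloud = cloud, lattice = lattice)
}

# boundary faces (corner cycles) via the same multiplicity scan as
# extract_surface_nodes
boundary_faces <- function(mesh) {
  el <- mesh$elements
  faces <- do.call(rbind, lapply(seq_len(6), function(f)
    el[, HEX_FACES[f, ], drop = FALSE]))
  key <- face_keys(faces)
  o <- order(key[, 1], key[, 2], key[, 3], key[, 4])
  k <- key[o, , drop = FALSE]
  nf <- nrow(k)
  same_next <- c(rowSums(k[-nf, , drop = FALSE] == k[-1, , drop = FALSE]) == 4, FALSE)
  same_prev <- c(FALSE, same_next[-nf])
  faces[o[!(same_next | same_prev)], , drop = FALSE]
}

fa_baseline <- function(U, V, pars) {
  r <- sqrt(((2 * U - 1)^2 + (2 * V - 1)^2) / 2)
  pars["core"] + (pars["rim"] - pars["core"]) * r
}

#' Generate the four metric volumes for one subject
#'
#' Rasterizes the warped mesh onto an axis-aligned voxel grid (a voxel is
#' in-mask iff its centre lies inside an element, by trilinear inversion);
#' masked voxel value = smooth baseline(material coordinates) + per-subject
#' intercept + group effect (case voxels with axial station in the effect
#' region, affected metrics only) + seeded Gaussian noise. FA is clamped to
#' the unit interval.
#'
#' @param mesh warped `hex_mesh` carrying template structure info
#' @param group "case" or "control"
#' @param effect an `effect_spec`
#' @param config a `sim_config`
#' @param seed integer seed for intercepts and noise
#' @return named list of four `scalar_volume`s
#' @export
generate_metric_volumes <- function(mesh, group = c("case", "control"),
                                    effect = effect_spec(),
                                    config = sim_config(), seed = 1L) {
  group <- match.arg(group)
  vx <- config$voxel_size
  lo <- apply(mesh$nodes, 2, min); hi <- apply(mesh$nodes, 2, max)
  origin <- lo - vx
  dims <- as.integer(ceiling((hi - origin) / vx)) + 2L
  ras <- cpp_rasterize(mesh$nodes, mesh$elements, origin, rep(vx, 3), dims)
  inside <- which(ras$element > 0)
  if (length(inside) < 100)
    stop(sprintf("voxel grid too coarse: only %d masked voxels (need >= 100)",
                 length(inside)))
  st <- mesh$structure
  if (is.null(st)) stop("mesh carries no structured-template layout information")
  e0 <- ras$element[inside] - 1L
  i <- e0 %% st$n_u; j <- (e0 %/% st$n_u) %% st$n_v; k <- e0 %/% (st$n_u * st$n_v)
  U <- (i + ras$u[inside]) / st$n_u
  V <- (j + ras$v[inside]) / st$n_v
  W <- (k + ras$w[inside]) / st$n_w
  in_region <- W >= effect$region[1] & W <= effect$region[2]

  affine <- rbind(cbind(diag(rep(vx, 3)), origin), c(0, 0, 0, 1))
  maskarr <- array(ras$element > 0, dim = dims)
  nmask <- length(inside)
  rand <- withr::with_seed(seed, list(
    intercept = rnorm(4, 0, config$subject_intercept_sd[METRICS]),
    noise = matrix(rnorm(4 * nmask), nmask, 4) *
      rep(config$noise_sd[METRICS], each = nmask)))
  names(rand$intercept) <- METRICS

  vols <- list()
  for (mi in seq_along(METRICS)) {
    m <- METRICS[mi]
    base <- if (m == "FA") fa_baseline(U, V, config$baselines$FA)
            else rep(config$baselines[[m]], nmask)
    vals <- base + rand$intercept[m] + rand$noise[, mi]
    if (group == "case" && m %in% effect$affected_metrics)
      vals <- vals + effect$delta[m] * in_region
    if (m == "FA") vals <- pmin(pmax(vals, 0), 1)
    data <- array(0, dim = dims)
    data[inside] <- vals
    vols[[m]] <- scalar_volume(data, affine, m, maskarr)
  }
  vols
}

#' Generate a full synthetic study bundle
#'
#' Per subject: a surface cloud (warped template) and four metric volumes;
#' plus the groups table and the ground truth. Reproducible from (config,
#' effect): every subject and stage reseeds from the master seed.
#'
#' @param config a `sim_config`
#' @param effect an `effect_spec`
#' @param template template `hex_mesh` (default: the full 20 480-element
#'   template; pass a coarser one for desk-scale experiments)
#' @param out_dir optional directory; when given, writes XYZ clouds, NIfTI
#'   volumes, `groups.csv` and `truth.json` and errors if the directory
#'   already contains files
#' @param group_warp_scales optional named vector overriding the shape warp
#'   scale per group (used to construct shape/metric dissociation studies)
#' @return invisibly, the in-memory bundle: `subjects` (list with `id`,
#'   `group`, `cloud`, `volumes`), `template`, `truth_mask`, `groups`,
#'   `config`, `effect`
#' @export
generate_cohort <- function(config = sim_config(), effect = effect_spec(),
                            template = NULL, out_dir = NULL,
                            group_warp_scales = NULL) {
  template <- template %||% build_template_tract_mesh(template_config())
  if (!is.null(out_dir)) {
    if (dir.exists(out_dir) && length(list.files(out_dir)))
      stop(sprintf("output directory '%s' already contains files", out_dir))
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  }
  groups <- c(rep("case", config$n_case), rep("control", config$n_control))
  ids <- c(sprintf("case%02d", seq_len(config$n_case)),
           sprintf("control%02d", seq_len(config$n_control)))
  subjects <- vector("list", length(ids))
  for (s in seq_along(ids)) {
    seed_s <- derive_seed(config$seed, s)
    ws <- if (!is.null(group_warp_scales)) group_warp_scales[[groups[s]]]
          else config$shape_warp_scale
    shp <- generate_subject_shape(template, ws, seed = derive_seed(seed_s, 1))
    vols <- generate_metric_volumes(shp$mesh, groups[s], effect, config,
                                    seed = derive_seed(seed_s, 2))
    subjects[[s]] <- list(id = ids[s], group = groups[s], cloud = shp$cloud,
                          mesh = shp$mesh, volumes = vols)
    if (!is.null(out_dir)) {
      write_xyz(shp$cloud, file.path(out_dir, paste0(ids[s], "_cloud.xyz")))
      for (m in METRICS)
        write_nifti(vols[[m]]$data, vols[[m]]$affine,
                    file.path(out_dir, sprintf("%s_%s.nii.gz", ids[s], m)))
    }
  }
  truth_mask <- element_truth_mask(template, effect)
  groups_df <- data.frame(subject_id = ids, group = groups)
  if (!is.null(out_dir)) {
    write.csv(groups_df, file.path(out_dir, "groups.csv"), row.names = FALSE)
    jsonlite::write_json(
      list(effect = list(affected_metrics = effect$affected_metrics,
                         region = effect$region,
                         delta = as.list(effect$delta)),
           truth_mask = truth_mask,
           seed = config$seed,
           subject_seeds = vapply(seq_along(ids), function(s)
             derive_seed(config$seed, s), 1L)),
      file.path(out_dir, "truth.json"), auto_unbox = TRUE, digits = NA)
  }
  invisible(list(subjects = subjects, template = template,
                 truth_mask = truth_mask, groups = groups_df,
                 config = config, effect = effect, out_dir = out_dir))
}

#' Morph the template to every subject and embed its metric volumes
#'
#' Convenience pipeline driver used by the cohort analyses: for each subject
#' in a bundle, fit the template to the cloud and assign metric fields.
#'
#' @param bundle a `generate_cohort` result
#' @param lattice_dims,params passed to [fit_to_point_cloud()]
#' @param max_dist passed to [assign_fields()]
#' @return list of `subject_model`s
#' @export
morph_and_embed_cohort <- function(bundle, lattice_dims = c(4L, 4L, 4L),
                                   params = fit_params(), max_dist = NULL) {
  lapply(bundle$subjects, function(s) {
    fit <- fit_to_point_cloud(bundle$template, s$cloud, lattice_dims, params)
    assign_fields(fit$mesh, s$volumes, max_dist = max_dist,
                  subject_id = s$id, group_label = s$group)
  })
}
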