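test_that("host lattice construction: box, control points, degenerate input", {
  cube <- as.matrix(expand.grid(0:1, 0:1, 0:1))
  lat <- build_host_lattice(cube, c(1, 1, 1), margin = 0.5)
  expect_equal(lat$origin, c(-0.5, -0.5, -0.5), ignore_attr = TRUE)
  expect_equal(lat$spacing, c(2, 2, 2), ignore_attr = TRUE)
  expect_identical(nrow(lat$control_points), 8L)
  expect_equal(range(lat$control_points), c(-0.5, 1.5))

  tpl <- small_template()
  lat4 <- build_host_lattice(tpl$nodes, c(4, 4, 4),
                             tractmorph:::default_lattice_margin(tpl$nodes))
  expect_identical(nrow(lat4$control_points), 125L)
  t <- sweep(sweep(tpl$nodes, 2, lat4$origin), 2, lat4$spacing, `/`)
  expect_true(all(t > 0) && all(sweep(t, 2, lat4$dims) < 0))  # strictly inside

  single <- build_host_lattice(matrix(c(1, 2, 3), 1), c(2, 2, 2), margin = 1)
  expect_true(all(single$spacing > 0))
  expect_error(build_host_lattice(matrix(0, 0, 3), c(1, 1, 1), 1), "empty")
  expect_error(build_host_lattice(cube, c(1, 1, 1), margin = 0), "margin")
})

test_that("embedding: corner/centre coordinates and round-trip identity", {
  lat <- build_host_lattice(matrix(runif(30), 10, 3) * 10, c(3, 2, 4), margin = 1)
  corner <- lat$origin + c(2, 1, 3) * lat$spacing   # min corner of cell (2,1,3)
  e <- embed_points(lat, rbind(corner))
  expect_equal(e$cell[1, ], c(2L, 1L, 3L), ignore_attr = TRUE)
  expect_equal(e$uvw[1, ], c(0, 0, 0), ignore_attr = TRUE)

  centre <- lat$origin + c(0.5, 0.5, 0.5) * lat$spacing
  ec <- embed_points(lat, rbind(centre))
  expect_equal(ec$uvw[1, ], c(0.5, 0.5, 0.5), ignore_attr = TRUE)

  withr::with_seed(8, {
    pts <- sweep(sweep(matrix(runif(300), 100, 3), 2, lat$dims, `*`), 2,
                 lat$spacing, `*`)
    pts <- sweep(pts, 2, lat$origin, `+`)
  })
  back <- evaluate_lattice(lat, embed_points(lat, pts))
  expect_lt(max(abs(back - pts)), 1e-9)

  far <- rbind(lat$origin - 5 * lat$spacing)
  expect_error(embed_points(lat, far), "outside")
})

test_that("lattice evaluation has identity, translation and affine precision", {
  withr::with_seed(9, {
    pts <- matrix(runif(300, -2, 7), 100, 3)
    A <- matrix(rnorm(9, sd = 0.4), 3, 3) + diag(3)
    b <- rnorm(3)
  })
  lat <- build_host_lattice(pts, c(3, 3, 3), margin = 1)
  emb <- embed_points(lat, pts)
  expect_lt(max(abs(evaluate_lattice(lat, emb) - pts)), 1e-9)

  latT <- lat
  latT$control_points <- sweep(lat$control_points, 2, c(1, 2, 3), `+`)
  expect_lt(max(abs(evaluate_lattice(latT, emb) - sweep(pts, 2, c(1, 2, 3), `+`))),
            1e-9)

  latA <- lat
  latA$control_points <- sweep(lat$control_points %*% t(A), 2, b, `+`)
  expect_lt(max(abs(evaluate_lattice(latA, emb) - sweep(pts %*% t(A), 2, b, `+`))),
            1e-9)
})

test_that("grid-indexed nearest neighbour is exactly brute force, ties included", {
  withr::with_seed(21, {
    ref <- matrix(runif(3 * 2000, 0, 10), ncol = 3)
    q <- matrix(runif(150, -1, 11), 50, 3)
  })
  got <- nearest_neighbour(q, ref)
  want <- nn_oracle(q, ref)
  expect_identical(got$index, want$index)
  expect_equal(got$distance, want$distance)

  # exact ties on an integer grid; smallest reference index must win
  ref2 <- as.matrix(expand.grid(x = 0:9, y = 0:9, z = 0:9))  # 1000 pts > grid cutoff
  storage.mode(ref2) <- "double"
  q2 <- as.matrix(expand.grid(x = c(0.5, 2.5), y = c(0.5, 4.5), z = c(1.5, 3.5)))
  got2 <- nearest_neighbour(q2, ref2)
  want2 <- nn_oracle(q2, ref2)
  expect_identical(got2$index, want2$index)
})

test_that("rms_error: zero on exact surface, exact for constant offsets, oracle", {
  tpl <- small_template()
  surf <- tpl$nodes[tpl$surface_nodes, ]
  expect_equal(rms_error(tpl, surf), 0)
  # constant 1 mm offset: exact when node spacing exceeds the offset, so a
  # node's own translate is its nearest cloud point
  coarse <- box_mesh(2, 2, 2, spacing = c(3, 3, 3))
  csurf <- coarse$nodes[coarse$surface_nodes, ]
  expect_equal(rms_error(coarse, sweep(csurf, 2, c(1, 0, 0), `+`)), 1.0,
               tolerance = 1e-12)
  withr::with_seed(4, cloud <- matrix(rnorm(90, sd = 20), 30, 3))
  want <- sqrt(mean(nn_oracle(surf, cloud)$distance^2))
  expect_equal(rms_error(tpl, cloud), want)
  expect_error(rms_error(tpl, matrix(0, 0, 3)), "empty")
})

test_that("fitting: self-fit is the identity, rigid translations are exact", {
  tpl <- small_template()
  surf <- tpl$nodes[tpl$surface_nodes, ]
  fit0 <- fit_to_point_cloud(tpl, surf)
  expect_lt(fit0$rmse, 1e-6)
  expect_lt(max(abs(fit0$mesh$nodes - tpl$nodes)), 1e-6)

  # modest shift (inside the nearest-point correspondence basin of a tube)
  shift <- c(1.2, -0.8, 1.0)
  fitT <- fit_to_point_cloud(tpl, sweep(surf, 2, shift, `+`))
  expect_lt(fitT$rmse, 1e-6)
  # affine precision: morphed mesh equals the directly translated template
  expect_lt(max(abs(fitT$mesh$nodes - sweep(tpl$nodes, 2, shift, `+`))), 1e-5)
  expect_identical(fitT$mesh$elements, tpl$elements)
  expect_error(fit_to_point_cloud(tpl, surf[1:5, ]), "at least 10")
})

test_that("fitting a warped subject: sub-mm RMSE, monotone objective, FFD transfer", {
  tpl <- small_template()
  shp <- generate_subject_shape(tpl, warp_scale = 2, seed = 31)
  fit <- fit_to_point_cloud(tpl, shp$cloud)
  expect_lt(fit$rmse, 1)                       # reported fit-quality bound
  expect_true(all(diff(fit$objective) <= 1e-8 * abs(fit$objective[1])))
  expect_identical(fit$mesh$elements, tpl$elements)
  expect_identical(nrow(fit$mesh$nodes), nrow(tpl$nodes))
  # relative-position preservation: every node (internal included) is the
  # lattice image of its material coordinates
  img <- evaluate_lattice(fit$lattice, fit$embedding)
  expect_lt(max(abs(img - fit$mesh$nodes)), 1e-9)
})

test_that("fit diagnostics and parameter validation", {
  expect_error(fit_params(smoothing_weight = -1), "smoothing_weight")
  expect_error(fit_params(rmse_tol = 0), "rmse_tol")
  p <- fit_params(smoothing_weight = 0.5, max_outer_iters = 5)
  f <- withr::local_tempfile(fileext = ".yaml")
  yaml::write_yaml(list(smoothing_weight = 0.5, max_outer_iters = 5), f)
  p2 <- read_fit_params(f)
  expect_equal(p2$smoothing_weight, 0.5)
  expect_equal(p2$max_outer_iters, 5L)
  expect_equal(p2$rmse_tol, 1e-3)

  # symmetric correspondence mode also converges on a warped subject
  tpl <- small_template()
  shp <- generate_subject_shape(tpl, warp_scale = 1, seed = 5)
  fs <- fit_to_point_cloud(tpl, shp$cloud,
                           params = fit_params(correspondence_mode = "symmetric",
                                               max_outer_iters = 10))
  expect_lt(fs$rmse, 1)
  expect_true(all(diff(fs$objective) <= 1e-8 * abs(fs$objective[1])))
})
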