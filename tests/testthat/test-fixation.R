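test_that("plate specs enforce the geometric invariants", {
  expect_error(plate_spec(thickness = 2.0), "thickness")
  expect_error(plate_spec(n_holes = 3), "even")
  expect_error(plate_spec(hole_pitch = 1.0), "overlap")
  sp <- plate_spec(n_holes = 4, center_space = 2.2, hole_pitch = 2.5)
  expect_equal(sp$holes, c(-4.85, -2.35, 2.35, 4.85))
})

test_that("device mesh respects plate thickness and screw count", {
  sp1 <- plate_spec(n_holes = 4, thickness = 1.0)
  d1 <- build_device_mesh(sp1)
  pn <- unique(as.vector(d1$elems[d1$region == "plate", ]))
  bb <- range(d1$nodes[pn, 3])
  expect_equal(bb, c(0, 1.0), tolerance = 1e-9)
  expect_equal(length(unique(d1$screw_id[d1$screw_id > 0])), 4)
  # extrusion scaling: 1.5 mm plate has 1.5x the plate volume
  d15 <- build_device_mesh(plate_spec(n_holes = 4, thickness = 1.5))
  v1 <- sum(mandifix:::.tet_volumes(d1$nodes, d1$elems)[d1$region == "plate"])
  v15 <- sum(mandifix:::.tet_volumes(d15$nodes, d15$elems)[d15$region == "plate"])
  expect_lt(abs(v15 / v1 - 1.5), 0.075)
  # 2-hole center-space plate carries exactly 2 screws
  d2 <- build_device_mesh(plate_spec(n_holes = 2, center_space = 2.2,
                                     hole_pitch = 2.5, edge_margin = 1.0))
  expect_equal(length(unique(d2$screw_id[d2$screw_id > 0])), 2)
})

scenario_counts <- list(symphysis = c(plates = 2, screws = 8),
                        body = c(plates = 2, screws = 8),
                        angle = c(plates = 1, screws = 6),
                        condylar_neck = c(plates = 2, screws = 6))

test_that("scenario fixation reproduces the per-site plate configuration", {
  m <- coarse_mandible()
  for (site in names(scenario_counts)) {
    pl <- scenario_fixation(site, 1.0, m$geom)
    expect_length(pl, scenario_counts[[site]][["plates"]])
    expect_equal(sum(vapply(pl, function(p) p$spec$n_holes, 1)),
                 scenario_counts[[site]][["screws"]])
    if (site == "condylar_neck")
      expect_true(all(vapply(pl, function(p) p$spec$center_space > 0, TRUE)))
  }
})

test_that("device placement merges cleanly and screw axes are thickness-invariant", {
  m <- coarse_mandible()
  fr <- insert_fracture(m, fracture_spec("body"))
  m1 <- place_devices(fr, 1.0)
  m15 <- place_devices(fr, 1.5)
  expect_true(all(c("plate", "screw") %in% m1$region))
  expect_true(mesh_quality(m1)$all_positive)
  axes <- function(mm) {
    out <- NULL
    for (dn in names(mm$devices)) {
      d <- mm$devices[[dn]]
      ids <- d$node_offset + seq_len(d$n_nodes)
      scr <- d$meta$screw_id
      for (k in sort(unique(scr[scr > 0]))) {
        sel <- ids[scr == k & d$kind == "screw"]
        out <- rbind(out, colMeans(mm$node_param[sel, c(1, 3), drop = FALSE]))
      }
    }
    out[order(out[, 1], out[, 2]), , drop = FALSE]
  }
  expect_lt(max(abs(axes(m1) - axes(m15))), 1e-6)
})

test_that("tie constraints interpolate slave positions and sum to one", {
  m <- coarse_mandible()
  fr <- insert_fracture(m, fracture_spec("body"))
  merged <- place_devices(fr, 1.0)
  ties <- build_ties(merged)
  expect_gt(length(ties$slave), 0)
  expect_lt(max(abs(rowSums(ties$weights) - 1)), 1e-9)
  expect_false(any(ties$slave %in% as.vector(ties$master_nodes)))
  # volumetric constraints reproduce the slave coordinates exactly
  # (quadratic shape functions are linearly complete on straight elements)
  interp <- matrix(0, length(ties$slave), 3)
  for (d in 1:3) {
    xm <- matrix(merged$nodes[ties$master_nodes, d], nrow(ties$weights), 10)
    interp[, d] <- rowSums(ties$weights * xm)
  }
  err <- sqrt(rowSums((interp - merged$nodes[ties$slave, ])^2))
  emb <- merged$node_param[ties$slave, 2] < m$geom$W / 2 - 1e-9
  expect_lt(max(err[emb]), 1e-8)
  # projection ties stay within the declared tolerance
  expect_lt(max(err[!emb]), 0.8)
})

test_that("barycentric interpolation weights reproduce points in a tet", {
  X4 <- rbind(c(0, 0, 0), c(2, 0.2, 0), c(0.1, 1.8, 0.1), c(0.3, 0.1, 2.2))
  X10 <- tet10_from_vertices(X4)
  set.seed(5)
  for (i in 1:10) {
    lam <- stats::runif(4); lam <- lam / sum(lam)
    p <- colSums(lam * X4)
    lamb <- mandifix:::.tet_bary(X4, p)
    expect_equal(lamb, lam, tolerance = 1e-10)
    w <- mandifix:::fk_shape_functions(lamb)
    expect_equal(sum(w), 1, tolerance = 1e-12)
    expect_equal(colSums(as.vector(w) * X10), p, tolerance = 1e-8)
  }
  # coincident with a vertex: single unit weight
  w <- mandifix:::fk_shape_functions(c(1, 0, 0, 0))
  expect_equal(as.vector(w), c(1, rep(0, 9)))
})

test_that("ties transmit rigid-body translation without internal force", {
  m <- coarse_mandible()
  fr <- insert_fracture(m, fracture_spec("angle"))
  merged <- place_devices(fr, 1.0)
  ties <- build_ties(merged)
  mats <- assign_materials(merged, "WE43", material_cards())
  lc <- manual_load(merged)
  sys <- assemble_system(merged, mats, lc, ties)
  n_red <- length(sys$f)
  tvec <- rep(c(1, 2, -3), n_red / 3)
  force <- as.vector(sys$K %*% tvec)
  expect_lt(max(abs(force)), 1e-6 * max(abs(sys$K)))
})

test_that("devices that would exit the bone are rejected", {
  m <- coarse_mandible()
  fr <- insert_fracture(m, fracture_spec("body"))
  long <- scenario_fixation("body", 1.0, m$geom)
  long[[1]]$spec$screw_length <- 10
  expect_error(place_devices(fr, 1.0, placements = long), "exits the bone")
})
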