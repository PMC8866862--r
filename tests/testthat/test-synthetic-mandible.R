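test_that("coarse mandible carries all bone labels and non-empty named sets", {
  m <- coarse_mandible()
  expect_setequal(unique(m$region),
                  c("symphysis", "body", "angle", "ramus", "condyle",
                    "coronoid_process", "trabecular", "teeth"))
  expect_true(all(vapply(m$face_sets, length, 1L) > 0))
  expect_true(all(vapply(m$node_sets, length, 1L) > 0))
  expect_equal(length(m$face_sets), 15L) # 7 muscles x 2 sides + occlusal
  q <- mesh_quality(m)
  expect_true(q$all_positive)
  expect_gt(q$min_scaled_jacobian, 0.05)
})

test_that("mesh is conforming with midside nodes at edge midpoints", {
  m <- coarse_mandible()
  el <- m$elems
  # every face occurs once (boundary) or twice (interior) with the same
  # corner node triple
  tri <- rbind(el[, 1:3], el[, c(1, 2, 4)], el[, c(2, 3, 4)], el[, c(1, 3, 4)])
  lo <- pmin(tri[, 1], tri[, 2], tri[, 3])
  hi <- pmax(tri[, 1], tri[, 2], tri[, 3])
  md <- tri[, 1] + tri[, 2] + tri[, 3] - lo - hi
  key <- paste(lo, md, hi)
  expect_true(all(table(key) <= 2))
  # straight quadratic edges
  mid5 <- (m$nodes[el[, 1], ] + m$nodes[el[, 2], ]) / 2
  expect_lt(max(abs(m$nodes[el[, 5], ] - mid5)), 1e-12)
  mid10 <- (m$nodes[el[, 3], ] + m$nodes[el[, 4], ]) / 2
  expect_lt(max(abs(m$nodes[el[, 10], ] - mid10)), 1e-12)
})

test_that("cortical volume matches the closed-form swept-shell oracle", {
  m <- coarse_mandible()
  p <- m$params; g <- m$geom
  A_cort <- g$W * g$H - (g$W - 2 * g$cort) * (g$H - 2 * g$cort)
  k2 <- 1 + (g$flare - 1) + (g$flare - 1)^2 / 3    # mean of k(s)^2 over head
  len_eff <- g$A + 2 * (g$rb * pi / 2 + g$Lram + g$Lneck + g$Lhead * k2)
  oracle <- A_cort * len_eff
  vols <- region_volumes(m)
  cort <- sum(vols[c("symphysis", "body", "angle", "ramus", "condyle",
                     "coronoid_process")])
  expect_lt(abs(cort - oracle) / oracle, 0.10)
  # teeth block: core-width ridge along the tooth row
  teeth_oracle <- (g$W - 2 * g$cort) * g$tooth_h * 2 * g$t_tooth
  expect_lt(abs(vols[["teeth"]] - teeth_oracle) / teeth_oracle, 0.10)
})

test_that("generator is deterministic", {
  m1 <- build_mandible(coarse_params())
  m2 <- build_mandible(coarse_params())
  expect_identical(m1$nodes, m2$nodes)
  expect_identical(m1$elems, m2$elems)
  expect_identical(m1$region, m2$region)
})

test_that("refinement at least doubles elements and keeps region fractions", {
  m2 <- coarse_mandible()
  m1 <- default_mandible()   # half the edge length
  expect_gt(nrow(m1$elems), 2 * nrow(m2$elems))
  f2 <- region_volumes(m2) / sum(region_volumes(m2))
  f1 <- region_volumes(m1) / sum(region_volumes(m1))
  expect_lt(max(abs(f1[names(f2)] - f2)), 0.05)
})

test_that("mesh is mirror-symmetric about the mid-sagittal plane", {
  m <- coarse_mandible()
  nv <- m$n_vertex
  nd <- m$nodes[seq_len(nv), , drop = FALSE]
  key <- paste(signif(nd[, 1], 10), signif(nd[, 2], 10), signif(nd[, 3], 10))
  mir <- paste(signif(-nd[, 1], 10), signif(nd[, 2], 10), signif(nd[, 3], 10))
  expect_true(all(mir %in% key))   # vertices mirror exactly
  # quadratic nodes mirror up to the meshing tolerance (cell-diagonal
  # orientation is translation- but not mirror-invariant on curved segments)
  h <- m$params$target_edge_length
  mids <- m$nodes[-seq_len(nv), , drop = FALSE]
  set.seed(1)
  idx <- sample(nrow(mids), 300)
  dev <- vapply(idx, function(i) {
    d2 <- (m$nodes[, 1] + mids[i, 1])^2 + (m$nodes[, 2] - mids[i, 2])^2 +
      (m$nodes[, 3] - mids[i, 3])^2
    sqrt(min(d2))
  }, numeric(1))
  expect_lt(max(dev), 0.25 * h)
})

test_that("degenerate geometry parameters are rejected", {
  expect_error(mandible_params(bend_radius = 2), "bend_radius")
  expect_error(mandible_params(cortical_thickness = 3), "cortical_thickness")
  expect_error(mandible_params(target_edge_length = -1), "positive")
})

test_that("fracture insertion labels the gap slab as granulation", {
  m <- coarse_mandible()
  fr <- insert_fracture(m, fracture_spec("body", 1.2))
  hs <- fr$elem_sets$healing_region
  expect_gt(length(hs), 0)
  expect_true(all(fr$region[hs] == "granulation"))
  expect_true(all(which(fr$region == "granulation") %in% hs))
  # slab thickness along the axis equals the gap width up to one edge length
  s <- fr$elem_param[hs, 1]
  h <- m$params$target_edge_length
  expect_lte(diff(range(s)), 1.2 / 2 + h)
  # idempotence
  fr2 <- insert_fracture(fr, fracture_spec("body", 1.2))
  expect_identical(fr$region, fr2$region)
  expect_error(insert_fracture(fr, fracture_spec("angle")), "different")
})

test_that("fracture gap width outside the validity range is rejected", {
  expect_error(fracture_spec("body", 0), "gap_width")
  expect_error(fracture_spec("body", 2.5), "gap_width")
})

test_that("condylar neck fracture sits on the neck segment of the axis", {
  m <- coarse_mandible()
  fr <- insert_fracture(m, fracture_spec("condylar_neck"))
  s <- mean(fr$elem_param[fr$elem_sets$healing_region, 1])
  g <- m$geom
  expect_gt(s, g$s3)
  expect_lt(s, g$s4)
})
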