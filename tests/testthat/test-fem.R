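test_that("element stiffness matches an independent 11-point quadrature", {
  X4 <- rbind(c(0, 0, 0), c(1.2, 0.1, 0), c(0.2, 1.1, -0.1),
              c(0.1, 0.2, 1.3))
  X10 <- tet10_from_vertices(X4)
  for (card in list(iso_card(), material_cards()$symphysis)) {
    C <- stiffness_voigt(card)
    K <- mandifix:::fk_elem_stiffness(X10, C)
    Ko <- keast11_stiffness(X10, C)
    expect_lt(max(abs(K - Ko)) / max(abs(Ko)), 1e-8)
    expect_lt(max(abs(K - t(K))) / max(abs(K)), 1e-12)
  }
})

test_that("an unconstrained element has exactly six rigid-body modes", {
  X10 <- tet10_from_vertices(rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0),
                                   c(0, 0, 1)))
  K <- mandifix:::fk_elem_stiffness(X10, stiffness_voigt(iso_card()))
  ev <- eigen(K, symmetric = TRUE, only.values = TRUE)$values
  expect_lt(max(abs(ev[25:30])) / ev[1], 1e-12)
  expect_gt(ev[24] / ev[1], 1e-8)
})

test_that("patch test: quadratic elements reproduce linear fields exactly", {
  for (card in material_cards())
    expect_lt(patch_test_strain(card), 1e-10)
})

test_that("slender cantilever matches Euler-Bernoulli beam theory within 2%", {
  mesh <- block_mesh(20, 2, 2, h = 0.5)   # 10 x 1 x 1 mm beam
  E <- 1200
  card <- material_card("beam", E, nu12 = 0.001, isotropic = TRUE)
  xyz <- mesh$node_param
  root <- which(abs(xyz[, 1]) < 1e-12)
  fd <- as.vector(rbind(3 * (root - 1) + 1, 3 * (root - 1) + 2,
                        3 * (root - 1) + 3))
  tipfaces <- which(apply(mesh$faces[, 2:4], 1,
                          function(nn) all(abs(xyz[nn, 1] - 10) < 1e-12)))
  P <- 1
  d <- distribute_on_patch(mesh, tipfaces, c(0, 0, -P))
  F <- matrix(0, nrow(mesh$nodes), 3)
  F[d$node, ] <- as.matrix(d[, 2:4])
  sys <- assemble_system(mesh, uniform_Cm(mesh, card),
                         manual_load(mesh, F, fixed_dofs = fd))
  sol <- solve_system(sys)
  tipnodes <- which(abs(xyz[, 1] - 10) < 1e-12)
  tip <- mean(sol$u[tipnodes, 3])
  delta <- P * 10^3 / (3 * E * (1 / 12))
  expect_lt(abs(-tip - delta) / delta, 0.02)
  # strain energy consistency: 0.5 f'u equals the integrated energy density
  en <- strain_energy(sol)
  en2 <- 0.5 * sum(sol$weight * rowSums(sol$strain * sol$stress))
  expect_lt(abs(en - en2) / en, 1e-8)
  # linearity: doubling all moduli halves the displacements
  card2 <- material_card("beam2", 2 * E, nu12 = 0.001, isotropic = TRUE)
  sys2 <- assemble_system(mesh, uniform_Cm(mesh, card2),
                          manual_load(mesh, F, fixed_dofs = fd))
  sol2 <- solve_system(sys2)
  expect_equal(sol2$u, sol$u / 2, tolerance = 1e-9)
})

test_that("simplified masseter load is balanced by the restraints", {
  m <- coarse_mandible()
  mats <- assign_materials(m, cards = material_cards())
  lc <- build_load_case(m, convergence_mode = TRUE)
  sol <- solve_system(assemble_system(m, mats, lc))
  re <- reaction_forces(sol)
  expect_equal(re$total, c(0, 50, -50), tolerance = 1e-6, ignore_attr = TRUE)
  resid <- re$total + applied_resultant(sol$system)
  expect_lt(max(abs(resid)), 1e-6)
})

test_that("a symmetric load on the symmetric mesh gives a symmetric field", {
  m <- coarse_mandible()
  mats <- assign_materials(m, cards = material_cards())
  F <- matrix(0, nrow(m$nodes), 3)
  for (p in c("SM_right", "SM_left")) {
    d <- distribute_on_patch(m, p, c(0, 0, 10))
    F[d$node, ] <- F[d$node, ] + as.matrix(d[, 2:4])
  }
  cnd <- c(m$node_sets$condyle_left, m$node_sets$condyle_right)
  fd <- as.vector(rbind(3 * (cnd - 1) + 1, 3 * (cnd - 1) + 2,
                        3 * (cnd - 1) + 3))
  sol <- solve_system(assemble_system(m, mats, manual_load(m, F, fd)))
  nv <- m$n_vertex
  nd <- m$nodes[seq_len(nv), ]
  key <- paste(signif(nd[, 1], 9), signif(nd[, 2], 9), signif(nd[, 3], 9))
  mir <- match(paste(signif(-nd[, 1], 9), signif(nd[, 2], 9),
                     signif(nd[, 3], 9)), key)
  u <- sol$u[seq_len(nv), ]
  scale <- max(abs(u))
  expect_lt(max(abs(u[, 1] + u[mir, 1])) / scale, 0.02)
  expect_lt(max(abs(u[, 2] - u[mir, 2])) / scale, 0.02)
  expect_lt(max(abs(u[, 3] - u[mir, 3])) / scale, 0.02)
})

test_that("insufficient restraints raise a singular-system error", {
  mesh <- block_mesh(2, 1, 1, h = 1)
  sys <- assemble_system(mesh, uniform_Cm(mesh, iso_card()),
                         manual_load(mesh, fixed_dofs = c(1L, 2L, 3L)))
  expect_error(solve_system(sys), "singular|indefinite|converge")
})
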