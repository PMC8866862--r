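# Shared fixtures. Coarse meshes (2 mm lattice) keep the unit suite fast;
# objects are built once per test run and cached in this environment.
.fx <- new.env(parent = emptyenv())

coarse_params <- function(h = 2.0) mandible_params(target_edge_length = h)

coarse_mandible <- function() {
  if (is.null(.fx$mesh2)) .fx$mesh2 <- build_mandible(coarse_params())
  .fx$mesh2
}

default_mandible <- function() {
  if (is.null(.fx$mesh1)) .fx$mesh1 <- build_mandible(mandible_params())
  .fx$mesh1
}

material_cards <- function() {
  if (is.null(.fx$cards)) .fx$cards <- load_material_table()
  .fx$cards
}

muscle_table <- function() {
  if (is.null(.fx$muscles)) .fx$muscles <- load_muscle_table()
  .fx$muscles
}

iso_card <- function(E = 15000, nu = 0.3)
  material_card("iso_test", E, nu12 = nu, isotropic = TRUE)

# Independent pure-R TET10 element stiffness with the Keast 11-point
# degree-4 rule; used as quadrature oracle against the C++ kernel.
keast11_stiffness <- function(X10, C) {
  X4 <- X10[1:4, , drop = FALSE]
  w <- c(-0.0131555555555556, rep(0.00762222222222222, 4),
         rep(0.0248888888888889, 6))
  a <- 1 / 14; b <- 11 / 14
  gp <- (1 + sqrt(5 / 14)) / 4; dp <- (1 - sqrt(5 / 14)) / 4
  pts <- rbind(rep(0.25, 4),
               c(b, a, a, a), c(a, b, a, a), c(a, a, b, a), c(a, a, a, b),
               c(gp, gp, dp, dp), c(gp, dp, gp, dp), c(gp, dp, dp, gp),
               c(dp, gp, gp, dp), c(dp, gp, dp, gp), c(dp, dp, gp, gp))
  J <- rbind(X4[1, ] - X4[4, ], X4[2, ] - X4[4, ], X4[3, ] - X4[4, ])
  detJ <- -det(J)
  Ji <- solve(J)
  gL <- rbind(t(Ji), -colSums(t(Ji)))
  ed <- rbind(c(1, 2), c(2, 3), c(3, 1), c(1, 4), c(2, 4), c(3, 4))
  K <- matrix(0, 30, 30)
  for (q in seq_along(w)) {
    lam <- pts[q, ]
    dn <- matrix(0, 10, 4)
    for (i in 1:4) dn[i, i] <- 4 * lam[i] - 1
    for (e in 1:6) {
      dn[4 + e, ed[e, 1]] <- 4 * lam[ed[e, 2]]
      dn[4 + e, ed[e, 2]] <- 4 * lam[ed[e, 1]]
    }
    dN <- dn %*% gL
    B <- matrix(0, 6, 30)
    for (i in 1:10) {
      cx <- 3 * (i - 1)
      B[1, cx + 1] <- dN[i, 1]; B[2, cx + 2] <- dN[i, 2]
      B[3, cx + 3] <- dN[i, 3]
      B[4, cx + 1] <- dN[i, 2]; B[4, cx + 2] <- dN[i, 1]
      B[5, cx + 1] <- dN[i, 3]; B[5, cx + 3] <- dN[i, 1]
      B[6, cx + 2] <- dN[i, 3]; B[6, cx + 3] <- dN[i, 2]
    }
    K <- K + w[q] * detJ * t(B) %*% C %*% B
  }
  K
}

# A straight TET10 from 4 vertex rows (midsides at edge midpoints).
tet10_from_vertices <- function(X4) {
  rbind(X4,
        (X4[1, ] + X4[2, ]) / 2, (X4[2, ] + X4[3, ]) / 2,
        (X4[3, ] + X4[1, ]) / 2, (X4[1, ] + X4[4, ]) / 2,
        (X4[2, ] + X4[4, ]) / 2, (X4[3, ] + X4[4, ]) / 2)
}

# Rectangular block of hex cells split to TET10 as a standalone labeled mesh
# (no anatomy); nx, ny, nz cells of size h.
block_mesh <- function(nx = 2, ny = 2, nz = 2, h = 1, label = "block") {
  xg <- h * 0:nx; yg <- h * 0:ny; zg <- h * 0:nz
  cells <- as.matrix(expand.grid(it = seq_len(nx), iu = seq_len(ny),
                                 iv = seq_len(nz)))
  m <- mandifix:::.structured_tet10(xg, yg, zg, cells,
                                    function(t, u, v) cbind(t, u, v))
  mesh <- list(nodes = m$nodes, elems = m$elems,
               region = rep(label, nrow(m$elems)),
               node_param = m$node_param,
               elem_param = matrix(0, nrow(m$elems), 3),
               n_vertex = m$n_vertex, midpair = m$midpair,
               node_sets = list(), face_sets = list(), elem_sets = list(),
               similitude = 1)
  class(mesh) <- "labeled_mesh"
  mesh$faces <- mandifix:::.boundary_faces(mesh$elems, nrow(mesh$nodes))
  mesh
}

# Minimal load-case wrapper for hand-built systems.
manual_load <- function(mesh, F = NULL, fixed_dofs = integer(),
                        sets = list()) {
  if (is.null(F)) F <- matrix(0, nrow(mesh$nodes), 3)
  structure(list(F = F, resultants = list(),
                 bc = list(sets = sets, fixed_dofs = fixed_dofs),
                 scale = 0, similitude = 1, convergence_mode = FALSE),
            class = "load_case")
}

# Patch test: prescribe a linear displacement field on the boundary of a
# small block and return the max deviation of the recovered strain from the
# constant field (zero for a conforming quadratic element implementation).
patch_test_strain <- function(card) {
  mesh <- block_mesh(2, 2, 2, h = 0.5)
  A <- matrix(c(1e-3, 4e-4, -2e-4,
                2e-4, -5e-4, 3e-4,
                -1e-4, 2e-4, 6e-4), 3, 3, byrow = TRUE)
  xyz <- mesh$node_param
  bnd <- which(apply(xyz, 1, function(p)
    any(abs(p - 0) < 1e-12 | abs(p - 1) < 1e-12)))
  fd <- as.vector(rbind(3 * (bnd - 1) + 1, 3 * (bnd - 1) + 2,
                        3 * (bnd - 1) + 3))
  uval <- t(A %*% t(xyz[bnd, , drop = FALSE]))
  sys <- assemble_system(mesh, uniform_Cm(mesh, card),
                         manual_load(mesh, fixed_dofs = fd))
  sys$fixed_value <- as.vector(t(uval))
  sol <- solve_system(sys)
  expected <- c(A[1, 1], A[2, 2], A[3, 3], A[1, 2] + A[2, 1],
                A[1, 3] + A[3, 1], A[2, 3] + A[3, 2])
  max(abs(sweep(sol$strain, 2, expected)))
}

# Uniform per-element stiffness rows for a single card.
uniform_Cm <- function(mesh, card) {
  C <- stiffness_voigt(card)
  ne <- nrow(mesh$elems)
  structure(list(Cm = matrix(rep(as.vector(t(C)), ne), ne, 36, byrow = TRUE),
                 card_name = rep(card$name, ne),
                 frames = NULL, cards = setNames(list(card), card$name),
                 device_material = card$name),
            class = "material_assignment")
}
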