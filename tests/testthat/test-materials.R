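test_that("packaged material table holds the twelve expected cards", {
  cards <- material_cards()
  expect_length(cards, 12)
  expect_equal(cards$symphysis$E1, 20492)
  expect_equal(cards$symphysis$nu12, 0.34)
  expect_equal(cards$symphysis$G12, 6908)
  expect_equal(cards$granulation$E1, 3)
  expect_equal(cards$granulation$nu12, 0.4)
  expect_equal(cards$granulation$G12, 1)
  expect_equal(cards$WE43$E1, 44200)
  expect_equal(cards$WE43$yield_strength, 162)
  expect_equal(cards$`Ti-6Al-4V`$yield_strength, 880)
  expect_equal(cards$PLA$yield_strength, 70)
  cortical <- c("symphysis", "body", "angle", "ramus", "condyle",
                "coronoid_process")
  for (cn in cortical) {
    cc <- cards[[cn]]
    expect_true(cc$E1 >= cc$E2 && cc$E2 >= cc$E3)
  }
})

test_that("isotropic stiffness matches the closed-form Lame constants", {
  C <- stiffness_voigt(iso_card(15000, 0.3))
  lam <- 15000 * 0.3 / (1.3 * 0.4); mu <- 15000 / 2.6
  expect_equal(C[1, 1], lam + 2 * mu, tolerance = 1e-10)
  expect_equal(C[1, 2], lam, tolerance = 1e-10)
  expect_equal(C[4, 4], mu, tolerance = 1e-10)
  expect_equal(C[1, 1], 20192.3, tolerance = 1e-4)
  expect_equal(C[1, 2], 8653.8, tolerance = 1e-4)
  expect_equal(C[4, 4], 5769.2, tolerance = 1e-4)
  set.seed(7)
  for (i in 1:20) {
    E <- runif(1, 10, 1e5); nu <- runif(1, 0.05, 0.45)
    Ci <- stiffness_voigt(material_card("r", E, nu12 = nu, isotropic = TRUE))
    lam <- E * nu / ((1 + nu) * (1 - 2 * nu)); mu <- E / (2 * (1 + nu))
    expect_equal(Ci[1, 1], lam + 2 * mu, tolerance = 1e-9)
    expect_equal(Ci[2, 3], lam, tolerance = 1e-9)
    expect_equal(Ci[6, 6], mu, tolerance = 1e-9)
  }
})

test_that("orthotropic stiffness inverts the explicit compliance", {
  cc <- material_cards()$symphysis
  S <- matrix(0, 6, 6)
  S[1, 1] <- 1 / cc$E1; S[2, 2] <- 1 / cc$E2; S[3, 3] <- 1 / cc$E3
  S[1, 2] <- S[2, 1] <- -cc$nu12 / cc$E1
  S[1, 3] <- S[3, 1] <- -cc$nu13 / cc$E1
  S[2, 3] <- S[3, 2] <- -cc$nu23 / cc$E2
  S[4, 4] <- 1 / cc$G12; S[5, 5] <- 1 / cc$G13; S[6, 6] <- 1 / cc$G23
  C <- stiffness_voigt(cc)
  expect_lt(max(abs(C - solve(S))) / max(abs(C)), 1e-8)
  expect_lt(max(abs(C - t(C))), 1e-10 * max(abs(C)))
})

test_that("thermodynamically inadmissible constants are rejected", {
  expect_error(material_card("bad", E1 = 100, E2 = 10000, E3 = 100,
                             nu12 = 0.45, nu23 = 0.3, nu13 = 0.3,
                             G12 = 50, G23 = 50, G13 = 50),
               "inadmissible")
  expect_error(material_card("neg", E1 = -5, nu12 = 0.3), "positive")
  expect_error(material_card("nu", E1 = 100, nu12 = 0.6), "Poisson")
})

# Independent Bond-matrix oracle for the Voigt order 11,22,33,12,13,23.
bond_matrix <- function(R) {
  iv <- c(1, 2, 3, 1, 1, 2); jv <- c(1, 2, 3, 2, 3, 3)
  M <- matrix(0, 6, 6)
  for (I in 1:6) for (J in 1:6) {
    i <- iv[I]; j <- jv[I]; k <- iv[J]; l <- jv[J]
    M[I, J] <- if (k == l) R[i, k] * R[j, k]
               else R[i, k] * R[j, l] + R[i, l] * R[j, k]
  }
  M
}

test_that("stiffness rotation matches the Bond-matrix oracle and conserves energy", {
  cc <- material_cards()$body
  C <- stiffness_voigt(cc)
  expect_equal(rotate_stiffness(C, diag(3)), C, tolerance = 1e-12)
  set.seed(11)
  for (i in 1:5) {
    Q <- qr.Q(qr(matrix(rnorm(9), 3)))
    if (det(Q) < 0) Q[, 1] <- -Q[, 1]
    Cg <- rotate_stiffness(C, Q)
    # Bond oracle: x_glob = R x_loc with R = t(Q)
    M <- bond_matrix(t(Q))
    expect_lt(max(abs(Cg - M %*% C %*% t(M))) / max(abs(C)), 1e-10)
    # energy invariance for a random strain
    toT <- function(v) matrix(c(v[1], v[4] / 2, v[5] / 2, v[4] / 2, v[2],
                                v[6] / 2, v[5] / 2, v[6] / 2, v[3]), 3, 3)
    toV <- function(Tm) c(diag(Tm), 2 * Tm[1, 2], 2 * Tm[1, 3], 2 * Tm[2, 3])
    eg <- rnorm(6)
    el <- toV(Q %*% toT(eg) %*% t(Q))
    expect_equal(sum(eg * (Cg %*% eg)), sum(el * (C %*% el)),
                 tolerance = 1e-10)
  }
  # a 90-degree rotation about e3 swaps the 11 and 22 entries
  R90 <- rbind(c(0, 1, 0), c(-1, 0, 0), c(0, 0, 1))
  Cr <- rotate_stiffness(C, R90)
  expect_equal(Cr[1, 1], C[2, 2], tolerance = 1e-8)
  expect_equal(Cr[2, 2], C[1, 1], tolerance = 1e-8)
  # isotropy: arbitrary rotations leave the matrix unchanged
  Ci <- stiffness_voigt(iso_card())
  set.seed(12)
  Q <- qr.Q(qr(matrix(rnorm(9), 3))); if (det(Q) < 0) Q[, 1] <- -Q[, 1]
  expect_lt(max(abs(rotate_stiffness(Ci, Q) - Ci)), 1e-8 * max(abs(Ci)))
  expect_error(rotate_stiffness(C, matrix(1, 3, 3)), "orthonormal")
})

test_that("material assignment maps labels to cards and aligns frames", {
  m <- coarse_mandible()
  fr <- insert_fracture(m, fracture_spec("body"))
  merged <- place_devices(fr, 1.0)
  asg <- assign_materials(merged, "PLA", material_cards())
  gran <- which(merged$region == "granulation")
  Cg <- stiffness_voigt(material_cards()$granulation)
  expect_equal(asg$Cm[gran[1], ], as.vector(t(Cg)), tolerance = 1e-12)
  dev <- which(merged$region %in% c("plate", "screw"))
  Cp <- stiffness_voigt(material_cards()$PLA)
  expect_equal(asg$Cm[dev[1], ], as.vector(t(Cp)), tolerance = 1e-12)
  # longitudinal frame axis follows the mandibular axis tangent: compare
  # against a central-difference tangent of the axis curve at the element
  for (lab in c("symphysis", "ramus")) {
    el <- which(merged$region == lab)[1]
    s0 <- merged$elem_param[el, 1]
    e1 <- asg$frames[el, 1:3]
    d <- 1e-4
    tv <- (mandifix:::.sweep_map(s0 + d, 0, 0, merged$geom) -
             mandifix:::.sweep_map(s0 - d, 0, 0, merged$geom)) / (2 * d)
    tv <- tv / sqrt(sum(tv^2))
    ang <- acos(pmin(1, abs(sum(e1 * tv)))) * 180 / pi
    expect_lt(ang, 5)
  }
  expect_error(assign_materials(merged, "unobtainium"), "material card")
})
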