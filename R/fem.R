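# Assembly and solution of the constrained linear-elastic system on TET10
# meshes. Element stiffness uses a 4-point Gauss rule (exact for the
# linear-strain integrand of straight-edged quadratic tets); tie slaves are
# eliminated through a sparse reduction matrix before Dirichlet rows/columns
# are removed; the reduced system is solved by sparse Cholesky.

# Sparse reduction matrix for tie elimination: u_full = T %*% u_reduced.
.tie_reduction <- function(ndof, ties) {
  if (is.null(ties)) {
    keep <- seq_len(ndof)
    return(list(T = Matrix::Diagonal(ndof), keep = keep,
                red_of_full = seq_len(ndof)))
  }
  sdof <- as.vector(vapply(1:3, function(d) 3 * (ties$slave - 1) + d,
                           numeric(length(ties$slave))))
  sdof <- sort(unique(sdof))
  keep <- setdiff(seq_len(ndof), sdof)
  red_of_full <- integer(ndof)
  red_of_full[keep] <- seq_along(keep)
  ii <- keep; jj <- seq_along(keep); xx <- rep(1, length(keep))
  m <- length(ties$slave)
  for (d in 1:3) {
    rows <- rep(3 * (ties$slave - 1) + d, 10)
    cols <- red_of_full[3 * (as.vector(ties$master_nodes) - 1) + d]
    vals <- as.vector(ties$weights)
    nz <- vals != 0
    ii <- c(ii, rows[nz]); jj <- c(jj, cols[nz]); xx <- c(xx, vals[nz])
  }
  T <- Matrix::sparseMatrix(i = ii, j = jj, x = xx,
                            dims = c(ndof, length(keep)))
  list(T = T, keep = keep, red_of_full = red_of_full)
}

#' Assemble the constrained finite-element system
#'
#' @param mesh a `labeled_mesh` (bone only or merged with devices).
#' @param materials a `material_assignment` from [assign_materials()].
#' @param load a `load_case` from [build_load_case()].
#' @param ties optional `tie_set` from [build_ties()].
#' @return object of class `fe_system`: reduced sparse symmetric stiffness,
#'   reduced load vector, fixed-DOF indices, the tie reduction operator and
#'   element volumes.
#' @export
assemble_system <- function(mesh, materials, load, ties = NULL) {
  stopifnot(inherits(materials, "material_assignment"))
  ndof <- 3L * nrow(mesh$nodes)
  tr <- fk_assemble_triplets(mesh$nodes, mesh$elems, materials$Cm)
  K <- Matrix::sparseMatrix(i = tr$i, j = tr$j, x = tr$x,
                            dims = c(ndof, ndof), symmetric = TRUE)
  volumes <- tr$volume; min_detJ <- tr$min_detJ
  rm(tr)
  red <- .tie_reduction(ndof, ties)
  f_full <- as.vector(t(load$F))
  if (is.null(ties)) {
    Kr <- K
    fr <- f_full
  } else {
    Kr <- Matrix::forceSymmetric(Matrix::crossprod(red$T, K %*% red$T))
    fr <- as.vector(Matrix::crossprod(red$T, f_full))
  }
  fixed_full <- load$bc$fixed_dofs
  if (!is.null(ties) && any(fixed_full %in% setdiff(seq_len(ndof), red$keep)))
    stop("boundary conditions may not act on tie slave nodes")
  fixed <- red$red_of_full[fixed_full]
  structure(list(K = Kr, f = fr, fixed = fixed, fixed_value = NULL,
                 reduction = red, ties = ties, ndof_full = ndof,
                 mesh = mesh, materials = materials, load = load,
                 volumes = volumes, min_detJ = min_detJ),
            class = "fe_system")
}

# Vectorized physical barycentric coordinates of points within (straight)
# host tets, followed by TET10 shape-function evaluation. spar: parametric
# coordinates used for host location; pts: physical coordinates.
.interp_weights <- function(mesh, spar, pts) {
  host <- .locate_bone_elements(mesh, spar)
  vA <- mesh$nodes[mesh$elems[host, 1], , drop = FALSE]
  vB <- mesh$nodes[mesh$elems[host, 2], , drop = FALSE]
  vC <- mesh$nodes[mesh$elems[host, 3], , drop = FALSE]
  vD <- mesh$nodes[mesh$elems[host, 4], , drop = FALSE]
  e1 <- vA - vD; e2 <- vB - vD; e3 <- vC - vD; r <- pts - vD
  cr23 <- cbind(e2[, 2] * e3[, 3] - e2[, 3] * e3[, 2],
                e2[, 3] * e3[, 1] - e2[, 1] * e3[, 3],
                e2[, 1] * e3[, 2] - e2[, 2] * e3[, 1])
  cr31 <- cbind(e3[, 2] * e1[, 3] - e3[, 3] * e1[, 2],
                e3[, 3] * e1[, 1] - e3[, 1] * e1[, 3],
                e3[, 1] * e1[, 2] - e3[, 2] * e1[, 1])
  cr12 <- cbind(e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2],
                e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3],
                e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1])
  det <- rowSums(e1 * cr23)
  l1 <- rowSums(r * cr23) / det
  l2 <- rowSums(r * cr31) / det
  l3 <- rowSums(r * cr12) / det
  lam <- cbind(l1, l2, l3, 1 - l1 - l2 - l3)
  W <- matrix(0, nrow(pts), 10)
  W[, 1:4] <- lam * (2 * lam - 1)
  ed <- rbind(c(1, 2), c(2, 3), c(3, 1), c(1, 4), c(2, 4), c(3, 4))
  for (e in 1:6) W[, 4 + e] <- 4 * lam[, ed[e, 1]] * lam[, ed[e, 2]]
  list(host = host, weights = W, nodes = mesh$elems[host, , drop = FALSE])
}

# Prolongation matrix (fine DOFs x coarse DOFs) interpolating fine nodal
# displacements from the coarse mesh's TET10 shape functions.
.prolongation <- function(coarse_mesh, fine_mesh) {
  g <- coarse_mesh$geom
  spar <- fine_mesh$node_param
  # clamp parametric coordinates into the coarse lattice range
  spar[, 1] <- pmin(pmax(spar[, 1], -g$s5), g$s5)
  iw <- .interp_weights(coarse_mesh, spar, fine_mesh$nodes)
  nf <- nrow(fine_mesh$nodes); nc <- nrow(coarse_mesh$nodes)
  ii <- jj <- xx <- vector("list", 3)
  for (d in 1:3) {
    ii[[d]] <- rep(3 * (seq_len(nf) - 1) + d, 10)
    jj[[d]] <- 3 * (as.vector(iw$nodes) - 1) + d
    xx[[d]] <- as.vector(iw$weights)
  }
  Matrix::sparseMatrix(i = unlist(ii), j = unlist(jj), x = unlist(xx),
                       dims = c(3 * nf, 3 * nc))
}

# Two-grid preconditioned conjugate gradients: M^{-1} = omega D^{-1} +
# P Acoarse^{-1} P'. Returns the solution on the free DOFs.
.pcg_two_grid <- function(Kff, rhs, Pf, coarse_chol, tol = 1e-10,
                          maxit = 400L, omega = 0.6) {
  dinv <- omega / Matrix::diag(Kff)
  Pt <- Matrix::t(Pf)
  prec <- function(r)
    dinv * r + as.vector(Pf %*% Matrix::solve(coarse_chol,
                                              as.vector(Pt %*% r)))
  x <- numeric(length(rhs))
  r <- rhs
  z <- prec(r)
  p <- z
  rz <- sum(r * z)
  nrhs <- sqrt(sum(rhs^2))
  for (it in seq_len(maxit)) {
    Kp <- as.vector(Kff %*% p)
    alpha <- rz / sum(p * Kp)
    x <- x + alpha * p
    r <- r - alpha * Kp
    if (sqrt(sum(r^2)) / nrhs < tol) return(list(x = x, iter = it))
    z <- prec(r)
    rz_new <- sum(r * z)
    p <- z + (rz_new / rz) * p
    rz <- rz_new
  }
  stop("two-grid PCG did not converge within ", maxit, " iterations")
}

#' Solve the assembled system
#'
#' Direct sparse (supernodal) Cholesky on the free DOFs; supports non-zero
#' prescribed displacements through `system$fixed_value`. For very large
#' tie-free systems with a coarser companion level available (mesh
#' convergence runs), a memory-lean two-grid preconditioned conjugate
#' gradient solver is used instead, converged to a relative residual of
#' 1e-10. Fails if the factorization detects an indefinite/singular matrix
#' (insufficient restraints) or the relative residual exceeds 1e-9.
#'
#' @param system an `fe_system`.
#' @param coarse optional coarse-level context, a list with elements
#'   `mesh`, `system` and `chol` (the factorized coarse free-DOF stiffness)
#'   from a previous, coarser solve of the same problem.
#' @param iterative_threshold free-DOF count above which the two-grid CG
#'   path is taken when `coarse` is available.
#' @return object of class `fe_solution` with nodal displacements,
#'   integration-point strain/stress tensors (Voigt), point weights, element
#'   ids and region labels, reduced-system vectors for reactions, and the
#'   solver residual.
#' @export
solve_system <- function(system, coarse = NULL,
                         iterative_threshold = 250000L) {
  n <- length(system$f)
  free <- setdiff(seq_len(n), system$fixed)
  uval <- rep(0, n)
  if (!is.null(system$fixed_value)) uval[system$fixed] <- system$fixed_value
  Kff <- system$K[free, free, drop = FALSE]
  rhs <- system$f[free]
  if (any(uval != 0))
    rhs <- rhs - as.vector(system$K[free, system$fixed, drop = FALSE] %*%
                             uval[system$fixed])
  ch <- NULL
  iterations <- NA_integer_
  if (!is.null(coarse) && length(free) > iterative_threshold &&
      is.null(system$ties)) {
    P <- .prolongation(coarse$mesh, system$mesh)
    free_c <- setdiff(seq_along(coarse$system$f), coarse$system$fixed)
    Pf <- P[free, free_c, drop = FALSE]
    cg <- .pcg_two_grid(Matrix::forceSymmetric(Kff), rhs, Pf, coarse$chol)
    uf <- cg$x
    iterations <- cg$iter
  } else {
    fail <- function(e) stop("singular or indefinite stiffness: ",
                             conditionMessage(e), call. = FALSE)
    ch <- tryCatch(Matrix::Cholesky(Matrix::forceSymmetric(Kff),
                                    LDL = FALSE, perm = TRUE, super = TRUE),
                   error = fail, warning = fail)
    uf <- as.vector(Matrix::solve(ch, rhs))
  }
  res <- sqrt(sum((as.vector(Kff %*% uf) - rhs)^2)) /
    max(sqrt(sum(rhs^2)), .Machine$double.eps)
  if (!is.finite(res) || res > 1e-9)
    stop("solver did not converge (relative residual ", signif(res, 3), ")")
  u_red <- uval
  u_red[free] <- uf
  u_full <- as.vector(system$reduction$T %*% u_red)
  rec <- fk_recover(system$mesh$nodes, system$mesh$elems,
                    system$materials$Cm, u_full)
  structure(list(u = matrix(u_full, ncol = 3, byrow = TRUE),
                 u_red = u_red,
                 strain = rec$strain, stress = rec$stress,
                 weight = rec$weight, element = rec$element,
                 point = rec$point,
                 region = system$mesh$region[rec$element],
                 residual = res, iterations = iterations,
                 factor = ch, free = free, system = system),
            class = "fe_solution")
}

#' Reaction force resultants at the restrained sets
#'
#' Reactions are `K u - f` on the reduced system, summed per named node set.
#' Global equilibrium holds: the sum of all reactions balances the applied
#' loads.
#'
#' @param solution an `fe_solution`.
#' @return list of 3-vectors per restrained set plus `total` (sum over all
#'   restrained DOFs) and `bite_force` (the vertical occlusal reaction, N).
#' @export
reaction_forces <- function(solution) {
  sys <- solution$system
  r <- as.vector(sys$K %*% solution$u_red) - sys$f
  red_of_full <- sys$reduction$red_of_full
  out <- list()
  total <- c(0, 0, 0)
  for (sn in names(sys$load$bc$sets)) {
    nodes <- sys$load$bc$sets[[sn]]
    v <- c(0, 0, 0)
    for (d in 1:3) {
      dofs <- red_of_full[3 * (nodes - 1) + d]
      fixed_d <- dofs[dofs %in% sys$fixed]
      v[d] <- sum(r[fixed_d])
    }
    out[[sn]] <- v
    total <- total + v
  }
  out$total <- total
  # the support reaction on the mandible acts downward while biting; the
  # bite force (mandible on food) is its opposite
  occ <- out$occlusal_right
  out$bite_force <- if (!is.null(occ)) -occ[3] else NA_real_
  out
}

#' Strain energy of a solved system
#'
#' @param solution an `fe_solution`.
#' @return 0.5 * f' u on the reduced system, N mm.
#' @export
strain_energy <- function(solution) {
  0.5 * sum(solution$system$f * solution$u_red)
}

#' Applied load resultant
#'
#' @param system an `fe_system`.
#' @return 3-vector sum of all applied nodal forces, N.
#' @export
applied_resultant <- function(system) {
  colSums(system$load$F)
}
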