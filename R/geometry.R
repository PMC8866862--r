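#' Parameters of the synthetic mandible generator
#'
#' Defines the desk-scale parametric stand-in for a segmented human mandible:
#' a horseshoe-shaped solid of rounded-rectangular cross-section swept along a
#' parametric axis (anterior arc, posterior bends, vertical rami, condylar
#' necks and flared condylar heads), with a cortical shell, trabecular core
#' and a teeth block fused to the crest along the anterior tooth row.
#'
#' The default dimensions correspond to roughly 0.4x nominal adult scale; the
#' loading module compensates by geometric similitude (see
#' [build_load_case()]), so stress and strain fields remain on a
#' physiological scale while meshes stay small enough for routine re-solves.
#'
#' Coordinate frame: X mediolateral (+X = anatomical right), Y anteroposterior
#' (+Y anterior), Z inferosuperior (+Z cranial). Units mm, N, MPa.
#'
#' @param arch_radius radius of the anterior body arc at the section axis, mm.
#' @param arch_span_angle angular span of the body arc, degrees.
#' @param body_height height of the body cross-section, mm.
#' @param body_width mediolateral width of the body cross-section, mm.
#' @param cortical_thickness thickness of the cortical shell, mm.
#' @param ramus_height length of the straight vertical ramus segment, mm.
#' @param condyle_neck_length length of the condylar neck segment, mm.
#' @param tooth_row_extent fraction of the body arc carrying the teeth block.
#' @param target_edge_length nominal lattice edge length, mm.
#' @param seed integer stored with the mesh (the generator is deterministic;
#'   the seed is recorded for provenance of downstream runs).
#' @param bend_radius radius of the body-to-ramus bend at the axis, mm; must
#'   exceed half the body height so swept cells cannot invert.
#' @param condyle_head_length length of the flared condylar head segment, mm.
#' @param condyle_head_flare widening factor of the section at the head top.
#' @param condyle_setback posterior offset of the condylar axis relative to
#'   the ramus center, mm (the condyle sits at the posterior ramus border).
#' @param tooth_height height of the teeth block above the crest, mm.
#' @param symphysis_arc_fraction fraction of the body arc labeled symphysis.
#' @param muscle_patch_radius default radius of muscle attachment patches, mm.
#' @param reference_arch_radius arch radius of the nominal full-scale adult
#'   mandible, mm; sets the similitude factor (arch_radius/reference)^2.
#' @return object of class `mandible_params`.
#' @export
mandible_params <- function(arch_radius = 9, arch_span_angle = 150,
                            body_height = 6, body_width = 5,
                            cortical_thickness = 1.25,
                            ramus_height = 6.5, condyle_neck_length = 5,
                            tooth_row_extent = 0.55,
                            target_edge_length = 1.0, seed = 1L,
                            bend_radius = 5, condyle_head_length = 2,
                            condyle_head_flare = 1.35, condyle_setback = 2.0,
                            tooth_height = 2,
                            symphysis_arc_fraction = 0.25,
                            muscle_patch_radius = 2.5,
                            reference_arch_radius = 22.5) {
  p <- list(arch_radius = arch_radius, arch_span_angle = arch_span_angle,
            body_height = body_height, body_width = body_width,
            cortical_thickness = cortical_thickness,
            ramus_height = ramus_height,
            condyle_neck_length = condyle_neck_length,
            tooth_row_extent = tooth_row_extent,
            target_edge_length = target_edge_length, seed = as.integer(seed),
            bend_radius = bend_radius,
            condyle_head_length = condyle_head_length,
            condyle_head_flare = condyle_head_flare,
            condyle_setback = condyle_setback,
            tooth_height = tooth_height,
            symphysis_arc_fraction = symphysis_arc_fraction,
            muscle_patch_radius = muscle_patch_radius,
            reference_arch_radius = reference_arch_radius)
  dims <- c("arch_radius", "arch_span_angle", "body_height", "body_width",
            "cortical_thickness", "ramus_height", "condyle_neck_length",
            "target_edge_length", "bend_radius", "condyle_head_length",
            "tooth_height")
  for (d in dims)
    if (!is.finite(p[[d]]) || p[[d]] <= 0)
      stop("mandible parameter '", d, "' must be positive")
  if (cortical_thickness >= body_width / 2 ||
      cortical_thickness >= body_height / 2)
    stop("cortical_thickness must be below half the body width and height")
  if (tooth_row_extent <= 0 || tooth_row_extent >= 1)
    stop("tooth_row_extent must be in (0, 1)")
  if (bend_radius <= body_height / 2)
    stop("bend_radius must exceed half the body height (swept cells invert)")
  class(p) <- "mandible_params"
  p
}

# Derived axis geometry: arc-length breakpoints of the sweep (right half;
# the left half is the mirror image).
.axis_geometry <- function(p) {
  theta <- p$arch_span_angle * pi / 180
  R <- p$arch_radius
  A <- R * theta
  s1 <- A / 2                                  # end of body arc
  s2 <- s1 + p$bend_radius * pi / 2            # end of angle bend
  s3 <- s2 + p$ramus_height                    # end of ramus
  s4 <- s3 + p$condyle_neck_length             # end of neck
  s5 <- s4 + p$condyle_head_length             # axis top (condylar head)
  list(R = R, theta = theta, A = A, rb = p$bend_radius,
       s1 = s1, s2 = s2, s3 = s3, s4 = s4, s5 = s5,
       Lram = p$ramus_height, Lneck = p$condyle_neck_length,
       Lhead = p$condyle_head_length, flare = p$condyle_head_flare,
       W = p$body_width, H = p$body_height, cort = p$cortical_thickness,
       t_tooth = p$tooth_row_extent * A / 2,
       s_sym = p$symphysis_arc_fraction * A / 2,
       tooth_h = p$tooth_height,
       neck_setback = p$condyle_setback,
       similitude = (p$arch_radius / p$reference_arch_radius)^2)
}

# Posterior offset of the condylar neck/head section center: the condyle
# sits at the posterior ramus border (the coronoid side is anterior), which
# sets the muscles' moment arms about the locked condyles.
.neck_offset_at <- function(sa, g) {
  -g$neck_setback * pmin(1, pmax(0, (sa - g$s3) / g$Lneck))
}

# Head-flare scale factor at axis coordinate |s|.
.flare_at <- function(sa, g) {
  k <- rep(1, length(sa))
  ih <- sa > g$s4
  if (any(ih))
    k[ih] <- 1 + (g$flare - 1) * pmin(1, (sa[ih] - g$s4) / g$Lhead)
  k
}

# Sweep map: parametric (s, u, v) -> physical (x, y, z). s is signed arc
# length along the axis (s = 0 at the symphysis, s > 0 on the right side),
# u the in-section coordinate towards the lateral (buccal) surface, v the
# in-section coordinate towards the crest (body) / anterior edge (ramus).
.sweep_map <- function(s, u, v, g) {
  n <- length(s)
  sa <- abs(s)
  sgn <- ifelse(s < 0, -1, 1)
  k <- .flare_at(sa, g)
  uu <- k * u
  vv <- k * v + .neck_offset_at(sa, g)
  x <- y <- z <- numeric(n)
  R <- g$R
  ib <- sa <= g$s1
  if (any(ib)) {
    phi <- sa[ib] / R
    x[ib] <- (R + uu[ib]) * sin(phi)
    y[ib] <- (R + uu[ib]) * cos(phi)
    z[ib] <- vv[ib]
  }
  phie <- g$s1 / R
  T0 <- c(cos(phie), -sin(phie))       # body tangent at arc end (xy)
  eu0 <- c(sin(phie), cos(phie))       # radial direction at arc end (xy)
  P1 <- c(R * sin(phie), R * cos(phie))
  ibd <- sa > g$s1 & sa <= g$s2
  if (any(ibd)) {
    be <- (sa[ibd] - g$s1) / g$rb
    x[ibd] <- P1[1] + g$rb * sin(be) * T0[1] + uu[ibd] * eu0[1] -
      vv[ibd] * sin(be) * T0[1]
    y[ibd] <- P1[2] + g$rb * sin(be) * T0[2] + uu[ibd] * eu0[2] -
      vv[ibd] * sin(be) * T0[2]
    z[ibd] <- g$rb * (1 - cos(be)) + vv[ibd] * cos(be)
  }
  ir <- sa > g$s2
  if (any(ir)) {
    P2 <- P1 + g$rb * T0
    x[ir] <- P2[1] + uu[ir] * eu0[1] - vv[ir] * T0[1]
    y[ir] <- P2[2] + uu[ir] * eu0[2] - vv[ir] * T0[2]
    z[ir] <- g$rb + (sa[ir] - g$s2)
  }
  cbind(x * sgn, y, z, deparse.level = 0)
}

# Local frame along the axis at signed arc length s: rows are (e1, e2, e3) =
# (longitudinal tangent, section "vertical" e_v, completing right-handed
# transverse axis). Returns an n x 9 matrix (row-major frame rows).
.sweep_frame <- function(s, g) {
  n <- length(s)
  sa <- abs(s)
  sgn <- ifelse(s < 0, -1, 1)
  e1 <- matrix(0, n, 3)
  ev <- matrix(0, n, 3)
  R <- g$R
  ib <- sa <= g$s1
  if (any(ib)) {
    phi <- sa[ib] / R
    e1[ib, ] <- cbind(cos(phi), -sgn[ib] * sin(phi), 0)
    ev[ib, ] <- cbind(0, 0, 1)[rep(1, sum(ib)), , drop = FALSE]
  }
  phie <- g$s1 / R
  ibd <- sa > g$s1 & sa <= g$s2
  if (any(ibd)) {
    be <- (sa[ibd] - g$s1) / g$rb
    T0x <- cos(phie); T0y <- -sgn[ibd] * sin(phie)
    e1[ibd, ] <- cbind(cos(be) * T0x, cos(be) * T0y, sin(be))
    ev[ibd, ] <- cbind(-sin(be) * T0x, -sin(be) * T0y, cos(be))
  }
  ir <- sa > g$s2
  if (any(ir)) {
    e1[ir, ] <- cbind(0, 0, 1)[rep(1, sum(ir)), , drop = FALSE]
    ev[ir, ] <- cbind(-cos(phie), sgn[ir] * sin(phie), 0)
  }
  e3 <- cbind(e1[, 2] * ev[, 3] - e1[, 3] * ev[, 2],
              e1[, 3] * ev[, 1] - e1[, 1] * ev[, 3],
              e1[, 1] * ev[, 2] - e1[, 2] * ev[, 1])
  cbind(e1, ev, e3)
}

# Banded 1D grid: each (snapped) segment subdivided into >= 1 cells of size
# close to h. Returns breakpoints and, per cell, the id of its segment.
.banded_grid <- function(bounds, h, min_cells = 1L) {
  pts <- bounds[1]
  seg <- integer(0)
  for (i in seq_len(length(bounds) - 1)) {
    len <- bounds[i + 1] - bounds[i]
    n <- max(min_cells, round(len / h))
    pts <- c(pts, bounds[i] + len * seq_len(n) / n)
    seg <- c(seg, rep(i, n))
  }
  list(pts = pts, seg = seg)
}
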