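# Miniplate/screw devices and tie constraints. Plates are meshed as lattice
# solids in plate-local coordinates (length a, width b, thickness z) with the
# hole cylinders removed; screws are smooth cylinders (elliptical
# square-to-disk mapped lattices) fused to the plate holes. At placement the
# local coordinates are wrapped onto the mandible surface through the same
# sweep map used by the bone mesher, so plates sit flush (up to the
# midsurface stand-off) on the curved lateral surface. Devices are joined to
# the model by linear multipoint tie constraints (no relative motion):
# plate-screw by projection onto the hole surface, screw-bone by volumetric
# embedding of the screw nodes in the bone elements.

#' Miniplate specification
#'
#' Dimensions default to the 2.0-miniplate system scaled consistently with
#' the desk-scale mandible geometry.
#'
#' @param n_holes even number of screw holes.
#' @param center_space gap between the two central holes straddling the
#'   fracture (condylar plates), mm; 0 for none.
#' @param thickness plate thickness, mm; 1.0 (clinical) or 1.5 (reinforced).
#' @param hole_pitch hole spacing, mm.
#' @param plate_width plate width, mm.
#' @param screw_length monocortical screw penetration below the bone
#'   surface, mm; must exceed the cortical thickness.
#' @param screw_diameter screw shaft diameter, mm.
#' @param hole_diameter plate hole diameter, mm.
#' @param edge_margin hole-center to plate-end margin, mm.
#' @param mesh_edge device lattice edge length, mm.
#' @param midsurface_offset distance of the plate midsurface from the bone
#'   surface, mm; shared between thickness variants so their midsurfaces
#'   coincide and screw positions are identical.
#' @return object of class `plate_spec`.
#' @export
plate_spec <- function(n_holes = 4, center_space = 0, thickness = 1.0,
                       hole_pitch = 3.0, plate_width = 2.2,
                       screw_length = 2.5, screw_diameter = 1.0,
                       hole_diameter = 1.1, edge_margin = 1.25,
                       mesh_edge = 0.33, midsurface_offset = 0.75) {
  if (!thickness %in% c(1.0, 1.5))
    stop("plate thickness must be 1.0 or 1.5 mm")
  if (n_holes %% 2 != 0 || n_holes < 2) stop("n_holes must be even")
  if (center_space < 0) stop("center_space must be >= 0")
  if (midsurface_offset < thickness / 2)
    stop("midsurface_offset must be at least half the plate thickness")
  if (center_space > 0)
    offs <- c(-1, 1) %o% (center_space / 2 + hole_pitch *
                            (seq_len(n_holes / 2) - 0.5))
  else
    offs <- matrix(hole_pitch * (seq_len(n_holes) - (n_holes + 1) / 2), 1)
  holes <- sort(as.vector(offs))
  if (min(diff(holes)) <= hole_diameter)
    stop("plate holes overlap")
  structure(list(n_holes = n_holes, center_space = center_space,
                 thickness = thickness, hole_pitch = hole_pitch,
                 plate_width = plate_width, screw_length = screw_length,
                 screw_diameter = screw_diameter,
                 hole_diameter = hole_diameter, edge_margin = edge_margin,
                 mesh_edge = mesh_edge,
                 midsurface_offset = midsurface_offset,
                 standoff = midsurface_offset - thickness / 2,
                 holes = holes,
                 length = 2 * (max(abs(holes)) + edge_margin)),
            class = "plate_spec")
}

# Plain lattice mesh in local coordinates through an arbitrary map.
.local_mesh <- function(xg, yg, zg, cells, map, label) {
  m <- .structured_tet10(xg, yg, zg, cells, map)
  vol <- .tet_volumes(m$nodes, m$elems)
  if (any(vol <= 0)) stop("degenerate element in device mesh")
  m$region <- rep(label, nrow(m$elems))
  m
}

#' Build a miniplate + screws device mesh in local coordinates
#'
#' Local frame: x along the plate, y across its width, z through the
#' thickness with the plate underside at z = 0. Screws extend from
#' z = -(screw_length + stand-off) to the plate top, fused to the holes.
#'
#' @param spec a [plate_spec()].
#' @return a device mesh (nodes, TET10 elems, region labels plate/screw,
#'   per-node kind and screw-lateral-surface flags, hole positions).
#' @export
build_device_mesh <- function(spec) {
  stopifnot(inherits(spec, "plate_spec"))
  he <- spec$mesh_edge
  L <- spec$length; w <- spec$plate_width; th <- spec$thickness
  nxt <- max(4L, round(L / he)); nyt <- max(3L, round(w / he))
  nzt <- max(2L, round(th / he))
  xg <- seq(-L / 2, L / 2, length.out = nxt + 1)
  yg <- seq(-w / 2, w / 2, length.out = nyt + 1)
  zg <- seq(0, th, length.out = nzt + 1)
  cells <- as.matrix(expand.grid(it = seq_len(nxt), iu = seq_len(nyt),
                                 iv = seq_len(nzt)))
  xc <- (xg[cells[, 1]] + xg[cells[, 1] + 1]) / 2
  yc <- (yg[cells[, 2]] + yg[cells[, 2] + 1]) / 2
  rh <- spec$hole_diameter / 2
  inhole <- rep(FALSE, nrow(cells))
  for (hx in spec$holes)
    inhole <- inhole | ((xc - hx)^2 + yc^2 <= rh^2)
  plate <- .local_mesh(xg, yg, zg, cells[!inhole, , drop = FALSE],
                       function(t, u, v) cbind(t, u, v, deparse.level = 0),
                       "plate")
  nodes <- plate$nodes; elems <- plate$elems; region <- plate$region
  midpair <- plate$midpair; nvert <- plate$n_vertex
  kind <- rep("plate", nrow(nodes))
  surf <- rep(FALSE, nrow(nodes))
  screw_id <- rep(0L, nrow(nodes))
  rs <- spec$screw_diameter / 2
  zlo <- -(spec$screw_length + spec$standoff)
  nsq <- max(3L, round(2 * rs / he))
  nzl <- max(3L, round((th - zlo) / he))
  sg <- seq(-1, 1, length.out = nsq + 1)
  szg <- seq(zlo, th, length.out = nzl + 1)
  scells <- as.matrix(expand.grid(it = seq_len(nsq), iu = seq_len(nsq),
                                  iv = seq_len(nzl)))
  for (k in seq_along(spec$holes)) {
    hx <- spec$holes[k]
    smap <- function(t, u, v)
      cbind(hx + rs * t * sqrt(1 - u^2 / 2),
            rs * u * sqrt(1 - t^2 / 2), v, deparse.level = 0)
    scr <- .local_mesh(sg, sg, szg, scells, smap, "screw")
    noff <- nrow(nodes)
    # midpair refers to vertex ids, which share the same offset as nodes
    nodes <- rbind(nodes, scr$nodes)
    elems <- rbind(elems, scr$elems + noff)
    region <- c(region, scr$region)
    midpair <- rbind(midpair, scr$midpair + noff)
    kind <- c(kind, rep("screw", nrow(scr$nodes)))
    lat <- pmax(abs(scr$node_param[, 1]), abs(scr$node_param[, 2])) > 1 - 1e-9
    surf <- c(surf, lat)
    screw_id <- c(screw_id, rep(k, nrow(scr$nodes)))
    nvert <- c(nvert, scr$n_vertex)
  }
  structure(list(nodes = nodes, elems = elems, region = region,
                 node_kind = kind, screw_surface = surf, screw_id = screw_id,
                 midpair = midpair, spec = spec),
            class = "device_mesh")
}

# Placement table for the four fracture scenarios (plates per site, anchored
# on the lateral surface; two parallel plates for symphysis/body, one 6-hole
# plate across the angle, 2-hole + 4-hole center-space plates on the neck).
.scenario_placements <- function(site, thickness, g) {
  std <- function(n) plate_spec(n_holes = n, thickness = thickness)
  neck <- function(n) plate_spec(n_holes = n, center_space = 2.2,
                                 thickness = thickness, hole_pitch = 2.5,
                                 edge_margin = 1.0)
  s_f <- .fracture_axis_position(g, site)
  switch(site,
    symphysis = list(list(spec = std(4), s = s_f, v = 0.9),
                     list(spec = std(4), s = s_f, v = -1.5)),
    body      = list(list(spec = std(4), s = s_f, v = 0.9),
                     list(spec = std(4), s = s_f, v = -1.5)),
    # the angle plate rides the superior (oblique-ridge) border
    angle     = list(list(spec = std(6), s = s_f, v = 1.2)),
    condylar_neck = list(list(spec = neck(2), s = s_f, v = 1.2),
                         list(spec = neck(4), s = s_f, v = -1.2)))
}

#' Scenario fixation configuration
#'
#' @param site fracture site.
#' @param thickness plate thickness (1.0 or 1.5 mm).
#' @param geom internal geometry (taken from the mesh in [place_devices()]).
#' @return list of plate placements (spec, axis anchor `s`, width anchor `v`).
#' @export
scenario_fixation <- function(site, thickness = 1.0, geom) {
  .scenario_placements(site, thickness, geom)
}

#' Place the scenario's fixation devices on the fractured mandible
#'
#' Wraps the plates onto the lateral bone surface straddling the healing
#' region and drives the monocortical screws radially into the bone. Both
#' plate thickness variants share the plate midsurface position, so screw
#' axes are identical between variants.
#'
#' @param mesh a fractured `labeled_mesh`.
#' @param placements optional override of [scenario_fixation()].
#' @param thickness plate thickness, mm.
#' @return the merged `labeled_mesh` (bone + devices) with device bookkeeping.
#' @export
place_devices <- function(mesh, thickness = 1.0, placements = NULL) {
  stopifnot(inherits(mesh, "labeled_mesh"))
  if (is.null(mesh$fracture))
    stop("insert the fracture before placing devices")
  g <- mesh$geom
  if (is.null(placements))
    placements <- .scenario_placements(mesh$fracture$site, thickness, g)
  devices <- list()
  for (pi in seq_along(placements)) {
    pl <- placements[[pi]]
    if (pl$spec$screw_length <= g$cort)
      stop("screws must engage beyond the cortical shell")
    dev <- build_device_mesh(pl$spec)
    # local -> sweep parameters: s along plate, v across, u outward normal;
    # the width axis is mirrored so the lattice orientation stays positive
    # under the (s, v, u) axis permutation of the sweep map
    sp <- pl$s + dev$nodes[, 1]
    vp <- pl$v - dev$nodes[, 2]
    up <- g$W / 2 + pl$spec$standoff + dev$nodes[, 3]
    inbone <- dev$node_kind == "screw" & up < g$W / 2 - 1e-9
    if (any(inbone)) {
      bad <- abs(vp[inbone]) > g$H / 2 - 1e-9 | abs(sp[inbone]) > g$s5 |
        up[inbone] < -g$W / 2 + 1e-9
      if (any(bad)) stop("screw exits the bone (placement error)")
    }
    xyz <- .sweep_map(sp, up, vp, g)
    # straight quadratic edges: midside nodes at mapped-endpoint midpoints
    xyz_mid <- (xyz[dev$midpair[, 1], , drop = FALSE] +
                xyz[dev$midpair[, 2], , drop = FALSE]) / 2
    mids <- sort(unique(as.vector(dev$elems[, 5:10])))
    xyz[mids, ] <- xyz_mid
    vol <- .tet_volumes(xyz, dev$elems)
    if (any(vol <= 0)) stop("degenerate element after device placement")
    devices[[paste0("device_", pi)]] <-
      list(nodes = xyz, elems = dev$elems, region = dev$region,
           node_param = cbind(sp, up, vp),
           elem_param = matrix(NA_real_, nrow(dev$elems), 3),
           kind = dev$node_kind, meta = list(spec = pl$spec, s = pl$s,
                                             v = pl$v,
                                             screw_surface = dev$screw_surface,
                                             screw_id = dev$screw_id))
  }
  merged <- .merge_meshes(mesh, devices)
  merged$fixation <- list(site = mesh$fracture$site, thickness = thickness,
                          placements = placements)
  merged
}

# Closest point on triangle (a, b, c) to p; returns barycentric (l1, l2, l3).
.closest_tri_bary <- function(p, a, b, c) {
  ab <- b - a; ac <- c - a; ap <- p - a
  d1 <- sum(ab * ap); d2 <- sum(ac * ap)
  if (d1 <= 0 && d2 <= 0) return(c(1, 0, 0))
  bp <- p - b; d3 <- sum(ab * bp); d4 <- sum(ac * bp)
  if (d3 >= 0 && d4 <= d3) return(c(0, 1, 0))
  vc <- d1 * d4 - d3 * d2
  if (vc <= 0 && d1 >= 0 && d3 <= 0) {
    v <- d1 / (d1 - d3); return(c(1 - v, v, 0))
  }
  cp <- p - c; d5 <- sum(ab * cp); d6 <- sum(ac * cp)
  if (d6 >= 0 && d5 <= d6) return(c(0, 0, 1))
  vb <- d5 * d2 - d1 * d6
  if (vb <= 0 && d2 >= 0 && d6 <= 0) {
    w <- d2 / (d2 - d6); return(c(1 - w, 0, w))
  }
  va <- d3 * d6 - d5 * d4
  if (va <= 0 && (d4 - d3) >= 0 && (d5 - d6) >= 0) {
    w <- (d4 - d3) / ((d4 - d3) + (d5 - d6)); return(c(0, 1 - w, w))
  }
  den <- va + vb + vc
  v <- vb / den; w <- vc / den
  c(1 - v - w, v, w)
}

# Locate bone elements containing parametric points; returns element ids.
.locate_bone_elements <- function(mesh, spar) {
  gr <- mesh$grids
  ntc <- length(gr$t) - 1; nuc <- length(gr$u) - 1; nvc <- length(gr$v) - 1
  # bias exact-gridline coordinates towards the interior (a point on a
  # shared face belongs to either cell): s and u towards the symphysis /
  # section core so tooth-row and cortical-band boundaries resolve inward,
  # v downwards towards the bone
  eps <- 1e-9
  sb <- spar[, 1] - sign(spar[, 1]) * eps
  ub <- spar[, 2] - sign(spar[, 2]) * eps
  it <- pmin(pmax(findInterval(sb, gr$t, rightmost.closed = TRUE), 1), ntc)
  iu <- pmin(pmax(findInterval(ub, gr$u, rightmost.closed = TRUE), 1), nuc)
  iv <- pmin(pmax(findInterval(spar[, 3] - eps, gr$v, rightmost.closed = TRUE), 1), nvc)
  ck <- ((mesh$cells[, 1] - 1) * nuc + (mesh$cells[, 2] - 1)) * nvc +
    mesh$cells[, 3]
  key <- ((it - 1) * nuc + (iu - 1)) * nvc + iv
  crow <- match(key, ck)
  # points exactly on a lattice plane can bin into an excluded cell (e.g.
  # the crest outside the tooth row); fall back to an included neighbour
  if (anyNA(crow)) {
    miss <- which(is.na(crow))
    for (off in list(c(0, 0, -1), c(0, -1, 0), c(-1, 0, 0), c(1, 0, 0),
                     c(0, 1, 0), c(0, -1, -1), c(-1, 0, -1), c(1, 0, -1))) {
      if (!length(miss)) break
      it2 <- pmin(pmax(it[miss] + off[1], 1), ntc)
      iu2 <- pmin(pmax(iu[miss] + off[2], 1), nuc)
      iv2 <- pmin(pmax(iv[miss] + off[3], 1), nvc)
      tryrow <- match(((it2 - 1) * nuc + (iu2 - 1)) * nvc + iv2, ck)
      ok <- !is.na(tryrow)
      if (any(ok)) {
        crow[miss[ok]] <- tryrow[ok]
        it[miss[ok]] <- it2[ok]; iu[miss[ok]] <- iu2[ok]
        iv[miss[ok]] <- iv2[ok]
        miss <- miss[!ok]
      }
    }
    if (length(miss)) stop("tie slave lies outside the bone lattice")
  }
  xf <- (spar[, 1] - gr$t[it]) / (gr$t[it + 1] - gr$t[it])
  yf <- (spar[, 2] - gr$u[iu]) / (gr$u[iu + 1] - gr$u[iu])
  zf <- (spar[, 3] - gr$v[iv]) / (gr$v[iv + 1] - gr$v[iv])
  # sub-tet of the 6-way split from the ordering of the cell-local fractions
  tet <- ifelse(xf >= yf & yf >= zf, 1L,
         ifelse(yf >= xf & xf >= zf, 2L,
         ifelse(yf >= zf & zf >= xf, 3L,
         ifelse(zf >= yf & yf >= xf, 4L,
         ifelse(zf >= xf & xf >= yf, 5L, 6L)))))
  (crow - 1L) * 6L + tet
}

# Physical barycentric coordinates of p in the (straight) tet with corner
# coordinates X (4 x 3).
.tet_bary <- function(X, p) {
  M <- t(X[1:3, , drop = FALSE]) - X[4, ]
  lam <- solve(M, p - X[4, ])
  c(lam, 1 - sum(lam))
}

#' Build tie constraints between devices and bone
#'
#' Screw nodes embedded in the bone are constrained volumetrically to the
#' displacement interpolated by the TET10 shape functions of their host bone
#' element; screw lateral-surface nodes at plate level are projected onto the
#' nearest plate boundary face (quadratic face interpolation). Constraint
#' weights sum to one, so rigid-body motion transmits exactly and the
#' constraints generate no spurious internal force.
#'
#' @param mesh a merged `labeled_mesh` from [place_devices()].
#' @param tol maximum projection distance for plate-screw ties, mm.
#' @return object of class `tie_set` with slave node ids, master element ids,
#'   master node matrix and the interpolation weight matrix (m x 10).
#' @export
build_ties <- function(mesh, tol = 0.8) {
  if (is.null(mesh$devices)) stop("mesh carries no devices")
  g <- mesh$geom
  slave <- integer(0); melem <- integer(0)
  wts <- matrix(0, 0, 10)
  for (dn in names(mesh$devices)) {
    d <- mesh$devices[[dn]]
    ids <- d$node_offset + seq_len(d$n_nodes)
    kind <- d$kind
    spar <- mesh$node_param[ids, , drop = FALSE]
    # --- screw-bone: nodes below the bone surface
    emb <- which(kind == "screw" & spar[, 2] < g$W / 2 - 1e-9)
    if (length(emb)) {
      host <- .locate_bone_elements(mesh, spar[emb, , drop = FALSE])
      w <- matrix(0, length(emb), 10)
      for (i in seq_along(emb)) {
        Xc <- mesh$nodes[mesh$elems[host[i], 1:4], , drop = FALSE]
        lam <- .tet_bary(Xc, mesh$nodes[ids[emb[i]], ])
        w[i, ] <- fk_shape_functions(lam)
      }
      slave <- c(slave, ids[emb]); melem <- c(melem, host)
      wts <- rbind(wts, w)
    }
    # --- plate-screw: screw lateral-surface nodes at plate level
    standoff <- d$meta$spec$standoff
    band <- which(kind == "screw" & d$meta$screw_surface &
                    spar[, 2] >= g$W / 2 + standoff - 1e-9)
    if (length(band)) {
      eids <- d$elem_offset + seq_len(d$n_elems)
      pel <- eids[mesh$region[eids] == "plate"]
      sub <- mesh$elems[pel, , drop = FALSE]
      bf <- .boundary_faces(sub, nrow(mesh$nodes))
      bf[, 1] <- pel[bf[, 1]]
      cent <- .face_centroids(mesh$nodes, bf)
      for (i in band) {
        p <- mesh$nodes[ids[i], ]
        d2 <- (cent[, 1] - p[1])^2 + (cent[, 2] - p[2])^2 +
          (cent[, 3] - p[3])^2
        cand <- which(d2 <= (tol + 1.0)^2)
        if (!length(cand)) stop("tie projection: no master face near slave")
        best <- NULL; bestd <- Inf; bestlam <- NULL
        for (f in cand) {
          a <- mesh$nodes[bf[f, 2], ]; b <- mesh$nodes[bf[f, 3], ]
          cc <- mesh$nodes[bf[f, 4], ]
          lam <- .closest_tri_bary(p, a, b, cc)
          q <- lam[1] * a + lam[2] * b + lam[3] * cc
          dd <- sum((q - p)^2)
          if (dd < bestd) { bestd <- dd; best <- f; bestlam <- lam }
        }
        if (sqrt(bestd) > tol)
          stop("tie projection: slave node farther than tolerance from any master face")
        l <- bestlam
        fw <- c(l * (2 * l - 1), 4 * l[1] * l[2], 4 * l[2] * l[3],
                4 * l[3] * l[1])
        fnodes <- bf[best, 2:7]
        enodes <- mesh$elems[bf[best, 1], ]
        w <- numeric(10)
        w[match(fnodes, enodes)] <- fw
        slave <- c(slave, ids[i]); melem <- c(melem, bf[best, 1])
        wts <- rbind(wts, w)
      }
    }
  }
  master_nodes <- mesh$elems[melem, , drop = FALSE]
  if (any(master_nodes == matrix(slave, length(slave), 10)))
    stop("tie constraint references its own slave as master")
  if (any(slave %in% as.vector(master_nodes)))
    stop("tie constraint graph is cyclic")
  if (max(abs(rowSums(wts) - 1)) > 1e-9)
    stop("tie weights must sum to one")
  structure(list(slave = slave, master_elem = melem,
                 master_nodes = master_nodes, weights = wts),
            class = "tie_set")
}
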