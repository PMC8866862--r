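# Structured TET10 meshing on a logical lattice. Every included lattice cell
# is split into six tetrahedra sharing the cell's main diagonal; the split is
# translation-invariant, so shared faces of neighbouring cells carry the same
# diagonal and the mesh is conforming by construction. Midside nodes are
# inserted at the physical midpoints of the straight tet edges.

# Decomposition of the unit cell (corner bits t,u,v) into 6 positive tets.
# Corners ordered c000 c100 c010 c110 c001 c101 c011 c111 (columns 1..8).
.HEX6 <- matrix(c(1, 2, 4, 8,
                  1, 4, 3, 8,
                  1, 3, 7, 8,
                  1, 7, 5, 8,
                  1, 5, 6, 8,
                  1, 6, 2, 8), nrow = 6, byrow = TRUE)

# Build a TET10 mesh from lattice cells. tg, ug, vg: grid point vectors;
# cells: m x 3 matrix of 1-based cell indices; map: function(t, u, v) -> n x 3
# physical coordinates. Returns nodes, TET10 connectivity, node parametric
# coordinates, per-element cell row, midside bookkeeping.
.structured_tet10 <- function(tg, ug, vg, cells, map) {
  nup <- length(ug); nvp <- length(vg)
  vid <- function(i, j, k) ((i - 1) * nup + (j - 1)) * nvp + k
  it <- cells[, 1]; iu <- cells[, 2]; iv <- cells[, 3]
  corners <- cbind(vid(it,     iu,     iv),
                   vid(it + 1, iu,     iv),
                   vid(it,     iu + 1, iv),
                   vid(it + 1, iu + 1, iv),
                   vid(it,     iu,     iv + 1),
                   vid(it + 1, iu,     iv + 1),
                   vid(it,     iu + 1, iv + 1),
                   vid(it + 1, iu + 1, iv + 1))
  m <- nrow(cells)
  conn4 <- matrix(0, 6 * m, 4)
  for (tt in 1:6)
    conn4[(seq_len(m) - 1) * 6 + tt, ] <- corners[, .HEX6[tt, ], drop = FALSE]
  elem_cell <- rep(seq_len(m), each = 6)
  used <- sort(unique(as.vector(corners)))
  remap <- integer(max(used)); remap[used] <- seq_along(used)
  conn4[] <- remap[conn4]
  k0 <- (used - 1) %% nvp + 1
  j0 <- ((used - 1) %/% nvp) %% nup + 1
  i0 <- (used - 1) %/% (nvp * nup) + 1
  vpar <- cbind(tg[i0], ug[j0], vg[k0])
  vxyz <- map(vpar[, 1], vpar[, 2], vpar[, 3])
  nv <- nrow(vpar)
  # unique edges over the 6 standard TET10 edges of every element
  ep <- rbind(conn4[, c(1, 2)], conn4[, c(2, 3)], conn4[, c(3, 1)],
              conn4[, c(1, 4)], conn4[, c(2, 4)], conn4[, c(3, 4)])
  a <- pmin(ep[, 1], ep[, 2]); b <- pmax(ep[, 1], ep[, 2])
  key <- (a - 1) * nv + b
  ukey <- unique(key)
  mid_id <- match(key, ukey) + nv
  first <- !duplicated(key)
  ua <- a[first]; ub <- b[first]
  mxyz <- (vxyz[ua, , drop = FALSE] + vxyz[ub, , drop = FALSE]) / 2
  mpar <- (vpar[ua, , drop = FALSE] + vpar[ub, , drop = FALSE]) / 2
  ne <- nrow(conn4)
  conn10 <- cbind(conn4, matrix(mid_id, ne, 6))
  list(nodes = rbind(vxyz, mxyz), elems = conn10,
       node_param = rbind(vpar, mpar), n_vertex = nv,
       midpair = cbind(ua, ub), elem_cell = elem_cell)
}

# Signed volumes of the (straight) tetrahedra.
.tet_volumes <- function(nodes, elems) {
  p1 <- nodes[elems[, 1], , drop = FALSE]
  d1 <- nodes[elems[, 2], , drop = FALSE] - p1
  d2 <- nodes[elems[, 3], , drop = FALSE] - p1
  d3 <- nodes[elems[, 4], , drop = FALSE] - p1
  (d1[, 1] * (d2[, 2] * d3[, 3] - d2[, 3] * d3[, 2]) -
   d1[, 2] * (d2[, 1] * d3[, 3] - d2[, 3] * d3[, 1]) +
   d1[, 3] * (d2[, 1] * d3[, 2] - d2[, 2] * d3[, 1])) / 6
}

# Boundary faces of a TET10 mesh (faces owned by exactly one element).
# Returns a matrix with columns: element id, 3 corner node ids, 3 midside ids.
.boundary_faces <- function(elems, nnodes) {
  ne <- nrow(elems)
  faces <- rbind(elems[, c(1, 2, 3, 5, 6, 7)],
                 elems[, c(1, 2, 4, 5, 9, 8)],
                 elems[, c(2, 3, 4, 6, 10, 9)],
                 elems[, c(1, 3, 4, 7, 10, 8)])
  eid <- rep(seq_len(ne), 4)
  tri <- faces[, 1:3, drop = FALSE]
  lo <- pmin(tri[, 1], tri[, 2], tri[, 3])
  hi <- pmax(tri[, 1], tri[, 2], tri[, 3])
  md <- tri[, 1] + tri[, 2] + tri[, 3] - lo - hi
  key <- (lo * as.numeric(nnodes) + md) * nnodes + hi
  cnt <- table(key)
  bnd <- cnt[match(key, names(cnt))] == 1L
  cbind(elem = eid[bnd], faces[bnd, , drop = FALSE])
}

.face_areas <- function(nodes, faces) {
  p1 <- nodes[faces[, 2], , drop = FALSE]
  e1 <- nodes[faces[, 3], , drop = FALSE] - p1
  e2 <- nodes[faces[, 4], , drop = FALSE] - p1
  cr <- cbind(e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2],
              e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3],
              e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1])
  sqrt(rowSums(cr^2)) / 2
}

.face_centroids <- function(nodes, faces) {
  (nodes[faces[, 2], , drop = FALSE] + nodes[faces[, 3], , drop = FALSE] +
     nodes[faces[, 4], , drop = FALSE]) / 3
}

#' Build the synthetic labeled mandible mesh
#'
#' Generates the parametric mandible of [mandible_params()] as a conforming
#' quadratic tetrahedral (TET10) mesh with per-element anatomical region
#' labels (six cortical regions, trabecular core, teeth block) and the named
#' node/face sets used by loading and boundary conditions: both condyles, the
#' right occlusal patch (molar--premolar band) and seven muscle attachment
#' patches per side.
#'
#' Region labels are assigned in sweep-parameter space with grid lines
#' snapped to the cortical interfaces and segment boundaries, so region
#' volume fractions are stable under mesh refinement. The mesh is
#' mirror-symmetric about the mid-sagittal plane.
#'
#' @param params a [mandible_params()] object.
#' @return object of class `labeled_mesh`.
#' @export
build_mandible <- function(params = mandible_params()) {
  stopifnot(inherits(params, "mandible_params"))
  g <- .axis_geometry(params)
  h <- params$target_edge_length
  # t-grid: snapped right-half segments, mirrored. Segment ids:
  # 1 symphysis, 2 body (tooth row), 3 body, 4 angle bend, 5 lower ramus,
  # 6 upper ramus, 7 condylar neck, 8 condylar head.
  tb <- c(0, g$s_sym, g$t_tooth, g$s1, g$s2, (g$s2 + g$s3) / 2, g$s3, g$s4, g$s5)
  tr <- .banded_grid(tb, h)
  tg <- c(-rev(tr$pts[-1]), tr$pts)
  tseg <- c(rev(tr$seg), tr$seg)
  if (any(abs(diff(tg)) < params$cortical_thickness / 16))
    stop("cortical shell cannot be resolved at this target_edge_length")
  ur <- .banded_grid(c(-g$W / 2, -g$W / 2 + g$cort, g$W / 2 - g$cort, g$W / 2), h)
  ug <- ur$pts; useg <- ur$seg
  vr <- .banded_grid(c(-g$H / 2, -g$H / 2 + g$cort, g$H / 2 - g$cort, g$H / 2,
                       g$H / 2 + g$tooth_h), h)
  vg <- vr$pts; vseg <- vr$seg
  ntc <- length(tg) - 1; nuc <- length(ug) - 1; nvc <- length(vg) - 1
  cells <- as.matrix(expand.grid(it = seq_len(ntc), iu = seq_len(nuc),
                                 iv = seq_len(nvc)))
  csegt <- tseg[cells[, 1]]; csegu <- useg[cells[, 2]]; csegv <- vseg[cells[, 3]]
  keep <- csegv <= 3 | (csegv == 4 & csegu == 2 & csegt <= 2)
  cells <- cells[keep, , drop = FALSE]
  csegt <- csegt[keep]; csegu <- csegu[keep]; csegv <- csegv[keep]
  sc <- (tg[cells[, 1]] + tg[cells[, 1] + 1]) / 2
  uc <- (ug[cells[, 2]] + ug[cells[, 2] + 1]) / 2
  vc <- (vg[cells[, 3]] + vg[cells[, 3] + 1]) / 2
  lab <- character(nrow(cells))
  cortical <- csegu != 2 | csegv %in% c(1, 3)
  lab[!cortical] <- "trabecular"
  seg_lab <- c("symphysis", "body", "body", "angle", "ramus", "ramus",
               "condyle", "condyle")
  lab[cortical] <- seg_lab[csegt[cortical]]
  lab[cortical & csegt == 6 & vc > 0] <- "coronoid_process"
  lab[csegv == 4] <- "teeth"
  msh <- .structured_tet10(tg, ug, vg, cells,
                           function(t, u, v) .sweep_map(t, u, v, g))
  vol <- .tet_volumes(msh$nodes, msh$elems)
  if (any(vol <= 0)) stop("degenerate element: non-positive Jacobian")
  region <- rep(lab, each = 6)
  elem_param <- cbind(rep(sc, each = 6), rep(uc, each = 6), rep(vc, each = 6))
  mesh <- list(nodes = msh$nodes, elems = msh$elems, region = region,
               node_param = msh$node_param, elem_param = elem_param,
               n_vertex = msh$n_vertex, midpair = msh$midpair,
               elem_cell = msh$elem_cell,
               cells = cells, grids = list(t = tg, u = ug, v = vg),
               params = params, geom = g,
               node_sets = list(), face_sets = list(), elem_sets = list(),
               similitude = g$similitude)
  class(mesh) <- "labeled_mesh"
  mesh$faces <- .boundary_faces(mesh$elems, nrow(mesh$nodes))
  mesh <- .build_named_sets(mesh)
  mesh
}

# Muscle attachment anchor table in sweep coordinates (right side; the left
# side mirrors s). surface: lateral (u = +W/2), medial (u = -W/2),
# anterior (v = +H/2 on the ramus).
.muscle_anchors <- function(g, radius) {
  data.frame(
    name    = c("SM", "DM", "MPt", "AT", "MT", "PT", "LPt"),
    surface = c("lateral", "lateral", "medial", "anterior", "anterior",
                "anterior", "medial"),
    s = c(g$s2 + 1.0, g$s2 + 3.0, g$s2 + 1.5,
          g$s2 + 0.70 * g$Lram, g$s2 + 0.45 * g$Lram, g$s2 + 0.22 * g$Lram,
          g$s3 + 0.75 * g$Lneck),
    v = c(1.2, 0.5, 1.2, g$H / 2, g$H / 2, g$H / 2, 0),
    radius = c(radius, radius, radius, min(radius, 2.0), min(radius, 2.0),
               min(radius, 2.0), min(radius, 1.2)),
    stringsAsFactors = FALSE)
}

# Occlusal band (right molar--second premolar) as fractions of the tooth row.
.OCCLUSAL_BAND <- c(0.60, 0.92)

.build_named_sets <- function(mesh) {
  g <- mesh$geom
  fc <- mesh$faces
  np <- mesh$node_param
  tol <- 1e-6
  corner_par <- function(col) cbind(np[fc[, 2], col], np[fc[, 3], col],
                                    np[fc[, 4], col])
  us <- corner_par(2); vs <- corner_par(3); ss <- corner_par(1)
  on_surface <- function(which) {
    switch(which,
      lateral  = rowSums(abs(us - g$W / 2) < tol) == 3,
      medial   = rowSums(abs(us + g$W / 2) < tol) == 3,
      anterior = rowSums(abs(vs - g$H / 2) < tol) == 3,
      teeth_top = rowSums(abs(vs - (g$H / 2 + g$tooth_h)) < tol) == 3)
  }
  cent <- .face_centroids(mesh$nodes, fc)
  anchors <- .muscle_anchors(g, mesh$params$muscle_patch_radius)
  face_sets <- list()
  for (side in c("right", "left")) {
    sgn <- if (side == "right") 1 else -1
    for (i in seq_len(nrow(anchors))) {
      a <- anchors[i, ]
      upar <- switch(a$surface, lateral = g$W / 2, medial = -g$W / 2,
                     anterior = 0)
      vpar <- if (a$surface == "anterior") g$H / 2 else a$v
      pt <- .sweep_map(sgn * a$s, upar, vpar, g)
      d2 <- (cent[, 1] - pt[1])^2 + (cent[, 2] - pt[2])^2 + (cent[, 3] - pt[3])^2
      sel <- on_surface(a$surface) & d2 <= a$radius^2 &
        rowMeans(ss) * sgn > 0
      face_sets[[paste0(a$name, "_", side)]] <- which(sel)
    }
  }
  occ <- on_surface("teeth_top") &
    rowMeans(ss) >= .OCCLUSAL_BAND[1] * g$t_tooth &
    rowMeans(ss) <= .OCCLUSAL_BAND[2] * g$t_tooth
  face_sets[["occlusal_right"]] <- which(occ)
  empty <- names(face_sets)[vapply(face_sets, length, 1L) == 0]
  if (length(empty))
    stop("empty named face set(s): ", paste(empty, collapse = ", "))
  node_sets <- list(
    condyle_right = which(np[, 1] >= g$s5 - 1e-9),
    condyle_left  = which(np[, 1] <= -(g$s5 - 1e-9)),
    occlusal_right = sort(unique(as.vector(fc[occ, 2:7]))))
  mesh$face_sets <- face_sets
  mesh$node_sets <- node_sets
  mesh
}

#' Mesh quality metrics
#'
#' @param mesh a `labeled_mesh`.
#' @return list with element count, node count, min/mean volume, and the
#'   minimum scaled Jacobian (6*sqrt(2)*V / l_rms^3, 1 for a regular tet).
#' @export
mesh_quality <- function(mesh) {
  vol <- .tet_volumes(mesh$nodes, mesh$elems)
  el <- mesh$elems
  pairs <- list(c(1, 2), c(2, 3), c(3, 1), c(1, 4), c(2, 4), c(3, 4))
  l2 <- 0
  for (p in pairs) {
    d <- mesh$nodes[el[, p[1]], , drop = FALSE] - mesh$nodes[el[, p[2]], , drop = FALSE]
    l2 <- l2 + rowSums(d^2)
  }
  lrms <- sqrt(l2 / 6)
  sj <- 6 * sqrt(2) * vol / lrms^3
  list(n_elements = nrow(el), n_nodes = nrow(mesh$nodes),
       min_volume = min(vol), total_volume = sum(vol),
       min_scaled_jacobian = min(sj), all_positive = all(vol > 0))
}

#' Total mesh volume per region label
#'
#' @param mesh a `labeled_mesh`.
#' @return named numeric vector of volumes (mm^3).
#' @export
region_volumes <- function(mesh) {
  vol <- .tet_volumes(mesh$nodes, mesh$elems)
  tapply(vol, mesh$region, sum)
}

#' @exportS3Method print labeled_mesh
print.labeled_mesh <- function(x, ...) {
  cat("labeled_mesh:", nrow(x$nodes), "nodes,", nrow(x$elems),
      "TET10 elements\n")
  cat("regions:", paste(names(table(x$region)), table(x$region),
                        sep = "=", collapse = ", "), "\n")
  if (length(x$node_sets))
    cat("node sets:", paste(names(x$node_sets), collapse = ", "), "\n")
  if (length(x$elem_sets))
    cat("element sets:", paste(names(x$elem_sets), collapse = ", "), "\n")
  invisible(x)
}

# Merge device meshes into the bone mesh (node/element offsets; sets kept).
.merge_meshes <- function(bone, devices) {
  nodes <- bone$nodes; elems <- bone$elems; region <- bone$region
  node_param <- bone$node_param
  elem_param <- bone$elem_param
  elem_sets <- bone$elem_sets
  node_sets <- bone$node_sets
  dev_info <- list()
  for (dn in names(devices)) {
    d <- devices[[dn]]
    noff <- nrow(nodes); eoff <- nrow(elems)
    nodes <- rbind(nodes, d$nodes)
    elems <- rbind(elems, d$elems + noff)
    region <- c(region, d$region)
    node_param <- rbind(node_param, d$node_param)
    elem_param <- rbind(elem_param, d$elem_param)
    elem_sets[[dn]] <- eoff + seq_len(nrow(d$elems))
    dev_info[[dn]] <- list(node_offset = noff, elem_offset = eoff,
                           n_nodes = nrow(d$nodes), n_elems = nrow(d$elems),
                           kind = d$kind, meta = d$meta)
  }
  out <- bone
  out$nodes <- nodes; out$elems <- elems; out$region <- region
  out$node_param <- node_param; out$elem_param <- elem_param
  out$elem_sets <- elem_sets; out$node_sets <- node_sets
  out$devices <- dev_info
  out$n_bone_nodes <- nrow(bone$nodes)
  out
}
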