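# Post-operative unilateral-clenching load case. Seven mastication muscle
# groups act per side (superficial/deep masseter, anterior/medial/posterior
# temporalis, medial and inferior lateral pterygoid); the right side is the
# working side, the left the balancing side. Muscle forces are reduced to 20%
# of maximum to represent post-operative loading, and additionally scaled by
# the geometric-similitude factor of the desk-scale mandible so stress and
# strain magnitudes stay on the full-scale level.

#' Load the packaged mastication muscle table
#'
#' One row per muscle group: maximum and post-operative (20%) force
#' magnitudes, direction cosines (the X cosine flips sign between sides) and
#' fiber activation values for the working and balancing sides.
#'
#' @param path optional override CSV with the packaged columns.
#' @return data.frame of class `muscle_table`.
#' @export
load_muscle_table <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "muscles_table2.csv",
                        package = "mandifix", mustWork = TRUE)
  tb <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("name", "max_force", "postop_force", "cos_x_right", "cos_x_left",
            "cos_y", "cos_z", "act_working", "act_balancing")
  if (!setequal(names(tb), need))
    stop("muscle table schema mismatch")
  if (any(abs(tb$postop_force - 0.2 * tb$max_force) > 0.005))
    stop("post-operative forces must equal 20% of maximum forces")
  nrm <- sqrt(tb$cos_x_right^2 + tb$cos_y^2 + tb$cos_z^2)
  if (any(abs(nrm - 1) > 1e-3))
    stop("direction cosines must have unit norm (1e-3)")
  if (any(tb$act_working < 0 | tb$act_working > 1 |
          tb$act_balancing < 0 | tb$act_balancing > 1))
    stop("activations must lie in [0, 1]")
  if (any(tb$cos_x_right != -tb$cos_x_left))
    stop("X cosines must flip sign between sides")
  class(tb) <- c("muscle_table", "data.frame")
  tb
}

#' Muscle force vector for one side
#'
#' Post-operative force magnitude times the side's direction cosines times the
#' side's fiber activation. The working side uses the right cosine signs, the
#' balancing side the left.
#'
#' @param entry one row of [load_muscle_table()] (data.frame or list).
#' @param side `"working"` or `"balancing"`.
#' @return force 3-vector, N.
#' @export
muscle_force_vector <- function(entry, side = c("working", "balancing")) {
  side <- match.arg(side)
  if (side == "working")
    entry$postop_force * entry$act_working *
      c(entry$cos_x_right, entry$cos_y, entry$cos_z)
  else
    entry$postop_force * entry$act_balancing *
      c(entry$cos_x_left, entry$cos_y, entry$cos_z)
}

#' Distribute a resultant force over a surface patch
#'
#' Consistent nodal loads of a uniform traction over the quadratic triangular
#' faces of the patch. For straight-edged quadratic triangles the consistent
#' load vector puts zero on the corners and a third of each face's share on
#' every midside node; the nodal forces sum to the resultant exactly.
#'
#' @param mesh a `labeled_mesh`.
#' @param face_set integer face indices (rows of `mesh$faces`) or the name of
#'   a face set.
#' @param resultant force 3-vector, N.
#' @return data.frame with columns node, fx, fy, fz (only loaded nodes).
#' @export
distribute_on_patch <- function(mesh, face_set, resultant) {
  if (is.character(face_set)) {
    fs <- mesh$face_sets[[face_set]]
    if (is.null(fs)) stop("unknown face set '", face_set, "'")
    face_set <- fs
  }
  if (!length(face_set)) stop("empty patch")
  faces <- mesh$faces[face_set, , drop = FALSE]
  areas <- .face_areas(mesh$nodes, faces)
  total <- sum(areas)
  tr <- resultant / total          # uniform traction
  mids <- as.vector(faces[, 5:7])
  w <- rep(areas / 3, 3)
  fx <- tapply(w * tr[1], mids, sum)
  nodes <- as.integer(names(fx))
  out <- data.frame(node = nodes,
                    fx = as.numeric(fx),
                    fy = as.numeric(tapply(w * tr[2], mids, sum)),
                    fz = as.numeric(tapply(w * tr[3], mids, sum)))
  out
}

#' Build the unilateral-clenching load case and boundary conditions
#'
#' Applies every muscle resultant (force magnitude x scale x activation x
#' direction cosines x similitude) as a uniform traction over its attachment
#' patch. Boundary conditions: both condyles fixed in all three translations
#' (solid elements carry no rotational DOFs, so fixing translations over the
#' condylar patch also suppresses its rotations) and the right
#' molar--premolar occlusal nodes restrained vertically (Z).
#'
#' In convergence mode the muscle table is replaced by the single simplified
#' masseter load (Fx = 0, Fy = -50 N, Fz = 50 N) on the right superficial
#' masseter patch, as used for mesh-convergence verification.
#'
#' @param mesh a `labeled_mesh` with named sets.
#' @param table a [load_muscle_table()].
#' @param scale fraction of maximum muscle force (0.2 = post-operative).
#' @param similitude force scale factor for the desk-scale geometry; default
#'   is the mesh's own `(arch_radius/reference)^2`. Ignored in convergence
#'   mode, where the printed simplified load is applied verbatim.
#' @param convergence_mode logical.
#' @return object of class `load_case`: nodal force matrix `F` (n x 3), named
#'   patch resultants, and the `bc` boundary-condition set.
#' @export
build_load_case <- function(mesh, table = load_muscle_table(), scale = 0.2,
                            similitude = NULL, convergence_mode = FALSE) {
  if (scale < 0 || scale > 1) stop("scale must lie in [0, 1]")
  if (is.null(similitude)) similitude <- mesh$similitude
  n <- nrow(mesh$nodes)
  F <- matrix(0, n, 3)
  resultants <- list()
  if (convergence_mode) {
    res <- c(0, -50, 50)
    d <- distribute_on_patch(mesh, "SM_right", res)
    F[d$node, ] <- F[d$node, ] + as.matrix(d[, 2:4])
    resultants[["SM_right"]] <- res
  } else {
    for (i in seq_len(nrow(table))) {
      e <- table[i, ]
      for (side in c("right", "left")) {
        patch <- paste0(e$name, "_", side)
        if (is.null(mesh$face_sets[[patch]]))
          stop("missing muscle attachment patch '", patch, "'")
        role <- if (side == "right") "working" else "balancing"
        act <- if (role == "working") e$act_working else e$act_balancing
        cosx <- if (side == "right") e$cos_x_right else e$cos_x_left
        res <- e$max_force * scale * act * c(cosx, e$cos_y, e$cos_z) *
          similitude
        d <- distribute_on_patch(mesh, patch, res)
        F[d$node, ] <- F[d$node, ] + as.matrix(d[, 2:4])
        resultants[[patch]] <- res
      }
    }
  }
  ns <- mesh$node_sets
  if (!length(ns$condyle_left) || !length(ns$condyle_right) ||
      !length(ns$occlusal_right))
    stop("mesh is missing condyle/occlusal node sets")
  if (length(intersect(c(ns$condyle_left, ns$condyle_right),
                       ns$occlusal_right)))
    stop("restraint node sets must be disjoint")
  fixed <- c(rbind(3 * (ns$condyle_left - 1) + 1,
                   3 * (ns$condyle_left - 1) + 2,
                   3 * (ns$condyle_left - 1) + 3),
             rbind(3 * (ns$condyle_right - 1) + 1,
                   3 * (ns$condyle_right - 1) + 2,
                   3 * (ns$condyle_right - 1) + 3),
             3 * (ns$occlusal_right - 1) + 3)
  bc <- list(sets = list(condyle_left = ns$condyle_left,
                         condyle_right = ns$condyle_right,
                         occlusal_right = ns$occlusal_right),
             fixed_dofs = sort(unique(fixed)))
  structure(list(F = F, resultants = resultants, bc = bc, scale = scale,
                 similitude = if (convergence_mode) 1 else similitude,
                 convergence_mode = convergence_mode),
            class = "load_case")
}
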