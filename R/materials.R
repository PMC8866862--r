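# Elastic material cards and orthotropic stiffness assembly. Cortical bone is
# orthotropic in a local frame aligned with the mandibular axis (direction 1
# longitudinal, 2 tangential, 3 transverse); trabecular bone, teeth,
# granulation tissue and the device alloys/polymer are isotropic. Voigt order
# is 11, 22, 33, 12, 13, 23 with engineering shear strains.

#' Construct a material card
#'
#' @param name card label.
#' @param E1,E2,E3 elastic moduli, MPa (equal for isotropic cards).
#' @param nu12,nu23,nu13 Poisson ratios.
#' @param G12,G23,G13 shear moduli, MPa; for isotropic cards they may be `NA`,
#'   in which case `G = E/(2(1+nu))` is used.
#' @param yield_strength yield strength, MPa (device materials only).
#' @param isotropic logical flag.
#' @return object of class `material_card`.
#' @export
material_card <- function(name, E1, E2 = E1, E3 = E1,
                          nu12, nu23 = nu12, nu13 = nu12,
                          G12 = NA, G23 = G12, G13 = G12,
                          yield_strength = NA, isotropic = FALSE) {
  card <- list(name = name, E1 = E1, E2 = E2, E3 = E3,
               nu12 = nu12, nu23 = nu23, nu13 = nu13,
               G12 = G12, G23 = G23, G13 = G13,
               yield_strength = yield_strength, isotropic = isotropic)
  if (any(c(E1, E2, E3) <= 0)) stop("moduli must be positive")
  nus <- c(nu12, nu23, nu13)
  if (any(nus <= 0 | nus >= 0.5)) stop("Poisson ratios must lie in (0, 0.5)")
  if (isotropic && (E1 != E2 || E2 != E3 || nu12 != nu23 || nu23 != nu13))
    stop("isotropic card must have equal moduli and Poisson ratios")
  class(card) <- "material_card"
  # thermodynamic admissibility (positive definite compliance)
  invisible(stiffness_voigt(card))
  card
}

#' Load the packaged bone/tissue/device material table
#'
#' Returns the twelve cards used by the study: six orthotropic cortical
#' regions, isotropic trabecular bone, teeth and granulation tissue, and the
#' three device materials (Ti-6Al-4V, WE43 magnesium alloy, PLA) with their
#' yield strengths (880, 162 and 70 MPa).
#'
#' @param path optional override CSV with the same columns as the packaged
#'   table.
#' @return named list of [material_card()] objects.
#' @export
load_material_table <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "materials_table1.csv",
                        package = "mandifix", mustWork = TRUE)
  tb <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("name", "E1", "E2", "E3", "nu12", "nu23", "nu13",
            "G12", "G23", "G13", "yield_strength", "isotropic")
  if (!setequal(names(tb), need))
    stop("material table schema mismatch; expected columns: ",
         paste(need, collapse = ", "))
  cards <- lapply(seq_len(nrow(tb)), function(i) {
    r <- tb[i, ]
    material_card(r$name, r$E1, r$E2, r$E3, r$nu12, r$nu23, r$nu13,
                  r$G12, r$G23, r$G13, r$yield_strength, r$isotropic)
  })
  names(cards) <- tb$name
  cortical <- c("symphysis", "body", "angle", "ramus", "condyle",
                "coronoid_process")
  for (cn in intersect(cortical, names(cards))) {
    cc <- cards[[cn]]
    if (!(cc$E1 >= cc$E2 && cc$E2 >= cc$E3))
      stop("cortical card ", cn, " violates E1 >= E2 >= E3")
  }
  cards
}

# Shear moduli with the isotropic fallback G = E/(2(1+nu)).
.card_shear <- function(card) {
  gs <- c(card$G12, card$G23, card$G13)
  if (any(is.na(gs))) {
    if (!card$isotropic)
      stop("orthotropic card ", card$name, " is missing shear moduli")
    giso <- card$E1 / (2 * (1 + card$nu12))
    gs[is.na(gs)] <- giso
  }
  gs
}

#' Orthotropic stiffness matrix in Voigt notation
#'
#' Builds the 6x6 compliance from the engineering constants (minor Poisson
#' ratios derived by symmetry, nu_ji = nu_ij * E_j / E_i) and returns its
#' inverse. Voigt order 11, 22, 33, 12, 13, 23; engineering shear.
#'
#' @param card a [material_card()].
#' @return symmetric positive-definite 6x6 matrix, MPa.
#' @export
stiffness_voigt <- function(card) {
  gs <- .card_shear(card)
  S <- matrix(0, 6, 6)
  S[1, 1] <- 1 / card$E1; S[2, 2] <- 1 / card$E2; S[3, 3] <- 1 / card$E3
  S[1, 2] <- S[2, 1] <- -card$nu12 / card$E1
  S[1, 3] <- S[3, 1] <- -card$nu13 / card$E1
  S[2, 3] <- S[3, 2] <- -card$nu23 / card$E2
  S[4, 4] <- 1 / gs[1]   # G12
  S[5, 5] <- 1 / gs[3]   # G13
  S[6, 6] <- 1 / gs[2]   # G23
  ev <- eigen(S, symmetric = TRUE, only.values = TRUE)$values
  if (any(ev <= 0))
    stop("material card ", card$name,
         " is thermodynamically inadmissible (compliance not PD)")
  C <- solve(S)
  (C + t(C)) / 2
}

#' Rotate a Voigt stiffness matrix into global coordinates
#'
#' Full fourth-order tensor rotation of the stiffness given in a local
#' orthonormal frame. Strain energy density is invariant under the
#' transformation.
#'
#' @param C 6x6 stiffness in the local frame.
#' @param frame 3x3 matrix whose rows are the local basis vectors e1
#'   (longitudinal), e2 (tangential), e3 (transverse) in global coordinates.
#' @return 6x6 stiffness in global coordinates.
#' @export
rotate_stiffness <- function(C, frame) {
  frame <- as.matrix(frame)
  if (max(abs(frame %*% t(frame) - diag(3))) > 1e-8)
    stop("frame is not orthonormal")
  if (det(frame) < 0) stop("frame is not right-handed")
  fk_rotate_stiffness(C, frame)
}

# Map mesh region labels to material card names.
.region_card <- function(region, device_material) {
  out <- region
  out[region %in% c("plate", "screw")] <- device_material
  out
}

#' Assign material cards and local frames to every element
#'
#' Cortical elements receive their regional orthotropic card in a local frame
#' whose first axis follows the mandibular axis tangent; trabecular, teeth and
#' granulation elements get their isotropic cards; plate and screw elements
#' get the chosen device card.
#'
#' @param mesh a `labeled_mesh` (optionally with fracture/devices merged).
#' @param device_material `"Ti-6Al-4V"`, `"WE43"` or `"PLA"` (any card name).
#' @param cards material table, as from [load_material_table()].
#' @param override named list of replacement [material_card()]s (used e.g. by
#'   the convergence mode to impose isotropic bone properties).
#' @return object of class `material_assignment` with per-element rotated
#'   stiffness rows, card names and the yield-strength lookup.
#' @export
assign_materials <- function(mesh, device_material = "Ti-6Al-4V",
                             cards = load_material_table(),
                             override = NULL) {
  if (!is.null(override)) for (nm in names(override)) cards[[nm]] <- override[[nm]]
  cortical <- c("symphysis", "body", "angle", "ramus", "condyle",
                "coronoid_process")
  cname <- .region_card(mesh$region, device_material)
  bad <- setdiff(unique(cname), names(cards))
  if (length(bad)) stop("no material card for label(s): ",
                        paste(bad, collapse = ", "))
  ne <- nrow(mesh$elems)
  Cm <- matrix(0, ne, 36)
  frames <- matrix(rep(c(1, 0, 0, 0, 1, 0, 0, 0, 1), ne), ne, 9, byrow = TRUE)
  for (nm in unique(cname)) {
    idx <- which(cname == nm)
    C <- stiffness_voigt(cards[[nm]])
    if (nm %in% cortical && !isTRUE(cards[[nm]]$isotropic)) {
      fr <- .sweep_frame(mesh$elem_param[idx, 1], mesh$geom)
      frames[idx, ] <- fr
      Cm[idx, ] <- fk_rotate_batch(C, fr)
    } else {
      Cm[idx, ] <- matrix(rep(as.vector(t(C)), length(idx)),
                          length(idx), 36, byrow = TRUE)
    }
  }
  structure(list(Cm = Cm, card_name = cname, frames = frames, cards = cards,
                 device_material = device_material),
            class = "material_assignment")
}
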