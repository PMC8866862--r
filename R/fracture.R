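#' Fracture scenario specification
#'
#' A simple fracture is modeled as a thin gap slab across the full bone
#' section, filled with soft granulation tissue (the healing region) rather
#' than topologically splitting the mesh: load transfer happens through the
#' granulation tissue and the fixation device, and interfragmentary strains
#' are evaluated inside the slab.
#'
#' @param site one of `"symphysis"`, `"body"`, `"angle"`, `"condylar_neck"`.
#' @param gap_width slab thickness along the axis normal, mm (default 1.2).
#' @return object of class `fracture_spec`.
#' @export
fracture_spec <- function(site = c("symphysis", "body", "angle",
                                   "condylar_neck"),
                          gap_width = 1.2) {
  site <- match.arg(site)
  if (!is.finite(gap_width) || gap_width < 1.0 || gap_width > 2.0)
    stop("gap_width must lie in [1.0, 2.0] mm")
  structure(list(site = site, gap_width = gap_width),
            class = "fracture_spec")
}

# Axis position of each fracture site (signed arc length, right side).
.fracture_axis_position <- function(g, site) {
  # angle fractures run obliquely behind the molar region, i.e. through the
  # anterior part of the angle bend; neck fractures sit on the lower neck
  switch(site,
         symphysis     = 0,
         body          = (g$t_tooth + g$s1) / 2,
         angle         = g$s1 + 2.0,
         condylar_neck = g$s3 + 1.2)
}

#' Insert a fracture gap into the mandible mesh
#'
#' Relabels all elements whose parametric centroid lies within the gap slab
#' as `granulation` and records them as the `healing_region` element set.
#' Inserting the same spec twice is a no-op; a second, different fracture is
#' rejected.
#'
#' @param mesh a `labeled_mesh` from [build_mandible()].
#' @param spec a [fracture_spec()].
#' @return the modified `labeled_mesh`.
#' @export
insert_fracture <- function(mesh, spec) {
  stopifnot(inherits(mesh, "labeled_mesh"), inherits(spec, "fracture_spec"))
  if (!is.null(mesh$fracture)) {
    if (identical(mesh$fracture, spec)) return(mesh)
    stop("mesh already carries a different fracture")
  }
  g <- mesh$geom
  s_f <- .fracture_axis_position(g, spec$site)
  # snap the cut plane to the nearest lattice column so the realized slab
  # thickness (in cell layers) is identical across fracture sites; the
  # tie-break at the symphysis midline picks the right side (paramedian cut)
  centers <- sort(unique(mesh$elem_param[, 1]))
  d <- abs(centers - s_f)
  cand <- centers[d == min(d)]
  s_f <- max(cand)
  in_slab <- abs(mesh$elem_param[, 1] - s_f) <= spec$gap_width / 2
  if (!any(in_slab)) stop("fracture slab does not intersect the solid")
  slab_elems <- which(in_slab)
  guarded <- c(mesh$face_sets, list())
  for (fs in names(guarded)) {
    felems <- mesh$faces[guarded[[fs]], 1]
    if (any(felems %in% slab_elems))
      stop("fracture slab intersects named surface set '", fs, "'")
  }
  mesh$region[slab_elems] <- "granulation"
  mesh$elem_sets$healing_region <- slab_elems
  mesh$fracture <- spec
  mesh
}
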