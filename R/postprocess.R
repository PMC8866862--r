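# Post-processing of integration-point fields: principal strains in the
# healing region (dominant tensile/compressive selection, 15% interfragmentary
# strain criterion) and peak device von Mises stress with the top-0.1%
# exclusion / 10-highest-average rule, expressed as a fraction of the device
# material's yield strength.

# Voigt (11,22,33,12,13,23, engineering shear) -> symmetric 3x3 tensor.
.voigt_to_tensor <- function(v, shear_factor = 0.5) {
  matrix(c(v[1], shear_factor * v[4], shear_factor * v[5],
           shear_factor * v[4], v[2], shear_factor * v[6],
           shear_factor * v[5], shear_factor * v[6], v[3]), 3, 3)
}

#' Maximum and minimum principal strains of a strain tensor
#'
#' @param tensor symmetric 3x3 strain tensor, or a length-6 Voigt vector with
#'   engineering shear.
#' @return c(eps_max, eps_min), the largest and smallest eigenvalues.
#' @export
principal_strains <- function(tensor) {
  if (is.numeric(tensor) && length(tensor) == 6)
    tensor <- .voigt_to_tensor(tensor)
  if (max(abs(tensor - t(tensor))) > 1e-10)
    stop("strain tensor is not symmetric")
  ev <- eigen((tensor + t(tensor)) / 2, symmetric = TRUE,
              only.values = TRUE)$values
  c(ev[1], ev[3])
}

#' Dominant (largest-magnitude) principal strain
#'
#' Keeps whichever of the maximum and minimum principal strains has the
#' larger absolute value, preserving its sign; ties resolve to the tensile
#' (maximum) value.
#'
#' @param eps_max,eps_min principal strains with `eps_max >= eps_min`.
#' @return signed scalar.
#' @export
dominant_strain <- function(eps_max, eps_min) {
  if (any(eps_max < eps_min)) stop("eps_max must be >= eps_min")
  ifelse(abs(eps_max) >= abs(eps_min), eps_max, eps_min)
}

#' von Mises equivalent stress
#'
#' @param stress symmetric 3x3 stress tensor, a length-6 Voigt vector, or a
#'   matrix of Voigt rows.
#' @return scalar (or vector) equivalent stress, MPa.
#' @export
von_mises <- function(stress) {
  if (is.matrix(stress) && ncol(stress) == 6) {
    s <- stress
  } else if (is.numeric(stress) && length(stress) == 6) {
    s <- matrix(stress, 1, 6)
  } else {
    t3 <- as.matrix(stress)
    s <- matrix(c(t3[1, 1], t3[2, 2], t3[3, 3], t3[1, 2], t3[1, 3],
                  t3[2, 3]), 1, 6)
  }
  sqrt(0.5 * ((s[, 1] - s[, 2])^2 + (s[, 2] - s[, 3])^2 +
                (s[, 3] - s[, 1])^2) +
         3 * (s[, 4]^2 + s[, 5]^2 + s[, 6]^2))
}

#' Peak device stress with singularity exclusion
#'
#' Sorts the integration-point von Mises values, excludes the top 0.1%
#' (ceil(0.001 N) values, guarding against stress singularities at the tie
#' constraints) and averages the 10 next-highest values. The yield ratio is
#' the peak divided by the device material's yield strength.
#'
#' @param values per-point von Mises stresses, MPa (at least 20).
#' @param yield_strength device yield strength, MPa.
#' @return object of class `device_peak`: peak (MPa), yield_ratio, elastic
#'   flag, number of points and number excluded.
#' @export
peak_device_stress <- function(values, yield_strength) {
  n <- length(values)
  if (n < 20) stop("need at least 20 stress values")
  drop <- ceiling(0.001 * n)
  srt <- sort(values, decreasing = TRUE)
  kept <- srt[-seq_len(drop)]
  if (length(kept) < 10) stop("too few values after exclusion")
  peak <- mean(kept[1:10])
  structure(list(peak = peak, yield_ratio = peak / yield_strength,
                 elastic = peak < yield_strength, n = n, n_excluded = drop),
            class = "device_peak")
}

.box_stats <- function(x) {
  if (!length(x))
    return(c(min = NA, q1 = NA, median = NA, q3 = NA, max = NA))
  q <- stats::quantile(x, c(0.25, 0.5, 0.75), names = FALSE)
  c(min = min(x), q1 = q[1], median = q[2], q3 = q[3], max = max(x))
}

#' Summarize healing-region strains
#'
#' Computes the dominant principal strain at every integration point of the
#' healing region, splits the points into tensile and compressive subsets by
#' its sign (zero counts as tensile), and reports box statistics (min, Q1,
#' median, Q3, max) per subset in percent, plus the fraction of points below
#' the 15% interfragmentary strain criterion.
#'
#' @param solution an `fe_solution`.
#' @param mesh the solved `labeled_mesh` (for the healing element set).
#' @param volume_weighted if TRUE, quartiles are weighted by integration-point
#'   volume shares; default is unweighted over points.
#' @return object of class `healing_summary`.
#' @export
summarize_healing <- function(solution, mesh = solution$system$mesh,
                              volume_weighted = FALSE) {
  hs <- mesh$elem_sets$healing_region
  if (is.null(hs) || !length(hs)) stop("healing region is empty")
  sel <- solution$element %in% hs
  if (!any(sel)) stop("no integration points in the healing region")
  eps <- solution$strain[sel, , drop = FALSE]
  dom <- numeric(nrow(eps))
  for (i in seq_len(nrow(eps))) {
    pr <- principal_strains(eps[i, ])
    dom[i] <- dominant_strain(pr[1], pr[2])
  }
  w <- if (volume_weighted) solution$weight[sel] else rep(1, length(dom))
  wbox <- function(x, wx) {
    if (!length(x)) return(c(min = NA, q1 = NA, median = NA, q3 = NA, max = NA))
    ord <- order(x)
    cw <- cumsum(wx[ord]) / sum(wx)
    qf <- function(p) x[ord][which(cw >= p)[1]]
    c(min = min(x), q1 = qf(0.25), median = qf(0.5), q3 = qf(0.75),
      max = max(x))
  }
  box <- if (volume_weighted) wbox else function(x, wx) .box_stats(x)
  tens <- dom >= 0
  wmed <- wbox(abs(dom), w)["median"]
  structure(list(
    dominant_pct = 100 * dom,
    tensile = 100 * box(dom[tens], w[tens]),
    compressive = 100 * box(abs(dom[!tens]), w[!tens]),
    median_abs_pct = 100 * unname(
      if (volume_weighted) wmed else stats::median(abs(dom))),
    fraction_below_15 = sum(w * (abs(dom) < 0.15)) / sum(w),
    n_points = length(dom)), class = "healing_summary")
}

#' Peak von Mises stress of the fixation devices in a solved scenario
#'
#' @param solution an `fe_solution` of a merged bone+device model.
#' @param yield_strength yield strength of the device material, MPa (looked
#'   up from the material assignment when NULL).
#' @return a `device_peak` (see [peak_device_stress()]).
#' @export
device_peak <- function(solution, yield_strength = NULL) {
  sel <- solution$region %in% c("plate", "screw")
  if (!any(sel)) stop("solution carries no device elements")
  if (is.null(yield_strength)) {
    mat <- solution$system$materials
    yield_strength <- mat$cards[[mat$device_material]]$yield_strength
  }
  vm <- von_mises(solution$stress[sel, , drop = FALSE])
  peak_device_stress(vm, yield_strength)
}

#' Volume-weighted average von Mises stress over a region label
#'
#' @param solution an `fe_solution`.
#' @param region region label (e.g. "symphysis").
#' @return scalar MPa.
#' @export
region_average_vm <- function(solution, region) {
  sel <- solution$region == region
  if (!any(sel)) stop("no integration points in region ", region)
  vm <- von_mises(solution$stress[sel, , drop = FALSE])
  sum(vm * solution$weight[sel]) / sum(solution$weight[sel])
}

#' Volume-weighted average principal strains over a region label
#'
#' @param solution an `fe_solution`.
#' @param region region label.
#' @return c(eps_max, eps_min) averages.
#' @export
region_average_principal <- function(solution, region) {
  sel <- which(solution$region == region)
  if (!length(sel)) stop("no integration points in region ", region)
  pr <- vapply(sel, function(i) principal_strains(solution$strain[i, ]),
               numeric(2))
  w <- solution$weight[sel]
  c(sum(pr[1, ] * w), sum(pr[2, ] * w)) / sum(w)
}
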