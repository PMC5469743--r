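# Trajectory metrics and microscopy quantification.
#
# The image procedures mirror how the experimental data were measured:
# boundary-normalized radial intensity profiles for penetration depth,
# whole-vs-core ROI intensity increases, nuclear-stain blob segmentation
# with intensity and area gates, positive-area fractions, and Euclidean
# distances from stained regions to the nearest vessel.

# internal: linear interpolation of a trajectory's radius at time t
traj_radius_at <- function(traj, t) {
  if (t < min(traj$t_h) - 1e-9 || t > max(traj$t_h) + 1e-9)
    stop(sprintf("time %g h outside trajectory span [%g, %g]",
                 t, min(traj$t_h), max(traj$t_h)))
  stats::approx(traj$t_h, traj$radius_um, xout = t, rule = 2)$y
}

#' Percent radius regression relative to dosing time
#'
#' `100 * (1 - r(t) / r(t_dose))`, with linear interpolation between
#' trajectory samples.
#'
#' @param traj A trajectory from [run_schedule()].
#' @param t Evaluation time (h).
#' @param t_dose Dosing time (h); defaults to the trajectory's first
#'   recorded dose, or its start.
#' @export
regression_percent <- function(traj, t, t_dose = NULL) {
  if (is.null(t_dose)) {
    dt0 <- attr(traj, "dose_times")
    t_dose <- if (length(dt0) > 0) dt0[1] else traj$t_h[1]
  }
  if (t < t_dose) stop("regression_percent: t must not precede the dose")
  100 * (1 - traj_radius_at(traj, t) / traj_radius_at(traj, t_dose))
}

#' Minimal tumor size along a trajectory
#'
#' @param traj A trajectory.
#' @return List with `fraction` (global minimum of `r(t)/r(0)`) and `t_h`
#'   (time of the minimum; ties resolved to the earliest sample).
#' @export
minimal_size <- function(traj) {
  if (nrow(traj) == 0) stop("minimal_size: empty trajectory")
  frac <- traj$radius_um / traj$radius_um[1]
  i <- which.min(frac) # which.min returns the first (earliest) minimum
  list(fraction = frac[i], t_h = traj$t_h[i])
}

#' Treated radius as a fraction of untreated control
#'
#' @param treated,control Trajectories sharing the time span.
#' @param t Evaluation time (h).
#' @export
fraction_of_control <- function(treated, control, t) {
  rc <- traj_radius_at(control, t)
  if (rc <= 0) stop("fraction_of_control: control radius is zero at t")
  traj_radius_at(treated, t) / rc
}

#' Circular region-of-interest specification
#'
#' The core radius is fixed at half the whole-spheroid radius.
#'
#' @param center Length-2 vector `(x, y)` in pixels.
#' @param outer Whole-spheroid radius in pixels.
#' @return Object of class `roi_spec` with `center`, `outer`, `core`.
#' @export
roi_spec <- function(center, outer) {
  if (outer <= 0) stop("roi_spec: outer radius must be > 0")
  structure(list(center = as.numeric(center), outer = as.numeric(outer),
                 core = as.numeric(outer) / 2), class = "roi_spec")
}

# internal: pixel-center distances from roi center; image indexed [row=y, col=x]
pixel_radii <- function(image, roi) {
  ny <- nrow(image); nx <- ncol(image)
  xs <- matrix(rep(seq_len(nx), each = ny), ny, nx)
  ys <- matrix(rep(seq_len(ny), nx), ny, nx)
  sqrt((xs - roi$center[1])^2 + (ys - roi$center[2])^2)
}

#' Boundary-normalized radial intensity profile
#'
#' Bins pixel intensities by depth from the spheroid boundary inward and
#' divides by the outermost bin's mean, so the profile starts at 1 at the
#' boundary. Empty bins are reported as `NA` (never interpolated).
#'
#' @param image Grey-level image matrix.
#' @param roi An [roi_spec()] lying within the image.
#' @param n_bins Number of radial bins.
#' @param pixel_size_um Physical pixel size (um) used for the depth axis.
#' @return Data frame with `depth_um` (bin centers, boundary = 0 inward) and
#'   `intensity` (normalized mean).
#' @export
radial_profile <- function(image, roi, n_bins = 25, pixel_size_um = 1) {
  r <- pixel_radii(image, roi)
  if (roi$center[1] - roi$outer < 0.5 || roi$center[2] - roi$outer < 0.5 ||
      roi$center[1] + roi$outer > ncol(image) + 0.5 ||
      roi$center[2] + roi$outer > nrow(image) + 0.5)
    stop("radial_profile: roi extends beyond the image")
  inside <- r <= roi$outer
  depth <- (roi$outer - r[inside]) * pixel_size_um
  vals <- image[inside]
  edges <- seq(0, roi$outer * pixel_size_um, length.out = n_bins + 1)
  bin <- cut(depth, edges, include.lowest = TRUE, labels = FALSE)
  means <- rep(NA_real_, n_bins)
  agg <- tapply(vals, bin, mean)
  means[as.integer(names(agg))] <- agg
  if (is.na(means[1]) || means[1] == 0)
    stop("radial_profile: outermost bin is empty or zero; cannot normalize")
  data.frame(depth_um = (edges[-1] + edges[-(n_bins + 1)]) / 2,
             intensity = means / means[1])
}

#' Penetration depth from a normalized radial profile
#'
#' First depth at which the profile falls below `threshold` (default 1/e of
#' the boundary value), linearly interpolated between bins. Returns `Inf`
#' ("beyond measured range") if the profile never crosses the threshold.
#'
#' @param profile Data frame from [radial_profile()] (`depth_um`,
#'   `intensity`, with the boundary bin normalized to 1).
#' @param threshold Crossing threshold.
#' @export
penetration_depth <- function(profile, threshold = exp(-1)) {
  d <- profile$depth_um; v <- profile$intensity
  ok <- !is.na(v)
  d <- d[ok]; v <- v[ok]
  if (abs(v[1] - 1) > 1e-6)
    stop("penetration_depth: profile must be boundary-normalized (starts at 1)")
  below <- which(v < threshold)
  if (length(below) == 0) return(Inf)
  i <- below[1]
  if (i == 1) return(d[1])
  d[i - 1] + (v[i - 1] - threshold) / (v[i - 1] - v[i]) * (d[i] - d[i - 1])
}

#' Whole-spheroid and core intensity increase over untreated
#'
#' `100 * (mean_treated / mean_untreated - 1)` within the whole-spheroid
#' disk and within the half-radius core disk.
#'
#' @param treated_img,untreated_img Matched grey-level images.
#' @param roi An [roi_spec()] shared by both images.
#' @return Named vector `c(whole = %, core = %)`.
#' @export
core_periphery_increase <- function(treated_img, untreated_img, roi) {
  if (!all(dim(treated_img) == dim(untreated_img)))
    stop("core_periphery_increase: image dimensions differ")
  r <- pixel_radii(treated_img, roi)
  whole <- r <= roi$outer
  core <- r <= roi$core
  mu_w <- mean(untreated_img[whole]); mu_c <- mean(untreated_img[core])
  if (mu_w == 0 || mu_c == 0)
    stop("core_periphery_increase: untreated mean intensity is zero")
  c(whole = 100 * (mean(treated_img[whole]) / mu_w - 1),
    core = 100 * (mean(treated_img[core]) / mu_c - 1))
}

#' Segmentation parameters for nuclear-stain blobs
#'
#' @param intensity_offset Threshold above background (grey levels).
#' @param area_min,area_max Strict area gates (pixels^2).
#' @param exclude_edges Drop components touching the frame edge.
#' @export
segmentation_params <- function(intensity_offset = 750, area_min = 100,
                                area_max = 1000, exclude_edges = TRUE) {
  if (!(area_min > 0 && area_min < area_max))
    stop("segmentation_params: need 0 < area_min < area_max")
  structure(list(intensity_offset = intensity_offset, area_min = area_min,
                 area_max = area_max, exclude_edges = exclude_edges),
            class = "segmentation_params")
}

# internal: 8-connected component labeling (two-pass union-find)
label_components_8 <- function(mask) {
  ny <- nrow(mask); nx <- ncol(mask)
  labels <- matrix(0L, ny, nx)
  parent <- integer(0)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  nlab <- 0L
  for (x in seq_len(nx)) {
    for (y in seq_len(ny)) {
      if (!mask[y, x]) next
      nb <- integer(0)
      if (x > 1) {
        if (mask[y, x - 1]) nb <- c(nb, labels[y, x - 1])
        if (y > 1 && mask[y - 1, x - 1]) nb <- c(nb, labels[y - 1, x - 1])
        if (y < ny && mask[y + 1, x - 1]) nb <- c(nb, labels[y + 1, x - 1])
      }
      if (y > 1 && mask[y - 1, x]) nb <- c(nb, labels[y - 1, x])
      if (length(nb) == 0) {
        nlab <- nlab + 1L
        parent[nlab] <- nlab
        labels[y, x] <- nlab
      } else {
        roots <- vapply(unique(nb), find, integer(1))
        r0 <- min(roots)
        labels[y, x] <- r0
        for (r in roots) parent[r] <- r0
      }
    }
  }
  if (nlab > 0) {
    roots <- vapply(seq_len(nlab), find, integer(1))
    relab <- match(roots, sort(unique(roots)))
    nz <- labels > 0
    labels[nz] <- relab[labels[nz]]
  }
  labels
}

#' Segment nuclear-stain (dead-cell) blobs
#'
#' Thresholds the image at `background_level + intensity_offset`, labels
#' 8-connected components, keeps those with `area_min < area < area_max`
#' (strict), and discards components overlapping the frame edge.
#'
#' @param image Grey-level image matrix.
#' @param background_level Background intensity.
#' @param p A [segmentation_params()].
#' @return Data frame with one row per accepted blob: `x`, `y` (centroid,
#'   pixels) and `area` (pixels^2).
#' @export
draq7_segment <- function(image, background_level, p = segmentation_params()) {
  if (!is.matrix(image)) stop("draq7_segment: image must be a 2D matrix")
  mask <- image >= background_level + p$intensity_offset
  if (!any(mask))
    return(data.frame(x = numeric(), y = numeric(), area = numeric()))
  labels <- label_components_8(mask)
  ny <- nrow(image); nx <- ncol(image)
  ids <- which(labels > 0)
  lab <- labels[ids]
  ys <- ((ids - 1L) %% ny) + 1L
  xs <- ((ids - 1L) %/% ny) + 1L
  area <- tabulate(lab)
  cx <- tapply(xs, lab, mean); cy <- tapply(ys, lab, mean)
  on_edge <- tapply(xs == 1 | xs == nx | ys == 1 | ys == ny, lab, any)
  keep <- area > p$area_min & area < p$area_max
  if (p$exclude_edges) keep <- keep & !on_edge
  data.frame(x = as.numeric(cx[keep]), y = as.numeric(cy[keep]),
             area = as.numeric(area[keep]), row.names = NULL)
}

#' Flag membrane-retracted cells
#'
#' A cell is retracted when its area decreased by at least 33%:
#' `(before - after) / before >= 0.33`.
#'
#' @param areas_before,areas_after Paired positive cell areas.
#' @return Logical vector of retraction flags.
#' @export
classify_retracted <- function(areas_before, areas_after) {
  if (length(areas_before) != length(areas_after))
    stop("classify_retracted: before/after vectors must pair up")
  if (any(areas_before <= 0) || any(areas_after <= 0))
    stop("classify_retracted: areas must be positive")
  (areas_before - areas_after) / areas_before >= 0.33
}

#' Percent of image area above a threshold
#'
#' @param image Image matrix.
#' @param threshold Positivity threshold (strictly above).
#' @export
area_fraction_positive <- function(image, threshold) {
  100 * mean(image > threshold)
}

#' Distances from positive pixels to the nearest vessel
#'
#' Exact Euclidean distance transform from the vessel mask, sampled at the
#' positive pixels and scaled to micrometers.
#'
#' @param positive_mask,vessel_mask Logical/0-1 matrices of equal shape.
#' @param pixel_size_um Physical pixel size (um).
#' @return Numeric vector of distances (um), one per positive pixel.
#' @export
distances_to_vessels <- function(positive_mask, vessel_mask, pixel_size_um = 1) {
  if (!all(dim(positive_mask) == dim(vessel_mask)))
    stop("distances_to_vessels: masks must share a shape")
  if (!any(vessel_mask > 0)) stop("distances_to_vessels: vessel mask is empty")
  d <- EBImage::imageData(EBImage::distmap(1 - (vessel_mask > 0)))
  as.numeric(d[positive_mask > 0]) * pixel_size_um
}

#' Percent cytostaticity relative to an untreated control
#'
#' Growth suppression relative to control:
#' `100 * (1 - (n_end_treated - n0) / (n_end_control - n0))`.
#'
#' @param n0 Initial cell count (> 0).
#' @param n_end_treated,n_end_control Final counts; the control must have
#'   grown (`n_end_control > n0`).
#' @export
cytostaticity_percent <- function(n0, n_end_treated, n_end_control) {
  if (n0 <= 0) stop("cytostaticity_percent: n0 must be > 0")
  if (n_end_control <= n0)
    stop("cytostaticity_percent: undefined when the control did not grow")
  100 * (1 - (n_end_treated - n0) / (n_end_control - n0))
}
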