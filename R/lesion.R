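# Lesion state and tissue-region classification.
#
# The tumor is described by volume fractions on the grid: `phi` (viable
# tumor) and `nec` (necrotic debris). A node belongs to the lesion when
# phi + nec > 0.5. Within the lesion, nodes are labeled by the local
# oxygen level sigma (dimensionless, vessel level = 1):
#   proliferating  sigma >= sigma_P
#   hypoxic        sigma_N <= sigma < sigma_P
#   necrotic       sigma < sigma_N, or necrotic debris dominates (nec > phi)

REGION_LEVELS <- c("host", "proliferating", "hypoxic", "necrotic")
REGION_HOST <- 0L; REGION_PROLIF <- 1L; REGION_HYPOXIC <- 2L; REGION_NECROTIC <- 3L

#' Oxygen thresholds separating tissue regions
#'
#' @param sigma_P Proliferation threshold (viable tissue proliferates at or
#'   above this oxygen level).
#' @param sigma_N Necrosis threshold (viable tissue dies below this level).
#'   Both are dimensionless oxygen concentrations with the vessel level
#'   normalized to 1; `0 < sigma_N < sigma_P < 1` is required.
#' @return Object of class `tissue_thresholds`.
#' @export
tissue_thresholds <- function(sigma_P = 0.35, sigma_N = 0.08) {
  if (!(sigma_N > 0 && sigma_N < sigma_P && sigma_P < 1))
    stop("tissue_thresholds: need 0 < sigma_N < sigma_P < 1")
  structure(list(sigma_P = sigma_P, sigma_N = sigma_N),
            class = "tissue_thresholds")
}

#' Create a lesion state
#'
#' @param grid A [sim_grid()].
#' @param phi Viable tumor volume fraction field (in `[0, 1]`).
#' @param nec Necrotic volume fraction field (in `[0, 1]`, `phi + nec <= 1`).
#' @param t Simulation time in hours.
#' @return Object of class `lesion_state` with fields `phi`, `nec`, `labels`
#'   (integer region codes, see [region_labels()]), `t` and `grid`.
#' @export
lesion_state <- function(grid, phi = scalar_field(grid), nec = scalar_field(grid),
                         t = 0) {
  phi <- scalar_field(grid, phi); nec <- scalar_field(grid, nec)
  if (any(phi < -1e-12) || any(nec < -1e-12) || any(phi + nec > 1 + 1e-9))
    stop("lesion_state: need phi, nec >= 0 and phi + nec <= 1 everywhere")
  labels <- matrix(REGION_HOST, grid$ny, grid$nx)
  labels[phi + nec > 0.5] <- REGION_HYPOXIC
  structure(list(phi = phi, nec = nec, labels = labels, t = t, grid = grid),
            class = "lesion_state")
}

#' @export
print.lesion_state <- function(x, ...) {
  cat(sprintf("<lesion_state t = %.1f h, radius = %.1f um, %d tumor nodes>\n",
              x$t, effective_radius(x), sum(tumor_mask(x))))
  invisible(x)
}

#' Lesion support mask
#'
#' Logical matrix marking nodes occupied by the lesion (`phi + nec > 0.5`).
#' @param lesion A [lesion_state()].
#' @export
tumor_mask <- function(lesion) (lesion$phi + lesion$nec) > 0.5

#' Region label codes
#'
#' Returns the named integer codes used in `lesion$labels`:
#' host = 0, proliferating = 1, hypoxic = 2, necrotic = 3.
#' @export
region_labels <- function() {
  stats::setNames(c(REGION_HOST, REGION_PROLIF, REGION_HYPOXIC, REGION_NECROTIC),
                  REGION_LEVELS)
}

#' Classify tissue regions from the oxygen field
#'
#' Labels every lesion node as proliferating, hypoxic or necrotic according
#' to the local oxygen concentration and the necrotic-debris content; all
#' other nodes are host.
#'
#' @param sigma Oxygen field on the lesion's grid.
#' @param lesion A [lesion_state()].
#' @param thr A [tissue_thresholds()].
#' @return The lesion with updated `labels`.
#' @export
classify_tissue <- function(sigma, lesion, thr) {
  check_field(sigma, lesion$grid, "sigma")
  stopifnot(inherits(thr, "tissue_thresholds"))
  inside <- tumor_mask(lesion)
  lab <- matrix(REGION_HOST, lesion$grid$ny, lesion$grid$nx)
  lab[inside] <- REGION_HYPOXIC
  lab[inside & sigma >= thr$sigma_P] <- REGION_PROLIF
  lab[inside & (sigma < thr$sigma_N | lesion$nec > lesion$phi)] <- REGION_NECROTIC
  lesion$labels <- lab
  lesion
}

#' Tissue-region fractions of the lesion
#'
#' @param lesion A classified [lesion_state()].
#' @return Named numeric vector `c(fP, fH, fN)`: fractions of lesion nodes
#'   labeled proliferating, hypoxic and necrotic (summing to 1).
#' @export
tissue_fractions <- function(lesion) {
  inside <- tumor_mask(lesion)
  n <- sum(inside)
  if (n == 0) stop("tissue_fractions: lesion has no tumor nodes")
  lab <- lesion$labels[inside]
  c(fP = sum(lab == REGION_PROLIF) / n,
    fH = sum(lab == REGION_HYPOXIC) / n,
    fN = sum(lab == REGION_NECROTIC) / n)
}

#' Effective lesion radius
#'
#' Radius (um) of the disk with the same area as the lesion support:
#' `sqrt(area / pi)` with `area = n_tumor_nodes * h^2`. Returns 0 for an
#' empty lesion.
#'
#' @param lesion A [lesion_state()].
#' @export
effective_radius <- function(lesion) {
  n <- sum(tumor_mask(lesion))
  sqrt(n * lesion$grid$h^2 / pi)
}
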