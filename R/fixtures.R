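# Synthetic fixtures with planted ground truth.
#
# Every generator is a pure function of (spec, seed): fixed seed gives
# identical output, and the planted truth is returned alongside the data so
# quantification operations can be validated by round-trip.

#' Generate a spheroid image with a planted penetration profile
#'
#' Disk of radius `radius_px` whose intensity decays exponentially with
#' depth from the boundary, `exp(-depth / decay_um)`, under multiplicative
#' Gaussian noise; uniform background outside.
#'
#' @param spec List: `size` (image side, px), `radius_px`, `decay_um`
#'   (planted penetration length), `pixel_size_um`, `noise_sd`
#'   (multiplicative, fraction of signal), `background`.
#' @param seed Integer seed.
#' @return List `image` (matrix) and `truth` (planted parameters incl. the
#'   [roi_spec()] used).
#' @export
gen_spheroid_image <- function(spec = list(), seed = 1) {
  s <- utils::modifyList(list(size = 129, radius_px = 55, decay_um = 20,
                              pixel_size_um = 2, noise_sd = 0.05,
                              background = 0.01), spec)
  if (s$decay_um >= s$radius_px * s$pixel_size_um)
    stop("gen_spheroid_image: decay length must be below the spheroid radius")
  withr::with_seed(seed, {
    ctr <- c((s$size + 1) / 2, (s$size + 1) / 2)
    roi <- roi_spec(ctr, s$radius_px)
    img <- matrix(s$background, s$size, s$size)
    r <- pixel_radii(img, roi)
    inside <- r <= s$radius_px
    depth <- (s$radius_px - r[inside]) * s$pixel_size_um
    noise <- 1 + stats::rnorm(sum(inside), 0, s$noise_sd)
    img[inside] <- pmax(exp(-depth / s$decay_um) * noise, 0)
    list(image = img, truth = list(decay_um = s$decay_um, roi = roi,
                                   pixel_size_um = s$pixel_size_um,
                                   noise_sd = s$noise_sd))
  })
}

#' Generate an intravital-microscopy style image pair
#'
#' Vessel mask of a few straight vessels; intensity decays from the vessels
#' with length `L_pre_um` in the pre-exposure image and `L_post_um` after
#' (defaults 10 and 20 um, the measured diffusion distances without and
#' with RF).
#'
#' @param spec List: `size`, `pixel_size_um`, `L_pre_um`, `L_post_um`,
#'   `noise_sd`, `positive_threshold`.
#' @param seed Integer seed.
#' @return List `pre`, `post` (images), `vessel_mask`, and `truth` holding
#'   the planted lengths and resulting positive-area fractions.
#' @export
gen_ivm_pair <- function(spec = list(), seed = 1) {
  s <- utils::modifyList(list(size = 96, pixel_size_um = 1, L_pre_um = 10,
                              L_post_um = 20, noise_sd = 0.05,
                              positive_threshold = 0.25), spec)
  withr::with_seed(seed, {
    n <- s$size
    vm <- matrix(0, n, n)
    rows <- sort(sample(seq(10, n - 10), 2))
    cols <- sample(seq(10, n - 10), 1)
    vm[rows, ] <- 1; vm[, cols] <- 1
    d <- EBImage::imageData(EBImage::distmap(1 - vm)) * s$pixel_size_um
    mk <- function(L) {
      img <- exp(-d / L) * (1 + matrix(stats::rnorm(n * n, 0, s$noise_sd), n, n))
      pmax(img, 0)
    }
    pre <- mk(s$L_pre_um); post <- mk(s$L_post_um)
    list(pre = pre, post = post, vessel_mask = vm,
         truth = list(L_pre_um = s$L_pre_um, L_post_um = s$L_post_um,
                      positive_threshold = s$positive_threshold,
                      frac_pre = area_fraction_positive(pre, s$positive_threshold),
                      frac_post = area_fraction_positive(post, s$positive_threshold)))
  })
}

#' Generate a blob image for segmentation tests
#'
#' Disk-shaped blobs of specified areas over a uniform background. The
#' truth records each blob's rasterized area, whether it touches the frame
#' edge, and which pass the area gates. Layouts whose overlapping-blob
#' fraction exceeds 0.2 are regenerated (with a warning).
#'
#' @param spec List: `size`, `n_blobs`, `area_px2` (scalar or vector of
#'   nominal blob areas), `background`, `amplitude` (intensity above
#'   background), `force_edge` (number of blobs planted at the edge),
#'   `noise_sd` (additive, grey levels).
#' @param seed Integer seed.
#' @return List `image` and `truth` (`centers`, `areas`, `on_edge`,
#'   `n_gate_pass`: blobs inside the gates and off the edge).
#' @export
gen_blob_image <- function(spec = list(), seed = 1) {
  s <- utils::modifyList(list(size = 256, n_blobs = 10, area_px2 = 400,
                              background = 1000, amplitude = 1000,
                              force_edge = 0, noise_sd = 0), spec)
  areas <- rep_len(s$area_px2, s$n_blobs)
  radii <- sqrt(areas / pi)
  for (attempt in 1:20) {
    out <- withr::with_seed(seed + (attempt - 1L) * 1000L, {
      n <- s$size
      cx <- numeric(s$n_blobs); cy <- numeric(s$n_blobs)
      margin <- ceiling(radii) + 2
      for (i in seq_len(s$n_blobs)) {
        if (i <= s$force_edge) {
          cx[i] <- 1; cy[i] <- stats::runif(1, margin[i], n - margin[i])
        } else {
          cx[i] <- stats::runif(1, margin[i], n - margin[i])
          cy[i] <- stats::runif(1, margin[i], n - margin[i])
        }
      }
      overlaps <- 0
      if (s$n_blobs > 1) {
        dmat <- as.matrix(stats::dist(cbind(cx, cy)))
        rsum <- outer(radii, radii, `+`)
        diag(dmat) <- Inf
        overlaps <- sum(apply(dmat < rsum, 1, any))
      }
      img <- matrix(s$background, n, n)
      xs <- matrix(rep(seq_len(n), each = n), n, n)
      ys <- matrix(rep(seq_len(n), n), n, n)
      ras_area <- numeric(s$n_blobs); on_edge <- logical(s$n_blobs)
      for (i in seq_len(s$n_blobs)) {
        m <- (xs - cx[i])^2 + (ys - cy[i])^2 <= radii[i]^2
        img[m] <- s$background + s$amplitude
        ras_area[i] <- sum(m)
        idx <- which(m, arr.ind = TRUE)
        on_edge[i] <- any(idx == 1 | idx[, 1] == n | idx[, 2] == n)
      }
      # component-level truth on the noiseless mask: touching blobs merge,
      # which is exactly what a segmenter can observe
      union_mask <- img > s$background
      lab <- label_components_8(union_mask)
      ids <- which(lab > 0)
      comp_area <- tabulate(lab[ids])
      yy <- ((ids - 1L) %% n) + 1L; xx <- ((ids - 1L) %/% n) + 1L
      comp_edge <- as.logical(tapply(xx == 1 | xx == n | yy == 1 | yy == n,
                                     lab[ids], any))
      if (s$noise_sd > 0)
        img <- img + matrix(stats::rnorm(n * n, 0, s$noise_sd), n, n)
      list(image = img, overlap_frac = overlaps / max(s$n_blobs, 1),
           truth = list(centers = cbind(x = cx, y = cy), areas = ras_area,
                        on_edge = on_edge, comp_area = comp_area,
                        comp_edge = comp_edge))
    })
    if (out$overlap_frac <= 0.2) break
    warning("gen_blob_image: overlapping-blob fraction > 0.2, regenerating")
  }
  gates <- segmentation_params()
  out$truth$n_gate_pass <- sum(out$truth$comp_area > gates$area_min &
                               out$truth$comp_area < gates$area_max &
                               !out$truth$comp_edge)
  out[c("image", "truth")]
}

#' Generate paired cell areas with a planted retraction fraction
#'
#' Lognormal baseline areas; a planted fraction shrinks by clearly more
#' than 33% and the rest by clearly less, so retraction flags can be
#' recovered exactly.
#'
#' @param spec List: `n`, `fraction_retracted`, `meanlog`, `sdlog`,
#'   `margin` (distance of shrinkage from the 33% boundary).
#' @param seed Integer seed.
#' @return List `before`, `after`, `truth` (logical flags).
#' @export
gen_cell_areas <- function(spec = list(), seed = 1) {
  s <- utils::modifyList(list(n = 600, fraction_retracted = 0.4,
                              meanlog = log(300), sdlog = 0.4,
                              margin = 0.07), spec)
  withr::with_seed(seed, {
    before <- stats::rlnorm(s$n, s$meanlog, s$sdlog)
    flags <- seq_len(s$n) <= round(s$fraction_retracted * s$n)
    flags <- sample(flags)
    shrink <- ifelse(flags,
                     stats::runif(s$n, 0.33 + s$margin, 0.70),
                     stats::runif(s$n, 0.02, 0.33 - s$margin))
    after <- before * (1 - shrink)
    list(before = before, after = after, truth = flags)
  })
}

#' Generate the calibrated pre-treatment hypovascularized lesion
#'
#' Builds the reference lesion the therapy comparisons start from: a
#' regular capillary bed pruned inside the tumor (hypovascularization),
#' heterogeneous ECM from smoothed seeded noise (fibrosis), untreated
#' growth with angiogenesis until the lesion reaches the target radius, and
#' finally calibration of the tissue thresholds (within bounds) so the
#' tissue composition matches the reference hypoxic/proliferating/necrotic
#' fractions.
#'
#' @param config List overriding defaults: `grid`, `init_radius`,
#'   `target_radius` (um), `phi0`, `spacing_nodes`, `p_prune`,
#'   `ecm_mean`, `ecm_sd`, `max_hours`, `target_fractions`
#'   (`c(fP, fH, fN)`), `tol` (allowed deviation per fraction).
#' @param seed Integer seed.
#' @param params A [sim_params()] bundle for the growth phase.
#' @return List: `lesion` (classified), `net`, `sigma`, `E`, `thresholds`
#'   (calibrated), `fractions` (achieved), `growth_hours`.
#' @export
gen_pretreatment_lesion <- function(config = list(), seed = 1,
                                    params = sim_params()) {
  cf <- utils::modifyList(
    list(grid = sim_grid(140, 140, 10), init_radius = 300,
         target_radius = 400, phi0 = 0.75, spacing_nodes = 10, p_prune = 0.8,
         ecm_mean = 0.6, ecm_sd = 0.15, smooth_sigma = 3, max_hours = 600,
         target_fractions = c(fP = 0.25, fH = 0.58, fN = 0.17), tol = 0.05),
    config)
  grid <- cf$grid
  cx <- (grid$nx - 1) * grid$h / 2; cy <- (grid$ny - 1) * grid$h / 2
  E <- withr::with_seed(seed, {
    noise <- matrix(stats::rnorm(grid$ny * grid$nx), grid$ny, grid$nx)
    sm <- EBImage::imageData(EBImage::gblur(noise, sigma = cf$smooth_sigma))
    clip01(cf$ecm_mean + cf$ecm_sd * sm / stats::sd(sm))
  })
  phi <- matrix(0, grid$ny, grid$nx)
  phi[disk_mask(grid, cx, cy, cf$init_radius)] <- cf$phi0
  lesion <- lesion_state(grid, phi = phi)
  net <- build_capillary_grid(grid, cf$spacing_nodes)
  net <- prune_intratumoral(net, lesion, cf$p_prune, rng_seed = seed)
  net <- mark_perfusion_connectivity(net, lesion)

  traj <- run_schedule(lesion, net, therapy_schedule(), params,
                       t_end = cf$max_hours, seed = seed, E = E,
                       stop_radius = cf$target_radius)
  state <- attr(traj, "final_state")
  lesion <- state$lesion; net <- state$net; sigma <- state$sigma; E <- state$E

  thr <- calibrate_thresholds(lesion, sigma, cf$target_fractions, cf$tol)
  lesion <- classify_tissue(sigma, lesion, thr)
  fr <- tissue_fractions(lesion)
  if (any(abs(fr - cf$target_fractions[names(fr)]) > cf$tol))
    stop(sprintf(
      "gen_pretreatment_lesion: calibration failed; closest fractions fP=%.3f fH=%.3f fN=%.3f",
      fr[["fP"]], fr[["fH"]], fr[["fN"]]))
  list(lesion = lesion, net = net, sigma = sigma, E = E, thresholds = thr,
       fractions = fr, growth_hours = state$t)
}

# internal: choose (sigma_P, sigma_N) by quantile matching of the oxygen
# distribution over lesion nodes so the composition hits the target
calibrate_thresholds <- function(lesion, sigma, target, tol) {
  inside <- tumor_mask(lesion)
  if (!any(inside)) stop("calibrate_thresholds: empty lesion")
  sig <- sigma[inside]
  forced <- (lesion$nec > lesion$phi)[inside] # necrotic regardless of oxygen
  f_forced <- mean(forced)
  fN_target <- target[["fN"]]; fP_target <- target[["fP"]]
  if (f_forced > fN_target + tol)
    stop(sprintf("calibrate_thresholds: necrotic debris already %.2f > target %.2f + tol",
                 f_forced, fN_target))
  sig_free <- sig[!forced]
  pN <- max((fN_target * length(sig) - sum(forced)) / length(sig_free), 0)
  sigma_N <- as.numeric(stats::quantile(sig_free, pN, type = 1))
  sigma_P <- as.numeric(stats::quantile(sig, 1 - fP_target, type = 1))
  eps <- 1e-6
  sigma_N <- min(max(sigma_N, eps), 0.98)
  sigma_P <- min(max(sigma_P, sigma_N + eps), 1 - eps)
  tissue_thresholds(sigma_P = sigma_P, sigma_N = sigma_N)
}
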