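# Ground-truthed synthetic 3D nuclei: an ellipsoidal nucleus containing
# non-overlapping spherical DAPI-dense chromocenters, per-channel intensity
# folds inside the chromocenters, optional marker channels (EdU / Aurora-B
# for the marker staging scheme, hCdt1 / Geminin for FUCCI), then PSF blur
# and Poisson + Gaussian noise. Ground-truth masks are returned pre-blur,
# pre-noise.

#' Simulation configuration for one synthetic nucleus
#'
#' @param nucleus_radii (z, y, x) ellipsoid semi-axes in micrometres. The
#'   default is a flattened adherent nucleus (5 um tall, 9 um wide).
#' @param voxel_size (z, y, x) voxel pitch in micrometres; the default z-step
#'   is the confocal acquisition step of 0.172 um.
#' @param n_chromocenters integer count, or a length-2 range from which the
#'   count is drawn uniformly (default 6 to 15).
#' @param chromocenter_radius (mean, sd) of the domain radius in micrometres.
#' @param dapi_fold DAPI intensity fold of chromocenters over nucleoplasm
#'   (> 1; chromocenters are DAPI-dense by definition).
#' @param channel_folds named numeric vector of enrichment folds r per
#'   channel role (e.g. `c(SIGNAL = 1.8)`): intensity inside chromocenters is
#'   `base_level * r`, nucleoplasm is `base_level`.
#' @param base_level nucleoplasm intensity in photon counts (Poisson scale).
#' @param psf_sigma isotropic PSF sigma in micrometres (0 disables blur).
#' @param noise list: `poisson` (logical, shot noise) and `gaussian_sd`
#'   (read noise in counts). `list(poisson = FALSE, gaussian_sd = 0)` is
#'   noiseless.
#' @param stage optional cell-cycle stage to render. With
#'   `scheme = "markers"` one of G1, EarlyS, MidS, LateS, G2 (EdU and
#'   Aurora-B channels are rendered); with `scheme = "fucci"` one of
#'   EarlyG1, LateG1_EarlyS, MidLateS, G2 (hCdt1 and Geminin channels).
#' @param scheme "none", "markers" or "fucci".
#' @param edu_amplitude,aurorab_level,fucci_levels marker rendering
#'   intensities (photon counts). `fucci_levels` is
#'   `c(negative, positive, high)`.
#' @param seed integer RNG seed; identical config + seed gives bit-identical
#'   output.
#' @return a `simulation_config` object.
#' @export
simulation_config <- function(nucleus_radii = c(2.5, 4.5, 4.5),
                              voxel_size = c(0.172, 0.08, 0.08),
                              n_chromocenters = c(6L, 15L),
                              chromocenter_radius = c(0.6, 0.1),
                              dapi_fold = 3,
                              channel_folds = c(SIGNAL = 1),
                              base_level = 100,
                              psf_sigma = 0.1,
                              noise = list(poisson = TRUE, gaussian_sd = 2),
                              stage = NULL,
                              scheme = c("none", "markers", "fucci"),
                              edu_amplitude = 500,
                              aurorab_level = 150,
                              fucci_levels = c(0, 120, 300),
                              seed = 1L) {
  scheme <- match.arg(scheme)
  stopifnot(length(nucleus_radii) == 3L, all(nucleus_radii > 0),
            length(voxel_size) == 3L, all(voxel_size > 0),
            all(n_chromocenters >= 0), length(n_chromocenters) %in% c(1L, 2L),
            chromocenter_radius[1L] > 0, dapi_fold > 1,
            base_level > 0, psf_sigma >= 0)
  if (length(channel_folds) > 0) {
    stopifnot(!is.null(names(channel_folds)), all(channel_folds > 0),
              all(names(channel_folds) %in% setdiff(CHANNEL_ROLES, "DAPI")))
  }
  if (scheme == "markers" && !is.null(stage)) {
    stopifnot(stage %in% c("G1", "EarlyS", "MidS", "LateS", "G2"))
  }
  if (scheme == "fucci" && !is.null(stage)) {
    stopifnot(stage %in% c("EarlyG1", "LateG1_EarlyS", "MidLateS", "G2"))
  }
  structure(list(nucleus_radii = as.numeric(nucleus_radii),
                 voxel_size = as.numeric(voxel_size),
                 n_chromocenters = n_chromocenters,
                 chromocenter_radius = as.numeric(chromocenter_radius),
                 dapi_fold = dapi_fold, channel_folds = channel_folds,
                 base_level = base_level, psf_sigma = psf_sigma,
                 noise = noise, stage = stage, scheme = scheme,
                 edu_amplitude = edu_amplitude,
                 aurorab_level = aurorab_level,
                 fucci_levels = as.numeric(fucci_levels),
                 seed = as.integer(seed)),
            class = "simulation_config")
}

# voxel-centre coordinates (um) per axis, origin at the array centre
axis_coords <- function(n, v) ((seq_len(n) - 0.5) - n / 2) * v

# sphere mask written into a bounding box of `arr`-shaped FALSE array
add_sphere <- function(mask, centre, radius, coords) {
  rngs <- lapply(1:3, function(ax) {
    which(abs(coords[[ax]] - centre[ax]) <= radius)
  })
  if (any(lengths(rngs) == 0L)) return(mask)
  dz <- outer(coords[[1L]][rngs[[1L]]] - centre[1L],
              coords[[2L]][rngs[[2L]]] - centre[2L],
              function(a, b) a^2 + b^2)
  sub <- outer(dz, (coords[[3L]][rngs[[3L]]] - centre[3L])^2, `+`) <= radius^2
  dim(sub) <- lengths(rngs)
  mask[rngs[[1L]], rngs[[2L]], rngs[[3L]]] <-
    mask[rngs[[1L]], rngs[[2L]], rngs[[3L]], drop = FALSE] | sub
  mask
}

# uniform point in the unit ball (rejection)
runif_ball <- function() {
  repeat {
    p <- runif(3L, -1, 1)
    if (sum(p^2) <= 1) return(p)
  }
}

#' Generate one synthetic nucleus with ground truth
#'
#' @param config a [simulation_config()].
#' @return list with `stack` (an [image_stack()]) and `truth`: the pre-noise
#'   nucleus mask, chromocenter mask and label array, per-channel folds,
#'   rendered stage, and per-domain centres/radii (um, array origin).
#' @export
generate_nucleus <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  withr::with_seed(config$seed, generate_nucleus_impl(config))
}

generate_nucleus_impl <- function(config) {
  vs <- config$voxel_size
  rad <- config$nucleus_radii
  margin_um <- pmax(3 * config$psf_sigma, 0.4)
  d <- as.integer(2 * ceiling(rad / vs) + 2 * (ceiling(margin_um / vs) + 1L))
  coords <- lapply(1:3, function(ax) axis_coords(d[ax], vs[ax]))

  # ellipsoidal nucleus
  ez <- (coords[[1L]] / rad[1L])^2
  ey <- (coords[[2L]] / rad[2L])^2
  ex <- (coords[[3L]] / rad[3L])^2
  nucleus <- outer(outer(ez, ey, `+`), ex, `+`) <= 1

  # chromocenter placement: non-overlapping spheres fully inside the nucleus
  n_cc <- if (length(config$n_chromocenters) == 2L) {
    sample(config$n_chromocenters[1L]:config$n_chromocenters[2L], 1L)
  } else as.integer(config$n_chromocenters)
  layout <- NULL
  for (attempt in seq_len(10L)) {
    cc_centres <- matrix(numeric(0), 0L, 3L)
    cc_radii <- numeric(0)
    ok <- TRUE
    for (i in seq_len(n_cc)) {
      ri <- max(0.25 * config$chromocenter_radius[1L],
                rnorm(1L, config$chromocenter_radius[1L],
                      config$chromocenter_radius[2L]))
      placed <- FALSE
      for (try in seq_len(200L)) {
        p <- runif_ball() * (rad - ri)
        if (sum((p / (rad - ri))^2) > 1) next
        if (nrow(cc_centres) > 0L) {
          dmin <- sqrt(colSums((t(cc_centres) - p)^2))
          if (any(dmin < cc_radii + ri + 0.05)) next
        }
        cc_centres <- rbind(cc_centres, p)
        cc_radii <- c(cc_radii, ri)
        placed <- TRUE
        break
      }
      if (!placed) { ok <- FALSE; break }
    }
    if (ok) { layout <- list(centres = cc_centres, radii = cc_radii); break }
  }
  if (is.null(layout)) {
    chr_stop("chromofied_placement_error",
             sprintf("could not place %d non-overlapping chromocenters", n_cc))
  }
  cc_centres <- layout$centres
  cc_radii <- layout$radii
  cc_labels <- array(0L, d)
  for (i in seq_len(n_cc)) {
    sph <- add_sphere(array(FALSE, d), cc_centres[i, ], cc_radii[i], coords)
    cc_labels[sph] <- i
  }
  cc_mask <- cc_labels > 0L

  base <- config$base_level
  channels <- list()
  roles <- c(DAPI = "DAPI")
  channels$DAPI <- base * nucleus + base * (config$dapi_fold - 1) * cc_mask
  for (role in names(config$channel_folds)) {
    x <- base * nucleus
    x[cc_mask] <- base * config$channel_folds[[role]]
    channels[[role]] <- x
    roles[role] <- role
  }

  if (config$scheme == "markers") {
    ren <- render_marker_channels(config, nucleus, cc_mask, coords, d)
    channels$EDU <- ren$edu
    channels$AURORAB <- ren$aurorab
    roles["EDU"] <- "EDU"
    roles["AURORAB"] <- "AURORAB"
  } else if (config$scheme == "fucci") {
    lv <- fucci_stage_levels(config$stage, config$fucci_levels)
    channels$HCDT1 <- lv[1L] * nucleus
    channels$GEMININ <- lv[2L] * nucleus
    roles["HCDT1"] <- "HCDT1"
    roles["GEMININ"] <- "GEMININ"
  }

  truth <- list(nucleus_mask = nucleus, cc_mask = cc_mask,
                cc_labels = cc_labels, n_chromocenters = n_cc,
                cc_centres = cc_centres, cc_radii = cc_radii,
                channel_folds = config$channel_folds,
                stage = config$stage, scheme = config$scheme,
                pattern = NA_character_)

  # optics then detection noise
  if (config$psf_sigma > 0) {
    channels <- lapply(channels, gaussian_blur3d,
                       sigma_vox = config$psf_sigma / vs)
  }
  if (isTRUE(config$noise$poisson)) {
    channels <- lapply(channels, function(x) {
      array(rpois(length(x), pmax(x, 0)), dim(x))
    })
  }
  gs <- config$noise$gaussian_sd
  if (!is.null(gs) && gs > 0) {
    channels <- lapply(channels, function(x) {
      pmax(x + array(rnorm(length(x), 0, gs), dim(x)), 0)
    })
  }
  list(stack = image_stack(channels, vs, roles), truth = truth)
}

fucci_stage_levels <- function(stage, levels) {
  # (hCdt1, Geminin) rendering levels: ++ = high, + = positive, - = negative
  switch(stage,
         EarlyG1 = c(levels[3L], levels[1L]),
         LateG1_EarlyS = c(levels[2L], levels[2L]),
         MidLateS = c(levels[1L], levels[2L]),
         G2 = c(levels[1L], levels[3L]),
         chr_stop("chromofied_config_error",
                  "fucci scheme requires a FUCCI stage"))
}

# EdU / Aurora-B channels for one marker-scheme stage.
# Early S: many small foci throughout the nucleoplasm (euchromatin);
# Mid S: ring of signal around the chromocenters;
# Late S: a few large foci hugging the nuclear border;
# G2: Aurora-B positive, EdU negative; G1: both negative.
render_marker_channels <- function(config, nucleus, cc_mask, coords, d) {
  edu <- array(0, d)
  aurorab <- array(0, d)
  stage <- config$stage
  if (is.null(stage)) {
    chr_stop("chromofied_config_error", "markers scheme requires a stage")
  }
  amp <- config$edu_amplitude
  rad <- config$nucleus_radii
  if (stage == "EarlyS") {
    n_foci <- sample(50:80, 1L)
    foci <- array(FALSE, d)
    for (i in seq_len(n_foci)) {
      p <- runif_ball() * (rad - 0.3)
      foci <- add_sphere(foci, p, runif(1L, 0.2, 0.35), coords)
    }
    # chromocenters have not replicated yet: no EdU inside them
    foci <- foci & nucleus & !cc_mask
    edu[foci] <- amp
  } else if (stage == "MidS") {
    ring_vox <- pmax(1L, round(0.3 / config$voxel_size))
    ring <- dilate_mask(cc_mask, ring_vox) & !cc_mask & nucleus
    edu[ring] <- amp
  } else if (stage == "LateS") {
    n_foci <- sample(5:8, 1L)
    foci <- array(FALSE, d)
    for (i in seq_len(n_foci)) {
      dir <- runif_ball()
      dir <- dir / sqrt(sum(dir^2))
      p <- dir * (rad - 0.2)  # centre just inside the ellipsoid surface
      foci <- add_sphere(foci, p, runif(1L, 0.7, 0.9), coords)
    }
    foci <- foci & nucleus
    edu[foci] <- amp
  } else if (stage == "G2") {
    aurorab <- config$aurorab_level * nucleus
  }
  list(edu = edu, aurorab = aurorab)
}

#' Extract segmentation-grade objects from a ground truth
#'
#' Wraps the generator's truth masks as a [nucleus_mask()] and
#' [chromocenter_set()] so the enrichment and classification modules can be
#' run on ground truth directly (bypassing segmentation).
#'
#' @param truth the `truth` element of [generate_nucleus()]'s result.
#' @param voxel_size (z, y, x) voxel pitch in micrometres.
#' @param nucleus_id id to assign (default 1).
#' @return list with elements `nucleus` and `domains`.
#' @export
truth_masks <- function(truth, voxel_size, nucleus_id = 1L) {
  list(nucleus = nucleus_mask(nucleus_id, truth$nucleus_mask, voxel_size),
       domains = chromocenter_set(nucleus_id, truth$cc_labels, voxel_size))
}
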