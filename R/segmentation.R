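# Nucleus and chromocenter segmentation from the DAPI channel.
#
# Nuclei: Otsu threshold on the smoothed DAPI channel, 3D connected
# components, per-slice hole filling, size and border filters.
# Chromocenters: within-nucleus threshold at mean + k * sd of nuclear DAPI
# ("DAPI-dense regions"), connected components, size filter.

#' Nucleus mask
#'
#' @param nucleus_id integer id.
#' @param mask 3D logical array (same grid as the source stack).
#' @param voxel_size (z, y, x) voxel pitch in micrometres.
#' @return `nucleus_mask` object with `volume` (um^3) and `centroid` (um).
#' @export
nucleus_mask <- function(nucleus_id, mask, voxel_size) {
  stopifnot(is.logical(mask), length(dim(mask)) == 3L)
  n <- sum(mask)
  st <- component_stats(array(as.integer(mask), dim(mask)), voxel_size)
  structure(list(nucleus_id = as.integer(nucleus_id), mask = mask,
                 voxel_size = as.numeric(voxel_size),
                 n_voxels = n, volume = n * prod(voxel_size),
                 centroid = if (n > 0) c(st$cz, st$cy, st$cx) else rep(NA_real_, 3L)),
            class = "nucleus_mask")
}

#' Set of chromocenter domains within one nucleus
#'
#' @param nucleus_id integer id of the parent nucleus.
#' @param labels integer 3D array; 0 background, 1..k domain ids.
#' @param voxel_size (z, y, x) voxel pitch in micrometres.
#' @return `chromocenter_set` with a `domains` data.frame (domain_id,
#'   n_voxels, volume, centroid cz/cy/cx in um) and the label array.
#' @export
chromocenter_set <- function(nucleus_id, labels, voxel_size) {
  stopifnot(length(dim(labels)) == 3L)
  st <- component_stats(labels, voxel_size)
  names(st)[names(st) == "id"] <- "domain_id"
  structure(list(nucleus_id = as.integer(nucleus_id), labels = labels,
                 voxel_size = as.numeric(voxel_size),
                 n_domains = nrow(st), domains = st),
            class = "chromocenter_set")
}

#' @export
print.nucleus_mask <- function(x, ...) {
  cat(sprintf("<nucleus_mask> id %d, %.1f um^3 (%d voxels)\n",
              x$nucleus_id, x$volume, x$n_voxels))
  invisible(x)
}

#' @export
print.chromocenter_set <- function(x, ...) {
  cat(sprintf("<chromocenter_set> nucleus %d: %d domain(s), total %.2f um^3\n",
              x$nucleus_id, x$n_domains, sum(x$domains$volume)))
  invisible(x)
}

#' Segment nuclei from the DAPI channel
#'
#' Gaussian smoothing (sigma in micrometres, converted to anisotropic voxel
#' sigmas), global Otsu threshold, 3D connected components, per-slice hole
#' filling, then removal of components below `min_nucleus_volume` or touching
#' the image border (whole-nucleus ratios cannot be computed for clipped
#' nuclei).
#'
#' @param stack an [image_stack()] with a DAPI role.
#' @param smooth_sigma smoothing sigma in micrometres (default 0.3).
#' @param min_nucleus_volume minimum nucleus volume in um^3 (default 50).
#' @return list of [nucleus_mask()] objects (possibly empty; a constant or
#'   empty DAPI image yields zero nuclei, not an error).
#' @export
segment_nuclei <- function(stack, smooth_sigma = 0.3, min_nucleus_volume = 50) {
  dapi <- get_channel(stack, "DAPI")
  vs <- stack$voxel_size
  sm <- if (smooth_sigma > 0) gaussian_blur3d(dapi, smooth_sigma / vs) else dapi
  thr <- otsu_threshold(sm)
  if (is.na(thr)) return(list())
  fg <- fill_holes_slices(sm > thr)
  labs <- label_components(fg)
  st <- component_stats(labs, vs)
  if (nrow(st) == 0L) return(list())
  d <- dim(labs)
  border_ids <- unique(c(labs[1L, , ], labs[d[1L], , ], labs[, 1L, ],
                         labs[, d[2L], ], labs[, , 1L], labs[, , d[3L]]))
  keep <- st$id[st$volume >= min_nucleus_volume & !(st$id %in% border_ids)]
  out <- list()
  for (i in seq_along(keep)) {
    out[[i]] <- nucleus_mask(i, labs == keep[i], vs)
  }
  out
}

#' Segment chromocenters (DAPI-dense domains) within a nucleus
#'
#' Threshold at mean + k * sd of the DAPI intensity over the nucleus voxels,
#' 3D connected components, size filter.
#'
#' @param stack an [image_stack()].
#' @param nucleus a [nucleus_mask()].
#' @param k threshold stringency in nuclear-DAPI standard deviations
#'   (default 2).
#' @param min_domain_volume minimum domain volume in um^3 (default 0.15).
#' @return a [chromocenter_set()] (possibly with zero domains, e.g. for
#'   uniform DAPI).
#' @export
segment_chromocenters <- function(stack, nucleus, k = 2,
                                  min_domain_volume = 0.15) {
  stopifnot(inherits(nucleus, "nucleus_mask"))
  if (nucleus$n_voxels == 0L) {
    chr_stop("chromofied_data_error", "nucleus mask is empty")
  }
  dapi <- get_channel(stack, "DAPI")
  vals <- dapi[nucleus$mask]
  thr <- mean(vals) + k * stats::sd(vals)
  mask <- dapi > thr & nucleus$mask
  labs <- label_components(mask)
  st <- component_stats(labs, stack$voxel_size)
  keep <- st$id[st$volume >= min_domain_volume]
  out <- array(0L, dim(labs))
  for (i in seq_along(keep)) out[labs == keep[i]] <- i
  chromocenter_set(nucleus$nucleus_id, out, stack$voxel_size)
}

#' Voxel-level Jaccard index of two masks
#'
#' @param a,b logical arrays of identical dimension.
#' @return |a & b| / |a | b| (1 when both empty).
#' @export
mask_jaccard <- function(a, b) {
  u <- sum(a | b)
  if (u == 0L) return(1)
  sum(a & b) / u
}
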