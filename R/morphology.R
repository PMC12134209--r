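# Low-level 3D image primitives shared by the segmentation and cell-cycle
# modules. Arrays are indexed [z, y, x]; voxel_size is the (z, y, x) pitch
# in micrometres.

#' Label connected components in a 3D logical mask
#'
#' 6-connectivity (faces only). Degenerate axes of size 1 reduce this to 2D
#' or 1D labeling.
#'
#' @param mask 3D logical array.
#' @return Integer array of the same dimension; 0 is background, components
#'   are numbered 1..k in scan order.
#' @export
label_components <- function(mask) {
  stopifnot(is.logical(mask), length(dim(mask)) == 3L)
  mask[is.na(mask)] <- FALSE
  .label3d_cpp(mask, as.integer(dim(mask)))
}

#' Per-component size, volume and centroid
#'
#' @param labels integer label array as returned by [label_components()].
#' @param voxel_size numeric (z, y, x) voxel pitch in micrometres.
#' @return data.frame with columns `id`, `n_voxels`, `volume` (um^3) and
#'   centroid coordinates `cz`, `cy`, `cx` in micrometres measured from the
#'   array origin (voxel centres at (i - 0.5) * pitch).
#' @export
component_stats <- function(labels, voxel_size) {
  stopifnot(length(dim(labels)) == 3L, length(voxel_size) == 3L)
  ids <- sort(unique(labels[labels > 0L]))
  if (length(ids) == 0L) {
    return(data.frame(id = integer(), n_voxels = integer(), volume = numeric(),
                      cz = numeric(), cy = numeric(), cx = numeric()))
  }
  d <- dim(labels)
  idx <- which(labels > 0L)
  lab <- labels[idx]
  z <- ((idx - 1L) %% d[1L]) + 1L
  y <- (((idx - 1L) %/% d[1L]) %% d[2L]) + 1L
  x <- ((idx - 1L) %/% (d[1L] * d[2L])) + 1L
  n <- tabulate(lab, nbins = max(ids))[ids]
  vvol <- prod(voxel_size)
  cz <- (tapply(z, lab, mean)[as.character(ids)] - 0.5) * voxel_size[1L]
  cy <- (tapply(y, lab, mean)[as.character(ids)] - 0.5) * voxel_size[2L]
  cx <- (tapply(x, lab, mean)[as.character(ids)] - 0.5) * voxel_size[3L]
  data.frame(id = as.integer(ids), n_voxels = as.integer(n),
             volume = n * vvol, cz = as.numeric(cz), cy = as.numeric(cy),
             cx = as.numeric(cx), row.names = NULL)
}

# 1D Gaussian convolution matrix with edge renormalization (rows sum to 1)
gauss_matrix <- function(n, sigma) {
  r <- max(1L, ceiling(3 * sigma))
  i <- seq_len(n)
  D <- outer(i, i, function(a, b) a - b)
  K <- exp(-(D^2) / (2 * sigma^2))
  K[abs(D) > r] <- 0
  K / rowSums(K)
}

#' Separable anisotropic 3D Gaussian blur
#'
#' @param a 3D numeric array.
#' @param sigma_vox per-axis (z, y, x) standard deviation in voxels; axes
#'   with sigma <= 0 are left untouched.
#' @return blurred array, same dimension.
#' @export
gaussian_blur3d <- function(a, sigma_vox) {
  stopifnot(length(dim(a)) == 3L, length(sigma_vox) == 3L)
  d <- dim(a)
  if (sigma_vox[1L] > 0 && d[1L] > 1L) {
    a <- array(gauss_matrix(d[1L], sigma_vox[1L]) %*% matrix(a, d[1L]), d)
  }
  if (sigma_vox[2L] > 0 && d[2L] > 1L) {
    a <- aperm(a, c(2L, 1L, 3L))
    a <- array(gauss_matrix(d[2L], sigma_vox[2L]) %*% matrix(a, d[2L]),
               d[c(2L, 1L, 3L)])
    a <- aperm(a, c(2L, 1L, 3L))
  }
  if (sigma_vox[3L] > 0 && d[3L] > 1L) {
    a <- aperm(a, c(3L, 2L, 1L))
    a <- array(gauss_matrix(d[3L], sigma_vox[3L]) %*% matrix(a, d[3L]),
               d[c(3L, 2L, 1L)])
    a <- aperm(a, c(3L, 2L, 1L))
  }
  a
}

#' Otsu threshold of a numeric vector
#'
#' Bimodal split maximizing between-class variance on a 256-bin histogram
#' spanning the data range. Invariant to affine rescaling of the input.
#'
#' @param x numeric values.
#' @param nbins number of histogram bins.
#' @return threshold value (voxels with `x > threshold` are foreground), or
#'   `NA` for constant/empty input.
#' @export
otsu_threshold <- function(x, nbins = 256L) {
  x <- x[is.finite(x)]
  if (length(x) == 0L) return(NA_real_)
  rng <- range(x)
  if (rng[1L] == rng[2L]) return(NA_real_)
  br <- seq(rng[1L], rng[2L], length.out = nbins + 1L)
  h <- as.numeric(tabulate(findInterval(x, br, rightmost.closed = TRUE,
                                        all.inside = TRUE), nbins))
  mids <- (br[-1L] + br[-length(br)]) / 2
  w <- cumsum(h)
  m <- cumsum(h * mids)
  n <- w[nbins]
  mt <- m[nbins]
  w0 <- w[-nbins]
  w1 <- n - w0
  valid <- w0 > 0 & w1 > 0
  mu0 <- m[-nbins] / w0
  mu1 <- (mt - m[-nbins]) / w1
  bcv <- w0 * w1 * (mu0 - mu1)^2
  bcv[!valid] <- -Inf
  k <- which.max(bcv)
  br[k + 1L]
}

# integer offsets inside an anisotropic ellipsoid of voxel radii r = (z,y,x)
ball_offsets <- function(r_vox) {
  r <- pmax(0L, as.integer(round(r_vox)))
  g <- expand.grid(dz = -r[1L]:r[1L], dy = -r[2L]:r[2L], dx = -r[3L]:r[3L])
  rr <- pmax(r, 1L)  # avoid 0-division for flat axes
  keep <- (g$dz / rr[1L])^2 + (g$dy / rr[2L])^2 + (g$dx / rr[3L])^2 <= 1
  g[keep & !(g$dz == 0 & g$dy == 0 & g$dx == 0), , drop = FALSE]
}

#' Binary dilation / erosion with an anisotropic element
#'
#' `shape = "ellipsoid"` uses the exact anisotropic ball;
#' `shape = "box"` applies three separable 1D passes (much faster for
#' large radii, with a rectangular footprint).
#'
#' @param mask 3D logical array.
#' @param r_vox per-axis (z, y, x) radius in voxels (rounded to integers).
#' @param shape structuring element, "ellipsoid" or "box".
#' @return logical array. For erosion, voxels outside the array count as
#'   background, so the mask retreats from the array border.
#' @export
dilate_mask <- function(mask, r_vox, shape = c("ellipsoid", "box")) {
  stopifnot(length(dim(mask)) == 3L)
  shape <- match.arg(shape)
  mask[is.na(mask)] <- FALSE
  d <- as.integer(dim(mask))
  r <- pmax(0L, as.integer(round(r_vox)))
  if (shape == "box") {
    for (ax in 1:3) {
      if (r[ax] == 0L) next
      off <- matrix(0L, 2L * r[ax], 3L)
      off[, ax] <- setdiff(-r[ax]:r[ax], 0L)
      mask <- .dilate3d_cpp(mask, d, off)
    }
    return(mask)
  }
  off <- ball_offsets(r)
  if (nrow(off) == 0L) return(mask)
  .dilate3d_cpp(mask, d, as.matrix(cbind(off$dz, off$dy, off$dx)))
}

#' @rdname dilate_mask
#' @export
erode_mask <- function(mask, r_vox, shape = c("ellipsoid", "box")) {
  stopifnot(length(dim(mask)) == 3L)
  shape <- match.arg(shape)
  mask[is.na(mask)] <- FALSE
  d <- as.integer(dim(mask))
  r <- pmax(0L, as.integer(round(r_vox)))
  if (shape == "box") {
    for (ax in 1:3) {
      if (r[ax] == 0L) next
      off <- matrix(0L, 2L * r[ax], 3L)
      off[, ax] <- setdiff(-r[ax]:r[ax], 0L)
      mask <- .erode3d_cpp(mask, d, off)
    }
    return(mask)
  }
  off <- ball_offsets(r)
  if (nrow(off) == 0L) return(mask)
  .erode3d_cpp(mask, d, as.matrix(cbind(off$dz, off$dy, off$dx)))
}

#' Fill holes slice-by-slice along z
#'
#' A hole is a background component of a z-slice not connected to the slice
#' border. 2D filling avoids sealing the nuclear interior through
#' z-anisotropy artifacts.
#'
#' @param mask 3D logical array.
#' @return logical array with per-slice holes set to `TRUE`.
#' @export
fill_holes_slices <- function(mask) {
  stopifnot(length(dim(mask)) == 3L)
  d <- dim(mask)
  out <- mask
  for (z in seq_len(d[1L])) {
    sl <- array(!mask[z, , , drop = FALSE], c(1L, d[2L], d[3L]))
    lab <- label_components(sl)
    border_ids <- unique(c(lab[1L, 1L, ], lab[1L, d[2L], ],
                           lab[1L, , 1L], lab[1L, , d[3L]]))
    hole <- lab > 0L & !(lab %in% border_ids)
    out[z, , ] <- mask[z, , ] | hole[1L, , ]
  }
  out
}
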