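#' Multi-channel 3D image stack
#'
#' Container for a 3D fluorescence acquisition: one numeric voxel array per
#' channel (indexed `[z, y, x]`), the physical voxel pitch, and a map from
#' channel roles (see [CHANNEL_ROLES]) to channel names.
#'
#' @param channels named list of 3D numeric arrays, all the same dimension,
#'   non-negative intensities.
#' @param voxel_size numeric (z, y, x) voxel pitch in micrometres.
#' @param channel_roles named character vector mapping roles (names) to
#'   entries of `channels` (values). A `DAPI` role is required.
#' @return An object of class `image_stack`.
#' @examples
#' a <- array(runif(4 * 8 * 8), c(4, 8, 8))
#' stk <- image_stack(list(dapi = a), c(0.3, 0.1, 0.1), c(DAPI = "dapi"))
#' dim(get_channel(stk, "DAPI"))
#' @export
image_stack <- function(channels, voxel_size, channel_roles) {
  stopifnot(is.list(channels), length(channels) >= 1L,
            !is.null(names(channels)), all(nzchar(names(channels))))
  dims <- lapply(channels, dim)
  if (any(vapply(dims, length, 1L) != 3L)) {
    chr_stop("chromofied_shape_error", "all channels must be 3D arrays")
  }
  if (length(unique(vapply(dims, paste, "", collapse = "x"))) != 1L) {
    chr_stop("chromofied_shape_error", "all channels must share one shape")
  }
  voxel_size <- as.numeric(voxel_size)
  stopifnot(length(voxel_size) == 3L, all(voxel_size > 0))
  channel_roles <- unlist(channel_roles)
  if (!("DAPI" %in% names(channel_roles))) {
    chr_stop("chromofied_config_error", "a DAPI channel role is required")
  }
  bad <- setdiff(names(channel_roles), CHANNEL_ROLES)
  if (length(bad) > 0L) {
    chr_stop("chromofied_config_error",
             paste0("unknown channel role(s): ", paste(bad, collapse = ", ")))
  }
  missing_ch <- setdiff(channel_roles, names(channels))
  if (length(missing_ch) > 0L) {
    chr_stop("chromofied_config_error",
             paste0("roles point at missing channel(s): ",
                    paste(missing_ch, collapse = ", ")))
  }
  structure(list(channels = channels, voxel_size = voxel_size,
                 channel_roles = channel_roles),
            class = "image_stack")
}

#' @export
print.image_stack <- function(x, ...) {
  d <- dim(x$channels[[1L]])
  cat(sprintf("<image_stack> %d x %d x %d (z,y,x), voxel %.3f x %.3f x %.3f um\n",
              d[1L], d[2L], d[3L],
              x$voxel_size[1L], x$voxel_size[2L], x$voxel_size[3L]))
  for (role in names(x$channel_roles)) {
    cat(sprintf("  %-8s -> %s\n", role, x$channel_roles[[role]]))
  }
  invisible(x)
}

#' Extract a channel array by role
#'
#' @param stack an [image_stack()].
#' @param role one of [CHANNEL_ROLES].
#' @return the channel's 3D numeric array.
#' @export
get_channel <- function(stack, role) {
  stopifnot(inherits(stack, "image_stack"))
  if (!(role %in% names(stack$channel_roles))) {
    chr_stop("chromofied_config_error",
             paste0("stack has no channel with role ", role))
  }
  stack$channels[[stack$channel_roles[[role]]]]
}

#' @rdname get_channel
#' @export
has_channel <- function(stack, role) {
  role %in% names(stack$channel_roles)
}

#' Write / read an image stack as multi-page TIFF plus sidecar metadata
#'
#' Channels are concatenated along pages (channel-major: all z of channel 1,
#' then channel 2, ...) in a 32-bit float baseline TIFF; voxel size and the
#' channel/role map go to a `<path>.meta.tsv` sidecar so the stack
#' round-trips exactly.
#'
#' @param stack an [image_stack()].
#' @param path output TIFF path.
#' @return `write_image_stack` returns `path` invisibly; `read_image_stack`
#'   returns an [image_stack()].
#' @export
write_image_stack <- function(stack, path) {
  stopifnot(inherits(stack, "image_stack"))
  d <- dim(stack$channels[[1L]])
  slices <- list()
  for (ch in names(stack$channels)) {
    a <- stack$channels[[ch]]
    for (z in seq_len(d[1L])) {
      slices[[length(slices) + 1L]] <- matrix(a[z, , ], d[2L], d[3L])
    }
  }
  write_tiff(slices, path)
  meta <- data.frame(
    key = c("n_channels", "nz", "channels", "voxel_z", "voxel_y", "voxel_x",
            paste0("role_", names(stack$channel_roles))),
    value = c(length(stack$channels), d[1L],
              paste(names(stack$channels), collapse = ","),
              stack$voxel_size, unname(stack$channel_roles)))
  write.table(meta, paste0(path, ".meta.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' @rdname write_image_stack
#' @export
read_image_stack <- function(path) {
  meta <- read.table(paste0(path, ".meta.tsv"), sep = "\t", header = TRUE,
                     colClasses = "character")
  kv <- setNames(meta$value, meta$key)
  nz <- as.integer(kv[["nz"]])
  ch_names <- strsplit(kv[["channels"]], ",", fixed = TRUE)[[1L]]
  slices <- read_tiff(path)
  stopifnot(length(slices) == nz * length(ch_names))
  d2 <- dim(slices[[1L]])
  channels <- list()
  for (i in seq_along(ch_names)) {
    a <- array(0, c(nz, d2[1L], d2[2L]))
    for (z in seq_len(nz)) a[z, , ] <- slices[[(i - 1L) * nz + z]]
    channels[[ch_names[i]]] <- a
  }
  roles_idx <- grepl("^role_", names(kv))
  roles <- setNames(unname(kv[roles_idx]), sub("^role_", "", names(kv)[roles_idx]))
  image_stack(channels,
              as.numeric(c(kv[["voxel_z"]], kv[["voxel_y"]], kv[["voxel_x"]])),
              roles)
}
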