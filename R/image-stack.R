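# Two-channel confocal stacks: container plus TIFF I/O.

#' Confocal image stack
#'
#' A 3-D voxel grid per channel, indexed `[z, y, x]` with slice `z = 1` at the
#' substratum plane (thickness and roughness are substratum-referenced).
#' Channels are typically `cells` (nucleic-acid stain) and `eps`
#' (polysaccharide stain) and must share dimensions.
#'
#' @param channels named list of 3-D arrays (numeric intensities or logical).
#' @param voxel_size `c(dz, dy, dx)` in micrometres, all > 0.
#' @return object of class `image_stack`.
#' @export
image_stack <- function(channels, voxel_size) {
  if (!is.list(channels) || is.null(names(channels)) || any(names(channels) == ""))
    stop("'channels' must be a named list of 3-D arrays", call. = FALSE)
  dims <- lapply(channels, dim)
  if (any(vapply(dims, length, integer(1)) != 3L))
    stop("each channel must be a 3-D array indexed [z, y, x]", call. = FALSE)
  if (length(unique(lapply(dims, as.integer))) != 1L)
    stop("channel shape mismatch: all channels must share dimensions",
         call. = FALSE)
  if (length(voxel_size) != 3L || any(!is.finite(voxel_size)) || any(voxel_size <= 0))
    stop("'voxel_size' must be c(dz, dy, dx) in um, all > 0", call. = FALSE)
  structure(list(channels = channels,
                 voxel_size = as.numeric(voxel_size)),
            class = "image_stack")
}

#' @export
print.image_stack <- function(x, ...) {
  d <- dim(x$channels[[1]])
  cat(sprintf("Image stack: %d z-slice(s) x %d x %d, voxel %.3g x %.3g x %.3g um\n",
              d[1], d[2], d[3],
              x$voxel_size[1], x$voxel_size[2], x$voxel_size[3]))
  cat("  channels:", paste(names(x$channels), collapse = ", "), "\n")
  invisible(x)
}

#' @export
dim.image_stack <- function(x) dim(x$channels[[1]])

#' Read a confocal stack from multi-page TIFF
#'
#' Two layouts are supported: one single-channel multi-page TIFF per channel
#' (`path` a named character vector, one file per channel), or one interleaved
#' TIFF whose pages alternate between channels in the order given by
#' `channel_names`. Voxel size is not read from TIFF metadata and must be
#' supplied. If the stack was acquired top-down, set
#' `acquisition = "top-down"` to flip the z axis so slice 1 is the substratum.
#'
#' @param path character vector of file path(s). For the per-channel layout,
#'   names give channel roles (e.g. `c(cells = "a.tif", eps = "b.tif")`).
#' @param voxel_size `c(dz, dy, dx)` in micrometres.
#' @param channel_names channel order for the interleaved layout.
#' @param acquisition `"bottom-up"` (slice 1 already the substratum) or
#'   `"top-down"` (z axis reversed on read).
#' @return an [image_stack()].
#' @export
read_image_stack <- function(path, voxel_size = NULL,
                             channel_names = c("cells", "eps"),
                             acquisition = c("bottom-up", "top-down")) {
  acquisition <- match.arg(acquisition)
  if (is.null(voxel_size))
    stop("'voxel_size' must be given: TIFF metadata is not parsed", call. = FALSE)
  for (p in path)
    if (!file.exists(p)) stop("file not found: '", p, "'", call. = FALSE)

  read_pages <- function(p) {
    pages <- tiff::readTIFF(p, all = TRUE, as.is = FALSE)
    if (!is.list(pages)) pages <- list(pages)
    pages
  }
  pages_to_array <- function(pages) {
    d <- dim(pages[[1]])
    arr <- array(0, dim = c(length(pages), d[1], d[2]))
    for (z in seq_along(pages)) {
      pg <- pages[[z]]
      if (!identical(dim(pg), d))
        stop("page shape mismatch within TIFF", call. = FALSE)
      arr[z, , ] <- pg
    }
    arr
  }

  per_channel <- !is.null(names(path)) && all(names(path) != "")
  if (per_channel) {
    channels <- lapply(path, function(p) pages_to_array(read_pages(p)))
    names(channels) <- names(path)
  } else if (length(path) > 1L) {
    stop("per-channel TIFFs must be a named vector mapping role -> file",
         call. = FALSE)
  } else {
    pages <- read_pages(path)
    k <- length(channel_names)
    if (length(pages) %% k != 0L)
      stop("interleaved TIFF page count (", length(pages),
           ") is not a multiple of the channel count (", k, ")", call. = FALSE)
    channels <- lapply(seq_len(k), function(i) {
      pages_to_array(pages[seq(i, length(pages), by = k)])
    })
    names(channels) <- channel_names
  }

  dims <- unique(lapply(channels, dim))
  if (length(dims) != 1L)
    stop("channel shape mismatch between TIFF files", call. = FALSE)

  if (acquisition == "top-down") {
    nz <- dim(channels[[1]])[1]
    channels <- lapply(channels, function(a) a[nz:1, , , drop = FALSE])
  }
  image_stack(channels, voxel_size)
}

#' Write a stack as one multi-page TIFF per channel
#'
#' Logical channels are written as 8-bit 0/1 images and read back exactly;
#' numeric channels must lie in `[0, 1]` (the TIFF convention used by the
#' `tiff` package).
#'
#' @param stack an [image_stack()].
#' @param paths named character vector, one output file per channel.
#' @return `paths`, invisibly.
#' @export
write_image_stack <- function(stack, paths) {
  if (!all(names(stack$channels) %in% names(paths)))
    stop("'paths' must name a file for every channel", call. = FALSE)
  for (ch in names(stack$channels)) {
    a <- stack$channels[[ch]]
    if (is.logical(a)) a <- a * 1.0
    if (any(a < 0 | a > 1))
      stop("channel '", ch, "' has intensities outside [0, 1]; rescale ",
           "before writing", call. = FALSE)
    pages <- lapply(seq_len(dim(a)[1]), function(z) a[z, , ])
    tiff::writeTIFF(pages, paths[[ch]], bits.per.sample = 8L)
  }
  invisible(paths)
}
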