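# Raster I/O and programmatic fixture images. PNG/JPEG go through the png and
# jpeg packages when present; ASCII netpbm (P2/P3) is the dependency-free
# text format used for fixtures.

#' Read a raster image as an H x W x C array in [0, 1]
#'
#' Dispatches on the file extension: `.png` (needs the png package), `.jpg` /
#' `.jpeg` (needs jpeg), `.pgm` / `.ppm` / `.pnm` (ASCII netpbm, built in).
#'
#' @param path file path.
#' @return numeric array `H x W x C`, values in `[0, 1]`.
#' @export
read_image <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  ext <- tolower(sub(".*\\.", "", path))
  img <- switch(ext,
    png = {
      if (!requireNamespace("png", quietly = TRUE))
        stop("reading PNG requires the 'png' package", call. = FALSE)
      png::readPNG(path)
    },
    jpg = ,
    jpeg = {
      if (!requireNamespace("jpeg", quietly = TRUE))
        stop("reading JPEG requires the 'jpeg' package", call. = FALSE)
      jpeg::readJPEG(path)
    },
    pgm = ,
    ppm = ,
    pnm = read_pnm(path),
    stop("unsupported image extension: .", ext, call. = FALSE))
  if (is.matrix(img)) img <- array(img, c(dim(img), 1L))
  if (length(dim(img)) == 3L && dim(img)[3L] == 4L)
    img <- img[, , 1:3, drop = FALSE]   # drop alpha
  img
}

#' Read an ASCII netpbm image (P2 greymap or P3 pixmap)
#'
#' @param path file path.
#' @return numeric array `H x W x C` (C = 1 for P2, 3 for P3) in `[0, 1]`.
#' @export
read_pnm <- function(path) {
  txt <- readLines(path, warn = FALSE)
  txt <- sub("#.*$", "", txt)
  tok <- scan(text = paste(txt, collapse = " "), what = character(),
              quiet = TRUE)
  magic <- tok[1L]
  if (!magic %in% c("P2", "P3"))
    stop("only ASCII netpbm (P2/P3) is supported, got ", magic, call. = FALSE)
  nums <- as.numeric(tok[-1L])
  W <- nums[1L]; H <- nums[2L]; maxval <- nums[3L]
  px <- nums[-(1:3)]
  C <- if (magic == "P2") 1L else 3L
  if (length(px) != H * W * C)
    stop("pixel count mismatch in ", path, call. = FALSE)
  # file order: row-major, channels interleaved
  a <- array(0, c(H, W, C))
  for (cc in seq_len(C)) {
    a[, , cc] <- matrix(px[seq(cc, length(px), by = C)],
                        nrow = H, ncol = W, byrow = TRUE)
  }
  a / maxval
}

#' Write an array as ASCII netpbm (P2 if 1 channel, P3 if 3)
#'
#' @param image `H x W x C` array (C 1 or 3) with values in `[0, 1]`.
#' @param path output path.
#' @param maxval integer maximum pixel value.
#' @return `path`, invisibly.
#' @export
write_pnm <- function(image, path, maxval = 255L) {
  if (is.matrix(image)) image <- array(image, c(dim(image), 1L))
  d <- dim(image)
  if (length(d) != 3L || !d[3L] %in% c(1L, 3L))
    stop("image must be H x W x 1 or H x W x 3", call. = FALSE)
  q <- round(pmin(pmax(image, 0), 1) * maxval)
  magic <- if (d[3L] == 1L) "P2" else "P3"
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(magic, paste(d[2L], d[1L]), as.character(maxval)), con)
  # row-major, channel-interleaved
  for (i in seq_len(d[1L])) {
    row <- as.vector(t(matrix(q[i, , ], d[2L], d[3L])))
    writeLines(paste(row, collapse = " "), con)
  }
  invisible(path)
}

#' Generate fixture images spanning a range of structure and contrast
#'
#' Produces a seeded mixture of oriented gratings, Gaussian blobs and
#' filtered-noise textures whose contrast and spatial scale vary, which is
#' enough to spread the network's entropy-collapse rates. These are stand-ins
#' for natural scenes, not models of them.
#'
#' @param n number of images.
#' @param size `c(height, width)` in pixels.
#' @param channels 1 (greyscale) or 3.
#' @param seed integer seed.
#' @param dir if non-`NULL`, images are also written there as ASCII netpbm
#'   files named `fix####.pgm`/`.ppm`.
#' @return named list of `H x W x channels` arrays in `[0, 1]`.
#' @export
make_fixture_images <- function(n, size = c(32L, 32L), channels = 3L,
                                seed = 1L, dir = NULL) {
  stopifnot(n >= 1L, channels %in% c(1L, 3L))
  set.seed(seed)
  H <- size[1L]; W <- size[2L]
  yy <- matrix(seq(0, 1, length.out = H), H, W)
  xx <- matrix(seq(0, 1, length.out = W), H, W, byrow = TRUE)
  one <- function(kind) {
    contrast <- stats::runif(1, 0.1, 1)
    base <- switch(kind,
      grating = {
        f <- stats::runif(1, 1, 8)
        th <- stats::runif(1, 0, pi)
        0.5 + 0.5 * sin(2 * pi * f * (cos(th) * xx + sin(th) * yy) +
                        stats::runif(1, 0, 2 * pi))
      },
      blob = {
        cx <- stats::runif(1, 0.2, 0.8); cy <- stats::runif(1, 0.2, 0.8)
        s <- stats::runif(1, 0.05, 0.3)
        exp(-((xx - cx)^2 + (yy - cy)^2) / (2 * s^2))
      },
      noise = {
        z <- matrix(stats::runif(H * W), H, W)
        k <- sample(1:3, 1)          # crude smoothing radius
        if (k > 1) {
          z <- t(apply(apply(z, 2, stats::filter, rep(1 / k, k)), 1,
                       stats::filter, rep(1 / k, k)))
          z[is.na(z)] <- 0.5
        }
        z
      })
    base <- 0.5 + contrast * (base - 0.5)
    a <- array(0, c(H, W, channels))
    for (cc in seq_len(channels)) {
      gain <- if (channels == 3L) stats::runif(1, 0.6, 1) else 1
      a[, , cc] <- pmin(pmax(0.5 + gain * (base - 0.5), 0), 1)
    }
    a
  }
  kinds <- sample(c("grating", "blob", "noise"), n, replace = TRUE)
  imgs <- lapply(kinds, one)
  names(imgs) <- sprintf("fix%04d", seq_len(n))
  if (!is.null(dir)) {
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    ext <- if (channels == 1L) "pgm" else "ppm"
    for (id in names(imgs))
      write_pnm(imgs[[id]], file.path(dir, paste0(id, ".", ext)))
  }
  imgs
}
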