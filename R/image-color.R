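#' Read an image as an 8-bit sRGB raster
#'
#' Reads a PNG or JPEG image and returns it as an integer array of shape
#' `height x width x 3` with channel values in \[0, 255\].  Grayscale images
#' are expanded to three identical channels; an alpha channel, if present,
#' is dropped.
#'
#' @param path path to a PNG or JPEG file.
#' @return integer array `c(height, width, 3)`.
#' @export
readImageRaster <- function(path) {
    img <- EBImage::readImage(path)
    d <- dim(img)
    px <- EBImage::imageData(img)
    if (length(d) == 2L) {
        px <- array(rep(px, 3L), dim = c(d[1], d[2], 3L))
    } else if (d[3] >= 3L) {
        px <- px[, , 1:3, drop = FALSE]
    } else {
        px <- array(rep(px[, , 1L], 3L), dim = c(d[1], d[2], 3L))
    }
    # EBImage stores x (width) first; rasters here are row-major height x width
    out <- aperm(px, c(2L, 1L, 3L))
    array(as.integer(roundHalfAway(out * 255)), dim = dim(out))
}

#' Write an 8-bit sRGB raster to an image file
#'
#' Inverse of [readImageRaster()]: writes a `height x width x 3` integer
#' array (channels in \[0, 255\]) as PNG or JPEG, chosen from the file
#' extension.
#'
#' @param image integer array `c(height, width, 3)`.
#' @param path output path ending in `.png`, `.jpg` or `.jpeg`.
#' @return `path`, invisibly.
#' @export
writeImageRaster <- function(image, path) {
    .checkRaster(image)
    px <- aperm(image / 255, c(2L, 1L, 3L))
    img <- EBImage::Image(px, colormode = "Color")
    EBImage::writeImage(img, path)
    invisible(path)
}

#' Read a region mask
#'
#' Reads a petal-selection mask as a logical `height x width` matrix.
#' Supported formats: a single-channel PNG where nonzero pixels are
#' selected, or a plain-text run-length file (see [writeRegionMaskRle()]).
#'
#' @param path path to a mask PNG or a `.rle` text file.
#' @return logical matrix `height x width`.
#' @export
readRegionMask <- function(path) {
    if (grepl("\\.rle$", path, ignore.case = TRUE))
        return(readRegionMaskRle(path))
    img <- EBImage::readImage(path)
    px <- EBImage::imageData(img)
    if (length(dim(px)) == 3L)
        px <- px[, , 1L]
    t(px != 0)
}

#' Run-length text encoding of region masks
#'
#' A mask run-length file is plain text: the first line holds
#' `height width`; every following line holds `row start end` (1-based,
#' inclusive column range of selected pixels in that row).
#'
#' @param mask logical matrix `height x width`.
#' @param path output file path.
#' @return `writeRegionMaskRle()` returns `path` invisibly;
#'   `readRegionMaskRle()` returns a logical matrix.
#' @export
writeRegionMaskRle <- function(mask, path) {
    stopifnot(is.matrix(mask))
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(paste(nrow(mask), ncol(mask)), con)
    for (i in seq_len(nrow(mask))) {
        r <- rle(as.logical(mask[i, ]))
        ends <- cumsum(r$lengths)
        starts <- ends - r$lengths + 1L
        sel <- which(r$values)
        if (length(sel))
            writeLines(paste(i, starts[sel], ends[sel]), con)
    }
    invisible(path)
}

#' @rdname writeRegionMaskRle
#' @export
readRegionMaskRle <- function(path) {
    lines <- readLines(path)
    dims <- as.integer(strsplit(lines[1], "\\s+")[[1]])
    mask <- matrix(FALSE, dims[1], dims[2])
    for (ln in lines[-1]) {
        f <- as.integer(strsplit(ln, "\\s+")[[1]])
        mask[f[1], f[2]:f[3]] <- TRUE
    }
    mask
}

.checkRaster <- function(image) {
    if (!is.array(image) || length(dim(image)) != 3L || dim(image)[3] != 3L)
        stop("image must be a height x width x 3 array")
    if (any(is.na(image)) || any(image < 0 | image > 255))
        stop("image channel values must lie in [0, 255]")
    invisible(image)
}

.regionMeans <- function(image, mask) {
    .checkRaster(image)
    if (!is.matrix(mask) || !identical(dim(mask), dim(image)[1:2]))
        stop("mask dimensions must match the image")
    mask <- mask != 0
    n <- sum(mask)
    if (n == 0L)
        stop("region mask selects no pixels")
    c(r = mean(image[, , 1][mask]),
      g = mean(image[, , 2][mask]),
      b = mean(image[, , 3][mask]),
      n = n)
}

#' Average the color of a masked region
#'
#' Collapses a selected image region to a single sRGB triple by taking the
#' per-channel arithmetic mean over the masked pixels and rounding half away
#' from zero to 8-bit integers.  This reproduces, as a plain mean, the
#' photo-editor workflow of resizing a copied petal selection to a single
#' 1x1 pixel.  Averaging happens directly on the stored 8-bit sRGB values
#' (no linear-light conversion), matching what a default sRGB resize does.
#'
#' @param image integer array `height x width x 3`, channels in \[0, 255\].
#' @param mask logical (or 0/1) matrix matching the image dimensions;
#'   `TRUE` marks selected pixels.
#' @return named integer vector `c(r, g, b)`.
#' @examples
#' img <- array(0L, c(2, 2, 3))
#' img[, , 1] <- c(255, 255, 0, 0)   # half red, half cyan
#' img[, , 2] <- c(0, 0, 255, 255)
#' img[, , 3] <- c(0, 0, 255, 255)
#' averageRegionColor(img, matrix(TRUE, 2, 2))  # averages to gray
#' @export
averageRegionColor <- function(image, mask) {
    m <- .regionMeans(image, mask)
    stats::setNames(as.integer(roundHalfAway(m[c("r", "g", "b")])),
                    c("r", "g", "b"))
}

#' Average the color of several regions
#'
#' Combines several petal samples into one color.  With `weighting =
#' "equal"` (the default) each region contributes equally regardless of its
#' pixel count — the behaviour when equal-sized samples are pasted in a row
#' and resized to one pixel.  With `weighting = "pixels"` all selected
#' pixels are pooled, which is faithful to the paste-then-resize mechanics
#' when the sample areas differ.
#'
#' @inheritParams averageRegionColor
#' @param masks a list of masks, each as in [averageRegionColor()].
#' @param weighting `"equal"` or `"pixels"`.
#' @return named integer vector `c(r, g, b)`.
#' @export
averageMultiRegion <- function(image, masks,
                               weighting = c("equal", "pixels")) {
    weighting <- match.arg(weighting)
    if (!is.list(masks) || length(masks) == 0L)
        stop("supply a non-empty list of region masks")
    means <- t(vapply(masks, function(m) .regionMeans(image, m),
                      numeric(4)))
    w <- if (weighting == "equal") rep(1, nrow(means)) else means[, "n"]
    avg <- colSums(means[, c("r", "g", "b"), drop = FALSE] * w) / sum(w)
    stats::setNames(as.integer(roundHalfAway(avg)), c("r", "g", "b"))
}
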