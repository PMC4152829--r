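#' @title Bipolar hue values
#'
#' @description
#' `BipolarHue` is a numeric vector on the bipolar hue scale, the
#' linearization of the hue circle onto \[-60, 40\] obtained by cutting the
#' circle at red so that pure blue (240 degrees) sits near zero.  One bipolar
#' unit equals 3.6 degrees.  Exact red is the cut point and is printed dually
#' as `40/-60`; the `redWrap` slot records which elements are exact red so
#' that display code can render the dual label while arithmetic stays a
#' function.
#'
#' @slot redWrap logical vector, one flag per value; `TRUE` only for values
#'   arising from a hue of exactly 0 degrees (mod 360).
#'
#' @seealso [hueToBipolar()], [bipolarToHue()], [bipolarLabel()]
#' @examples
#' b <- hueToBipolar(c(0, 120, 240, 360))
#' as.numeric(b)
#' redWrap(b)
#' @exportClass BipolarHue
setClass("BipolarHue",
    contains = "numeric",
    representation(redWrap = "logical"))

setValidity("BipolarHue", function(object) {
    v <- as.numeric(object)
    if (length(object@redWrap) != length(v))
        return("redWrap must have one flag per value")
    ok <- is.na(v) | (v >= -60 & v <= 40)
    if (!all(ok))
        return("bipolar hue values must lie in [-60, 40]")
    # 40 is reachable only through the 360-degree wrap input
    at40 <- !is.na(v) & v == 40
    if (any(at40 & !object@redWrap))
        return("value 40 is only valid at the red wrap (hue 360)")
    wrapped <- !is.na(v) & object@redWrap
    if (any(wrapped & !(v == -60 | v == 40)))
        return("redWrap may be set only where the value is -60 or 40")
    TRUE
})

#' @describeIn BipolarHue-class extract the red-wrap flags.
#' @param x a `BipolarHue` object.
#' @export
redWrap <- function(x) {
    stopifnot(is(x, "BipolarHue"))
    x@redWrap
}

setMethod("show", "BipolarHue", function(object) {
    cat("BipolarHue of length", length(object), "\n")
    print(bipolarLabel(object))
    invisible(object)
})

#' Round half away from zero
#'
#' Commercial rounding used to reproduce printed tables: ties are rounded
#' away from zero (so 23.5 -> 24 and -23.5 -> -24), unlike [round()]'s
#' round-half-to-even.  Internal computation is always full precision; this
#' helper exists for display fidelity only.
#'
#' @param x numeric vector.
#' @param digits integer, decimal places to keep.
#' @return numeric vector rounded to `digits` places.
#' @examples
#' roundHalfAway(c(0.5, -0.5, 23.333, -26.6667), 2)
#' @export
roundHalfAway <- function(x, digits = 0) {
    p <- 10^digits
    sign(x) * floor(abs(x) * p + 0.5) / p
}

.checkChannels <- function(r, g, b) {
    rgb <- cbind(r = r, g = g, b = b)
    if (any(is.na(rgb)))
        stop("RGB channels must not contain missing values")
    if (any(rgb < 0 | rgb > 255))
        stop("RGB channels must lie in [0, 255]")
    rgb
}

.rgbArgs <- function(r, g, b) {
    if (is.null(g) && is.null(b)) {
        m <- if (is.data.frame(r)) as.matrix(r) else r
        if (!is.matrix(m) || ncol(m) != 3L)
            stop("supply three channel vectors or an n x 3 matrix")
        list(r = m[, 1L], g = m[, 2L], b = m[, 3L])
    } else {
        list(r = r, g = g, b = b)
    }
}

#' Convert 8-bit sRGB to HSV
#'
#' Standard hexcone conversion of 8-bit sRGB triples (the 0-255 Photoshop
#' convention) to hue/saturation/value.  Hue is reported in degrees
#' \[0, 360); saturation and value in percent.  Achromatic colors
#' (saturation 0, i.e. `r == g == b`) have no hue: `h_degree` is `NA` for
#' them, never a silent 0, and every downstream classifier branches on that
#' tag.
#'
#' @param r,g,b integer channel vectors in \[0, 255\]; alternatively `r` may
#'   be an n x 3 matrix or data frame of channels with `g` and `b` omitted.
#' @return a data frame with columns `h_degree` (degrees or `NA`),
#'   `s_percent` and `v_percent`.
#' @examples
#' rgbToHsv(0, 0, 255)        # pure blue: 240 degrees
#' rgbToHsv(128, 128, 128)    # gray: hue undefined
#' @export
rgbToHsv <- function(r, g = NULL, b = NULL) {
    a <- .rgbArgs(r, g, b)
    .checkChannels(a$r, a$g, a$b)
    hsv <- grDevices::rgb2hsv(a$r, a$g, a$b, maxColorValue = 255)
    h <- hsv["h", ] * 360
    s <- hsv["s", ] * 100
    v <- hsv["v", ] * 100
    h[s == 0] <- NA_real_
    data.frame(h_degree = unname(h), s_percent = unname(s),
               v_percent = unname(v))
}

#' Convert HSV to 8-bit sRGB
#'
#' Inverse hexcone conversion; channels are rounded to the nearest 8-bit
#' integer.  An undefined (`NA`) hue is only consistent with zero
#' saturation.
#'
#' @param h hue in degrees \[0, 360\], or `NA` for achromatic colors;
#'   alternatively a data frame as returned by [rgbToHsv()] with `s` and `v`
#'   omitted.
#' @param s,v saturation and value in percent \[0, 100\].
#' @return a data frame with integer columns `r`, `g`, `b`.
#' @examples
#' hsvToRgb(240, 100, 100)  # pure blue
#' hsvToRgb(NA, 0, 100)     # white
#' @export
hsvToRgb <- function(h, s = NULL, v = NULL) {
    if (is.null(s) && is.null(v) && is.data.frame(h)) {
        s <- h$s_percent
        v <- h$v_percent
        h <- h$h_degree
    }
    n <- max(length(h), length(s), length(v))
    h <- rep_len(h, n); s <- rep_len(s, n); v <- rep_len(v, n)
    if (any(is.na(s)) || any(is.na(v)) || any(s < 0 | s > 100) ||
        any(v < 0 | v > 100))
        stop("saturation and value must lie in [0, 100]")
    if (any(is.na(h) & s > 0))
        stop("undefined hue is inconsistent with saturation > 0")
    if (any(!is.na(h) & (h < 0 | h > 360)))
        stop("hue must lie in [0, 360] degrees")
    hh <- ifelse(is.na(h), 0, h)
    cols <- grDevices::hsv(hh / 360, s / 100, v / 100)
    m <- t(grDevices::col2rgb(cols))
    data.frame(r = as.integer(m[, "red"]), g = as.integer(m[, "green"]),
               b = as.integer(m[, "blue"]))
}

#' Map hue degrees onto the bipolar scale
#'
#' The affine transform `h * 100/360 - 60` maps the hue circle, cut at red,
#' onto the bipolar range \[-60, 40\]: 0 degrees (red) maps to -60, 240
#' degrees (blue) to 6.67, and the closed upper wrap 360 degrees to 40.
#' Exact red (0 or 360) is flagged via the `redWrap` slot because it is
#' conventionally printed dually as `40/-60`.  `NA` (undefined) hues
#' propagate as `NA`, never as a number.
#'
#' @param h hue in degrees, in \[0, 360\]; `NA` allowed.
#' @return a [BipolarHue-class] vector.
#' @examples
#' as.numeric(hueToBipolar(120))   # pure green, -26.67
#' hueToBipolar(c(0, 360))         # the red wrap, printed 40/-60
#' @export
hueToBipolar <- function(h) {
    h <- as.numeric(h)
    if (any(!is.na(h) & (h < 0 | h > 360)))
        stop("hue must lie in [0, 360] degrees")
    v <- h * 100 / 360 - 60
    wrap <- !is.na(h) & (h %% 360) == 0
    new("BipolarHue", v, redWrap = wrap)
}

#' Map bipolar hue values back to degrees
#'
#' Exact inverse of [hueToBipolar()]: `(b + 60) * 3.6`.
#'
#' @param b a [BipolarHue-class] vector or plain numeric in \[-60, 40\].
#' @return hue in degrees; `NA` propagates.
#' @examples
#' bipolarToHue(-26.67)  # about 120 degrees (green)
#' @export
bipolarToHue <- function(b) {
    v <- as.numeric(b)
    if (any(!is.na(v) & (v < -60 | v > 40)))
        stop("bipolar hue values must lie in [-60, 40]")
    (v + 60) * 3.6
}

#' Printed form of bipolar hue values
#'
#' Renders bipolar hue values at a chosen precision with round-half-away
#' rounding; exact red is rendered with its conventional dual label
#' `40/-60`.
#'
#' @param b a [BipolarHue-class] vector or plain numeric.
#' @param digits decimal places for the printed value.
#' @return character vector.
#' @examples
#' bipolarLabel(hueToBipolar(c(0, 240, 300)))
#' @export
bipolarLabel <- function(b, digits = 0) {
    v <- as.numeric(b)
    wrap <- if (is(b, "BipolarHue")) redWrap(b)
            else !is.na(v) & (v == -60 | v == 40)
    out <- formatC(roundHalfAway(v, digits), format = "f", digits = digits)
    out[wrap] <- "40/-60"
    out[is.na(v)] <- NA_character_
    out
}
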