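#' @title The controlled flower-color vocabulary
#'
#' @description
#' `ColorVocabulary` holds the fourteen color terms used for annotation:
#' eight principal colors (red, magenta, purple, blue, cyan, green, yellow,
#' orange), each anchored at an exact RGB/HSV definition and a PATO URI, and
#' six intermediate terms (greenish-yellow, yellowish-orange, orangish-red,
#' reddish-purple, purplish-blue, bluish-green), each naming a half-open hue
#' range `[lo, hi)` with a PATO or EOL URI.  The six intermediate ranges
#' partition the hue circle \[0, 360) with no gap or overlap, which the class
#' validity enforces.
#'
#' Purple is kept as a distinct term for URI fidelity, but hue
#' classification treats purple and magenta as synonymous (both sit at 300
#' degrees; purple is the half-value form), so purple is never returned by
#' [principalTermForHue()].
#'
#' Display strings (`hsv_printed`, `bipolar_printed`) are stored verbatim as
#' conventionally printed, including the red wrap notation `40/-60` /
#' `-60(0)` and historical roundings that differ from the exact transform;
#' all numeric logic derives from the degree columns only.
#'
#' @slot terms a data frame with one row per term: `label`, `kind`
#'   (`"principal"` or `"intermediate"`), `anchor_hue`, `r`, `g`, `b`
#'   (principal only), `range_lo`, `range_hi` (intermediate only),
#'   `hsv_printed`, `bipolar_printed`, `uri`.
#'
#' @seealso [colorVocabulary()], [rangeTermForHue()], [principalTermForHue()]
#' @exportClass ColorVocabulary
setClass("ColorVocabulary", representation(terms = "data.frame"))

.uriPrefixes <- c("http://purl.obolibrary.org/obo/PATO_",
                  "http://eol.org/schema/terms/")

setValidity("ColorVocabulary", function(object) {
    t <- object@terms
    need <- c("label", "kind", "anchor_hue", "r", "g", "b", "range_lo",
              "range_hi", "hsv_printed", "bipolar_printed", "uri")
    if (!all(need %in% names(t)))
        return("missing registry columns")
    if (!all(t$kind %in% c("principal", "intermediate")))
        return("kind must be principal or intermediate")
    pr <- t$kind == "principal"
    if (any(is.na(t$anchor_hue[pr])) || any(!is.na(t$range_lo[pr])))
        return("principal terms must set anchor_hue and not a range")
    if (any(!is.na(t$anchor_hue[!pr])) || any(is.na(t$range_lo[!pr])))
        return("intermediate terms must set a range and not an anchor")
    ok <- vapply(t$uri, function(u) any(startsWith(u, .uriPrefixes)),
                 logical(1))
    if (!all(ok))
        return("URIs must be PATO purl or EOL schema identifiers")
    # the intermediate ranges must partition [0, 360)
    iv <- t[!pr, c("range_lo", "range_hi")]
    iv <- iv[order(iv$range_lo), ]
    if (nrow(iv) > 0 &&
        (iv$range_lo[1] != 0 || iv$range_hi[nrow(iv)] != 360 ||
         any(iv$range_hi[-nrow(iv)] != iv$range_lo[-1])))
        return("intermediate ranges must partition [0, 360)")
    TRUE
})

setMethod("show", "ColorVocabulary", function(object) {
    t <- object@terms
    cat("ColorVocabulary with", sum(t$kind == "principal"),
        "principal and", sum(t$kind == "intermediate"),
        "intermediate color terms\n")
    print(t[, c("label", "kind", "anchor_hue", "range_lo", "range_hi",
                "uri")], row.names = FALSE)
    invisible(object)
})

#' Construct the color-term registry
#'
#' Builds the immutable vocabulary of eight principal and six intermediate
#' color terms with their RGB/HSV anchors, hue ranges, printed display
#' strings and PATO/EOL URIs.
#'
#' @return a [ColorVocabulary-class] object.
#' @examples
#' vocab <- colorVocabulary()
#' colorTerm(vocab, "blue")
#' @export
colorVocabulary <- function() {
    pato <- function(id) paste0("http://purl.obolibrary.org/obo/PATO_", id)
    eol <- function(slug) paste0("http://eol.org/schema/terms/", slug)
    p <- data.frame(
        label = c("red", "magenta", "purple", "blue", "cyan", "green",
                  "yellow", "orange"),
        kind = "principal",
        anchor_hue = c(0, 300, 300, 240, 180, 120, 60, 30),
        r = c(255, 255, 128, 0, 0, 0, 255, 255),
        g = c(0, 0, 0, 0, 255, 255, 255, 128),
        b = c(0, 255, 128, 255, 255, 0, 0, 0),
        range_lo = NA_real_, range_hi = NA_real_,
        hsv_printed = c("0°,100%,100%", "300°,100%,100%",
                        "300°,100%,50%", "240°,100%,100%",
                        "180°,100%,100%", "120°,100%,100%",
                        "60°,100%,100%", "30°,100%,100%"),
        bipolar_printed = c("40/-60", "20", "20", "7", "-10", "-30",
                            "-43", "-52"),
        uri = c(pato("0000322"), pato("0000321"), pato("0000951"),
                pato("0000318"), pato("0000319"), pato("0000320"),
                pato("0000324"), pato("0000953")),
        stringsAsFactors = FALSE)
    i <- data.frame(
        label = c("greenish-yellow", "yellowish-orange", "orangish-red",
                  "reddish-purple", "purplish-blue", "bluish-green"),
        kind = "intermediate",
        anchor_hue = NA_real_,
        r = NA_integer_, g = NA_integer_, b = NA_integer_,
        range_lo = c(60, 30, 0, 300, 240, 120),
        range_hi = c(120, 60, 30, 360, 300, 240),
        hsv_printed = NA_character_,
        bipolar_printed = c("-43,-27", "-51,-43", "-60(0),-51",
                            "23,-60(0)", "7,23", "-27,7"),
        uri = c(pato("0001941"), pato("0001944"), eol("orangish-red"),
                eol("reddish-purple"), eol("purplish-blue"),
                eol("bluish-green")),
        stringsAsFactors = FALSE)
    new("ColorVocabulary", terms = rbind(p, i))
}

#' Access the vocabulary term table
#'
#' @param vocab a [ColorVocabulary-class] object.
#' @param kind optionally restrict to `"principal"` or `"intermediate"`
#'   terms.
#' @return a data frame, one row per term.
#' @export
colorTerms <- function(vocab, kind = NULL) {
    stopifnot(is(vocab, "ColorVocabulary"))
    t <- vocab@terms
    if (!is.null(kind)) {
        kind <- match.arg(kind, c("principal", "intermediate"))
        t <- t[t$kind == kind, , drop = FALSE]
    }
    rownames(t) <- NULL
    t
}

#' Look up one term by label
#'
#' @inheritParams colorTerms
#' @param label a term label, e.g. `"blue"` or `"purplish-blue"`.
#' @return a one-row data frame.
#' @export
colorTerm <- function(vocab, label) {
    t <- colorTerms(vocab)
    hit <- t[t$label == label, , drop = FALSE]
    if (nrow(hit) != 1L)
        stop("unknown color term: ", label)
    rownames(hit) <- NULL
    hit
}

.requireDefinedHue <- function(h) {
    if (any(is.na(h)))
        stop("hue is undefined (achromatic color); use the achromatic ",
             "annotation path instead of hue classification")
    if (any(h < 0 | h >= 360))
        stop("hue must lie in [0, 360) degrees")
    h
}

#' Intermediate range term containing a hue
#'
#' Returns the unique intermediate color term whose half-open degree range
#' `[lo, hi)` contains each hue.  A hue exactly on a boundary belongs to the
#' range that starts there (so 240 degrees is purplish-blue, not
#' bluish-green).
#'
#' @param h hue in degrees, in \[0, 360); must be defined (not `NA`).
#' @param vocab a [ColorVocabulary-class] object.
#' @return a data frame with one row per input hue, columns `label` and
#'   `uri`.
#' @examples
#' rangeTermForHue(c(270, 0, 350))
#' @export
rangeTermForHue <- function(h, vocab = colorVocabulary()) {
    h <- .requireDefinedHue(as.numeric(h))
    t <- colorTerms(vocab, "intermediate")
    idx <- vapply(h, function(x) which(x >= t$range_lo & x < t$range_hi),
                  integer(1))
    data.frame(label = t$label[idx], uri = t$uri[idx],
               stringsAsFactors = FALSE)
}

#' Nearest principal color for a hue
#'
#' Labels a hue with the principal color whose anchor hue is nearest on the
#' color wheel (circular distance, period 360 degrees).  Ties are broken
#' toward the lower anchor hue, and purple is excluded from the candidates
#' because purple and magenta are synonymous at the hue level (both anchor
#' at 300 degrees).
#'
#' @inheritParams rangeTermForHue
#' @return a data frame with one row per input hue, columns `label` and
#'   `uri`.
#' @examples
#' principalTermForHue(251)  # 11 degrees from blue vs 49 from magenta
#' principalTermForHue(270)  # equidistant; resolves to blue
#' @export
principalTermForHue <- function(h, vocab = colorVocabulary()) {
    h <- .requireDefinedHue(as.numeric(h))
    t <- colorTerms(vocab, "principal")
    t <- t[t$label != "purple", , drop = FALSE]
    t <- t[order(t$anchor_hue), , drop = FALSE]
    idx <- vapply(h, function(x) {
        d <- abs(x - t$anchor_hue) %% 360
        d <- pmin(d, 360 - d)
        which.min(d)  # ties resolve to the first, i.e. lowest anchor hue
    }, integer(1))
    data.frame(label = t$label[idx], uri = t$uri[idx],
               stringsAsFactors = FALSE)
}

#' Annotate an RGB color with vocabulary terms
#'
#' Bundles the full derivation for one or more sRGB triples: HSV, the
#' bipolar hue value, the nearest principal term, the containing
#' intermediate range term, both URIs, and the achromatic flag.  Achromatic
#' inputs (gray/white/black) yield a record with the flag set and `NA` hue
#' fields and terms rather than an error.
#'
#' @inheritParams rgbToHsv
#' @param vocab a [ColorVocabulary-class] object.
#' @return a data frame with one row per input color and columns `r`, `g`,
#'   `b`, `h_degree`, `s_percent`, `v_percent`, `h_bipolar`, `achromatic`,
#'   `principal_label`, `principal_uri`, `range_label`, `range_uri`.
#' @examples
#' annotateColor(0, 0, 255)      # blue / purplish-blue
#' annotateColor(200, 200, 200)  # achromatic
#' @export
annotateColor <- function(r, g = NULL, b = NULL, vocab = colorVocabulary()) {
    a <- .rgbArgs(r, g, b)
    hsv <- rgbToHsv(a$r, a$g, a$b)
    achrom <- is.na(hsv$h_degree)
    out <- data.frame(r = a$r, g = a$g, b = a$b,
                      h_degree = hsv$h_degree,
                      s_percent = hsv$s_percent,
                      v_percent = hsv$v_percent,
                      h_bipolar = as.numeric(hueToBipolar(hsv$h_degree)),
                      achromatic = achrom,
                      principal_label = NA_character_,
                      principal_uri = NA_character_,
                      range_label = NA_character_,
                      range_uri = NA_character_,
                      stringsAsFactors = FALSE)
    if (any(!achrom)) {
        hh <- hsv$h_degree[!achrom]
        pt <- principalTermForHue(hh, vocab)
        rt <- rangeTermForHue(hh, vocab)
        out$principal_label[!achrom] <- pt$label
        out$principal_uri[!achrom] <- pt$uri
        out$range_label[!achrom] <- rt$label
        out$range_uri[!achrom] <- rt$uri
    }
    out
}

#' Serialize / restore the vocabulary registry
#'
#' `writeColorVocabulary()` writes the registry as a tab-delimited file
#' mirroring the layout of the principal/intermediate color tables (label,
#' kind, RGB, degree anchor or range, printed HSV and bipolar strings, URI);
#' `readColorVocabulary()` restores it.  A write/read round trip reproduces
#' every URI byte for byte.
#'
#' @param vocab a [ColorVocabulary-class] object.
#' @param path file path of the tab-delimited registry.
#' @return `writeColorVocabulary()` returns `path` invisibly;
#'   `readColorVocabulary()` returns a [ColorVocabulary-class] object.
#' @export
writeColorVocabulary <- function(vocab, path) {
    stopifnot(is(vocab, "ColorVocabulary"))
    utils::write.table(vocab@terms, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, na = "")
    invisible(path)
}

#' @rdname writeColorVocabulary
#' @export
readColorVocabulary <- function(path) {
    t <- utils::read.delim(path, stringsAsFactors = FALSE, na.strings = "")
    num <- c("anchor_hue", "range_lo", "range_hi", "r", "g", "b")
    for (col in num) t[[col]] <- as.numeric(t[[col]])
    new("ColorVocabulary", terms = t)
}
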