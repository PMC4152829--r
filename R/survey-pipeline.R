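#' Read a specimen image record table
#'
#' Reads a tab-delimited survey file (UTF-8, header row, no quoting) with
#' columns `image_id`, `species`, `locality`, `cultivated`, `r`, `g`, `b`.
#' Unknown columns are dropped with a warning.  Rows with missing RGB values
#' are rejected with a warning that names their line numbers; malformed or
#' out-of-range channel values raise an error naming the offending line.
#'
#' @param path path to the tab-delimited records file.
#' @return a data frame of image records, `cultivated` as logical and the
#'   channels as integers.
#' @seealso [generateSurvey()] for producing files in this format.
#' @export
readRecords <- function(path) {
    if (!file.exists(path))
        stop("records file not found: ", path)
    raw <- utils::read.delim(path, colClasses = "character",
                             na.strings = c("", "NA"), quote = "",
                             comment.char = "#")
    need <- c("image_id", "species", "locality", "cultivated",
              "r", "g", "b")
    missing <- setdiff(need, names(raw))
    if (length(missing))
        stop("records file lacks required columns: ",
             paste(missing, collapse = ", "))
    extra <- setdiff(names(raw), need)
    if (length(extra))
        warning("ignoring unknown columns: ", paste(extra, collapse = ", "))
    raw <- raw[need]
    lineno <- seq_len(nrow(raw)) + 1L  # physical line, after the header

    chan <- lapply(raw[c("r", "g", "b")], function(x)
        suppressWarnings(as.numeric(x)))
    present <- !is.na(raw$r) & !is.na(raw$g) & !is.na(raw$b)
    bad <- present & (is.na(chan$r) | is.na(chan$g) | is.na(chan$b))
    if (any(bad))
        stop("malformed RGB value at line ",
             paste(lineno[bad], collapse = ", "))
    oob <- present &
        (chan$r < 0 | chan$r > 255 | chan$g < 0 | chan$g > 255 |
         chan$b < 0 | chan$b > 255)
    if (any(oob))
        stop("RGB channel outside [0, 255] at line ",
             paste(lineno[oob], collapse = ", "))
    if (any(!present))
        warning("dropping ", sum(!present),
                " row(s) with missing RGB at line ",
                paste(lineno[!present], collapse = ", "))

    out <- data.frame(image_id = raw$image_id[present],
                      species = raw$species[present],
                      locality = raw$locality[present],
                      cultivated = tolower(raw$cultivated[present]) %in%
                          c("true", "t", "1", "yes"),
                      r = as.integer(chan$r[present]),
                      g = as.integer(chan$g[present]),
                      b = as.integer(chan$b[present]),
                      stringsAsFactors = FALSE)
    rownames(out) <- NULL
    out
}

#' Sample up to n images per species, locality first
#'
#' Applies the survey sampling rule: for each species, localities are
#' ordered with non-cultivated (wild) localities before cultivated ones
#' (gardens), stably by first appearance within each class; one image is
#' taken from each locality in that order, and if fewer than
#' `maxPerSpecies` localities exist, a second image per locality is taken,
#' and so on round-robin until `maxPerSpecies` images are reached or the
#' species is exhausted.  Which image counts as the "first" of a locality
#' is drawn from the seeded generator, since record order carries no
#' meaning.
#'
#' @param records a data frame of image records (see [readRecords()]).
#' @param maxPerSpecies maximum images retained per species.
#' @param seed integer seed; required so that sampling is reproducible.
#' @return the sampled subset of `records`, species in order of first
#'   appearance.
#' @export
selectSample <- function(records, maxPerSpecies = 10, seed) {
    if (missing(seed))
        stop("a seed is required for reproducible sampling")
    stopifnot(maxPerSpecies >= 1)
    old <- .Random.seed_save()
    on.exit(.Random.seed_restore(old))
    set.seed(seed)

    pick <- function(sp) {
        sub <- records[records$species == sp, , drop = FALSE]
        locs <- unique(sub$locality)
        # a locality counts as cultivated only if all its records are
        loc_cult <- vapply(locs, function(l)
            all(sub$cultivated[sub$locality == l]), logical(1))
        locs <- c(locs[!loc_cult], locs[loc_cult])
        per_loc <- lapply(locs, function(l) {
            idx <- which(sub$locality == l)
            idx[sample.int(length(idx))]
        })
        chosen <- integer(0)
        round <- 1L
        while (length(chosen) < maxPerSpecies) {
            added <- FALSE
            for (q in per_loc) {
                if (length(q) >= round) {
                    chosen <- c(chosen, q[round])
                    added <- TRUE
                    if (length(chosen) >= maxPerSpecies) break
                }
            }
            if (!added) break
            round <- round + 1L
        }
        sub[chosen, , drop = FALSE]
    }
    out <- do.call(rbind, lapply(unique(records$species), pick))
    rownames(out) <- NULL
    out
}

.Random.seed_save <- function() {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        get(".Random.seed", envir = globalenv())
    else NULL
}

.Random.seed_restore <- function(old) {
    if (!is.null(old))
        assign(".Random.seed", old, envir = globalenv())
}

#' Derive hue fields for survey records
#'
#' Converts each record's RGB triple to HSV and fills the derived columns:
#' `h_degree` (hue in degrees, `NA` when achromatic), `h_bipolar` (the
#' bipolar transform of the hue) and `achromatic`.  Saturation and value
#' are computed transiently and discarded — the analysis keeps only hue,
#' because brightness depends on display conditions and saturation is out
#' of scope.
#'
#' @param records a data frame with integer columns `r`, `g`, `b`.
#' @return `records` with columns `h_degree`, `h_bipolar`, `achromatic`
#'   appended (replaced if present).
#' @export
convertRecords <- function(records) {
    hsv <- rgbToHsv(records$r, records$g, records$b)
    records$h_degree <- hsv$h_degree
    records$h_bipolar <- as.numeric(hueToBipolar(hsv$h_degree))
    records$achromatic <- is.na(hsv$h_degree)
    records
}

.requireConverted <- function(records) {
    if (!all(c("h_degree", "h_bipolar", "achromatic") %in% names(records)))
        stop("records lack derived hue columns; run convertRecords() first")
    invisible(records)
}

#' Per-species median hue summaries
#'
#' Summarizes each species by the linear median of `h_degree` over its
#' chromatic records (even counts average the central pair).  The bipolar
#' median is derived from the unrounded degree median, and the species is
#' labelled with the nearest principal color and the containing
#' intermediate range term.  Achromatic records carry no hue and are
#' excluded from the medians but counted; a species with only achromatic
#' records gets an `NA` median and is flagged.
#'
#' @param records converted records (see [convertRecords()]).
#' @param vocab a [ColorVocabulary-class] object for labelling.
#' @return a data frame with one row per species: `species`, `n_images`,
#'   `n_achromatic`, `median_h_degree`, `median_h_bipolar`,
#'   `principal_label`, `range_label`, `achromatic_only`.
#' @export
speciesMedians <- function(records, vocab = colorVocabulary()) {
    .requireConverted(records)
    sp <- unique(records$species)
    rows <- lapply(sp, function(s) {
        sub <- records[records$species == s, , drop = FALSE]
        h <- sub$h_degree[!sub$achromatic]
        med <- if (length(h)) stats::median(h) else NA_real_
        data.frame(species = s,
                   n_images = nrow(sub),
                   n_achromatic = sum(sub$achromatic),
                   median_h_degree = med,
                   median_h_bipolar = as.numeric(hueToBipolar(med)),
                   principal_label = if (is.na(med)) NA_character_
                       else principalTermForHue(med %% 360, vocab)$label,
                   range_label = if (is.na(med)) NA_character_
                       else rangeTermForHue(med %% 360, vocab)$label,
                   achromatic_only = length(h) == 0L,
                   stringsAsFactors = FALSE)
    })
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    out
}

#' Overall median hue across all images
#'
#' The per-image (not per-species) linear median of `h_degree` over all
#' chromatic records, with the bipolar value derived from the unrounded
#' degree median.  Printed renderings use the conventional precisions:
#' nearest degree and two bipolar decimals.
#'
#' @param records converted records (see [convertRecords()]).
#' @return a list with `h_degree`, `h_bipolar` (full precision),
#'   `h_degree_printed`, `h_bipolar_printed`, `n` (chromatic images) and
#'   `n_achromatic`.  All-achromatic input yields `NA` medians.
#' @examples
#' rec <- convertRecords(data.frame(r = c(0, 30, 255), g = 0,
#'                                  b = c(255, 255, 0)))
#' overallMedian(rec)
#' @export
overallMedian <- function(records) {
    .requireConverted(records)
    h <- records$h_degree[!records$achromatic]
    med <- if (length(h)) stats::median(h) else NA_real_
    bip <- as.numeric(hueToBipolar(med))
    list(h_degree = med,
         h_bipolar = bip,
         h_degree_printed = if (is.na(med)) NA_real_
             else roundHalfAway(med),
         h_bipolar_printed = if (is.na(bip)) NA_real_
             else roundHalfAway(bip, 2),
         n = length(h),
         n_achromatic = sum(records$achromatic))
}

#' Histogram of species median hues on the bipolar scale
#'
#' Bins species median bipolar hues into equal-width bins spanning
#' \[-60, 40\], left-closed/right-open with the last bin closed.  Each bin
#' also reports its midpoint mapped back to degrees, which is what colors
#' the bars in the survey figure.
#'
#' @param summaries a species summary table (see [speciesMedians()]) or a
#'   numeric vector of bipolar median values.
#' @param binWidth bin width in bipolar units (default 5; one bipolar unit
#'   is 3.6 degrees).
#' @return a data frame with one row per bin: `bin_lo`, `bin_hi`, `count`,
#'   `midpoint_bipolar`, `midpoint_hue`.
#' @export
hueHistogram <- function(summaries, binWidth = 5) {
    if (!is.numeric(binWidth) || length(binWidth) != 1L || binWidth <= 0)
        stop("binWidth must be a positive number of bipolar units")
    x <- if (is.data.frame(summaries)) summaries$median_h_bipolar
         else as.numeric(summaries)
    x <- x[!is.na(x)]
    if (length(x) == 0L)
        stop("no species with a defined median hue")
    lo <- seq(-60, 40 - 1e-9, by = binWidth)
    hi <- pmin(lo + binWidth, 40)
    count <- vapply(seq_along(lo), function(i) {
        inbin <- x >= lo[i] & (x < hi[i] | (hi[i] == 40 & x == 40))
        sum(inbin)
    }, integer(1))
    mid <- (lo + hi) / 2
    data.frame(bin_lo = lo, bin_hi = hi, count = count,
               midpoint_bipolar = mid, midpoint_hue = bipolarToHue(mid))
}

#' Export URI-bearing color annotations
#'
#' Writes one row (CSV) or object (JSON) per input with identifiers, the
#' RGB triple, hue degree and bipolar values, principal and range labels
#' with their ontology URIs, and the achromatic flag.  Column order is
#' fixed; re-loading reproduces hue values to printed precision.  Accepts
#' either converted image records or species summary tables.
#'
#' @param x converted records ([convertRecords()]) or species summaries
#'   ([speciesMedians()]).
#' @param path output file path.
#' @param format `"csv"` or `"json"`.
#' @param vocab a [ColorVocabulary-class] object supplying labels and URIs.
#' @return the exported data frame, invisibly.
#' @export
exportAnnotations <- function(x, path, format = c("csv", "json"),
                              vocab = colorVocabulary()) {
    format <- match.arg(format)
    if ("median_h_degree" %in% names(x)) {
        h <- x$median_h_degree
        out <- data.frame(species = x$species, n_images = x$n_images,
                          h_degree = h, h_bipolar = x$median_h_bipolar,
                          achromatic = is.na(h), stringsAsFactors = FALSE)
    } else {
        .requireConverted(x)
        h <- x$h_degree
        out <- data.frame(image_id = x$image_id, species = x$species,
                          locality = x$locality, cultivated = x$cultivated,
                          r = x$r, g = x$g, b = x$b,
                          h_degree = h, h_bipolar = x$h_bipolar,
                          achromatic = x$achromatic,
                          stringsAsFactors = FALSE)
    }
    out$principal_label <- NA_character_
    out$principal_uri <- NA_character_
    out$range_label <- NA_character_
    out$range_uri <- NA_character_
    def <- !is.na(h)
    if (any(def)) {
        pt <- principalTermForHue(h[def] %% 360, vocab)
        rt <- rangeTermForHue(h[def] %% 360, vocab)
        out$principal_label[def] <- pt$label
        out$principal_uri[def] <- pt$uri
        out$range_label[def] <- rt$label
        out$range_uri[def] <- rt$uri
    }
    if (format == "csv") {
        utils::write.csv(out, path, row.names = FALSE, na = "")
    } else {
        jsonlite::write_json(out, path, dataframe = "rows", digits = NA,
                             na = "null", pretty = TRUE)
    }
    invisible(out)
}

#' Survey scatterplot with species-median histogram
#'
#' Draws the survey overview figure: each image's bipolar hue against its
#' index, horizontal reference lines at the pure hues of green, cyan, blue,
#' magenta and red, and, alongside, a histogram of species median hues with
#' bars colored by their bin midpoint hue.
#'
#' @param records converted records (see [convertRecords()]).
#' @param binWidth histogram bin width in bipolar units.
#' @param vocab a [ColorVocabulary-class] object for the reference hues.
#' @return invisibly, the histogram table from [hueHistogram()].
#' @export
plotHueSurvey <- function(records, binWidth = 5, vocab = colorVocabulary()) {
    .requireConverted(records)
    hist <- hueHistogram(speciesMedians(records, vocab), binWidth)
    chrom <- records[!records$achromatic, , drop = FALSE]
    old <- graphics::par(no.readonly = TRUE)
    on.exit(graphics::par(old))
    graphics::layout(matrix(1:2, 1), widths = c(3, 1))
    graphics::par(mar = c(4, 4, 2, 0.5))
    graphics::plot(seq_len(nrow(chrom)), chrom$h_bipolar,
                   pch = 16, cex = 0.5, ylim = c(-60, 40),
                   xlab = "image", ylab = "bipolar hue",
                   main = "Image hues")
    anchors <- colorTerms(vocab, "principal")
    anchors <- anchors[anchors$label %in%
                       c("green", "cyan", "blue", "magenta", "red"), ]
    for (i in seq_len(nrow(anchors)))
        graphics::abline(h = anchors$anchor_hue[i] * 100 / 360 - 60,
                         col = grDevices::rgb(anchors$r[i], anchors$g[i],
                                              anchors$b[i],
                                              maxColorValue = 255))
    graphics::par(mar = c(4, 0.5, 2, 1))
    cols <- grDevices::hsv(hist$midpoint_hue / 360, 1, 1)
    graphics::barplot(hist$count, horiz = TRUE, col = cols, border = NA,
                      main = "Species medians", xlab = "count")
    invisible(hist)
}
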