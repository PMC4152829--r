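#' Specification of a synthetic flower image
#'
#' Describes a stylized flower used to exercise the region-averaging and
#' hue-recovery machinery with known ground truth: `nPetals` elliptical
#' petals arranged radially around a central disc on a plain background.
#' Petal color is given in HSV so that hue is the controlled quantity;
#' per-channel Gaussian RGB noise with standard deviation `noiseSd` is
#' added to petal pixels and clipped to \[0, 255\].
#'
#' @param nPetals number of petals (>= 3).
#' @param petalHue petal hue in degrees \[0, 360).
#' @param petalSaturation,petalValue petal saturation and value in percent;
#'   full by default so that hue is the only informative channel.
#' @param noiseSd per-channel RGB noise standard deviation (>= 0).
#' @param centerDiscRgb,backgroundRgb sRGB triples for the central disc and
#'   the background.
#' @param imageSize side length of the square raster in pixels (>= 32 so
#'   the petal geometry fits).
#' @param seed integer seed controlling the noise.
#' @return a `FlowerSpec` list.
#' @seealso [renderFlower()]
#' @export
flowerSpec <- function(nPetals = 5, petalHue = 240, petalSaturation = 100,
                       petalValue = 100, noiseSd = 0,
                       centerDiscRgb = c(255, 200, 0),
                       backgroundRgb = c(34, 85, 34),
                       imageSize = 96, seed = 1) {
    stopifnot(nPetals >= 3, noiseSd >= 0,
              petalHue >= 0, petalHue < 360,
              petalSaturation >= 0, petalSaturation <= 100,
              petalValue >= 0, petalValue <= 100,
              length(centerDiscRgb) == 3, length(backgroundRgb) == 3)
    structure(list(nPetals = nPetals, petalHue = petalHue,
                   petalSaturation = petalSaturation,
                   petalValue = petalValue, noiseSd = noiseSd,
                   centerDiscRgb = centerDiscRgb,
                   backgroundRgb = backgroundRgb,
                   imageSize = imageSize, seed = seed),
              class = "FlowerSpec")
}

#' Render a synthetic flower image and its petal mask
#'
#' Draws the flower described by a [flowerSpec()]: petal pixels take the
#' RGB equivalent of the petal HSV color plus seeded Gaussian channel noise
#' (clipped to \[0, 255\]); the returned mask covers exactly the petal
#' pixels, excluding the central disc, so that averaging over the mask
#' recovers the petal color.
#'
#' @param spec a `FlowerSpec`.
#' @return a list with `image` (integer array `size x size x 3`) and
#'   `mask` (logical matrix).
#' @examples
#' fl <- renderFlower(flowerSpec(petalHue = 240, noiseSd = 0))
#' averageRegionColor(fl$image, fl$mask)
#' @export
renderFlower <- function(spec) {
    stopifnot(inherits(spec, "FlowerSpec"))
    S <- spec$imageSize
    if (S < 32)
        stop("imageSize too small: the petal geometry does not fit")
    cx <- (S + 1) / 2
    rd <- 0.10 * S          # central disc radius
    d <- 0.28 * S           # petal center distance from flower center
    a <- 0.18 * S           # petal semi-axis, radial
    bax <- 0.10 * S         # petal semi-axis, tangential
    if (d + a > S / 2)
        stop("petals do not fit inside the raster")

    xs <- matrix(rep(seq_len(S), each = S), S)   # column index
    ys <- matrix(rep(seq_len(S), times = S), S)  # row index
    petal <- matrix(FALSE, S, S)
    for (k in seq_len(spec$nPetals)) {
        t <- 2 * pi * (k - 1) / spec$nPetals
        px <- cx + d * cos(t)
        py <- cx + d * sin(t)
        u <- (xs - px) * cos(t) + (ys - py) * sin(t)
        w <- -(xs - px) * sin(t) + (ys - py) * cos(t)
        petal <- petal | ((u / a)^2 + (w / bax)^2 <= 1)
    }
    disc <- (xs - cx)^2 + (ys - cx)^2 <= rd^2
    mask <- petal & !disc

    base <- as.numeric(hsvToRgb(spec$petalHue, spec$petalSaturation,
                                spec$petalValue)[1, ])
    img <- array(0, c(S, S, 3))
    for (ch in 1:3) img[, , ch] <- spec$backgroundRgb[ch]

    old <- .Random.seed_save()
    on.exit(.Random.seed_restore(old))
    set.seed(spec$seed)
    n <- sum(mask)
    for (ch in 1:3) {
        plane <- img[, , ch]
        vals <- base[ch] + stats::rnorm(n, 0, spec$noiseSd)
        plane[mask] <- pmin(255, pmax(0, roundHalfAway(vals)))
        plane[disc] <- spec$centerDiscRgb[ch]
        img[, , ch] <- plane
    }
    list(image = array(as.integer(img), dim(img)), mask = mask)
}

#' Specification of a synthetic image survey
#'
#' Describes a synthetic specimen-image survey with the statistical
#' structure the hue analysis assumes: species hue centers drawn from a
#' normal distribution on degrees (wrapped to \[0, 360)), within-species
#' hue noise around each center, a small fraction of achromatic
#' (white/gray) records, and locality/cultivation metadata.  The defaults
#' concentrate hues between blue (240 degrees) and magenta (300 degrees),
#' the regime the survey analysis is aimed at.
#'
#' @param nSpecies number of species.
#' @param imagesPerSpecies images generated per species.
#' @param hueCenterMean,hueCenterSd mean and standard deviation (degrees)
#'   of the species hue-center distribution.
#' @param withinSpeciesSd within-species hue noise standard deviation
#'   (degrees); noise is added and wrapped to \[0, 360).
#' @param achromaticFraction expected fraction of records replaced by
#'   near-gray (equal-channel) RGB values, in \[0, 1\].
#' @param nLocalitiesPerSpecies localities per species; images are assigned
#'   round-robin.
#' @param cultivatedFraction expected fraction of cultivated (garden)
#'   localities, in \[0, 1\].
#' @param seed integer seed; the whole survey is a deterministic function
#'   of the spec including this seed.
#' @return a `SurveySpec` list.
#' @seealso [generateSurvey()], [groundTruth()]
#' @export
surveySpec <- function(nSpecies = 100, imagesPerSpecies = 10,
                       hueCenterMean = 270, hueCenterSd = 25,
                       withinSpeciesSd = 10, achromaticFraction = 0.05,
                       nLocalitiesPerSpecies = 5, cultivatedFraction = 0.3,
                       seed = 1) {
    stopifnot(nSpecies >= 1, imagesPerSpecies >= 1,
              hueCenterSd >= 0, withinSpeciesSd >= 0,
              achromaticFraction >= 0, achromaticFraction <= 1,
              nLocalitiesPerSpecies >= 1,
              cultivatedFraction >= 0, cultivatedFraction <= 1)
    structure(list(nSpecies = nSpecies,
                   imagesPerSpecies = imagesPerSpecies,
                   hueCenterMean = hueCenterMean,
                   hueCenterSd = hueCenterSd,
                   withinSpeciesSd = withinSpeciesSd,
                   achromaticFraction = achromaticFraction,
                   nLocalitiesPerSpecies = nLocalitiesPerSpecies,
                   cultivatedFraction = cultivatedFraction,
                   seed = seed),
              class = "SurveySpec")
}

# One deterministic draw of the whole survey: records plus ground truth.
.simulateSurvey <- function(spec) {
    stopifnot(inherits(spec, "SurveySpec"))
    old <- .Random.seed_save()
    on.exit(.Random.seed_restore(old))
    set.seed(spec$seed)

    ns <- spec$nSpecies
    ni <- spec$imagesPerSpecies
    sp_names <- sprintf("species_%03d", seq_len(ns))
    centers <- (stats::rnorm(ns, spec$hueCenterMean, spec$hueCenterSd)) %% 360

    rows <- vector("list", ns)
    truth_rows <- vector("list", ns)
    for (s in seq_len(ns)) {
        hues <- (centers[s] +
                 stats::rnorm(ni, 0, spec$withinSpeciesSd)) %% 360
        achrom <- stats::runif(ni) < spec$achromaticFraction
        rgb <- hsvToRgb(hues, 100, 100)
        if (any(achrom)) {
            gray <- sample(150:255, sum(achrom), replace = TRUE)
            rgb$r[achrom] <- gray
            rgb$g[achrom] <- gray
            rgb$b[achrom] <- gray
        }
        nloc <- spec$nLocalitiesPerSpecies
        loc_idx <- ((seq_len(ni) - 1L) %% nloc) + 1L
        cult_loc <- stats::runif(nloc) < spec$cultivatedFraction
        rows[[s]] <- data.frame(
            image_id = sprintf("img_%03d_%02d", s, seq_len(ni)),
            species = sp_names[s],
            locality = sprintf("loc_%03d_%02d", s, loc_idx),
            cultivated = cult_loc[loc_idx],
            r = rgb$r, g = rgb$g, b = rgb$b,
            stringsAsFactors = FALSE)
        h_chrom <- hues[!achrom]
        truth_rows[[s]] <- data.frame(
            species = sp_names[s],
            center_hue = centers[s],
            n_chromatic = length(h_chrom),
            median_h_degree = if (length(h_chrom))
                stats::median(h_chrom) else NA_real_,
            stringsAsFactors = FALSE)
        truth_rows[[s]]$hues_chromatic <- I(list(h_chrom))
    }
    records <- do.call(rbind, rows)
    truth <- do.call(rbind, truth_rows)
    all_h <- unlist(truth$hues_chromatic)
    truth$hues_chromatic <- NULL
    truth$median_h_bipolar <- as.numeric(hueToBipolar(truth$median_h_degree))
    list(records = records, truth = truth,
         overall_median_h_degree = stats::median(all_h),
         overall_median_h_bipolar =
             as.numeric(hueToBipolar(stats::median(all_h))))
}

#' Generate a synthetic survey record file
#'
#' Draws the survey described by a [surveySpec()] and writes it as a
#' tab-delimited records file readable by [readRecords()]: species hue
#' centers from the center distribution, per-image hue = center plus
#' wrapped noise, converted to RGB at the configured (full, by default)
#' saturation and value; an `achromaticFraction` of rows is replaced by
#' equal-channel gray.  The first line is a `# seed=<seed>` comment so a
#' file can be matched to its spec.  The output is fully determined by the
#' spec (including its seed).
#'
#' @param spec a `SurveySpec`.
#' @param path output path for the tab-delimited records file.
#' @return invisibly, the records data frame that was written.
#' @export
generateSurvey <- function(spec, path) {
    sim <- .simulateSurvey(spec)
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(paste0("# seed=", spec$seed), con)
    utils::write.table(sim$records, con, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    invisible(sim$records)
}

#' Ground truth for a synthetic survey
#'
#' Recomputes, from the same seed as [generateSurvey()], the exact species
#' hue centers and the realized per-species and overall medians of the
#' generated hues *before* 8-bit RGB quantization.  These are the reference
#' values for recovery assertions: the analysis pipeline run on the
#' generated file matches them up to RGB quantization error (below 0.3
#' degrees at full saturation and value).
#'
#' @param spec the same `SurveySpec` passed to [generateSurvey()].
#' @return a list with `species` (data frame: `species`, `center_hue`,
#'   `n_chromatic`, `median_h_degree`, `median_h_bipolar`),
#'   `overall_median_h_degree` and `overall_median_h_bipolar`.
#' @export
groundTruth <- function(spec) {
    sim <- .simulateSurvey(spec)
    list(species = sim$truth,
         overall_median_h_degree = sim$overall_median_h_degree,
         overall_median_h_bipolar = sim$overall_median_h_bipolar)
}
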