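writeRecordsFile <- function(lines) {
    path <- withr::local_tempfile(fileext = ".tsv",
                                  .local_envir = parent.frame())
    writeLines(c("image_id\tspecies\tlocality\tcultivated\tr\tg\tb",
                 lines), path)
    path
}

test_that("well-formed record files parse with typed columns", {
    path <- writeRecordsFile(c(
        "i1\tGentiana nivalis\tAlps\tFALSE\t10\t20\t200",
        "i2\tGentiana nivalis\tAlps\tFALSE\t15\t25\t210",
        "i3\tViola odorata\tGarden\tTRUE\t120\t30\t180"))
    rec <- readRecords(path)
    expect_equal(nrow(rec), 3L)
    expect_type(rec$cultivated, "logical")
    expect_identical(rec$cultivated, c(FALSE, FALSE, TRUE))
    expect_identical(rec$r, c(10L, 15L, 120L))
})

test_that("bad rows are rejected with their line numbers", {
    oob <- writeRecordsFile(c("i1\ts\tl\tFALSE\t10\t20\t200",
                              "i2\ts\tl\tFALSE\t300\t20\t200"))
    expect_error(readRecords(oob), "line 3")
    malformed <- writeRecordsFile("i1\ts\tl\tFALSE\tabc\t20\t200")
    expect_error(readRecords(malformed), "malformed.*line 2")
    gap <- writeRecordsFile(c("i1\ts\tl\tFALSE\t10\t20\t200",
                              "i2\ts\tl\tFALSE\t\t20\t200"))
    expect_warning(rec <- readRecords(gap), "missing RGB.*line 3")
    expect_equal(nrow(rec), 1L)
    expect_error(readRecords(tempfile(fileext = ".tsv")), "not found")
    short <- withr::local_tempfile(fileext = ".tsv")
    writeLines(c("image_id\tspecies\tr\tg\tb", "i1\ts\t1\t2\t3"), short)
    expect_error(readRecords(short), "required columns")
})

test_that("unknown columns are ignored with a warning", {
    path <- withr::local_tempfile(fileext = ".tsv")
    writeLines(c("image_id\tspecies\tlocality\tcultivated\tr\tg\tb\tnotes",
                 "i1\ts\tl\tFALSE\t1\t2\t3\thello"), path)
    expect_warning(rec <- readRecords(path), "unknown columns: notes")
    expect_false("notes" %in% names(rec))
})

test_that("generated surveys round-trip through the record reader", {
    path <- withr::local_tempfile(fileext = ".tsv")
    written <- generateSurvey(surveySpec(nSpecies = 6, imagesPerSpecies = 5,
                                         seed = 42), path)
    back <- readRecords(path)
    expect_equal(back, written, ignore_attr = TRUE)
})

test_that("sampling keeps at most 10 images, localities first", {
    fix <- samplingFixture()
    out <- selectSample(fix, maxPerSpecies = 10, seed = 42)

    a <- out[out$species == "A", ]
    expect_equal(nrow(a), 10L)
    expect_equal(length(unique(a$locality)), 10L)
    # all seven wild localities are kept, then the first three gardens
    expect_true(all(sprintf("LA%02d", 6:12) %in% a$locality))
    expect_setequal(setdiff(a$locality, sprintf("LA%02d", 6:12)),
                    sprintf("LA%02d", 1:3))
    # wild localities come before cultivated ones in the sampled order
    expect_true(max(which(!a$cultivated)) < min(which(a$cultivated)))

    b <- out[out$species == "B", ]
    expect_equal(nrow(b), 10L)
    # round-robin over three localities: 4 + 3 + 3
    expect_equal(sort(as.integer(table(b$locality)), decreasing = TRUE),
                 c(4L, 3L, 3L))

    # "up to 10": species with fewer images keeps them all
    expect_equal(nrow(out[out$species == "C", ]), 4L)
})

test_that("sampling is seed-deterministic and requires a seed", {
    fix <- samplingFixture()
    expect_identical(selectSample(fix, seed = 1), selectSample(fix, seed = 1))
    expect_error(selectSample(fix), "seed")
    # with multiple images per locality the seed decides which is "first"
    s1 <- selectSample(fix, seed = 1)
    s2 <- selectSample(fix, seed = 2)
    expect_setequal(s1$species, s2$species)
})

test_that("record conversion fills hue fields and flags achromatics", {
    rec <- data.frame(image_id = c("a", "b", "c"), species = "s",
                      locality = "l", cultivated = FALSE,
                      r = c(0L, 255L, 30L), g = c(0L, 255L, 200L),
                      b = c(255L, 255L, 90L))
    conv <- convertRecords(rec)
    expect_equal(conv$h_degree[1], 240)
    expect_equal(roundHalfAway(conv$h_bipolar[1], 2), 6.67)
    expect_true(conv$achromatic[2])
    expect_true(is.na(conv$h_degree[2]))
    # batch conversion equals the per-record color ops
    hsv <- rgbToHsv(rec$r, rec$g, rec$b)
    expect_equal(conv$h_degree, hsv$h_degree)
    expect_equal(conv$h_bipolar, as.numeric(hueToBipolar(hsv$h_degree)))
})

syntheticConverted <- function(h, species = "s") {
    data.frame(image_id = paste0("i", seq_along(h)), species = species,
               locality = "l", cultivated = FALSE,
               r = 0L, g = 0L, b = 0L,
               h_degree = h,
               h_bipolar = as.numeric(hueToBipolar(h)),
               achromatic = is.na(h), stringsAsFactors = FALSE)
}

test_that("species medians use the linear median over chromatic records", {
    one <- speciesMedians(syntheticConverted(251))
    expect_equal(one$median_h_degree, 251)
    expect_equal(roundHalfAway(one$median_h_bipolar, 2), 9.72)
    expect_identical(one$principal_label, "blue")
    expect_identical(one$range_label, "purplish-blue")

    odd <- speciesMedians(syntheticConverted(c(240, 250, 300)))
    expect_equal(odd$median_h_degree, 250)

    # achromatic records are counted but excluded from the median
    mixed <- speciesMedians(syntheticConverted(c(240, NA, 260)))
    expect_equal(mixed$median_h_degree, 250)
    expect_equal(mixed$n_images, 3L)
    expect_equal(mixed$n_achromatic, 1L)
    expect_false(mixed$achromatic_only)

    ghost <- speciesMedians(syntheticConverted(c(NA_real_, NA_real_)))
    expect_true(ghost$achromatic_only)
    expect_true(is.na(ghost$median_h_degree))

    # brute-force sort-and-pick oracle on a larger draw
    set.seed(42)
    h <- runif(50, 0, 360)
    got <- speciesMedians(syntheticConverted(h))
    srt <- sort(h)
    expect_equal(got$median_h_degree, (srt[25] + srt[26]) / 2)
    # invariant under record permutation
    expect_equal(speciesMedians(syntheticConverted(sample(h))),
                 got)
})

test_that("the overall median is per-image with printed renderings", {
    got <- overallMedian(syntheticConverted(c(240, 250.85, 300)))
    expect_equal(got$h_degree, 250.85)
    expect_equal(got$h_bipolar, 250.85 * 100 / 360 - 60)
    expect_equal(got$h_degree_printed, 251)
    expect_equal(got$h_bipolar_printed, 9.68)

    pair <- overallMedian(syntheticConverted(c(230, 250)))
    expect_equal(pair$h_degree, 240)
    expect_equal(roundHalfAway(pair$h_bipolar, 2), 6.67)

    allgray <- overallMedian(syntheticConverted(c(NA_real_, NA_real_)))
    expect_true(is.na(allgray$h_degree))
    expect_equal(allgray$n_achromatic, 2L)
})

test_that("species histogram bins the bipolar scale and conserves counts", {
    hist <- hueHistogram(data.frame(median_h_bipolar = 9.68), binWidth = 5)
    hit <- hist[hist$count > 0, ]
    expect_equal(nrow(hit), 1L)
    expect_equal(c(hit$bin_lo, hit$bin_hi), c(5, 10))
    expect_equal(hit$midpoint_hue, bipolarToHue(7.5))

    set.seed(42)
    med <- c(runif(200, -60, 40), NA, 40, -60)
    h2 <- hueHistogram(data.frame(median_h_bipolar = med), binWidth = 5)
    expect_equal(sum(h2$count), 202L)  # NA median carries no hue
    # independent linear-scan binning oracle
    want <- vapply(seq_len(nrow(h2)), function(i) {
        x <- med[!is.na(med)]
        sum(x >= h2$bin_lo[i] &
            (x < h2$bin_hi[i] | (h2$bin_hi[i] == 40 & x == 40)))
    }, integer(1))
    expect_equal(h2$count, want)
    # near-uniform draws give near-uniform counts
    expect_gt(stats::chisq.test(h2$count)$p.value, 1e-4)
    expect_error(hueHistogram(data.frame(median_h_bipolar = 1), 0),
                 "positive")
})

test_that("annotation exports round-trip and carry ontology URIs", {
    rec <- convertRecords(data.frame(
        image_id = c("i1", "i2"), species = c("s1", "s2"),
        locality = "l", cultivated = FALSE,
        r = c(0L, 200L), g = c(0L, 200L), b = c(255L, 200L)))
    csv <- withr::local_tempfile(fileext = ".csv")
    out <- exportAnnotations(rec, csv, "csv")
    back <- utils::read.csv(csv)
    expect_equal(nrow(back), 2L)
    expect_identical(back$principal_uri[1],
                     "http://purl.obolibrary.org/obo/PATO_0000318")
    expect_identical(back$range_label[1], "purplish-blue")
    expect_true(back$achromatic[2])
    expect_equal(back$h_degree[1], out$h_degree[1], tolerance = 0.01)
    expect_equal(back$h_bipolar[1], out$h_bipolar[1], tolerance = 0.01)

    json <- withr::local_tempfile(fileext = ".json")
    exportAnnotations(rec, json, "json")
    parsed <- jsonlite::read_json(json, simplifyVector = TRUE)
    expect_equal(nrow(parsed), 2L)
    expect_identical(parsed$range_uri[1],
                     "http://eol.org/schema/terms/purplish-blue")

    # identical inputs write byte-identical exports
    csv2 <- withr::local_tempfile(fileext = ".csv")
    exportAnnotations(rec, csv2, "csv")
    expect_identical(readLines(csv), readLines(csv2))

    # summaries export with species-level columns
    scsv <- withr::local_tempfile(fileext = ".csv")
    sm <- exportAnnotations(speciesMedians(rec), scsv, "csv")
    expect_identical(sm$species, c("s1", "s2"))
    expect_identical(sm$principal_label[1], "blue")
})

test_that("the pipeline recovers the synthetic generator's structure", {
    spec <- surveySpec(seed = 42)  # 100 species x 10 images, sd 10
    path <- withr::local_tempfile(fileext = ".tsv")
    generateSurvey(spec, path)
    truth <- groundTruth(spec)
    med <- speciesMedians(convertRecords(readRecords(path)))
    med <- med[match(truth$species$species, med$species), ]

    # pipeline medians match the realized pre-quantization medians
    ok <- !is.na(med$median_h_degree) & !is.na(truth$species$median_h_degree)
    expect_true(all(ok))
    expect_true(all(hueDist(med$median_h_degree,
                            truth$species$median_h_degree) < 0.5))
    # and sit within 3x the within-species noise scale of the true centers
    expect_true(all(hueDist(med$median_h_degree,
                            truth$species$center_hue) <
                    3 * spec$withinSpeciesSd))

    # a larger survey pins the overall median near the configured
    # population median of 270 degrees
    big <- surveySpec(nSpecies = 500, seed = 42)
    bpath <- withr::local_tempfile(fileext = ".tsv")
    generateSurvey(big, bpath)
    om <- overallMedian(convertRecords(readRecords(bpath)))
    expect_lt(abs(om$h_degree - 270), 1)
    expect_lt(abs(om$h_degree - groundTruth(big)$overall_median_h_degree),
              0.5)
})
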