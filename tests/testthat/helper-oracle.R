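# Independent oracles, coded from the textbook definitions and kept free of
# the package's implementation paths.

# Hexcone RGB -> HSV, straight from the piecewise 60-degree sector formula.
oracleRgbToHsv <- function(r, g, b) {
    mx <- max(r, g, b)
    mn <- min(r, g, b)
    d <- mx - mn
    v <- mx / 255 * 100
    s <- if (mx == 0) 0 else d / mx * 100
    h <- if (d == 0) NA_real_
         else if (mx == r) 60 * (((g - b) / d) %% 6)
         else if (mx == g) 60 * ((b - r) / d + 2)
         else 60 * ((r - g) / d + 4)
    c(h = h, s = s, v = v)
}

# Brute-force per-channel accumulation over a masked region.
oracleRegionMean <- function(image, mask) {
    acc <- c(0, 0, 0)
    n <- 0
    for (i in seq_len(nrow(mask))) {
        for (j in seq_len(ncol(mask))) {
            if (mask[i, j]) {
                acc <- acc + image[i, j, ]
                n <- n + 1
            }
        }
    }
    acc / n
}

# Circular distance between two hue angles in degrees.
hueDist <- function(a, b) {
    d <- abs(a - b) %% 360
    pmin(d, 360 - d)
}

# A coarse but well-spread grid of 8-bit channel values.
channelGrid <- function() seq(0, 255, by = 17)

# Small fixed survey fixture used by sampling-rule tests.
samplingFixture <- function() {
    rbind(
        # species A: 12 localities, one image each; first five cultivated
        data.frame(image_id = sprintf("a%02d", 1:12), species = "A",
                   locality = sprintf("LA%02d", 1:12),
                   cultivated = rep(c(TRUE, FALSE), c(5, 7)),
                   r = 10L, g = 20L, b = 200L, stringsAsFactors = FALSE),
        # species B: 3 localities x 5 images
        data.frame(image_id = sprintf("b%02d", 1:15), species = "B",
                   locality = rep(sprintf("LB%d", 1:3), each = 5),
                   cultivated = FALSE,
                   r = 0L, g = 0L, b = 255L, stringsAsFactors = FALSE),
        # species C: only 4 images
        data.frame(image_id = sprintf("c%02d", 1:4), species = "C",
                   locality = sprintf("LC%d", 1:4), cultivated = FALSE,
                   r = 255L, g = 0L, b = 255L, stringsAsFactors = FALSE))
}
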