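#' Checkerboard mask image
#'
#' Alternating black/white tiles; with an even tile count the mean luminance
#' is exactly 0.5, which makes the mask a natural luminance anchor for the
#' rest of the stimulus set.
#'
#' @param tiles_per_side number of tiles per side (must be even).
#' @param px image side length in pixels (must be divisible by
#'   `tiles_per_side`).
#' @return a `stimulus_image`: matrix in \[0,1\] with attributes `kind` and
#'   `params`.
#' @export
make_checkerboard <- function(tiles_per_side, px) {
  abort_if(tiles_per_side %% 2 != 0, "parameter error: tiles_per_side must be even")
  abort_if(px %% tiles_per_side != 0,
           "parameter error: px (%d) not divisible by tiles_per_side (%d)",
           px, tiles_per_side)
  tile <- px / tiles_per_side
  idx <- (seq_len(px) - 1) %/% tile
  img <- (outer(idx, idx, "+") %% 2) * 1.0
  stimulus_image(img, "mask", params = list(tiles = tiles_per_side))
}

#' Kanizsa triangle and its distorted variant
#'
#' Three dark discs with a 60-degree wedge notch are placed at the vertices
#' of an equilateral triangle on a light background. In the canonical
#' variant every notch faces the centroid, inducing the illusory triangle;
#' in the distorted variant the same discs have their notches rotated
#' outward by seeded random angles, destroying the illusory contour while
#' keeping the total ink (dark pixel count) essentially identical, so the
#' two variants stay luminance-matched by construction.
#'
#' @param variant `"canonical"` or `"distorted"`.
#' @param px image side length in pixels (>= 64).
#' @param rotation_seed seed for the distorted notch angles.
#' @return a `stimulus_image` (binary matrix; ink = 0, background = 1).
#' @export
make_kanizsa <- function(variant = c("canonical", "distorted"), px = 256,
                         rotation_seed = 1) {
  variant <- match.arg(variant)
  abort_if(px < 64, "parameter error: px must be >= 64")
  cx <- (px + 1) / 2
  cy <- (px + 1) / 2
  circum <- 0.30 * px
  r <- px / 8
  vert_ang <- c(pi / 2, pi / 2 + 2 * pi / 3, pi / 2 + 4 * pi / 3)
  vx <- cx + circum * cos(vert_ang)
  vy <- cy - circum * sin(vert_ang)  # row axis points down
  notch <- if (variant == "canonical") {
    atan2(-(cy - vy), cx - vx)
  } else {
    with_seed(rotation_seed,
              atan2(-(cy - vy), cx - vx) + pi + stats::runif(3, -pi / 3, pi / 3))
  }
  xs <- matrix(rep(seq_len(px), each = px), px, px)   # column coordinate
  ys <- matrix(rep(seq_len(px), times = px), px, px)  # row coordinate
  img <- matrix(1, px, px)
  for (k in 1:3) {
    dx <- xs - vx[k]
    dy <- ys - vy[k]
    in_disc <- dx^2 + dy^2 <= r^2
    ang <- atan2(-dy, dx)
    d <- (ang - notch[k] + pi) %% (2 * pi) - pi
    in_wedge <- abs(d) <= pi / 6
    img[in_disc & !in_wedge] <- 0
  }
  stimulus_image(img, paste0("kanizsa_", variant),
                 params = list(px = px, rotation_seed = rotation_seed,
                               notch_angles = notch))
}

#' Synthetic two-tone pattern (Mooney-style stand-in)
#'
#' The original degraded-photograph Mooney face set is not redistributable;
#' this generator produces synthetic stand-ins with the same surface
#' statistics: a smoothed Gaussian random field thresholded at its median
#' into a binary two-tone image. `face_proxy` images are made bilaterally
#' symmetric and receive two dark upper-half blob features (schematic
#' eye region); `scrambled` images are the same image with its blocks
#' randomly permuted, which preserves the pixel-value histogram (hence ink
#' and mean luminance) while destroying the global gestalt.
#'
#' @param kind `"face_proxy"` or `"scrambled"`.
#' @param seed integer seed (a `scrambled` image with seed `s` is the
#'   permutation of the `face_proxy` with seed `s`).
#' @param px image side length (must be divisible by `blocks`).
#' @param blocks scrambling grid size per side.
#' @return a binary `stimulus_image` (values in \{0, 1\}).
#' @export
make_two_tone_pattern <- function(kind = c("face_proxy", "scrambled"), seed = 1,
                                  px = 256, blocks = 8) {
  kind <- match.arg(kind)
  abort_if(px %% blocks != 0, "parameter error: px not divisible by blocks")
  face <- with_seed(seed, {
    f <- smooth_field(matrix(stats::rnorm(px * px), px, px), sigma = px / 24)
    f <- (f + f[, px:1]) / 2                      # bilateral symmetry
    xs <- matrix(rep(seq_len(px), each = px), px, px) / px
    ys <- matrix(rep(seq_len(px), times = px), px, px) / px
    eyes <- exp(-(((xs - 0.35)^2 + (ys - 0.38)^2)) / (2 * 0.08^2)) +
      exp(-(((xs - 0.65)^2 + (ys - 0.38)^2)) / (2 * 0.08^2))
    # dark upper-half features: schematic eye blobs plus a mild vertical
    # shading gradient (two-tone portraits are darker around hair/eyes)
    f <- f - stats::sd(f) * (2.5 * eyes + 0.8 * (0.5 - ys))
    (f > stats::median(f)) * 1.0
  })
  img <- if (kind == "face_proxy") {
    face
  } else {
    with_seed(seed + 104729L, scramble_blocks(face, blocks))
  }
  stimulus_image(img, kind, params = list(seed = seed, px = px, blocks = blocks))
}

# FFT low-pass smoothing with a Gaussian transfer function
smooth_field <- function(f, sigma) {
  px <- nrow(f)
  fr <- c(0:(px %/% 2), -((px - px %/% 2 - 1):1)) / px
  d2 <- outer(fr^2, fr^2, "+")
  g <- exp(-2 * pi^2 * sigma^2 * d2)
  Re(stats::fft(stats::fft(f) * g, inverse = TRUE)) / length(f)
}

# random block permutation (uses current RNG stream)
scramble_blocks <- function(img, blocks) {
  px <- nrow(img)
  b <- px / blocks
  pieces <- vector("list", blocks^2)
  k <- 1
  for (i in seq_len(blocks)) for (j in seq_len(blocks)) {
    pieces[[k]] <- img[((i - 1) * b + 1):(i * b), ((j - 1) * b + 1):(j * b)]
    k <- k + 1
  }
  pieces <- pieces[sample(length(pieces))]
  out <- matrix(0, px, px)
  k <- 1
  for (i in seq_len(blocks)) for (j in seq_len(blocks)) {
    out[((i - 1) * b + 1):(i * b), ((j - 1) * b + 1):(j * b)] <- pieces[[k]]
    k <- k + 1
  }
  out
}

stimulus_image <- function(pixels, kind, params = list()) {
  abort_if(!is.matrix(pixels) || any(pixels < 0) || any(pixels > 1),
           "stimulus images must be rectangular with values in [0, 1]")
  structure(pixels, kind = kind, params = params, class = c("stimulus_image", "matrix"))
}

#' Mean luminance of an image
#' @param img a `stimulus_image` or numeric matrix in \[0,1\].
#' @return mean pixel value.
#' @export
mean_luminance <- function(img) mean(unclass(img))

#' Build the full stimulus set
#'
#' Assembles the counts used by the paradigm: 30 face stand-ins and 30
#' distorted (scrambled) versions, 2 Kanizsa triangles and 2 distorted
#' Kanizsa figures, plus the checkerboard mask.
#'
#' @param seed base seed for all image generators.
#' @param px image side length in pixels.
#' @return a `stimulus_set`: list with `images` (list of
#'   `stimulus_image`), `kind`, `variant_id` and `mean_luminance` vectors.
#' @export
build_stimulus_set <- function(seed = 1, px = 256) {
  images <- c(
    lapply(seq_len(30), function(i) make_two_tone_pattern("face_proxy", seed + i, px)),
    lapply(seq_len(30), function(i) make_two_tone_pattern("scrambled", seed + i, px)),
    lapply(1:2, function(i) make_kanizsa("canonical", px, seed + i)),
    lapply(1:2, function(i) make_kanizsa("distorted", px, seed + i)),
    list(make_checkerboard(8, px))
  )
  kind <- vapply(images, function(x) attr(x, "kind"), character(1))
  structure(list(images = images, kind = kind,
                 variant_id = seq_along(images),
                 mean_luminance = vapply(images, mean_luminance, numeric(1))),
            class = "stimulus_set")
}

#' Equalize mean luminance across a stimulus set
#'
#' Brings every image's mean luminance within `tolerance` of the set's
#' grand mean by flipping randomly chosen pixels of the over-represented
#' tone (dark pixels brightened when the image is too dark, and vice
#' versa), the programmatic analogue of mean-luminance matching across
#' blocks.
#'
#' @param set a `stimulus_set`.
#' @param tolerance maximum allowed absolute deviation of each image's mean
#'   from the grand mean (luminance units, image values in \[0,1\]).
#' @param seed seed for the pixel choices.
#' @return the equalized `stimulus_set`, with a `report` attribute (data
#'   frame of before/after means).
#' @export
equalize_mean_luminance <- function(set, tolerance = 0.01, seed = 1) {
  abort_if(length(set$images) == 0, "equalization error: empty stimulus set")
  before <- vapply(set$images, mean_luminance, numeric(1))
  grand <- mean(before)
  set$images <- with_seed(seed, lapply(set$images, function(img) {
    m <- mean_luminance(img)
    delta <- grand - m
    if (abs(delta) <= tolerance) return(img)
    n_flip <- round(abs(delta) * length(img))
    pool <- if (delta > 0) which(img < 0.5) else which(img >= 0.5)
    abort_if(length(pool) < n_flip,
             "equalization error: image saturated, tolerance unattainable")
    flip <- sample(pool, n_flip)
    img[flip] <- if (delta > 0) 1 else 0
    abort_if(abs(mean_luminance(img) - grand) > max(tolerance, 1 / length(img)),
             "equalization error: tolerance unattainable at pixel resolution")
    img
  }))
  after <- vapply(set$images, mean_luminance, numeric(1))
  set$mean_luminance <- after
  attr(set, "report") <- data.frame(variant_id = set$variant_id, kind = set$kind,
                                    before = before, after = after,
                                    target = grand)
  set
}

#' Write a stimulus set to disk
#'
#' Writes each image as a plain-text portable graymap (PGM, `P2`) plus a
#' tab-separated manifest mapping `variant_id` to file and kind. PNG export
#' via the `grDevices` png device is used when available.
#'
#' @param set a `stimulus_set`.
#' @param dir output directory (created if needed).
#' @param format `"pgm"` (plain text) or `"png"`.
#' @return the manifest data frame, invisibly.
#' @export
write_stimulus_set <- function(set, dir, format = c("pgm", "png")) {
  format <- match.arg(format)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  files <- character(length(set$images))
  for (i in seq_along(set$images)) {
    img <- set$images[[i]]
    stem <- sprintf("%03d_%s", set$variant_id[i], set$kind[i])
    if (format == "pgm") {
      files[i] <- file.path(dir, paste0(stem, ".pgm"))
      write_pgm(img, files[i])
    } else {
      files[i] <- file.path(dir, paste0(stem, ".png"))
      grDevices::png(files[i], width = ncol(img), height = nrow(img))
      graphics::par(mar = c(0, 0, 0, 0))
      graphics::image(t(unclass(img))[, nrow(img):1], col = grDevices::gray(seq(0, 1, length.out = 256)),
                      axes = FALSE, useRaster = TRUE)
      grDevices::dev.off()
    }
  }
  manifest <- data.frame(variant_id = set$variant_id, file = basename(files),
                         kind = set$kind, mean_luminance = set$mean_luminance)
  utils::write.table(manifest, file.path(dir, "manifest.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(manifest)
}

write_pgm <- function(img, path) {
  vals <- round(unclass(img) * 255)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("P2", paste(ncol(img), nrow(img)), "255"), con)
  utils::write.table(vals, con, row.names = FALSE, col.names = FALSE)
}

#' Read a plain-text PGM image
#' @param path file written by [write_stimulus_set()].
#' @return numeric matrix in \[0,1\].
#' @export
read_pgm <- function(path) {
  lines <- readLines(path)
  lines <- lines[!grepl("^#", lines)]
  abort_if(lines[1] != "P2", "parse error: not a plain PGM file")
  dims <- as.integer(strsplit(trimws(lines[2]), "\\s+")[[1]])
  maxv <- as.numeric(lines[3])
  vals <- scan(text = paste(lines[-(1:3)], collapse = "\n"), quiet = TRUE)
  matrix(vals, nrow = dims[2], ncol = dims[1], byrow = TRUE) / maxv
}
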