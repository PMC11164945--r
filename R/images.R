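#' Render one synthetic B-mode-like image
#'
#' Simulates the two textbook sonographic signs of hepatic steatosis on a
#' grayscale image: increased echogenicity (mean brightness grows with
#' grade) and posterior beam attenuation (intensity decays faster with depth
#' at higher grades). Texture is fully developed speckle: the envelope of two
#' independent Gaussian fields smoothed to correlation length
#' `speckle_scale`, which is Rayleigh-distributed before smoothing. Pixel
#' values are quantized to integers in \[0, 255\] so images survive 8-bit PNG
#' round trips bit-exactly.
#'
#' The pixel model is
#' `I(r, c) = (base_level + site_gain + echogenicity_slope * grade) *
#'  exp(-(attenuation_base + attenuation_slope * grade) * depth) * S(r, c)`
#' with `depth` the row position in \[0, 1\] and `S` the unit-mean speckle
#' field.
#'
#' @param grade integer steatosis grade 0-3.
#' @param height,width positive image dimensions in pixels.
#' @param config a [cohort_config()] supplying the echogenicity model.
#' @param seed integer; same seed and parameters give bit-identical pixels.
#' @param site optional site name; adds the configured `site_gain` offset
#'   (scanner/preset difference between centers).
#' @return numeric `height x width` matrix with integer values in \[0, 255\].
#' @export
render_image <- function(grade, height, width, config, seed, site = NULL) {
  if (!grade %in% 0:3) stop("grade must be an integer in 0..3")
  if (height < 1 || width < 1) stop("image dimensions must be positive")
  gain <- if (!is.null(site)) unname(config$site_gain[site]) else 0
  if (is.na(gain)) stop("unknown site '", site, "' in site_gain")
  sscale <- config$speckle_scale
  if (!is.null(site) && !is.null(names(sscale)) && site %in% names(sscale))
    sscale <- sscale[site]
  sscale <- unname(sscale[1])
  # blur kernel (2 ceil(3 sigma) + 1 wide) must fit inside the frame
  sscale <- min(sscale, (min(height, width) - 1) / 7)
  with_seed(seed, {
    g1 <- matrix(rnorm(height * width), height, width)
    g2 <- matrix(rnorm(height * width), height, width)
    if (sscale > 0) {
      g1 <- EBImage::gblur(g1, sigma = sscale)
      g2 <- EBImage::gblur(g2, sigma = sscale)
    }
    env <- sqrt(g1^2 + g2^2)
    speckle <- env / mean(env)
    abase <- config$attenuation_base
    if (!is.null(site) && !is.null(names(abase)) && site %in% names(abase))
      abase <- abase[site]
    base <- config$base_level + gain + config$echogenicity_slope * grade
    rate <- unname(abase[1]) + config$attenuation_slope * grade
    depth <- matrix(seq(0, 1, length.out = height), height, width)
    img <- base * exp(-rate * depth) * speckle
    fov <- "linear"
    if (!is.null(site) && !is.null(config$fov) && site %in% names(config$fov))
      fov <- config$fov[[site]]
    mask <- if (identical(fov, "sector")) sector_mask(height, width)
            else matrix(1, height, width)
    img <- img * mask
    ag <- FALSE
    if (!is.null(site) && !is.null(config$auto_gain) &&
        site %in% names(config$auto_gain))
      ag <- isTRUE(config$auto_gain[[site]])
    if (ag) img <- img * (config$base_level + unname(gain)) /
      mean(img[mask > 0])
    img <- round(pmin(pmax(img, 0), 255))
    img
  })
}

# fan-shaped insonified region of a sector probe: apex at the top center,
# half-angle 40 degrees, radius the image height
sector_mask <- function(height, width, half_angle = 40) {
  r <- matrix(seq_len(height), height, width)
  c0 <- (width + 1) / 2
  cc <- matrix(rep(seq_len(width), each = height), height, width)
  ang <- atan2(cc - c0, r) * 180 / pi
  (abs(ang) <= half_angle) * (sqrt(r^2 + (cc - c0)^2) <= height)
}

#' Generate all images for a cohort
#'
#' Renders `images_per_patient` images per patient at the site's configured
#' resolution. Deterministic: image seeds are derived from the cohort seed,
#' the patient's position and the acquisition index.
#'
#' @param cohort data.frame from [generate_cohort()].
#' @param config the same [cohort_config()].
#' @return named list, one entry per `patient_id`, each a list of
#'   `images_per_patient` grayscale matrices.
#' @export
generate_images <- function(cohort, config) {
  out <- vector("list", nrow(cohort))
  names(out) <- cohort$patient_id
  for (i in seq_len(nrow(cohort))) {
    s <- cohort$site[i]
    sz <- config$image_size[[s]]
    out[[i]] <- lapply(seq_len(config$images_per_patient), function(k) {
      render_image(cohort$grade[i], sz[1], sz[2], config,
                   seed = derive_seed(config$seed, 3L, i, k), site = s)
    })
  }
  out
}

#' Write a cohort to disk as PNG images plus a CSV manifest
#'
#' One 8-bit grayscale PNG per image, named
#' `<patient_id>_<acquisition_index>.png`, and a manifest CSV with one row
#' per image (columns `patient_id`, `site`, `grade`, `binary_class`, `sex`,
#' `age`, `bmi`, `image_path`).
#'
#' @param cohort data.frame from [generate_cohort()].
#' @param images list from [generate_images()].
#' @param directory output directory (created if absent).
#' @return invisibly, the manifest path.
#' @export
write_dataset <- function(cohort, images, directory) {
  dir.create(directory, recursive = TRUE, showWarnings = FALSE)
  rows <- vector("list", nrow(cohort))
  for (i in seq_len(nrow(cohort))) {
    pid <- cohort$patient_id[i]
    imgs <- images[[pid]]
    if (is.null(imgs)) stop("no images for patient '", pid, "'")
    paths <- sprintf("%s_%d.png", pid, seq_along(imgs))
    for (k in seq_along(imgs))
      png::writePNG(imgs[[k]] / 255, file.path(directory, paths[k]))
    rows[[i]] <- data.frame(cohort[i, , drop = FALSE],
                            image_path = paths, row.names = NULL)
  }
  manifest <- do.call(rbind, rows)
  mpath <- file.path(directory, "manifest.csv")
  write.csv(manifest, mpath, row.names = FALSE)
  invisible(mpath)
}

#' Read a dataset written by [write_dataset()] (or any directory of PNGs
#' with a conforming manifest)
#'
#' @param directory dataset directory containing `manifest.csv`.
#' @return list with `cohort` (one row per patient) and `images` (named list
#'   of grayscale matrices per patient, values in \[0, 255\]).
#' @export
read_dataset <- function(directory) {
  mpath <- file.path(directory, "manifest.csv")
  if (!file.exists(mpath)) stop("manifest.csv not found in ", directory)
  manifest <- read.csv(mpath, stringsAsFactors = FALSE)
  need <- c("patient_id", "site", "grade", "binary_class", "sex", "age",
            "bmi", "image_path")
  missing_cols <- setdiff(need, names(manifest))
  if (length(missing_cols))
    stop("manifest is missing columns: ", paste(missing_cols, collapse = ", "))
  paths <- file.path(directory, manifest$image_path)
  absent <- manifest$image_path[!file.exists(paths)]
  if (length(absent))
    stop("manifest references missing files: ",
         paste(absent, collapse = ", "))
  cohort <- unique(manifest[, setdiff(need, "image_path")])
  rownames(cohort) <- NULL
  images <- split(paths, manifest$patient_id)[unique(manifest$patient_id)]
  images <- lapply(images, function(ps)
    lapply(ps, function(p) round(png::readPNG(p) * 255)))
  list(cohort = cohort, images = images)
}
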