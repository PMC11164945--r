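#' Configuration for the synthetic two-site cohort
#'
#' Builds the configuration object consumed by [generate_cohort()],
#' [generate_images()] and [render_image()]. Defaults reproduce the study
#' conditions of a two-center hepatic steatosis cohort: a private-like site
#' with 153 patients (35/51/29/38 across grades 0-3) and a public-like site
#' with 55 patients (17/20/8/10), ten B-mode-like grayscale images per
#' patient, and site demographics (private: age 52 +/- 13 y, BMI 30.8 +/- 8.0
#' kg/m^2, 49% male; public: age 40 +/- 9 y, BMI 45.9 +/- 5.6 kg/m^2, 20%
#' male). The `"tiny"` profile keeps the cohort structure but renders 64 x 64
#' images so full experiments run at desk scale.
#'
#' Image appearance is controlled by an echogenicity model: mean intensity
#' grows with steatosis grade (`echogenicity_slope`, intensity units per
#' grade), posterior attenuation grows with grade (`attenuation_slope`, added
#' to `attenuation_base` per grade, in units of log-intensity over the full
#' image depth), and texture is spatially correlated Rayleigh speckle with
#' correlation length `speckle_scale` pixels. `site_gain` models
#' scanner/preset differences between centers as an additive intensity
#' offset per site.
#'
#' @param profile `"full"` (native image resolutions: 960 x 1280
#'   private-like, 434 x 636 public-like) or `"tiny"` (64 x 64 both sites).
#' @param per_site_grade_counts named list, one integer vector of length 4
#'   (grades 0-3) per site.
#' @param images_per_patient integer >= 1.
#' @param image_size named list, `c(height, width)` per site.
#' @param demographics named list per site with entries `age_mean`, `age_sd`,
#'   `bmi_mean`, `bmi_sd`, `male_fraction`.
#' @param base_level mean echogenicity (intensity units) of a grade-0 liver.
#' @param echogenicity_slope intensity units added per steatosis grade.
#' @param attenuation_base,attenuation_slope depth attenuation rate and its
#'   per-grade increment.
#' @param speckle_scale speckle correlation length in pixels; a named
#'   per-site vector models transducer differences (a low-frequency sector
#'   probe produces coarser speckle than higher-frequency linear probes), or
#'   a single number for identical texture at both sites.
#' @param site_gain named numeric, additive intensity offset per site.
#' @param fov per-site field-of-view geometry: `"linear"` (full rectangular
#'   frame) or `"sector"` (fan-shaped insonified region with black
#'   surround, as produced by a phased/sector probe).
#' @param auto_gain per-site logical: `TRUE` emulates automatic gain
#'   compensation (each image rescaled to a fixed mean brightness within
#'   the insonified region), as applied by default scanner presets; on such
#'   a site the steatosis signal survives only in the depth-attenuation
#'   profile and texture, not in absolute brightness.
#' @param seed integer; the whole cohort (and its images) is a pure function
#'   of this configuration.
#' @return A list of class `"cohort_config"`.
#' @export
cohort_config <- function(profile = c("full", "tiny"),
                          per_site_grade_counts = list(
                            private_like = c(35L, 51L, 29L, 38L),
                            public_like = c(17L, 20L, 8L, 10L)),
                          images_per_patient = 10L,
                          image_size = NULL,
                          demographics = list(
                            private_like = list(age_mean = 52, age_sd = 13,
                                                bmi_mean = 30.8, bmi_sd = 8.0,
                                                male_fraction = 0.49),
                            public_like = list(age_mean = 40, age_sd = 9,
                                               bmi_mean = 45.9, bmi_sd = 5.6,
                                               male_fraction = 0.20)),
                          base_level = 80,
                          echogenicity_slope = 15,
                          attenuation_base = 0.4,
                          attenuation_slope = 0.45,
                          speckle_scale = c(private_like = 2.5,
                                            public_like = 5),
                          site_gain = c(private_like = 0, public_like = 18),
                          fov = c(private_like = "linear",
                                  public_like = "sector"),
                          auto_gain = c(private_like = FALSE,
                                        public_like = TRUE),
                          seed = 1L) {
  profile <- match.arg(profile)
  # accept list-shaped inputs (e.g. parsed YAML) for the named vectors
  speckle_scale <- unlist(speckle_scale)
  site_gain <- unlist(site_gain)
  fov <- unlist(fov)
  auto_gain <- unlist(auto_gain)
  if (!is.null(image_size))
    image_size <- lapply(image_size, function(v) as.integer(unlist(v)))
  if (is.null(image_size)) {
    image_size <- if (profile == "full")
      list(private_like = c(960L, 1280L), public_like = c(434L, 636L))
    else
      list(private_like = c(64L, 64L), public_like = c(64L, 64L))
  }
  sites <- names(per_site_grade_counts)
  if (is.null(sites) || any(sites == ""))
    stop("per_site_grade_counts must be a named list of sites")
  for (s in sites) {
    cnt <- per_site_grade_counts[[s]]
    if (length(cnt) != 4L || any(!is.finite(cnt)) || any(cnt < 0) ||
        any(cnt != round(cnt)))
      stop("per_site_grade_counts[['", s,
           "']] must be 4 non-negative integers (grades 0-3)")
    if (sum(cnt) < 1)
      stop("per_site_grade_counts[['", s, "']]: site has no patients")
  }
  if (!is.numeric(images_per_patient) || images_per_patient < 1)
    stop("images_per_patient must be >= 1")
  for (s in sites)
    if (any(image_size[[s]] < 1)) stop("image_size[['", s, "']] must be positive")
  cfg <- list(profile = profile,
              per_site_grade_counts = lapply(per_site_grade_counts, as.integer),
              images_per_patient = as.integer(images_per_patient),
              image_size = image_size,
              demographics = demographics,
              base_level = base_level,
              echogenicity_slope = echogenicity_slope,
              attenuation_base = attenuation_base,
              attenuation_slope = attenuation_slope,
              speckle_scale = speckle_scale,
              site_gain = site_gain,
              fov = fov,
              auto_gain = auto_gain,
              seed = as.integer(seed))
  class(cfg) <- "cohort_config"
  cfg
}

# rejection-sampled truncated normal (lower bound only)
rtnorm_lower <- function(n, mean, sd, lower) {
  out <- rnorm(n, mean, sd)
  bad <- which(out < lower)
  while (length(bad)) {
    out[bad] <- rnorm(length(bad), mean, sd)
    bad <- bad[out[bad] < lower]
  }
  out
}

#' Generate the synthetic patient cohort
#'
#' Draws one patient record per configured slot: per-site per-grade counts are
#' honored exactly (counts are configuration, never sampled), ages and BMIs
#' come from truncated normals (age >= 18 years, BMI >= 15 kg/m^2) with the
#' configured site means and SDs, and sex is Bernoulli in the configured male
#' fraction. The binary class is `"S0"` for grade 0 and `"S1plus"` otherwise.
#'
#' @param config a [cohort_config()].
#' @return A data.frame with one row per patient: `patient_id`, `site`,
#'   `grade`, `binary_class`, `sex`, `age`, `bmi`.
#' @examples
#' cohort <- generate_cohort(cohort_config("tiny"))
#' table(cohort$site, cohort$grade)
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  with_seed(derive_seed(config$seed, 1L), {
    rows <- list()
    for (s in names(config$per_site_grade_counts)) {
      cnt <- config$per_site_grade_counts[[s]]
      dem <- config$demographics[[s]]
      if (is.null(dem))
        stop("demographics missing for site '", s, "'")
      n <- sum(cnt)
      grade <- rep(0:3, times = cnt)
      rows[[s]] <- data.frame(
        patient_id = sprintf("%s_%03d", s, seq_len(n)),
        site = s,
        grade = grade,
        binary_class = ifelse(grade == 0, "S0", "S1plus"),
        sex = ifelse(rbinom(n, 1L, dem$male_fraction) == 1L, "M", "F"),
        age = round(rtnorm_lower(n, dem$age_mean, dem$age_sd, 18), 1),
        bmi = round(rtnorm_lower(n, dem$bmi_mean, dem$bmi_sd, 15), 1),
        stringsAsFactors = FALSE)
    }
    cohort <- do.call(rbind, rows)
    rownames(cohort) <- NULL
    cohort
  })
}

#' Patient-level class-balanced train/test split
#'
#' Reserves, per site, `n_test_per_site / 2` patients of class S0 and the
#' same number of class S1plus, sampled uniformly without replacement; all
#' remaining patients form the training pool. The split is by patient — all
#' images of a patient follow the patient — so no image of a test patient can
#' leak into training.
#'
#' @param cohort data.frame from [generate_cohort()].
#' @param n_test_per_site even integer, test patients reserved per site.
#' @param seed integer RNG seed.
#' @return list with data.frames `train_patients` and `test_patients`.
#' @export
make_test_split <- function(cohort, n_test_per_site = 10L, seed = 1L) {
  if (n_test_per_site %% 2L != 0L)
    stop("n_test_per_site must be even (half per binary class)")
  half <- n_test_per_site %/% 2L
  with_seed(derive_seed(seed, 2L), {
    test_ids <- character(0)
    for (s in unique(cohort$site)) {
      for (cl in c("S0", "S1plus")) {
        ids <- cohort$patient_id[cohort$site == s & cohort$binary_class == cl]
        if (length(ids) < half)
          stop("site '", s, "' has only ", length(ids), " patients of class ",
               cl, "; need ", half)
        test_ids <- c(test_ids, sample(ids, half))
      }
    }
    list(train_patients = cohort[!cohort$patient_id %in% test_ids, ,
                                 drop = FALSE],
         test_patients = cohort[cohort$patient_id %in% test_ids, ,
                                drop = FALSE])
  })
}
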