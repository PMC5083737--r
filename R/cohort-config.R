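#' Generative parameters for the six discriminating nuclear features
#'
#' Per-class means and standard deviations of the six karyometric
#' features that separate chronic pancreatitis, IPMN, and pancreatic
#' carcinoma in the reference cohort: nuclear roundness (form factor),
#' a run-length-matrix summary, short and long run emphasis, run
#' percentage, and the count of lightly stained pixels. These are the
#' defaults used by the synthetic-cohort generator.
#'
#' @return A data frame with columns `feature`, `class`, `mean`, `sd`;
#'   one row per feature/class combination (18 rows).
#' @export
#' @examples
#' informative_defaults()
informative_defaults <- function() {
  feats <- c("nuclear_roundness", "rlm_summary", "short_run_emphasis",
             "long_run_emphasis", "run_percentage", "n_light_pixels")
  means <- rbind(
    nuclear_roundness  = c(1.63, 1.79, 1.69),
    rlm_summary        = c(12.80, 10.08, 10.85),
    short_run_emphasis = c(0.51, 0.47, 0.46),
    long_run_emphasis  = c(9.83, 11.50, 10.58),
    run_percentage     = c(467.37, 511.37, 723.86),
    n_light_pixels     = c(230.17, 340.87, 581.29))
  sds <- rbind(
    nuclear_roundness  = c(0.04, 0.10, 0.04),
    rlm_summary        = c(1.16, 2.44, 1.98),
    short_run_emphasis = c(0.03, 0.04, 0.03),
    long_run_emphasis  = c(0.91, 0.86, 0.84),
    run_percentage     = c(47.33, 128.25, 165.97),
    n_light_pixels     = c(51.18, 171.84, 227.73))
  data.frame(
    feature = rep(feats, each = 3),
    class = rep(karyo_classes(), times = length(feats)),
    mean = as.vector(t(means[feats, ])),
    sd = as.vector(t(sds[feats, ])),
    stringsAsFactors = FALSE)
}

#' Configuration for synthetic karyometry cohorts
#'
#' Bundles and validates every knob of the synthetic-cohort generator:
#' cohort composition, the nuclei-per-tissue distribution, the number of
#' uninformative noise features, and the per-class generative
#' parameters of the informative features.
#'
#' @param n_per_class Integer vector of length 3: tissues per class in
#'   the order CP, IPMN, PC. Default `c(12, 16, 16)`, the reference
#'   cohort composition.
#' @param nuclei_mean Expected nuclei imaged per tissue (default 180).
#' @param nuclei_sd Standard deviation of nuclei per tissue (default
#'   22). Counts are drawn normal, rounded, and truncated at 1.
#' @param n_noise_features Number of uninformative standard-normal
#'   feature dimensions appended to the informative panel (default 87,
#'   so the full panel has 93 dimensions).
#' @param informative_params Data frame as returned by
#'   [informative_defaults()]: per-class mean and sd for each
#'   informative feature.
#' @param nucleus_dispersion Within-tissue nucleus-level standard
#'   deviation, expressed as a multiple of the tissue-level sd of the
#'   same feature (default 3).
#' @param seed Integer seed driving all randomness of the generator.
#' @return A validated list of class `cohort_config`.
#' @export
#' @examples
#' cfg <- cohort_config(seed = 7)
#' cfg$n_per_class
cohort_config <- function(n_per_class = c(CP = 12, IPMN = 16, PC = 16),
                          nuclei_mean = 180, nuclei_sd = 22,
                          n_noise_features = 87,
                          informative_params = informative_defaults(),
                          nucleus_dispersion = 3,
                          seed = 1L) {
  n_per_class <- as.integer(n_per_class)
  if (length(n_per_class) != 3 || anyNA(n_per_class) || any(n_per_class < 0))
    stop("n_per_class must be three non-negative counts (CP, IPMN, PC)")
  names(n_per_class) <- karyo_classes()
  if (!is.numeric(nuclei_mean) || length(nuclei_mean) != 1)
    stop("nuclei_mean must be a single number")
  if (nuclei_sd < 0) stop("nuclei_sd must be >= 0")
  if (n_noise_features < 0) stop("n_noise_features must be >= 0")
  req <- c("feature", "class", "mean", "sd")
  if (!all(req %in% names(informative_params)))
    stop("informative_params needs columns feature, class, mean, sd")
  if (any(informative_params$sd <= 0))
    stop("every informative-feature sd must be > 0")
  if (nucleus_dispersion <= 0) stop("nucleus_dispersion must be > 0")
  structure(list(
    n_per_class = n_per_class,
    nuclei_mean = nuclei_mean,
    nuclei_sd = nuclei_sd,
    n_noise_features = as.integer(n_noise_features),
    informative_params = informative_params,
    nucleus_dispersion = nucleus_dispersion,
    seed = as.integer(seed)), class = "cohort_config")
}

# informative feature names in panel order
informative_features <- function(config) {
  unique(config$informative_params$feature)
}

noise_feature_names <- function(config) {
  if (config$n_noise_features == 0) return(character(0))
  sprintf("noise_%03d", seq_len(config$n_noise_features))
}

#' Feature-panel column names of a cohort configuration
#'
#' @param config A [cohort_config()].
#' @return Character vector: informative feature names followed by the
#'   noise dimensions (`noise_001`, ...).
#' @export
feature_names <- function(config = cohort_config()) {
  c(informative_features(config), noise_feature_names(config))
}
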