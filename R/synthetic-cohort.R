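#' Generate a tissue-level synthetic feature cohort
#'
#' Draws one feature vector per tissue. Each informative feature is an
#' independent normal draw with that class's generative mean and sd;
#' noise features are standard normal, identically distributed across
#' classes. This is the "tier-2" entry point: it emulates the
#' per-tissue averaged feature table that the classification pipeline
#' consumes, without rendering any images.
#'
#' @param config A [cohort_config()]. `config$seed` makes the output
#'   fully reproducible.
#' @return A data frame with columns `tissue_id`, `class`, then the
#'   feature panel ([feature_names()]); one row per tissue. With an
#'   all-zero `n_per_class` the table is empty but keeps its full
#'   column schema.
#' @export
#' @examples
#' cohort <- gen_feature_cohort(cohort_config(seed = 1))
#' dim(cohort)
#' table(cohort$class)
gen_feature_cohort <- function(config = cohort_config()) {
  stopifnot(inherits(config, "cohort_config"))
  withr::with_seed(config$seed, gen_feature_cohort_impl(config))
}

gen_feature_cohort_impl <- function(config) {
  feats <- feature_names(config)
  inf <- informative_features(config)
  rows <- vector("list", 3)
  for (ci in seq_along(karyo_classes())) {
    cls <- karyo_classes()[ci]
    n <- config$n_per_class[[cls]]
    if (n == 0) next
    X <- matrix(NA_real_, n, length(feats), dimnames = list(NULL, feats))
    for (f in inf) {
      par <- config$informative_params[
        config$informative_params$feature == f &
          config$informative_params$class == cls, ]
      X[, f] <- rnorm(n, par$mean, par$sd)
    }
    nn <- config$n_noise_features
    if (nn > 0)
      X[, noise_feature_names(config)] <- matrix(rnorm(n * nn), n, nn)
    rows[[ci]] <- data.frame(
      tissue_id = sprintf("%s_%03d", cls, seq_len(n)),
      class = cls, X, stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  if (is.null(out)) {
    out <- data.frame(tissue_id = character(0), class = character(0))
    for (f in feats) out[[f]] <- numeric(0)
  }
  out$class <- as_karyo_class(out$class)
  rownames(out) <- NULL
  out
}

#' Generate a nucleus-level synthetic cohort
#'
#' Two-stage ("tier-2") hierarchy: each tissue receives a latent class
#' mean vector (informative features drawn from the class generative
#' normals, noise features from a standard normal), and each of its
#' nuclei is an independent normal draw around that latent mean with sd
#' equal to `nucleus_dispersion` times the tissue-level sd. The number
#' of nuclei per tissue is drawn normal(`nuclei_mean`, `nuclei_sd`),
#' rounded, and truncated at 1 — emulating roughly 180 +/- 22 imaged
#' nuclei per lesion. Optionally renders grayscale images for a leading
#' subset of nuclei per tissue via [render_nucleus()] using the
#' class presets.
#'
#' @param config A [cohort_config()].
#' @param images_per_tissue Number of leading nuclei per tissue for
#'   which an image/mask pair is rendered (default 0: feature tier
#'   only).
#' @return An object of class `nucleus_cohort`: a list with
#'   `nuclei` (data frame `tissue_id`, `nucleus_id`, `class`, feature
#'   panel), `tissues` (data frame of latent per-tissue means with the
#'   same feature columns plus `n_nuclei`), `images` (named list of
#'   [nucleus_image()] objects, possibly empty), and `config`.
#' @export
#' @examples
#' cc <- cohort_config(n_per_class = c(2, 2, 2), nuclei_mean = 20,
#'                     nuclei_sd = 4, seed = 3)
#' coh <- gen_nucleus_cohort(cc)
#' head(coh$tissues$n_nuclei)
gen_nucleus_cohort <- function(config = cohort_config(),
                               images_per_tissue = 0) {
  stopifnot(inherits(config, "cohort_config"))
  if (config$nuclei_mean <= 0) stop("nuclei_mean must be > 0")
  withr::with_seed(config$seed,
                   gen_nucleus_cohort_impl(config, images_per_tissue))
}

gen_nucleus_cohort_impl <- function(config, images_per_tissue) {
  feats <- feature_names(config)
  inf <- informative_features(config)
  nn <- config$n_noise_features
  n_tis <- sum(config$n_per_class)
  if (n_tis == 0) stop("empty cohort")

  cls_vec <- rep(karyo_classes(), times = config$n_per_class)
  tid <- unlist(lapply(karyo_classes(), function(cl)
    sprintf("%s_%03d", cl, seq_len(config$n_per_class[[cl]]))))
  counts <- pmax(1L, as.integer(round(
    rnorm(n_tis, config$nuclei_mean, config$nuclei_sd))))

  # per-class sd lookup for informative features
  sd_of <- function(f, cl) config$informative_params$sd[
    config$informative_params$feature == f &
      config$informative_params$class == cl]
  mean_of <- function(f, cl) config$informative_params$mean[
    config$informative_params$feature == f &
      config$informative_params$class == cl]

  latent <- matrix(NA_real_, n_tis, length(feats),
                   dimnames = list(NULL, feats))
  nuc_rows <- vector("list", n_tis)
  for (i in seq_len(n_tis)) {
    cl <- cls_vec[i]
    for (f in inf) latent[i, f] <- rnorm(1, mean_of(f, cl), sd_of(f, cl))
    if (nn > 0) latent[i, noise_feature_names(config)] <- rnorm(nn)
    m <- counts[i]
    Xn <- matrix(NA_real_, m, length(feats), dimnames = list(NULL, feats))
    for (f in inf)
      Xn[, f] <- rnorm(m, latent[i, f],
                       config$nucleus_dispersion * sd_of(f, cl))
    if (nn > 0)
      Xn[, noise_feature_names(config)] <- matrix(
        rnorm(m * nn, 0, config$nucleus_dispersion), m, nn) +
        rep(latent[i, noise_feature_names(config)], each = m)
    nuc_rows[[i]] <- data.frame(
      tissue_id = tid[i], nucleus_id = sprintf("n%04d", seq_len(m)),
      class = cl, Xn, stringsAsFactors = FALSE)
  }
  nuclei <- do.call(rbind, nuc_rows)
  nuclei$class <- as_karyo_class(nuclei$class)
  rownames(nuclei) <- NULL

  tissues <- data.frame(tissue_id = tid, class = as_karyo_class(cls_vec),
                        n_nuclei = counts, latent,
                        stringsAsFactors = FALSE)
  rownames(tissues) <- NULL

  images <- list()
  if (images_per_tissue > 0) {
    presets <- class_presets()
    for (i in seq_len(n_tis)) {
      k <- min(images_per_tissue, counts[i])
      for (j in seq_len(k)) {
        spec <- presets[[cls_vec[i]]]
        images[[sprintf("%s_n%04d", tid[i], j)]] <-
          render_nucleus(spec, seed = sample.int(.Machine$integer.max, 1))
      }
    }
  }

  structure(list(nuclei = nuclei, tissues = tissues, images = images,
                 config = config),
            class = "nucleus_cohort")
}

#' @export
print.nucleus_cohort <- function(x, ...) {
  cat(sprintf("nucleus_cohort: %d tissues, %d nuclei, %d features, %d images\n",
              nrow(x$tissues), nrow(x$nuclei),
              length(feature_names(x$config)), length(x$images)))
  print(table(x$tissues$class))
  invisible(x)
}
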