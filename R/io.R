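#' Read a validated feature table
#'
#' Reads a comma-separated feature table (UTF-8, '.' decimal, header
#' mandatory) and validates its schema: a `tissue_id` column, an
#' optional `class` column restricted to CP/IPMN/PC, an optional
#' `nucleus_id` column for nucleus-level tables, and numeric feature
#' columns. Errors name the offending column and row.
#'
#' @param path Path to a CSV file.
#' @param require_class Error when the `class` column is absent.
#' @return Data frame with `class` (when present) as the canonical
#'   factor and all feature columns numeric.
#' @export
read_feature_table <- function(path, require_class = FALSE) {
  if (!file.exists(path)) stop(sprintf("input file not found: %s", path))
  df <- read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (!"tissue_id" %in% names(df))
    stop(sprintf("%s: missing required column 'tissue_id'", path))
  if (require_class && !"class" %in% names(df))
    stop(sprintf("%s: missing required column 'class'", path))
  if ("class" %in% names(df)) {
    bad <- which(!df$class %in% karyo_classes())
    if (length(bad) > 0)
      stop(sprintf("%s: unknown class label '%s' at row %d", path,
                   df$class[bad[1]], bad[1]))
    df$class <- as_karyo_class(df$class)
  }
  featcols <- setdiff(names(df), c("tissue_id", "nucleus_id", "class"))
  if (length(featcols) == 0) stop(sprintf("%s: no feature columns", path))
  for (fc in featcols) {
    v <- suppressWarnings(as.numeric(df[[fc]]))
    bad <- which(is.na(v) & !is.na(df[[fc]]))
    if (length(bad) > 0)
      stop(sprintf("%s: non-numeric value '%s' in column '%s' at row %d",
                   path, df[[fc]][bad[1]], fc, bad[1]))
    if (anyNA(v))
      stop(sprintf("%s: missing value in column '%s' at row %d",
                   path, fc, which(is.na(v))[1]))
    df[[fc]] <- v
  }
  df
}

#' Write a feature table
#'
#' Comma-separated, UTF-8, header row, '.' decimal; floating-point
#' columns are serialized with 9 significant digits so that a
#' write/read round trip preserves numeric content to float precision.
#'
#' @param df Feature table (as produced by [gen_feature_cohort()] or
#'   read by [read_feature_table()]).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_feature_table <- function(df, path) {
  out <- df
  for (nm in names(out)) {
    if (is.numeric(out[[nm]]) && !is.integer(out[[nm]]))
      out[[nm]] <- signif(out[[nm]], 9)
    if (is.factor(out[[nm]])) out[[nm]] <- as.character(out[[nm]])
  }
  write.csv(out, path, row.names = FALSE, quote = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Write a nucleus image/mask pair as grayscale PNG
#'
#' 8-bit grayscale PNG, intensity 0 = fully stained (dark), 255 =
#' light; the mask goes to a sibling `<stem>_mask.png` binary PNG.
#'
#' @param n A [nucleus_image()].
#' @param stem Output path without extension.
#' @return Character vector of the two paths written, invisibly.
#' @export
write_nucleus_png <- function(n, stem) {
  stopifnot(inherits(n, "nucleus_image"))
  img <- paste0(stem, ".png")
  msk <- paste0(stem, "_mask.png")
  EBImage::writeImage(EBImage::Image(n$pixels / 255), img, type = "png")
  EBImage::writeImage(EBImage::Image(n$mask * 1), msk, type = "png")
  invisible(c(img, msk))
}

#' Read a nucleus image (and optional mask) from PNG/TIFF
#'
#' @param path Grayscale image path; intensities are rescaled to
#'   \[0, 255\].
#' @param mask_path Optional binary mask path; when absent the whole
#'   frame is taken as in-mask.
#' @return A [nucleus_image()].
#' @export
read_nucleus_image <- function(path, mask_path = NULL) {
  px <- round(as.matrix(EBImage::imageData(EBImage::readImage(path))) * 255)
  mask <- if (is.null(mask_path)) matrix(TRUE, nrow(px), ncol(px)) else
    as.matrix(EBImage::imageData(EBImage::readImage(mask_path))) > 0.5
  nucleus_image(px, mask)
}

#' Serialize a fitted model to JSON
#'
#' Stores the class order, penalty kind, full lambda path, selected
#' lambda, cross-validation criterion, standardization constants, and
#' the original-scale intercepts and coefficient matrix at the selected
#' lambda. The file round-trips through [read_model_json()] into a
#' `karyo_model` usable by [predict_proba()].
#'
#' @param m A `karyo_cv` (preferred) or `karyo_path` (its last path
#'   point is stored).
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_model_json <- function(m, path) {
  if (inherits(m, "karyo_cv")) {
    fit <- m$fit; lam <- m$lambda_selected; crit <- m$criterion
  } else if (inherits(m, "karyo_path")) {
    fit <- m; lam <- m$lambda[length(m$lambda)]; crit <- NA_character_
  } else stop("unsupported model object")
  l <- which.min(abs(fit$lambda - lam))
  beta <- fit$beta[, , l, drop = TRUE]
  if (is.null(dim(beta))) beta <- matrix(beta, ncol = length(fit$classes))
  obj <- list(
    format = "karyoclass-model",
    version = as.character(utils::packageVersion("karyoclass")),
    classes = fit$classes,
    penalty = fit$penalty,
    cv_criterion = crit,
    lambda_path = fit$lambda,
    lambda_selected = lam,
    feature_names = fit$feature_names,
    center = unname(fit$center),
    scale = unname(fit$scale),
    a0 = unname(fit$a0[, l]),
    beta = unname(as.data.frame(beta)),
    selected_features = selected_features(fit, lambda = lam))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Deserialize a model written by [write_model_json()]
#'
#' @param path JSON path.
#' @return Object of class `karyo_model` with `a0`, `beta`, `classes`,
#'   `penalty`, `lambda_selected`, `feature_names`,
#'   `selected_features`.
#' @export
read_model_json <- function(path) {
  if (!file.exists(path)) stop(sprintf("model file not found: %s", path))
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(obj$format, "karyoclass-model"))
    stop(sprintf("%s is not a karyoclass model file", path))
  beta <- as.matrix(obj$beta)
  dimnames(beta) <- list(obj$feature_names, obj$classes)
  structure(list(a0 = obj$a0, beta = beta, classes = obj$classes,
                 penalty = obj$penalty,
                 lambda_selected = obj$lambda_selected,
                 lambda_path = obj$lambda_path,
                 feature_names = obj$feature_names,
                 selected_features = obj$selected_features),
            class = "karyo_model")
}

#' Write a run manifest
#'
#' Provenance record for one pipeline run: tool version, subcommand,
#' full parameter set, seeds, input/output paths with MD5 digests, and
#' a timestamp. Exactly one manifest per output directory.
#'
#' @param dir Output directory.
#' @param subcommand Name of the pipeline step.
#' @param params Named list of parameters (must include any seeds).
#' @param inputs,outputs Character vectors of file paths to digest.
#' @return Path of the manifest written, invisibly.
#' @export
write_manifest <- function(dir, subcommand, params, inputs = character(0),
                           outputs = character(0)) {
  digest <- function(paths) {
    paths <- paths[file.exists(paths)]
    as.list(tools::md5sum(paths))
  }
  obj <- list(tool = "karyoclass",
              version = as.character(utils::packageVersion("karyoclass")),
              subcommand = subcommand,
              parameters = params,
              inputs = digest(inputs),
              outputs = digest(outputs),
              timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
  path <- file.path(dir, "manifest.json")
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
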