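# Frozen-model transfer: apply a model trained on one cohort to another
# cohort's connectomes via dot product, and validate the predictions
# against the external cohort's age with motion control and Bonferroni
# correction across the model family.

#' Apply a frozen predictive model to new connectomes
#'
#' Pure dot product plus intercept; no refitting and no recentring with
#' external statistics (the training-cohort centring is baked into the
#' stored coefficients and intercept). When both the model and the call
#' carry an atlas, their fingerprints must match.
#'
#' @param model A `pls_model`.
#' @param X_new Subjects x edges matrix in the model's edge ordering.
#' @param atlas Optional atlas of `X_new`, checked against the hash
#'   recorded at training time.
#' @return Numeric vector of predicted scores.
#' @export
apply_model <- function(model, X_new, atlas = NULL) {
  stopifnot(inherits(model, "pls_model"))
  if (!is.null(atlas) && !is.null(model$atlas_hash) &&
      atlas_hash(atlas) != model$atlas_hash) {
    stop("incompatible feature space: atlas hash mismatch (model ",
         model$atlas_hash, ", data ", atlas_hash(atlas), ")")
  }
  predict(model, X_new)
}

#' Validate transferred predictions against external age
#'
#' Partial correlation between the model-predicted scores and the external
#' cohort's age, controlling for mean framewise displacement, with a
#' Bonferroni-adjusted significance threshold across all models applied to
#' the cohort (age plus eight cognitive metrics = 9 by default in the full
#' pipeline).
#'
#' @param predicted Transferred predictions.
#' @param external_age External cohort ages.
#' @param external_fd Mean FD values (or `NULL` for a plain correlation).
#' @param n_models_tested Size of the Bonferroni family (default 1).
#' @param alpha Family-wise alpha (default 0.05).
#' @param target_name Stored label.
#' @return List with `target_name`, `partial_r`, `p`, `bonferroni_alpha`,
#'   `passed`.
#' @export
validate_transfer <- function(predicted, external_age, external_fd = NULL,
                              n_models_tested = 1L, alpha = 0.05,
                              target_name = "") {
  if (length(predicted) != length(external_age)) {
    stop("invalid input: length mismatch")
  }
  if (is.null(external_fd)) {
    n <- length(predicted)
    r <- stats::cor(predicted, external_age)
    tstat <- r * sqrt((n - 2) / (1 - r^2))
    p <- 2 * stats::pt(-abs(tstat), n - 2)
  } else {
    pa <- partial_accuracy(external_age, predicted, external_fd)
    r <- pa$r
    p <- pa$p
  }
  thr <- alpha / n_models_tested
  list(target_name = target_name, partial_r = r, p = p,
       bonferroni_alpha = thr, passed = p < thr)
}

#' Save a predictive model as JSON
#'
#' Plain-text serialization: target, component count, training metadata,
#' atlas fingerprint, intercept and the full coefficient vector.
#'
#' @param model A `pls_model`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
save_model <- function(model, path) {
  stopifnot(inherits(model, "pls_model"))
  jsonlite::write_json(unclass(model), path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

#' Read a predictive model saved by [save_model()]
#' @param path Path to the JSON file.
#' @return A `pls_model`.
#' @export
read_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  obj$coefficients <- as.numeric(obj$coefficients)
  obj$x_center <- as.numeric(obj$x_center)
  structure(obj, class = "pls_model")
}
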