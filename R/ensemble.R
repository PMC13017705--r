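# Ensemble assembly: cross-validated AUC per learner, AUC-weighted model
# averaging with an inclusion cutoff, and max-TSS binarization threshold.

#' Area under the ROC curve (Mann-Whitney)
#'
#' The probability that a random presence scores above a random background
#' point, counting ties as 1/2: the mean over all presence x background
#' pairs of 1 (presence higher), 0.5 (tie), 0 (lower). Computed via the
#' rank-sum identity with average ranks, which is exactly that pair mean.
#'
#' @param scores_presence,scores_background non-empty numeric score vectors.
#' @return AUC in `[0, 1]`.
#' @export
auc <- function(scores_presence, scores_background) {
  np <- length(scores_presence); nb <- length(scores_background)
  if (!np || !nb) fc_stop("fc_undefined_auc", "empty score vector")
  r <- rank(c(scores_presence, scores_background), ties.method = "average")
  (sum(r[seq_len(np)]) - np * (np + 1) / 2) / (np * nb)
}

# Stratified fold assignment: shuffles indices and deals them round-robin.
fold_ids <- function(n, n_folds) rep_len(seq_len(n_folds), n)[sample.int(n)]

#' Cross-validated AUC of one learner kind
#'
#' Stratified k-fold over presence and background cells: the learner is
#' refit on each training split and scored on the held-out cells; returns
#' the mean held-out AUC. If there are fewer presences (or backgrounds)
#' than folds, the fold count is reduced with a warning.
#'
#' @param kind learner kind (see [fit_learner()]).
#' @param ds a `modeling_dataset`.
#' @param n_folds number of folds (>= 2); default 5.
#' @param seed integer seed for fold assignment.
#' @param ... passed to [fit_learner()].
#' @return mean held-out AUC.
#' @export
cross_validated_auc <- function(kind, ds, n_folds = 5, seed = 1, ...) {
  if (n_folds < 2) fc_stop("fc_invalid_parameter", "n_folds must be >= 2")
  np <- nrow(ds$X_presence); nb <- nrow(ds$X_background)
  if (min(np, nb) < n_folds) {
    fc_warn("fc_folds_reduced", "reducing folds from %d to %d", n_folds, min(np, nb))
    n_folds <- max(2L, min(np, nb))
  }
  fc_with_seed(seed, {
    fp <- fold_ids(np, n_folds)
    fb <- fold_ids(nb, n_folds)
    mean(vapply(seq_len(n_folds), function(f) {
      sub <- structure(list(
        species_id = ds$species_id,
        X_presence = ds$X_presence[fp != f, , drop = FALSE],
        X_background = ds$X_background[fb != f, , drop = FALSE],
        covariate_names = ds$covariate_names), class = "modeling_dataset")
      fit <- fit_learner(kind, sub, ...)
      auc(predict_suitability(fit, ds$X_presence[fp == f, , drop = FALSE]),
          predict_suitability(fit, ds$X_background[fb == f, , drop = FALSE]))
    }, 0))
  })
}

#' Combine learners into an AUC-weighted ensemble
#'
#' Learners with cross-validated AUC below `auc_cutoff` (or failed fits,
#' AUC `NA`) are excluded with weight 0. Included learners are weighted
#' proportionally to `max(AUC - 0.5, 0)`, so chance-level learners carry no
#' weight; weights sum to 1.
#'
#' @param learners named list of fitted learners (names = kinds).
#' @param aucs named numeric vector of cross-validated AUCs.
#' @param auc_cutoff inclusion threshold; default 0.7.
#' @param species_id optional id carried on the model.
#' @return object of class `ensemble_model` (without a binarization
#'   threshold yet; see [fit_species_ensemble()]).
#' @export
build_ensemble <- function(learners, aucs, auc_cutoff = 0.7,
                           species_id = NULL) {
  kinds <- names(aucs)
  included <- kinds[!is.na(aucs) & aucs >= auc_cutoff & kinds %in% names(learners)]
  if (!length(included))
    fc_stop("fc_unmodelable",
            "species %s: no learner reaches AUC cutoff %.2f",
            species_id %||% "?", auc_cutoff)
  raw <- pmax(aucs[included] - 0.5, 0)
  w <- if (sum(raw) > 0) raw / sum(raw) else rep(1 / length(raw), length(raw))
  weights <- stats::setNames(rep(0, length(kinds)), kinds)
  weights[included] <- w
  structure(list(species_id = species_id, learners = learners,
                 auc = aucs, weights = weights, included = included,
                 auc_cutoff = auc_cutoff, threshold_tss = NA_real_,
                 covariate_names = NULL, train_range = NULL),
            class = "ensemble_model")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Maximum-TSS binarization threshold
#'
#' Scans candidate thresholds (the unique observed scores plus midpoints
#' between consecutive unique scores) and returns the one maximizing
#' TSS = sensitivity + specificity - 1, with sensitivity = P(presence
#' score >= t) and specificity = P(background score < t). Ties are broken
#' toward the lower threshold.
#'
#' @param scores_presence,scores_background non-empty score vectors.
#' @return the selected threshold.
#' @export
max_tss_threshold <- function(scores_presence, scores_background) {
  if (!length(scores_presence) || !length(scores_background))
    fc_stop("fc_invalid_parameter", "empty score vector")
  u <- sort(unique(c(scores_presence, scores_background)))
  cand <- sort(unique(c(u, if (length(u) > 1L) (u[-1L] + u[-length(u)]) / 2)))
  tss <- vapply(cand, function(t)
    mean(scores_presence >= t) + mean(scores_background < t) - 1, 0)
  cand[which(tss >= max(tss) - 1e-12)[1L]]
}

#' Ensemble suitability prediction
#'
#' Weighted mean of the included learners' suitabilities. If the model
#' carries a training range, covariates are clamped to it first (see
#' [fit_species_ensemble()]).
#'
#' @param em an `ensemble_model`.
#' @param X covariate matrix with columns named as in training.
#' @param clamp clamp covariates to the training range (default TRUE when
#'   a range is stored).
#' @return suitability vector in `[0, 1]`.
#' @export
predict_ensemble <- function(em, X, clamp = TRUE) {
  if (!is.null(em$covariate_names)) {
    missing <- setdiff(em$covariate_names, colnames(X))
    if (length(missing))
      fc_stop("fc_projection_error", "missing covariate layer(s): %s",
              paste(missing, collapse = ", "))
    X <- X[, em$covariate_names, drop = FALSE]
  }
  if (clamp && !is.null(em$train_range)) {
    X <- pmin(pmax(X, rep(em$train_range$min, each = nrow(X))),
              rep(em$train_range$max, each = nrow(X)))
  }
  out <- rep(0, nrow(X))
  for (kind in em$included)
    out <- out + em$weights[[kind]] * predict_suitability(em$learners[[kind]], X)
  pmin(pmax(out, 0), 1)
}

#' Fit the full per-species ensemble
#'
#' Runs cross-validated AUC for each of the five learner kinds (failed fits
#' are recorded as `NA` and excluded), refits the passing learners on all
#' data, combines them with AUC-derived weights, and selects the max-TSS
#' binarization threshold from the ensemble's scores on the training
#' presences and backgrounds. The covariate training range (min/max over
#' presence + background cells) is stored for projection-time clamping.
#'
#' @param ds a `modeling_dataset`.
#' @param kinds learner kinds to include; default all five.
#' @param n_folds CV folds; default 5.
#' @param auc_cutoff inclusion threshold; default 0.7.
#' @param seed integer seed (folds; one stream per learner).
#' @return a complete `ensemble_model` with `threshold_tss` set.
#' @export
fit_species_ensemble <- function(ds, kinds = LEARNER_KINDS, n_folds = 5,
                                 auc_cutoff = 0.7, seed = 1) {
  aucs <- stats::setNames(rep(NA_real_, length(kinds)), kinds)
  learners <- stats::setNames(vector("list", length(kinds)), kinds)
  for (i in seq_along(kinds)) {
    kind <- kinds[i]
    res <- tryCatch({
      a <- cross_validated_auc(kind, ds, n_folds = n_folds, seed = seed + i)
      list(auc = a, fit = fit_learner(kind, ds))
    }, fc_fit_failure = function(e) NULL)
    if (!is.null(res)) { aucs[kind] <- res$auc; learners[[kind]] <- res$fit }
  }
  em <- build_ensemble(learners[!vapply(learners, is.null, TRUE)],
                       aucs, auc_cutoff, species_id = ds$species_id)
  em$covariate_names <- ds$covariate_names
  Xall <- rbind(ds$X_presence, ds$X_background)
  em$train_range <- list(min = apply(Xall, 2, min), max = apply(Xall, 2, max))
  em$threshold_tss <- max_tss_threshold(
    predict_ensemble(em, ds$X_presence, clamp = FALSE),
    predict_ensemble(em, ds$X_background, clamp = FALSE))
  em
}

#' @export
print.ensemble_model <- function(x, ...) {
  cat(sprintf("<ensemble_model> %s | included: %s | threshold_tss = %.3f\n",
              x$species_id %||% "?", paste(x$included, collapse = ", "),
              x$threshold_tss))
  print(round(rbind(auc = x$auc, weight = x$weights[names(x$auc)]), 3))
  invisible(x)
}
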