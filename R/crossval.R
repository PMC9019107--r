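# k-fold cross-validated classification accuracy of the facing models.

.make_folds <- function(data, folds, by_bird) {
  n <- nrow(data)
  if (by_bird) {
    birds <- unique(data$bird_id)
    fb <- sample(rep_len(seq_len(folds), length(birds)))
    fb[match(data$bird_id, birds)]
  } else {
    sample(rep_len(seq_len(folds), n))
  }
}

#' Cross-validated accuracy of a facing model
#'
#' Tenfold (by default) cross-validation: the data are randomly split into
#' folds, the model refitted on each 90% training set, and predictions on
#' the held-out 10% classified as facing when the fitted probability exceeds
#' the threshold. Accuracy is the mean and SD of the per-fold percentage of
#' correct predictions. Folds are observation-level by default (a bird's
#' fixes may appear in both sets, in which case its estimated random
#' intercept is used); `by_bird = TRUE` holds out whole birds instead. Birds
#' absent from a training set are predicted with a random intercept of 0.
#' A randomization in which some training fold lacks one of the two response
#' classes is re-drawn (at most `max_retries` times).
#'
#' @param data Annotated data frame appropriate for the model
#'   ([subset_gamm()] output for `model = "gamm"`, [subset_glmm()] for
#'   `"glmm"`).
#' @param model `"gamm"` or `"glmm"`.
#' @param config GLMM configuration (ignored for the GAMM).
#' @param folds Number of folds; default 10.
#' @param seed Random seed for the fold assignment (mandatory).
#' @param threshold Classification threshold on the probability scale;
#'   default 0.5.
#' @param by_bird Assign whole birds to folds; default `FALSE`.
#' @param k GAMM spline basis dimension.
#' @param max_retries Fold re-randomizations allowed; default 5.
#' @return List with `accuracy_mean` and `accuracy_sd` (percent),
#'   `per_fold`, `folds`, `retries`.
#' @export
cross_validate_accuracy <- function(data, model = c("gamm", "glmm"),
                                    config = "with_thermal",
                                    folds = 10, seed, threshold = 0.5,
                                    by_bird = FALSE, k = 10,
                                    max_retries = 5) {
  model <- match.arg(model)
  if (missing(seed)) stop("'seed' is mandatory", call. = FALSE)
  set.seed(seed)
  fold_id <- NULL
  retries <- 0
  repeat {
    cand <- .make_folds(data, folds, by_bird)
    ok <- all(vapply(seq_len(folds), function(f) {
      tr <- data$facing[cand != f]
      length(tr) > 0 && length(unique(tr)) == 2 && sum(cand == f) > 0
    }, logical(1)))
    if (ok) { fold_id <- cand; break }
    retries <- retries + 1
    if (retries > max_retries) {
      stop("could not build folds with both response classes in every ",
           "training set after ", max_retries, " retries", call. = FALSE)
    }
  }
  per_fold <- numeric(folds)
  for (f in seq_len(folds)) {
    train <- data[fold_id != f, , drop = FALSE]
    test <- data[fold_id == f, , drop = FALSE]
    p <- if (model == "gamm") {
      fit <- fit_facing_gamm(train, k = k, min_per_class = 1)
      .predict_gamm_prob(fit, test)
    } else {
      fit <- fit_facing_glmm(train, config = config)
      stats::predict(fit$model, newdata = test, type = "response",
                     allow.new.levels = TRUE)
    }
    per_fold[f] <- 100 * mean((p > threshold) == (test$facing == 1))
  }
  list(accuracy_mean = mean(per_fold),
       accuracy_sd = stats::sd(per_fold),
       per_fold = per_fold, folds = folds, retries = retries)
}

# probability predictions from a facing_gamm on new data; unseen birds get a
# random intercept of 0 (prediction with the bird term excluded)
.predict_gamm_prob <- function(fit, newdata) {
  nd <- newdata
  nd$height_class <- factor(as.character(nd$height_class),
                            levels = fit$classes)
  if (any(is.na(nd$height_class))) {
    stop("test data contain a height class absent from the training data",
         call. = FALSE)
  }
  if (!fit$has_re) {
    return(as.numeric(mgcv::predict.gam(fit$model, newdata = nd,
                                        type = "response")))
  }
  train_levels <- levels(fit$model$model$bird_id)
  seen <- nd$bird_id %in% train_levels
  p <- numeric(nrow(nd))
  if (any(seen)) {
    nds <- nd[seen, , drop = FALSE]
    nds$bird_id <- factor(as.character(nds$bird_id), levels = train_levels)
    p[seen] <- as.numeric(mgcv::predict.gam(fit$model, newdata = nds,
                                            type = "response"))
  }
  if (any(!seen)) {
    ndu <- nd[!seen, , drop = FALSE]
    ndu$bird_id <- factor(train_levels[1], levels = train_levels)
    p[!seen] <- as.numeric(mgcv::predict.gam(fit$model, newdata = ndu,
                                             type = "response",
                                             exclude = "s(bird_id)"))
  }
  p
}
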