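ENVELOPE_VARS <- c("bio1", "bio3", "bio12", "bio13")

#' Area under the ROC curve (Mann-Whitney form)
#'
#' Equals the probability that a randomly chosen presence outscores a randomly
#' chosen (pseudo)absence, with ties counted one half.
#'
#' @param scores numeric suitability scores.
#' @param labels logical or 0/1 vector; `TRUE`/1 = presence.
#' @return AUC in `[0, 1]`.
#' @export
compute_auc <- function(scores, labels) {
  labels <- as.logical(labels)
  stopifnot(length(scores) == length(labels))
  npos <- sum(labels); nneg <- sum(!labels)
  if (npos == 0 || nneg == 0) stop("AUC requires both classes")
  r <- rank(scores)
  (sum(r[labels]) - npos * (npos + 1) / 2) / (npos * nneg)
}

#' Threshold maximising sensitivity + specificity
#'
#' Evaluates sensitivity + specificity at every midpoint between adjacent
#' distinct sorted scores (presence predicted when `score >= cutoff`) and
#' returns the maximising cutoff, ties broken toward the smallest cutoff.
#'
#' @inheritParams compute_auc
#' @return the selected cutoff.
#' @export
select_threshold <- function(scores, labels) {
  labels <- as.logical(labels)
  npos <- sum(labels); nneg <- sum(!labels)
  if (npos == 0 || nneg == 0) stop("threshold selection requires both classes")
  s <- sort(unique(scores))
  if (length(s) == 1) return(s)
  cand <- (s[-1] + s[-length(s)]) / 2
  # integer objective TP * n_neg + TN * n_pos orders identically to
  # sensitivity + specificity but makes ties exact, so the smallest-cutoff
  # tie-break is deterministic
  j <- vapply(cand, function(ct) {
    pred <- scores >= ct
    sum(pred & labels) * nneg + sum(!pred & !labels) * npos
  }, numeric(1))
  cand[which.max(j)]
}

# ---- learners -------------------------------------------------------------
# Each learner is a list(kind, fit(data) -> model, score(model, newdata) ->
# numeric in [0, 1]). `data` has a logical/0-1 `label` column plus the four
# bioclim covariates.

#' Fit the rectilinear (percentile-depth) climatic envelope
#'
#' A presence-only envelope model: the suitability of a point is the minimum
#' over climate variables of the percentile tail depth `2 * min(F(v), 1 -
#' F(v))`, where `F` is the presence-sample empirical CDF evaluated with the
#' midpoint convention `F(v) = (#\{z < v\} + 0.5 #\{z = v\}) / n`. Scores lie
#' in `[0, 1]`; points outside the presence min-max on any variable score 0;
#' a variable constant across presences contributes 1 at its single value and
#' 0 elsewhere.
#'
#' @param presence_climate data frame of presence climate values with columns
#'   `bio1`, `bio3`, `bio12`, `bio13` (at least 2 rows).
#' @return object of class `rect_envelope` with a `predict`-style scorer via
#'   [score_rect_envelope()].
#' @export
fit_rectilinear_envelope <- function(presence_climate) {
  stopifnot(nrow(presence_climate) >= 2)
  samples <- lapply(ENVELOPE_VARS, function(v) sort(presence_climate[[v]]))
  names(samples) <- ENVELOPE_VARS
  structure(list(samples = samples), class = "rect_envelope")
}

#' Score cells with a rectilinear envelope
#' @param fit a `rect_envelope` from [fit_rectilinear_envelope()].
#' @param newdata data frame with the four bioclim columns.
#' @return numeric scores in `[0, 1]`.
#' @export
score_rect_envelope <- function(fit, newdata) {
  depth <- vapply(ENVELOPE_VARS, function(v) {
    z <- fit$samples[[v]]
    n <- length(z)
    x <- newdata[[v]]
    cnt_le <- findInterval(x, z)
    cnt_lt <- findInterval(x, z, left.open = TRUE)
    f <- (cnt_lt + 0.5 * (cnt_le - cnt_lt)) / n
    d <- 2 * pmin(f, 1 - f)
    d[x < z[1] | x > z[n]] <- 0
    d
  }, numeric(nrow(newdata)))
  if (nrow(newdata) == 1) depth <- matrix(depth, nrow = 1)
  apply(depth, 1, min)
}

learner_bioclim <- function() {
  list(
    kind = "rectilinear-envelope",
    fit = function(data) fit_rectilinear_envelope(data[as.logical(data$label), ,
                                                       drop = FALSE]),
    score = function(model, newdata) score_rect_envelope(model, newdata)
  )
}

learner_glm <- function() {
  list(
    kind = "linear-logistic",
    fit = function(data) {
      if (length(unique(data$label)) < 2) stop("GLM learner needs both classes")
      f <- stats::as.formula(paste("label ~", paste(ENVELOPE_VARS, collapse = " + ")))
      suppressWarnings(glm(f, family = binomial(), data = data))
    },
    score = function(model, newdata) {
      as.numeric(predict(model, newdata = newdata, type = "response"))
    }
  )
}

learner_rf <- function(ntree = 500, seed = 1L) {
  list(
    kind = "random-forest",
    fit = function(data) {
      if (length(unique(data$label)) < 2) stop("RF learner needs both classes")
      set.seed(seed)
      randomForest::randomForest(
        x = data[, ENVELOPE_VARS, drop = FALSE],
        y = factor(data$label, levels = c(0, 1)),
        ntree = ntree
      )
    },
    score = function(model, newdata) {
      as.numeric(predict(model, newdata = newdata[, ENVELOPE_VARS, drop = FALSE],
                         type = "prob")[, "1"])
    }
  )
}

#' The three envelope learners
#'
#' Returns the learner set used for the climatic-envelope ensemble: the
#' rectilinear presence-only envelope, a logistic GLM on the four bioclim
#' variables (linear terms, with intercept), and a seeded random forest with
#' 500 trees and default feature subsampling.
#'
#' @param rf_seed seed for the random-forest fit.
#' @param ntree number of random-forest trees.
#' @return named list of learners.
#' @export
envelope_learners <- function(rf_seed = 1L, ntree = 500) {
  list(bioclim = learner_bioclim(),
       glm = learner_glm(),
       rf = learner_rf(ntree = ntree, seed = rf_seed))
}

#' Stratified k-fold cross-validated mean AUC for a learner
#'
#' Folds are stratified by class and assigned with a seeded draw. A fold whose
#' test split lacks one class (or whose training split does) is skipped with a
#' warning; the mean is over valid folds. If no fold is valid an error is
#' raised (e.g. the leave-one-out degenerate case).
#'
#' @param learner a learner list (see [envelope_learners()]).
#' @param data data frame with `label` and the bioclim covariates.
#' @param k number of folds (default 5).
#' @param seed seed for fold assignment.
#' @return mean AUC over valid folds.
#' @export
kfold_auc <- function(learner, data, k = 5, seed = 1L) {
  n <- nrow(data)
  if (n < k) stop("need at least k observations")
  set.seed(seed)
  fold <- integer(n)
  if (k == n) {
    fold <- seq_len(n)  # leave-one-out: every fold is a single observation
  } else {
    for (cls in unique(data$label)) {
      idx <- which(data$label == cls)
      fold[idx] <- sample(rep_len(seq_len(k), length(idx)))
    }
  }
  aucs <- numeric(0)
  for (f in seq_len(k)) {
    train <- data[fold != f, , drop = FALSE]
    test <- data[fold == f, , drop = FALSE]
    if (length(unique(train$label)) < 2 || length(unique(test$label)) < 2) {
      warning(sprintf("fold %d skipped: single-class split", f))
      next
    }
    model <- learner$fit(train)
    aucs <- c(aucs, compute_auc(learner$score(model, test), test$label))
  }
  if (length(aucs) == 0) stop("no valid folds: every split was single-class")
  mean(aucs)
}

#' Fit the three-learner climatic envelope ensemble for one species
#'
#' Runs seeded 5-fold cross-validation for each learner to obtain a mean AUC,
#' refits each learner on the full data, and selects its
#' max(sensitivity + specificity) threshold from the full-data scores.
#' Learners with mean CV AUC below `auc_floor` are flagged failed; the species
#' is retained only if at least two learners pass.
#'
#' @param data data frame with `label` (1 = presence) and columns `bio1`,
#'   `bio3`, `bio12`, `bio13`.
#' @param species_id species label.
#' @param k CV folds (default 5).
#' @param auc_floor minimum mean CV AUC (default 0.6; strict `<` discards).
#' @param seed integer seed controlling folds and the random forest.
#' @return object of class `envelope_ensemble`: list with `species_id`,
#'   `fits` (per learner: `kind`, `model`, `mean_cv_auc`, `threshold`,
#'   `passed`), and `retained`.
#' @export
fit_climate_envelope <- function(data, species_id = "?", k = 5,
                                 auc_floor = 0.6, seed = 1L) {
  learners <- envelope_learners(rf_seed = stream_seed(seed, "rf"))
  fits <- lapply(names(learners), function(nm) {
    lrn <- learners[[nm]]
    cv_auc <- kfold_auc(lrn, data, k = k,
                        seed = stream_seed(seed, paste0("cv_", nm)))
    model <- lrn$fit(data)
    passed <- cv_auc >= auc_floor
    threshold <- if (passed) {
      select_threshold(lrn$score(model, data), data$label)
    } else NA_real_
    list(kind = lrn$kind, learner = nm, model = model, score_fun = lrn$score,
         mean_cv_auc = cv_auc, threshold = threshold, passed = passed)
  })
  names(fits) <- names(learners)
  structure(
    list(species_id = species_id, fits = fits,
         retained = sum(vapply(fits, `[[`, logical(1), "passed")) >= 2),
    class = "envelope_ensemble"
  )
}

#' Screen ensemble learners and species by cross-validated AUC
#'
#' Learners with mean CV AUC below `auc_floor` (strict `<`) are dropped; the
#' species is retained only if at least two learners remain.
#'
#' @param ensemble an `envelope_ensemble`.
#' @param auc_floor screening floor (default 0.6).
#' @return the ensemble with non-passing learners dropped from `fits`;
#'   `retained` is `FALSE` when fewer than two learners pass.
#' @export
screen_learners <- function(ensemble, auc_floor = 0.6) {
  keep <- vapply(ensemble$fits, function(f) f$mean_cv_auc >= auc_floor,
                 logical(1))
  ensemble$fits <- ensemble$fits[keep]
  ensemble$retained <- sum(keep) >= 2
  ensemble
}

#' Two-thirds consensus presence mask for a climate scenario
#'
#' Each passing learner votes presence where its score on the supplied climate
#' field reaches its threshold (closed lower bound). A cell enters the mask
#' when at least `ceiling(2/3 * m)` of the `m` passing learners vote presence
#' (3 learners: 2 votes; 2 learners: both). Future-scenario masks reuse the
#' fitted learners and thresholds unchanged, only the climate field differs.
#'
#' @param ensemble an `envelope_ensemble` with at least two passing learners.
#' @param climate a `climate_field` covering the prediction grid, ordered by
#'   cell id.
#' @param rule `"two-thirds"` (default) or `"majority"` (`> m/2`).
#' @return logical vector over the field's cells, with attributes
#'   `species_id` and `scenario`; class `consensus_mask`.
#' @export
consensus_mask <- function(ensemble, climate, rule = c("two-thirds", "majority")) {
  rule <- match.arg(rule)
  fits <- Filter(function(f) f$passed, ensemble$fits)
  m <- length(fits)
  if (m < 2) stop("consensus requires at least two passing learners")
  votes <- rowSums(vapply(fits, function(f) {
    f$score_fun(f$model, climate) >= f$threshold
  }, logical(nrow(climate))))
  need <- if (rule == "two-thirds") ceiling(2 / 3 * m) else floor(m / 2) + 1
  structure(votes >= need, species_id = ensemble$species_id,
            scenario = climate$scenario[1], class = "consensus_mask")
}

#' Per-learner summary table for an envelope ensemble
#' @param ensemble an `envelope_ensemble` (possibly screened).
#' @return data frame `species_id`, `learner`, `kind`, `mean_cv_auc`,
#'   `threshold`, `passed`.
#' @export
envelope_summary <- function(ensemble) {
  data.frame(
    species_id = ensemble$species_id,
    learner = vapply(ensemble$fits, `[[`, character(1), "learner"),
    kind = vapply(ensemble$fits, `[[`, character(1), "kind"),
    mean_cv_auc = vapply(ensemble$fits, `[[`, numeric(1), "mean_cv_auc"),
    threshold = vapply(ensemble$fits, `[[`, numeric(1), "threshold"),
    passed = vapply(ensemble$fits, `[[`, logical(1), "passed"),
    row.names = NULL
  )
}
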