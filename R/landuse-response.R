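#' Principal components of the land-cover composition
#'
#' Centred (unscaled) PCA of the per-cell cover proportions. A fixed number of
#' leading components (default 7) is retained for the pooled evaluation model;
#' the cumulative explained variance is reported so the retention choice can
#' be checked against the data.
#'
#' @param grid a [landscape_grid()].
#' @param n_retained number of components to keep (default 7).
#' @return object of class `landcover_pca`: list with `loadings`
#'   (columns = components), `explained` (variance fractions, non-increasing),
#'   `cumulative`, `n_retained`, `center`.
#' @export
pca_landcover <- function(grid, n_retained = 7) {
  X <- cover_matrix(grid)
  if (nrow(X) < 2) stop("PCA requires at least 2 cells")
  if (all(abs(sweep(X, 2, colMeans(X))) < 1e-12)) {
    stop("land-cover matrix is constant; PCA undefined")
  }
  pc <- prcomp(X, center = TRUE, scale. = FALSE)
  ev <- pc$sdev^2
  n_retained <- min(n_retained, ncol(pc$rotation))
  structure(
    list(loadings = pc$rotation, explained = ev / sum(ev),
         cumulative = cumsum(ev) / sum(ev),
         n_retained = n_retained, center = pc$center),
    class = "landcover_pca"
  )
}

#' Project cover proportions onto retained principal components
#' @param pca a `landcover_pca`.
#' @param grid a [landscape_grid()] (or matrix of proportions).
#' @return matrix of scores, `n_cells` x `n_retained`, columns `PC1..PCk`.
#' @export
pca_scores <- function(pca, grid) {
  X <- if (inherits(grid, "landscape_grid")) cover_matrix(grid) else as.matrix(grid)
  S <- sweep(X, 2, pca$center) %*% pca$loadings[, seq_len(pca$n_retained), drop = FALSE]
  colnames(S) <- paste0("PC", seq_len(pca$n_retained))
  S
}

#' Pooled mixed-effects evaluation model with per-species AUC screening
#'
#' Fits, per cross-validation fold, a binomial mixed-effects model of
#' presence/pseudoabsence on the retained land-cover PCs with global fixed
#' effects and species-level random intercept and slopes (diagonal covariance;
#' simplified to a random intercept if the fit fails to converge). Each
#' datapoint is held out exactly once; held-out predictions give a per-species
#' AUC and max(sensitivity + specificity) threshold, averaged over folds.
#' Species whose mean AUC falls below `auc_floor` are flagged eliminated.
#'
#' @param pooled data frame with columns `species_id`, `label` (0/1) and
#'   `PC1..PCk`.
#' @param k folds (default 5).
#' @param seed seed for fold assignment.
#' @param auc_floor screening floor on mean AUC (default 0.6).
#' @return data frame `species_id`, `eval_auc`, `threshold`, `retained`.
#' @export
fit_eval_mixed_model <- function(pooled, k = 5, seed = 1L, auc_floor = 0.6) {
  pcs <- grep("^PC[0-9]+$", names(pooled), value = TRUE)
  if (length(pcs) == 0) stop("pooled data must contain PC columns")
  ids <- sort(unique(pooled$species_id))
  set.seed(seed)
  fold <- integer(nrow(pooled))
  for (s in ids) {
    for (cls in 0:1) {
      idx <- which(pooled$species_id == s & pooled$label == cls)
      if (length(idx)) fold[idx] <- sample(rep_len(seq_len(k), length(idx)))
    }
  }
  fixed <- paste(pcs, collapse = " + ")
  form_full <- stats::as.formula(
    sprintf("label ~ %s + (1 + %s || species_id)", fixed, fixed))
  form_simple <- stats::as.formula(
    sprintf("label ~ %s + (1 | species_id)", fixed))
  ctl <- lme4::glmerControl(optimizer = "bobyqa", calc.derivs = FALSE,
                            check.conv.singular = "ignore")
  fit_one <- function(train) {
    m <- tryCatch(
      suppressMessages(suppressWarnings(
        lme4::glmer(form_full, data = train, family = binomial(),
                    nAGQ = 0, control = ctl))),
      error = function(e) NULL)
    if (is.null(m)) {
      m <- suppressMessages(suppressWarnings(
        lme4::glmer(form_simple, data = train, family = binomial(),
                    nAGQ = 0, control = ctl)))
    }
    m
  }
  auc_mat <- matrix(NA_real_, length(ids), k, dimnames = list(ids, NULL))
  thr_mat <- auc_mat
  for (f in seq_len(k)) {
    train <- pooled[fold != f, , drop = FALSE]
    test <- pooled[fold == f, , drop = FALSE]
    m <- fit_one(train)
    p <- as.numeric(predict(m, newdata = test, type = "response",
                            allow.new.levels = TRUE))
    for (s in ids) {
      sel <- test$species_id == s
      if (length(unique(test$label[sel])) == 2) {
        auc_mat[s, f] <- compute_auc(p[sel], test$label[sel])
        thr_mat[s, f] <- select_threshold(p[sel], test$label[sel])
      }
    }
  }
  eval_auc <- rowMeans(auc_mat, na.rm = TRUE)
  data.frame(species_id = ids,
             eval_auc = eval_auc,
             threshold = rowMeans(thr_mat, na.rm = TRUE),
             retained = !is.na(eval_auc) & eval_auc >= auc_floor,
             row.names = NULL)
}

#' Elicited prior for the land-use coefficients
#'
#' The prior is a product of independent zero-mean normals, one per land-cover
#' class, on the log-odds scale per percentage point of cover. The elicited
#' standard deviation is 1 (default) or 1/6.
#'
#' @param sd prior standard deviation (default 1).
#' @param dimension number of coefficients (default 24).
#' @return object of class `prior_spec`.
#' @export
prior_spec <- function(sd = 1, dimension = 24) {
  stopifnot(sd > 0, dimension >= 1)
  structure(list(mean = 0, sd = sd, dimension = as.integer(dimension)),
            class = "prior_spec")
}

#' Prior probability mass in an interval (per coefficient)
#' @param prior a [prior_spec()].
#' @param lower,upper interval bounds on the log-odds scale.
#' @return probability that a single coefficient lies in `[lower, upper]`.
#' @export
prior_mass <- function(prior, lower = -1, upper = 1) {
  pnorm(upper, 0, prior$sd) - pnorm(lower, 0, prior$sd)
}

#' Bayesian no-intercept logistic land-use model (MAP + Laplace)
#'
#' Models presence/pseudoabsence as a logistic function of the 24 land-cover
#' percentages with no constant term. The posterior over coefficients is
#' approximated as Gaussian: the mean is the MAP of log-likelihood + log
#' prior (found by damped Newton iteration; the prior guarantees a finite
#' optimum even for separable data) and the covariance is the inverse
#' negative Hessian at the MAP. With zero observations the posterior equals
#' the prior.
#'
#' @param y 0/1 response vector.
#' @param x_pct matrix of land-cover covariates in percentage points (0-100),
#'   one row per observation.
#' @param prior a [prior_spec()] (default unit sd).
#' @param species_id species label carried in the result.
#' @param max_iter,tol Newton iteration controls.
#' @return object of class `landuse_model`: list with `species_id`,
#'   `beta_mean`, `beta_cov`, `prior`, `converged`, and slots `eval_auc`,
#'   `threshold` (NA until filled by the evaluation screen).
#' @export
fit_bayes_landuse <- function(y, x_pct, prior = prior_spec(),
                              species_id = "?", max_iter = 100, tol = 1e-10) {
  X <- as.matrix(x_pct)
  p <- ncol(X)
  prior_prec <- 1 / prior$sd^2
  if (length(y) == 0) {
    return(structure(
      list(species_id = species_id, beta_mean = rep(0, p),
           beta_cov = diag(prior$sd^2, p), prior = prior, converged = TRUE,
           eval_auc = NA_real_, threshold = NA_real_),
      class = "landuse_model"))
  }
  stopifnot(length(y) == nrow(X), all(y %in% c(0, 1)))
  neg_log_post <- function(b) {
    eta <- drop(X %*% b)
    # -sum(y*eta - log(1+exp(eta))) + penalty, computed stably
    sum(log1p(exp(-abs(eta))) + pmax(eta, 0) - y * eta) +
      0.5 * prior_prec * sum(b^2)
  }
  beta <- rep(0, p)
  f_old <- neg_log_post(beta)
  converged <- FALSE
  H <- diag(prior_prec, p)
  for (it in seq_len(max_iter)) {
    eta <- drop(X %*% beta)
    mu <- plogis(eta)
    g <- drop(crossprod(X, mu - y)) + prior_prec * beta
    w <- mu * (1 - mu)
    H <- crossprod(X * w, X) + diag(prior_prec, p)
    step <- solve(H, g)
    # damped Newton: halve until the objective does not increase
    lambda <- 1
    repeat {
      beta_new <- beta - lambda * step
      f_new <- neg_log_post(beta_new)
      if (f_new <= f_old + 1e-12 || lambda < 1e-8) break
      lambda <- lambda / 2
    }
    moved <- max(abs(beta_new - beta))
    beta <- beta_new
    f_old <- f_new
    if (moved < tol) { converged <- TRUE; break }
  }
  # Hessian and gradient at the final point
  eta <- drop(X %*% beta)
  mu <- plogis(eta)
  g <- drop(crossprod(X, mu - y)) + prior_prec * beta
  converged <- converged || max(abs(g)) <= 1e-6
  if (!converged) {
    warning(sprintf("species '%s': MAP Newton iteration did not fully converge",
                    species_id))
  }
  w <- mu * (1 - mu)
  H <- crossprod(X * w, X) + diag(prior_prec, p)
  cov <- chol2inv(chol(H))
  structure(
    list(species_id = species_id, beta_mean = beta,
         beta_cov = (cov + t(cov)) / 2, prior = prior, converged = converged,
         eval_auc = NA_real_, threshold = NA_real_),
    class = "landuse_model"
  )
}

#' Predict occurrence probability masked by the climatic envelope
#'
#' Evaluates `plogis(beta_mean . cover_percent)` inside the consensus mask
#' and sets every cell outside it to exactly zero. Switching to a future-
#' climate mask re-zeros accordingly with unchanged coefficients.
#'
#' @param model a `landuse_model`.
#' @param grid a [landscape_grid()].
#' @param mask logical vector over grid cells (e.g. a [consensus_mask()]).
#' @return numeric vector of per-cell probabilities (class
#'   `probability_surface`, attributes `species_id`, `scenario`).
#' @export
predict_masked_probability <- function(model, grid, mask) {
  stopifnot(length(mask) == nrow(grid))
  p <- plogis(as.vector(cover_percent(grid) %*% model$beta_mean))
  p[!mask] <- 0
  structure(p, species_id = model$species_id,
            scenario = attr(mask, "scenario") %||% NA_character_,
            class = "probability_surface")
}
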