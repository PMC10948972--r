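test_that("AUC matches its defining examples", {
  expect_equal(compute_auc(c(0.9, 0.8, 0.2, 0.1), c(1, 1, 0, 0)), 1.0)
  expect_equal(compute_auc(rep(0.5, 6), c(1, 1, 1, 0, 0, 0)), 0.5)
  expect_error(compute_auc(1:3, c(1, 1, 1)), "both classes")
})

test_that("AUC equals pairwise enumeration on random small sets with ties", {
  set.seed(31)
  for (r in 1:200) {
    n <- sample(2:12, 1)
    labels <- c(0, 1, rbinom(n - 2, 1, 0.5))  # guarantee both classes
    scores <- round(runif(n), sample(0:2, 1)) # induce ties
    expect_equal(compute_auc(scores, labels),
                 auc_pairwise_oracle(scores, labels))
  }
})

test_that("threshold selection matches exhaustive search", {
  # perfectly separated: smallest midpoint within the gap
  expect_equal(select_threshold(c(0.9, 0.8, 0.2, 0.1), c(1, 1, 0, 0)), 0.5)
  set.seed(32)
  for (r in 1:100) {
    n <- sample(4:12, 1)
    labels <- c(0, 1, rbinom(n - 2, 1, 0.5))
    scores <- round(runif(n), 2)
    expect_equal(select_threshold(scores, labels),
                 threshold_exhaustive_oracle(scores, labels))
  }
})

test_that("rectilinear envelope scores centre 1, outside 0", {
  set.seed(33)
  pres <- data.frame(bio1 = sort(rnorm(9, 10)), bio3 = sort(runif(9, 30, 40)),
                     bio12 = sort(runif(9, 600, 900)),
                     bio13 = sort(runif(9, 150, 280)))
  fit <- fit_rectilinear_envelope(pres)
  centre <- as.data.frame(lapply(pres, median))
  expect_equal(score_rect_envelope(fit, centre), 1)
  beyond <- centre; beyond$bio1 <- max(pres$bio1) + 1
  expect_equal(score_rect_envelope(fit, beyond), 0)
})

test_that("rectilinear envelope equals a hand-computed percentile-depth oracle", {
  set.seed(34)
  pres <- data.frame(bio1 = rnorm(10, 10), bio3 = runif(10, 30, 40),
                     bio12 = runif(10, 600, 900), bio13 = runif(10, 150, 280))
  fit <- fit_rectilinear_envelope(pres)
  q <- data.frame(bio1 = 10.2, bio3 = 34, bio12 = 810, bio13 = 200)
  # oracle: direct empirical-CDF computation per variable
  depths <- vapply(names(q), function(v) {
    z <- pres[[v]]; x <- q[[v]]
    if (x < min(z) || x > max(z)) return(0)
    f <- (sum(z < x) + 0.5 * sum(z == x)) / length(z)
    2 * min(f, 1 - f)
  }, numeric(1))
  expect_equal(score_rect_envelope(fit, q), min(depths))
})

test_that("a constant presence variable scores 1 at its value, 0 elsewhere", {
  pres <- data.frame(bio1 = rep(10, 5), bio3 = 1:5, bio12 = 700 + 1:5,
                     bio13 = 200 + 1:5)
  fit <- fit_rectilinear_envelope(pres)
  at <- data.frame(bio1 = 10, bio3 = 3, bio12 = 703, bio13 = 203)
  expect_gt(score_rect_envelope(fit, at), 0)
  off <- at; off$bio1 <- 10.01
  expect_equal(score_rect_envelope(fit, off), 0)
})

separable_data <- function(n = 40, seed = 35) {
  set.seed(seed)
  data.frame(
    label = rep(c(1, 0), each = n / 2),
    bio1 = c(rnorm(n / 2, 14, 0.5), rnorm(n / 2, 6, 0.5)),
    bio3 = runif(n, 30, 40),
    bio12 = runif(n, 600, 900),
    bio13 = runif(n, 150, 280)
  )
}

test_that("GLM learner matches an independently coded IRLS fit", {
  set.seed(36)
  d <- data.frame(bio1 = rnorm(20, 10, 2), bio3 = runif(20, 30, 40),
                  bio12 = runif(20, 600, 900), bio13 = runif(20, 150, 280))
  d$label <- rbinom(20, 1, plogis(0.8 * (d$bio1 - 10)))
  if (length(unique(d$label)) < 2) d$label[1:2] <- c(0, 1)
  fit <- envelope_learners()$glm$fit(d)
  # oracle: iteratively reweighted least squares coded from scratch
  X <- cbind(1, as.matrix(d[, c("bio1", "bio3", "bio12", "bio13")]))
  y <- d$label
  b <- rep(0, 5)
  for (i in 1:60) {
    eta <- drop(X %*% b)
    mu <- 1 / (1 + exp(-eta))
    W <- mu * (1 - mu)
    z <- eta + (y - mu) / W
    b <- solve(crossprod(X * W, X), crossprod(X * W, z))
  }
  expect_equal(unname(coef(fit)), unname(drop(b)), tolerance = 1e-6)
})

test_that("learners separate separable data and not shuffled labels", {
  d <- separable_data(60)
  lr <- envelope_learners(rf_seed = 99)
  expect_gt(kfold_auc(lr$glm, d, seed = 1), 0.95)
  expect_gt(kfold_auc(lr$rf, d, seed = 1), 0.95)
  set.seed(37)
  d$label <- sample(d$label)
  expect_lt(abs(kfold_auc(lr$glm, d, seed = 1) - 0.5), 0.2)
})

test_that("cross-validation handles perfect, constant and degenerate scorers", {
  d <- separable_data(30)
  perfect <- list(kind = "perfect", fit = function(data) NULL,
                  score = function(model, nd) nd$bio1)
  expect_equal(kfold_auc(perfect, d, seed = 2), 1.0)
  constant <- list(kind = "const", fit = function(data) NULL,
                   score = function(model, nd) rep(0.5, nrow(nd)))
  expect_equal(kfold_auc(constant, d, seed = 2), 0.5)
  expect_error(suppressWarnings(kfold_auc(perfect, d, k = 30, seed = 2)),
               "no valid folds")
})

fake_ensemble <- function(aucs, scores_list = NULL, thresholds = NULL) {
  fits <- lapply(seq_along(aucs), function(i) {
    list(kind = "fake", learner = paste0("L", i), model = i,
         score_fun = if (!is.null(scores_list)) {
           local({ s <- scores_list[[i]]; function(model, nd) s })
         } else function(model, nd) rep(0, nrow(nd)),
         mean_cv_auc = aucs[i],
         threshold = if (!is.null(thresholds)) thresholds[i] else 0.5,
         passed = aucs[i] >= 0.6)
  })
  names(fits) <- paste0("L", seq_along(aucs))
  structure(list(species_id = "spX", fits = fits, retained = TRUE),
            class = "envelope_ensemble")
}

test_that("learner screening drops AUC < 0.6 and needs two passing learners", {
  e1 <- screen_learners(fake_ensemble(c(0.9, 0.59, 0.61)))
  expect_length(e1$fits, 2)
  expect_true(e1$retained)
  e2 <- screen_learners(fake_ensemble(c(0.59, 0.58, 0.95)))
  expect_length(e2$fits, 1)
  expect_false(e2$retained)
  e3 <- screen_learners(fake_ensemble(c(0.6, 0.6, 0.1)))
  expect_true(e3$retained)  # exactly 0.6 passes: discard rule is strict <
})

test_that("consensus applies the two-thirds ceiling rule", {
  grid <- gen_landscape(synthetic_config(n_rows = 1, n_cols = 3, seed = 1))
  cl <- flat_climate(grid)
  # three learners, per-cell votes (1,1,0) / (1,0,0) / (1,1,1)
  s <- list(c(1, 1, 1), c(1, 0, 1), c(0, 0, 1))
  m <- consensus_mask(fake_ensemble(c(0.9, 0.9, 0.9), s), cl)
  expect_equal(as.logical(m), c(TRUE, FALSE, TRUE))
  # two learners: both votes required
  m2 <- consensus_mask(fake_ensemble(c(0.9, 0.9), s[1:2]), cl)
  expect_equal(as.logical(m2), c(TRUE, FALSE, TRUE))
  s3 <- list(c(1, 1, 1), c(0, 0, 1))
  m3 <- consensus_mask(fake_ensemble(c(0.9, 0.9), s3), cl)
  expect_equal(as.logical(m3), c(FALSE, FALSE, TRUE))
})

test_that("raising any learner threshold never adds cells to the mask", {
  set.seed(38)
  grid <- gen_landscape(synthetic_config(n_rows = 5, n_cols = 5, seed = 2))
  cl <- flat_climate(grid)
  scores <- replicate(3, runif(25), simplify = FALSE)
  for (r in 1:20) {
    th1 <- runif(3); th2 <- th1 + runif(3, 0, 0.3)
    m1 <- consensus_mask(fake_ensemble(rep(0.9, 3), scores, th1), cl)
    m2 <- consensus_mask(fake_ensemble(rep(0.9, 3), scores, th2), cl)
    expect_true(all(m1 | !m2))  # m2 subset of m1
  }
})

test_that("fitted ensembles vote with unchanged thresholds on new climates", {
  d <- separable_data(120, seed = 39)
  ens <- screen_learners(fit_climate_envelope(d, species_id = "spY", seed = 4))
  expect_gte(length(ens$fits), 2)
  # a "future" field the learners never saw during fitting
  field <- climate_field(1:25, "future", seq(0, 20, length.out = 25),
                         rep(35, 25), rep(750, 25), rep(220, 25))
  m <- consensus_mask(ens, field)
  # oracle: apply each stored threshold by hand and count votes
  votes <- rowSums(vapply(ens$fits, function(f)
    f$score_fun(f$model, field) >= f$threshold, logical(25)))
  expect_equal(as.logical(m), votes >= ceiling(2 / 3 * length(ens$fits)))
  # rescoring is deterministic
  expect_equal(as.logical(consensus_mask(ens, field)), as.logical(m))
})
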