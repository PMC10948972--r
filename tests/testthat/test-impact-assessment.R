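test_that("expected area sums probabilities over modifiable cells only", {
  grid <- grid_from_cover(random_cover(10, seed = 61), 2, 5,
                          modifiable = rep(c(TRUE, FALSE), 5))
  expect_equal(expected_area(rep(0, 10), grid), 0)
  expect_equal(expected_area(rep(0.5, 10), grid), 2.5)
  set.seed(62)
  p <- runif(10)
  # oracle: independent summation
  expect_equal(expected_area(p, grid), sum(p[c(1, 3, 5, 7, 9)]),
               tolerance = 1e-9)
})

test_that("linearised variance matches the scalar delta-method formula", {
  cover <- matrix(0, 1, 24)
  cover[1, 1] <- 0.3; cover[1, 2] <- 0.7
  grid <- grid_from_cover(cover, 1, 1)
  beta <- c(0.05, rep(0, 23))
  sigma2 <- 0.01^2
  cv <- matrix(0, 24, 24); cv[1, 1] <- sigma2
  m <- make_model(beta, cv)
  v <- area_variance_linearised(m, grid, TRUE)
  p <- plogis(0.05 * 30)
  expect_equal(v, (p * (1 - p) * 30)^2 * sigma2)
  expect_equal(area_variance_linearised(make_model(beta), grid, TRUE), 0)
  bad <- make_model(beta, matrix(-1, 24, 24))
  expect_error(area_variance_linearised(bad, grid, TRUE), "semidefinite")
})

test_that("an identical scenario produces no gains or losses", {
  grid <- grid_from_cover(random_cover(20, seed = 63), 4, 5)
  set.seed(64)
  m <- make_model(rnorm(24, 0, 0.1), diag(1e-4, 24))
  out <- prob_relative_change(m, grid, rep(TRUE, 20), grid, rep(TRUE, 20),
                              n_draws = 500, seed = 5)
  expect_equal(out$p_gain, 0)
  expect_equal(out$p_loss, 0)
})

test_that("a degenerate posterior with a 1.2x scenario is a certain gain", {
  # two grids whose class-1 percentages differ; beta fixed (zero covariance)
  c1 <- matrix(rep(c(0.5, 0.5, rep(0, 22)), 4), 4, 24, byrow = TRUE)
  c2 <- matrix(rep(c(0.8, 0.2, rep(0, 22)), 4), 4, 24, byrow = TRUE)
  g1 <- grid_from_cover(c1, 2, 2); g2 <- grid_from_cover(c2, 2, 2)
  beta <- c(0.05, -0.05, rep(0, 22))
  a1 <- 4 * plogis(sum(beta * c1[1, ] * 100))
  a2 <- 4 * plogis(sum(beta * c2[1, ] * 100))
  expect_gt(a2, 1.2 * a1)
  out <- prob_relative_change(make_model(beta), g1, rep(TRUE, 4),
                              g2, rep(TRUE, 4), n_draws = 200, seed = 6)
  expect_equal(out$p_gain, 1)
  expect_equal(out$p_loss, 0)
})

test_that("gain probability matches an analytic 1-D posterior oracle", {
  # one free coefficient: the gain event is a half-line in beta_1
  c_base <- matrix(rep(c(0.2, 0.8, rep(0, 22)), 2), 2, 24, byrow = TRUE)
  c_scen <- matrix(rep(c(0.6, 0.4, rep(0, 22)), 2), 2, 24, byrow = TRUE)
  gb <- grid_from_cover(c_base, 1, 2); gs <- grid_from_cover(c_scen, 1, 2)
  mu <- 0.01; s <- 0.02
  cv <- matrix(0, 24, 24); cv[1, 1] <- s^2
  m <- make_model(c(mu, rep(0, 23)), cv)
  out <- prob_relative_change(m, gb, rep(TRUE, 2), gs, rep(TRUE, 2),
                              change_level = 0.10, n_draws = 200000, seed = 7)
  # oracle: the gain event {area_scen >= 1.1 area_base} is the set where
  # h(b) >= 0; h crosses zero twice (saturation caps the ratio at high b),
  # so the event is an interval and its probability is a normal-CDF
  # difference
  h <- function(b) 2 * plogis(60 * b) - 1.1 * 2 * plogis(20 * b)
  r1 <- uniroot(h, c(-0.2, 0.05), tol = 1e-12)$root
  r2 <- uniroot(h, c(0.05, 0.5), tol = 1e-12)$root
  expect_lt(h(r1 - 0.005), 0); expect_gt(h(r1 + 0.005), 0)
  expect_gt(h(r2 - 0.005), 0); expect_lt(h(r2 + 0.005), 0)
  p_exact <- pnorm(r2, mu, s) - pnorm(r1, mu, s)
  expect_lt(abs(out$p_gain - p_exact), 0.005)
})

test_that("count distributions match exact Poisson-binomial enumeration", {
  probs <- c(0.95, 0.9, 0.8, 0.6, 0.4, 0.2, 0.1)
  set.seed(65)
  ind <- sapply(probs, function(p) rbinom(200000, 1, p))
  d <- species_count_distribution(ind)
  oracle <- pb_interval_oracle(probs)
  expect_equal(c(d$lower, d$upper), oracle)
  expect_equal(d$mean, sum(probs), tolerance = 0.01)
  # degenerate cases
  all1 <- species_count_distribution(matrix(1, 100, 5))
  expect_equal(c(all1$mean, all1$lower, all1$upper), c(5, 5, 5))
  all0 <- species_count_distribution(matrix(0, 100, 5))
  expect_equal(c(all0$mean, all0$lower, all0$upper), c(0, 0, 0))
})

test_that("no posterior draw is both a gain and a loss", {
  set.seed(66)
  a_base <- c(0, 0, runif(200, 0, 10))
  a_scen <- c(0, 3, runif(200, 0, 10))
  cls <- landshift:::classify_change(a_base, a_scen, 0.10)
  expect_false(any(cls$gain & cls$loss))
  # zero-baseline convention: gain iff scenario area positive, never a loss
  expect_false(cls$gain[1]); expect_true(cls$gain[2])
  expect_false(cls$loss[1]); expect_false(cls$loss[2])
})

test_that("count intervals widen weakly as posterior covariance scales up", {
  grid <- grid_from_cover(random_cover(30, seed = 67), 5, 6)
  g2 <- allocate_local(grid, make_scenario("t", 0.05, 0.15))
  set.seed(68)
  beta <- rnorm(24, 0, 0.05)
  base_cov <- diag(2e-4, 24)
  masks <- list(spA = rep(TRUE, 30))
  width <- sapply(c(1, 4), function(k) {
    m <- make_model(beta, base_cov * k, id = "spA")
    imp <- assess_impacts(list(m), grid, g2, masks, masks,
                          n_draws = 4000, seed = 9)
    s <- imp$summary
    s$avg_habitable_upper - s$avg_habitable_lower
  })
  expect_gte(width[2], width[1])
})

test_that("zero-uncertainty species average exactly as stated", {
  # two species at p = 0.5 over 40% / 80% of the modifiable area
  grid <- grid_from_cover(random_cover(20, seed = 69), 4, 5)
  mask_a <- rep(c(TRUE, FALSE, FALSE, FALSE, FALSE), 4)  # p=0.5 on 4 cells
  mask_b <- rep(c(TRUE, TRUE, FALSE, FALSE, FALSE), 4)   # p=0.5 on 8 cells
  models <- list(make_model(rep(0, 24), id = "a"), make_model(rep(0, 24), id = "b"))
  masks <- list(a = mask_a, b = mask_b)
  imp <- assess_impacts(models, grid, grid, masks, masks,
                        n_draws = 200, seed = 10)
  # fractions 0.5*4/20 = 0.1 and 0.5*8/20 = 0.2 -> average 0.15
  expect_equal(imp$summary$avg_habitable_fraction, 0.15)
  expect_equal(imp$summary$avg_habitable_lower, 0.15)
  expect_equal(imp$summary$avg_habitable_upper, 0.15)
  expect_equal(imp$summary$n_gain10, 0)
  expect_equal(imp$summary$n_loss10, 0)
  expect_equal(imp$species$sd_area, c(0, 0))
})

test_that("probability surfaces never escape their masks through assessment", {
  cfg <- synthetic_config(n_rows = 10, n_cols = 10, n_species = 3, seed = 70)
  sim <- simulate_study(cfg)
  ids <- vapply(sim$species, `[[`, character(1), "species_id")
  for (sp in sim$species) {
    mask <- true_suitable(sp, sim$climate$baseline)
    surf <- predict_masked_probability(
      make_model(sp$true_beta, id = sp$species_id), sim$grid, mask)
    expect_true(all(surf[!mask] == 0))
    expect_true(all(surf >= 0 & surf <= 1))
  }
})
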