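test_that("pairwise posteriors follow the two-model logistic form", {
  expect_equal(pairwise_posterior(5, 5), 0.5)
  expect_equal(pairwise_posterior(-3, 0), 1 / (1 + exp(3)))
  expect_equal(pairwise_posterior(-3, 0) + pairwise_posterior(0, -3), 1)
  Fs <- seq(-10, 10, by = 0.5)
  expect_true(all(diff(pairwise_posterior(Fs, 0)) > 0))
  expect_equal(pairwise_posterior(-1000, 0), 0)
  expect_equal(pairwise_posterior(1000, 0), 1)
})

test_that("the HDH is the highest sub-threshold order", {
  p <- c(0.001, 0.01, 0.04, 0.3, 0.5)
  expect_equal(compute_hdh(p, L = 1:5), list(hdh = 3L, indistinguishable = FALSE))
  expect_equal(compute_hdh(rep(0.2, 5), L = 1:5),
               list(hdh = 0L, indistinguishable = TRUE))
  expect_equal(compute_hdh(rep(0.01, 5), L = 1:5)$hdh, 5L)
  # non-monotone curves: highest crossing wins even across a gap
  p2 <- c(0.01, 0.3, 0.01, 0.3, 0.3)
  expect_equal(compute_hdh(p2, L = 1:5)$hdh, 3L)
  # named input carries the orders
  expect_equal(compute_hdh(c(`2` = 0.01, `4` = 0.2))$hdh, 2L)
})

test_that("fixed-effects posteriors are a shift-invariant softmax", {
  expect_equal(fixed_effects_posterior(c(1, 1, 1)), rep(1 / 3, 3))
  set.seed(1)
  F <- rnorm(7, sd = 3)
  p <- fixed_effects_posterior(F)
  expect_equal(sum(p), 1, tolerance = 1e-12)
  expect_equal(fixed_effects_posterior(F + 123.4), p, tolerance = 1e-12)
  expect_error(fixed_effects_posterior(numeric(0)), "empty")
})

test_that("evidence pools by summation and the pooled posterior matches summed differences", {
  F1 <- c(a = -3, b = 0, c = 2)
  expect_equal(pool_evidence(rbind(F1)), F1)
  expect_equal(pool_evidence(rbind(F1, F1)), 2 * F1)
  expect_error(pool_evidence(list(c(1, 2), c(1, 2, 3))), "ragged")

  set.seed(2)
  runs <- matrix(rnorm(5 * 3), 5, 3)
  pooled <- pool_evidence(runs)
  expect_equal(
    pairwise_posterior(pooled[1], pooled[3]),
    stats::plogis(sum(runs[, 1] - runs[, 3]))
  )
})

test_that("log power ratios behave as variance ratios", {
  J <- matrix(rnorm(20 * 40), 20, 40)
  same <- power_modulation(J, 1:20, 1:20)
  expect_equal(same$log_power_ratio, rep(0, 20))

  Jd <- cbind(J[, 1:20], 2 * J[, 1:20])
  doubled <- power_modulation(Jd, 1:20, 21:40)
  expect_equal(doubled$log_power_ratio, rep(log(4), 20))

  out <- power_modulation(J, 1:15, 16:40)
  oracle <- log(rowMeans(J[, 16:40]^2) / rowMeans(J[, 1:15]^2))
  expect_equal(out$log_power_ratio, oracle)

  Jz <- J; Jz[3, 1:15] <- 0
  outz <- power_modulation(Jz, 1:15, 16:40)
  expect_true(outz$undefined[3])
  expect_true(is.na(outz$log_power_ratio[3]))

  # multi-trial input adds a t statistic across trials
  trials <- lapply(1:6, function(i) matrix(rnorm(20 * 40), 20, 40))
  mt <- power_modulation(trials, 1:20, 21:40)
  expect_true(all(c("t_statistic", "n_trials") %in% names(mt)))
  expect_equal(mt$n_trials[1], 6L)
})

test_that("joint modulation probability mixes per-model posteriors by evidence weight", {
  m1 <- tibble::tibble(vertex = 1:4, p_decrease = c(1, 1, 0.5, 0.2))
  m2 <- tibble::tibble(vertex = 1:4, p_decrease = c(1, 0.5, 0.5, 0.6))
  out <- joint_modulation_probability(list(m1, m2), weights = c(0.25, 0.75))
  expect_equal(out$p_decrease,
               0.25 * m1$p_decrease + 0.75 * m2$p_decrease)
  expect_equal(out$p_decrease[1], 1)           # all mass below zero
  expect_equal(out$p_decrease[3], 0.5)         # symmetric posteriors
  expect_error(joint_modulation_probability(list(m1, m2), c(0.5, 0.2)),
               "sum to 1")
})

test_that("the modulation posterior flags confident decreases", {
  nd <- 30; nt <- 20
  J <- matrix(0, nd, nt)
  J[1, 1:10] <- 5    # strong pre-window activity, silent post: decrease
  J[2, 11:20] <- 5   # the mirror image: increase
  fake <- structure(
    list(J_hat = J, V = diag(nt), posterior_var = rep(0.01, nd)),
    class = "inversion_result"
  )
  mp <- modulation_posterior(fake, pre_window = 1:10, post_window = 11:20,
                             n_draws = 400, seed = 3)
  expect_gt(mp$p_decrease[1], 0.99)
  expect_lt(mp$p_decrease[2], 0.01)
  # vertices with no signal and equal windows hover near one half
  expect_true(all(abs(mp$p_decrease[3:nd] - 0.5) < 0.2))
})

test_that("comparison tables assemble pooling, HDH, and surviving-set posteriors", {
  ev <- tidyr::expand_grid(L = 1:6, rep = 1:3)
  set.seed(4)
  base <- c(-20, -10, -4, -0.5, -0.2, 0)   # pooled deficits vs reference
  ev$F <- base[ev$L] / 3 + rnorm(nrow(ev), sd = 0.01)
  tab <- model_comparison_table(ev, threshold = 0.05, reference_L = 6)
  expect_s3_class(tab, "model_comparison")
  expect_equal(attr(tab, "hdh"), 3L)
  expect_true(all(tab$in_surviving_set == (tab$L > 3)))
  expect_equal(sum(tab$posterior, na.rm = TRUE), 1, tolerance = 1e-12)
  pooled <- tapply(ev$F, ev$L, sum)
  expect_equal(tab$F_pooled, as.numeric(pooled))
  g <- glance(tab)
  expect_equal(g$hdh, 3L)
  expect_false(g$indistinguishable)
})

test_that("noise-only data leave surface models indistinguishable at the nominal rate", {
  ctx <- small_cortex(seed = 21)
  sens <- generate_sensor_array(48)
  fit <- fit_wfs(ctx, Lmax = 6)
  fam <- harmonic_family(fit, c(1, 2, 4, 6))
  lead <- lapply(fam$meshes[c("L1", "L2", "L4", "L6")],
                 function(m) compute_leadfield(m, sens)$K)
  sv <- svd(lead$L6)
  U <- t(sv$u[, 1:32])
  lib <- suppressWarnings(build_patch_library(fam$reference, 48, fwhm = 12,
                                              seed = 3))
  n_seeds <- 20
  hits <- 0L; total <- 0L
  for (s in seq_len(n_seeds)) {
    set.seed(1000 + s)
    Y <- matrix(rnorm(48 * 60), 48, 60)
    Yu <- U %*% Y
    V <- svd(Yu)$v[, 1:8]
    Fs <- vapply(names(lead), function(nm) {
      red <- structure(list(U = U, V = V, K = U %*% lead[[nm]], Y = Yu %*% V,
                            n_samples_full = 60), class = "reduced_problem")
      invert(Y, lead[[nm]], method = "MSP", library = lib, reduced = red,
             seed = s)$F
    }, numeric(1))
    p <- pairwise_posterior(Fs[1:3], Fs[4])
    hits <- hits + sum(p < 0.05)
    total <- total + 3L
  }
  # the discrimination rate on pure noise stays within the nominal 5 %
  # (binomial slack for 60 draws)
  expect_lte(hits / total, 0.05 + 2 * sqrt(0.05 * 0.95 / total))
})
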