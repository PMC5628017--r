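# Hierarchical inference: prior recovery, conjugate updates, contrasts,
# draw bookkeeping. Heavier posterior-correctness checks (grid oracle,
# parameter recovery) live in test-acceptance.R.

fix_all_group <- c(
  mu_R0 = 50, sd_R0 = 10, a_alpha1 = 2, b_alpha1 = 2,
  a_alpha_inf = 2, b_alpha_inf = 2,
  mu_A_h1 = 0, mu_A_h6 = 5, sd_A_h1 = 8, sd_A_h6 = 8,
  mu_B_h1_u13 = 0, mu_B_h1_u22 = 0, mu_B_h6_u13 = 0, mu_B_h6_u22 = 0,
  sd_B_h1_u13 = 5, sd_B_h1_u22 = 5, sd_B_h6_u13 = 5, sd_B_h6_u22 = 5,
  k_sigma_h1_u13 = 4, k_sigma_h1_u22 = 4, k_sigma_h6_u13 = 4,
  k_sigma_h6_u22 = 4,
  lambda_sigma_h1_u13 = 0.4, lambda_sigma_h1_u22 = 0.4,
  lambda_sigma_h6_u13 = 0.4, lambda_sigma_h6_u22 = 0.4
)

test_that("a likelihood-free run recovers the hyperpriors", {
  sim <- generate_study(tiny_config(n_subjects = 6, games = 32))
  fit <- fit_hierarchical(sim$study, "rfpc", n_chains = 4, n_iter = 1000,
                          burn_in = 500, seed = 2, prior_only = TRUE,
                          refit_on_failure = FALSE)
  mu <- group_draws(fit, "mu_R0")
  se <- sd(mu) / sqrt(ess_bulk(mu))
  expect_lt(abs(mean(mu) - 50), 3 * se + 0.5)
  # SD of the mu_R0 marginal should approach its hyperprior SD of 14
  expect_gt(sd(mu), 10)
  expect_lt(sd(mu), 18)
  # support constraints hold throughout
  expect_true(all(subject_draws(fit, "alpha1") > 0 &
                    subject_draws(fit, "alpha1") < 1))
  expect_true(all(subject_draws(fit, "sigma_h6_u13") > 0))
  # Beta shapes stay inside their uniform hyperprior boxes
  expect_true(all(group_draws(fit, "a_alpha1") >= 0.1 &
                    group_draws(fit, "a_alpha1") <= 10))
  expect_true(all(group_draws(fit, "b_alpha1") >= 0.5))
})

test_that("subject draws follow their fixed priors without data", {
  sim <- generate_study(tiny_config(n_subjects = 8, games = 32))
  fit <- fit_hierarchical(sim$study, "vertex", n_chains = 4, n_iter = 1000,
                          burn_in = 500, seed = 4, prior_only = TRUE,
                          fix_group = fix_all_group, sample_group = FALSE,
                          refit_on_failure = FALSE)
  # sigma_s ~ Gamma(4, 0.4): mean 10, sd 5
  s <- as.vector(subject_draws(fit, "sigma_h6_u13"))
  expect_equal(mean(s), 10, tolerance = 0.06)
  expect_equal(sd(s), 5, tolerance = 0.1)
  # A_s ~ N(5, 8)
  a <- as.vector(subject_draws(fit, "A_h6"))
  expect_equal(mean(a), 5, tolerance = 0.06)
  expect_equal(sd(a), 8, tolerance = 0.1)
})

test_that("Gaussian group-mean update matches the conjugate closed form", {
  sim <- generate_study(tiny_config(n_subjects = 10, games = 32))
  # clamp every subject's A_h6 at 7 and the prior SD at 5: the mu_A_h6
  # conditional is then exactly Gaussian
  fit <- fit_hierarchical(
    sim$study, "rfpc", n_chains = 4, n_iter = 2000, burn_in = 200, seed = 6,
    prior_only = TRUE,
    fix_group = c(sd_A_h6 = 5),
    fix_subject = c(A_h6 = 7),
    refit_on_failure = FALSE
  )
  S <- 10
  prec <- 1 / 100^2 + S / 5^2
  m_star <- (0 / 100^2 + S * 7 / 5^2) / prec
  s_star <- sqrt(1 / prec)
  mu <- as.vector(group_draws(fit, "mu_A_h6"))
  expect_equal(mean(mu), m_star, tolerance = 0.02)
  expect_equal(sd(mu), s_star, tolerance = 0.05)
})

test_that("contrasts of equivalent fits centre on zero", {
  sim <- generate_study(tiny_config(n_subjects = 5, games = 32, seed = 13))
  # fit the same condition's data twice under different seeds
  f1 <- fit_hierarchical(sim$study, "rfpc", n_chains = 2, n_iter = 500,
                         burn_in = 500, seed = 21, refit_on_failure = FALSE)
  f2 <- fit_hierarchical(sim$study, "rfpc", n_chains = 2, n_iter = 500,
                         burn_in = 500, seed = 22, refit_on_failure = FALSE)
  pair <- structure(list(rfpc = f1, vertex = f2),
                    class = "horizon_fit_pair")
  con <- contrast(pair, "mu_R0")
  expect_lt(abs(con$mean), 3)
  expect_gt(con$frac_below_0, 0.15)
  expect_gt(con$frac_above_0, 0.15)
  expect_equal(con$frac_below_0 + con$frac_above_0, 1,
               tolerance = 0.01)
  # mismatched protocols are refused
  f3 <- fit_hierarchical(sim$study, "rfpc", n_chains = 2, n_iter = 100,
                         burn_in = 100, seed = 23, refit_on_failure = FALSE)
  pair_bad <- structure(list(rfpc = f1, vertex = f3),
                        class = "horizon_fit_pair")
  expect_error(contrast(pair_bad, "mu_R0"), "draw counts")
})

test_that("delta-A is exactly zero when the bonus ignores horizon", {
  sim <- generate_study(tiny_config(n_subjects = 4, games = 32))
  fits <- lapply(c("rfpc", "vertex"), function(tms) {
    fit_hierarchical(sim$study, tms, n_chains = 2, n_iter = 300,
                     burn_in = 100, seed = 8, prior_only = TRUE,
                     fix_group = c(mu_A_h1 = 4, mu_A_h6 = 4),
                     fix_subject = c(A_h1 = 4, A_h6 = 4),
                     refit_on_failure = FALSE)
  })
  names(fits) <- c("rfpc", "vertex")
  dA <- delta_A_contrast(structure(fits, class = "horizon_fit_pair"))
  expect_true(all(dA$dA_rfpc == 0))
  expect_true(all(dA$change == 0))
})

test_that("draw tables and summaries are complete and well-indexed", {
  sim <- generate_study(tiny_config(n_subjects = 3, games = 32))
  fit <- fit_hierarchical(sim$study, "rfpc", n_chains = 2, n_iter = 100,
                          burn_in = 100, seed = 3, refit_on_failure = FALSE)
  tab <- draws_table(fit)
  expect_equal(nrow(tab), 2 * 100 * (26 + 13 * 3))
  expect_setequal(unique(tab$level), c("group", "subject"))
  ps <- posterior_summary(fit)
  expect_equal(nrow(ps), 26)
  expect_true(all(is.finite(ps$mean)))
  pm <- subject_posterior_means(fit)
  expect_equal(nrow(pm), 13 * 3)
  # missing-session subjects are retained prior-only via the subject list
  fit2 <- fit_hierarchical(sim$study, "rfpc", n_chains = 2, n_iter = 50,
                           burn_in = 50, seed = 3,
                           subjects = c(fit$subjects, "S99"),
                           refit_on_failure = FALSE)
  expect_true("S99" %in% fit2$subjects)
  expect_equal(dim(fit2$subject)[4], 4)
})

test_that("split-Rhat flags separated chains and passes mixed ones", {
  set.seed(10)
  good <- matrix(rnorm(4000), ncol = 4)
  bad <- cbind(matrix(rnorm(2000), ncol = 2),
               matrix(rnorm(2000, mean = 5), ncol = 2))
  expect_lt(split_rhat(good), 1.02)
  expect_gt(split_rhat(bad), 1.5)
  # drift within a chain registers through splitting
  drift <- matrix(rnorm(4000) + rep(seq(0, 6, length.out = 1000), 4),
                  ncol = 4)
  expect_gt(split_rhat(drift), 1.2)
})
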