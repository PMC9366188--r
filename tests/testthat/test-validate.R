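test_that("prior-check report covers the monitored parameters and tolerances scale with ESS", {
  st <- abc_tree()
  rep <- prior_check(st, default_prior(), clock_model(1),
                     subst_config("JC", ncat = 1),
                     L = 1, nseq = 1, nsample = 600, burnin = 150)
  expect_true(all(c("tau_A,B,C", "theta_A", "theta_A,B,C", "mu1") %in%
                  rep$table$param))
  expect_true(all(rep$table$tol > 0))
  expect_true(rep$pass)
})

test_that("the empirical prior reference reproduces analytic marginals", {
  ## forward draws used as the Bayesian-simulation reference must agree
  ## with the known prior laws (Dirichlet marginals are Beta, invG theta)
  st <- abc_tree()
  pr <- default_prior()
  cm <- clock2_iid_G()
  sc <- subst_config("GTR", ncat = 5)
  mon <- c("theta_A", "a", "nu_bar", "TH1", "TL1")
  set.seed(12)
  ref <- t(replicate(3000, {
    str <- coalclock:::sample_inner_taus(st, coalclock:::prior_sample(1, pr$tau))
    str$theta <- coalclock:::prior_sample(st$nnode, pr$theta)
    coalclock:::prior_draw_row(str, pr, cm, sc, mon, 1L)
  }))
  D <- function(x, cdf) max(abs(cdf(sort(x)) - seq_along(x) / length(x)))
  expect_lt(D(ref[, "theta_A"], function(q)
    coalclock:::prior_cdf(q, pr$theta)), 0.035)
  expect_lt(D(ref[, "a"], function(q) pbeta(q, 1, 5)), 0.035)
  expect_lt(D(ref[, "nu_bar"], function(q) pgamma(q, 2, 20)), 0.035)
  ## TH exceeds the root age, TL is positive
  expect_true(all(ref[, "TL1"] > 0))
})

test_that("corrupted log-normal density is visibly different", {
  ## dropping the -nu/2 correction shifts the density mode upward
  st <- abc_tree()
  cm <- clock_model(2, "LN", nu = list("iid", 5, 2, 2))
  cmbad <- cm; cmbad$drop_ln_bias <- TRUE
  r <- rep(1.4, st$nnode)
  expect_gt(log_density_branch_rates(r, st, cmbad, 1, 1),
            log_density_branch_rates(r, st, cm, 1, 1))
})
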