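test_that("hyperpriors on the shared rate means", {
  cm <- clock_model(2, "G", mu = list("iid", 5, 0, 0), nu = list("iid", 5, 10, 10))
  ## G(10,10) density at 1 is 10^10 e^-10 / Gamma(10) = 1.25110
  expect_equal(exp(log_hyperprior_means(1, 1, cm)), 1.25110, tolerance = 1e-5)
  ## mu fixed at 1 contributes nothing
  cm2 <- clock_model(2, "G", mu = list("iid", 5, 2, 2), nu = list("iid", 5, 10, 10))
  expect_equal(log_hyperprior_means(2, 1, cm2) - log_hyperprior_means(2, 1, cm),
               dgamma(2, 2, 2, log = TRUE))
  ## G(2,20) prior mean is 0.1
  expect_equal(2 / 20, 0.1)
})

test_that("conditional i.i.d. and gamma-Dirichlet locus priors", {
  ## iid, alpha = 5, mean 1, single locus at 1: 5^5 e^-5 / Gamma(5)
  expect_equal(exp(log_prior_locus_params(1, 5, "iid", mean = 1)),
               0.87733, tolerance = 1e-5)
  ## dir with L = 1 reduces to the G(alpha_bar, beta_bar) density
  expect_equal(log_prior_locus_params(0.7, 5, "dir", hyper = c(3, 4)),
               dgamma(0.7, 3, 4, log = TRUE), tolerance = 1e-10)
  ## dir vs iid disagree on a generic vector; dir matches a manual evaluation
  v <- c(0.5, 1.4, 1.1)
  L <- 3; a <- 5; ab <- 2; bb <- 20
  manual_dir <- ab * log(bb / L) - lgamma(ab) + lgamma(L * a) - L * lgamma(a) +
    (ab - L * a) * log(sum(v)) - bb * sum(v) / L + (a - 1) * sum(log(v))
  expect_equal(log_prior_locus_params(v, a, "dir", hyper = c(ab, bb)),
               manual_dir, tolerance = 1e-10)
  expect_false(isTRUE(all.equal(manual_dir,
               log_prior_locus_params(v, a, "iid", mean = 1))))
  ## fixed-mean dir lives on the scaled simplex
  expect_identical(log_prior_locus_params(c(1.5, 1.1, 0.9), 5, "dir", mean = 1),
                   -Inf)
  w <- coalclock:::sample_locus_params(6, 5, "dir", mean = 1)
  expect_equal(sum(w), 6, tolerance = 1e-9)
})

test_that("independent-rates (clock 2) branch-rate densities", {
  st <- abc_tree()
  cmG <- clock_model(2, "G", nu = list("iid", 5, 2, 20))
  r <- rep(1, st$nnode)
  ## per-branch G(mu^2/nu, mu/nu) at r = 1, mu = 1, nu = 0.1: 1.25110 each
  expect_equal(exp(log_density_branch_rates(r, st, cmG, 1, 0.1) / st$nnode),
               1.25110, tolerance = 1e-5)
  cmLN <- clock_model(2, "LN", nu = list("iid", 5, 2, 20))
  ## log-normal with -nu/2 correction at r = 1, nu = 0.04: 1.98478 each
  expect_equal(exp(log_density_branch_rates(r, st, cmLN, 1, 0.04) / st$nnode),
               1.98478, tolerance = 1e-5)
  expect_identical(log_density_branch_rates(c(-1, r[-1]), st, cmG, 1, 0.1), -Inf)
})

test_that("sampled rates match the stated moments", {
  st <- ab_tree()
  set.seed(5)
  cmG <- clock_model(2, "G", nu = list("iid", 5, 2, 20))
  rs <- replicate(3e4, coalclock:::sample_branch_rates(st, cmG, 1, 0.1)[1])
  expect_equal(mean(rs), 1, tolerance = 0.02)
  expect_equal(var(rs), 0.1, tolerance = 0.03)
  cmLN <- clock_model(2, "LN", nu = list("iid", 5, 2, 20))
  rs <- replicate(3e4, coalclock:::sample_branch_rates(st, cmLN, 1, 0.1)[1])
  expect_equal(mean(rs), 1, tolerance = 0.02)
  expect_equal(var(rs), (exp(0.1) - 1) * 1^2, tolerance = 0.03)
  ## strict clock: all branch rates equal the locus rate
  expect_true(all(coalclock:::sample_branch_rates(st, clock_model(1), 0.7, NA) == 0.7))
})

test_that("correlated-rates model: parameter count and near-zero-duration correlation", {
  st <- abc_tree(tau_ab = 0.0001, tau_abc = 0.05)
  cm3 <- clock_model(3, "LN", nu = list("iid", 5, 2, 20))
  cm2 <- clock_model(2, "LN", nu = list("iid", 5, 2, 20))
  L <- 7
  rr3 <- sample_rates(st, cm3, L)
  rr2 <- sample_rates(st, cm2, L)
  ## clock 3 fixes the root-stem rate to mu_i: exactly L fewer free rates
  expect_true(all(rr3$rates[, st$root] == rr3$mu))
  free3 <- L * (2 * st$s - 2); free2 <- L * (2 * st$s - 1)
  expect_equal(free2 - free3, L)
  ## daughters of a very short parent branch are almost perfectly correlated:
  ## A and B hang below node AB whose branch (tau_AB -> tau_ABC) is long, but
  ## tips A and B have duration tau_AB ~ 0, so corr(rA, rB | rAB) ~ 1
  set.seed(8)
  pair <- t(replicate(4000, {
    r <- coalclock:::sample_branch_rates(st, cm3, 1, 0.2)
    r[1:2]
  }))
  expect_gt(cor(log(pair[, 1]), log(pair[, 2])), 0.99)
  ## conditional means: E(daughter | parent) = parent (bias correction)
  st2 <- abc_tree(tau_ab = 0.02, tau_abc = 0.05)
  set.seed(9)
  draws <- t(replicate(3e4, coalclock:::sample_branch_rates(st2, cm3, 1.3, 0.1)))
  expect_equal(colMeans(draws)[1:2], c(1.3, 1.3), tolerance = 0.03,
               ignore_attr = TRUE)
})

test_that("clock-3 sampler agrees with the implemented density (both kernels)", {
  st <- abc_tree(tau_ab = 0.02, tau_abc = 0.05)
  for (kern in c("G", "LN")) {
    cm <- clock_model(3, kern, nu = list("iid", 5, 2, 20))
    set.seed(17)
    ## importance check: average of exp(logdens difference) between two
    ## parameter settings equals the likelihood-ratio expectation = 1 only
    ## under the sampling law; use a moment identity instead: the density
    ## must integrate the sampled histogram correctly via self-normalised
    ## importance weights against an independent proposal.
    mu <- 1; nu <- 0.15
    samp <- t(replicate(4000, coalclock:::sample_branch_rates(st, cm, mu, nu)))
    free <- coalclock:::nonroot_branches(st)
    ## proposal: independent log-normal around mu
    prop <- matrix(exp(rnorm(4000 * length(free), log(mu), 0.6)), 4000)
    ld_target <- apply(prop, 1, function(z) {
      r <- rep(mu, st$nnode); r[free] <- z
      log_density_branch_rates(r, st, cm, mu, nu)
    })
    ld_prop <- rowSums(dnorm(log(prop), log(mu), 0.6, log = TRUE) - log(prop))
    w <- exp(ld_target - ld_prop)
    ## importance-weighted mean of each coordinate matches the sampler mean
    for (j in seq_along(free)) {
      expect_equal(sum(w * prop[, j]) / sum(w), mean(samp[, free[j]]),
                   tolerance = 0.08)
    }
  }
})

test_that("branch lengths sum segment contributions", {
  ## two populations crossed: (tau_AB - t_u) * r_A + (t_s - tau_AB) * r_AB
  st <- ab_tree(tau0 = 0.1, theta = 0.01)
  gt <- gene_tree(parent = c(4L, 4L, 5L, 5L, 0L), age = c(0, 0, 0, 0.05, 0.15),
                  species = c(1L, 1L, 2L), st = st)
  rates <- numeric(st$nnode)
  rates[1] <- 1.2                      # species A
  rates[st$root] <- 0.8                # root population
  rates[2] <- 1.0
  len <- gene_tree_branch_lengths(gt, st, rates)
  expect_equal(len[4], (0.1 - 0.05) * 1.2 + (0.15 - 0.1) * 0.8)  # = 0.10
  ## identity rates: lengths equal time spans
  len1 <- gene_tree_branch_lengths(gt, st, rep(1, st$nnode))
  spans <- ifelse(gt$parent > 0, gt$age[pmax(gt$parent, 1L)] - gt$age, 0)
  expect_equal(len1, spans)
  ## tree length equals an independent per-segment accumulation
  st3 <- abc_tree()
  set.seed(3)
  gt3 <- sample_gene_tree(st3, c(2, 2, 1))
  r3 <- coalclock:::sample_branch_rates(st3, clock2_iid_G(), 1, 0.1)
  len3 <- gene_tree_branch_lengths(gt3, st3, r3)
  acc <- 0
  for (id in seq_len(gt3$nnode)) {
    m <- gt3$segments[[id]]
    if (!is.null(m)) for (k in seq_len(nrow(m)))
      acc <- acc + (m[k, "to"] - m[k, "from"]) * r3[m[k, "pop"]]
  }
  expect_equal(sum(len3), unname(acc))
})
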