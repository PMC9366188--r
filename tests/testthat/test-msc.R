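test_that("coalescent waiting-time density: two lineages in one population", {
  ## two sequences from species A coalesce at 0.004 inside population A
  st <- species_tree("(A#0.01,B#0.01):0.05#0.01;")
  gt <- gene_tree(parent = c(3L, 3L, 0L), age = c(0, 0, 0.004),
                  species = c(1L, 1L), st = st)
  expect_equal(msc_log_density(gt, st), log(2 / 0.01) - (2 / 0.01) * 0.004,
               tolerance = 1e-12)  # = 4.49832
})

test_that("survival terms and per-population factorisation", {
  ## a and b pass uncoalesced through population AB of duration 0.005
  st <- species_tree("((A#0.01,B#0.01):0.001#0.01,C#0.01):0.006#0.02;")
  t1 <- 0.0065; t2 <- 0.008
  gt <- gt_abc(t1, t2, st)   # both coalescences in the root population
  thr <- 0.02
  manual <- -(2 / 0.01) * 0.005 +                       # survival in AB
    log(2 / thr) - (6 / thr) * (t1 - 0.006) +            # 3 -> 2 lineages
    log(2 / thr) - (2 / thr) * (t2 - t1)                 # 2 -> 1
  expect_equal(msc_log_density(gt, st), manual, tolerance = 1e-10)
})

test_that("single-sequence locus has zero log density", {
  st <- ab_tree()
  gt <- gene_tree(parent = 0L, age = 0, species = 1L, st = st)
  expect_equal(msc_log_density(gt, st), 0)
})

test_that("relabelling sequences within a species leaves the density unchanged", {
  st <- abc_tree()
  set.seed(1)
  for (k in 1:5) {
    gt <- sample_gene_tree(st, c(3, 2, 1))
    perm <- c(sample(1:3), 3 + sample(1:2), 6)  # permute within species
    gt2 <- gt
    gt2$species <- gt$species  # species labels unchanged under within-species permutation
    ## permute the tip attachment: swap parents of permuted tips
    gt2$parent[seq_len(6)] <- gt$parent[perm]
    expect_equal(msc_log_density(coalclock:::refresh_embedding(gt2, st), st),
                 msc_log_density(gt, st), tolerance = 1e-10)
  }
})

test_that("sampler respects the support and the escape probability", {
  st <- abc_tree(tau_ab = 0.01, tau_abc = 0.03, theta = 0.02)
  set.seed(42)
  n <- 4000
  ages <- numeric(n); coal_in_ab <- logical(n)
  for (k in seq_len(n)) {
    gt <- sample_gene_tree(st, c(1, 1, 0))
    ages[k] <- max(gt$age)
    coal_in_ab[k] <- max(gt$age) < 0.03
  }
  expect_true(all(ages >= 0.01))          # never below tau_AB
  p <- 1 - exp(-2 * (0.03 - 0.01) / 0.02) # escape probability 1 - e^{-2D/theta}
  expect_equal(mean(coal_in_ab), p, tolerance = 4 * sqrt(p * (1 - p) / n))
})

test_that("sampler and density agree on the root-age distribution (s = 2)", {
  st <- ab_tree(tau0 = 0.05, theta = 0.01)
  set.seed(7)
  ages <- replicate(4000, max(sample_gene_tree(st, 1L)$age))
  ## closed form: tau0 + Exp(2/theta)
  Fexp <- function(q) 1 - exp(-2 * pmax(q - 0.05, 0) / 0.01)
  D <- max(abs(Fexp(sort(ages)) - seq_along(ages) / length(ages)))
  expect_lt(D, 1.63 / sqrt(4000) * 1.5)
})

test_that("species-parameter priors: gamma root age and conditional flat ages", {
  st <- ab_tree(tau0 = 0.1, theta = 0.01)
  cfg <- msc_prior(tau = list("gamma", 2, 20), theta = list("invgamma", 3, 0.002))
  lp <- log_prior_species_params(st, cfg)
  lp_manual <- log(400 * 0.1 * exp(-2)) +               # ln(40) - 2 = 1.68888
    sum(coalclock:::dinvgamma_log(st$theta[!is.na(st$theta)], 3, 0.002))
  expect_equal(lp, lp_manual, tolerance = 1e-10)
  expect_equal(log(400 * 0.1 * exp(-2)), 1.68888, tolerance = 1e-5)
  ## inverse-gamma prior mean beta/(alpha-1)
  set.seed(1)
  draws <- coalclock:::prior_sample(2e5, list(family = "invgamma", alpha = 3, beta = 0.2))
  expect_equal(mean(draws), 0.2 / (3 - 1), tolerance = 0.01)
  ## beta prior support: -Inf outside the bounds, no exception
  cfgb <- msc_prior(theta = list("beta", 2, 2, a = 0.001, b = 0.01))
  stb <- ab_tree(theta = 0.5)
  expect_identical(log_prior_species_params(stb, cfgb), -Inf)
  ## conditional flat-Dirichlet normalisation integrates to 1 (s = 3)
  st3 <- abc_tree(tau_ab = 0.004, tau_abc = 0.02)
  lp3 <- log_prior_species_params(st3, cfg)
  ## relative to the s=2-style terms the inner age contributes -log(tau0)
  st3b <- st3; st3b$tau[match("A,B", st3$clade)] <- 0.015
  expect_equal(lp3, log_prior_species_params(st3b, cfg), tolerance = 1e-12)
})
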