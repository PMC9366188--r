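test_that("posterior caches always match a from-scratch recomputation", {
  st <- abc_tree()
  model <- msc_model(st, default_prior(), clock2_iid_G(),
                     subst_config("GTR", ncat = 5))
  sim <- simulate(model, nsim = 3, nsites = 80, nseq = 2, seed = 11)
  ## debug mode recomputes every cached density each sweep and stops on
  ## any disagreement, exercising every move against the cache-free oracle
  fit <- mscfit(model, sim, mcmc_control(burnin = 40, nsample = 60,
                                         sampfreq = 1, debug = TRUE), seed = 5)
  expect_equal(nrow(fit$trace$samples), 60)
  ## reordering loci leaves the log posterior of the (permuted) state intact
  e <- coalclock:::mcmc_state(st, model$prior, model$clock, model$subst,
                              data = sim, usedata = TRUE)
  lp <- coalclock:::log_posterior_state(e)
  perm <- c(2, 3, 1)
  for (f in c("loci", "gt", "subst", "eig", "crates")) e[[f]] <- e[[f]][perm]
  e$mu <- e$mu[perm]; e$nu <- e$nu[perm]; e$rates <- e$rates[perm, ]
  ev <- lapply(1:3, function(i) coalclock:::locus_eval(e, i))
  for (i in 1:3) coalclock:::set_locus_cache(e, i, ev[[i]])
  expect_equal(coalclock:::log_posterior_state(e), lp, tolerance = 1e-9)
})

test_that("prior-only chains sample the analytic priors", {
  st <- abc_tree()
  rep <- prior_check(st, default_prior(), clock2_iid_G(),
                     subst_config("GTR", ncat = 5),
                     L = 2, nseq = 1, nsample = 1500, burnin = 300)
  expect_true(rep$pass)
  expect_true(all(c("tau_A,B,C", "theta_A", "a", "alpha", "nu_bar", "mu1")
                  %in% rep$table$param))
})

test_that("bounded theta priors are never violated", {
  st <- abc_tree()
  pr <- msc_prior(tau = list("gamma", 2, 20),
                  theta = list("beta", 2, 2, a = 0.001, b = 0.02))
  model <- msc_model(st, pr, clock_model(1), subst_config("JC", ncat = 1))
  fit <- mscfit(model, data = NULL,
                mcmc_control(burnin = 100, nsample = 400, sampfreq = 1,
                             usedata = FALSE), L = 1, nseq = 2, seed = 8)
  th <- fit$trace$samples[, grep("^theta_", colnames(fit$trace$samples))]
  expect_true(all(th > 0.001 & th < 0.02))
})

test_that("two-species posterior matches dense grid integration", {
  ## one locus, two sequences, JC, strict clock with the locus rate pinned:
  ## the only unknowns are tau0, theta_root and the coalescent time t
  set.seed(40)
  st <- ab_tree(tau0 = 0.03, theta = 0.005)
  mJC <- subst_model("JC")
  gt <- gene_tree(parent = c(3L, 3L, 0L), age = c(0, 0, 0.035),
                  species = 1:2, tip.label = c("A1^A", "B1^B"), st = st)
  aln <- simulate_alignment(gt, c(0.035, 0.035, 0), mJC, 400)
  nd <- sum(aln[1, ] != aln[2, ]); ns <- ncol(aln)

  pr <- msc_prior(tau = list("gamma", 4, 100), theta = list("gamma", 4, 400))
  pinned <- clock_model(1, mu = list("iid", 1e8, 0, 0))
  model <- msc_model(st, pr, pinned, subst_config("JC", ncat = 1))
  data <- msc_data(list(aln), tree = st)
  fit <- mscfit(model, data,
                mcmc_control(burnin = 500, nsample = 6000, sampfreq = 2),
                seed = 3)
  tau_post <- fit$trace$samples[, "tau_A,B"]

  ## grid oracle: p(tau0 | x) ~ G(tau0) * int int G(th) (2/th) e^{-2(t-tau0)/th} L(2t)
  likJC <- function(d) {
    pdif <- 3 / 4 - 3 / 4 * exp(-4 * d / 3)
    nd * log(pdif / 3) + (ns - nd) * log(1 - pdif)
  }
  taug <- seq(1e-4, 0.12, length.out = 140)
  thg <- seq(1e-4, 0.05, length.out = 90)
  post <- vapply(taug, function(tau0) {
    v <- 0
    for (th in thg) {
      tg <- tau0 + seq(1e-5, 6 * th, length.out = 150)
      intg <- sum(exp(likJC(2 * tg) - (2 / th) * (tg - tau0))) * (2 / th) *
        (tg[2] - tg[1])
      v <- v + dgamma(th, 4, 400) * intg
    }
    dgamma(tau0, 4, 100) * v
  }, 0)
  post <- post / sum(post) / (taug[2] - taug[1])
  grid_mean <- sum(taug * post) * (taug[2] - taug[1])
  grid_cdf <- cumsum(post) * (taug[2] - taug[1])
  expect_equal(mean(tau_post), grid_mean, tolerance = 0.05)
  ## quantiles agree within Monte-Carlo tolerance
  for (q in c(0.25, 0.5, 0.75)) {
    gq <- taug[which.min(abs(grid_cdf - q))]
    expect_equal(unname(quantile(tau_post, q)), gq, tolerance = 0.08)
  }
})

test_that("NNI species-tree move: mapping, constraints, and uniform prior over topologies", {
  ## (a) rates transfer by branch identity: a gene tree fully coalesced in
  ## the root population keeps its topology and ages but changes lengths
  st <- abc_tree(tau_ab = 0.01, tau_abc = 0.02)
  gt <- gt_abc(0.03, 0.05, st)          # both nodes above tau_ABC
  rates <- c(1.5, 0.7, 1.1, 0.9, 1.3)   # per node id: A, B, C, AB, root
  len1 <- gene_tree_branch_lengths(gt, st, rates)
  ## NNI: swap B with C; node 4 keeps tau and theta, its clade becomes A,C
  st2 <- st
  st2$children[[4]] <- c(1L, 3L)
  st2$children[[5]] <- c(4L, 2L)
  st2$parent[2] <- 5L; st2$parent[3] <- 4L
  st2$clade <- coalclock:::clade_keys(st2)
  expect_equal(st2$clade[4], "A,C")
  gt2 <- coalclock:::refresh_embedding(gt, st2)
  expect_true(validate_compatibility(gt2, st2)$ok)
  len2 <- gene_tree_branch_lengths(gt2, st2, rates)
  expect_false(isTRUE(all.equal(len1, len2)))   # likelihood would change
  ## (b) prior-only tree search visits the three rooted topologies uniformly
  model <- msc_model(st, default_prior(), clock_model(1),
                     subst_config("JC", ncat = 1))
  fit <- mscfit(model, data = NULL,
                mcmc_control(burnin = 200, nsample = 3000, sampfreq = 1,
                             usedata = FALSE, search = TRUE),
                L = 2, nseq = 1, seed = 13)
  tp <- table(fit$trace$topology) / length(fit$trace$topology)
  expect_equal(length(tp), 3L)
  expect_true(all(abs(tp - 1 / 3) < 0.12))
  ## (c) a declared clade constraint is never broken
  stc <- species_tree(write_newick(st), constraints = list(c("A", "B")))
  modelc <- msc_model(stc, default_prior(), clock_model(1),
                      subst_config("JC", ncat = 1))
  fitc <- mscfit(modelc, data = NULL,
                 mcmc_control(burnin = 100, nsample = 800, sampfreq = 1,
                              usedata = FALSE, search = TRUE),
                 L = 1, nseq = 1, seed = 14)
  expect_true(all(grepl("(A,B)", fitc$trace$topology, fixed = TRUE)))
})

test_that("trace summaries: HPD, ESS, topology posterior", {
  expect_equal(hpd_interval(rep(3, 50)), c(3, 3))
  set.seed(2)
  x <- rnorm(4e4)
  h <- hpd_interval(x, 0.95)
  expect_equal(h, c(-1.96, 1.96), tolerance = 0.04)
  tr <- structure(list(samples = matrix(x, ncol = 1,
                                        dimnames = list(NULL, "p")),
                       topology = sample(c("(A,B);", "(B,C);"), 4e4, TRUE)),
                  class = "mcmc_trace")
  sm <- summarize_trace(tr)
  expect_equal(sum(sm$topologies), 1)
  expect_gt(sm$table["p", "ess"], 1e4)
})
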