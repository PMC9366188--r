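test_that("generator construction and reversibility", {
  mJC <- subst_model("JC")
  Q <- rate_matrix(mJC)
  expect_equal(unname(Q[1, -1]), rep(1 / 3, 3))
  expect_equal(rowSums(Q), rep(0, 4))
  set.seed(2)
  m <- subst_model("GTR", pi = rdir <- {g <- rgamma(4, 5); g / sum(g)},
                   exch = rgamma(6, 3))
  Qg <- rate_matrix(m)
  expect_equal(rowSums(Qg), rep(0, 4), tolerance = 1e-12)
  expect_equal(sum(m$pi * -diag(Qg)), 1, tolerance = 1e-12)     # mean rate 1
  ## detailed balance pi_i Q_ij = pi_j Q_ji
  B <- m$pi * Qg
  expect_equal(B, t(B), tolerance = 1e-12)
  ## JC arises from GTR with equal frequencies and exchangeabilities
  expect_equal(rate_matrix(subst_model("GTR")), rate_matrix(mJC))
})

test_that("transition probabilities", {
  Q <- rate_matrix(subst_model("JC"))
  P <- transition_probs(Q, 0.1)
  expect_equal(P[1, 1], 1 / 4 + 3 / 4 * exp(-4 * 0.1 / 3), tolerance = 1e-10)
  expect_equal(P[1, 1], 0.90638, tolerance = 1e-5)
  expect_equal(transition_probs(Q, 0), diag(4), tolerance = 1e-12)
  set.seed(4)
  m <- subst_model("GTR", pi = {g <- rgamma(4, 5); g / sum(g)}, exch = rgamma(6, 3))
  Qg <- rate_matrix(m)
  P1 <- transition_probs(Qg, 0.07, m$pi)
  P2 <- transition_probs(Qg, 0.05, m$pi)
  expect_equal(P1 %*% P2, transition_probs(Qg, 0.12, m$pi), tolerance = 1e-9)
  expect_equal(rowSums(P1), rep(1, 4), tolerance = 1e-12)
  expect_error(transition_probs(Qg, -0.1), "negative")
})

test_that("discrete-gamma category rates", {
  expect_identical(discrete_gamma_rates(0.5, 1), 1)
  for (a in c(0.3, 1, 2, 7)) expect_equal(mean(discrete_gamma_rates(a, 5)), 1)
  ## category means against direct quadrature of the Gamma(2,2) density
  r <- discrete_gamma_rates(2, 5)
  cuts <- qgamma(seq(0, 1, by = 0.2), 2, 2)
  oracle <- vapply(1:5, function(k) {
    5 * integrate(function(x) x * dgamma(x, 2, 2), cuts[k], cuts[k + 1],
                  rel.tol = 1e-10)$value
  }, 0)
  expect_equal(r, oracle, tolerance = 1e-6)
})

test_that("pruning likelihood: closed forms and brute-force enumeration", {
  mJC <- subst_model("JC")
  ## two identical one-site sequences, total path 0.1
  st <- ab_tree(tau0 = 0.02)
  gt <- gene_tree(parent = c(3L, 3L, 0L), age = c(0, 0, 0.05),
                  species = 1:2, tip.label = c("x", "y"), st = st)
  aln <- matrix(c("T", "T"), 2, 1, dimnames = list(c("x", "y"), NULL))
  ll <- log_likelihood(aln, gt, c(0.05, 0.05, 0), mJC)
  d <- 0.1
  expect_equal(exp(ll), 0.25 * (0.25 + 0.75 * exp(-4 * d / 3)), tolerance = 1e-10)
  expect_equal(exp(ll), 0.22659, tolerance = 1e-4)
  ## zero-length tree, identical sequences: product of 1/4 per site
  aln2 <- matrix(rep(c("A", "A"), 3), 2, 3, dimnames = list(c("x", "y"), NULL))
  expect_equal(log_likelihood(aln2, gt, c(0, 0, 0), mJC), 3 * log(0.25))
  ## ambiguity codes integrate over compatible states: N row is uninformative
  alnN <- matrix(c("T", "N"), 2, 1, dimnames = list(c("x", "y"), NULL))
  expect_equal(exp(log_likelihood(alnN, gt, c(0.05, 0.05, 0), mJC)), 0.25)

  ## 4-tip GTR+Gamma vs brute-force sum over ancestral states x categories
  set.seed(11)
  m <- subst_model("GTR", pi = {g <- rgamma(4, 8); g / sum(g)},
                   exch = rgamma(6, 3), alpha = 0.7, ncat = 4)
  st4 <- fig_tree()
  gt4 <- sample_gene_tree(st4, 1L)
  len <- gene_tree_branch_lengths(gt4, st4, rep(1, st4$nnode))
  aln4 <- simulate_alignment(gt4, len, m, 30)
  ll <- log_likelihood(aln4, gt4, len, m)
  ## brute force
  Q <- rate_matrix(m)
  cr <- discrete_gamma_rates(m$alpha, m$ncat)
  bases <- c("T", "C", "A", "G")
  po <- coalclock:::gt_postorder(gt4)
  ints <- po[po > gt4$n]
  brute_site <- function(sitechars) {
    tot <- 0
    for (cat in seq_along(cr)) {
      Ps <- lapply(seq_len(gt4$nnode), function(id)
        if (gt4$parent[id] > 0) transition_probs(Q, len[id] * cr[cat], m$pi) else NULL)
      states <- rep(NA_integer_, gt4$nnode)
      states[seq_len(gt4$n)] <- match(sitechars, bases)
      rec_sum <- 0
      grid <- expand.grid(rep(list(1:4), length(ints)))
      for (g in seq_len(nrow(grid))) {
        states[ints] <- unlist(grid[g, ])
        p <- m$pi[states[gt4$root]]
        for (id in seq_len(gt4$nnode)) {
          pa <- gt4$parent[id]
          if (pa > 0) p <- p * Ps[[id]][states[pa], states[id]]
        }
        rec_sum <- rec_sum + p
      }
      tot <- tot + rec_sum / length(cr)
    }
    log(tot)
  }
  ll_brute <- sum(apply(aln4, 2, brute_site))
  expect_equal(ll, ll_brute, tolerance = 1e-8)
})

test_that("pruning likelihood matches phangorn on a GTR+Gamma tree", {
  skip_if_not_installed("phangorn")
  set.seed(21)
  st4 <- fig_tree()
  gt4 <- sample_gene_tree(st4, 1L)
  len <- gene_tree_branch_lengths(gt4, st4, rep(1, st4$nnode))
  m <- subst_model("GTR", pi = c(0.22, 0.28, 0.3, 0.2),
                   exch = c(4, 1.2, 0.8, 1.1, 0.9, 3.5), alpha = 0.6, ncat = 5)
  aln <- simulate_alignment(gt4, len, m, 200)
  ll <- log_likelihood(aln, gt4, len, m)
  tr <- ape::read.tree(text = write_gene_tree_newick(gt4, len))
  dat <- phangorn::phyDat(aln, type = "DNA")
  ## phangorn order: bases ACGT; exchangeabilities Q in order
  ## AC, AG, AT, CG, CT, GT; ours is TC, TA, TG, CA, CG, AG on (T,C,A,G)
  bf <- m$pi[c(3, 2, 4, 1)]                      # A C G T
  Qp <- m$exch[c(4, 6, 2, 5, 1, 3)]              # AC AG AT CG CT GT
  fit <- phangorn::pml(tr, dat, bf = bf, Q = Qp, shape = m$alpha, k = 5)
  expect_equal(ll, as.numeric(fit$logLik), tolerance = 1e-4)
})

test_that("simulation is stationary and consistent with the JC distance", {
  set.seed(5)
  m <- subst_model("HKY", pi = c(0.35, 0.15, 0.3, 0.2), kappa = 3)
  st <- ab_tree(tau0 = 0.02)
  gt <- gene_tree(parent = c(3L, 3L, 0L), age = c(0, 0, 0.05),
                  species = 1:2, tip.label = c("x", "y"), st = st)
  aln <- simulate_alignment(gt, c(0.1, 0.1, 0), m, 4e4)
  frq <- table(factor(aln, levels = c("T", "C", "A", "G"))) / length(aln)
  expect_equal(as.numeric(frq), m$pi, tolerance = 0.02)
  ## JC-corrected distance between the two tips ~ their path length
  mJC <- subst_model("JC")
  alnJC <- simulate_alignment(gt, c(0.08, 0.08, 0), mJC, 1e5)
  p <- mean(alnJC[1, ] != alnJC[2, ])
  dhat <- -3 / 4 * log(1 - 4 * p / 3)
  expect_equal(dhat, 0.16, tolerance = 0.04)
  ## zero-length edges copy the parent sequence
  aln0 <- simulate_alignment(gt, c(0, 0, 0), mJC, 50)
  expect_identical(aln0[1, ], aln0[2, ])
})
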