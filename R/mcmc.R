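#' MCMC run settings
#'
#' @param burnin Burn-in sweeps (discarded; step sizes are auto-tuned here
#'   and frozen afterwards, which preserves detailed balance for the
#'   retained sample).
#' @param nsample Number of retained samples.
#' @param sampfreq Sweeps between retained samples.
#' @param usedata If `FALSE` the likelihood is fixed at 1 so the chain
#'   samples from the prior (the first validation harness).
#' @param search If `TRUE`, propose NNI changes to the species tree
#'   (species-tree search); otherwise the species tree is fixed (parameter
#'   estimation).  Search is intended for small trees (roughly s <= 6):
#'   trans-model moves mix slowly under relaxed clocks, and the
#'   correlated-rates model especially so.
#' @param tune Auto-tune proposal step sizes during burn-in.
#' @param debug Recompute all cached densities from scratch every sweep and
#'   stop on any mismatch.
#' @return A list of class `mcmc_control`.
#' @export
mcmc_control <- function(burnin = 500L, nsample = 1000L, sampfreq = 2L,
                         usedata = TRUE, search = FALSE, tune = TRUE,
                         debug = FALSE) {
  stopifnot(burnin >= 0, nsample > 0, sampfreq > 0)
  structure(list(burnin = as.integer(burnin), nsample = as.integer(nsample),
                 sampfreq = as.integer(sampfreq), usedata = usedata,
                 search = search, tune = tune, debug = debug),
            class = "mcmc_control")
}

#' Substitution-model configuration for inference
#'
#' Which substitution model each locus carries, which of its parameters are
#' sampled, and their priors: Dirichlet on the base frequencies, Dirichlet
#' on the exchangeabilities, gamma on the among-site shape `alpha`, gamma on
#' `kappa` for K80/HKY.  Defaults are the uniform Dirichlets.
#'
#' @param model `"JC"`, `"K80"`, `"HKY"`, `"GTR"`.
#' @param ncat Discrete-gamma categories (1 = no among-site variation).
#' @param alpha_prior `c(shape, rate)` for alpha; ignored when `ncat = 1`.
#' @param pi_alpha Dirichlet parameters for the base frequencies.
#' @param exch_alpha Dirichlet parameters for the exchangeabilities.
#' @param kappa_prior `c(shape, rate)` for kappa (K80/HKY).
#' @return A list of class `subst_config`.
#' @export
subst_config <- function(model = "GTR", ncat = 5L, alpha_prior = c(2, 1),
                         pi_alpha = rep(1, 4), exch_alpha = rep(1, 6),
                         kappa_prior = c(2, 1)) {
  model <- match.arg(toupper(model), c("JC", "K80", "HKY", "GTR"))
  structure(list(model = model, ncat = as.integer(ncat),
                 alpha_prior = alpha_prior, pi_alpha = pi_alpha,
                 exch_alpha = exch_alpha, kappa_prior = kappa_prior),
            class = "subst_config")
}

## ---- state --------------------------------------------------------------

## dummy pattern block used in prior-only runs
.dummy_cmp <- list(part = matrix(1, 4, 1), weights = 0, nsites = 0)

## Build the sampler state.  'data' is NULL (prior-only) or a list with
## $alignments (list of character matrices) and $species (per locus, integer
## species id per sequence, rows matching the alignment).
mcmc_state <- function(st, prior, clock, scfg, data = NULL, L = NULL,
                       nseq = 1L, usedata = !is.null(data), init = NULL) {
  e <- new.env(parent = emptyenv())
  e$st <- st
  e$prior <- prior
  e$clock <- clock
  e$scfg <- scfg
  e$usedata <- usedata && !is.null(data)
  if (!is.null(data)) L <- length(data$alignments)
  if (is.null(L)) stop("need data or L")
  e$L <- L

  e$loci <- vector("list", L)
  e$gt <- vector("list", L)
  for (i in seq_len(L)) {
    if (!is.null(data)) {
      aln <- data$alignments[[i]]
      labs <- rownames(aln)
      sp <- data$species[[i]]
      cmp <- compress_alignment(aln, labs)
      e$loci[[i]] <- list(cmp = cmp, labels = labs, species = as.integer(sp))
    } else {
      sp <- rep(seq_len(st$s), rep_len(as.integer(nseq), st$s))
      e$loci[[i]] <- list(cmp = .dummy_cmp,
                          labels = paste0(st$tip.label[sp], seq_along(sp), "^", st$tip.label[sp]),
                          species = sp)
    }
    g <- if (!is.null(init$gene_trees)) init$gene_trees[[i]]
         else sample_gene_tree(st, tabulate(e$loci[[i]]$species, st$s))
    e$gt[[i]] <- list(parent = g$parent, age = g$age, species = g$species,
                      n = g$n)
  }

  rr <- sample_rates(st, clock, L)
  e$mu_bar <- rr$mu_bar; e$nu_bar <- rr$nu_bar
  e$mu <- rr$mu; e$nu <- rr$nu; e$rates <- rr$rates
  if (!is.null(init$rates)) {
    ## warm start from supplied latents where they fit this clock model
    e$mu <- init$rates$mu
    if (clock$type > 1 && !anyNA(init$rates$nu)) e$nu <- init$rates$nu
    if (!is.null(init$clock_type) && init$clock_type == clock$type)
      e$rates <- init$rates$rates
    else if (clock$type == 1) e$rates <- matrix(e$mu, L, st$nnode)
    else if (clock$type == 3) e$rates[, st$root] <- e$mu
  }

  e$subst <- vector("list", L)
  for (i in seq_len(L)) {
    e$subst[[i]] <- if (!is.null(init$subst) &&
                        init$subst[[i]]$model == scfg$model &&
                        (init$subst[[i]]$ncat > 1) == (scfg$ncat > 1))
      init$subst[[i]] else draw_subst_from_prior(scfg)
  }
  e$eig <- vector("list", L)
  e$crates <- vector("list", L)
  for (i in seq_len(L)) refresh_subst_cache(e, i)

  e$lnMSC <- numeric(L); e$lnL <- numeric(L); e$TL <- numeric(L)
  e$spm <- vector("list", L); e$pop <- vector("list", L)
  for (i in seq_len(L)) {
    ev <- locus_eval(e, i)
    if (!ev$ok) stop("initial state incompatible at locus ", i)
    set_locus_cache(e, i, ev)
  }
  e$steps <- list(gage = 0.005, groot = 0.5, tau = 0.003, tau0 = 0.3,
                  theta = 0.5, mu = 0.3, nu = 0.5, rate = 0.4, nubar = 0.5,
                  mubar = 0.3, alpha = 0.5, kappa = 0.4, pi = 200, trs = 0.5,
                  exch = 150, mix = 0.3)
  e$acc <- list(); e$try <- list()
  e$topology_trace <- character(0)
  e
}

draw_subst_from_prior <- function(scfg) {
  rdir <- function(a) { g <- stats::rgamma(length(a), a); g / sum(g) }
  alpha <- if (scfg$ncat > 1) stats::rgamma(1, scfg$alpha_prior[1], scfg$alpha_prior[2]) else NULL
  switch(scfg$model,
    JC = subst_model("JC", alpha = alpha, ncat = scfg$ncat),
    K80 = subst_model("K80", kappa = stats::rgamma(1, scfg$kappa_prior[1], scfg$kappa_prior[2]),
                      alpha = alpha, ncat = scfg$ncat),
    HKY = subst_model("HKY", pi = rdir(scfg$pi_alpha),
                      kappa = stats::rgamma(1, scfg$kappa_prior[1], scfg$kappa_prior[2]),
                      alpha = alpha, ncat = scfg$ncat),
    GTR = subst_model("GTR", pi = rdir(scfg$pi_alpha), exch = rdir(scfg$exch_alpha),
                      alpha = alpha, ncat = scfg$ncat))
}

refresh_subst_cache <- function(e, i) {
  m <- e$subst[[i]]
  e$eig[[i]] <- eigen_Q(rate_matrix(m), m$pi)
  e$crates[[i]] <- discrete_gamma_rates(if (is.null(m$alpha)) 1 else m$alpha,
                                        if (is.null(m$alpha)) 1L else m$ncat)
}

locus_eval <- function(e, i, gt = e$gt[[i]], rates = e$rates[i, ],
                       st = e$st, usedata = e$usedata) {
  eg <- e$eig[[i]]
  cmp <- e$loci[[i]]$cmp
  m <- e$subst[[i]]
  cpp_locus_eval(gt$parent, gt$age, gt$species,
                 st$parent, st$tau, st$theta, st$root,
                 rates, usedata, cmp$part, cmp$weights,
                 m$pi, eg$U, eg$Uinv, eg$lam, e$crates[[i]])
}

set_locus_cache <- function(e, i, ev) {
  e$lnMSC[i] <- ev$lnMSC; e$lnL[i] <- ev$lnL; e$TL[i] <- ev$TL
  e$pop[[i]] <- ev$pop; e$spm[[i]] <- ev$spm
}

## ---- log prior pieces ---------------------------------------------------

lp_mu <- function(e, mu = e$mu, mu_bar = e$mu_bar) {
  cm <- e$clock$mu
  hyper <- if (e$clock$mu_fixed) c(0, 0) else c(cm$alpha_bar, cm$beta_bar)
  log_prior_locus_params(mu, cm$alpha, cm$structure, mean = mu_bar, hyper = hyper)
}

lp_nu <- function(e, nu = e$nu, nu_bar = e$nu_bar) {
  if (e$clock$type == 1) return(0)
  cn <- e$clock$nu
  if (cn$structure == "iid")
    log_prior_locus_params(nu, cn$alpha, "iid", mean = nu_bar)
  else
    log_prior_locus_params(nu, cn$alpha, "dir", hyper = c(cn$alpha_bar, cn$beta_bar))
}

lp_rates_i <- function(e, i, rates = e$rates[i, ], st = e$st,
                       mu = e$mu[i], nu = e$nu[i]) {
  log_density_branch_rates(rates, st, e$clock, mu, nu)
}

lp_subst_i <- function(e, i, m = e$subst[[i]]) {
  sc <- e$scfg
  lp <- 0
  ldir <- function(x, a) sum((a - 1) * log(x)) + lgamma(sum(a)) - sum(lgamma(a))
  if (sc$model %in% c("HKY", "GTR")) lp <- lp + ldir(m$pi, sc$pi_alpha)
  if (sc$model == "GTR") lp <- lp + ldir(m$exch / sum(m$exch), sc$exch_alpha)
  if (sc$model %in% c("K80", "HKY"))
    lp <- lp + stats::dgamma(m$kappa, sc$kappa_prior[1], sc$kappa_prior[2], log = TRUE)
  if (!is.null(m$alpha))
    lp <- lp + stats::dgamma(m$alpha, sc$alpha_prior[1], sc$alpha_prior[2], log = TRUE)
  lp
}

## full log posterior (prior-only runs drop the likelihood)
log_posterior_state <- function(e) {
  sum(e$lnMSC) + (if (e$usedata) sum(e$lnL) else 0) +
    log_prior_species_params(e$st, e$prior) +
    lp_mu(e) + lp_nu(e) + log_hyperprior_means(e$mu_bar, e$nu_bar, e$clock) +
    sum(vapply(seq_len(e$L), function(i) lp_rates_i(e, i), 0)) +
    sum(vapply(seq_len(e$L), function(i) lp_subst_i(e, i), 0))
}

## ---- proposal helpers ---------------------------------------------------

reflect <- function(x, lo, hi) {
  if (hi <= lo) return(lo)
  span <- hi - lo
  y <- (x - lo) %% (2 * span)
  lo + ifelse(y > span, 2 * span - y, y)
}

bump <- function(e, what, accepted) {
  e$try[[what]] <- (e$try[[what]] %||% 0) + 1
  e$acc[[what]] <- (e$acc[[what]] %||% 0) + accepted
}

`%||%` <- function(a, b) if (is.null(a)) b else a

mh_accept <- function(logratio) {
  is.finite(logratio) && (logratio >= 0 || log(stats::runif(1)) < logratio)
}

rdirichlet1 <- function(a) { g <- stats::rgamma(length(a), a); g / sum(g) }
ldirichlet <- function(x, a) sum((a - 1) * log(x)) + lgamma(sum(a)) - sum(lgamma(a))

## ---- per-locus moves ----------------------------------------------------

move_gene_ages <- function(e, i) {
  gt <- e$gt[[i]]
  if (gt$n < 2) return(invisible())
  spm <- e$spm[[i]]
  for (id in (gt$n + 1L):(2L * gt$n - 1L)) {
    kids <- which(gt$parent == id)
    lb <- max(gt$age[kids], e$st$tau[spm[id]])
    pa <- gt$parent[id]
    t <- gt$age[id]
    if (pa > 0L) {
      t1 <- reflect(t + e$steps$gage * (stats::runif(1) - 0.5), lb, gt$age[pa])
      lhast <- 0
      what <- "gage"
    } else {
      c0 <- exp(e$steps$groot * (stats::runif(1) - 0.5))
      t1 <- lb + (t - lb) * c0
      lhast <- log(c0)
      what <- "groot"
    }
    gt2 <- gt; gt2$age[id] <- t1
    ev <- locus_eval(e, i, gt = gt2)
    lr <- ev$lnMSC - e$lnMSC[i] +
      (if (e$usedata) ev$lnL - e$lnL[i] else 0) + lhast
    ok <- ev$ok && mh_accept(lr)
    if (ok) { gt <- gt2; e$gt[[i]] <- gt2; set_locus_cache(e, i, ev) }
    bump(e, what, ok)
  }
}

## population of a lineage (by its subtree species-MRCA) at time t
lineage_pop_at <- function(st, spm_node, t) {
  p <- spm_node
  if (t < st$tau[p]) return(0L)
  while (st$parent[p] > 0L && st$tau[st$parent[p]] <= t) p <- st$parent[p]
  p
}

## subtree-prune-regraft among lineages contemporary with the chosen node,
## keeping all coalescent times fixed; targets restricted to the pruned
## lineage's population, so the candidate set is identical forwards and
## backwards and the Hastings ratio is 1.
move_gene_topology <- function(e, i) {
  gt <- e$gt[[i]]
  n <- gt$n
  if (n < 3) return(invisible())
  nn <- 2L * n - 1L
  root <- which(gt$parent == 0L)
  cand_u <- setdiff((n + 1L):nn, root)
  u <- if (length(cand_u) == 1L) cand_u else sample(cand_u, 1L)
  kids <- which(gt$parent == u)
  cidx <- sample(2L, 1L)
  cc <- kids[cidx]; d <- kids[3L - cidx]
  t <- gt$age[u]
  pp <- gt$parent[u]
  ## spliced tree: d takes u's place under pp
  par2 <- gt$parent
  par2[d] <- pp
  spm <- e$spm[[i]]
  popc <- lineage_pop_at(e$st, spm[cc], t)
  if (popc == 0L) return(invisible())
  ## lineages crossing t in the spliced tree (excluding the pruned pair)
  cross <- which(vapply(seq_len(nn), function(v) {
    if (v == u || v == cc) return(FALSE)
    pv <- par2[v]
    gt$age[v] < t && (pv == 0L || gt$age[pv] > t)
  }, logical(1)))
  ## root lineage of the spliced tree extends upward indefinitely
  same_pop <- cross[vapply(cross, function(v)
    lineage_pop_at(e$st, spm[v], t) == popc, logical(1))]
  if (!length(same_pop)) { bump(e, "gspr", FALSE); return(invisible()) }
  z <- if (length(same_pop) == 1L) same_pop else sample(same_pop, 1L)
  if (z == d) { bump(e, "gspr", TRUE); return(invisible()) }  # identity
  par2[z] <- u
  par2[u] <- gt$parent[z]
  gt2 <- gt; gt2$parent <- par2
  ev <- locus_eval(e, i, gt = gt2)
  lr <- ev$lnMSC - e$lnMSC[i] + (if (e$usedata) ev$lnL - e$lnL[i] else 0)
  ok <- ev$ok && mh_accept(lr)
  if (ok) { e$gt[[i]] <- gt2; set_locus_cache(e, i, ev) }
  bump(e, "gspr", ok)
}

move_mu <- function(e, i) {
  cm <- e$clock
  if (cm$mu$structure == "dir" && cm$mu_fixed) return(move_mu_pair(e))
  c0 <- exp(e$steps$mu * (stats::runif(1) - 0.5))
  mu1 <- e$mu[i] * c0
  mu2v <- e$mu; mu2v[i] <- mu1
  lr <- lp_mu(e, mu2v) - lp_mu(e) + log(c0)
  needs_len <- cm$type %in% c(1, 3)  # mu is itself a branch rate
  if (cm$type > 1) {
    r2 <- e$rates[i, ]
    if (cm$type == 3) r2[e$st$root] <- mu1
    lr <- lr + lp_rates_i(e, i, rates = r2, mu = mu1) - lp_rates_i(e, i)
  } else r2 <- rep(mu1, e$st$nnode)
  if (needs_len) {
    ev <- locus_eval(e, i, rates = r2)
    lr <- lr + (if (e$usedata) ev$lnL - e$lnL[i] else 0)
  } else ev <- NULL
  ok <- mh_accept(lr)
  if (ok) {
    e$mu[i] <- mu1
    if (cm$type != 2) e$rates[i, ] <- r2 else e$rates[i, ] <- e$rates[i, ]
    if (cm$type == 3) e$rates[i, e$st$root] <- mu1
    if (!is.null(ev)) set_locus_cache(e, i, ev)
  }
  bump(e, "mu", ok)
}

## pairwise transfer preserving sum(mu) = L (gamma-Dirichlet with fixed mean)
move_mu_pair <- function(e) {
  if (e$L < 2) return(invisible())
  ij <- sample(e$L, 2L)
  d <- e$steps$mu * 0.2 * (stats::runif(1) - 0.5)
  mu2 <- e$mu
  mu2[ij[1]] <- e$mu[ij[1]] + d
  mu2[ij[2]] <- e$mu[ij[2]] - d
  if (any(mu2[ij] <= 0)) { bump(e, "mu", FALSE); return(invisible()) }
  lr <- lp_mu(e, mu2) - lp_mu(e)
  cm <- e$clock
  evs <- list()
  for (k in 1:2) {
    i <- ij[k]
    r2 <- e$rates[i, ]
    if (cm$type == 1) r2 <- rep(mu2[i], e$st$nnode)
    if (cm$type == 3) r2[e$st$root] <- mu2[i]
    if (cm$type > 1)
      lr <- lr + lp_rates_i(e, i, rates = r2, mu = mu2[i]) - lp_rates_i(e, i)
    if (cm$type %in% c(1, 3)) {
      ev <- locus_eval(e, i, rates = r2)
      lr <- lr + (if (e$usedata) ev$lnL - e$lnL[i] else 0)
      evs[[k]] <- list(i = i, ev = ev, r2 = r2)
    } else evs[[k]] <- list(i = i, ev = NULL, r2 = r2)
  }
  ok <- mh_accept(lr)
  if (ok) {
    e$mu <- mu2
    for (k in 1:2) {
      i <- evs[[k]]$i
      if (cm$type != 2) e$rates[i, ] <- evs[[k]]$r2
      if (cm$type == 3) e$rates[i, e$st$root] <- mu2[i]
      if (!is.null(evs[[k]]$ev)) set_locus_cache(e, i, evs[[k]]$ev)
    }
  }
  bump(e, "mu", ok)
}

## joint multiplier on a locus's overall rate and its whole branch-rate
## vector; under the correlated log-normal the conditional rate density is
## shape-invariant under this map, so it decorrelates mu_i from the rates
move_mu_scale_locus <- function(e, i) {
  cm <- e$clock
  if (cm$type == 1) return(invisible())
  if (cm$mu$structure == "dir" && cm$mu_fixed) return(invisible())
  c0 <- exp(e$steps$mu * (stats::runif(1) - 0.5))
  mu2v <- e$mu; mu2v[i] <- e$mu[i] * c0
  r2 <- e$rates[i, ] * c0
  nfree <- if (cm$type == 2) e$st$nnode else e$st$nnode - 1L
  lr <- (nfree + 1) * log(c0) +
    lp_mu(e, mu2v) - lp_mu(e) +
    lp_rates_i(e, i, rates = r2, mu = mu2v[i]) - lp_rates_i(e, i)
  ev <- locus_eval(e, i, rates = r2)
  lr <- lr + (if (e$usedata) ev$lnL - e$lnL[i] else 0)
  ok <- ev$ok && mh_accept(lr)
  if (ok) {
    e$mu[i] <- mu2v[i]
    e$rates[i, ] <- r2
    set_locus_cache(e, i, ev)
  }
  bump(e, "muscale", ok)
}

move_nu <- function(e, i) {
  if (e$clock$type == 1) return(invisible())
  c0 <- exp(e$steps$nu * (stats::runif(1) - 0.5))
  nu1 <- e$nu[i] * c0
  nu2v <- e$nu; nu2v[i] <- nu1
  lr <- lp_nu(e, nu2v) - lp_nu(e) + log(c0) +
    lp_rates_i(e, i, nu = nu1) - lp_rates_i(e, i)
  ok <- mh_accept(lr)
  if (ok) e$nu[i] <- nu1
  bump(e, "nu", ok)
}

move_rates_locus <- function(e, i) {
  cm <- e$clock
  if (cm$type == 1) return(invisible())
  free <- if (cm$type == 2) seq_len(e$st$nnode) else nonroot_branches(e$st)
  for (j in free) {
    c0 <- exp(e$steps$rate * (stats::runif(1) - 0.5))
    r2 <- e$rates[i, ]
    r2[j] <- r2[j] * c0
    lr <- lp_rates_i(e, i, rates = r2) - lp_rates_i(e, i) + log(c0)
    ev <- locus_eval(e, i, rates = r2)
    lr <- lr + (if (e$usedata) ev$lnL - e$lnL[i] else 0)
    ok <- mh_accept(lr)
    if (ok) { e$rates[i, j] <- r2[j]; set_locus_cache(e, i, ev) }
    bump(e, "rate", ok)
  }
}

move_subst <- function(e, i) {
  sc <- e$scfg
  m <- e$subst[[i]]
  propose_simplex <- function(x, conc, what) {
    a <- conc * x
    x1 <- rdirichlet1(a)
    if (any(x1 < 1e-8)) return(NULL)
    list(x = x1, lhast = ldirichlet(x, conc * x1) - ldirichlet(x1, a))
  }
  try_update <- function(m2, lhast, what) {
    old_eig <- e$eig[[i]]; old_cr <- e$crates[[i]]; old_m <- e$subst[[i]]
    e$subst[[i]] <- m2
    refresh_subst_cache(e, i)
    ev <- locus_eval(e, i)
    lr <- (if (e$usedata) ev$lnL - e$lnL[i] else 0) +
      lp_subst_i(e, i, m2) - lp_subst_i(e, i, old_m) + lhast
    ok <- mh_accept(lr)
    if (ok) set_locus_cache(e, i, ev)
    else { e$subst[[i]] <- old_m; e$eig[[i]] <- old_eig; e$crates[[i]] <- old_cr }
    bump(e, what, ok)
  }
  if (sc$model %in% c("HKY", "GTR")) {
    pr <- propose_simplex(m$pi, e$steps$pi, "pi")
    if (!is.null(pr)) { m2 <- m; m2$pi <- pr$x; try_update(m2, pr$lhast, "pi") }
  }
  if (sc$model == "GTR") {
    ex <- m$exch / sum(m$exch)
    pr <- propose_simplex(ex, e$steps$exch, "exch")
    if (!is.null(pr)) { m2 <- m; m2$exch <- pr$x; try_update(m2, pr$lhast, "exch") }
  }
  if (sc$model %in% c("K80", "HKY")) {
    c0 <- exp(e$steps$kappa * (stats::runif(1) - 0.5))
    m2 <- e$subst[[i]]
    m2$kappa <- m2$kappa * c0
    m2$exch <- c(m2$kappa, 1, 1, 1, 1, m2$kappa)
    try_update(m2, log(c0), "kappa")
  }
  m <- e$subst[[i]]
  if (!is.null(m$alpha)) {
    c0 <- exp(e$steps$alpha * (stats::runif(1) - 0.5))
    m2 <- m; m2$alpha <- m$alpha * c0
    try_update(m2, log(c0), "alpha")
  }
}

## ---- global moves -------------------------------------------------------

## rubber-band proposal for one species divergence time: gene-tree node ages
## in the two daughter populations and in the branch's own population are
## rescaled affinely with the moving boundary; for the root age, nodes in
## the (infinite) root population are shifted.
move_tau <- function(e, k) {
  st <- e$st
  is_root <- k == st$root
  kids <- st$children[[k]]
  tL <- max(st$tau[kids])
  tk <- st$tau[k]
  if (is_root) {
    c0 <- exp(e$steps$tau0 * (stats::runif(1) - 0.5))
    t1 <- tk * c0
    if (t1 <= tL) { bump(e, "tau0", FALSE); return(invisible()) }
    lhast <- log(c0)
  } else {
    tU <- st$tau[st$parent[k]]
    t1 <- reflect(tk + e$steps$tau * (stats::runif(1) - 0.5), tL, tU)
    lhast <- 0
  }
  st2 <- st
  st2$tau[k] <- t1
  logJ <- 0
  gts2 <- e$gt
  for (i in seq_len(e$L)) {
    pop <- e$pop[[i]]
    age <- e$gt[[i]]$age
    n <- e$gt[[i]]$n
    internal <- seq_along(pop) > n   # tips sit fixed at age 0
    for (d in kids) {
      sel <- which(pop == d & internal)
      if (length(sel)) {
        f <- (t1 - st$tau[d]) / (tk - st$tau[d])
        age[sel] <- st$tau[d] + (age[sel] - st$tau[d]) * f
        logJ <- logJ + length(sel) * log(f)
      }
    }
    sel <- which(pop == k & internal)
    if (length(sel)) {
      if (is_root) {
        age[sel] <- age[sel] + (t1 - tk)
      } else {
        tU <- st$tau[st$parent[k]]
        f <- (tU - t1) / (tU - tk)
        age[sel] <- t1 + (age[sel] - tk) * f
        logJ <- logJ + length(sel) * log(f)
      }
    }
    gts2[[i]]$age <- age
  }
  lr <- lhast + logJ +
    log_prior_species_params(st2, e$prior) - log_prior_species_params(st, e$prior)
  evs <- vector("list", e$L)
  for (i in seq_len(e$L)) {
    ev <- locus_eval(e, i, gt = gts2[[i]], st = st2)
    if (!ev$ok) { lr <- -Inf; break }
    evs[[i]] <- ev
    lr <- lr + ev$lnMSC - e$lnMSC[i] + (if (e$usedata) ev$lnL - e$lnL[i] else 0)
  }
  ok <- mh_accept(lr)
  if (ok) {
    e$st <- st2
    e$gt <- gts2
    for (i in seq_len(e$L)) set_locus_cache(e, i, evs[[i]])
  }
  bump(e, if (is_root) "tau0" else "tau", ok)
}

move_theta <- function(e, j) {
  st <- e$st
  c0 <- exp(e$steps$theta * (stats::runif(1) - 0.5))
  st2 <- st
  st2$theta[j] <- st$theta[j] * c0
  lr <- log(c0) + prior_log_density(st2$theta[j], e$prior$theta) -
    prior_log_density(st$theta[j], e$prior$theta)
  if (!is.finite(lr)) { bump(e, "theta", FALSE); return(invisible()) }
  dMSC <- 0
  evs <- vector("list", e$L)
  for (i in seq_len(e$L)) {
    ## theta never enters branch lengths, so the likelihood cache is reused
    ev <- locus_eval(e, i, st = st2, usedata = FALSE)
    ev$lnL <- e$lnL[i]
    evs[[i]] <- ev
    dMSC <- dMSC + ev$lnMSC - e$lnMSC[i]
  }
  lr <- lr + dMSC
  ok <- mh_accept(lr)
  if (ok) {
    e$st <- st2
    for (i in seq_len(e$L)) set_locus_cache(e, i, evs[[i]])
  }
  bump(e, "theta", ok)
}

move_hyper_means <- function(e) {
  cm <- e$clock
  if (!cm$mu_fixed && cm$mu$structure == "iid") {
    c0 <- exp(e$steps$mubar * (stats::runif(1) - 0.5))
    mb <- e$mu_bar * c0
    lr <- log(c0) +
      stats::dgamma(mb, cm$mu$alpha_bar, cm$mu$beta_bar, log = TRUE) -
      stats::dgamma(e$mu_bar, cm$mu$alpha_bar, cm$mu$beta_bar, log = TRUE) +
      lp_mu(e, mu_bar = mb) - lp_mu(e)
    ok <- mh_accept(lr)
    if (ok) e$mu_bar <- mb
    bump(e, "mubar", ok)
  }
  if (cm$type > 1 && cm$nu$structure == "iid") {
    c0 <- exp(e$steps$nubar * (stats::runif(1) - 0.5))
    nb <- e$nu_bar * c0
    lr <- log(c0) +
      stats::dgamma(nb, cm$nu$alpha_bar, cm$nu$beta_bar, log = TRUE) -
      stats::dgamma(e$nu_bar, cm$nu$alpha_bar, cm$nu$beta_bar, log = TRUE) +
      lp_nu(e, nu_bar = nb) - lp_nu(e)
    ok <- mh_accept(lr)
    if (ok) e$nu_bar <- nb
    bump(e, "nubar", ok)
  }
}

## joint scale move on the variance hierarchy: nu_bar (when sampled) and
## all nu_i multiplied together, removing the slow random-walk exploration
## of the hierarchy's overall level that single-site multipliers leave
move_nu_scale <- function(e) {
  cm <- e$clock
  if (cm$type == 1) return(invisible())
  c0 <- exp(e$steps$nubar * (stats::runif(1) - 0.5))
  nu2 <- e$nu * c0
  iid <- cm$nu$structure == "iid"
  nb2 <- if (iid) e$nu_bar * c0 else e$nu_bar
  lr <- (e$L + iid) * log(c0) +
    lp_nu(e, nu2, nb2) - lp_nu(e) +
    log_hyperprior_means(e$mu_bar, nb2, cm) -
    log_hyperprior_means(e$mu_bar, e$nu_bar, cm)
  for (i in seq_len(e$L))
    lr <- lr + lp_rates_i(e, i, nu = nu2[i]) - lp_rates_i(e, i)
  ok <- mh_accept(lr)
  if (ok) { e$nu <- nu2; e$nu_bar <- nb2 }
  bump(e, "nuscale", ok)
}

## whole-state scale move: all divergence times, coalescent times and thetas
move_mixing <- function(e) {
  c0 <- exp(e$steps$mix * (stats::runif(1) - 0.5))
  st2 <- e$st
  ints <- internal_nodes(st2)
  st2$tau[ints] <- st2$tau[ints] * c0
  st2$theta <- st2$theta * c0
  nscale <- length(ints) + sum(!is.na(st2$theta))
  gts2 <- e$gt
  for (i in seq_len(e$L)) {
    gts2[[i]]$age <- gts2[[i]]$age * c0
    nscale <- nscale + gts2[[i]]$n - 1L
  }
  lr <- nscale * log(c0) +
    log_prior_species_params(st2, e$prior) - log_prior_species_params(e$st, e$prior)
  evs <- vector("list", e$L)
  for (i in seq_len(e$L)) {
    ev <- locus_eval(e, i, gt = gts2[[i]], st = st2)
    if (!ev$ok) { lr <- -Inf; break }
    evs[[i]] <- ev
    lr <- lr + ev$lnMSC - e$lnMSC[i] + (if (e$usedata) ev$lnL - e$lnL[i] else 0)
  }
  ok <- mh_accept(lr)
  if (ok) {
    e$st <- st2
    e$gt <- gts2
    for (i in seq_len(e$L)) set_locus_cache(e, i, evs[[i]])
  }
  bump(e, "mix", ok)
}

## joint time/rate rescaling: times (taus, coalescent ages, thetas) scale by
## c while rates scale down so every branch length -- and the likelihood --
## is unchanged; this decorrelates the time scale from the locus rates.
## The variance parameters transform with the exponent that keeps each
## kernel's shape: -2 for the gamma kernels, 0 for the clock-2 log-normal
## (nu is a log-rate variance), -1 for the geometric Brownian motion
## (variance accrues per unit time).  Skipped when the locus rates live on
## the fixed-mean simplex, which a common rescaling would leave.
move_time_rate_scale <- function(e) {
  cm <- e$clock
  if (cm$mu$structure == "dir" && cm$mu_fixed) return(invisible())
  c0 <- exp(e$steps$trs * (stats::runif(1) - 0.5))
  knu <- if (cm$type == 1) 0
         else if (cm$kernel == "G") -2
         else if (cm$type == 2) 0 else -1
  st2 <- e$st
  ints <- internal_nodes(st2)
  st2$tau[ints] <- st2$tau[ints] * c0
  st2$theta <- st2$theta * c0
  mu2 <- e$mu / c0
  mu_bar2 <- if (cm$mu_fixed) e$mu_bar else e$mu_bar / c0
  nu2 <- e$nu * c0^knu
  nu_bar2 <- if (cm$type > 1 && cm$nu$structure == "iid") e$nu_bar * c0^knu else e$nu_bar
  rates2 <- e$rates / c0
  nfree_rates <- if (cm$type == 1) 0 else if (cm$type == 2) e$L * st2$nnode
                 else e$L * (st2$nnode - 1L)
  logJ <- (length(ints) + sum(!is.na(st2$theta))) * log(c0) -
    (nfree_rates + e$L + (!cm$mu_fixed)) * log(c0) +
    (if (cm$type > 1) knu * (e$L + (cm$nu$structure == "iid")) * log(c0) else 0)
  gts2 <- e$gt
  for (i in seq_len(e$L)) {
    gts2[[i]]$age <- gts2[[i]]$age * c0
    logJ <- logJ + (gts2[[i]]$n - 1L) * log(c0)
  }
  old <- list(mu = e$mu, nu = e$nu, mu_bar = e$mu_bar, nu_bar = e$nu_bar,
              rates = e$rates)
  lr <- logJ +
    log_prior_species_params(st2, e$prior) - log_prior_species_params(e$st, e$prior) +
    log_hyperprior_means(mu_bar2, nu_bar2, cm) -
    log_hyperprior_means(e$mu_bar, e$nu_bar, cm) +
    lp_mu(e, mu2, mu_bar2) - lp_mu(e) + lp_nu(e, nu2, nu_bar2) - lp_nu(e)
  evs <- vector("list", e$L)
  for (i in seq_len(e$L)) {
    lr <- lr + log_density_branch_rates(rates2[i, ], st2, cm, mu2[i], nu2[i]) -
      lp_rates_i(e, i)
    ## branch lengths are invariant by construction: reuse the likelihood
    ev <- locus_eval(e, i, gt = gts2[[i]], rates = rates2[i, ], st = st2,
                     usedata = FALSE)
    if (!ev$ok) { lr <- -Inf; break }
    ev$lnL <- e$lnL[i]
    evs[[i]] <- ev
    lr <- lr + ev$lnMSC - e$lnMSC[i]
  }
  ok <- mh_accept(lr)
  if (ok) {
    e$st <- st2
    e$gt <- gts2
    e$mu <- mu2; e$nu <- nu2; e$mu_bar <- mu_bar2; e$nu_bar <- nu_bar2
    e$rates <- rates2
    for (i in seq_len(e$L)) set_locus_cache(e, i, evs[[i]])
  }
  bump(e, "trscale", ok)
}

## ---- sweep and driver ---------------------------------------------------

mcmc_sweep <- function(e, search = FALSE) {
  for (i in seq_len(e$L)) {
    move_gene_ages(e, i)
    move_gene_topology(e, i)
    move_mu(e, i)
    move_mu_scale_locus(e, i)
    move_nu(e, i)
    move_rates_locus(e, i)
    move_subst(e, i)
  }
  for (k in internal_nodes(e$st)) move_tau(e, k)
  for (j in which(!is.na(e$st$theta))) move_theta(e, j)
  move_hyper_means(e)
  move_nu_scale(e)
  move_mixing(e)
  move_time_rate_scale(e)
  if (search) move_species_tree(e)
}

tune_steps <- function(e) {
  dir_down <- c("pi", "exch")  # concentration: larger = smaller step
  for (w in names(e$try)) {
    tr <- e$try[[w]]
    if (is.null(tr) || tr < 20) next
    rate <- e$acc[[w]] / tr
    key <- switch(w, gspr = NA, w)
    if (is.na(key) || is.null(e$steps[[key]])) next
    f <- exp(rate - 0.3)
    if (key %in% dir_down) f <- 1 / f
    e$steps[[key]] <- min(max(e$steps[[key]] * f, 1e-4), 1e4)
  }
  e$acc <- list(); e$try <- list()
}

monitor_names <- function(e) {
  st <- e$st
  ints <- internal_nodes(st)
  nm <- c(paste0("tau_", st$clade[ints]),
          paste0("theta_", st$clade[which(!is.na(st$theta))]))
  if (!e$clock$mu_fixed) nm <- c(nm, "mu_bar")
  if (e$clock$type > 1) nm <- c(nm, "nu_bar", "nu1")
  nm <- c(nm, "mu1")
  sc <- e$scfg
  if (sc$model %in% c("HKY", "GTR")) nm <- c(nm, paste0("pi", c("T", "C", "A", "G")))
  if (sc$model == "GTR") nm <- c(nm, letters[1:6])
  if (sc$model %in% c("K80", "HKY")) nm <- c(nm, "kappa")
  if (sc$ncat > 1) nm <- c(nm, "alpha")
  c(nm, "TH1", "TL1", "lnP")
}

monitor_row <- function(e) {
  st <- e$st
  ints <- internal_nodes(st)
  v <- c(st$tau[ints], st$theta[which(!is.na(st$theta))])
  if (!e$clock$mu_fixed) v <- c(v, e$mu_bar)
  if (e$clock$type > 1) {
    nb <- if (e$clock$nu$structure == "iid") e$nu_bar else mean(e$nu)
    v <- c(v, nb, e$nu[1])
  }
  v <- c(v, e$mu[1])
  sc <- e$scfg
  m <- e$subst[[1]]
  if (sc$model %in% c("HKY", "GTR")) v <- c(v, m$pi)
  if (sc$model == "GTR") v <- c(v, m$exch / sum(m$exch))
  if (sc$model %in% c("K80", "HKY")) v <- c(v, m$kappa)
  if (sc$ncat > 1) v <- c(v, m$alpha)
  g1 <- e$gt[[1]]
  TH <- max(g1$age)
  c(v, TH, e$TL[1], log_posterior_state(e))
}

debug_check <- function(e) {
  for (i in seq_len(e$L)) {
    ev <- locus_eval(e, i)
    if (abs(ev$lnMSC - e$lnMSC[i]) > 1e-6 ||
        (e$usedata && abs(ev$lnL - e$lnL[i]) > 1e-6))
      stop("cache mismatch at locus ", i)
  }
}

## Core driver.  Returns an 'mcmc_trace': samples matrix, species-tree
## topology strings per sample, final state, acceptance rates.
run_mcmc <- function(e, ctrl) {
  e$usedata <- ctrl$usedata && e$usedata
  ## burn-in with tuning
  for (it in seq_len(ctrl$burnin)) {
    mcmc_sweep(e, ctrl$search)
    if (ctrl$tune && it %% 50 == 0) tune_steps(e)
    if (ctrl$debug) debug_check(e)
  }
  e$acc <- list(); e$try <- list()
  nm <- monitor_names(e)
  out <- matrix(NA_real_, ctrl$nsample, length(nm),
                dimnames = list(NULL, nm))
  topo <- character(ctrl$nsample)
  for (si in seq_len(ctrl$nsample)) {
    for (k in seq_len(ctrl$sampfreq)) mcmc_sweep(e, ctrl$search)
    out[si, ] <- monitor_row(e)
    topo[si] <- topology_string(e$st)
    if (ctrl$debug && si %% 50 == 0) debug_check(e)
  }
  acc <- vapply(names(e$try), function(w) e$acc[[w]] / e$try[[w]], 0)
  structure(list(samples = out, topology = topo, state = e,
                 control = ctrl, acceptance = acc),
            class = "mcmc_trace")
}

## canonical (label-sorted) topology-only Newick string
topology_string <- function(st) {
  rec <- function(id) {
    if (id <= st$s) return(st$tip.label[id])
    kids <- vapply(st$children[[id]], rec, "")
    paste0("(", paste(sort(kids), collapse = ","), ")")
  }
  paste0(rec(st$root), ";")
}
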