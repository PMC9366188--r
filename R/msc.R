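#' Prior configuration for species-tree parameters
#'
#' Priors for the species-tree root age `tau0` and the population sizes
#' `theta`.  The root age takes a gamma `G(alpha, beta)` (mean `alpha/beta`)
#' or inverse-gamma `invG(alpha, beta)` (mean `beta/(alpha-1)`) prior; the
#' non-root node ages are uniform over their order-constrained region given
#' `tau0` (the flat-Dirichlet convention).  Each theta takes an independent
#' inverse-gamma, gamma, or bounded beta prior; `beta(alpha, beta, a, b)` is a
#' beta density rescaled to `a < theta < b` with mean `(alpha*b + beta*a) /
#' (alpha + beta)`.
#'
#' @param tau list(family = "gamma"|"invgamma", alpha, beta).
#' @param theta list(family = "invgamma"|"gamma"|"beta", alpha, beta, and for
#'   beta also `a` and `b` with `a < b`).
#' @return An object of class `msc_prior`.
#' @examples
#' msc_prior(tau = list("gamma", 2, 20), theta = list("invgamma", 3, 0.002))
#' @export
msc_prior <- function(tau = list("gamma", 2, 20),
                      theta = list("invgamma", 3, 0.002)) {
  norm <- function(x, what) {
    nms <- names(x) %||% rep("", length(x))
    slots <- c("family", "alpha", "beta", "a", "b")
    nms[!nzchar(nms)] <- setdiff(slots, nms)[seq_len(sum(!nzchar(nms)))]
    names(x) <- nms
    x$family <- match.arg(x$family, c("gamma", "invgamma", "beta"))
    if (x$alpha <= 0 || x$beta <= 0) stop(what, " prior parameters must be positive")
    if (x$family == "beta") {
      if (what == "tau") stop("beta prior is only available for theta")
      if (is.null(x$a) || is.null(x$b) || x$a >= x$b)
        stop("beta prior on theta needs bounds a < b")
    }
    x
  }
  structure(list(tau = norm(tau, "tau"), theta = norm(theta, "theta")),
            class = "msc_prior")
}

dinvgamma_log <- function(x, alpha, beta) {
  ifelse(x > 0, alpha * log(beta) - lgamma(alpha) - (alpha + 1) * log(x) - beta / x, -Inf)
}

rinvgamma <- function(n, alpha, beta) beta / stats::rgamma(n, alpha)

## log prior density of one scalar under a tau/theta prior spec
prior_log_density <- function(x, spec) {
  switch(spec$family,
    gamma = stats::dgamma(x, spec$alpha, spec$beta, log = TRUE),
    invgamma = dinvgamma_log(x, spec$alpha, spec$beta),
    beta = {
      u <- (x - spec$a) / (spec$b - spec$a)
      ifelse(u > 0 & u < 1,
             stats::dbeta(u, spec$alpha, spec$beta, log = TRUE) - log(spec$b - spec$a),
             -Inf)
    })
}

prior_sample <- function(n, spec) {
  switch(spec$family,
    gamma = stats::rgamma(n, spec$alpha, spec$beta),
    invgamma = rinvgamma(n, spec$alpha, spec$beta),
    beta = spec$a + (spec$b - spec$a) * stats::rbeta(n, spec$alpha, spec$beta))
}

prior_cdf <- function(q, spec) {
  switch(spec$family,
    gamma = stats::pgamma(q, spec$alpha, spec$beta),
    invgamma = 1 - stats::pgamma(spec$beta / pmax(q, .Machine$double.xmin), spec$alpha),
    beta = stats::pbeta((q - spec$a) / (spec$b - spec$a), spec$alpha, spec$beta))
}

## number of linear extensions of the non-root internal nodes under the
## ancestor partial order (parent must be older); exact by DFS for small s.
count_linear_extensions <- function(st) {
  nodes <- setdiff(internal_nodes(st), st$root)
  k <- length(nodes)
  if (k <= 1) return(1)
  ## ancestor matrix among 'nodes'
  is_anc <- matrix(FALSE, k, k)
  for (i in seq_len(k)) {
    p <- st$parent[nodes[i]]
    while (p > 0L) {
      j <- match(p, nodes)
      if (!is.na(j)) is_anc[j, i] <- TRUE
      p <- st$parent[p]
    }
  }
  cnt <- 0L
  used <- rep(FALSE, k)
  ## build orderings from oldest to youngest: place ancestors first
  rec <- function(placed) {
    if (placed == k) { cnt <<- cnt + 1L; return(invisible()) }
    for (i in seq_len(k)) {
      if (!used[i] && all(used[is_anc[, i]])) {
        used[i] <<- TRUE
        rec(placed + 1L)
        used[i] <<- FALSE
      }
    }
  }
  rec(0L)
  cnt
}

#' Log prior density of species divergence times and population sizes
#'
#' Sum of the root-age log prior, the conditional flat-Dirichlet log density
#' of the non-root node ages given the root age (uniform over the
#' order-constrained region, normalised exactly), and independent log priors
#' for every theta.  Values outside the support (a theta beyond its beta
#' bounds, node ages violating the topology's order constraints) give `-Inf`
#' rather than an error, so rejection in a sampler is automatic.
#'
#' @param st A `species_tree` with `tau` and `theta` set.
#' @param cfg An [msc_prior()].
#' @return Scalar log density.
#' @export
log_prior_species_params <- function(st, cfg) {
  s <- st$s
  tau0 <- st$tau[st$root]
  lp <- prior_log_density(tau0, cfg$tau)
  ints <- internal_nodes(st)
  for (id in ints) {
    p <- st$parent[id]
    if (p > 0L && st$tau[p] <= st$tau[id]) return(-Inf)
    if (st$tau[id] <= 0) return(-Inf)
  }
  if (s > 2) {
    nle <- count_linear_extensions(st)
    lp <- lp - (s - 2) * log(tau0) + lgamma(s - 1) - log(nle)
  }
  lp + sum(prior_log_density(st$theta[!is.na(st$theta)], cfg$theta))
}

## sample non-root taus uniformly given tau0 (rejection on order constraints)
sample_inner_taus <- function(st, tau0) {
  st$tau[st$root] <- tau0
  inner <- setdiff(internal_nodes(st), st$root)
  if (length(inner) == 0) return(st)
  repeat {
    st$tau[inner] <- stats::runif(length(inner), 0, tau0)
    ok <- TRUE
    for (id in c(inner, st$root)) {
      for (k in st$children[[id]]) {
        if (k > st$s && st$tau[k] >= st$tau[id]) { ok <- FALSE; break }
      }
      if (!ok) break
    }
    if (ok) return(st)
  }
}

## per-population bookkeeping: lineages entering, coalescent event ages
pop_history <- function(gt, st) {
  nn <- st$nnode
  coal_ids <- if (gt$nnode > gt$n) (gt$n + 1L):gt$nnode else integer(0)
  ncoal <- tabulate(gt$pop[coal_ids], nbins = nn)
  n_in <- integer(nn)
  for (j in postorder_nodes(st)) {
    n_in[j] <- if (j <= st$s) sum(gt$species == j)
               else sum(n_in[st$children[[j]]] - ncoal[st$children[[j]]])
  }
  events <- vector("list", nn)
  for (id in coal_ids) {
    j <- gt$pop[id]
    events[[j]] <- c(events[[j]], gt$age[id])
  }
  list(n_in = n_in, ncoal = ncoal, events = lapply(events, sort))
}

#' Log density of a gene tree under the multispecies coalescent
#'
#' The product over species-tree populations of exponential waiting-time
#' densities for each coalescence (total rate `j*(j-1)/theta` while `j`
#' lineages are present, i.e. `2/theta` per pair) and survival probabilities
#' for lineages leaving the population uncoalesced; the root population
#' extends to infinity and absorbs all remaining lineages.
#'
#' @param gt A `gene_tree` compatible with `st` (embedding refreshed).
#' @param st A `species_tree`.
#' @return Scalar log density; `-Inf` for an embedding-violating tree.
#' @export
msc_log_density <- function(gt, st) {
  if (is.null(gt$pop)) gt <- refresh_embedding(gt, st)
  if (any(gt$pop == 0L)) return(-Inf)
  h <- pop_history(gt, st)
  ld <- 0
  for (j in seq_len(st$nnode)) {
    n <- h$n_in[j]
    if (n < 2L && h$ncoal[j] == 0L) next  # no pair ever present: no contribution
    theta <- st$theta[j]
    if (is.na(theta)) stop("theta not set for population ", st$clade[j])
    upper <- if (st$parent[j] > 0L) st$tau[st$parent[j]] else Inf
    t <- st$tau[j]
    for (y in h$events[[j]]) {
      ld <- ld + log(2 / theta) - (n * (n - 1) / theta) * (y - t)
      t <- y
      n <- n - 1L
    }
    if (is.finite(upper)) {
      ld <- ld - (n * (n - 1) / theta) * (upper - t)
    } else if (n != 1L) return(-Inf)
  }
  ld
}

#' Sample a gene tree under the multispecies coalescent
#'
#' Forward simulation of the structured coalescent: within each population,
#' pairs coalesce at rate `2/theta` until the population's interval ends;
#' surviving lineages enter the parent population, and everything coalesces
#' in the root population.
#'
#' @param st A `species_tree`.
#' @param nseq Integer vector of sequences sampled per species (recycled to
#'   `s`; species may contribute 0).
#' @return A `gene_tree` with its embedding attached.
#' @export
sample_gene_tree <- function(st, nseq = 1L) {
  nseq <- rep_len(as.integer(nseq), st$s)
  n <- sum(nseq)
  if (n < 1L) stop("need at least one sequence")
  nn <- 2L * n - 1L
  parent <- integer(nn)
  age <- numeric(nn)
  species <- rep(seq_len(st$s), nseq)
  ## "individual^species" labelling, e.g. "A1^A"
  tip.label <- unlist(lapply(seq_len(st$s), function(sp)
    paste0(st$tip.label[sp], seq_len(nseq[sp]), "^", st$tip.label[sp])),
    use.names = FALSE)
  if (length(tip.label) == 0) tip.label <- character(0)

  next_node <- n
  lineages <- vector("list", st$nnode)  # active lineage node ids per pop
  for (sp in seq_len(st$s)) lineages[[sp]] <- which(species == sp)

  ord <- internal_nodes(st)
  pops <- c(seq_len(st$s), ord[order(st$tau[ord])])
  for (j in pops) {
    lin <- lineages[[j]]
    if (j > st$s) for (k in st$children[[j]]) lin <- c(lin, lineages[[k]])
    t <- st$tau[j]
    upper <- if (st$parent[j] > 0L) st$tau[st$parent[j]] else Inf
    theta <- st$theta[j]
    m <- length(lin)
    if (m >= 2L && is.na(theta))
      stop("theta not set for population ", st$clade[j])
    while (m >= 2L) {
      w <- stats::rexp(1, rate = m * (m - 1) / theta)
      if (t + w > upper) break
      t <- t + w
      pair <- sample(m, 2L)
      next_node <- next_node + 1L
      parent[lin[pair]] <- next_node
      age[next_node] <- t
      lin <- c(lin[-pair], next_node)
      m <- m - 1L
    }
    lineages[[j]] <- lin
  }
  gene_tree(parent, age, species, tip.label, st = st)
}
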