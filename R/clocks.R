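#' Relaxed-clock model specification
#'
#' Describes how substitution rates vary among loci and among species-tree
#' branches.  `type = 1` is the strict clock (one rate `mu_i` per locus);
#' `type = 2` the independent-rates model (each of the `2s-1` species-tree
#' branches, root stem included, gets an i.i.d. rate with mean `mu_i` and
#' variance parameter `nu_i`); `type = 3` the correlated-rates model
#' (daughter-branch rates conditioned on the mother-branch rate, the root
#' stem rate being `mu_i` itself, so `2s-2` free rates per locus).  The
#' kernel is `"G"` (gamma) or `"LN"` (log-normal; for type 3 this is
#' geometric Brownian motion on log rates).
#'
#' The per-locus overall rates `mu_i` and variance parameters `nu_i` each get
#' either the conditional i.i.d. (`"iid"`) prior -- `G(alpha, alpha/mean)`
#' around a shared mean -- or the gamma-Dirichlet (`"dir"`) prior, in which
#' the total over loci is partitioned by a Dirichlet with the given
#' concentration.  The shared means carry gamma hyperpriors `G(alpha_bar,
#' beta_bar)`; `alpha_bar = beta_bar = 0` for `mu` fixes the mean overall
#' rate at 1 (the no-fossil-calibration convention used throughout).
#'
#' @param type 1, 2 or 3.
#' @param kernel `"G"` or `"LN"` (ignored for type 1).
#' @param mu list(structure = "iid"|"dir", alpha, alpha_bar, beta_bar).
#' @param nu list(structure = "iid"|"dir", alpha, alpha_bar, beta_bar)
#'   (ignored for type 1 unless given).
#' @return An object of class `clock_model`.
#' @examples
#' clock_model(2, "G", mu = list("iid", 5, 0, 0), nu = list("iid", 5, 2, 20))
#' @export
clock_model <- function(type = 1, kernel = c("G", "LN"),
                        mu = list("iid", 5, 0, 0),
                        nu = list("iid", 5, 2, 20)) {
  kernel <- match.arg(toupper(kernel[1]), c("G", "LN"))
  norm <- function(x) {
    if (is.null(names(x))) names(x) <- c("structure", "alpha", "alpha_bar", "beta_bar")[seq_along(x)]
    x$structure <- match.arg(x$structure, c("iid", "dir"))
    for (f in c("alpha", "alpha_bar", "beta_bar"))
      if (is.null(x[[f]]) || x[[f]] < 0) stop("clock hyperparameters must be >= 0")
    x
  }
  if (!type %in% 1:3) stop("clock type must be 1, 2 or 3")
  cm <- structure(list(type = as.integer(type), kernel = kernel,
                       mu = norm(mu), nu = norm(nu)), class = "clock_model")
  cm$mu_fixed <- cm$mu$alpha_bar == 0 && cm$mu$beta_bar == 0
  if (!cm$mu_fixed && (cm$mu$alpha_bar == 0 || cm$mu$beta_bar == 0))
    stop("mu hyperprior needs both alpha_bar and beta_bar positive (or both 0 to fix)")
  if (type > 1 && (cm$nu$alpha_bar <= 0 || cm$nu$beta_bar <= 0))
    stop("relaxed clocks need a proper gamma hyperprior on nu_bar")
  cm
}

#' @export
print.clock_model <- function(x, ...) {
  lab <- c("strict clock", "independent rates", "correlated rates")[x$type]
  cat("Clock model ", x$type, " (", lab, ")", sep = "")
  if (x$type > 1) cat(", kernel ", x$kernel, sep = "")
  cat("\n  mu: ", x$mu$structure, " alpha=", x$mu$alpha,
      if (x$mu_fixed) ", mean fixed at 1"
      else sprintf(", mu_bar ~ G(%g,%g)", x$mu$alpha_bar, x$mu$beta_bar), "\n", sep = "")
  if (x$type > 1)
    cat("  nu: ", x$nu$structure, " alpha=", x$nu$alpha,
        sprintf(", nu_bar ~ G(%g,%g)", x$nu$alpha_bar, x$nu$beta_bar), "\n", sep = "")
  invisible(x)
}

#' Log hyperprior of the shared rate means
#'
#' Gamma log densities of the mean overall rate `mu_bar` and mean variance
#' parameter `nu_bar`; the `mu_bar` term is omitted when the mean rate is
#' fixed at 1 (no fossil calibrations), and the `nu_bar` term under the
#' strict clock.
#'
#' @param mu_bar,nu_bar Scalars (> 0 where used).
#' @param model A [clock_model()].
#' @return Scalar log density.
#' @export
log_hyperprior_means <- function(mu_bar, nu_bar, model) {
  lp <- 0
  if (!model$mu_fixed)
    lp <- lp + stats::dgamma(mu_bar, model$mu$alpha_bar, model$mu$beta_bar, log = TRUE)
  if (model$type > 1 && model$nu$structure == "iid")
    lp <- lp + stats::dgamma(nu_bar, model$nu$alpha_bar, model$nu$beta_bar, log = TRUE)
  lp
}

#' Joint log prior of per-locus rate parameters
#'
#' Under `"iid"`, a product of `G(alpha, alpha/mean)` densities.  Under
#' `"dir"` the total `L * mean` is partitioned by a Dirichlet with
#' concentration `alpha`: with a proper gamma hyperprior on the mean the
#' joint density over the unconstrained positive vector is used (the
#' gamma-Dirichlet); with the mean fixed (hyper = c(0, 0)) the values live on
#' the scaled simplex `sum(values) = L * mean` and the density is the
#' Dirichlet on proportions.
#'
#' @param values Positive vector of length `L` (the `mu_i` or `nu_i`).
#' @param alpha Concentration / shape parameter.
#' @param structure `"iid"` or `"dir"`.
#' @param mean The shared mean (`mu_bar` or `nu_bar`); required for `"iid"`
#'   and for `"dir"` with a fixed mean.
#' @param hyper For `"dir"`: `c(alpha_bar, beta_bar)` of the gamma hyperprior
#'   on the mean, or `c(0, 0)` when the mean is fixed.
#' @return Scalar log density (`-Inf` off the support).
#' @export
log_prior_locus_params <- function(values, alpha, structure = c("iid", "dir"),
                                   mean = NULL, hyper = c(0, 0)) {
  structure <- match.arg(structure)
  L <- length(values)
  if (L == 0) stop("no loci")
  if (any(values <= 0)) return(-Inf)
  if (structure == "iid") {
    if (is.null(mean)) stop("iid prior needs the shared mean")
    return(sum(stats::dgamma(values, alpha, alpha / mean, log = TRUE)))
  }
  S <- sum(values)
  if (hyper[1] > 0) {
    ## gamma-Dirichlet: gamma on the average, Dirichlet on proportions
    ab <- hyper[1]; bb <- hyper[2]
    ab * log(bb / L) - lgamma(ab) + lgamma(L * alpha) - L * lgamma(alpha) +
      (ab - L * alpha) * log(S) - bb * S / L + (alpha - 1) * sum(log(values))
  } else {
    if (is.null(mean)) stop("dir prior with fixed mean needs 'mean'")
    if (abs(S - L * mean) > 1e-8 * L * mean) return(-Inf)
    if (L == 1) return(0)  # point mass: the single value equals the mean
    lgamma(L * alpha) - L * lgamma(alpha) +
      (alpha - 1) * sum(log(values / S)) - (L - 1) * log(S)
  }
}

## sample the per-locus vector under iid/dir given the mean (or hyper)
sample_locus_params <- function(L, alpha, structure, mean = NULL, hyper = c(0, 0)) {
  if (structure == "iid") return(stats::rgamma(L, alpha, alpha / mean))
  S <- if (hyper[1] > 0) L * stats::rgamma(1, hyper[1], hyper[2]) else L * mean
  w <- stats::rgamma(L, alpha)
  S * w / sum(w)
}

## non-root branch ids (nodes whose branch has finite duration)
nonroot_branches <- function(st) setdiff(seq_len(st$nnode), st$root)

## log density of clock-2 LN (eq with -nu/2 bias correction so E(r) = mu).
## 'drop_bias' reproduces a deliberately corrupted density used by the
## validation harness as a negative control.
dln_rate <- function(r, mu, nu, drop_bias = FALSE) {
  shift <- if (drop_bias) 0 else nu / 2
  -log(r) - 0.5 * log(2 * pi * nu) - (log(r / mu) + shift)^2 / (2 * nu)
}

rln_rate <- function(n, mu, nu) exp(log(mu) - nu / 2 + sqrt(nu) * stats::rnorm(n))

## bivariate normal log pdf with common correlation structure
dbvnorm_log <- function(y1, y2, m1, m2, v1, v2, cv) {
  det <- v1 * v2 - cv * cv
  z1 <- y1 - m1; z2 <- y2 - m2
  q <- (v2 * z1 * z1 - 2 * cv * z1 * z2 + v1 * z2 * z2) / det
  -log(2 * pi) - 0.5 * log(det) - 0.5 * q
}

## clock-3 LN per-internal-node pieces: for node j with parent-branch rate ra,
## parent duration Da (0 at the root), daughters c1, c2 with durations D1, D2.
clock3_ln_node <- function(r1, r2, ra, nu, Da, D1, D2, what = "density") {
  v1 <- nu * (Da + D1) / 2
  v2 <- nu * (Da + D2) / 2
  cv <- nu * Da / 2
  if (what == "density") {
    dbvnorm_log(log(r1), log(r2), log(ra) - v1 / 2, log(ra) - v2 / 2,
                v1, v2, cv) - log(r1) - log(r2)
  } else {
    ## sample: shared segment first, then independent continuations
    z <- stats::rnorm(1, 0, sqrt(cv))
    y1 <- log(ra) - v1 / 2 + z + stats::rnorm(1, 0, sqrt(v1 - cv))
    y2 <- log(ra) - v2 / 2 + z + stats::rnorm(1, 0, sqrt(v2 - cv))
    c(exp(y1), exp(y2))
  }
}

#' Log density of per-branch rates at one locus
#'
#' Independent-rates model (clock 2): a product over the `2s-1` branches of
#' gamma `G(mu^2/nu, mu/nu)` (mean `mu`, variance `nu`) or log-normal
#' densities with the `-nu/2` mean correction.  Correlated-rates model
#' (clock 3): a pre-order product over internal nodes of daughter-rate
#' densities given the parent rate -- independent gammas `G(r_a^2/nu,
#' r_a/nu)` per daughter, or a bivariate log-normal whose covariance comes
#' from the shared parent-midpoint-to-node segment of the underlying
#' geometric Brownian motion (daughter rates become perfectly correlated as
#' the parent branch duration shrinks to 0).  The root stem rate is a free
#' rate under clock 2 and is `mu` itself under clock 3.
#'
#' @param rates Numeric vector indexed by species-tree node id (rate of the
#'   branch above each node; the root entry is the root-stem rate).
#' @param st A `species_tree`.
#' @param model A [clock_model()].
#' @param mu,nu The locus's overall rate and variance parameter.
#' @return Scalar log density (`-Inf` for nonpositive rates); 0 under the
#'   strict clock, whose rates are deterministic.
#' @export
log_density_branch_rates <- function(rates, st, model, mu, nu) {
  if (model$type == 1) return(0)
  if (any(rates <= 0, na.rm = TRUE)) return(-Inf)
  if (model$type == 2) {
    r <- rates[seq_len(st$nnode)]
    if (model$kernel == "G")
      return(sum(stats::dgamma(r, mu^2 / nu, mu / nu, log = TRUE)))
    return(sum(dln_rate(r, mu, nu, drop_bias = isTRUE(model$drop_ln_bias))))
  }
  ## clock 3: rates[root] must equal mu (not a free parameter)
  ld <- 0
  if (model$kernel == "G") {
    for (j in nonroot_branches(st)) {
      pa <- st$parent[j]
      ra <- if (pa == st$root) mu else rates[pa]
      ld <- ld + stats::dgamma(rates[j], ra^2 / nu, ra / nu, log = TRUE)
    }
    return(ld)
  }
  for (a in internal_nodes(st)) {
    kids <- st$children[[a]]
    ra <- if (a == st$root) mu else rates[a]
    Da <- if (a == st$root) 0 else st$tau[st$parent[a]] - st$tau[a]
    ld <- ld + clock3_ln_node(rates[kids[1]], rates[kids[2]], ra, nu, Da,
                              st$tau[a] - st$tau[kids[1]],
                              st$tau[a] - st$tau[kids[2]])
  }
  ld
}

#' Sample the full rate structure for L loci
#'
#' Draws the shared means (`mu_bar` fixed at 1 or gamma; `nu_bar` gamma),
#' the per-locus `mu_i` and `nu_i` under their iid/dir priors, and the
#' per-branch rates under the clock model, mirroring
#' [log_density_branch_rates()] exactly.
#'
#' @param st A `species_tree`.
#' @param model A [clock_model()].
#' @param L Number of loci.
#' @return A list with `mu_bar`, `nu_bar`, vectors `mu`, `nu` (length `L`),
#'   and `rates`, an `L x (2s-1)` matrix of branch rates indexed by
#'   species-tree node id (root column = root-stem rate; equals `mu_i` under
#'   clocks 1 and 3).
#' @export
sample_rates <- function(st, model, L) {
  mu_bar <- if (model$mu_fixed) 1 else stats::rgamma(1, model$mu$alpha_bar, model$mu$beta_bar)
  mu <- sample_locus_params(L, model$mu$alpha, model$mu$structure, mean = mu_bar,
                            hyper = c(model$mu$alpha_bar, model$mu$beta_bar) *
                              (!model$mu_fixed))
  nu_bar <- NA_real_
  nu <- rep(NA_real_, L)
  if (model$type > 1) {
    if (model$nu$structure == "iid") {
      nu_bar <- stats::rgamma(1, model$nu$alpha_bar, model$nu$beta_bar)
      nu <- sample_locus_params(L, model$nu$alpha, "iid", mean = nu_bar)
    } else {
      nu <- sample_locus_params(L, model$nu$alpha, "dir",
                                hyper = c(model$nu$alpha_bar, model$nu$beta_bar))
      nu_bar <- mean(nu)
    }
  }
  rates <- matrix(NA_real_, L, st$nnode)
  for (i in seq_len(L)) rates[i, ] <- sample_branch_rates(st, model, mu[i], nu[i])
  list(mu_bar = mu_bar, nu_bar = nu_bar, mu = mu, nu = nu, rates = rates)
}

## one locus's branch-rate vector (indexed by species-tree node id)
sample_branch_rates <- function(st, model, mu, nu) {
  r <- rep(mu, st$nnode)
  if (model$type == 1) return(r)
  if (model$type == 2) {
    n <- st$nnode
    r <- if (model$kernel == "G") stats::rgamma(n, mu^2 / nu, mu / nu)
         else rln_rate(n, mu, nu)
    return(r)
  }
  ## clock 3, pre-order from the root; root stem keeps mu
  r[st$root] <- mu
  ord <- rev(postorder_nodes(st))  # parents before children
  for (a in ord) {
    if (a <= st$s) next
    kids <- st$children[[a]]
    ra <- if (a == st$root) mu else r[a]
    if (model$kernel == "G") {
      r[kids] <- stats::rgamma(2, ra^2 / nu, ra / nu)
    } else {
      Da <- if (a == st$root) 0 else st$tau[st$parent[a]] - st$tau[a]
      r[kids] <- clock3_ln_node(NULL, NULL, ra, nu, Da,
                                st$tau[a] - st$tau[kids[1]],
                                st$tau[a] - st$tau[kids[2]], what = "sample")
    }
  }
  r
}

#' Gene-tree branch lengths from segment maps and branch rates
#'
#' Each gene-tree edge's length is the sum over the populations it traverses
#' of (time spent in the population) x (that population's rate at this
#' locus).  Under the strict clock this reduces to `mu * span`.
#'
#' @param gt A `gene_tree` with its embedding attached.
#' @param st A `species_tree`.
#' @param rates Branch-rate vector indexed by species-tree node id.
#' @return Numeric vector over gene-tree nodes: length of the edge above each
#'   node (0 for the root).
#' @export
gene_tree_branch_lengths <- function(gt, st, rates) {
  if (is.null(gt$segments)) stop("gene tree has no segment map; call refresh_embedding()")
  len <- numeric(gt$nnode)
  for (id in seq_len(gt$nnode)) {
    m <- gt$segments[[id]]
    if (is.null(m)) next
    r <- rates[m[, 1L]]
    if (anyNA(r)) stop("missing rate for a traversed population")
    len[id] <- sum((m[, 3L] - m[, 2L]) * r)
  }
  len
}
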