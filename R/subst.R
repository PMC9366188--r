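#' Nucleotide substitution models (JC, K80, HKY, GTR) with discrete-gamma
#' among-site rate variation
#'
#' The general time-reversible generator is built from base frequencies
#' `pi = (piT, piC, piA, piG)` and exchangeabilities `(a, b, c, d, e, f)` for
#' the pairs (TC, TA, TG, CA, CG, AG), scaled so that the mean rate at
#' stationarity is 1; JC, K80 and HKY are the usual constrained cases
#' (K80/HKY via the transition/transversion ratio `kappa`, which scales the
#' TC and AG entries).  Among-site rate variation uses `ncat` discrete gamma
#' categories with equal probabilities and category-mean rates (off when
#' `ncat = 1`).  Priors, used by the sampler and the simulator: uniform
#' Dirichlet on `pi`, uniform Dirichlet on the exchangeabilities, and a
#' gamma prior on the shape `alpha`.
#'
#' @param model `"JC"`, `"K80"`, `"HKY"` or `"GTR"`.
#' @param pi Base frequencies in T, C, A, G order (forced to 1/4 for JC/K80).
#' @param exch Exchangeabilities (GTR); any positive scale.
#' @param kappa Transition/transversion ratio (K80/HKY).
#' @param alpha Gamma shape for among-site rates; `NULL` disables.
#' @param ncat Number of discrete-gamma categories (default 5).
#' @param alpha_prior `c(shape, rate)` of the gamma prior on `alpha`.
#' @return An object of class `subst_model`.
#' @examples
#' m <- subst_model("GTR", pi = c(.3, .2, .3, .2), exch = c(4, 1, 1, 1, 1, 4),
#'                  alpha = 0.5, ncat = 5)
#' @export
subst_model <- function(model = c("JC", "K80", "HKY", "GTR"),
                        pi = rep(0.25, 4), exch = rep(1, 6), kappa = 2,
                        alpha = NULL, ncat = 5L, alpha_prior = c(2, 1)) {
  model <- match.arg(toupper(model[1]), c("JC", "K80", "HKY", "GTR"))
  if (model %in% c("JC", "K80")) pi <- rep(0.25, 4)
  if (model == "JC") exch <- rep(1, 6)
  if (model %in% c("K80", "HKY")) exch <- c(kappa, 1, 1, 1, 1, kappa)
  if (length(pi) != 4 || any(pi <= 0)) stop("pi must be 4 positive frequencies")
  pi <- pi / sum(pi)
  if (length(exch) != 6 || any(exch <= 0)) stop("need 6 positive exchangeabilities")
  if (!is.null(alpha) && alpha <= 0) stop("alpha must be positive")
  if (is.null(alpha)) ncat <- 1L
  structure(list(model = model, pi = pi, exch = exch, kappa = kappa,
                 alpha = alpha, ncat = as.integer(ncat),
                 alpha_prior = alpha_prior),
            class = "subst_model")
}

#' GTR rate matrix (generator)
#'
#' Builds the 4x4 generator `Q[i,j] = s_ij * pi_j` from the model's
#' exchangeabilities and frequencies, scaled so `sum_i pi_i * (-Q[i,i]) = 1`
#' (branch lengths in expected substitutions per site).
#'
#' @param m A [subst_model()].
#' @return A 4x4 matrix with rows/cols in T, C, A, G order.
#' @export
rate_matrix <- function(m) {
  e <- m$exch; pi <- m$pi
  S <- matrix(0, 4, 4)
  S[1, 2] <- S[2, 1] <- e[1]  # T-C
  S[1, 3] <- S[3, 1] <- e[2]  # T-A
  S[1, 4] <- S[4, 1] <- e[3]  # T-G
  S[2, 3] <- S[3, 2] <- e[4]  # C-A
  S[2, 4] <- S[4, 2] <- e[5]  # C-G
  S[3, 4] <- S[4, 3] <- e[6]  # A-G
  Q <- S * rep(pi, each = 4)
  diag(Q) <- -rowSums(Q)
  Q / sum(pi * -diag(Q))
}

## spectral decomposition of a reversible Q via the symmetrised matrix
## B = diag(sqrt(pi)) Q diag(1/sqrt(pi)); returns U, Uinv, lam with
## Q = U diag(lam) Uinv.
eigen_Q <- function(Q, pi) {
  sp <- sqrt(pi)
  B <- Q * (sp %o% (1 / sp))
  B <- (B + t(B)) / 2
  ei <- eigen(B, symmetric = TRUE)
  list(U = ei$vectors / sp, Uinv = t(ei$vectors) * rep(sp, each = 4),
       lam = ei$values)
}

#' Transition probability matrix P(t) = exp(Qt)
#'
#' @param Q A generator from [rate_matrix()] (or any reversible generator
#'   with the stationary distribution recoverable from its rows).
#' @param t Branch length (>= 0).
#' @param pi Stationary frequencies (taken from `Q` via its left null vector
#'   if missing).
#' @return A 4x4 stochastic matrix; `P(0)` is the identity.
#' @export
transition_probs <- function(Q, t, pi = NULL) {
  if (t < 0) stop("negative branch length")
  if (is.null(pi)) {
    ns <- eigen(t(Q))
    v <- Re(ns$vectors[, which.min(abs(ns$values))])
    pi <- v / sum(v)
  }
  eg <- eigen_Q(Q, pi)
  P <- eg$U %*% (exp(eg$lam * t) * eg$Uinv)
  P[P < 0] <- 0
  P / rowSums(P)
}

#' Discrete-gamma category rates
#'
#' `k` equal-probability categories with category-mean rates under a
#' Gamma(alpha, alpha) distribution (mean 1); the returned rates average
#' exactly 1.
#'
#' @param alpha Shape (> 0).
#' @param k Number of categories (>= 1).
#' @return Numeric vector of `k` rates.
#' @export
discrete_gamma_rates <- function(alpha, k) {
  if (k == 1) return(1)
  cuts <- stats::qgamma(seq(0, 1, length.out = k + 1), alpha, alpha)
  ## mean within each slice: k * (F_{alpha+1}(b) - F_{alpha+1}(a)) for G(alpha, alpha)
  p <- stats::pgamma(cuts, alpha + 1, alpha)
  r <- k * diff(p)
  r / mean(r) * 1  # guard against roundoff; already ~1
}

## ---- alignments ---------------------------------------------------------

IUPAC <- list(
  T = "T", C = "C", A = "A", G = "G", U = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
  V = c("A", "C", "G"), N = c("T", "C", "A", "G"),
  "-" = c("T", "C", "A", "G"), "?" = c("T", "C", "A", "G"))
BASES <- c("T", "C", "A", "G")

## character matrix -> per-tip partial rows (4*ntip x npat) + weights
compress_alignment <- function(aln, tip.label) {
  aln <- toupper(aln)
  if (is.null(rownames(aln))) stop("alignment must have row names")
  idx <- match(tip.label, rownames(aln))
  if (anyNA(idx)) stop("alignment lacks sequence for tip: ",
                       tip.label[which(is.na(idx))[1]])
  aln <- aln[idx, , drop = FALSE]
  ntip <- nrow(aln)
  key <- apply(aln, 2, paste, collapse = "")
  tab <- table(key)
  pats <- names(tab)
  npat <- length(pats)
  part <- matrix(0, 4 * ntip, npat)
  for (p in seq_len(npat)) {
    chars <- strsplit(pats[p], "")[[1]]
    for (t in seq_len(ntip)) {
      states <- IUPAC[[chars[t]]]
      if (is.null(states)) stop("unknown state '", chars[t], "' in alignment")
      part[4 * (t - 1) + match(states, BASES), p] <- 1
    }
  }
  list(part = part, weights = as.numeric(tab), nsites = ncol(aln))
}

#' Phylogenetic log-likelihood by Felsenstein pruning
#'
#' Sums over ancestral states by pruning, over `ncat` equal-probability
#' discrete-gamma rate categories; IUPAC ambiguity codes and gaps contribute
#' a partial likelihood of 1 for every compatible state (treated as missing,
#' never stripped).
#'
#' @param aln Character matrix (sequences x sites) with row names matching
#'   the gene-tree tip labels, or a precompressed object from the internal
#'   pattern compressor.
#' @param gt A `gene_tree`.
#' @param lengths Per-node branch lengths (edge above each node), e.g. from
#'   [gene_tree_branch_lengths()].
#' @param m A [subst_model()].
#' @return Scalar log-likelihood.
#' @export
log_likelihood <- function(aln, gt, lengths, m) {
  cmp <- if (is.list(aln) && !is.null(aln$part)) aln
         else compress_alignment(aln, gt$tip.label)
  if (gt$n == 1) {
    ## single sequence: product of stationary frequencies
    part <- cmp$part[seq_len(4), , drop = FALSE]
    return(sum(cmp$weights * log(colSums(part * m$pi))))
  }
  Q <- rate_matrix(m)
  eg <- eigen_Q(Q, m$pi)
  crates <- discrete_gamma_rates(if (is.null(m$alpha)) 1 else m$alpha,
                                 if (is.null(m$alpha)) 1L else m$ncat)
  po <- gt_postorder(gt)
  ints <- po[po > gt$n]
  c1 <- vapply(ints, function(i) gt$children[[i]][1], 1L)
  c2 <- vapply(ints, function(i) gt$children[[i]][2], 1L)
  cpp_pruning_loglik(gt$n, gt$nnode, gt$root, ints, c1, c2,
                     as.numeric(lengths), cmp$part, cmp$weights,
                     m$pi, eg$U, eg$Uinv, eg$lam, crates)
}

#' Simulate an alignment along a gene tree
#'
#' Root states are drawn from the stationary frequencies; each site is
#' assigned one of the discrete-gamma rate categories; states then evolve
#' edge by edge through `P(length * rate)`.  The same discrete-gamma
#' machinery is used here and in [log_likelihood()], so simulation and
#' inference share one model exactly.
#'
#' @param gt A `gene_tree`.
#' @param lengths Per-node branch lengths.
#' @param m A [subst_model()].
#' @param nsites Number of sites.
#' @return Character matrix (sequences x sites) with tip labels as row names.
#' @export
simulate_alignment <- function(gt, lengths, m, nsites) {
  Q <- rate_matrix(m)
  eg <- eigen_Q(Q, m$pi)
  crates <- discrete_gamma_rates(if (is.null(m$alpha)) 1 else m$alpha,
                                 if (is.null(m$alpha)) 1L else m$ncat)
  k <- length(crates)
  cat_of <- sample.int(k, nsites, replace = TRUE)
  states <- matrix(0L, gt$nnode, nsites)
  states[gt$root, ] <- sample.int(4, nsites, replace = TRUE, prob = m$pi)
  ord <- rev(gt_postorder(gt))  # parents before children
  for (id in ord) {
    pa <- gt$parent[id]
    if (pa == 0L) next
    if (lengths[id] == 0) { states[id, ] <- states[pa, ]; next }
    for (c in seq_len(k)) {
      sel <- which(cat_of == c)
      if (!length(sel)) next
      P <- eg$U %*% (exp(eg$lam * lengths[id] * crates[c]) * eg$Uinv)
      P[P < 0] <- 0
      P <- P / rowSums(P)
      cum <- t(apply(P, 1, cumsum))
      u <- stats::runif(length(sel))
      from <- states[pa, sel]
      states[id, sel] <- 1L + (u > cum[from, 1]) + (u > cum[from, 2]) +
        (u > cum[from, 3])
    }
  }
  out <- matrix(BASES[states[seq_len(gt$n), , drop = FALSE]], gt$n, nsites)
  rownames(out) <- gt$tip.label
  out
}
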