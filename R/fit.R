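#' Full model specification for the MSC with relaxed clocks
#'
#' Bundles the species tree (topology, starting divergence times and
#' population sizes), the priors on `tau`/`theta`, the clock model and the
#' substitution-model configuration into one object, the analogue of a model
#' formula: [mscfit()] fits it to multilocus data, and [simulate.msc_model()]
#' generates data from it.
#'
#' @param tree A [species_tree()] with `tau` and `theta` set (they are the
#'   simulation truth and the chain's starting point; under inference they
#'   are sampled).
#' @param prior An [msc_prior()].
#' @param clock A [clock_model()].
#' @param subst A [subst_config()] (inference priors) -- the simulator draws
#'   locus substitution parameters from the same Dirichlet/gamma families.
#' @return An object of class `msc_model`.
#' @export
msc_model <- function(tree, prior = msc_prior(), clock = clock_model(1),
                      subst = subst_config("JC", ncat = 1L)) {
  stopifnot(inherits(tree, "species_tree"), inherits(prior, "msc_prior"),
            inherits(clock, "clock_model"))
  structure(list(tree = tree, prior = prior, clock = clock, subst = subst),
            class = "msc_model")
}

#' @export
print.msc_model <- function(x, ...) {
  cat("MSC + relaxed-clock model\n")
  print(x$tree)
  print(x$clock)
  cat("Substitution model:", x$subst$model,
      if (x$subst$ncat > 1) sprintf("+ Gamma(%d categories)", x$subst$ncat) else "",
      "\n")
  invisible(x)
}

#' Fit the MSC + relaxed-clock model by MCMC
#'
#' Runs the Metropolis-Hastings sampler targeting the joint posterior of
#' species divergence times, population sizes, per-locus rates and variance
#' parameters, branch rates, substitution parameters and gene trees given
#' multilocus alignments.  With `mcmc_control(search = TRUE)` the species
#' tree itself is sampled through NNI moves (small trees); otherwise it is
#' fixed and only its parameters are estimated.
#'
#' @param model An [msc_model()].
#' @param data A dataset: either the result of [simulate.msc_model()] /
#'   [msc_data()] or `NULL` for a prior-only run (then give `L` and `nseq`).
#' @param control An [mcmc_control()].
#' @param L,nseq Number of loci and sequences per species, for prior-only
#'   runs without data.
#' @param init `NULL` (start from prior draws) or `"truth"`: when `data` is
#'   a simulated dataset carrying its latent variables, start the chain at
#'   them (a warm start; the stationary distribution is unaffected).
#' @param seed Optional integer seed.
#' @return An object of class `mscfit`: the trace, summaries and final
#'   state.  Methods: `print`, `summary`, `coef` (posterior means), `plot`
#'   (trace and density per parameter), `logLik` (posterior mean
#'   log-likelihood).
#' @export
mscfit <- function(model, data = NULL, control = mcmc_control(),
                   L = NULL, nseq = 1L, init = NULL, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (control$search && model$clock$type == 3)
    warning("species-tree search under the correlated-rates model mixes poorly; ",
            "results for more than ~20 loci should be treated as unreliable")
  if (identical(init, "truth")) {
    if (!inherits(data, "msc_sim")) stop("init = 'truth' needs a simulated dataset")
    init <- list(gene_trees = data$gene_trees, rates = data$rates,
                 subst = data$subst, clock_type = data$clock$type)
  }
  e <- mcmc_state(model$tree, model$prior, model$clock, model$subst,
                  data = data, L = L, nseq = nseq,
                  usedata = control$usedata && !is.null(data), init = init)
  trace <- run_mcmc(e, control)
  fit <- structure(list(model = model, trace = trace,
                        summary = summarize_trace(trace),
                        control = control),
                   class = "mscfit")
  fit
}

#' @export
print.mscfit <- function(x, ...) {
  cat("MSC relaxed-clock fit:", ncol(x$trace$samples), "monitored quantities,",
      nrow(x$trace$samples), "samples\n")
  cat("MAP species tree:", x$summary$topology_names[1],
      sprintf("(P = %.3f)\n", x$summary$topologies[1]))
  invisible(x)
}

#' @export
summary.mscfit <- function(object, ...) object$summary

#' @export
coef.mscfit <- function(object, ...) {
  st <- stats::setNames(object$summary$table$mean, rownames(object$summary$table))
  st[names(st) != "lnP"]
}

#' @export
logLik.mscfit <- function(object, ...) {
  ll <- mean(object$trace$samples[, "lnP"])
  structure(ll, class = "logLik", df = NA_integer_)
}

#' @export
plot.mscfit <- function(x, pars = NULL, ...) {
  sm <- x$trace$samples
  if (is.null(pars)) pars <- setdiff(colnames(sm), "lnP")[1:min(4, ncol(sm) - 1)]
  op <- graphics::par(mfrow = c(length(pars), 2), mar = c(3, 3, 1.5, 0.5))
  on.exit(graphics::par(op))
  for (p in pars) {
    graphics::plot(sm[, p], type = "l", main = p, xlab = "", ylab = "")
    graphics::plot(stats::density(sm[, p]), main = "", xlab = "", ylab = "")
  }
  invisible(x)
}

#' Bundle alignments and their species map into a dataset
#'
#' @param alignments List of character matrices (sequences x sites), row
#'   names labelling sequences.
#' @param species Either a per-locus list of integer/character species
#'   assignments (one per sequence) or a single named map (an Imap:
#'   sequence-label prefix -> species) applied to every locus.  Labels of
#'   the form `"individual^species"` are parsed directly when `species` is
#'   `NULL`.
#' @param tree The `species_tree` the species names refer to.
#' @return A list of class `msc_data` with `$alignments` and `$species`.
#' @export
msc_data <- function(alignments, species = NULL, tree) {
  L <- length(alignments)
  spl <- vector("list", L)
  for (i in seq_len(L)) {
    labs <- rownames(alignments[[i]])
    sp <- if (is.null(species)) {
      parts <- sub("^.*\\^", "", labs)
      parts
    } else if (is.list(species)) species[[i]] else unname(species[match_imap(labs, species)])
    idx <- if (is.character(sp)) match(sp, tree$tip.label) else as.integer(sp)
    if (anyNA(idx)) stop("locus ", i, ": sequence cannot be mapped to a species")
    spl[[i]] <- idx
  }
  structure(list(alignments = alignments, species = spl), class = "msc_data")
}

## match sequence labels against an Imap (named vector individual -> species)
match_imap <- function(labs, imap) {
  ind <- sub("\\^.*$", "", labs)
  i <- match(ind, names(imap))
  if (anyNA(i)) stop("no Imap entry for individual: ", ind[which(is.na(i))[1]])
  i
}
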