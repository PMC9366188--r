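#' Shortest (highest posterior density) interval
#'
#' @param x Numeric sample.
#' @param prob Coverage probability (default 0.95).
#' @return `c(lower, upper)`, the shortest interval containing `prob` of the
#'   sample; zero width for a constant sample.
#' @export
hpd_interval <- function(x, prob = 0.95) {
  x <- sort(x)
  n <- length(x)
  if (n == 0) stop("empty sample")
  k <- max(1L, ceiling(prob * n))
  if (k >= n) return(c(x[1], x[n]))
  width <- x[(k + 1):n] - x[1:(n - k)]
  i <- which.min(width)
  c(x[i], x[i + k])
}

#' Effective sample size of an autocorrelated chain
#'
#' Spectral estimate through an AR fit (the spectral density at frequency
#' zero), capped at the chain length.
#'
#' @param x Numeric chain.
#' @return Scalar ESS.
#' @export
effective_size <- function(x) {
  n <- length(x)
  v <- stats::var(x)
  if (!is.finite(v) || v == 0) return(n)
  a <- try(stats::ar(x, order.max = min(20, n %/% 4)), silent = TRUE)
  if (inherits(a, "try-error") || length(a$ar) == 0) return(n)
  s0 <- a$var.pred / (1 - sum(a$ar))^2
  min(n, n * v / s0)
}

#' Summarize an MCMC trace
#'
#' Posterior means, shortest 95% HPD intervals and effective sample sizes
#' per monitored parameter, plus the posterior distribution over species-tree
#' topologies and the MAP tree (ties broken by first occurrence).
#'
#' @param trace An `mcmc_trace` from the sampler.
#' @param prob HPD coverage probability.
#' @return A list of class `mcmc_summary` with `table` (data frame) and
#'   `topologies` (named probabilities, MAP first).
#' @export
summarize_trace <- function(trace, prob = 0.95) {
  x <- trace$samples
  if (nrow(x) == 0) stop("empty trace")
  tab <- data.frame(
    mean = colMeans(x),
    median = apply(x, 2, stats::median),
    hpd_lower = apply(x, 2, function(v) hpd_interval(v, prob)[1]),
    hpd_upper = apply(x, 2, function(v) hpd_interval(v, prob)[2]),
    ess = apply(x, 2, effective_size))
  tp <- table(trace$topology)
  tp <- tp / sum(tp)
  first_seen <- vapply(names(tp), function(t) match(t, trace$topology), 1L)
  ord <- order(-as.numeric(tp), first_seen)
  tp <- tp[ord]
  structure(list(table = tab, topologies = as.numeric(tp),
                 topology_names = names(tp), prob = prob),
            class = "mcmc_summary")
}

#' @export
print.mcmc_summary <- function(x, ...) {
  cat("Posterior summary (", format(100 * x$prob), "% HPD):\n", sep = "")
  print(round(x$table, 5))
  if (length(x$topologies) > 1 || TRUE) {
    cat("\nSpecies-tree topologies:\n")
    for (i in seq_along(x$topologies))
      cat(sprintf("  %.3f  %s%s\n", x$topologies[i], x$topology_names[i],
                  if (i == 1) "  (MAP)" else ""))
  }
  invisible(x)
}
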