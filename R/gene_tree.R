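#' Gene trees embedded in a species tree
#'
#' A gene tree is the genealogy of the sequences sampled at one locus: a
#' rooted binary topology with coalescent node ages (tips at 0) and a map from
#' each tip to the species it was sampled from.  Under the multispecies
#' coalescent every coalescence must happen inside a population that is
#' ancestral to (or is) every species carrying the node's descendant tips,
#' within that population's time interval.  Each gene-tree branch may traverse
#' several populations; the *segment map* records, for every branch, the
#' ordered populations it crosses with entry and exit times, and is the basis
#' for converting coalescent times plus per-population rates into branch
#' lengths.
#'
#' @param parent Integer vector over the `2n-1` gene-tree nodes (tips first),
#'   0 at the root.
#' @param age Numeric node ages (tips 0).
#' @param species Integer vector of length `n`: species-tree tip id for each
#'   gene-tree tip.
#' @param tip.label Optional tip labels (default `"<species>^<i>"` style).
#' @param st Optional `species_tree`; if given, the lineage-to-population map
#'   is computed immediately.
#' @return An object of class `gene_tree`.
#' @export
gene_tree <- function(parent, age, species, tip.label = NULL, st = NULL) {
  n <- length(species)
  nn <- length(parent)
  if (nn != 2L * n - 1L) stop("parent must have length 2n-1")
  children <- vector("list", nn)
  root <- 0L
  for (id in seq_len(nn)) {
    p <- parent[id]
    if (p == 0L) root <- id else children[[p]] <- c(children[[p]], id)
  }
  if (is.null(tip.label)) tip.label <- paste0("s", seq_len(n))
  gt <- structure(list(
    n = n, nnode = nn, root = root, parent = as.integer(parent),
    children = children, age = as.numeric(age),
    species = as.integer(species), tip.label = tip.label
  ), class = "gene_tree")
  if (!is.null(gt) && any(gt$age[seq_len(n)] != 0)) stop("gene-tree tips must be at age 0")
  if (!is.null(st)) gt <- refresh_embedding(gt, st)
  gt
}

gt_postorder <- function(gt) {
  out <- integer(0)
  stack <- gt$root
  ## iterative: reverse preorder == postorder for output order handling
  visit <- integer(0)
  while (length(stack)) {
    id <- stack[[length(stack)]]
    stack <- stack[-length(stack)]
    visit <- c(visit, id)
    stack <- c(stack, gt$children[[id]])
  }
  rev(visit)
}

## species-tree MRCA node of each gene-tree node's descendant species
gt_species_mrca <- function(gt, st) {
  spm <- integer(gt$nnode)
  for (id in gt_postorder(gt)) {
    if (id <= gt$n) spm[id] <- gt$species[id]
    else {
      kids <- gt$children[[id]]
      spm[id] <- st_mrca(st, spm[kids[1]], spm[kids[2]])
    }
  }
  spm
}

## population (species-tree node id) in which each gene-tree node resides:
## the population on the path mrca -> root whose interval contains the age.
## Returns 0 for a node lying below the floor of its MRCA population.
gt_node_pops <- function(gt, st, spm = NULL) {
  if (is.null(spm)) spm <- gt_species_mrca(gt, st)
  pop <- integer(gt$nnode)
  for (id in seq_len(gt$nnode)) {
    t <- gt$age[id]
    p <- spm[id]
    if (t < st$tau[p]) { pop[id] <- 0L; next }
    while (st$parent[p] > 0L && st$tau[st$parent[p]] <= t) p <- st$parent[p]
    pop[id] <- p
  }
  pop
}

## recompute the embedding (MRCA map, populations, segment map) from scratch
refresh_embedding <- function(gt, st) {
  spm <- gt_species_mrca(gt, st)
  pop <- gt_node_pops(gt, st, spm)
  gt$spmrca <- spm
  gt$pop <- pop
  gt$segments <- if (any(pop == 0L)) NULL else segment_map(gt, st, pop)
  gt
}

## Segment map: for each non-root node id, a matrix with columns
## (pop, from, to) partitioning the edge id -> parent(id).
segment_map <- function(gt, st, pop = gt$pop) {
  segs <- vector("list", gt$nnode)
  for (id in seq_len(gt$nnode)) {
    pa <- gt$parent[id]
    if (pa == 0L) next
    t0 <- gt$age[id]; t1 <- gt$age[pa]
    p <- pop[id]
    rows <- list()
    enter <- t0
    while (st$parent[p] > 0L && st$tau[st$parent[p]] < t1) {
      rows[[length(rows) + 1L]] <- c(p, enter, st$tau[st$parent[p]])
      enter <- st$tau[st$parent[p]]
      p <- st$parent[p]
    }
    rows[[length(rows) + 1L]] <- c(p, enter, t1)
    m <- do.call(rbind, rows)
    colnames(m) <- c("pop", "from", "to")
    segs[[id]] <- m
  }
  segs
}

#' Check that a gene tree is compatible with a species tree
#'
#' Verifies the multispecies-coalescent embedding constraints: tips at age 0,
#' parent older than child, every coalescent node at an age at or above the
#' divergence time of the most recent population containing all its
#' descendant species, and (when a segment map is attached) that each edge's
#' segments exactly partition the edge's time span.
#'
#' @param gt A `gene_tree`.
#' @param st A `species_tree`.
#' @return A list with elements `ok` (logical) and `message` (naming the
#'   first violation, or `"ok"`).
#' @export
validate_compatibility <- function(gt, st) {
  fail <- function(msg) list(ok = FALSE, message = msg)
  if (any(gt$age[seq_len(gt$n)] != 0)) return(fail("gene-tree tip not at age 0"))
  for (id in seq_len(gt$nnode)) {
    pa <- gt$parent[id]
    if (pa > 0L && gt$age[pa] <= gt$age[id])
      return(fail(sprintf("node %d not older than its child %d", pa, id)))
  }
  spm <- gt_species_mrca(gt, st)
  for (id in seq_len(gt$nnode)[-seq_len(gt$n)]) {
    if (gt$age[id] < st$tau[spm[id]])
      return(fail(sprintf(
        "coalescence %d at age %g below the floor tau(%s)=%g",
        id, gt$age[id], st$clade[spm[id]], st$tau[spm[id]])))
  }
  if (!is.null(gt$segments)) {
    for (id in seq_len(gt$nnode)) {
      m <- gt$segments[[id]]
      if (is.null(m)) next
      span <- gt$age[gt$parent[id]] - gt$age[id]
      if (abs(sum(m[, "to"] - m[, "from"]) - span) > 1e-9 * max(1, span))
        return(fail(sprintf("segments of edge %d do not partition its span", id)))
      if (m[1, "from"] != gt$age[id] || m[nrow(m), "to"] != gt$age[gt$parent[id]])
        return(fail(sprintf("segments of edge %d do not match its endpoints", id)))
    }
  }
  list(ok = TRUE, message = "ok")
}

#' @export
print.gene_tree <- function(x, ...) {
  cat("Gene tree with", x$n, "tips, root age",
      format(x$age[x$root], digits = 6), "\n")
  invisible(x)
}

#' Write a gene tree as a plain Newick string with branch lengths
#'
#' @param gt A `gene_tree`.
#' @param lengths Optional per-node branch lengths (edge above each node);
#'   defaults to time spans (age differences).
#' @param digits Significant digits.
#' @return A Newick string.
#' @export
write_gene_tree_newick <- function(gt, lengths = NULL, digits = 10) {
  if (is.null(lengths)) {
    lengths <- numeric(gt$nnode)
    for (id in seq_len(gt$nnode))
      if (gt$parent[id] > 0L) lengths[id] <- gt$age[gt$parent[id]] - gt$age[id]
  }
  fmt <- function(x) format(x, digits = digits, scientific = FALSE, trim = TRUE)
  rec <- function(id) {
    out <- if (id <= gt$n) gt$tip.label[id]
    else {
      kids <- gt$children[[id]]
      paste0("(", rec(kids[1]), ",", rec(kids[2]), ")")
    }
    if (gt$parent[id] > 0L) out <- paste0(out, ":", fmt(lengths[id]))
    out
  }
  paste0(rec(gt$root), ";")
}
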