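## Species-tree NNI move for Bayesian tree search (small trees).
##
## The move swaps one child of an internal non-root node k with k's sibling.
## Divergence times and thetas stay attached to their node ids, so the
## parameters transfer by branch identity (the clade subtended by k changes,
## e.g. tau_AB becomes tau_AC); per-locus branch rates transfer the same
## way, which changes gene-tree branch lengths and hence the likelihood even
## when a gene tree itself needs no rearrangement.  Gene-tree nodes whose
## two child lineages no longer share a population at the node's age are
## pruned and regrafted at the same age onto a lineage drawn uniformly from
## the population of the pruned child; the proposal probability of a
## rearranged gene tree (summed over all choice paths that produce it, both
## forwards and backwards) enters the Hastings ratio.

## species-MRCA of every gene node given a parent vector (ascending ages;
## nodes with a single attached child inherit that child's set)
spm_from_par <- function(par, age, species, st) {
  gn <- length(par)
  n <- length(species)
  spm <- integer(gn)
  spm[seq_len(n)] <- species
  ints <- order(age[(n + 1L):gn]) + n
  for (id in ints) {
    kids <- which(par == id)
    if (length(kids) == 0L) next
    s <- spm[kids[1]]
    for (k in kids[-1]) s <- st_mrca(st, s, spm[k])
    spm[id] <- s
  }
  spm
}

## first (youngest) gene node whose child lineages are in different
## populations of 'st' at the node's age; 0 if none
first_conflict <- function(par, age, species, st) {
  n <- length(species)
  gn <- length(par)
  spm <- spm_from_par(par, age, species, st)
  ints <- order(age[(n + 1L):gn]) + n
  for (id in ints) {
    kids <- which(par == id)
    if (length(kids) != 2L) next
    p1 <- lineage_pop_at(st, spm[kids[1]], age[id])
    p2 <- lineage_pop_at(st, spm[kids[2]], age[id])
    if (p1 == 0L || p2 == 0L || p1 != p2) return(id)
  }
  0L
}

## candidate reattachment lineages for 'moved' (child of detached node id)
## at time t in the spliced tree: edges crossing t (the spliced root counts
## as extending upward) whose lineage lies in the same population
regraft_candidates <- function(par_spliced, age, species, st, id, moved, t) {
  spm <- spm_from_par(par_spliced, age, species, st)
  pm <- lineage_pop_at(st, spm[moved], t)
  if (pm == 0L) return(integer(0))
  gn <- length(par_spliced)
  out <- integer(0)
  for (v in seq_len(gn)) {
    if (v == id || v == moved) next
    pv <- par_spliced[v]
    if (pv == id) next                 # only 'moved' hangs from id
    if (age[v] >= t) next
    if (pv != 0L && age[pv] <= t) next
    if (lineage_pop_at(st, spm[v], t) == pm) out <- c(out, v)
  }
  out
}

## regraft on the unspliced parent vector: kept is spliced to id's old
## parent, id is inserted into z's edge with children (moved, z); z is never
## id, kept, or a child of id, so its parent entry is still valid here
apply_regraft <- function(par, id, moved, kept, z) {
  pid <- par[id]; pz <- par[z]
  par[kept] <- pid
  par[id] <- pz
  par[z] <- id
  par
}

## sample a remapping of one gene tree onto st_new; returns NULL if stuck
remap_propose <- function(gt, st_new) {
  par <- gt$parent
  repeat {
    id <- first_conflict(par, gt$age, gt$species, st_new)
    if (id == 0L) break
    kids <- which(par == id)
    mi <- sample(2L, 1L)
    moved <- kids[mi]; kept <- kids[3L - mi]
    sp <- par
    sp[kept] <- sp[id]; sp[id] <- -1L
    cands <- regraft_candidates(sp, gt$age, gt$species, st_new, id, moved,
                                gt$age[id])
    if (!length(cands)) return(NULL)
    z <- if (length(cands) == 1L) cands else sample(cands, 1L)
    par <- apply_regraft(par, id, moved, kept, z)
  }
  g2 <- gt; g2$parent <- par
  g2
}

## total proposal probability of transforming gt into target_par under
## st_new, summing over all (moved child, target lineage) choice paths
remap_prob <- function(gt, st_new, target_par) {
  rec <- function(par) {
    id <- first_conflict(par, gt$age, gt$species, st_new)
    if (id == 0L) return(as.numeric(all(par == target_par)))
    kids <- which(par == id)
    tot <- 0
    for (mi in 1:2) {
      moved <- kids[mi]; kept <- kids[3L - mi]
      sp <- par
      sp[kept] <- sp[id]; sp[id] <- -1L
      cands <- regraft_candidates(sp, gt$age, gt$species, st_new, id, moved,
                                  gt$age[id])
      if (!length(cands)) next
      for (z in cands) {
        p2 <- apply_regraft(par, id, moved, kept, z)
        tot <- tot + 0.5 / length(cands) * rec(p2)
      }
    }
    tot
  }
  rec(gt$parent)
}

## one NNI proposal on the species tree with full gene-tree remapping
move_species_tree <- function(e) {
  st <- e$st
  if (st$s < 3) return(invisible())
  cand <- setdiff(internal_nodes(st), st$root)
  if (!length(cand)) return(invisible())
  k <- if (length(cand) == 1L) cand else sample(cand, 1L)
  p <- st$parent[k]
  sib <- setdiff(st$children[[p]], k)
  ck <- st$children[[k]][sample(2L, 1L)]
  if (st$tau[sib] >= st$tau[k]) { bump(e, "nni", FALSE); return(invisible()) }
  st2 <- st
  st2$children[[k]] <- c(setdiff(st$children[[k]], ck), sib)
  st2$children[[p]] <- c(k, ck)
  st2$parent[sib] <- k
  st2$parent[ck] <- p
  st2$clade <- clade_keys(st2)
  if (!satisfies_constraints(st2)) { bump(e, "nni", FALSE); return(invisible()) }

  gts2 <- e$gt
  lqf <- 0; lqb <- 0
  for (i in seq_len(e$L)) {
    g2 <- remap_propose(e$gt[[i]], st2)
    if (is.null(g2)) { bump(e, "nni", FALSE); return(invisible()) }
    gts2[[i]] <- g2
    if (!identical(g2$parent, e$gt[[i]]$parent)) {
      qf <- remap_prob(e$gt[[i]], st2, g2$parent)
      qb <- remap_prob(g2, st, e$gt[[i]]$parent)
      if (qb <= 0) { bump(e, "nni", FALSE); return(invisible()) }
      lqf <- lqf + log(qf); lqb <- lqb + log(qb)
    }
  }
  lr <- lqb - lqf +
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
  bump(e, "nni", ok)
}
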