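#' Rooted species trees for the multispecies coalescent
#'
#' A species tree couples a rooted binary topology over `s` species with node
#' ages `tau` (divergence times, in expected substitutions per site; tips at
#' age 0) and per-population mutation-scaled sizes `theta` (theta = 4*N*mu, one
#' per branch including the root stem).  Internal nodes are addressed by the
#' set of tip labels they subtend, so that parameters can be transferred by
#' clade identity when the topology changes.
#'
#' @param newick A rooted binary Newick string.  Internal node ages may be
#'   given inline as `:age` and population sizes as `#theta` (both optional);
#'   values supplied through `tau`/`theta` override inline annotations.
#' @param tau Named numeric vector of internal-node ages; names are clade keys
#'   (sorted tip labels joined by `,`, e.g. `"A,B"`).
#' @param theta Named numeric vector of population sizes; names are tip labels
#'   or clade keys.  The entry for the root clade is the root-stem theta.
#' @param constraints Optional list of character vectors of tip labels, each
#'   declaring a clade that the topology must (and any proposed topology will)
#'   respect.
#' @param outgroup Optional single tip label; shorthand for the constraint
#'   that all remaining species form a clade.
#' @return An object of class `species_tree`.
#' @examples
#' st <- species_tree("((A#0.01, B#0.01):0.01#0.012, C#0.022):0.02#0.025;")
#' @export
species_tree <- function(newick, tau = NULL, theta = NULL,
                         constraints = NULL, outgroup = NULL) {
  st <- parse_newick_annotated(newick)
  if (!is.null(tau)) {
    idx <- match(names(tau), st$clade)
    if (anyNA(idx)) stop("unknown clade in 'tau': ", names(tau)[is.na(idx)][1])
    st$tau[idx] <- unname(tau)
  }
  if (!is.null(theta)) {
    idx <- match(names(theta), st$clade)
    if (anyNA(idx)) stop("unknown clade in 'theta': ", names(theta)[is.na(idx)][1])
    st$theta[idx] <- unname(theta)
  }
  if (!is.null(outgroup)) {
    if (!outgroup %in% st$tip.label) stop("outgroup is not a tip label")
    constraints <- c(constraints, list(setdiff(st$tip.label, outgroup)))
  }
  st$constraints <- constraints
  st$outgroup <- outgroup
  validate_species_tree(st)
  st
}

## ---- annotated Newick dialect ------------------------------------------

## Parses rooted binary Newick with optional ':age' and '#theta' annotations.
## Tips are numbered 1..s in order of appearance, internal nodes s+1..2s-1 in
## the order their subtree closes (postorder); the root is node 2s-1.
parse_newick_annotated <- function(text) {
  text <- gsub("[[:space:]]", "", text)
  text <- sub(";$", "", text)
  chars <- strsplit(text, "")[[1]]
  pos <- 1L
  n_chars <- length(chars)
  tips <- character(0)
  nodes <- list()  # each: list(children=, age=, theta=, label=)

  peek <- function() if (pos <= n_chars) chars[pos] else ""
  read_token <- function(allowed) {
    start <- pos
    while (pos <= n_chars && grepl(allowed, chars[pos])) pos <<- pos + 1L
    paste(chars[start:(pos - 1L)], collapse = "")
  }
  read_number <- function() as.numeric(read_token("[0-9eE+.\\-]"))

  parse_clade <- function() {
    if (peek() == "(") {
      pos <<- pos + 1L
      left <- parse_clade()
      if (peek() != ",") stop("expected ',' at position ", pos)
      pos <<- pos + 1L
      right <- parse_clade()
      if (peek() != ")") stop("expected ')' at position ", pos)
      pos <<- pos + 1L
      label <- if (grepl("[A-Za-z0-9_]", peek())) read_token("[A-Za-z0-9_.\\^]") else ""
      node <- list(children = c(left, right), age = NA_real_,
                   theta = NA_real_, label = label, tip = NA_integer_)
    } else {
      label <- read_token("[A-Za-z0-9_.\\^]")
      if (!nzchar(label)) stop("expected tip label at position ", pos)
      tips <<- c(tips, label)
      node <- list(children = integer(0), age = 0, theta = NA_real_,
                   label = label, tip = length(tips))
    }
    while (peek() %in% c(":", "#")) {
      what <- peek(); pos <<- pos + 1L
      val <- read_number()
      if (what == ":") node$age <- val else node$theta <- val
    }
    nodes[[length(nodes) + 1L]] <<- node
    length(nodes)
  }

  root_i <- parse_clade()
  if (pos <= n_chars) stop("trailing characters in Newick string")
  s <- length(tips)
  if (s < 2) stop("species tree needs at least 2 tips")
  nn <- 2L * s - 1L
  if (length(nodes) != nn) stop("tree is not binary")

  ## renumber: tips 1..s by appearance, internals s+1.. in close (postorder) order
  newid <- integer(nn)
  next_int <- s
  for (i in seq_along(nodes)) {
    if (length(nodes[[i]]$children) == 0L) newid[i] <- nodes[[i]]$tip
    else { next_int <- next_int + 1L; newid[i] <- next_int }
  }
  parent <- integer(nn)
  children <- vector("list", nn)
  age <- numeric(nn); th <- rep(NA_real_, nn)
  label <- character(nn)
  for (i in seq_along(nodes)) {
    id <- newid[i]
    kids <- newid[nodes[[i]]$children]
    children[[id]] <- kids
    for (k in kids) parent[k] <- id
    age[id] <- if (id <= s) 0 else nodes[[i]]$age
    th[id] <- nodes[[i]]$theta
    label[id] <- nodes[[i]]$label
  }
  root <- newid[root_i]
  st <- structure(list(
    s = s, nnode = nn, root = root, tip.label = tips,
    parent = parent, children = children,
    tau = age, theta = th, node.label = label,
    constraints = NULL, outgroup = NULL
  ), class = "species_tree")
  st$clade <- clade_keys(st)
  st
}

#' Write a species tree in the annotated Newick dialect
#'
#' Emits internal-node ages as `:age` and population sizes as `#theta`, the
#' same dialect [species_tree()] reads; reading the result back reproduces
#' the tree exactly.
#'
#' @param st A `species_tree`.
#' @param digits Significant digits used for numbers (default keeps full
#'   double precision).
#' @return A single Newick string, terminated by `;`.
#' @export
write_newick <- function(st, digits = 15) {
  fmt <- function(x) format(x, digits = digits, scientific = FALSE, trim = TRUE)
  rec <- function(id) {
    if (id <= st$s) out <- st$tip.label[id]
    else {
      kids <- st$children[[id]]
      out <- paste0("(", rec(kids[1]), ",", rec(kids[2]), ")")
      if (!is.na(st$tau[id]) && st$tau[id] != 0) out <- paste0(out, ":", fmt(st$tau[id]))
    }
    if (!is.na(st$theta[id])) out <- paste0(out, "#", fmt(st$theta[id]))
    out
  }
  paste0(rec(st$root), ";")
}

## clade key of every node: sorted tip labels joined by ","
clade_keys <- function(st) {
  key <- character(st$nnode)
  for (id in postorder_nodes(st)) {
    if (id <= st$s) key[id] <- st$tip.label[id]
    else {
      tips <- sort(unlist(strsplit(key[st$children[[id]]], ",", fixed = TRUE)))
      key[id] <- paste(tips, collapse = ",")
    }
  }
  key
}

## node ids in postorder (children before parents)
postorder_nodes <- function(st) {
  out <- integer(0)
  rec <- function(id) {
    for (k in st$children[[id]]) rec(k)
    out[[length(out) + 1L]] <<- id
  }
  rec(st$root)
  unlist(out)
}

## internal nodes only, root last
internal_nodes <- function(st) {
  po <- postorder_nodes(st)
  po[po > st$s]
}

validate_species_tree <- function(st) {
  s <- st$s
  if (any(st$tau[seq_len(s)] != 0)) stop("tips must be at age 0")
  for (id in seq_len(st$nnode)) {
    p <- st$parent[id]
    if (p > 0L) {
      if (is.na(st$tau[p]) || is.na(st$tau[id]))
        stop("missing age on internal node")
      if (st$tau[p] <= st$tau[id])
        stop("parent age must exceed child age (node ", id, ")")
    }
  }
  if (any(!is.na(st$tau) & st$tau < 0)) stop("negative node age")
  if (any(!is.na(st$theta) & st$theta <= 0)) stop("theta must be positive")
  if (!is.null(st$constraints)) {
    for (cl in st$constraints) {
      if (!all(cl %in% st$tip.label)) stop("constraint names unknown tip")
      if (!clade_in_tree(st, cl)) stop("constraint incompatible with topology: ",
                                       paste(cl, collapse = ","))
    }
  }
  invisible(st)
}

## is the given set of tips a clade of st?
clade_in_tree <- function(st, tips) {
  key <- paste(sort(tips), collapse = ",")
  key %in% st$clade
}

## does the tree satisfy all declared constraints?
satisfies_constraints <- function(st) {
  if (is.null(st$constraints)) return(TRUE)
  all(vapply(st$constraints, function(cl) clade_in_tree(st, cl), logical(1)))
}

## MRCA of two species-tree nodes
st_mrca <- function(st, a, b) {
  anc <- function(id) {
    out <- id
    while (st$parent[id] > 0L) { id <- st$parent[id]; out <- c(out, id) }
    out
  }
  aa <- anc(a)
  for (x in anc(b)) if (x %in% aa) return(x)
  st$root
}

#' Internal-branch length in coalescent units
#'
#' The duration of a species-tree branch divided by half its population size,
#' `2 * (tau_parent - tau_child) / theta`: the scale on which incomplete
#' lineage sorting operates.  Short internal branches (well under one
#' coalescent unit) make the species tree hard to recover.
#'
#' @param st A `species_tree`.
#' @param branch An internal node id or a clade key (e.g. `"A,B"`); the branch
#'   is the one directly above that node.
#' @return A scalar, the branch length in coalescent units.
#' @examples
#' st <- species_tree("(((A,B):0.1#0.05,C):0.105#0.01,O):0.2#0.01;")
#' coalescent_unit_length(st, "A,B")  # 2*(0.105-0.1)/0.05 = 0.2
#' @export
coalescent_unit_length <- function(st, branch) {
  id <- if (is.character(branch)) match(branch, st$clade) else as.integer(branch)
  if (is.na(id) || id < 1 || id > st$nnode) stop("unknown branch: ", branch)
  if (id <= st$s) stop("branch above a tip has no defined child age for this measure")
  p <- st$parent[id]
  if (p == 0L) stop("the root stem has unbounded duration")
  if (is.na(st$theta[id])) stop("theta not set for branch ", st$clade[id])
  2 * (st$tau[p] - st$tau[id]) / st$theta[id]
}

#' @export
print.species_tree <- function(x, ...) {
  cat("Species tree with", x$s, "species:", paste(x$tip.label, collapse = ", "), "\n")
  cat("  ", write_newick(x, digits = 6), "\n")
  if (!is.null(x$constraints) && length(x$constraints))
    cat("  constraints:", paste(vapply(x$constraints, paste, "", collapse = ","),
                                collapse = " | "), "\n")
  invisible(x)
}
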