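#' Read and write multi-locus PHYLIP alignments
#'
#' The multi-locus dialect: loci concatenated as blocks, each starting with
#' a `n_seq n_site` header line followed by one `label  sequence` line per
#' sequence.  Labels of the form `individual^species` carry the species
#' assignment inline; otherwise an Imap provides it.  Round-trips exactly.
#'
#' @param path File path.
#' @return `read_phylip`: a list of character matrices (one per locus, row
#'   names = labels).
#' @export
read_phylip <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  out <- list()
  i <- 1L
  while (i <= length(lines)) {
    hdr <- strsplit(trimws(lines[i]), "[[:space:]]+")[[1]]
    if (length(hdr) != 2L || anyNA(suppressWarnings(as.integer(hdr))))
      stop("malformed PHYLIP header at line ", i)
    ns <- as.integer(hdr[1]); nsite <- as.integer(hdr[2])
    if (i + ns > length(lines)) stop("truncated PHYLIP block at line ", i)
    labs <- character(ns)
    m <- matrix("", ns, nsite)
    for (k in seq_len(ns)) {
      fld <- strsplit(trimws(lines[i + k]), "[[:space:]]+")[[1]]
      labs[k] <- fld[1]
      seqchars <- strsplit(toupper(paste(fld[-1], collapse = "")), "")[[1]]
      if (length(seqchars) != nsite)
        stop("sequence length mismatch for ", fld[1], " (locus ", length(out) + 1L, ")")
      m[k, ] <- seqchars
    }
    if (anyDuplicated(labs)) stop("duplicate sequence label in locus ", length(out) + 1L)
    rownames(m) <- labs
    out[[length(out) + 1L]] <- m
    i <- i + ns + 1L
  }
  out
}

#' @rdname read_phylip
#' @param alignments List of character matrices.
#' @export
write_phylip <- function(alignments, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (aln in alignments) {
    writeLines(paste(nrow(aln), ncol(aln)), con)
    for (k in seq_len(nrow(aln)))
      writeLines(paste0(rownames(aln)[k], "  ",
                        paste(aln[k, ], collapse = "")), con)
    writeLines("", con)
  }
  invisible(path)
}

#' Read and write per-locus FASTA files
#'
#' @param path File path.
#' @return `read_fasta`: a character matrix with row names.
#' @export
read_fasta <- function(path) {
  lines <- readLines(path)
  hdr <- grep("^>", lines)
  if (!length(hdr)) stop("no FASTA records in ", path)
  labs <- sub("^>\\s*", "", lines[hdr])
  ends <- c(hdr[-1] - 1L, length(lines))
  seqs <- vapply(seq_along(hdr), function(k)
    toupper(paste(lines[(hdr[k] + 1L):ends[k]], collapse = "")), "")
  ncol <- unique(nchar(seqs))
  if (length(ncol) != 1) stop("ragged alignment in ", path)
  m <- do.call(rbind, strsplit(seqs, ""))
  rownames(m) <- labs
  if (anyDuplicated(labs)) stop("duplicate sequence label in ", path)
  m
}

#' @rdname read_fasta
#' @param aln Character matrix with row names.
#' @param width Line width for sequence wrapping.
#' @export
write_fasta <- function(aln, path, width = 70L) {
  con <- file(path, "w")
  on.exit(close(con))
  for (k in seq_len(nrow(aln))) {
    writeLines(paste0(">", rownames(aln)[k]), con)
    s <- paste(aln[k, ], collapse = "")
    starts <- seq(1L, nchar(s), by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1L, nchar(s))), con)
  }
  invisible(path)
}

#' Read/write a two-column individual-to-species map (Imap)
#'
#' @param path File path.
#' @return `read_imap`: named character vector (individual -> species).
#' @export
read_imap <- function(path) {
  tab <- utils::read.table(path, header = FALSE, col.names = c("ind", "species"),
                           colClasses = "character")
  stats::setNames(tab$species, tab$ind)
}

#' @rdname read_imap
#' @param imap Named character vector.
#' @export
write_imap <- function(imap, path) {
  utils::write.table(data.frame(names(imap), unname(imap)), path,
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

## ---- control files ------------------------------------------------------

#' Parse a control file
#'
#' A documented subset of the bpp control grammar.  Recognised keys:
#' `seed`, `seqfile`, `imapfile`, `outfile`, `treefile`, `species&tree`
#' (species count and labels, then per-species sequence counts, then the
#' Newick tree, possibly over three lines), `constraint`, `outgroup`,
#' `tauprior = gamma|invgamma a b`, `thetaprior = gamma|invgamma a b |
#' beta a b lo hi`, `locusrate = 1 amu_bar bmu_bar amu iid|dir` (with
#' `amu_bar = bmu_bar = 0` fixing the mean rate at 1; the short form
#' `locusrate = 1 amu iid` is also accepted), `clock = 1 | 2|3 anu_bar
#' bnu_bar anu iid|dir G|LN` (also `clock = 2 nubar anu iid g` fixing the
#' prior mean), `model = JC|K80|HKY|GTR`, `alphaprior = a b ncat`, `loci = L
#' nsites`, `burnin`, `nsample`, `sampfreq`, `usedata`, `speciestree`
#' (0 = fixed tree, 1 = NNI search).  Kernel tokens are case-insensitive.
#' Unknown keys draw a warning, never a silent ignore.
#'
#' @param text Control-file contents as a single string or character vector
#'   of lines; or a file path.
#' @return A list of class `msc_control_config` with components `tree`
#'   (species_tree), `prior`, `clock`, `subst`, `nseq`, `files`, `mcmc`,
#'   `loci`, `seed`, `search`.
#' @export
parse_control <- function(text) {
  if (length(text) == 1 && file.exists(text)) text <- readLines(text)
  lines <- unlist(strsplit(text, "\n"))
  lines <- sub("\\*.*$", "", lines)   # '*' comments ('#' carries theta values)
  lines <- trimws(lines)
  ## continuation lines (species&tree block spans 3 lines)
  items <- list()
  cur <- NULL
  for (ln in lines[nzchar(lines)]) {
    if (grepl("=", ln, fixed = TRUE)) {
      kv <- strsplit(ln, "=", fixed = TRUE)[[1]]
      cur <- tolower(trimws(kv[1]))
      val <- trimws(paste(kv[-1], collapse = "="))
      items[[cur]] <- c(items[[cur]], val)
    } else if (!is.null(cur)) {
      items[[cur]] <- c(items[[cur]], ln)
    } else stop("control line outside any key: ", ln)
  }
  toks <- function(v) strsplit(trimws(paste(v, collapse = " ")), "[[:space:]]+")[[1]]
  num <- function(v) {
    x <- suppressWarnings(as.numeric(v))
    if (anyNA(x)) stop("non-numeric value in control file: ", paste(v, collapse = " "))
    x
  }

  known <- c("seed", "seqfile", "imapfile", "outfile", "treefile",
             "species&tree", "constraint", "outgroup", "tauprior",
             "thetaprior", "locusrate", "clock", "model", "alphaprior",
             "loci", "burnin", "nsample", "sampfreq", "usedata",
             "speciestree")
  unknown <- setdiff(names(items), known)
  if (length(unknown))
    warning("unknown control keys ignored: ", paste(unknown, collapse = ", "))

  ## species & tree
  if (is.null(items[["species&tree"]])) stop("control file lacks species&tree")
  sv <- items[["species&tree"]]
  head_toks <- toks(sv[1])
  s <- as.integer(head_toks[1])
  labels <- head_toks[2:(s + 1)]
  rest <- sv[-1]
  nseq <- rep(1L, s)
  nwk <- NULL
  for (ln in rest) {
    tk <- toks(ln)
    if (all(grepl("^[0-9]+$", tk)) && length(tk) == s) nseq <- as.integer(tk)
    else nwk <- paste0(nwk, ln)
  }
  if (is.null(nwk)) stop("species&tree block lacks a Newick tree")
  constraints <- NULL
  if (!is.null(items$constraint)) {
    constraints <- lapply(items$constraint, function(v)
      toks(gsub("[(),]", " ", v)))
  }
  outgroup <- if (!is.null(items$outgroup)) trimws(items$outgroup[1]) else NULL
  tree <- species_tree(nwk, constraints = constraints, outgroup = outgroup)
  if (!setequal(tree$tip.label, labels))
    stop("species&tree labels do not match the Newick tips")

  ## priors
  pr_parse <- function(v, what) {
    tk <- toks(v)
    fam <- tolower(tk[1])
    if (!fam %in% c("gamma", "invgamma", "beta"))
      stop("unknown ", what, " prior family: ", tk[1])
    p <- num(tk[-1])
    if (fam == "beta") list(family = "beta", alpha = p[1], beta = p[2], a = p[3], b = p[4])
    else list(family = fam, alpha = p[1], beta = p[2])
  }
  tau_pr <- if (!is.null(items$tauprior)) pr_parse(items$tauprior, "tau")
            else list(family = "gamma", alpha = 2, beta = 20)
  th_pr <- if (!is.null(items$thetaprior)) pr_parse(items$thetaprior, "theta")
           else list(family = "invgamma", alpha = 3, beta = 0.002)
  prior <- msc_prior(tau = tau_pr, theta = th_pr)

  ## locusrate: "1 amu_bar bmu_bar amu iid|dir" or "1 amu iid|dir" or "0"
  mu_spec <- list("iid", 5, 0, 0)
  if (!is.null(items$locusrate)) {
    tk <- toks(items$locusrate)
    if (tk[1] == "0") mu_spec <- list("iid", 1e9, 0, 0)   # effectively constant
    else if (length(tk) == 5)
      mu_spec <- list(tolower(tk[5]), num(tk[4]), num(tk[2]), num(tk[3]))
    else if (length(tk) == 3)
      mu_spec <- list(tolower(tk[3]), num(tk[2]), 0, 0)
    else stop("locusrate takes 1, 3 or 5 arguments")
  }

  ## clock: "1" | "{2|3} anu_bar bnu_bar anu iid|dir G|LN" |
  ##        "{2|3} nubar anu iid|dir g" (fixed-mean shorthand used in
  ##        simulation: implemented as a sharp G(1e4, 1e4/nubar) hyperprior)
  ctype <- 1L; kern <- "G"; nu_spec <- list("iid", 5, 2, 20)
  if (!is.null(items$clock)) {
    tk <- toks(items$clock)
    ctype <- as.integer(tk[1])
    if (ctype > 1) {
      if (length(tk) == 6) {
        nu_spec <- list(tolower(tk[5]), num(tk[4]), num(tk[2]), num(tk[3]))
        kern <- toupper(tk[6])
      } else if (length(tk) == 5) {
        nubar <- num(tk[2])
        nu_spec <- list(tolower(tk[4]), num(tk[3]), 1e4, 1e4 / nubar)
        kern <- toupper(tk[5])
      } else stop("clock takes 1, 5 or 6 arguments")
      if (!kern %in% c("G", "LN")) stop("clock kernel must be G or LN")
    }
  }
  clock <- clock_model(ctype, kern, mu = mu_spec, nu = nu_spec)

  model <- toupper(if (!is.null(items$model)) trimws(items$model) else "JC")
  ap <- if (!is.null(items$alphaprior)) num(toks(items$alphaprior)) else NULL
  subst <- if (is.null(ap) || ap[1] == 0)
    subst_config(model, ncat = 1L)
  else subst_config(model, ncat = if (length(ap) >= 3) as.integer(ap[3]) else 5L,
                    alpha_prior = ap[1:2])

  loci <- if (!is.null(items$loci)) as.integer(num(toks(items$loci))) else c(10L, 500L)
  gi <- function(k, d) if (!is.null(items[[k]])) as.integer(num(toks(items[[k]]))[1]) else d
  structure(list(
    tree = tree, prior = prior, clock = clock, subst = subst,
    nseq = nseq, labels = labels,
    files = list(seqfile = items$seqfile, imapfile = items$imapfile,
                 outfile = items$outfile, treefile = items$treefile),
    mcmc = list(burnin = gi("burnin", 500L), nsample = gi("nsample", 1000L),
                sampfreq = gi("sampfreq", 2L)),
    loci = loci, seed = gi("seed", NA_integer_),
    usedata = gi("usedata", 1L) == 1L,
    search = gi("speciestree", 0L) == 1L
  ), class = "msc_control_config")
}
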