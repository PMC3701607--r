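# Independent oracles used to cross-check the package's estimators.

GENCODE <- Biostrings::GENETIC_CODE
BASES <- c("A", "C", "G", "T")
STOPS <- names(GENCODE)[GENCODE == "*"]

# --- NG86 oracle: literal enumeration, written independently of the
# package's cached lookup tables ------------------------------------------

oracle_ng86_sites <- function(codon) {
  b <- strsplit(codon, "")[[1]]
  aa <- GENCODE[[codon]]
  S <- 0
  for (pos in 1:3) {
    muts <- vapply(setdiff(BASES, b[pos]), function(nt) {
      x <- b; x[pos] <- nt; paste(x, collapse = "")
    }, character(1))
    muts <- muts[!muts %in% STOPS]
    if (length(muts) > 0) S <- S + mean(GENCODE[muts] == aa)
  }
  c(S = S, N = 3 - S)
}

# all orderings of the differing positions, as a list of index vectors
all_orderings <- function(v) {
  if (length(v) <= 1) return(list(v))
  out <- list()
  for (i in seq_along(v)) {
    for (rest in all_orderings(v[-i])) out[[length(out) + 1]] <- c(v[i], rest)
  }
  out
}

oracle_ng86_diffs <- function(codA, codB) {
  a <- strsplit(codA, "")[[1]]; b <- strsplit(codB, "")[[1]]
  pos <- which(a != b)
  if (length(pos) == 0) return(c(Sd = 0, Nd = 0))
  paths <- lapply(all_orderings(pos), function(ord) {
    cur <- a; syn <- 0; stop_hit <- FALSE; prev <- GENCODE[[codA]]
    for (p in ord) {
      cur[p] <- b[p]
      cod <- paste(cur, collapse = "")
      aa <- GENCODE[[cod]]
      if (aa == "*") stop_hit <- TRUE
      if (aa == prev) syn <- syn + 1
      prev <- aa
    }
    list(syn = syn, stop_hit = stop_hit)
  })
  clean <- Filter(function(p) !p$stop_hit, paths)
  use <- if (length(clean) > 0) clean else paths
  Sd <- mean(vapply(use, function(p) p$syn, numeric(1)))
  c(Sd = Sd, Nd = length(pos) - Sd)
}

sense_codons <- function() setdiff(names(GENCODE), STOPS)

# --- global alignment oracle: textbook three-state Gotoh DP in plain R,
# gap run of length L costing open + L * ext ------------------------------

oracle_align_score <- function(a, b, match = 5, mismatch = -4,
                               open = -10, ext = -1) {
  x <- strsplit(a, "")[[1]]; y <- strsplit(b, "")[[1]]
  n <- length(x); m <- length(y)
  NEG <- -1e9
  Mm <- matrix(NEG, n + 1, m + 1)  # last column aligned x[i]~y[j]
  Ix <- matrix(NEG, n + 1, m + 1)  # gap in y (x consumed)
  Iy <- matrix(NEG, n + 1, m + 1)  # gap in x
  Mm[1, 1] <- 0
  for (i in seq_len(n)) Ix[i + 1, 1] <- open + ext * i
  for (j in seq_len(m)) Iy[1, j + 1] <- open + ext * j
  for (i in seq_len(n)) {
    for (j in seq_len(m)) {
      s <- if (x[i] == y[j]) match else mismatch
      Mm[i + 1, j + 1] <- max(Mm[i, j], Ix[i, j], Iy[i, j]) + s
      Ix[i + 1, j + 1] <- max(Mm[i, j + 1] + open + ext,
                              Ix[i, j + 1] + ext)
      Iy[i + 1, j + 1] <- max(Mm[i + 1, j] + open + ext,
                              Iy[i + 1, j] + ext)
    }
  }
  max(Mm[n + 1, m + 1], Ix[n + 1, m + 1], Iy[n + 1, m + 1])
}

# --- reconciliation oracle: minimize D + L over every ancestor-consistent
# mapping of internal gene nodes -------------------------------------------

oracle_min_reconciliation <- function(gene_tree, species_tree, leaf_map) {
  ntip_g <- length(gene_tree$tip.label)
  ch_g <- toxdiverge:::phylo_children(gene_tree)
  par_s <- toxdiverge:::phylo_parent(species_tree)
  ch_s <- toxdiverge:::phylo_children(species_tree)
  depth_s <- toxdiverge:::phylo_depths(species_tree)
  anc_s <- toxdiverge:::ancestor_paths(species_tree)
  sp_idx <- match(leaf_map[gene_tree$tip.label], species_tree$tip.label)
  internal <- rev(toxdiverge:::phylo_postorder(gene_tree))
  internal <- sort(setdiff(internal, seq_len(ntip_g)))
  # postorder over internal nodes so children are assigned first
  post <- Filter(function(v) v > ntip_g, toxdiverge:::phylo_postorder(gene_tree))
  nnodes <- ntip_g + gene_tree$Nnode
  best <- Inf
  in_subtree <- function(v, s) s %in% anc_s[[v]]
  cost_of <- function(M) {
    D <- 0; L <- 0
    for (g in post) {
      kids <- ch_g[[g]]
      # duplication unless the children's images sit in distinct child
      # subtrees of M(g)
      sep <- FALSE
      if (length(ch_s[[M[g]]]) == 2) {
        c1 <- ch_s[[M[g]]][1]; c2 <- ch_s[[M[g]]][2]
        sep <- (in_subtree(M[kids[1]], c1) && in_subtree(M[kids[2]], c2)) ||
               (in_subtree(M[kids[1]], c2) && in_subtree(M[kids[2]], c1))
      }
      dup <- !sep
      if (dup) D <- D + 1
      for (c in kids) {
        steps <- depth_s[M[c]] - depth_s[M[g]]
        L <- L + if (dup) steps else steps - 1
      }
    }
    c(D = D, L = L)
  }
  M <- rep(NA_integer_, nnodes)
  M[seq_len(ntip_g)] <- sp_idx
  recurse <- function(k) {
    if (k > length(post)) {
      co <- cost_of(M)
      tot <- unname(co[1] + co[2])
      if (tot < best) best <<- tot
      return(invisible())
    }
    g <- post[k]
    kids <- ch_g[[g]]
    # candidates: ancestors-or-equal of both children's images
    cand <- Reduce(intersect, lapply(kids, function(c) anc_s[[M[c]]]))
    for (s in cand) {
      M[g] <<- s
      recurse(k + 1)
    }
    M[g] <<- NA_integer_
  }
  recurse(1)
  best
}

# random rooted binary gene tree over species A/B/Out
random_gene_tree <- function(n_leaves, species = c("A", "B", "Out")) {
  phy <- ape::rtree(n_leaves, rooted = TRUE)
  phy$tip.label <- paste0("g", seq_len(n_leaves))
  map <- stats::setNames(sample(species, n_leaves, replace = TRUE),
                         phy$tip.label)
  list(tree = phy, map = map)
}
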