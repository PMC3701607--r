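# Gene-tree / species-tree duplication-loss parsimony reconciliation:
# outgroup rooting, LCA mapping, event counting with per-species-branch
# loss attribution, and a neighbor-joining helper for synthetic runs.

# ---- small phylo helpers (ape trees) --------------------------------------

phylo_root <- function(phy) length(phy$tip.label) + 1L

phylo_children <- function(phy) {
  n <- length(phy$tip.label) + phy$Nnode
  ch <- vector("list", n)
  for (e in seq_len(nrow(phy$edge))) {
    p <- phy$edge[e, 1]; c <- phy$edge[e, 2]
    ch[[p]] <- c(ch[[p]], c)
  }
  ch
}

phylo_parent <- function(phy) {
  n <- length(phy$tip.label) + phy$Nnode
  par <- rep(NA_integer_, n)
  par[phy$edge[, 2]] <- phy$edge[, 1]
  par
}

phylo_depths <- function(phy) {
  par <- phylo_parent(phy)
  n <- length(par)
  d <- rep(NA_integer_, n)
  d[phylo_root(phy)] <- 0L
  # repeated sweeps; trees here are small
  repeat {
    todo <- which(is.na(d) & !is.na(par) & !is.na(d[par]))
    if (length(todo) == 0L) break
    d[todo] <- d[par[todo]] + 1L
  }
  d
}

# postorder sequence of node ids (children before parents)
phylo_postorder <- function(phy) {
  po <- ape::reorder.phylo(phy, "postorder")
  unique(c(po$edge[, 2], phylo_root(phy)))
}

node_label <- function(phy, node) {
  ntip <- length(phy$tip.label)
  if (node <= ntip) return(phy$tip.label[node])
  if (!is.null(phy$node.label) && nzchar(phy$node.label[node - ntip]))
    return(phy$node.label[node - ntip])
  paste0("node", node)
}

is_binary_rooted <- function(phy) {
  ch <- phylo_children(phy)
  internal <- which(lengths(ch) > 0)
  all(lengths(ch[internal]) == 2L)
}

#' Root a tree on the edge separating an outgroup
#'
#' The root is placed on the edge between the outgroup and the remaining
#' leaves; a degree-two original root is suppressed. Rooting an
#' already-rooted tree with the same outgroup is idempotent.
#'
#' @param tree an [ape::phylo] tree (rooted or unrooted)
#' @param outgroup_labels tip labels forming the outgroup
#' @return rooted `phylo` tree
#' @export
root_with_outgroup <- function(tree, outgroup_labels) {
  missing <- setdiff(outgroup_labels, tree$tip.label)
  if (length(missing) > 0) {
    stop("outgroup label(s) absent from tree: ", paste(missing, collapse = ", "))
  }
  if (!ape::is.monophyletic(tree, outgroup_labels)) {
    ingroup <- setdiff(tree$tip.label, outgroup_labels)
    stop("outgroup is not separable from the ingroup; conflicting leaves: ",
         paste(ingroup, collapse = ", "))
  }
  rooted <- ape::root(tree, outgroup = outgroup_labels, resolve.root = TRUE)
  rooted
}

# ---- LCA mapping ----------------------------------------------------------

# ancestor id lists (self first, root last) for every node
ancestor_paths <- function(phy) {
  par <- phylo_parent(phy)
  lapply(seq_along(par), function(v) {
    path <- v
    while (!is.na(par[path[length(path)]])) path <- c(path, par[path[length(path)]])
    path
  })
}

species_lca_fn <- function(species_tree) {
  paths <- ancestor_paths(species_tree)
  function(u, v) {
    if (u == v) return(u)
    pu <- paths[[u]]
    pv <- paths[[v]]
    common <- intersect(pu, pv)
    common[1]  # paths are ordered tipward-to-root, intersect keeps pu order
  }
}

#' LCA mapping of a gene tree onto a species tree
#'
#' Computed in post-order: a leaf maps to its species; an internal node to
#' the species-tree LCA of its children's images.
#'
#' @param gene_tree rooted binary `phylo`
#' @param species_tree rooted binary `phylo`
#' @param leaf_species_map named character vector: gene leaf -> species tip
#'   label (or a tibble/data.frame with columns `leaf`, `species`)
#' @return integer vector over gene-tree node ids giving the mapped
#'   species-tree node id
#' @export
lca_map <- function(gene_tree, species_tree, leaf_species_map) {
  if (is.data.frame(leaf_species_map)) {
    leaf_species_map <- stats::setNames(leaf_species_map$species,
                                        leaf_species_map$leaf)
  }
  single_leaf <- length(gene_tree$tip.label) == 1L
  if (!single_leaf && !is_binary_rooted(gene_tree)) {
    stop("gene tree must be rooted and binary")
  }
  if (!is_binary_rooted(species_tree)) stop("species tree must be rooted and binary")
  ntip_g <- length(gene_tree$tip.label)
  sp <- leaf_species_map[gene_tree$tip.label]
  if (anyNA(sp)) {
    stop("gene leaf without a species assignment: ",
         paste(gene_tree$tip.label[is.na(sp)], collapse = ", "))
  }
  sp_idx <- match(sp, species_tree$tip.label)
  if (anyNA(sp_idx)) {
    stop("species not in species tree: ",
         paste(unique(sp[is.na(sp_idx)]), collapse = ", "))
  }
  lca <- species_lca_fn(species_tree)
  ch <- phylo_children(gene_tree)
  M <- rep(NA_integer_, ntip_g + gene_tree$Nnode)
  M[seq_len(ntip_g)] <- sp_idx
  if (single_leaf) {
    M[] <- sp_idx  # the root maps with its only leaf
    return(M)
  }
  for (g in phylo_postorder(gene_tree)) {
    if (g <= ntip_g) next
    kids <- ch[[g]]
    M[g] <- Reduce(lca, M[kids])
  }
  M
}

#' Duplication-loss event counts from an LCA mapping
#'
#' A gene node is a duplication iff it maps to the same species node as at
#' least one of its children. Losses along an edge (g, c) number
#' `depth(M(c)) - depth(M(g)) - 1` below a speciation and
#' `depth(M(c)) - depth(M(g))` below a duplication; each loss is
#' attributed to the species branch (sibling lineage) where the copy
#' disappeared.
#'
#' @param gene_tree rooted binary `phylo`
#' @param species_tree rooted binary `phylo`
#' @param M mapping from [lca_map()]
#' @return object of class `reconciliation`: list with `duplications` (D),
#'   `losses` (L), `events` tibble (gene node, event), `loss_branches`
#'   tibble (species node label, losses), and the mapping `M`
#' @export
count_events <- function(gene_tree, species_tree, M) {
  ntip_g <- length(gene_tree$tip.label)
  if (ntip_g == 1L) {
    return(structure(list(
      duplications = 0L, losses = 0L,
      events = tibble::tibble(node = integer(), event = character(),
                              species_node = character()),
      loss_branches = tibble::tibble(species_branch = character(),
                                     losses = integer()),
      M = M, gene_tree = gene_tree, species_tree = species_tree),
      class = "reconciliation"))
  }
  ch_g <- phylo_children(gene_tree)
  par_s <- phylo_parent(species_tree)
  ch_s <- phylo_children(species_tree)
  depth <- phylo_depths(species_tree)
  internal <- which(lengths(ch_g) > 0)
  sp_paths <- ancestor_paths(species_tree)
  for (g in internal) {
    for (c in ch_g[[g]]) {
      if (!M[g] %in% sp_paths[[M[c]]]) {
        stop("inconsistent mapping: child maps outside its parent's subtree")
      }
    }
  }
  is_dup <- vapply(internal, function(g) any(M[ch_g[[g]]] == M[g]), logical(1))
  D <- sum(is_dup)
  nsp <- length(species_tree$tip.label) + species_tree$Nnode
  loss_at <- rep(0L, nsp)
  L <- 0L
  for (k in seq_along(internal)) {
    g <- internal[k]
    for (c in ch_g[[g]]) {
      # species path from M(c) up to (excluding) M(g)
      path <- integer(0)
      v <- M[c]
      while (v != M[g]) { path <- c(path, v); v <- par_s[v] }
      path <- rev(path)  # topmost first: child of M(g) ... M(c)
      # a speciation sends the lineage into the first step for free
      lost_steps <- if (is_dup[k]) path else path[-1]
      if (length(lost_steps) > 0) {
        # entering node v from its parent loses the copy in v's sibling
        for (v in lost_steps) {
          sib <- setdiff(ch_s[[par_s[v]]], v)
          loss_at[sib] <- loss_at[sib] + 1L
          L <- L + 1L
        }
      }
    }
  }
  events <- tibble::tibble(
    node = internal,
    event = ifelse(is_dup, "duplication", "speciation"),
    species_node = vapply(internal, function(g) node_label(species_tree, M[g]),
                          character(1))
  )
  loss_branches <- tibble::tibble(
    species_branch = vapply(which(loss_at > 0), function(v)
      node_label(species_tree, v), character(1)),
    losses = loss_at[loss_at > 0]
  )
  structure(list(duplications = D, losses = L, events = events,
                 loss_branches = loss_branches, M = M,
                 gene_tree = gene_tree, species_tree = species_tree),
            class = "reconciliation")
}

#' @export
print.reconciliation <- function(x, ...) {
  cat("<reconciliation>", x$duplications, "duplication(s),",
      x$losses, "loss(es)\n")
  if (nrow(x$loss_branches) > 0) {
    for (i in seq_len(nrow(x$loss_branches))) {
      cat("  ", x$loss_branches$losses[i], "loss(es) in",
          x$loss_branches$species_branch[i], "\n")
    }
  }
  invisible(x)
}

#' Reconcile a gene tree with a species tree
#'
#' Convenience wrapper: optional outgroup rooting, LCA mapping, and event
#' counting.
#'
#' @inheritParams lca_map
#' @param outgroup optional gene-tree outgroup labels used to root first
#' @return a `reconciliation` object (see [count_events()])
#' @export
reconcile <- function(gene_tree, species_tree, leaf_species_map,
                      outgroup = NULL) {
  if (!is.null(outgroup)) {
    gene_tree <- root_with_outgroup(gene_tree, outgroup)
  }
  M <- lca_map(gene_tree, species_tree, leaf_species_map)
  count_events(gene_tree, species_tree, M)
}

#' Neighbor-joining tree from a distance matrix
#'
#' Validates the matrix (symmetric, non-negative, zero diagonal, n >= 3)
#' and delegates to [ape::nj()].
#'
#' @param distance_matrix square numeric matrix with dimnames
#' @return unrooted `phylo` tree
#' @export
nj_tree <- function(distance_matrix) {
  m <- as.matrix(distance_matrix)
  if (nrow(m) != ncol(m) || nrow(m) < 3) stop("need a square matrix, n >= 3")
  if (any(abs(m - t(m)) > 1e-8)) stop("distance matrix is not symmetric")
  if (any(diag(m) != 0)) stop("distance matrix diagonal must be zero")
  if (any(m < 0)) stop("negative distances")
  ape::nj(m)
}
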