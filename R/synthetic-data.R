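# Synthetic two-species venom-gland transcriptome generator with known
# ground truth: gene-family birth-death histories, per-gene omega,
# expression profiles, and overlapping paired-end reads.

#' Simulation configuration
#'
#' Defaults emulate the study design: two congeneric ingroup species (A,
#' B) plus an outgroup; on the order of a hundred shared nontoxin genes
#' with conserved expression and low omega; a set of toxin gene families
#' named after the venom toxin classes, undergoing birth-death
#' duplication/loss with elevated omega and strongly divergent
#' between-species class expression; and overlapping 100-nt read pairs
#' from 150-nt fragments.
#'
#' Species-tree branch lengths are expected substitutions per codon at
#' omega = 1; family birth/death rates are events per unit of that same
#' branch-length scale.
#'
#' @param n_nontoxins number of shared nontoxin genes
#' @param toxin_families named list of family specs, each a list with
#'   `birth`, `death`, `omega`
#' @param nontoxin_omega dN/dS for nontoxins
#' @param kappa transition/transversion rate ratio
#' @param coding_length CDS length in nt (multiple of 3)
#' @param species_tree newick for the rooted 3-taxon species tree
#' @param expression_noise_sd log-scale between-species noise for nontoxin
#'   abundances
#' @param toxin_divergence log-scale between-species shift of toxin family
#'   shares
#' @param toxin_fraction fraction of reads drawn from toxin transcripts
#' @param read_length,fragment_length,n_read_pairs read simulation sizes;
#'   pairs overlap at their 3' ends by `2 * read_length - fragment_length`
#' @param error_rate per-base sequencing error probability
#' @param seed integer seed; a fixed seed makes all outputs byte-identical
#' @return validated config list of class `sim_config`
#' @export
sim_config <- function(n_nontoxins = 150,
                       toxin_families = default_toxin_families(),
                       nontoxin_omega = 0.18,
                       kappa = 2,
                       coding_length = 450,
                       species_tree = "((A:0.015,B:0.015)AB:0.085,Out:0.1)Root;",
                       expression_noise_sd = 0.2,
                       toxin_divergence = 1.5,
                       toxin_fraction = 0.41,
                       read_length = 100,
                       fragment_length = 150,
                       n_read_pairs = 5000,
                       error_rate = 1e-4,
                       seed = 1) {
  cfg <- list(n_nontoxins = n_nontoxins, toxin_families = toxin_families,
              nontoxin_omega = nontoxin_omega, kappa = kappa,
              coding_length = coding_length, species_tree = species_tree,
              expression_noise_sd = expression_noise_sd,
              toxin_divergence = toxin_divergence,
              toxin_fraction = toxin_fraction,
              read_length = read_length, fragment_length = fragment_length,
              n_read_pairs = n_read_pairs, error_rate = error_rate,
              seed = seed)
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

default_toxin_families <- function() {
  spec <- list(
    SVSP  = c(12, 4, 0.9), PLA2 = c(12, 4, 1.0), CTL = c(14, 5, 0.8),
    SVMP  = c(10, 4, 0.7), BPP  = c(4, 1, 0.5),  MYO = c(4, 2, 0.6),
    CRISP = c(4, 2, 0.5),  LAAO = c(3, 1, 0.4),  VEGF = c(6, 2, 0.6),
    KUN   = c(6, 2, 0.7),  NGF  = c(3, 1, 0.4),  NUC = c(3, 1, 0.4),
    PDE   = c(4, 2, 0.5),  HYAL = c(3, 1, 0.5),  VESP = c(3, 1, 0.6),
    VF    = c(3, 1, 0.5))
  lapply(spec, function(x) list(birth = x[1], death = x[2], omega = x[3]))
}

validate_sim_config <- function(cfg) {
  stopifnot(cfg$n_nontoxins >= 0,
            cfg$coding_length %% 3 == 0, cfg$coding_length > 0,
            cfg$nontoxin_omega > 0, cfg$kappa > 0,
            cfg$expression_noise_sd >= 0, cfg$toxin_divergence >= 0,
            cfg$toxin_fraction > 0, cfg$toxin_fraction < 1,
            cfg$read_length > 0,
            cfg$fragment_length >= cfg$read_length,
            cfg$fragment_length < 2 * cfg$read_length,
            cfg$n_read_pairs >= 0,
            cfg$error_rate >= 0, cfg$error_rate < 1)
  for (nm in names(cfg$toxin_families)) {
    f <- cfg$toxin_families[[nm]]
    if (!all(is.finite(c(f$birth, f$death, f$omega))) ||
        f$birth < 0 || f$death < 0 || f$omega < 0) {
      stop("nonviable rates for family ", nm)
    }
  }
  tr <- ape::read.tree(text = cfg$species_tree)
  stopifnot(length(tr$tip.label) == 3, all(tr$edge.length > 0))
  invisible(cfg)
}

#' Read or write a simulation config as YAML
#' @param path YAML file
#' @return a `sim_config`
#' @export
read_sim_config <- function(path) {
  do.call(sim_config, yaml::read_yaml(path))
}

#' @rdname read_sim_config
#' @param config a `sim_config`
#' @export
write_sim_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

# species tree as a nested list (name, len, children) for the birth-death
# recursion
species_tree_nested <- function(newick) {
  phy <- ape::read.tree(text = newick)
  ch <- phylo_children(phy)
  build <- function(node, len) {
    nm <- node_label(phy, node)
    kids <- ch[[node]]
    el <- phy$edge.length[match(node, phy$edge[, 2])]
    list(name = nm, len = if (is.na(len)) 0 else len,
         children = lapply(kids, function(k)
           build(k, phy$edge.length[match(k, phy$edge[, 2])])))
  }
  build(phylo_root(phy), NA)
}

# ---- gene-family birth-death simulation -----------------------------------

#' Simulate one toxin gene family's duplication-loss history
#'
#' A birth-death process runs along each species-tree branch starting from
#' a single ancestral copy at the root; every birth is a duplication and
#' every death a loss, tallied per species branch. Families with no
#' surviving copies in either ingroup species are resampled (the number of
#' attempts is recorded); persistent extinction is an error.
#'
#' @param config a [sim_config()]
#' @param family_spec list with `birth`, `death`, `omega` (and optionally
#'   `name`)
#' @param name family name used in gene labels
#' @param max_resample resample budget before giving up
#' @return list of class `gene_family_history`: `tree` (phylo),
#'   `leaf_species` (named vector), `true_events` (tibble: branch,
#'   duplications, losses), `omega`, `resamples`
#' @export
simulate_gene_family <- function(config, family_spec, name = "FAM",
                                 max_resample = 100) {
  b <- family_spec$birth; d <- family_spec$death
  stopifnot(is.finite(b), is.finite(d), b >= 0, d >= 0)
  stree <- species_tree_nested(config$species_tree)
  env <- new.env()
  attempt <- 0L
  repeat {
    attempt <- attempt + 1L
    if (attempt > max_resample) {
      stop("family ", name, " went extinct in both ingroup species after ",
           max_resample, " resamples (death rate too high?)")
    }
    env$D <- list(); env$L <- list()
    tree <- sim_bd_species_node(stree, b, d, env, at_root = TRUE)
    if (is.null(tree)) next
    leaves <- bd_leaves(tree)
    species <- vapply(leaves, `[[`, character(1), "species")
    if (!any(species %in% c("A", "B"))) next  # extinct in both ingroups
    break
  }
  cnt <- new.env(); cnt$i <- 0L
  labelled <- bd_label(tree, name, cnt)
  nwk <- if (!is.null(labelled$tree$node$label)) {
    # single surviving gene: wrap so the newick parses as a 1-tip tree
    paste0("(", bd_newick(labelled$tree), ");")
  } else {
    paste0(bd_newick(labelled$tree), ";")
  }
  phy <- ape::read.tree(text = nwk)
  br <- sort(union(names(env$D), names(env$L)))
  ev <- tibble::tibble(branch = as.character(br))
  ev$duplications <- vapply(ev$branch, function(x)
    sum(unlist(env$D[[x]]), 0L), numeric(1))
  ev$losses <- vapply(ev$branch, function(x)
    sum(unlist(env$L[[x]]), 0L), numeric(1))
  structure(list(tree = phy, leaf_species = labelled$species,
                 true_events = ev, omega = family_spec$omega,
                 family = name, resamples = attempt - 1L),
            class = "gene_family_history")
}

# one gene lineage evolving within (and below) a species-tree node's branch
sim_bd_species_node <- function(snode, b, d, env, at_root = FALSE) {
  if (at_root) {
    # the ancestral copy sits at the species root: an immediate speciation
    kids <- lapply(snode$children, function(k) sim_bd_species_node(k, b, d, env))
    alive <- !vapply(kids, is.null, logical(1))
    if (!any(alive)) return(NULL)
    if (sum(alive) == 1L) return(kids[alive][[1]])
    return(list(len = 0, node = list(left = kids[[1]], right = kids[[2]])))
  }
  res <- sim_bd_branch(snode$len, b, d, env, snode$name)
  if (is.null(res)) return(NULL)
  attach_ends(res, snode, b, d, env)
}

# birth-death within one species branch; "end" markers reach the branch end
sim_bd_branch <- function(t_rem, b, d, env, branch) {
  rate <- b + d
  wait <- if (rate > 0) stats::rexp(1, rate) else Inf
  if (wait >= t_rem) return(list(len = t_rem, node = "end"))
  if (stats::runif(1) < d / rate) {
    env$L[[branch]] <- c(env$L[[branch]], 1L)
    return(NULL)
  }
  env$D[[branch]] <- c(env$D[[branch]], 1L)
  l <- sim_bd_branch(t_rem - wait, b, d, env, branch)
  r <- sim_bd_branch(t_rem - wait, b, d, env, branch)
  if (is.null(l) && is.null(r)) return(NULL)
  if (is.null(l) || is.null(r)) {
    surv <- if (is.null(l)) r else l
    return(list(len = wait + surv$len, node = surv$node))
  }
  list(len = wait, node = list(left = l, right = r))
}

# replace "end" markers: species tips become gene leaves; internal species
# nodes speciate into both child branches
attach_ends <- function(sub, snode, b, d, env) {
  if (identical(sub$node, "end")) {
    if (length(snode$children) == 0) {
      return(list(len = sub$len, node = list(species = snode$name)))
    }
    kids <- lapply(snode$children, function(k) sim_bd_species_node(k, b, d, env))
    alive <- !vapply(kids, is.null, logical(1))
    if (!any(alive)) return(NULL)
    if (sum(alive) == 1L) {
      surv <- kids[alive][[1]]
      return(list(len = sub$len + surv$len, node = surv$node))
    }
    return(list(len = sub$len,
                node = list(left = kids[[1]], right = kids[[2]])))
  }
  l <- attach_ends(sub$node$left, snode, b, d, env)
  r <- attach_ends(sub$node$right, snode, b, d, env)
  if (is.null(l) && is.null(r)) return(NULL)
  if (is.null(l) || is.null(r)) {
    surv <- if (is.null(l)) r else l
    return(list(len = sub$len + surv$len, node = surv$node))
  }
  list(len = sub$len, node = list(left = l, right = r))
}

# surviving lineages ("end" markers) of a within-branch simulation
bd_branch_ends <- function(sub) {
  if (is.null(sub)) return(list())
  if (identical(sub$node, "end")) return(list(sub))
  c(bd_branch_ends(sub$node$left), bd_branch_ends(sub$node$right))
}

bd_leaves <- function(sub) {
  if (!is.null(sub$node$species)) return(list(sub$node))
  c(bd_leaves(sub$node$left), bd_leaves(sub$node$right))
}

bd_label <- function(sub, family, cnt) {
  species <- character(0)
  walk <- function(s) {
    if (!is.null(s$node$species)) {
      cnt$i <- cnt$i + 1L
      lab <- paste0(family, "_", s$node$species, "_", cnt$i)
      species[lab] <<- s$node$species
      return(list(len = s$len, node = list(species = s$node$species, label = lab)))
    }
    list(len = s$len, node = list(left = walk(s$node$left),
                                  right = walk(s$node$right)))
  }
  tree <- walk(sub)
  list(tree = tree, species = species)
}

bd_newick <- function(sub) {
  if (!is.null(sub$node$label)) {
    return(paste0(sub$node$label, ":", format(sub$len, digits = 10)))
  }
  paste0("(", bd_newick(sub$node$left), ",", bd_newick(sub$node$right),
         "):", format(sub$len, digits = 10))
}

# ---- codon sequence evolution along a gene tree ---------------------------

#' Evolve codon sequences along a gene tree
#'
#' A GY94/M0-style codon process (transition/transversion ratio kappa,
#' nonsynonymous changes scaled by omega, zero rate into stop codons) is
#' simulated site-wise with exponential waiting times along every branch.
#' Branch lengths are expected substitutions per codon at omega = 1.
#'
#' @param gene_tree rooted `phylo` with branch lengths
#' @param omega dN/dS of the process
#' @param kappa transition/transversion rate ratio
#' @param coding_length sequence length in nt (multiple of 3)
#' @param ancestral optional ancestral CDS (random sense codons otherwise)
#' @return named character vector of leaf coding sequences
#' @export
evolve_codon_sequences <- function(gene_tree, omega, kappa, coding_length,
                                   ancestral = NULL) {
  if (coding_length %% 3 != 0) stop("coding length not a multiple of 3")
  if (any(gene_tree$edge.length < 0)) stop("negative branch length")
  tables <- codon_rate_tables(omega, kappa)
  ncod <- coding_length %/% 3
  root_states <- if (is.null(ancestral)) random_codon_states(ncod)
                 else seq_to_codon_states(ancestral)
  ntip <- length(gene_tree$tip.label)
  nnode <- ntip + gene_tree$Nnode
  states <- vector("list", nnode)
  states[[phylo_root(gene_tree)]] <- root_states
  pre <- ape::reorder.phylo(gene_tree, "cladewise")
  for (e in seq_len(nrow(pre$edge))) {
    p <- pre$edge[e, 1]; ch <- pre$edge[e, 2]
    states[[ch]] <- evolve_codon_states(states[[p]], pre$edge.length[e], tables)
  }
  out <- vapply(seq_len(ntip), function(i) codon_states_to_seq(states[[i]]),
                character(1))
  stats::setNames(out, gene_tree$tip.label)
}

# evolve a single pair of sequences separated by total path length t
# (used heavily by recovery tests); returns list(a =, b =)
evolve_sequence_pair <- function(omega, kappa, coding_length, t) {
  tables <- codon_rate_tables(omega, kappa)
  ncod <- coding_length %/% 3
  anc <- random_codon_states(ncod)
  a <- evolve_codon_states(anc, t / 2, tables)
  b <- evolve_codon_states(anc, t / 2, tables)
  list(a = codon_states_to_seq(a), b = codon_states_to_seq(b))
}

#' Simulate ortholog coding-sequence pairs at a known omega
#'
#' Convenience generator for parameter-recovery experiments: `n`
#' independent pairs, each evolved from a random ancestor along two
#' branches of length `t / 2`.
#'
#' @param n number of pairs
#' @param omega,kappa process parameters
#' @param coding_length CDS length (nt, multiple of 3)
#' @param t total path length between the pair (expected substitutions per
#'   codon at omega = 1)
#' @param class label attached to the pairs
#' @return tibble with `id_a`, `id_b`, `cds_a`, `cds_b`, `class`
#' @export
simulate_ortholog_pairs <- function(n, omega, kappa = 2, coding_length = 900,
                                    t = 0.1, class = "nontoxin") {
  rows <- lapply(seq_len(n), function(i) {
    p <- evolve_sequence_pair(omega, kappa, coding_length, t)
    tibble::tibble(id_a = sprintf("A_%s%04d", class, i),
                   id_b = sprintf("B_%s%04d", class, i),
                   cds_a = p$a, cds_b = p$b, class = class)
  })
  dplyr::bind_rows(rows)
}

# ---- expression -----------------------------------------------------------

#' Simulate per-species expression profiles
#'
#' Nontoxin abundances for species B equal species A times
#' lognormal(0, sd^2) noise; toxin family shares are shifted between
#' species by lognormal(0, divergence^2) factors; each species'
#' abundances are normalised to percentages summing to 100.
#'
#' @param config a [sim_config()]
#' @param genes tibble with `gene`, `class`, `family` (families for toxin
#'   rows); when NULL a skeleton is built from the config (one toxin gene
#'   per family)
#' @return tibble: `species`, `gene`, `class`, `family`, `abundance_pct`
#' @export
simulate_expression <- function(config, genes = NULL) {
  if (is.null(genes)) {
    genes <- dplyr::bind_rows(
      tibble::tibble(gene = sprintf("NT%04d", seq_len(config$n_nontoxins)),
                     class = "nontoxin", family = NA_character_),
      tibble::tibble(gene = paste0(names(config$toxin_families), "_1"),
                     class = "toxin", family = names(config$toxin_families))
    )
  }
  expr <- simulate_expression_two(config, genes, genes)
  dplyr::left_join(expr, genes, by = "gene") |>
    dplyr::select("species", "gene", "class", "family", "abundance_pct")
}

# ---- reads ----------------------------------------------------------------

#' Simulate overlapping paired-end reads from transcripts
#'
#' Fragments of fixed length are drawn from transcripts proportionally to
#' abundance with uniform start positions; each fragment yields a forward
#' read and a reverse-complemented mate whose 3' ends overlap by
#' `2 * read_length - fragment_length` bases. Errors are injected per base
#' at the configured rate; phred scores are constant at
#' `round(-10 log10(error_rate))` (40 when the rate is 0).
#'
#' @param transcripts named character vector
#' @param abundances abundance weights aligned with `transcripts`
#' @param config a [sim_config()]
#' @return tibble: `id`, `seq1`, `qual1`, `seq2`, `qual2`, `transcript`,
#'   `start` (fragment origin, ground truth)
#' @export
simulate_reads <- function(transcripts, abundances, config) {
  stopifnot(length(transcripts) == length(abundances), all(abundances >= 0))
  rl <- config$read_length; fl <- config$fragment_length
  n <- config$n_read_pairs
  lens <- nchar(transcripts)
  ok <- lens >= fl
  if (any(!ok)) {
    warning(sum(!ok), " transcript(s) shorter than the fragment length were skipped")
    transcripts <- transcripts[ok]; abundances <- abundances[ok]
    lens <- lens[ok]
  }
  stopifnot(length(transcripts) > 0, sum(abundances) > 0)
  prob <- abundances / sum(abundances)
  pick <- sample.int(length(transcripts), n, replace = TRUE, prob = prob)
  start <- floor(stats::runif(n) * (lens[pick] - fl + 1)) + 1L
  frag <- substr(transcripts[pick], start, start + fl - 1L)
  r1 <- substr(frag, 1L, rl)
  r2 <- vapply(substr(frag, fl - rl + 1L, fl), revcomp, character(1),
               USE.NAMES = FALSE)
  er <- config$error_rate
  inject <- function(seqs) {
    if (er == 0) return(seqs)
    vapply(seqs, function(s) {
      ch <- strsplit(s, "")[[1]]
      hit <- which(stats::runif(length(ch)) < er)
      if (length(hit) > 0) {
        ch[hit] <- vapply(ch[hit], function(b)
          sample(setdiff(c("A", "C", "G", "T"), b), 1L), character(1))
      }
      paste(ch, collapse = "")
    }, character(1), USE.NAMES = FALSE)
  }
  r1 <- inject(r1); r2 <- inject(r2)
  q <- if (er > 0) as.integer(round(-10 * log10(er))) else 40L
  q <- max(2L, min(q, 93L))
  tibble::tibble(
    id = sprintf("read%06d", seq_len(n)),
    seq1 = r1, qual1 = replicate(n, rep(q, rl), simplify = FALSE),
    seq2 = r2, qual2 = replicate(n, rep(q, rl), simplify = FALSE),
    transcript = names(transcripts)[pick],
    start = start
  )
}

# ---- full dataset ---------------------------------------------------------

random_nt <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

mutate_nt <- function(seq, p) {
  if (p <= 0) return(seq)
  ch <- strsplit(seq, "")[[1]]
  hit <- which(stats::runif(length(ch)) < min(p, 0.75))
  if (length(hit) > 0) {
    ch[hit] <- vapply(ch[hit], function(b)
      sample(setdiff(c("A", "C", "G", "T"), b), 1L), character(1))
  }
  paste(ch, collapse = "")
}

#' Simulate a complete two-species venom-gland transcriptome dataset
#'
#' Runs the full generator under the config seed: toxin gene-family
#' birth-death histories with codon sequences at the family omega,
#' nontoxin orthologs (one copy per species) at the nontoxin omega,
#' untranslated regions, expression profiles, and paired reads per
#' species. All downstream truth (family trees, per-branch event counts,
#' per-gene omega, abundances, read origins) is returned.
#'
#' @param config a [sim_config()]
#' @return list of class `sim_dataset` with `transcripts` (tibble:
#'   `species`, `id`, `gene`, `class`, `family`, `omega`, `seq`, `cds`,
#'   `abundance_pct`), `reads` (named list of read tibbles per species),
#'   `families` (list of `gene_family_history`), `ortholog_truth` (tibble
#'   of planted nontoxin pairs), `config`
#' @export
simulate_transcriptomes <- function(config = sim_config()) {
  validate_sim_config(config)
  set.seed(config$seed)
  stree_phy <- ape::read.tree(text = config$species_tree)
  # --- nontoxins: one copy per species, evolved jointly for speed
  ncod <- config$coding_length %/% 3
  ngene <- config$n_nontoxins
  nt_leaf <- list()
  if (ngene > 0) {
    tables_nt <- codon_rate_tables(config$nontoxin_omega, config$kappa)
    anc <- random_codon_states(ncod * ngene)
    nodes <- list()
    nodes[[node_label(stree_phy, phylo_root(stree_phy))]] <- anc
    pre <- ape::reorder.phylo(stree_phy, "cladewise")
    labs <- c(stree_phy$tip.label,
              if (!is.null(stree_phy$node.label)) stree_phy$node.label)
    for (e in seq_len(nrow(pre$edge))) {
      p <- node_label(stree_phy, pre$edge[e, 1])
      ch <- node_label(stree_phy, pre$edge[e, 2])
      nodes[[ch]] <- evolve_codon_states(nodes[[p]], pre$edge.length[e],
                                         tables_nt)
    }
    split_genes <- function(states) {
      vapply(seq_len(ngene), function(i) {
        codon_states_to_seq(states[((i - 1) * ncod + 1):(i * ncod)])
      }, character(1))
    }
    nt_leaf <- lapply(nodes[stree_phy$tip.label], split_genes)
  }
  # --- toxin families
  families <- list()
  fam_seqs <- list()
  for (nm in names(config$toxin_families)) {
    fam <- simulate_gene_family(config, config$toxin_families[[nm]], name = nm)
    families[[nm]] <- fam
    fam_seqs[[nm]] <- evolve_codon_sequences(
      fam$tree, fam$omega, config$kappa, config$coding_length)
  }
  # --- assemble per-species transcript tables
  utr5_len <- 30L; utr3_len <- 45L
  tipdist <- ape::node.depth.edgelength(stree_phy)[seq_len(3)]
  names(tipdist) <- stree_phy$tip.label
  rows <- list()
  add_gene <- function(species, gene, class, family, omega, cds, utr5, utr3) {
    mut_p <- tipdist[[species]] / 3  # nt-scale divergence from the root
    u5 <- mutate_nt(utr5, mut_p); u3 <- mutate_nt(utr3, mut_p)
    rows[[length(rows) + 1L]] <<- tibble::tibble(
      species = species, id = paste0(species, "_", gene), gene = gene,
      class = class, family = family, omega = omega,
      utr5 = u5, utr3 = u3, cds = cds, seq = paste0(u5, cds, u3))
  }
  if (ngene > 0) {
    nt_utr5 <- vapply(seq_len(ngene), function(i) random_nt(utr5_len), character(1))
    nt_utr3 <- vapply(seq_len(ngene), function(i) random_nt(utr3_len), character(1))
    for (sp in stree_phy$tip.label) {
      for (i in seq_len(ngene)) {
        add_gene(sp, sprintf("NT%04d", i), "nontoxin", NA_character_,
                 config$nontoxin_omega, nt_leaf[[sp]][i],
                 nt_utr5[i], nt_utr3[i])
      }
    }
  }
  for (nm in names(families)) {
    fam <- families[[nm]]
    u5 <- random_nt(utr5_len); u3 <- random_nt(utr3_len)
    for (leaf in names(fam$leaf_species)) {
      sp <- fam$leaf_species[[leaf]]
      add_gene(sp, leaf, "toxin", nm, fam$omega, fam_seqs[[nm]][[leaf]],
               u5, u3)
    }
  }
  transcripts <- dplyr::bind_rows(rows)
  # --- expression (ingroup species only) and reads
  reads <- list()
  genesA <- transcripts[transcripts$species == "A", c("gene", "class", "family")]
  genesB <- transcripts[transcripts$species == "B", c("gene", "class", "family")]
  expr <- simulate_expression_two(config, genesA, genesB)
  transcripts <- dplyr::left_join(
    transcripts, expr, by = c("species", "gene"))
  for (sp in c("A", "B")) {
    sub <- transcripts[transcripts$species == sp, , drop = FALSE]
    reads[[sp]] <- simulate_reads(
      stats::setNames(sub$seq, sub$id), sub$abundance_pct, config)
  }
  ortholog_truth <- if (ngene > 0) tibble::tibble(
    id_a = sprintf("A_NT%04d", seq_len(ngene)),
    id_b = sprintf("B_NT%04d", seq_len(ngene)),
    omega = config$nontoxin_omega) else tibble::tibble()
  structure(list(transcripts = transcripts, reads = reads,
                 families = families, ortholog_truth = ortholog_truth,
                 config = config),
            class = "sim_dataset")
}

# expression model where the two species have their own gene rows
# (nontoxins shared 1:1 by gene index; toxin copies species-specific)
simulate_expression_two <- function(config, genesA, genesB) {
  ntA <- genesA[genesA$class == "nontoxin", , drop = FALSE]
  ntB <- genesB[genesB$class == "nontoxin", , drop = FALSE]
  stopifnot(identical(ntA$gene, ntB$gene))
  base_nt <- stats::rlnorm(nrow(ntA), meanlog = log(50), sdlog = 1.2)
  nt_b <- base_nt * stats::rlnorm(nrow(ntA), 0, config$expression_noise_sd)
  toxA <- genesA[genesA$class == "toxin", , drop = FALSE]
  toxB <- genesB[genesB$class == "toxin", , drop = FALSE]
  fams <- union(toxA$family, toxB$family)
  share_a <- stats::rlnorm(length(fams), 0, 1)
  share_b <- share_a * stats::rlnorm(length(fams), 0, config$toxin_divergence)
  names(share_a) <- names(share_b) <- fams
  wA <- stats::rexp(nrow(toxA)) + 0.2
  wB <- stats::rexp(nrow(toxB)) + 0.2
  tox_a <- share_a[toxA$family] * wA
  tox_b <- share_b[toxB$family] * wB
  mix <- function(ntv, toxv) {
    out <- c(ntv / sum(ntv) * (1 - config$toxin_fraction),
             if (length(toxv)) toxv / sum(toxv) * config$toxin_fraction)
    100 * out / sum(out)
  }
  dplyr::bind_rows(
    tibble::tibble(species = "A", gene = c(ntA$gene, toxA$gene),
                   abundance_pct = mix(base_nt, tox_a)),
    tibble::tibble(species = "B", gene = c(ntB$gene, toxB$gene),
                   abundance_pct = mix(nt_b, tox_b))
  )
}

#' Write a simulated dataset to disk
#'
#' Standard formats: per-species transcript FASTA with
#' `|class=...|family=...` header tags, paired FASTQ (phred+33), newick
#' gene trees and species tree, and a ground-truth TSV.
#'
#' @param dataset a `sim_dataset`
#' @param dir output directory (created if needed)
#' @return the directory, invisibly
#' @export
write_simulation <- function(dataset, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  tr <- dataset$transcripts
  for (sp in unique(tr$species)) {
    sub <- tr[tr$species == sp, , drop = FALSE]
    hdr <- paste0(sub$id, "|class=", sub$class,
                  ifelse(is.na(sub$family), "",
                         paste0("|family=", sub$family)))
    seqs <- Biostrings::DNAStringSet(stats::setNames(sub$seq, hdr))
    Biostrings::writeXStringSet(seqs, file.path(dir, paste0(sp, "_transcripts.fasta")))
    if (!is.null(dataset$reads[[sp]])) {
      rd <- dataset$reads[[sp]]
      write_fastq_tbl(tibble::tibble(id = rd$id, seq = rd$seq1, qual = rd$qual1),
                      file.path(dir, paste0(sp, "_R1.fastq")))
      write_fastq_tbl(tibble::tibble(id = rd$id, seq = rd$seq2, qual = rd$qual2),
                      file.path(dir, paste0(sp, "_R2.fastq")))
    }
  }
  writeLines(dataset$config$species_tree, file.path(dir, "species_tree.nwk"))
  for (nm in names(dataset$families)) {
    ape::write.tree(dataset$families[[nm]]$tree,
                    file.path(dir, paste0("genetree_", nm, ".nwk")))
  }
  truth <- tr[, c("species", "id", "gene", "class", "family", "omega",
                  "abundance_pct")]
  utils::write.table(truth, file.path(dir, "truth.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(dir)
}
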