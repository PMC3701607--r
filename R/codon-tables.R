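# Genetic-code lookups and Nei-Gojobori counting tables.
#
# Everything here works on codon *indices* 1..64 into `td_codons()` so the
# per-pair estimators reduce to matrix lookups; the tables are computed once
# per session by explicit enumeration of single-nucleotide changes and
# mutational pathways, and cached.

.td_cache <- new.env(parent = emptyenv())

NT <- c("A", "C", "G", "T")

#' All 64 codons in fixed lexicographic order
#' @return character vector of length 64
#' @keywords internal
td_codons <- function() {
  if (is.null(.td_cache$codons)) {
    .td_cache$codons <- as.character(outer(
      outer(NT, NT, paste0), NT, paste0
    ))
  }
  .td_cache$codons
}

#' Amino acid encoded by each codon ("*" for stops)
#' @keywords internal
td_codon_aa <- function() {
  if (is.null(.td_cache$aa)) {
    gc <- Biostrings::GENETIC_CODE
    .td_cache$aa <- unname(gc[td_codons()])
  }
  .td_cache$aa
}

td_stop_idx <- function() which(td_codon_aa() == "*")

codon_index <- function(codons) {
  i <- match(toupper(codons), td_codons())
  if (anyNA(i)) {
    bad <- codons[is.na(i)]
    stop("not a codon over A/C/G/T: ", paste(unique(bad), collapse = ", "))
  }
  i
}

is_transition <- function(a, b) {
  (a %in% c("A", "G") && b %in% c("A", "G")) ||
    (a %in% c("C", "T") && b %in% c("C", "T"))
}

# Split codon strings into a 3-column base matrix
codon_bases <- function(codons) {
  matrix(unlist(strsplit(codons, "", fixed = TRUE)), ncol = 3, byrow = TRUE)
}

#' Synonymous and nonsynonymous site counts of a codon (NG86)
#'
#' For each codon position the synonymous fraction is the number of
#' single-nucleotide changes that preserve the amino acid divided by the
#' number of changes that do not create a stop codon. Summing the fractions
#' gives the synonymous site count S of the codon; N = 3 - S.
#'
#' @param codon a single non-stop codon (3 characters over A/C/G/T)
#' @return named numeric vector `c(S = ..., N = ...)`
#' @examples
#' ng86_sites("TTT")  # S = 1/3
#' ng86_sites("GCT")  # S = 1 (fourfold-degenerate third position)
#' @export
ng86_sites <- function(codon) {
  stopifnot(length(codon) == 1L)
  i <- codon_index(codon)
  if (td_codon_aa()[i] == "*") stop("stop codon has no NG86 sites: ", codon)
  tab <- ng86_site_table()
  c(S = tab$S[i], N = tab$N[i])
}

# Site counts for all 64 codons (NA rows for stops)
ng86_site_table <- function() {
  if (!is.null(.td_cache$sites)) return(.td_cache$sites)
  codons <- td_codons()
  aa <- td_codon_aa()
  S <- rep(NA_real_, 64L)
  for (i in seq_len(64L)) {
    if (aa[i] == "*") next
    b <- strsplit(codons[i], "")[[1]]
    s <- 0
    for (pos in 1:3) {
      syn <- 0L; nonstop <- 0L
      for (nt in setdiff(NT, b[pos])) {
        mut <- b; mut[pos] <- nt
        j <- match(paste(mut, collapse = ""), codons)
        if (aa[j] == "*") next
        nonstop <- nonstop + 1L
        if (aa[j] == aa[i]) syn <- syn + 1L
      }
      if (nonstop > 0L) s <- s + syn / nonstop
    }
    S[i] <- s
  }
  .td_cache$sites <- list(S = S, N = ifelse(is.na(S), NA_real_, 3 - S))
  .td_cache$sites
}

#' Pathway-averaged synonymous and nonsynonymous differences (NG86)
#'
#' Codon pairs differing at k positions are connected by k! mutational
#' pathways; each pathway's steps are classified synonymous or
#' nonsynonymous and the counts are averaged over pathways that avoid stop
#' codons. If every pathway passes through a stop, the average is taken
#' over all pathways with stop-creating steps counted as nonsynonymous.
#'
#' @param codA,codB two non-stop codons
#' @return named numeric vector `c(Sd = ..., Nd = ...)`; `Sd + Nd` equals the
#'   number of differing positions
#' @examples
#' ng86_differences("TTT", "TTC")  # one synonymous step
#' ng86_differences("TTT", "GTA")  # Sd = 0.5, Nd = 1.5
#' @export
ng86_differences <- function(codA, codB) {
  i <- codon_index(codA); j <- codon_index(codB)
  aa <- td_codon_aa()
  if (aa[i] == "*" || aa[j] == "*") stop("stop codons are not compared")
  m <- ng86_diff_matrices()
  c(Sd = m$Sd[i, j], Nd = m$Nd[i, j])
}

# all permutations of 1..n (n <= 3 here)
td_perms <- function(n) {
  if (n == 1L) return(list(1L))
  out <- list()
  for (k in seq_len(n)) {
    for (p in td_perms(n - 1L)) {
      rest <- seq_len(n)[-k]
      out[[length(out) + 1L]] <- c(k, rest[p])
    }
  }
  out
}

# Pathway-averaged difference counts for every ordered codon pair.
ng86_diff_matrices <- function() {
  if (!is.null(.td_cache$diffs)) return(.td_cache$diffs)
  codons <- td_codons()
  aa <- td_codon_aa()
  bases <- codon_bases(codons)
  Sd <- matrix(NA_real_, 64, 64)
  Nd <- matrix(NA_real_, 64, 64)
  for (i in seq_len(64L)) {
    if (aa[i] == "*") next
    for (j in seq_len(64L)) {
      if (aa[j] == "*") next
      pos <- which(bases[i, ] != bases[j, ])
      k <- length(pos)
      if (k == 0L) { Sd[i, j] <- 0; Nd[i, j] <- 0; next }
      paths <- td_perms(k)
      # per ordering: synonymous step count and whether a stop was crossed;
      # a step is synonymous iff the amino acid is unchanged, so steps into
      # or out of a stop codon classify as nonsynonymous automatically
      res <- lapply(paths, function(ord) {
        cur <- bases[i, ]
        s <- 0; blocked <- FALSE
        from_aa <- aa[i]
        for (p in pos[ord]) {
          cur[p] <- bases[j, p]
          to_aa <- aa[match(paste(cur, collapse = ""), codons)]
          if (to_aa == "*") blocked <- TRUE
          if (to_aa == from_aa) s <- s + 1
          from_aa <- to_aa
        }
        c(s = s, blocked = as.numeric(blocked))
      })
      s_path <- vapply(res, `[`, numeric(1), "s")
      ok <- vapply(res, `[`, numeric(1), "blocked") == 0
      # average over stop-free pathways; if none exist, over all pathways
      # (stop-crossing steps then count as nonsynonymous)
      use <- if (any(ok)) s_path[ok] else s_path
      Sd[i, j] <- mean(use)
      Nd[i, j] <- k - Sd[i, j]
    }
  }
  .td_cache$diffs <- list(Sd = Sd, Nd = Nd)
  .td_cache$diffs
}

# ---------------------------------------------------------------------------
# Codon substitution process (GY94/M0 style) used by the simulator.
#
# Single-nucleotide neighbour rates: kappa for transitions, 1 for
# transversions, multiplied by omega for nonsynonymous changes; changes into
# stop codons have rate 0. Rates are rescaled so that the mean total rate
# over the 61 sense codons at omega = 1 equals 1, making branch lengths
# expected substitutions per codon at omega = 1.

# Neighbour structure: for each codon, its 9 single-nt mutants with
# transition flag and synonymous flag.
td_codon_neighbors <- function() {
  if (!is.null(.td_cache$nbr)) return(.td_cache$nbr)
  codons <- td_codons()
  aa <- td_codon_aa()
  bases <- codon_bases(codons)
  to <- matrix(0L, 64, 9)
  ts <- matrix(FALSE, 64, 9)
  syn <- matrix(FALSE, 64, 9)
  for (i in seq_len(64L)) {
    col <- 0L
    for (pos in 1:3) {
      for (nt in setdiff(NT, bases[i, pos])) {
        col <- col + 1L
        mut <- bases[i, ]; mut[pos] <- nt
        j <- match(paste(mut, collapse = ""), codons)
        to[i, col] <- j
        ts[i, col] <- is_transition(bases[i, pos], nt)
        syn[i, col] <- aa[j] == aa[i]
      }
    }
  }
  .td_cache$nbr <- list(to = to, transition = ts, synonymous = syn)
  .td_cache$nbr
}

# Rate tables for a given omega/kappa: per-codon total rate, neighbour
# targets and cumulative transition probabilities. Stop rows are zero.
codon_rate_tables <- function(omega, kappa) {
  stopifnot(omega >= 0, kappa > 0)
  nbr <- td_codon_neighbors()
  aa <- td_codon_aa()
  rate_for <- function(om) {
    r <- ifelse(nbr$transition, kappa, 1) * ifelse(nbr$synonymous, 1, om)
    r[matrix(aa[nbr$to] == "*", 64, 9)] <- 0
    r[aa == "*", ] <- 0
    r
  }
  sense <- aa != "*"
  scale <- mean(rowSums(rate_for(1))[sense])
  r <- rate_for(omega) / scale
  total <- rowSums(r)
  cum <- t(apply(r, 1, cumsum))
  cum_norm <- cum / ifelse(total > 0, total, 1)
  list(total = total, to = nbr$to, cum = cum_norm,
       synonymous = nbr$synonymous)
}

# Evolve codon-state vector along a branch of length t (expected
# substitutions per codon at omega = 1). Vectorised Gillespie: only sites
# with a pending event are revisited.
evolve_codon_states <- function(states, t, tables) {
  if (t < 0) stop("negative branch length")
  if (t == 0) return(states)
  remaining <- rep(t, length(states))
  active <- seq_along(states)
  while (length(active) > 0L) {
    r <- tables$total[states[active]]
    wait <- stats::rexp(length(active), rate = pmax(r, 1e-300))
    wait[r == 0] <- Inf
    hit <- wait < remaining[active]
    idx <- active[hit]
    if (length(idx) > 0L) {
      remaining[idx] <- remaining[idx] - wait[hit]
      u <- stats::runif(length(idx))
      pick <- 1L + rowSums(tables$cum[states[idx], , drop = FALSE] < u)
      states[idx] <- tables$to[cbind(states[idx], pick)]
    }
    active <- idx
  }
  states
}

# Random sense-codon sequence (uniform over the 61 non-stop codons)
random_codon_states <- function(n_codons) {
  sense <- which(td_codon_aa() != "*")
  sample(sense, n_codons, replace = TRUE)
}

codon_states_to_seq <- function(states) {
  paste(td_codons()[states], collapse = "")
}

seq_to_codon_states <- function(seq) {
  n <- nchar(seq)
  if (n %% 3 != 0) stop("coding length not a multiple of 3")
  codon_index(substring(seq, seq(1, n, 3), seq(3, n, 3)))
}
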