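# Self-contained similarity search with ungapped Karlin-Altschul E-value
# statistics and dual (nucleotide + protein) reciprocal-best-hit orthology.

#' Solve for the Karlin-Altschul lambda parameter
#'
#' The unique positive root of sum_ij p_i p_j exp(lambda * s_ij) = 1,
#' defined when the expected pair score is negative and at least one score
#' is positive. Found by bracketed root-finding to 1e-12.
#'
#' @param matrix square substitution matrix (scores)
#' @param freqs letter background frequencies (recycled to both axes;
#'   must sum to 1 over the matrix alphabet)
#' @return lambda in nats per score unit
#' @examples
#' m <- matrix(-1, 4, 4); diag(m) <- 1
#' solve_lambda(m, rep(0.25, 4))  # log(3)
#' @export
solve_lambda <- function(matrix, freqs) {
  stopifnot(nrow(matrix) == ncol(matrix), length(freqs) == nrow(matrix))
  freqs <- freqs / sum(freqs)
  pp <- outer(freqs, freqs)
  expected <- sum(pp * matrix)
  if (expected >= 0 || !any(matrix > 0)) {
    stop("statistics undefined for this matrix/background ",
         "(expected score must be negative with at least one positive score)")
  }
  f <- function(lam) sum(pp * exp(lam * matrix)) - 1
  hi <- 1
  while (f(hi) < 0) hi <- hi * 2
  stats::uniroot(f, c(1e-10, hi), tol = 1e-12)$root
}

# Default ungapped statistics per mode. K values are the published
# ungapped constants (BLOSUM62 ~ 0.13; nt +1/-2 ~ 0.62); lambda is solved
# exactly for the scoring system and background.
ka_params <- function(mode = c("nt", "protein"), K = NULL) {
  mode <- match.arg(mode)
  key <- paste0("ka_", mode)
  if (is.null(.td_cache[[key]])) {
    if (mode == "nt") {
      m <- matrix(-2, 4, 4); diag(m) <- 1
      freqs <- rep(0.25, 4)
      Kdef <- 0.62
    } else {
      aas <- c("A","R","N","D","C","Q","E","G","H","I",
               "L","K","M","F","P","S","T","W","Y","V")
      m <- td_blosum62()[aas, aas]
      # Robinson-Robinson amino-acid background frequencies
      freqs <- c(A=0.07805, R=0.05129, N=0.04487, D=0.05364, C=0.01925,
                 Q=0.04264, E=0.06295, G=0.07377, H=0.02199, I=0.05142,
                 L=0.09019, K=0.05744, M=0.02243, F=0.03856, P=0.05203,
                 S=0.07120, T=0.05841, W=0.01330, Y=0.03216, V=0.06441)
      Kdef <- 0.13
    }
    .td_cache[[key]] <- list(lambda = solve_lambda(m, freqs),
                             K = Kdef, matrix = m, freqs = freqs)
  }
  p <- .td_cache[[key]]
  if (!is.null(K)) p$K <- K
  p
}

evalue_from_score <- function(score, m, n, params) {
  params$K * m * n * exp(-params$lambda * score)
}

bitscore_from_score <- function(score, params) {
  (params$lambda * score - log(params$K)) / log(2)
}

# k-mer index of a database: named list kmer -> integer vector of
# sequence indices containing it
kmer_index <- function(seqs, k) {
  idx <- new.env(parent = emptyenv())
  for (i in seq_along(seqs)) {
    s <- seqs[[i]]
    n <- nchar(s)
    if (n < k) next
    kmers <- unique(substring(s, 1:(n - k + 1), k:n))
    for (km in kmers) {
      idx[[km]] <- c(idx[[km]], i)
    }
  }
  idx
}

search_db <- function(seqs, mode, k) {
  list(seqs = seqs, mode = mode, k = k,
       index = kmer_index(seqs, k),
       total_length = sum(nchar(seqs)))
}

# Local-alignment score of query vs one subject (Smith-Waterman via
# Biostrings)
local_score <- function(query, subject, mode) {
  if (mode == "nt") {
    submat <- Biostrings::nucleotideSubstitutionMatrix(
      match = 1, mismatch = -2, baseOnly = FALSE)
    Biostrings::pairwiseAlignment(
      Biostrings::DNAString(query), Biostrings::DNAString(subject),
      substitutionMatrix = submat, gapOpening = 5, gapExtension = 2,
      type = "local", scoreOnly = TRUE)
  } else {
    Biostrings::pairwiseAlignment(
      Biostrings::AAString(query), Biostrings::AAString(subject),
      substitutionMatrix = td_blosum62(), gapOpening = 11, gapExtension = 1,
      type = "local", scoreOnly = TRUE)
  }
}

#' Best database hit for a query under an E-value cutoff
#'
#' Candidate subjects are those sharing at least one exact k-mer with the
#' query (k = 11 for nucleotide mode, 4 for protein); candidates are scored
#' with Smith-Waterman local alignment and ranked by the Karlin-Altschul
#' E-value `E = K m n exp(-lambda S)` with m the query length and n the
#' total database length. Ties break by higher raw score, then
#' lexicographic subject id.
#'
#' @param query query sequence (character)
#' @param database named character vector of subject sequences
#' @param mode `"nt"` or `"protein"`
#' @param e_cutoff maximum E-value (default 1e-6)
#' @param k seed length (default 11 nt / 4 protein)
#' @param max_candidates cap on the number of seeded candidates scored,
#'   keeping those sharing the most k-mers
#' @param K override for the Karlin-Altschul K constant
#' @return one-row tibble (`query`, `subject`, `score`, `bitscore`,
#'   `evalue`) or `NULL` if no hit passes the cutoff
#' @export
search_best_hit <- function(query, database, mode = c("nt", "protein"),
                            e_cutoff = 1e-6, k = NULL, max_candidates = 12,
                            K = NULL) {
  mode <- match.arg(mode)
  if (length(database) == 0L) stop("empty database")
  if (is.null(names(database))) stop("database sequences must be named")
  if (is.null(k)) k <- if (mode == "nt") 11L else 4L
  params <- ka_params(mode, K = K)
  db <- search_db(database, mode, k)
  best_hit_against(query, db, params, e_cutoff, max_candidates)
}

best_hit_against <- function(query, db, params, e_cutoff, max_candidates = 12) {
  n <- nchar(query)
  if (n < db$k) return(NULL)
  kmers <- unique(substring(query, 1:(n - db$k + 1), db$k:n))
  hits <- unlist(lapply(kmers, function(km) db$index[[km]]), use.names = FALSE)
  if (length(hits) == 0L) return(NULL)
  counts <- sort(table(hits), decreasing = TRUE)
  cand <- as.integer(names(counts))[seq_len(min(length(counts), max_candidates))]
  scores <- vapply(cand, function(i) local_score(query, db$seqs[[i]], db$mode),
                   numeric(1))
  ev <- evalue_from_score(scores, m = n, n = db$total_length, params)
  ord <- order(ev, -scores, names(db$seqs)[cand])
  best <- ord[1]
  if (ev[best] > e_cutoff) return(NULL)
  tibble::tibble(
    subject = names(db$seqs)[cand[best]],
    score = scores[best],
    bitscore = bitscore_from_score(scores[best], params),
    evalue = ev[best]
  )
}

# All best hits of set X against database Y in one mode
all_best_hits <- function(x_seqs, y_seqs, mode, e_cutoff, k, max_candidates) {
  params <- ka_params(mode)
  db <- search_db(y_seqs, mode, k)
  rows <- lapply(names(x_seqs), function(id) {
    h <- best_hit_against(x_seqs[[id]], db, params, e_cutoff, max_candidates)
    if (is.null(h)) return(NULL)
    dplyr::bind_cols(tibble::tibble(query = id), h)
  })
  dplyr::bind_rows(rows)
}

#' Dual reciprocal-best-hit ortholog identification
#'
#' A pair (a, b) is retained iff a and b are each other's best hits in the
#' nucleotide search (full transcripts, untranslated regions included) AND
#' in the protein search (translated coding sequences), with all four
#' searches under the E-value cutoff. Mitochondrially encoded entries are
#' excluded up front; entries whose coding region does not translate
#' (internal stop) are skipped with a message.
#'
#' @param setA,setB tibbles with columns `id`, `seq` (full transcript),
#'   `cds` (coding sequence), optional `mito` (logical) and `class`
#' @param e_cutoff E-value cutoff for all four searches (default 1e-6)
#' @param k_nt,k_protein seed lengths
#' @param max_candidates cap on seeded candidates per query
#' @return tibble of ortholog pairs: `id_a`, `id_b`, `evalue_nt`,
#'   `evalue_protein` (worse of the two directions for each mode), plus
#'   `class` when both members agree
#' @export
reciprocal_best_hits <- function(setA, setB, e_cutoff = 1e-6,
                                 k_nt = 11L, k_protein = 4L,
                                 max_candidates = 12) {
  prep <- function(set, label) {
    stopifnot(all(c("id", "seq", "cds") %in% names(set)))
    if ("mito" %in% names(set)) set <- set[!set$mito, , drop = FALSE]
    prot <- vapply(set$cds, function(cds) {
      p <- tryCatch(translate_cds(strip_terminal_stop(toupper(cds))),
                    error = function(e) NA_character_)
      if (!is.na(p) && grepl("*", p, fixed = TRUE)) NA_character_ else p
    }, character(1), USE.NAMES = FALSE)
    drop <- is.na(prot)
    if (any(drop)) {
      message("skipping ", sum(drop), " untranslatable sequence(s) in ",
              label, ": ", paste(set$id[drop], collapse = ", "))
    }
    set <- set[!drop, , drop = FALSE]
    set$protein <- prot[!drop]
    set
  }
  A <- prep(setA, "set A"); B <- prep(setB, "set B")
  nt_a <- stats::setNames(toupper(A$seq), A$id)
  nt_b <- stats::setNames(toupper(B$seq), B$id)
  aa_a <- stats::setNames(A$protein, A$id)
  aa_b <- stats::setNames(B$protein, B$id)
  h_nt_ab <- all_best_hits(nt_a, nt_b, "nt", e_cutoff, k_nt, max_candidates)
  h_nt_ba <- all_best_hits(nt_b, nt_a, "nt", e_cutoff, k_nt, max_candidates)
  h_aa_ab <- all_best_hits(aa_a, aa_b, "protein", e_cutoff, k_protein, max_candidates)
  h_aa_ba <- all_best_hits(aa_b, aa_a, "protein", e_cutoff, k_protein, max_candidates)
  mutual <- function(ab, ba) {
    if (nrow(ab) == 0L || nrow(ba) == 0L) {
      return(tibble::tibble(id_a = character(), id_b = character(),
                            evalue = numeric()))
    }
    j <- dplyr::inner_join(
      ab, ba, by = c(query = "subject", subject = "query"),
      suffix = c("_ab", "_ba"))
    tibble::tibble(id_a = j$query, id_b = j$subject,
                   evalue = pmax(j$evalue_ab, j$evalue_ba))
  }
  m_nt <- mutual(h_nt_ab, h_nt_ba)
  m_aa <- mutual(h_aa_ab, h_aa_ba)
  pairs <- dplyr::inner_join(m_nt, m_aa, by = c("id_a", "id_b"),
                             suffix = c("_nt", "_protein"))
  if ("class" %in% names(A) && "class" %in% names(B) && nrow(pairs) > 0) {
    ca <- A$class[match(pairs$id_a, A$id)]
    cb <- B$class[match(pairs$id_b, B$id)]
    pairs$class <- ifelse(ca == cb, ca, NA_character_)
  }
  dplyr::arrange(pairs, .data$id_a)
}
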