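# Pairwise global alignment, nucleotide p-distance, and single-linkage
# clustering of toxin coding sequences.

#' Global pairwise alignment with affine gap costs
#'
#' Needleman-Wunsch/Gotoh alignment (via [Biostrings::pairwiseAlignment]).
#' A gap run of length L costs `gap_open + L * gap_extend`. In nucleotide
#' mode scoring uses match/mismatch values; in protein mode a substitution
#' matrix (BLOSUM62 by default).
#'
#' @param a,b sequences (character or XString); non-empty unless the other
#'   is too, in which case an all-gap alignment is returned
#' @param match,mismatch nucleotide scores
#' @param gap_open,gap_extend gap penalties (negative scores)
#' @param mode `"nt"` or `"protein"`
#' @param matrix substitution matrix for protein mode
#' @return a list of class `pairwise_alignment` with gapped rows `a` and
#'   `b`, `score`, and counts `matches`, `mismatches`, `gap_columns`
#' @examples
#' global_align("ACGT", "ACGT")$score  # 4 * match
#' @export
global_align <- function(a, b, match = 5, mismatch = -4,
                         gap_open = -10, gap_extend = -1,
                         mode = c("nt", "protein"), matrix = NULL) {
  mode <- match.arg(mode)
  a <- toupper(as.character(a)); b <- toupper(as.character(b))
  check_alpha <- function(x) {
    ok <- if (mode == "nt") {
      grepl("^[ACGTRYSWKMBDHVN-]*$", x)
    } else {
      grepl("^[ACDEFGHIKLMNPQRSTVWYXBZ*]*$", x)
    }
    if (!ok) {
      bad <- regmatches(x, regexpr(
        if (mode == "nt") "[^ACGTRYSWKMBDHVN-]" else "[^ACDEFGHIKLMNPQRSTVWYXBZ*]", x))
      stop("illegal character in sequence: '", bad, "'")
    }
  }
  check_alpha(a); check_alpha(b)
  if (nchar(a) == 0L && nchar(b) == 0L) stop("both sequences empty")
  if (nchar(a) == 0L || nchar(b) == 0L) {
    n <- max(nchar(a), nchar(b))
    ga <- if (nchar(a)) a else strrep("-", n)
    gb <- if (nchar(b)) b else strrep("-", n)
    return(new_pairwise_alignment(ga, gb, gap_open + gap_extend * n))
  }
  if (mode == "nt") {
    submat <- Biostrings::nucleotideSubstitutionMatrix(
      match = match, mismatch = mismatch, baseOnly = FALSE)
    pa <- Biostrings::pairwiseAlignment(
      Biostrings::DNAString(a), Biostrings::DNAString(b),
      substitutionMatrix = submat,
      gapOpening = -gap_open, gapExtension = -gap_extend, type = "global")
  } else {
    if (is.null(matrix)) {
      matrix <- td_blosum62()
    }
    pa <- Biostrings::pairwiseAlignment(
      Biostrings::AAString(a), Biostrings::AAString(b),
      substitutionMatrix = matrix,
      gapOpening = -gap_open, gapExtension = -gap_extend, type = "global")
  }
  new_pairwise_alignment(as.character(Biostrings::alignedPattern(pa)),
                         as.character(Biostrings::alignedSubject(pa)),
                         Biostrings::score(pa))
}

td_blosum62 <- function() {
  if (is.null(.td_cache$blosum62)) {
    e <- new.env()
    utils::data("BLOSUM62", package = "Biostrings", envir = e)
    .td_cache$blosum62 <- e$BLOSUM62
  }
  .td_cache$blosum62
}

new_pairwise_alignment <- function(ga, gb, score) {
  ca <- strsplit(ga, "")[[1]]; cb <- strsplit(gb, "")[[1]]
  stopifnot(length(ca) == length(cb))
  gap <- ca == "-" | cb == "-"
  structure(
    list(a = ga, b = gb, score = unname(score),
         matches = sum(!gap & ca == cb),
         mismatches = sum(!gap & ca != cb),
         gap_columns = sum(gap),
         length = length(ca)),
    class = "pairwise_alignment")
}

#' @export
print.pairwise_alignment <- function(x, ...) {
  cat("<pairwise_alignment> score", x$score, "|", x$matches, "matches,",
      x$mismatches, "mismatches,", x$gap_columns, "gap columns\n")
  invisible(x)
}

#' Nucleotide p-distance of a pairwise alignment
#'
#' Proportion of differing positions among aligned non-gap columns; gap
#' columns are excluded from numerator and denominator.
#'
#' @param alignment a `pairwise_alignment` (or list with `matches` and
#'   `mismatches` counts)
#' @return fraction in `[0, 1]`
#' @export
p_distance <- function(alignment) {
  comp <- alignment$matches + alignment$mismatches
  if (comp == 0) stop("alignment has no ungapped columns to compare")
  alignment$mismatches / comp
}

#' Cluster sequences by single linkage at a divergence threshold
#'
#' Pairwise p-distances are computed from global alignments; an edge joins
#' two sequences when their distance is strictly below `threshold`, and the
#' connected components are the clusters. The representative of a cluster is
#' its longest member (ties broken lexicographically by name).
#'
#' @param seqs named character vector (or DNAStringSet) of coding sequences
#' @param threshold strict divergence threshold (default 0.01, i.e. < 1%)
#' @return tibble with columns `name`, `cluster`, `representative`,
#'   `cluster_size`
#' @export
cluster_sequences <- function(seqs, threshold = 0.01) {
  if (methods::is(seqs, "XStringSet")) {
    nm <- names(seqs); seqs <- as.character(seqs); names(seqs) <- nm
  }
  n <- length(seqs)
  if (n == 0L) stop("no sequences to cluster")
  if (is.null(names(seqs))) names(seqs) <- paste0("seq", seq_len(n))
  ord <- order(names(seqs))  # order-invariant clustering
  seqs <- seqs[ord]
  parent <- seq_len(n)
  findr <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  if (n > 1L) {
    for (i in seq_len(n - 1L)) {
      for (j in seq.int(i + 1L, n)) {
        ri <- findr(i); rj <- findr(j)
        if (ri == rj) next
        d <- p_distance(global_align(seqs[[i]], seqs[[j]]))
        if (d < threshold) parent[max(ri, rj)] <- min(ri, rj)
      }
    }
  }
  root <- vapply(seq_len(n), findr, integer(1))
  comp <- match(root, sort(unique(root)))
  tbl <- tibble::tibble(name = names(seqs),
                        length = nchar(unname(seqs)),
                        cluster = comp)
  rep_tbl <- tbl |>
    dplyr::arrange(.data$cluster, dplyr::desc(.data$length), .data$name) |>
    dplyr::distinct(.data$cluster, .keep_all = TRUE) |>
    dplyr::select("cluster", representative = "name")
  tbl |>
    dplyr::left_join(rep_tbl, by = "cluster") |>
    dplyr::add_count(.data$cluster, name = "cluster_size") |>
    dplyr::select("name", "cluster", "representative", "cluster_size") |>
    dplyr::arrange(.data$cluster, .data$name)
}
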