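# Codon-aware pairwise alignment, the 24-gapped-position filter, and
# Nei-Gojobori (1986) estimation of dS, dN and omega with Jukes-Cantor
# correction and the dS acceptance windows.

strip_terminal_stop <- function(cds) {
  n <- nchar(cds)
  if (n %% 3 != 0) stop("coding length not a multiple of 3")
  last <- toupper(substr(cds, n - 2L, n))
  if (last %in% c("TAA", "TAG", "TGA")) substr(cds, 1L, n - 3L) else cds
}

translate_cds <- function(cds) {
  as.character(Biostrings::translate(Biostrings::DNAString(cds),
                                     no.init.codon = TRUE))
}

#' Codon-aware pairwise alignment of two coding sequences
#'
#' The translated proteins are globally aligned and the protein gaps mapped
#' back onto whole codons, so gap runs always have nucleotide length 0 mod
#' 3. A single terminal stop codon is allowed and stripped; internal stops
#' reject the pair.
#'
#' @param cdsA,cdsB in-frame coding sequences (lengths multiples of 3)
#' @return list of class `codon_alignment` with gapped rows `a`, `b`,
#'   `gapped_positions` (nucleotide columns containing a gap) and the
#'   underlying protein alignment
#' @export
codon_align <- function(cdsA, cdsB) {
  cdsA <- strip_terminal_stop(toupper(as.character(cdsA)))
  cdsB <- strip_terminal_stop(toupper(as.character(cdsB)))
  pA <- translate_cds(cdsA); pB <- translate_cds(cdsB)
  if (grepl("*", pA, fixed = TRUE)) stop("internal stop codon in first sequence")
  if (grepl("*", pB, fixed = TRUE)) stop("internal stop codon in second sequence")
  aln <- global_align(pA, pB, mode = "protein")
  backtrans <- function(gapped_aa, cds) {
    cod <- substring(cds, seq(1, nchar(cds), 3), seq(3, nchar(cds), 3))
    chars <- strsplit(gapped_aa, "")[[1]]
    out <- character(length(chars))
    k <- 0L
    for (i in seq_along(chars)) {
      if (chars[i] == "-") out[i] <- "---"
      else { k <- k + 1L; out[i] <- cod[k] }
    }
    paste(out, collapse = "")
  }
  ga <- backtrans(aln$a, cdsA)
  gb <- backtrans(aln$b, cdsB)
  ca <- strsplit(ga, "")[[1]]; cb <- strsplit(gb, "")[[1]]
  structure(list(a = ga, b = gb,
                 gapped_positions = sum(ca == "-" | cb == "-"),
                 protein_alignment = aln),
            class = "codon_alignment")
}

#' Gap filter for codon alignments
#'
#' Excludes alignments with strictly more than `max_gapped` gapped
#' nucleotide positions (columns with a gap in either row).
#'
#' @param alignment a `codon_alignment`
#' @param max_gapped threshold (default 24)
#' @return `TRUE` (retained) or `FALSE` (excluded)
#' @export
gap_filter <- function(alignment, max_gapped = 24) {
  alignment$gapped_positions <= max_gapped
}

jc_correct <- function(p) {
  # Jukes-Cantor: d = -(3/4) ln(1 - 4p/3); saturated (p >= 3/4) -> NA
  ifelse(p >= 0.75, NA_real_, -0.75 * log(1 - 4 * p / 3))
}

#' NG86 pairwise substitution rates for an aligned coding pair
#'
#' Sums NG86 site counts (averaged over the two sequences) and
#' pathway-averaged difference counts over ungapped codon columns, converts
#' the proportions pS and pN to rates with the Jukes-Cantor correction, and
#' applies the dS windows: omega is reported only when `dS >= 0.001`
#' (`ds_too_small` otherwise) and pairs with `dS > 0.1` are flagged
#' `ds_too_large` (spurious-ortholog guard). Saturated proportions
#' (p >= 3/4) yield undefined rates.
#'
#' @param alignment a `codon_alignment`, or a list with gapped rows `a`/`b`
#' @param ids optional length-2 identifier vector
#' @param class `"toxin"` or `"nontoxin"` label carried into the result
#' @return one-row tibble: `id_a`, `id_b`, `class`, `S`, `N`, `Sd`, `Nd`,
#'   `pS`, `pN`, `dS`, `dN`, `omega`, `n_codons`, `gap_excluded`,
#'   `ds_too_small`, `ds_too_large`
#' @export
pairwise_rates <- function(alignment, ids = c(NA_character_, NA_character_),
                           class = NA_character_) {
  ca <- strsplit(alignment$a, "")[[1]]
  cb <- strsplit(alignment$b, "")[[1]]
  stopifnot(length(ca) == length(cb), length(ca) %% 3 == 0)
  ncod <- length(ca) %/% 3
  codA <- paste0(ca[seq_len(ncod) * 3 - 2], ca[seq_len(ncod) * 3 - 1], ca[seq_len(ncod) * 3])
  codB <- paste0(cb[seq_len(ncod) * 3 - 2], cb[seq_len(ncod) * 3 - 1], cb[seq_len(ncod) * 3])
  keep <- !grepl("-", codA, fixed = TRUE) & !grepl("-", codB, fixed = TRUE)
  codA <- codA[keep]; codB <- codB[keep]
  if (length(codA) == 0L) stop("no ungapped codon columns to compare")
  ia <- codon_index(codA); ib <- codon_index(codB)
  st <- ng86_site_table()
  dm <- ng86_diff_matrices()
  S <- (sum(st$S[ia]) + sum(st$S[ib])) / 2
  N <- (sum(st$N[ia]) + sum(st$N[ib])) / 2
  Sd <- sum(dm$Sd[cbind(ia, ib)])
  Nd <- sum(dm$Nd[cbind(ia, ib)])
  pS <- Sd / S; pN <- Nd / N
  dS <- jc_correct(pS); dN <- jc_correct(pN)
  ds_too_small <- !is.na(dS) & dS < 0.001
  ds_too_large <- !is.na(dS) & dS > 0.1
  # omega is only meaningful inside the dS window [0.001, 0.1]
  omega <- if (!is.na(dS) && !is.na(dN) && !ds_too_small && !ds_too_large)
    dN / dS else NA_real_
  tibble::tibble(
    id_a = ids[1], id_b = ids[2], class = class,
    S = S, N = N, Sd = Sd, Nd = Nd, pS = pS, pN = pN,
    dS = dS, dN = dN, omega = omega, n_codons = length(codA),
    gap_excluded = FALSE,
    ds_too_small = ds_too_small, ds_too_large = ds_too_large
  )
}

#' NG86 rates for a table of ortholog pairs
#'
#' Aligns each coding pair codon-aware, applies the gap filter, and
#' computes NG86/Jukes-Cantor rates for retained pairs. Pairs failing the
#' gap filter (or with internal stops) appear in the output flagged
#' `gap_excluded` with no rates.
#'
#' @param pairs tibble with columns `id_a`, `id_b`, `cds_a`, `cds_b` and
#'   optionally `class`
#' @param max_gapped gap-filter threshold (default 24 nucleotide positions)
#' @param align set to `FALSE` when the coding pairs are already aligned
#'   (equal length, gaps as `-` in whole codons), skipping the aligner
#' @return tibble, one row per input pair (see [pairwise_rates()])
#' @export
rates_table <- function(pairs, max_gapped = 24, align = TRUE) {
  stopifnot(all(c("id_a", "id_b", "cds_a", "cds_b") %in% names(pairs)))
  if (!"class" %in% names(pairs)) pairs$class <- NA_character_
  rows <- purrr::pmap(
    pairs[, c("id_a", "id_b", "cds_a", "cds_b", "class")],
    function(id_a, id_b, cds_a, cds_b, class) {
      excluded <- function() tibble::tibble(
        id_a = id_a, id_b = id_b, class = class,
        S = NA_real_, N = NA_real_, Sd = NA_real_, Nd = NA_real_,
        pS = NA_real_, pN = NA_real_, dS = NA_real_, dN = NA_real_,
        omega = NA_real_, n_codons = NA_integer_, gap_excluded = TRUE,
        ds_too_small = NA, ds_too_large = NA)
      aln <- if (align) {
        tryCatch(codon_align(cds_a, cds_b), error = function(e) NULL)
      } else {
        gp <- sum(strsplit(cds_a, "")[[1]] == "-" |
                    strsplit(cds_b, "")[[1]] == "-")
        structure(list(a = cds_a, b = cds_b, gapped_positions = gp),
                  class = "codon_alignment")
      }
      if (is.null(aln) || !gap_filter(aln, max_gapped)) return(excluded())
      pairwise_rates(aln, ids = c(id_a, id_b), class = class)
    })
  dplyr::bind_rows(rows)
}
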