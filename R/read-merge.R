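# Merging of 3'-overlapping read pairs into composite reads with
# recombined phred quality scores.

revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

#' Read a FASTQ file into a tibble
#'
#' @param path FASTQ file (4-line records, phred+33)
#' @return tibble with columns `id`, `seq`, `qual` (integer list-column of
#'   phred scores)
#' @export
read_fastq_tbl <- function(path) {
  x <- suppressWarnings(Biostrings::readQualityScaledDNAStringSet(path))
  quals <- as(Biostrings::quality(x), "IntegerList")
  tibble::tibble(
    id = names(x),
    seq = unname(as.character(x)),
    qual = unname(as.list(quals))
  )
}

#' Write a tibble of reads to FASTQ (phred+33)
#'
#' @param reads tibble with `id`, `seq`, `qual` columns
#' @param path output path
#' @export
write_fastq_tbl <- function(reads, path) {
  con <- file(path, "w")
  on.exit(close(con))
  if (nrow(reads) == 0L) return(invisible(path))
  qual_str <- vapply(reads$qual, function(q) {
    intToUtf8(pmin(pmax(q, 0L), 93L) + 33L)
  }, character(1))
  writeLines(paste0("@", reads$id, "\n", reads$seq, "\n+\n", qual_str), con)
  invisible(path)
}

validate_read <- function(seq, qual, id = "?") {
  if (nchar(seq) == 0L) stop("empty read: ", id)
  if (nchar(seq) != length(qual)) {
    stop("malformed record '", id, "': ", nchar(seq), " bases but ",
         length(qual), " quality scores")
  }
  invisible(TRUE)
}

# Trim an exact-match adapter: the read is truncated at the first
# occurrence of the adapter sequence (3' contamination after read-through).
trim_adapter <- function(seq, qual, adapter) {
  if (is.null(adapter) || !nzchar(adapter)) return(list(seq = seq, qual = qual))
  at <- regexpr(adapter, seq, fixed = TRUE)
  if (at > 0) {
    seq <- substr(seq, 1L, at - 1L)
    qual <- qual[seq_len(at - 1L)]
  }
  list(seq = seq, qual = qual)
}

#' Find the best 3' overlap between a read and its reverse-complemented mate
#'
#' Candidate overlap lengths `L >= min_overlap` compare the last `L` bases
#' of `r1` with the first `L` bases of `r2_revcomp`. Positions where either
#' base is N are excluded from both numerator and denominator of the
#' mismatch fraction. Among candidates with mismatch fraction
#' `<= max_mismatch_frac` the one with the fewest mismatches wins, ties
#' going to the longest overlap.
#'
#' @param r1 forward read sequence (character)
#' @param r2_revcomp reverse-complemented mate sequence (character)
#' @param min_overlap minimum overlap length (>= 1)
#' @param max_mismatch_frac maximum tolerated mismatch fraction in `[0, 1)`
#' @return the chosen overlap length, or `NA_integer_` if no candidate
#'   qualifies
#' @export
find_best_overlap <- function(r1, r2_revcomp, min_overlap = 10,
                              max_mismatch_frac = 0.1) {
  stopifnot(min_overlap >= 1, max_mismatch_frac >= 0, max_mismatch_frac < 1)
  if (nchar(r1) == 0L || nchar(r2_revcomp) == 0L) stop("empty read")
  c1 <- strsplit(toupper(r1), "")[[1]]
  c2 <- strsplit(toupper(r2_revcomp), "")[[1]]
  n1 <- length(c1); n2 <- length(c2)
  best_len <- NA_integer_; best_mm <- Inf
  if (min(n1, n2) < min_overlap) return(best_len)
  # longest candidates first so equal-mismatch ties resolve to the longest
  for (L in seq.int(min(n1, n2), min_overlap)) {
    s1 <- c1[seq.int(n1 - L + 1L, n1)]
    s2 <- c2[seq_len(L)]
    usable <- s1 != "N" & s2 != "N"
    denom <- sum(usable)
    mm <- sum(s1[usable] != s2[usable])
    frac <- if (denom == 0L) 0 else mm / denom
    if (frac <= max_mismatch_frac && mm < best_mm) {
      best_mm <- mm; best_len <- L
    }
  }
  best_len
}

#' Merge one read pair into a composite read
#'
#' `r2` is reverse-complemented (qualities reversed) and the best 3'
#' overlap located with [find_best_overlap()]. In the overlap, agreeing
#' positions take quality `min(q1 + q2, 93)`; disagreeing positions take
#' the higher-quality base with quality `|q1 - q2|` (on a quality tie, the
#' base from `r1` with quality 2). Flanking positions keep their original
#' qualities.
#'
#' @param r1,r2 lists with `id`, `seq`, `qual` fields (a tibble row works)
#' @param min_overlap,max_mismatch_frac overlap acceptance thresholds
#' @param adapter optional adapter sequence removed by exact suffix match
#'   before the overlap search
#' @return list of class `composite_read` with `id`, `seq`, `qual`,
#'   `overlap`, `source_ids`; or `NULL` if the pair has no acceptable
#'   overlap
#' @export
merge_pair <- function(r1, r2, min_overlap = 10, max_mismatch_frac = 0.1,
                       adapter = NULL) {
  validate_read(r1$seq, r1$qual, r1$id)
  validate_read(r2$seq, r2$qual, r2$id)
  t1 <- trim_adapter(r1$seq, r1$qual, adapter)
  t2 <- trim_adapter(r2$seq, r2$qual, adapter)
  if (nchar(t1$seq) == 0L || nchar(t2$seq) == 0L) return(NULL)
  s2 <- revcomp(t2$seq)
  q2 <- rev(t2$qual)
  L <- find_best_overlap(t1$seq, s2, min_overlap, max_mismatch_frac)
  if (is.na(L)) return(NULL)
  c1 <- strsplit(toupper(t1$seq), "")[[1]]
  c2 <- strsplit(toupper(s2), "")[[1]]
  q1 <- t1$qual
  n1 <- length(c1); n2 <- length(c2)
  o1 <- seq.int(n1 - L + 1L, n1)   # overlap positions in r1
  o2 <- seq_len(L)                 # overlap positions in r2rc
  ov_base <- character(L); ov_qual <- integer(L)
  agree <- c1[o1] == c2[o2]
  ov_base[agree] <- c1[o1][agree]
  ov_qual[agree] <- pmin(q1[o1][agree] + q2[o2][agree], 93L)
  if (any(!agree)) {
    qa <- q1[o1][!agree]; qb <- q2[o2][!agree]
    take1 <- qa > qb; tie <- qa == qb
    ba <- c1[o1][!agree]; bb <- c2[o2][!agree]
    ov_base[!agree] <- ifelse(take1 | tie, ba, bb)
    ov_qual[!agree] <- ifelse(tie, 2L, abs(qa - qb))
  }
  tail2 <- if (n2 > L) seq.int(L + 1L, n2) else integer(0)
  seq <- paste0(substr(t1$seq, 1L, n1 - L), paste(ov_base, collapse = ""),
                paste(c2[tail2], collapse = ""))
  qual <- c(q1[seq_len(n1 - L)], ov_qual, q2[tail2])
  structure(list(id = r1$id, seq = toupper(seq), qual = as.integer(qual),
                 overlap = L, source_ids = c(r1$id, r2$id)),
            class = "composite_read")
}

#' Merge a batch of read pairs
#'
#' @param pairs tibble with columns `id`, `seq1`, `qual1`, `seq2`, `qual2`
#'   (as produced by pairing two [read_fastq_tbl()] outputs)
#' @inheritParams merge_pair
#' @return list with `merged` (tibble: `id`, `seq`, `qual`, `overlap`) and
#'   `rejected` (tibble of pair ids that had no acceptable overlap), plus a
#'   `summary` row (counts, mean composite length, mean composite quality)
#' @export
merge_read_pairs <- function(pairs, min_overlap = 10, max_mismatch_frac = 0.1,
                             adapter = NULL) {
  res <- purrr::pmap(pairs, function(id, seq1, qual1, seq2, qual2, ...) {
    merge_pair(list(id = id, seq = seq1, qual = qual1),
               list(id = id, seq = seq2, qual = qual2),
               min_overlap, max_mismatch_frac, adapter)
  })
  ok <- !vapply(res, is.null, logical(1))
  merged <- tibble::tibble(
    id = pairs$id[ok],
    seq = vapply(res[ok], `[[`, character(1), "seq"),
    qual = lapply(res[ok], `[[`, "qual"),
    overlap = vapply(res[ok], `[[`, integer(1), "overlap")
  )
  summary <- tibble::tibble(
    n_pairs = nrow(pairs),
    n_merged = sum(ok),
    n_rejected = sum(!ok),
    mean_length = if (any(ok)) mean(nchar(merged$seq)) else NA_real_,
    mean_quality = if (any(ok)) mean(unlist(merged$qual)) else NA_real_
  )
  list(merged = merged,
       rejected = tibble::tibble(id = pairs$id[!ok]),
       summary = summary)
}
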