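# Seeded, full-length, ungapped protospacer search. Replaces short-read
# BLAST with an exact k-mer index plus Hamming verification; the seed
# length is chosen so the pigeonhole bound guarantees that every window
# within the mismatch budget shares at least one exact k-mer with the
# spacer, i.e. the search is provably exhaustive for ungapped matches.

#' Build an exact k-mer position index over a contig set
#'
#' @param contigs named character vector of sequences (uppercased
#'   internally).
#' @param k seed length; must satisfy the pigeonhole bound
#'   `k <= floor(Lmin/(m(Lmin)+1))` for the spacer set searched later
#'   (checked in [search_spacers()]). Default 7 is admissible for spacers
#'   30 nt or longer at 10% mismatches.
#' @return object of class `contig_index`.
#' @export
index_contigs <- function(contigs, k = 7L) {
  stopifnot(length(contigs) >= 1L, !is.null(names(contigs)))
  contigs <- toupper(contigs)
  lens <- nchar(contigs)
  short <- lens < k
  if (any(short)) {
    message(sum(short), " contig(s) shorter than k=", k, " left unindexed")
  }
  concat <- paste(contigs, collapse = "")
  n <- nchar(concat)
  starts <- c(0L, cumsum(lens))[seq_along(contigs)] + 1L # 1-based global
  ends <- cumsum(lens)                                   # inclusive

  ss <- kmer_strings(concat, k)
  ok <- acgt_mask(concat)
  bad <- cumsum(!ok)
  win_ok <- (bad[k:n] - c(0L, bad)[1:(n - k + 1L)]) == 0L
  # exclude k-mers spanning a contig boundary
  ctg_of <- findInterval(seq_len(n - k + 1L), starts)
  win_ok <- win_ok & (seq_len(n - k + 1L) + k - 1L <= ends[ctg_of])
  pos <- which(unname(win_ok))
  idx <- split(pos, ss[pos])

  structure(list(index = idx, raw = charToRaw(concat), k = as.integer(k),
                 contig_ids = names(contigs), starts = starts, ends = ends,
                 lengths = lens),
            class = "contig_index")
}

#' Search spacers against indexed contigs
#'
#' For each spacer and both orientations, every contig window of spacer
#' length sharing at least one exact k-mer seed with the (oriented) spacer
#' is verified by full-length Hamming comparison; a hit is reported iff
#' mismatches <= floor((1 - min_identity) * L). Coordinates are 0-based
#' half-open on the forward strand of the contig.
#'
#' @param spacers data.frame with `spacer_id` and `sequence` (the catalog
#'   from [dedup_spacers()]), or a named character vector.
#' @param index a [index_contigs()] result.
#' @param min_identity minimum full-length identity (default 0.90).
#' @return data.frame of hits: `spacer_id`, `contig_id`, `start`, `end`,
#'   `strand`, `mismatches`, `identity`, sorted by (contig, start,
#'   spacer); attribute `n_skipped` counts spacers shorter than k.
#' @export
search_spacers <- function(spacers, index, min_identity = 0.90) {
  stopifnot(inherits(index, "contig_index"))
  if (is.character(spacers)) {
    spacers <- data.frame(spacer_id = names(spacers),
                          sequence = unname(spacers),
                          stringsAsFactors = FALSE)
  }
  k <- index$k
  empty <- data.frame(spacer_id = character(0), contig_id = character(0),
                      start = integer(0), end = integer(0),
                      strand = character(0), mismatches = integer(0),
                      identity = numeric(0))
  if (!nrow(spacers)) return(empty)

  n_skipped <- 0L
  rows <- list()
  for (i in seq_len(nrow(spacers))) {
    sp <- toupper(spacers$sequence[i])
    L <- nchar(sp)
    if (L < k) { n_skipped <- n_skipped + 1L; next }
    m_allow <- floor_eps((1 - min_identity) * L)
    if (k > L %/% (m_allow + 1L)) {
      stop("seed k=", k, " violates the pigeonhole bound for a ", L,
           "-nt spacer at ", m_allow, " mismatches; rebuild the index ",
           "with k <= ", L %/% (m_allow + 1L))
    }
    for (strand in c("+", "-")) {
      q <- if (strand == "+") sp else revcomp(sp)
      qraw <- charToRaw(q)
      offs <- seq_len(L - k + 1L)
      kms <- substring(q, offs, offs + k - 1L)
      cand <- integer(0)
      for (o in seq_along(kms)) {
        p <- index$index[[kms[o]]]
        if (!is.null(p)) cand <- c(cand, p - offs[o] + 1L)
      }
      if (!length(cand)) next
      cand <- sort(unique(cand[cand >= 1L]))
      if (!length(cand)) next
      ctg <- findInterval(cand, index$starts)
      inb <- cand >= index$starts[ctg] & cand + L - 1L <= index$ends[ctg]
      cand <- cand[inb]; ctg <- ctg[inb]
      if (!length(cand)) next
      mm <- .hamming_windows(index$raw, cand, qraw)
      hit <- which(!is.na(mm) & mm <= m_allow)
      if (!length(hit)) next
      rows[[length(rows) + 1L]] <- data.frame(
        spacer_id = spacers$spacer_id[i],
        contig_id = index$contig_ids[ctg[hit]],
        start = cand[hit] - index$starts[ctg[hit]],
        end = cand[hit] - index$starts[ctg[hit]] + L,
        strand = strand,
        mismatches = as.integer(mm[hit]),
        identity = (L - mm[hit]) / L,
        stringsAsFactors = FALSE)
    }
  }
  if (n_skipped > 0L) {
    message(n_skipped, " spacer(s) shorter than k=", k, " skipped")
  }
  out <- if (length(rows)) do.call(rbind, rows) else empty
  out <- out[order(out$contig_id, out$start, out$spacer_id,
                   out$strand, method = "radix"), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_skipped") <- n_skipped
  out
}

#' Remove hits falling inside detected CRISPR arrays
#'
#' A spacer matching a CRISPR array on a metagenome contig is the array
#' itself, not a protospacer; hits whose interval overlaps any detected
#' array interval on the same contig are removed.
#'
#' @param hits data.frame from [search_spacers()].
#' @param arrays list of `crispr_array` (detected on the same contig set).
#' @return filtered hits; attribute `n_masked` counts removals.
#' @export
mask_array_hits <- function(hits, arrays) {
  if (!nrow(hits) || !length(arrays)) {
    attr(hits, "n_masked") <- 0L
    return(hits)
  }
  adf <- data.frame(
    contig_id = vapply(arrays, `[[`, "", "contig_id"),
    start = vapply(arrays, `[[`, 0L, "start"),
    end = vapply(arrays, `[[`, 0L, "end"), stringsAsFactors = FALSE)
  drop <- rep(FALSE, nrow(hits))
  for (i in seq_len(nrow(adf))) {
    drop <- drop | (hits$contig_id == adf$contig_id[i] &
                    hits$start < adf$end[i] & adf$start[i] < hits$end)
  }
  out <- hits[!drop, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_masked") <- sum(drop)
  out
}
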