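# Completeness calling and the candidate-MGE selection rule: contigs of
# length >= 2 kbp with >= 2 protospacer matches at >= 90% identity, or
# >= 1 match when completeness can be predicted from terminal repeats
# (>= 20 bp at <= 10% mismatches).

#' Find terminal repeats (DTR/ITR) of a contig
#'
#' Reports the longest end-anchored repeat: a DTR is a prefix of length L
#' matching the suffix of length L; an ITR is a prefix matching the
#' reverse complement of the suffix. The repeat must include the first and
#' last base, satisfy `min_len`, and carry at most
#' `max_mismatch_frac * L` mismatches. Only the first and last `window`
#' bases are examined. DTR is preferred over ITR on length ties.
#'
#' @param contig nucleotide string.
#' @param min_len minimum repeat length (default 20).
#' @param max_mismatch_frac maximum mismatch fraction (default 0.10).
#' @param window end window examined (default 2000 nt).
#' @param contig_id optional id recorded on the result.
#' @return data.frame (one row): `contig_id`, `kind` ("DTR"/"ITR"/"none"),
#'   `repeat_length`, `mismatches`, `mismatch_fraction`.
#' @export
find_terminal_repeats <- function(contig, min_len = 20L,
                                  max_mismatch_frac = 0.10,
                                  window = 2000L,
                                  contig_id = NA_character_) {
  contig <- toupper(contig)
  n <- nchar(contig)
  none <- data.frame(contig_id = contig_id, kind = "none",
                     repeat_length = 0L, mismatches = 0L,
                     mismatch_fraction = 0, stringsAsFactors = FALSE)
  if (n < 2L * min_len) return(none)
  w <- min(window, n %/% 2L)
  raw <- charToRaw(contig)
  pre <- raw[1:w]

  best <- list(kind = "none", len = 0L, mm = 0L)

  # ITR: prefix vs reverse complement of the suffix window is a fixed
  # alignment (position i pairs with base n-i+1 complemented), so one
  # cumulative mismatch scan finds the longest qualifying L directly
  itr_win <- charToRaw(revcomp(substr(contig, n - w + 1L, n)))
  mm_cum <- cumsum(pre != itr_win[1:w])
  Ls <- min_len:w
  ok <- mm_cum[Ls] <= max_mismatch_frac * Ls + 1e-9
  if (any(ok)) {
    L <- max(Ls[ok])
    best <- list(kind = "ITR", len = L, mm = as.integer(mm_cum[L]))
  }

  # DTR: candidate lengths from exact 6-mers shared between the end
  # windows (6 satisfies the pigeonhole bound down to L=20 at 2
  # mismatches), verified longest-first by direct comparison
  k <- 6L
  suf_str <- substr(contig, n - w + 1L, n)
  pre_km <- kmer_strings(substr(contig, 1L, w), k)
  suf_km <- kmer_strings(suf_str, k)
  shared <- intersect(unique(pre_km), unique(suf_km))
  if (length(shared)) {
    pidx <- split(seq_along(pre_km), pre_km)
    sidx <- split(seq_along(suf_km), suf_km)
    Lcand <- unlist(lapply(shared, function(km) {
      outer(pidx[[km]], sidx[[km]], function(p, q) w - q + p)
    }), use.names = FALSE)
    Lcand <- sort(unique(Lcand[Lcand >= min_len & Lcand <= w]),
                  decreasing = TRUE)
    for (L in Lcand) {
      if (L < best$len) break # shorter than current best: cannot win
      if (L == best$len && best$kind == "DTR") break
      mm <- sum(raw[1:L] != raw[(n - L + 1L):n])
      if (mm <= max_mismatch_frac * L + 1e-9) {
        if (L > best$len || best$kind == "ITR") {
          best <- list(kind = "DTR", len = as.integer(L),
                       mm = as.integer(mm))
        }
        break
      }
    }
  }

  if (best$kind == "none") return(none)
  data.frame(contig_id = contig_id, kind = best$kind,
             repeat_length = best$len, mismatches = best$mm,
             mismatch_fraction = best$mm / best$len,
             stringsAsFactors = FALSE)
}

#' Completeness calls for a contig set
#'
#' @param contigs named character vector.
#' @inheritParams find_terminal_repeats
#' @return data.frame with one row per contig.
#' @export
call_completeness <- function(contigs, min_len = 20L,
                              max_mismatch_frac = 0.10, window = 2000L) {
  out <- do.call(rbind, lapply(names(contigs), function(id) {
    find_terminal_repeats(contigs[[id]], min_len, max_mismatch_frac,
                          window, contig_id = id)
  }))
  rownames(out) <- NULL
  out
}

#' Apply the candidate-MGE selection rule
#'
#' A contig becomes a candidate MGE iff its length is >= `min_len` and it
#' has >= `min_hits` distinct protospacer hits (branch `multi_hit`), or
#' at least 1 hit together with a terminal-repeat completeness call (branch
#' `single_hit_complete`). Hits must already be identity-filtered and
#' array-masked; distinct means distinct (spacer, position, strand).
#'
#' @param contigs named character vector (for lengths).
#' @param hits data.frame from [mask_array_hits()].
#' @param completeness data.frame from [call_completeness()].
#' @param min_len minimum contig length (default 2000).
#' @param min_hits hit threshold for the multi-hit branch (default 2).
#' @return data.frame: `contig_id`, `length`, `n_hits`,
#'   `n_distinct_spacers`, `completeness`, `selection_branch`.
#' @export
select_candidates <- function(contigs, hits, completeness,
                              min_len = 2000L, min_hits = 2L) {
  lens <- stats::setNames(nchar(contigs), names(contigs))
  comp <- stats::setNames(completeness$kind, completeness$contig_id)
  if (nrow(hits)) {
    key <- paste(hits$contig_id, hits$spacer_id, hits$start, hits$strand)
    hits <- hits[!duplicated(key), , drop = FALSE]
  }
  rows <- list()
  for (id in unique(hits$contig_id)) {
    h <- hits[hits$contig_id == id, , drop = FALSE]
    len <- lens[[id]]
    if (is.null(len) || len < min_len) next
    ck <- comp[id]
    ck <- if (is.na(ck)) "none" else ck
    branch <- if (nrow(h) >= min_hits) "multi_hit"
              else if (nrow(h) >= 1L && ck != "none") "single_hit_complete"
              else NA_character_
    if (is.na(branch)) next
    rows[[length(rows) + 1L]] <- data.frame(
      contig_id = id, length = len, n_hits = nrow(h),
      n_distinct_spacers = length(unique(h$spacer_id)),
      completeness = ck, selection_branch = branch,
      stringsAsFactors = FALSE)
  }
  out <- if (length(rows)) do.call(rbind, rows) else data.frame(
    contig_id = character(0), length = integer(0), n_hits = integer(0),
    n_distinct_spacers = integer(0), completeness = character(0),
    selection_branch = character(0))
  out <- out[order(out$contig_id, method = "radix"), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Screen candidates against host genomes
#'
#' Automated, auditable stand-in for manual curation of likely host genome
#' fragments: a candidate whose best ANI and coverage against any supplied
#' host genome exceed the thresholds is flagged (never silently dropped).
#'
#' @param candidates data.frame from [select_candidates()].
#' @param contigs named character vector with the candidate sequences.
#' @param host_genomes named character vector of host genomes.
#' @param min_ani,min_cov flagging thresholds (defaults 0.98 and 0.50).
#' @return `candidates` with a logical `host_like` column appended.
#' @export
screen_host_like <- function(candidates, contigs, host_genomes,
                             min_ani = 0.98, min_cov = 0.50) {
  flag <- rep(FALSE, nrow(candidates))
  host_caches <- lapply(host_genomes, ani_cache)
  for (i in seq_len(nrow(candidates))) {
    seq_i <- ani_cache(contigs[[candidates$contig_id[i]]])
    for (hg in host_caches) {
      r <- pairwise_ani(seq_i, hg)
      if (r$ani >= min_ani && r$coverage_short >= min_cov) {
        flag[i] <- TRUE
        break
      }
    }
  }
  candidates$host_like <- flag
  candidates
}
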