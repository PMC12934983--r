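# Repeat-spacer array detection. Re-implements the CRT/MinCED-style scan:
# exact k-mer seeds recurring at admissible spacing initiate a candidate,
# the repeat is grown while all chained instances agree column-by-column,
# flanking diverged instances are walked in afterwards, and overlapping
# candidates are resolved by instance count, span, then position.

#' Array-detection parameters
#'
#' @param repeat_len allowed repeat length window (nt); the host lineage's
#'   repeats are all 29-31 nt, which is also the default.
#' @param spacer_len allowed spacer length window (nt).
#' @param min_repeats minimum repeat instances per array.
#' @param max_divergence maximum mismatches of a walked-in flanking repeat
#'   instance against the array consensus.
#' @param seed_k exact seed length initiating candidates.
#' @return list of class `array_params`.
#' @export
array_params <- function(repeat_len = c(29L, 31L), spacer_len = c(20L, 60L),
                         min_repeats = 3L, max_divergence = 2L,
                         seed_k = 8L) {
  stopifnot(repeat_len[1] <= repeat_len[2], spacer_len[1] <= spacer_len[2],
            min_repeats >= 2L, seed_k >= 4L,
            seed_k <= repeat_len[1])
  structure(list(repeat_len = as.integer(repeat_len),
                 spacer_len = as.integer(spacer_len),
                 min_repeats = as.integer(min_repeats),
                 max_divergence = as.integer(max_divergence),
                 seed_k = as.integer(seed_k)),
            class = "array_params")
}

# walk outward from an instance run looking for additional diverged repeat
# instances at admissible spacing; consensus is the unanimous core repeat.
# Returns integer starts (possibly empty) on the chosen side.
walk_instances <- function(raw, n, anchor, L, rep_raw, params, side) {
  smin <- L + params$spacer_len[1]; smax <- L + params$spacer_len[2]
  found <- integer(0)
  cur <- anchor
  repeat {
    cands <- if (side == "left") cur - (smin:smax) else cur + (smin:smax)
    cands <- cands[cands >= 1L & cands + L - 1L <= n]
    if (!length(cands)) break
    mm <- .hamming_windows(raw, cands, rep_raw)
    ok <- which(!is.na(mm) & mm <= params$max_divergence)
    if (!length(ok)) break
    # minimum distance, tie broken toward the smaller spacer (closest)
    best <- ok[order(mm[ok], abs(cands[ok] - cur))][1]
    cur <- cands[best]
    found <- c(found, cur)
  }
  found
}

# unanimity extension of a seed chain; returns list(starts, L) or NULL
extend_chain <- function(raw, n, starts, params) {
  k <- params$seed_k
  max_len <- params$repeat_len[2]
  acgt <- as.integer(charToRaw("ACGT"))
  # right extension
  off_r <- k
  while (off_r < max_len + 1L) {
    idx <- starts + off_r
    if (idx[length(idx)] > n) break
    col <- as.integer(raw[idx])
    if (!(col[1] %in% acgt) || any(col != col[1])) break
    off_r <- off_r + 1L
  }
  # left extension
  off_l <- 0L
  while (off_r + off_l < max_len + 1L) {
    idx <- starts - off_l - 1L
    if (idx[1] < 1L) break
    col <- as.integer(raw[idx])
    if (!(col[1] %in% acgt) || any(col != col[1])) break
    off_l <- off_l + 1L
  }
  L <- off_r + off_l
  if (L < params$repeat_len[1] || L > params$repeat_len[2]) return(NULL)
  list(starts = starts - off_l, L = L)
}

# split instance runs at inadmissible spacer gaps; returns list of integer
# vectors each of length >= 2
split_valid_runs <- function(starts, L, params) {
  if (length(starts) < 2L) return(list())
  gaps <- diff(starts) - L
  ok <- gaps >= params$spacer_len[1] & gaps <= params$spacer_len[2]
  runs <- list(); cur <- starts[1]
  for (i in seq_along(ok)) {
    if (ok[i]) cur <- c(cur, starts[i + 1L])
    else { if (length(cur) >= 2L) runs[[length(runs) + 1L]] <- cur
           cur <- starts[i + 1L] }
  }
  if (length(cur) >= 2L) runs[[length(runs) + 1L]] <- cur
  runs
}

#' Detect CRISPR repeat-spacer arrays in one sequence
#'
#' Exact `seed_k`-mer seeds recurring at admissible spacing (repeat window
#' plus spacer window) initiate candidates; the repeat is extended while
#' every chained instance agrees at the column (ambiguous bases never
#' extend); additional flanking instances within `max_divergence`
#' mismatches of the consensus are then walked in; candidates must satisfy
#' the repeat-length window, spacer-length window and `min_repeats`;
#' overlapping candidates are resolved by most instances, then longest
#' span, then leftmost start.
#'
#' @param sequence nucleotide string (uppercased internally); characters
#'   outside A/C/G/T act as universal mismatches.
#' @param params an [array_params()] object.
#' @param contig_id optional id recorded on the results.
#' @return list of `crispr_array` objects; each has `contig_id`, 0-based
#'   half-open `start`/`end`, `repeat_consensus`, `repeat_instances`
#'   (data.frame: start, sequence, mismatches), `spacers` (data.frame:
#'   start, end, sequence), and anchoring fields (filled later).
#' @export
detect_arrays <- function(sequence, params = array_params(),
                          contig_id = NA_character_) {
  sequence <- toupper(sequence)
  n <- nchar(sequence)
  if (n < 2L * params$repeat_len[1]) return(list())
  raw <- charToRaw(sequence)
  k <- params$seed_k

  ss <- kmer_strings(sequence, k)
  ok <- acgt_mask(sequence)
  bad <- cumsum(!ok)
  # window [i, i+k-1] clean iff no non-ACGT inside
  win_ok <- (bad[k:n] - c(0L, bad)[1:(n - k + 1L)]) == 0L
  pos <- which(win_ok)
  if (!length(pos)) return(list())
  km <- ss[pos]

  # sort by k-mer then position: equal k-mers become adjacent ascending
  ord <- order(km, pos, method = "radix")
  p_sorted <- pos[ord]; k_sorted <- km[ord]

  smin <- params$repeat_len[1] + params$spacer_len[1]
  smax <- params$repeat_len[2] + params$spacer_len[2]
  npos <- length(p_sorted)
  if (npos < 2L) return(list())
  d <- diff(p_sorted)
  same <- k_sorted[-npos] == k_sorted[-1]
  link <- same & d >= smin & d <= smax

  # maximal TRUE-runs of `link` give seed chains (>= 2 instances)
  candidates <- list()
  r <- rle(link)
  ends <- cumsum(r$lengths)
  starts_r <- ends - r$lengths + 1L
  for (i in which(r$values)) {
    chain <- p_sorted[starts_r[i]:(ends[i] + 1L)]
    ext <- extend_chain(raw, n, chain, params)
    if (is.null(ext)) next
    for (run in split_valid_runs(ext$starts, ext$L, params)) {
      candidates[[length(candidates) + 1L]] <- list(starts = run, L = ext$L)
    }
  }
  if (!length(candidates)) return(list())

  # dedupe identical candidates (one array seeds many k-mer offsets)
  sig <- vapply(candidates, function(cc) {
    paste(cc$L, paste(cc$starts, collapse = ","))
  }, character(1))
  candidates <- candidates[!duplicated(sig)]

  # walk in flanking diverged instances
  out <- list()
  for (cc in candidates) {
    L <- cc$L
    rep_seq <- substr(sequence, cc$starts[1], cc$starts[1] + L - 1L)
    rep_raw <- charToRaw(rep_seq)
    lefts <- walk_instances(raw, n, cc$starts[1], L, rep_raw, params, "left")
    rights <- walk_instances(raw, n, cc$starts[length(cc$starts)], L,
                             rep_raw, params, "right")
    starts <- c(rev(lefts), cc$starts, rights)
    if (length(starts) < params$min_repeats) next
    # trim terminal columns that are not unanimous across all instances:
    # the chained core is unanimous by construction, so disagreement at a
    # boundary column means a junk column absorbed by a subset chain or a
    # terminal substitution in a walked-in instance; either way it is not
    # repeat evidence
    repeat {
      if (L <= params$seed_k) break
      if (length(unique(as.integer(raw[starts]))) > 1L) {
        starts <- starts + 1L; L <- L - 1L
      } else if (length(unique(as.integer(raw[starts + L - 1L]))) > 1L) {
        L <- L - 1L
      } else break
    }
    # trimming may expose a repeat outside the admissible window
    if (L < params$repeat_len[1] || L > params$repeat_len[2]) next
    inst_seq <- substring(sequence, starts, starts + L - 1L)
    sp_start <- starts[-length(starts)] + L
    sp_end <- starts[-1]
    arr <- structure(list(
      contig_id = contig_id,
      start = starts[1] - 1L,
      end = starts[length(starts)] + L - 1L,
      repeat_consensus = NA_character_,
      repeat_instances = data.frame(start = starts - 1L,
                                    sequence = inst_seq,
                                    mismatches = NA_integer_,
                                    stringsAsFactors = FALSE),
      spacers = data.frame(start = sp_start - 1L, end = sp_end - 1L,
                           sequence = substring(sequence, sp_start,
                                                sp_end - 1L),
                           stringsAsFactors = FALSE),
      anchored = FALSE, anchor_ref = NA_character_,
      anchor_orientation = NA_character_, anchor_distance = NA_integer_),
      class = "crispr_array")
    arr$repeat_consensus <- consensus_repeat(arr)
    arr$repeat_instances$mismatches <- vapply(
      inst_seq, function(s) hamming(s, arr$repeat_consensus), 0L,
      USE.NAMES = FALSE)
    out[[length(out) + 1L]] <- arr
  }
  if (!length(out)) return(list())
  # post-trim duplicates collapse to one candidate
  sig2 <- vapply(out, function(a) {
    paste(a$start, a$end, paste(a$repeat_instances$start, collapse = ","))
  }, character(1))
  out <- out[!duplicated(sig2)]

  # overlap resolution: most instances, longest span, leftmost start
  ninst <- vapply(out, function(a) nrow(a$repeat_instances), 0L)
  span <- vapply(out, function(a) a$end - a$start, 0L)
  st <- vapply(out, function(a) a$start, 0L)
  ord <- order(-ninst, -span, st)
  chosen <- list()
  for (i in ord) {
    a <- out[[i]]
    clash <- any(vapply(chosen, function(b) {
      a$start < b$end && b$start < a$end
    }, logical(1)))
    if (!clash) chosen[[length(chosen) + 1L]] <- a
  }
  chosen[order(vapply(chosen, `[[`, 0L, "start"))]
}

#' Detect arrays across a contig set
#'
#' @param contigs named character vector of sequences.
#' @param params an [array_params()] object.
#' @return flat list of `crispr_array` objects with `contig_id` filled.
#' @export
detect_arrays_set <- function(contigs, params = array_params()) {
  out <- list()
  for (id in names(contigs)) {
    out <- c(out, detect_arrays(contigs[[id]], params, contig_id = id))
  }
  out
}

#' Consensus repeat of an array
#'
#' Per-column majority over the repeat instances of modal length; ties are
#' broken by alphabetical base.
#'
#' @param array a `crispr_array`.
#' @return nucleotide string.
#' @export
consensus_repeat <- function(array) {
  inst <- array$repeat_instances$sequence
  lens <- nchar(inst)
  tab <- table(lens)
  modal <- as.integer(names(tab)[which.max(tab)])
  inst <- inst[lens == modal]
  mat <- do.call(rbind, strsplit(inst, "", fixed = TRUE))
  cons <- apply(mat, 2L, function(col) {
    t <- sort(table(col), decreasing = TRUE)
    nm <- names(t)[t == max(t)]
    sort(nm)[1]
  })
  paste(cons, collapse = "")
}

#' @export
print.crispr_array <- function(x, ...) {
  cat(sprintf("CRISPR array %s:%d-%d  %d repeats (%d nt), %d spacers%s\n",
              x$contig_id, x$start, x$end, nrow(x$repeat_instances),
              nchar(x$repeat_consensus), nrow(x$spacers),
              if (isTRUE(x$anchored))
                paste0("  [anchored: ", x$anchor_ref, "/",
                       x$anchor_orientation, "]") else ""))
  invisible(x)
}
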