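# Average nucleotide identity by anchor chaining: maximal exact matches
# (>= 15 nt) are chained co-linearly by descending length and short
# inter-anchor gaps are closed by banded global alignment (compiled in
# src/align.cpp). Dereplication greedily clusters contigs at >= 98% ANI
# and >= 95% coverage of the shorter sequence.

ANCHOR_K <- 15L

# k-mer postings for one sequence: 2-bit numeric codes (exact doubles up
# to 4^15) with sorted group ranges, so two postings sets can be matched
# without string hashing. ACGT-clean k-mers only.
kmer_postings <- function(x, k = ANCHOR_K) {
  n <- nchar(x)
  if (n < k) {
    return(list(keys = numeric(0), pos = integer(0),
                gstart = integer(0), gend = integer(0)))
  }
  b <- base_codes(x)
  m <- n - k + 1L
  code <- numeric(m)
  valid <- rep(TRUE, m)
  for (t in 0:(k - 1L)) {
    v <- b[(1L + t):(m + t)]
    valid <- valid & !is.na(v)
    v[is.na(v)] <- 0L
    code <- code * 4 + v
  }
  pos <- which(valid)
  cd <- code[valid]
  o <- order(cd, pos)
  cd <- cd[o]; pos <- pos[o]
  brk <- if (length(cd)) c(TRUE, cd[-1] != cd[-length(cd)]) else logical(0)
  gstart <- which(brk)
  list(keys = cd[brk], pos = pos, gstart = gstart,
       gend = c(gstart[-1L] - 1L, length(cd)))
}

#' Precomputed ANI cache for one sequence
#'
#' Stores the sequence, its reverse complement and k-mer postings for
#' both, so repeated [pairwise_ani()] calls against the same sequence skip
#' re-indexing.
#'
#' @param x nucleotide string.
#' @return object of class `ani_cache`.
#' @export
ani_cache <- function(x) {
  x <- toupper(x)
  rc <- revcomp(x)
  structure(list(seq = x, rc = rc, post = kmer_postings(x),
                 post_rc = kmer_postings(rc)),
            class = "ani_cache")
}

# maximal exact matches >= k from two postings lists, data.frame(pa, pb,
# len), 1-based starts
anchors_from_postings <- function(ia, ib, k = ANCHOR_K) {
  none <- data.frame(pa = integer(0), pb = integer(0), len = integer(0))
  if (!length(ia$keys) || !length(ib$keys)) return(none)
  # match sorted numeric key vectors
  hit <- findInterval(ia$keys, ib$keys)
  sa <- which(hit > 0L)
  sa <- sa[ib$keys[hit[sa]] == ia$keys[sa]]
  if (!length(sa)) return(none)
  sb <- hit[sa]
  # pair every occurrence in a with every occurrence in b, per k-mer:
  # pa blocks are a1 x nb, a2 x nb, ...; pb blocks cycle b1..b_nb na times
  pa_l <- vector("list", length(sa)); pb_l <- vector("list", length(sa))
  for (t in seq_along(sa)) {
    av <- ia$pos[ia$gstart[sa[t]]:ia$gend[sa[t]]]
    bv <- ib$pos[ib$gstart[sb[t]]:ib$gend[sb[t]]]
    pa_l[[t]] <- rep(av, each = length(bv))
    pb_l[[t]] <- rep(bv, times = length(av))
  }
  pa <- unlist(pa_l, use.names = FALSE)
  pb <- unlist(pb_l, use.names = FALSE)
  diag <- pa - pb
  ord <- order(diag, pa)
  pa <- pa[ord]; pb <- pb[ord]; diag <- diag[ord]
  brk <- c(TRUE, diff(diag) != 0L | diff(pa) != 1L)
  grp <- cumsum(brk)
  st <- which(brk)
  ct <- tabulate(grp)
  data.frame(pa = pa[st], pb = pb[st], len = ct + k - 1L)
}

# greedy co-linear chain: anchors accepted by descending length when
# strictly before or after every accepted anchor on both sequences;
# tie-break keys are swap-invariant so ani(a,b) == ani(b,a)
chain_anchors <- function(anc) {
  if (!nrow(anc)) return(anc)
  ord <- order(-anc$len, anc$pa + anc$pb, abs(anc$pa - anc$pb))
  acc <- integer(0)
  for (i in ord) {
    pa1 <- anc$pa[i]; pa2 <- pa1 + anc$len[i] - 1L
    pb1 <- anc$pb[i]; pb2 <- pb1 + anc$len[i] - 1L
    compatible <- TRUE
    for (j in acc) {
      qa1 <- anc$pa[j]; qa2 <- qa1 + anc$len[j] - 1L
      qb1 <- anc$pb[j]; qb2 <- qb1 + anc$len[j] - 1L
      before <- pa2 < qa1 && pb2 < qb1
      after <- pa1 > qa2 && pb1 > qb2
      if (!before && !after) { compatible <- FALSE; break }
    }
    if (compatible) acc <- c(acc, i)
  }
  out <- anc[acc, , drop = FALSE]
  out[order(out$pa), , drop = FALSE]
}

ani_one_orientation <- function(a, b, pa, pb, max_gap = 500L, band = 50L) {
  anc <- chain_anchors(anchors_from_postings(pa, pb))
  if (!nrow(anc)) {
    return(list(matches = 0, columns = 0, aligned_short = 0))
  }
  matches <- sum(anc$len)
  columns <- sum(anc$len)
  ashort <- sum(anc$len)
  short_is_a <- nchar(a) <= nchar(b)
  if (nrow(anc) > 1L) {
    for (i in seq_len(nrow(anc) - 1L)) {
      ga1 <- anc$pa[i] + anc$len[i]; ga2 <- anc$pa[i + 1L] - 1L
      gb1 <- anc$pb[i] + anc$len[i]; gb2 <- anc$pb[i + 1L] - 1L
      la <- ga2 - ga1 + 1L; lb <- gb2 - gb1 + 1L
      if (la > max_gap || lb > max_gap) next # unaligned break in the chain
      if (la == 0L && lb == 0L) next
      if (la == 0L || lb == 0L) {
        columns <- columns + max(la, lb)
        if (short_is_a && la > 0L) ashort <- ashort + la
        if (!short_is_a && lb > 0L) ashort <- ashort + lb
        next
      }
      st <- .banded_global_stats(substr(a, ga1, ga2), substr(b, gb1, gb2),
                                 band = band)
      matches <- matches + st$matches
      columns <- columns + st$columns
      ashort <- ashort + (if (short_is_a) la else lb)
    }
  }
  list(matches = matches, columns = columns, aligned_short = ashort)
}

#' Pairwise ANI by anchor chaining
#'
#' Evaluates both orientations of `b` and keeps the better one (more
#' matched columns). ANI is matched columns over aligned columns along the
#' chain; coverage is the aligned fraction of the shorter sequence.
#'
#' @param a,b nucleotide strings, or [ani_cache()] objects for repeated
#'   comparisons.
#' @param max_gap largest inter-anchor gap closed by alignment (nt).
#' @param band half-width of the banded gap alignment.
#' @return list: `ani`, `coverage_short`, `orientation` ("+"/"-").
#' @export
pairwise_ani <- function(a, b, max_gap = 500L, band = 50L) {
  ca <- if (inherits(a, "ani_cache")) a else ani_cache(a)
  cb <- if (inherits(b, "ani_cache")) b else ani_cache(b)
  fwd <- ani_one_orientation(ca$seq, cb$seq, ca$post, cb$post,
                             max_gap, band)
  rev <- ani_one_orientation(ca$seq, cb$rc, ca$post, cb$post_rc,
                             max_gap, band)
  pick <- if (rev$matches > fwd$matches) rev else fwd
  orient <- if (rev$matches > fwd$matches) "-" else "+"
  if (pick$columns == 0) {
    return(list(ani = 0, coverage_short = 0, orientation = "+"))
  }
  list(ani = pick$matches / pick$columns,
       coverage_short = pick$aligned_short / min(nchar(ca$seq),
                                                 nchar(cb$seq)),
       orientation = orient)
}

#' Dereplicate candidate contigs by ANI clustering
#'
#' Greedy: contigs sorted by length descending (ties lexicographic by id)
#' join the first existing cluster whose representative reaches both
#' thresholds, else found a new cluster. The representative is therefore
#' always the longest member.
#'
#' @param contigs named character vector of candidate sequences.
#' @param min_ani ANI threshold (default 0.98).
#' @param min_cov coverage threshold on the shorter sequence (default
#'   0.95).
#' @return data.frame: `cluster_id`, `representative`, `contig_id`, `ani`,
#'   `coverage`, `orientation` (representatives listed with ani = 1).
#' @export
dedup_candidates <- function(contigs, min_ani = 0.98, min_cov = 0.95) {
  if (!length(contigs)) {
    return(data.frame(cluster_id = character(0), representative = character(0),
                      contig_id = character(0), ani = numeric(0),
                      coverage = numeric(0), orientation = character(0)))
  }
  ord <- order(-nchar(contigs), names(contigs), method = "radix")
  ids <- names(contigs)[ord]
  reps <- character(0)
  rep_cache <- list()
  rows <- list()
  for (id in ids) {
    placed <- FALSE
    cc <- ani_cache(contigs[[id]])
    for (r in reps) {
      res <- pairwise_ani(rep_cache[[r]], cc)
      if (res$ani >= min_ani && res$coverage_short >= min_cov) {
        rows[[length(rows) + 1L]] <- data.frame(
          representative = r, contig_id = id, ani = res$ani,
          coverage = res$coverage_short, orientation = res$orientation,
          stringsAsFactors = FALSE)
        placed <- TRUE
        break
      }
    }
    if (!placed) {
      reps <- c(reps, id)
      rep_cache[[id]] <- cc
      rows[[length(rows) + 1L]] <- data.frame(
        representative = id, contig_id = id, ani = 1, coverage = 1,
        orientation = "+", stringsAsFactors = FALSE)
    }
  }
  df <- do.call(rbind, rows)
  cl_id <- stats::setNames(sprintf("mgeclust%03d", seq_along(reps)), reps)
  df <- cbind(data.frame(cluster_id = unname(cl_id[df$representative]),
                         stringsAsFactors = FALSE), df)
  rownames(df) <- NULL
  df
}
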