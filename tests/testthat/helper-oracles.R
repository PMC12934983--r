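# Independent brute-force oracles used to cross-check the implementation.
# These deliberately share only the documented contracts, not code paths:
# array enumeration works by exhaustive shift-equality scanning instead of
# k-mer seeding, protospacer scanning uses Biostrings matchPattern,
# protein identity uses Biostrings pairwiseAlignment, and ORF enumeration
# translates with Biostrings.

suppressPackageStartupMessages(library(Biostrings))

acgt_ok <- function(x) charToRaw(x) %in% charToRaw("ACGT")

# --- exhaustive periodic-repeat enumerator (detect_arrays oracle) -------

oracle_detect_arrays <- function(sequence, params = array_params()) {
  sequence <- toupper(sequence)
  n <- nchar(sequence)
  raw <- charToRaw(sequence)
  okv <- acgt_ok(sequence)
  rep_min <- params$repeat_len[1]; rep_max <- params$repeat_len[2]
  smin <- rep_min + params$spacer_len[1]
  smax <- rep_max + params$spacer_len[2]

  # all (start, shift, run-length) equality runs >= rep_min
  pairs <- list()
  for (d in smin:smax) {
    if (n - d < rep_min) next
    eq <- (raw[1:(n - d)] == raw[(1 + d):n]) & okv[1:(n - d)] & okv[(1 + d):n]
    r <- rle(eq)
    ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
    for (i in which(r$values & r$lengths >= rep_min)) {
      pairs[[length(pairs) + 1L]] <- c(p = starts[i], d = d,
                                       len = r$lengths[i])
    }
  }
  if (!length(pairs)) return(list())
  pdf <- as.data.frame(do.call(rbind, pairs))

  # chain pairs whose instance-2 region overlaps (by >= rep_min) the next
  # pair's instance-1 region; a pair is a chain start when no pair's
  # instance-2 region overlaps its instance-1 region
  has_pred <- vapply(seq_len(nrow(pdf)), function(i) {
    ov <- pmin(pdf$p + pdf$d + pdf$len, pdf$p[i] + pdf$len[i]) -
      pmax(pdf$p + pdf$d, pdf$p[i])
    any(ov >= rep_min)
  }, logical(1))

  chains <- list()
  for (i in which(!has_pred)) {
    ds <- pdf$d[i]
    lo <- pdf$p[i] + pdf$d[i]; hi <- lo + pdf$len[i] # last-instance coords
    used <- i
    repeat {
      ov <- pmin(pdf$p + pdf$len, hi) - pmax(pdf$p, lo)
      nxt <- setdiff(which(ov >= rep_min), used)
      if (!length(nxt)) break
      j <- nxt[order(-ov[nxt], pdf$p[nxt])][1]
      lo2 <- max(lo, pdf$p[j]); hi2 <- min(hi, pdf$p[j] + pdf$len[j])
      if (hi2 - lo2 < rep_min) break
      ds <- c(ds, pdf$d[j])
      lo <- lo2 + pdf$d[j]; hi <- hi2 + pdf$d[j]
      used <- c(used, j)
    }
    L <- hi - lo
    if (L < rep_min || L > rep_max) next
    starts <- c(lo - rev(cumsum(rev(ds))), lo)
    chains[[length(chains) + 1L]] <- list(starts = starts, L = L)
  }
  if (!length(chains)) return(list())

  # spacer-window validity split (same contract as the implementation)
  runs <- list()
  for (ch in chains) {
    gaps <- diff(ch$starts) - ch$L
    ok <- gaps >= params$spacer_len[1] & gaps <= params$spacer_len[2]
    cur <- ch$starts[1]
    for (t in seq_along(ok)) {
      if (ok[t]) cur <- c(cur, ch$starts[t + 1L])
      else { if (length(cur) >= 2L) runs[[length(runs) + 1L]] <-
               list(starts = cur, L = ch$L)
             cur <- ch$starts[t + 1L] }
    }
    if (length(cur) >= 2L) runs[[length(runs) + 1L]] <-
      list(starts = cur, L = ch$L)
  }
  sig <- vapply(runs, function(cc) paste(cc$L,
                                         paste(cc$starts, collapse = ",")),
                character(1))
  runs <- runs[!duplicated(sig)]

  # walk-in of diverged flanking instances (brute force over spacings)
  out <- list()
  for (cc in runs) {
    L <- cc$L
    rep_seq <- substr(sequence, cc$starts[1], cc$starts[1] + L - 1L)
    starts <- cc$starts
    for (side in c("left", "right")) {
      repeat {
        anchor <- if (side == "left") starts[1] else starts[length(starts)]
        sps <- params$spacer_len[1]:params$spacer_len[2]
        cand <- if (side == "left") anchor - L - sps else anchor + L + sps
        keep <- cand >= 1L & cand + L - 1L <= n
        cand <- cand[keep]; spk <- sps[keep]
        if (!length(cand)) break
        mm <- vapply(cand, function(cs) {
          sum(charToRaw(substr(sequence, cs, cs + L - 1L)) !=
                charToRaw(rep_seq))
        }, 0L)
        okc <- which(mm <= params$max_divergence)
        if (!length(okc)) break
        j <- okc[order(mm[okc], spk[okc])][1]
        starts <- if (side == "left") c(cand[j], starts)
                  else c(starts, cand[j])
      }
    }
    if (length(starts) < params$min_repeats) next
    # terminal trim: drop boundary columns not unanimous across instances
    repeat {
      if (L <= params$seed_k) break
      if (length(unique(substring(sequence, starts, starts))) > 1L) {
        starts <- starts + 1L; L <- L - 1L
      } else if (length(unique(substring(sequence, starts + L - 1L,
                                         starts + L - 1L))) > 1L) {
        L <- L - 1L
      } else break
    }
    if (L < params$repeat_len[1] || L > params$repeat_len[2]) next
    out[[length(out) + 1L]] <- list(starts = starts, L = L)
  }
  if (!length(out)) return(list())
  sig <- vapply(out, function(cc) paste(cc$L,
                                        paste(cc$starts, collapse = ",")),
                character(1))
  out <- out[!duplicated(sig)]

  # overlap resolution: most instances, longest span, leftmost
  ninst <- vapply(out, function(a) length(a$starts), 0L)
  span <- vapply(out, function(a) a$starts[length(a$starts)] + a$L -
                   a$starts[1], 0L)
  st <- vapply(out, function(a) a$starts[1], 0L)
  ord <- order(-ninst, -span, st)
  chosen <- list()
  for (i in ord) {
    a <- out[[i]]
    a_lo <- a$starts[1]; a_hi <- a$starts[length(a$starts)] + a$L
    clash <- any(vapply(chosen, function(b) {
      b_lo <- b$starts[1]; b_hi <- b$starts[length(b$starts)] + b$L
      a_lo < b_hi && b_lo < a_hi
    }, logical(1)))
    if (!clash) chosen[[length(chosen) + 1L]] <- a
  }
  chosen <- chosen[order(vapply(chosen, function(a) a$starts[1], 0L))]
  lapply(chosen, function(a) {
    list(start = a$starts[1] - 1L,
         end = a$starts[length(a$starts)] + a$L - 1L,
         starts = a$starts - 1L, L = a$L,
         repeats = substring(sequence, a$starts, a$starts + a$L - 1L),
         spacers = substring(sequence,
                             a$starts[-length(a$starts)] + a$L,
                             a$starts[-1] - 1L))
  })
}

# compact comparable form of detect_arrays output
array_signature <- function(arrays) {
  lapply(arrays, function(a) {
    if (is.list(a) && inherits(a, "crispr_array")) {
      list(start = a$start, end = a$end,
           starts = a$repeat_instances$start,
           L = nchar(a$repeat_consensus),
           repeats = a$repeat_instances$sequence,
           spacers = a$spacers$sequence)
    } else {
      list(start = a$start, end = a$end, starts = a$starts, L = a$L,
           repeats = unname(a$repeats), spacers = unname(a$spacers))
    }
  })
}

# --- protospacer scan oracle (Biostrings) -------------------------------

oracle_search <- function(spacers, contigs, min_identity = 0.90) {
  rows <- list()
  for (i in seq_len(nrow(spacers))) {
    sp <- spacers$sequence[i]
    L <- nchar(sp)
    m_allow <- as.integer(floor((1 - min_identity) * L + 1e-9))
    for (strand in c("+", "-")) {
      q <- if (strand == "+") sp else as.character(
        reverseComplement(DNAString(sp)))
      for (cid in names(contigs)) {
        m <- matchPattern(DNAString(q), DNAString(contigs[[cid]]),
                          max.mismatch = m_allow, with.indels = FALSE)
        if (!length(m)) next
        mm <- vapply(seq_along(m), function(j) {
          sum(charToRaw(as.character(m[[j]])) != charToRaw(q))
        }, 0L)
        rows[[length(rows) + 1L]] <- data.frame(
          spacer_id = spacers$spacer_id[i], contig_id = cid,
          start = start(m) - 1L, end = start(m) - 1L + L,
          strand = strand, mismatches = mm, identity = (L - mm) / L,
          stringsAsFactors = FALSE)
      }
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else data.frame(
    spacer_id = character(0), contig_id = character(0), start = integer(0),
    end = integer(0), strand = character(0), mismatches = integer(0),
    identity = numeric(0))
  out <- out[order(out$contig_id, out$start, out$spacer_id, out$strand,
                   method = "radix"), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# --- terminal repeat oracle (direct exhaustive scan) --------------------

oracle_terminal_repeat <- function(contig, min_len = 20L,
                                   max_mismatch_frac = 0.10,
                                   window = 2000L) {
  n <- nchar(contig)
  if (n < 2L * min_len) return(list(kind = "none", len = 0L))
  w <- min(window, n %/% 2L)
  pre <- charToRaw(substr(contig, 1L, w))
  suf_full <- charToRaw(contig)[(n - w + 1L):n]
  rc_w <- charToRaw(as.character(reverseComplement(DNAString(
    substr(contig, n - w + 1L, n)))))
  best <- list(kind = "none", len = 0L)
  for (L in w:min_len) { # descending: first hit is the longest DTR
    if (sum(pre[1:L] != suf_full[(w - L + 1L):w]) <=
        max_mismatch_frac * L + 1e-9) {
      best <- list(kind = "DTR", len = L); break
    }
  }
  for (L in w:min_len) {
    if (L <= best$len) break
    if (sum(pre[1:L] != rc_w[1:L]) <= max_mismatch_frac * L + 1e-9) {
      best <- list(kind = "ITR", len = L)
      break
    }
  }
  best
}

# --- protein identity oracle (Biostrings pairwiseAlignment) -------------

oracle_protein_identity <- function(a, b) {
  if (is.null(.GlobalEnv$.blosum62_oracle)) {
    e <- new.env(); utils::data("BLOSUM62", package = "Biostrings",
                                envir = e)
    assign(".blosum62_oracle", e$BLOSUM62, envir = .GlobalEnv)
  }
  aln <- pairwiseAlignment(AAString(a), AAString(b),
                           substitutionMatrix = .GlobalEnv$.blosum62_oracle,
                           gapOpening = 11, gapExtension = 1,
                           type = "global")
  pa <- charToRaw(as.character(alignedPattern(aln)))
  sa <- charToRaw(as.character(alignedSubject(aln)))
  gap <- charToRaw("-")
  paired <- pa != gap & sa != gap
  list(identity = sum(paired & pa == sa) / length(pa),
       cov_a = sum(paired) / nchar(a), cov_b = sum(paired) / nchar(b))
}

# --- six-frame ORF oracle (Biostrings translation) ----------------------

oracle_orfs <- function(contig, min_aa = 60L) {
  n <- nchar(contig)
  rows <- list()
  starts_cod <- c("ATG", "GTG", "TTG")
  for (strand in c("+", "-")) {
    s <- if (strand == "+") contig else
      as.character(reverseComplement(DNAString(contig)))
    for (f in 0:2) {
      ncod <- (n - f) %/% 3L
      if (ncod < min_aa + 1L) next
      sub <- substr(s, f + 1L, f + 3L * ncod)
      aa <- strsplit(as.character(suppressWarnings(
        translate(DNAString(sub), if.fuzzy.codon = "X"))), "")[[1]]
      cods <- substring(sub, seq(1L, 3L * ncod, 3L),
                        seq(3L, 3L * ncod, 3L))
      prev <- 0L
      for (sp in which(aa == "*")) {
        seg <- seq_len(ncod)[seq_len(ncod) > prev & seq_len(ncod) < sp]
        cand <- seg[cods[seg] %in% starts_cod]
        if (length(cand) && sp - cand[1] >= min_aa) {
          s0 <- cand[1]
          nt1 <- f + (s0 - 1L) * 3L + 1L
          nt2 <- f + sp * 3L
          if (strand == "+") { st0 <- nt1 - 1L; en0 <- nt2 }
          else { st0 <- n - nt2; en0 <- n - nt1 + 1L }
          prot <- paste(c("M", aa[(s0 + 1L):(sp - 1L)]), collapse = "")
          rows[[length(rows) + 1L]] <- data.frame(
            start = st0, end = en0, strand = strand, protein = prot,
            stringsAsFactors = FALSE)
        }
        prev <- sp
      }
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else data.frame(
    start = integer(0), end = integer(0), strand = character(0),
    protein = character(0))
  out <- out[order(out$start, out$end, out$strand), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# --- misc ---------------------------------------------------------------

adjusted_rand <- function(a, b) mclust::adjustedRandIndex(a, b)

# plant a CRISPR array (identical instances, optional shared variant) in
# a random background; returns the genome and truth
plant_array_genome <- function(len = 50000, n_arrays = 1,
                               repeats = NULL, variant = FALSE,
                               n_inst_range = c(4, 8),
                               spacer_range = c(30, 50), gc = 0.45) {
  if (is.null(repeats)) {
    repeats <- vapply(1:3, function(i) random_dna(sample(29:31, 1), gc), "")
    names(repeats) <- paste0("rep", 1:3)
  }
  bg <- random_dna(len, gc)
  pos <- sort(sample(seq(1000L, len - 2000L), n_arrays))
  while (n_arrays > 1 && min(diff(pos)) < 1500) {
    pos <- sort(sample(seq(1000L, len - 2000L), n_arrays))
  }
  truth <- list()
  pieces <- character(0); prev <- 0L; shift <- 0L
  for (a in seq_len(n_arrays)) {
    r <- unname(repeats[sample.int(length(repeats), 1L)])
    if (variant && runif(1) < 0.5) r <- spacermine:::mutate_positions(r, 1L)
    ni <- spacermine:::sample_range(n_inst_range[1], n_inst_range[2])
    sps <- vapply(seq_len(ni - 1L), function(i) {
      random_dna(spacermine:::sample_range(spacer_range[1], spacer_range[2]), gc)
    }, "")
    arr <- paste(c(rbind(rep(r, ni - 1L), sps), r), collapse = "")
    pieces <- c(pieces, substr(bg, prev + 1L, pos[a]), arr)
    truth[[a]] <- list(start = pos[a] + shift, repeat_seq = r,
                       n_inst = ni, spacers = sps,
                       end = pos[a] + shift + nchar(arr))
    shift <- shift + nchar(arr)
    prev <- pos[a]
  }
  pieces <- c(pieces, substr(bg, prev + 1L, len))
  list(genome = paste(pieces, collapse = ""), truth = truth,
       repeats = repeats)
}
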