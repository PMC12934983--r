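# Deterministic six-frame longest-ORF calling (translation table 11).
# This is deliberately not a statistical gene finder: an ORF runs from a
# start codon (ATG/GTG/TTG) to the next in-frame stop, and per (frame,
# stop) only the longest ORF (first start after the previous stop) is
# reported, so every call is re-verifiable by hand.

ORF_STARTS <- c("ATG", "GTG", "TTG")

# codon tables indexed 1..64 by 16a+4b+c+1 with A=0,C=1,G=2,T=3;
# codons containing other characters get index NA
orf_tables <- local({
  env <- new.env()
  function() {
    if (is.null(env$aa)) {
      ct <- codon_table()
      bases <- c("A", "C", "G", "T")
      idx <- function(cod) {
        v <- match(strsplit(cod, "")[[1]], bases) - 1L
        16L * v[1] + 4L * v[2] + v[3] + 1L
      }
      aa <- character(64)
      for (cod in names(ct)) aa[idx(cod)] <- ct[[cod]]
      env$aa <- aa
      env$start <- vapply(ORF_STARTS, idx, 0L)
    }
    env
  }
})

# integer base codes of a sequence (A=0 C=1 G=2 T=3, NA otherwise)
base_codes <- function(x) {
  r <- as.integer(charToRaw(x))
  out <- rep(NA_integer_, length(r))
  out[r == 65L] <- 0L # A
  out[r == 67L] <- 1L # C
  out[r == 71L] <- 2L # G
  out[r == 84L] <- 3L # T
  out
}

#' Call ORFs on a contig (six frames, table 11)
#'
#' Codons containing non-ACGT characters translate to `X` and never act as
#' start or stop. Coordinates are 0-based half-open on the forward strand
#' and include the stop codon; initiator codons translate as M.
#'
#' @param contig nucleotide string.
#' @param min_aa minimum protein length in aa, stop excluded (default 60).
#' @param contig_id optional id recorded on the results.
#' @return data.frame: `orf_id`, `contig_id`, `start`, `end`, `strand`,
#'   `frame` (0-2 on its own strand), `length_aa`, `protein`.
#' @export
call_orfs <- function(contig, min_aa = 60L, contig_id = NA_character_) {
  contig <- toupper(contig)
  n <- nchar(contig)
  tb <- orf_tables()
  rows <- list()
  for (strand in c("+", "-")) {
    s <- if (strand == "+") contig else revcomp(contig)
    bc <- base_codes(s)
    for (f in 0:2) {
      ncod <- (n - f) %/% 3L
      if (ncod < min_aa + 1L) next
      st <- seq(f + 1L, by = 3L, length.out = ncod)
      ci <- 16L * bc[st] + 4L * bc[st + 1L] + bc[st + 2L] + 1L
      aa <- ifelse(is.na(ci), "X", tb$aa[ifelse(is.na(ci), 1L, ci)])
      stops <- which(aa == "*")
      is_start <- !is.na(ci) & ci %in% tb$start
      prev <- 0L
      for (sp in stops) {
        if (sp - prev > min_aa) { # need start + >= min_aa codons + stop
          seg <- (prev + 1L):(sp - 1L)
          starts_in <- seg[is_start[seg]]
          if (length(starts_in)) {
            s0 <- starts_in[1]
            len_aa <- sp - s0
            if (len_aa >= min_aa) {
              prot <- paste(c("M", aa[(s0 + 1L):(sp - 1L)]), collapse = "")
              nt1 <- st[s0]              # 1-based on strand s
              nt2 <- st[sp] + 2L         # inclusive end incl. stop codon
              if (strand == "+") {
                start0 <- nt1 - 1L; end0 <- nt2
              } else {
                start0 <- n - nt2; end0 <- n - nt1 + 1L
              }
              rows[[length(rows) + 1L]] <- data.frame(
                contig_id = contig_id, start = start0, end = end0,
                strand = strand, frame = f, length_aa = len_aa,
                protein = prot, stringsAsFactors = FALSE)
            }
          }
        }
        prev <- sp
      }
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else data.frame(
    contig_id = character(0), start = integer(0), end = integer(0),
    strand = character(0), frame = integer(0), length_aa = integer(0),
    protein = character(0))
  out <- out[order(out$start, out$end, out$strand), , drop = FALSE]
  rownames(out) <- NULL
  if (nrow(out)) {
    out <- cbind(data.frame(orf_id = sprintf("%s_orf%03d",
                                             contig_id %||% "ctg",
                                             seq_len(nrow(out))),
                            stringsAsFactors = FALSE), out)
  } else {
    out <- cbind(data.frame(orf_id = character(0),
                            stringsAsFactors = FALSE), out)
  }
  out
}

#' Call ORFs across a contig set
#'
#' @param contigs named character vector.
#' @param min_aa minimum protein length (aa).
#' @return combined data.frame from [call_orfs()].
#' @export
call_orfs_set <- function(contigs, min_aa = 60L) {
  if (!length(contigs)) return(call_orfs("", min_aa = min_aa))
  out <- do.call(rbind, lapply(names(contigs), function(id) {
    call_orfs(contigs[[id]], min_aa = min_aa, contig_id = id)
  }))
  rownames(out) <- NULL
  out
}
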