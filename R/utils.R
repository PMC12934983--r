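# Low-level sequence helpers shared across modules. Sequences travel as
# plain uppercase character scalars; hot paths work on raw byte vectors.

DNA_BASES <- c("A", "C", "G", "T")
DNA_RAW <- charToRaw("ACGT")

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Reverse complement of a nucleotide string
#'
#' Ambiguity codes other than N are passed through complemented where
#' defined by `chartr`; N stays N.
#'
#' @param x character scalar (A/C/G/T/N).
#' @return character scalar.
#' @export
revcomp <- function(x) {
  stopifnot(is.character(x), length(x) == 1L)
  rc <- chartr("ACGTN", "TGCAN", x)
  intToUtf8(rev(utf8ToInt(rc)))
}

#' Hamming distance between equal-length strings
#'
#' Any differing byte counts as a mismatch, so N vs N counts 0 but N vs A
#' counts 1; callers that must treat N as a universal mismatch mask first.
#'
#' @param a,b character scalars of equal length.
#' @return integer mismatch count.
#' @export
hamming <- function(a, b) {
  ra <- charToRaw(a); rb <- charToRaw(b)
  if (length(ra) != length(rb)) {
    stop("hamming() requires equal-length strings")
  }
  sum(ra != rb)
}

#' Draw a random DNA sequence at a given GC content
#'
#' Uses the current RNG stream; callers seed via `withr::with_seed`.
#'
#' @param n length in nt.
#' @param gc fraction G+C in (0,1).
#' @return character scalar of length `n`.
#' @export
random_dna <- function(n, gc = 0.5) {
  stopifnot(n >= 0, gc >= 0, gc <= 1)
  if (n == 0) return("")
  p <- c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)
  paste(sample(DNA_BASES, n, replace = TRUE, prob = p), collapse = "")
}

# logical vector: which positions of the string are A/C/G/T
acgt_mask <- function(x) {
  charToRaw(x) %in% DNA_RAW
}

# substitute exactly m positions (each to a different base); returns string
mutate_positions <- function(x, m) {
  if (m == 0L) return(x)
  ch <- strsplit(x, "", fixed = TRUE)[[1]]
  pos <- sample.int(length(ch), m)
  for (p in pos) {
    ch[p] <- sample(setdiff(DNA_BASES, ch[p]), 1L)
  }
  paste(ch, collapse = "")
}

# floor with epsilon guard for thresholds like floor(0.1 * L): binary
# floating point must not turn an exact boundary into an off-by-one.
floor_eps <- function(x) as.integer(floor(x + 1e-9))

# all k-mer substrings of a string (character vector, 1-based start order)
kmer_strings <- function(x, k) {
  n <- nchar(x)
  if (n < k) return(character(0))
  substring(x, 1:(n - k + 1L), k:n)
}

#' Write a named character vector of sequences as FASTA
#'
#' @param seqs named character vector (DNA).
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path) {
  set <- Biostrings::DNAStringSet(seqs)
  Biostrings::writeXStringSet(set, path, width = 70L)
  invisible(path)
}

write_fasta_aa <- function(seqs, path) {
  set <- Biostrings::AAStringSet(seqs)
  Biostrings::writeXStringSet(set, path, width = 70L)
  invisible(path)
}

#' Read a FASTA file as a named character vector
#'
#' Thin wrapper over [Biostrings::readDNAStringSet()]; uppercases and keeps
#' the first whitespace-delimited token of each header.
#'
#' @param path FASTA file.
#' @return named character vector of sequences.
#' @export
read_fasta <- function(path) {
  set <- Biostrings::readDNAStringSet(path)
  out <- toupper(as.character(set))
  names(out) <- sub("\\s.*$", "", names(out))
  out
}

write_tsv <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# uniform draw from the integer range [lo, hi]; safe when lo == hi
# (sample(x, 1) would otherwise sample from 1:x)
sample_range <- function(lo, hi) {
  lo + sample.int(hi - lo + 1L, 1L) - 1L
}
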