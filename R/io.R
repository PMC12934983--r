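# Standard-format writers: GFF3 and BED6 via rtracklayer, FASTA via
# Biostrings (see utils.R), GraphML via igraph.

# arrays -> GFF3: one region feature per array plus one child feature per
# repeat instance and per spacer, grouped by the array ID attribute
write_arrays_gff3 <- function(arrays, path) {
  if (!length(arrays)) {
    writeLines("##gff-version 3", path)
    return(invisible(path))
  }
  feats <- list()
  for (i in seq_along(arrays)) {
    a <- arrays[[i]]
    aid <- sprintf("array%03d", i)
    feats[[length(feats) + 1L]] <- data.frame(
      seqnames = a$contig_id, start = a$start + 1L, end = a$end,
      type = "repeat_region", ID = aid, Parent = NA_character_,
      note = sprintf("anchored=%s;consensus=%s",
                     isTRUE(a$anchored), a$repeat_consensus),
      stringsAsFactors = FALSE)
    ri <- a$repeat_instances
    feats[[length(feats) + 1L]] <- data.frame(
      seqnames = a$contig_id, start = ri$start + 1L,
      end = ri$start + nchar(ri$sequence), type = "direct_repeat",
      ID = sprintf("%s_rep%02d", aid, seq_len(nrow(ri))), Parent = aid,
      note = sprintf("mismatches=%d", ri$mismatches),
      stringsAsFactors = FALSE)
    sp <- a$spacers
    if (nrow(sp)) {
      feats[[length(feats) + 1L]] <- data.frame(
        seqnames = a$contig_id, start = sp$start + 1L, end = sp$end,
        type = "CRISPR_spacer",
        ID = sprintf("%s_sp%02d", aid, seq_len(nrow(sp))), Parent = aid,
        note = NA_character_, stringsAsFactors = FALSE)
    }
  }
  df <- do.call(rbind, feats)
  gr <- GenomicRanges::GRanges(
    seqnames = df$seqnames,
    ranges = IRanges::IRanges(start = df$start, end = df$end),
    type = df$type, ID = df$ID)
  S4Vectors::mcols(gr)$Parent <- ifelse(is.na(df$Parent), NA, df$Parent)
  S4Vectors::mcols(gr)$Note <- df$note
  rtracklayer::export(gr, path, format = "gff3")
  invisible(path)
}

write_orfs_gff3 <- function(orfs, path) {
  if (!nrow(orfs)) {
    writeLines("##gff-version 3", path)
    return(invisible(path))
  }
  gr <- GenomicRanges::GRanges(
    seqnames = orfs$contig_id,
    ranges = IRanges::IRanges(start = orfs$start + 1L, end = orfs$end),
    strand = orfs$strand, type = "CDS", ID = orfs$orf_id,
    frame = orfs$frame, phase = 0L)
  rtracklayer::export(gr, path, format = "gff3")
  invisible(path)
}

write_hits_bed <- function(hits, path) {
  if (!nrow(hits)) {
    file.create(path)
    return(invisible(path))
  }
  gr <- GenomicRanges::GRanges(
    seqnames = hits$contig_id,
    ranges = IRanges::IRanges(start = hits$start + 1L, end = hits$end),
    strand = hits$strand, name = hits$spacer_id, score = hits$mismatches)
  rtracklayer::export(gr, path, format = "bed")
  invisible(path)
}
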