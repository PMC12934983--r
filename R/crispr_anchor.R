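# Anchoring detected arrays to the reference repeat set and extracting the
# deduplicated spacer catalog. The anchor filter mirrors the stringent
# host-lineage filter: at most 1 mismatch to a reference genomic repeat, or
# to its reverse complement; Hamming distance is defined only for equal
# lengths, so no indel tolerance.

#' Match a repeat consensus against the reference repeat set
#'
#' A match requires some reference of equal length within Hamming distance
#' `max_mismatch` of the repeat or of its reverse complement. Among
#' multiple matches the minimum distance wins; ties go to reference order,
#' then forward orientation.
#'
#' @param repeat_seq repeat consensus (uppercase A/C/G/T).
#' @param reference named character vector of reference repeats.
#' @param max_mismatch maximum Hamming distance (default 1).
#' @return list(`ref_id`, `orientation` ("forward"/"reverse"), `distance`)
#'   or `NULL` when nothing matches.
#' @export
match_repeat_to_reference <- function(repeat_seq, reference,
                                      max_mismatch = 1L) {
  L <- nchar(repeat_seq)
  same <- which(nchar(reference) == L)
  if (!length(same)) return(NULL)
  rc <- revcomp(repeat_seq)
  best <- NULL
  for (i in same) {
    df <- hamming(repeat_seq, reference[[i]])
    dr <- hamming(rc, reference[[i]])
    d <- min(df, dr)
    if (d <= max_mismatch && (is.null(best) || d < best$distance)) {
      best <- list(ref_id = names(reference)[i],
                   orientation = if (df <= dr) "forward" else "reverse",
                   distance = as.integer(d))
      if (d == 0L) break
    }
  }
  best
}

#' Anchor arrays to the reference repeat set
#'
#' Fills the `anchored`/`anchor_*` fields of each array from
#' [match_repeat_to_reference()] on its consensus repeat.
#'
#' @param arrays list of `crispr_array`.
#' @param reference named character vector of reference repeats.
#' @param max_mismatch maximum Hamming distance (default 1).
#' @return the arrays with anchor fields filled.
#' @export
anchor_arrays <- function(arrays, reference, max_mismatch = 1L) {
  lapply(arrays, function(a) {
    m <- match_repeat_to_reference(a$repeat_consensus, reference,
                                   max_mismatch)
    if (!is.null(m)) {
      a$anchored <- TRUE
      a$anchor_ref <- m$ref_id
      a$anchor_orientation <- m$orientation
      a$anchor_distance <- m$distance
    }
    a
  })
}

#' Extract spacers from arrays
#'
#' Metagenomic arrays contribute spacers only when anchored; isolate-genome
#' arrays are kept regardless. Spacers containing non-ACGT characters are
#' dropped with a logged count.
#'
#' @param arrays list of `crispr_array` (anchor fields filled for
#'   metagenomic arrays).
#' @param origin_class `"isolate_genome"` or `"metagenome"`; recycled over
#'   arrays.
#' @return data.frame (one row per spacer): `sequence`, `length`,
#'   `contig_id`, `array_start`, `ordinal`, `origin_class`; attribute
#'   `n_dropped` counts spacers removed for ambiguity codes.
#' @export
extract_spacers <- function(arrays, origin_class = "metagenome") {
  if (length(origin_class) == 1L) {
    origin_class <- rep(origin_class, length(arrays))
  }
  stopifnot(all(origin_class %in% c("metagenome", "isolate_genome")),
            length(origin_class) == length(arrays) || length(arrays) == 0L)
  rows <- list()
  n_dropped <- 0L
  for (i in seq_along(arrays)) {
    a <- arrays[[i]]
    if (origin_class[i] == "metagenome" && !isTRUE(a$anchored)) next
    sp <- a$spacers
    if (!nrow(sp)) next
    clean <- grepl("^[ACGT]+$", sp$sequence)
    n_dropped <- n_dropped + sum(!clean)
    if (!any(clean)) next
    sp <- sp[clean, , drop = FALSE]
    rows[[length(rows) + 1L]] <- data.frame(
      sequence = sp$sequence, length = nchar(sp$sequence),
      contig_id = a$contig_id, array_start = a$start,
      ordinal = which(clean), origin_class = origin_class[i],
      stringsAsFactors = FALSE)
  }
  out <- if (length(rows)) do.call(rbind, rows) else data.frame(
    sequence = character(0), length = integer(0), contig_id = character(0),
    array_start = integer(0), ordinal = integer(0),
    origin_class = character(0))
  rownames(out) <- NULL
  if (n_dropped > 0L) {
    message(n_dropped, " spacer(s) dropped for non-ACGT characters")
  }
  attr(out, "n_dropped") <- n_dropped
  out
}

#' Deduplicate spacers into the unique catalog
#'
#' Exact-sequence deduplication, orientation-sensitive (a spacer and its
#' reverse complement stay distinct: orientation is defined by the array
#' and collapsing would conflate distinct acquisition events). Provenance
#' lists are merged; ids are assigned by first occurrence.
#'
#' @param spacers data.frame from [extract_spacers()].
#' @return list: `catalog` (data.frame `spacer_id`, `sequence`, `length`,
#'   `n_sources`, `origin_classes`) and `sources` (data.frame mapping
#'   `spacer_id` to each source array position).
#' @export
dedup_spacers <- function(spacers) {
  if (!nrow(spacers)) {
    return(list(
      catalog = data.frame(spacer_id = character(0), sequence = character(0),
                           length = integer(0), n_sources = integer(0),
                           origin_classes = character(0)),
      sources = data.frame(spacer_id = character(0), contig_id = character(0),
                           array_start = integer(0), ordinal = integer(0),
                           origin_class = character(0))))
  }
  first <- !duplicated(spacers$sequence)
  uniq <- spacers$sequence[first]
  ids <- sprintf("sp%05d", seq_along(uniq))
  id_of <- stats::setNames(ids, uniq)
  sources <- data.frame(spacer_id = unname(id_of[spacers$sequence]),
                        contig_id = spacers$contig_id,
                        array_start = spacers$array_start,
                        ordinal = spacers$ordinal,
                        origin_class = spacers$origin_class,
                        stringsAsFactors = FALSE)
  agg_n <- tapply(sources$spacer_id, sources$spacer_id, length)
  agg_o <- tapply(sources$origin_class, sources$spacer_id, function(x) {
    paste(sort(unique(x)), collapse = ",")
  })
  catalog <- data.frame(spacer_id = ids, sequence = uniq,
                        length = nchar(uniq),
                        n_sources = as.integer(agg_n[ids]),
                        origin_classes = as.character(agg_o[ids]),
                        stringsAsFactors = FALSE)
  list(catalog = catalog, sources = sources)
}
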