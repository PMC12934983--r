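# Seeded generator of host genomes, MGE families and metagenome contig sets
# with a ground-truth manifest. All randomness flows from the single seed in
# sim_params(); the exported generators can also be run standalone with an
# explicit seed.

AA20 <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
          "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

# stops in all three forward frames (TAG at offsets 0, 1 and 2), no start
# codons in any frame; placed directly upstream of each planted gene so the
# six-frame longest-ORF caller recovers exactly the planted coordinates
ORF_INSULATOR <- "TAGATAGATAGA"

# codon -> aa for translation table 11 (codon assignments equal the standard
# code; the table differs only in permitted initiators, handled separately)
codon_table <- function() {
  gc <- Biostrings::GENETIC_CODE
  stats::setNames(as.character(gc), names(gc))
}

# aa -> codons (deterministic order) for back-translation
codons_by_aa <- function() {
  ct <- codon_table()
  split(names(ct), ct)
}

random_protein <- function(n_aa) {
  paste(c("M", sample(AA20, n_aa - 1L, replace = TRUE)), collapse = "")
}

# substitute each position with prob q to a different aa (position 1 kept M
# so the start codon stays intact)
mutate_protein <- function(protein, q) {
  if (q <= 0) return(protein)
  ch <- strsplit(protein, "", fixed = TRUE)[[1]]
  hit <- which(runif(length(ch)) < q)
  hit <- hit[hit > 1L]
  for (p in hit) ch[p] <- sample(setdiff(AA20, ch[p]), 1L)
  paste(ch, collapse = "")
}

aa_identity_hamming <- function(a, b) {
  1 - hamming(a, b) / nchar(a)
}

# protein -> coding sequence. The ancestor fixes one codon per position;
# members re-encode only mutated positions, so a zero-divergence family has
# byte-identical shared modules.
encode_protein <- function(protein, anc_protein = NULL, anc_codons = NULL) {
  cba <- codons_by_aa()
  aa <- strsplit(protein, "", fixed = TRUE)[[1]]
  if (is.null(anc_codons)) {
    cods <- vapply(aa, function(a) {
      cs <- cba[[a]]
      cs[sample.int(length(cs), 1L)]
    }, character(1))
  } else {
    anc <- strsplit(anc_protein, "", fixed = TRUE)[[1]]
    cods <- anc_codons
    for (i in which(aa != anc)) {
      cs <- cba[[aa[i]]]
      cods[i] <- cs[sample.int(length(cs), 1L)]
    }
  }
  cods[1] <- "ATG"
  stop_cod <- c("TAA", "TAG", "TGA")[sample.int(3L, 1L)]
  list(codons = unname(cods),
       cds = paste(c(cods, stop_cod), collapse = ""))
}

#' Generate a reference CRISPR repeat set
#'
#' Draws `n` distinct repeat sequences with lengths inside the configured
#' 29-31 nt window; equal-length pairs are kept at Hamming distance >= 3 so
#' the downstream <=1-mismatch anchor filter is unambiguous.
#'
#' @param n number of repeats.
#' @param params a [sim_params()] object.
#' @param seed optional seed; if `NULL` the current RNG stream is used.
#' @return named character vector (`rep1`, `rep2`, ...).
#' @export
generate_repeat_family <- function(n, params = sim_params(), seed = NULL) {
  if (!is.null(seed)) {
    return(withr::with_seed(seed, generate_repeat_family(n, params)))
  }
  win <- params$repeat_length_window
  out <- character(0)
  tries <- 0L
  while (length(out) < n) {
    tries <- tries + 1L
    if (tries > 1000L * n) {
      stop("could not generate ", n, " repeats at pairwise Hamming >= 3")
    }
    len <- sample_range(win[1], win[2])
    cand <- random_dna(len, params$gc_content)
    same_len <- out[nchar(out) == len]
    if (length(same_len) &&
        any(vapply(same_len, function(s) hamming(s, cand), 0L) < 3L)) {
      next
    }
    out <- c(out, cand)
  }
  stats::setNames(out, paste0("rep", seq_len(n)))
}

#' Generate one MGE family
#'
#' Members share `n_core_modules` protein-coding core modules diverged at
#' the amino-acid level (target pairwise identity drawn per module from
#' `core_identity_range`, realized identity kept >= 0.40 by bounded
#' resampling) plus member-specific accessory ORFs. Every gene is a valid
#' ORF (ATG start, in-frame stop, no internal stop, >= 60 codons) in the
#' emitted nucleotide sequence. `round(frac_complete_mges * members)`
#' members carry a planted direct or inverted terminal repeat.
#'
#' @param params a [sim_params()] object.
#' @param family_id label, e.g. `"F01"`.
#' @param seed optional seed; `NULL` uses the current RNG stream.
#' @return list with `family_id` and `members`, each member a list of
#'   `mge_id`, `sequence`, `genes` (data.frame), `completeness`
#'   (`"DTR"`, `"ITR"` or `"none"`), `tr_length`, `tr_seq`.
#' @export
generate_mge_family <- function(params = sim_params(), family_id = "F01",
                                seed = NULL) {
  if (!is.null(seed)) {
    return(withr::with_seed(seed, generate_mge_family(params, family_id)))
  }
  nm <- params$mges_per_family
  ncore <- params$n_core_modules
  glc <- params$gene_length_codons

  # ancestor proteins + fixed codon usage per module
  anc <- vector("list", ncore)
  for (j in seq_len(ncore)) {
    pr <- random_protein(sample_range(glc[1], glc[2]))
    enc <- encode_protein(pr)
    anc[[j]] <- list(protein = pr, codons = enc$codons)
  }

  # member core proteins at controlled divergence
  member_core <- matrix("", nrow = nm, ncol = ncore)
  for (j in seq_len(ncore)) {
    target <- runif(1, params$core_identity_range[1],
                    params$core_identity_range[2])
    q <- 1 - sqrt(target)
    for (try in 1:30) {
      prots <- vapply(seq_len(nm), function(i) {
        mutate_protein(anc[[j]]$protein, q)
      }, character(1))
      ok <- TRUE
      if (nm > 1L) {
        for (a in seq_len(nm - 1L)) for (b in (a + 1L):nm) {
          if (aa_identity_hamming(prots[a], prots[b]) < 0.40) ok <- FALSE
        }
      }
      if (ok) break
    }
    member_core[, j] <- prots
  }

  n_complete <- round(params$frac_complete_mges * nm)
  complete_members <- sample.int(nm, n_complete)

  members <- vector("list", nm)
  for (i in seq_len(nm)) {
    mge_id <- sprintf("%sM%02d", family_id, i)
    # gene list: core modules in family order, accessory inserted at a
    # random member-specific slot (core + variable architecture)
    genes <- lapply(seq_len(ncore), function(j) {
      list(module = sprintf("%s_core%02d", family_id, j),
           protein = member_core[i, j], anc = anc[[j]])
    })
    for (a in seq_len(params$n_accessory)) {
      pr <- random_protein(sample_range(glc[1], glc[2]))
      slot <- sample.int(length(genes) + 1L, 1L)
      genes <- append(genes, list(list(
        module = sprintf("%s_acc%02d", mge_id, a),
        protein = pr, anc = NULL)), after = slot - 1L)
    }

    ig <- params$intergenic_length_range
    pieces <- character(0)
    gene_rows <- list()
    pos <- 0L # 0-based running coordinate within the body
    lead <- random_dna(sample_range(ig[1], ig[2]), params$gc_content)
    pieces <- c(pieces, lead); pos <- pos + nchar(lead)
    for (g in genes) {
      enc <- if (is.null(g$anc)) encode_protein(g$protein)
             else encode_protein(g$protein, g$anc$protein, g$anc$codons)
      pieces <- c(pieces, ORF_INSULATOR)
      pos <- pos + nchar(ORF_INSULATOR)
      gene_rows[[length(gene_rows) + 1L]] <- data.frame(
        gene_id = sprintf("%s_g%02d", mge_id, length(gene_rows) + 1L),
        module = g$module, start = pos, end = pos + nchar(enc$cds),
        strand = "+", protein = g$protein, stringsAsFactors = FALSE)
      pieces <- c(pieces, enc$cds); pos <- pos + nchar(enc$cds)
      tail_ig <- random_dna(sample_range(ig[1], ig[2]), params$gc_content)
      pieces <- c(pieces, tail_ig); pos <- pos + nchar(tail_ig)
    }
    body <- paste(pieces, collapse = "")
    gdf <- do.call(rbind, gene_rows)

    completeness <- "none"; tr_len <- 0L; tr <- ""
    if (i %in% complete_members) {
      trr <- params$terminal_repeat_length_range
      tr_len <- sample_range(trr[1], trr[2])
      tr <- random_dna(tr_len, params$gc_content)
      completeness <- c("DTR", "ITR")[sample.int(2L, 1L)]
      seq <- if (completeness == "DTR") paste0(tr, body, tr)
             else paste0(tr, body, revcomp(tr))
      gdf$start <- gdf$start + tr_len
      gdf$end <- gdf$end + tr_len
    } else {
      seq <- body
    }
    members[[i]] <- list(mge_id = mge_id, sequence = seq, genes = gdf,
                         completeness = completeness,
                         tr_length = tr_len, tr_seq = tr)
  }
  list(family_id = family_id, members = members)
}

# draw one spacer length from the discretized empirical-like distribution
draw_spacer_length <- function(params) {
  rng <- params$spacer_length_range
  lens <- rng[1]:rng[2]
  w <- dnorm(lens, params$spacer_length_median, 4)
  lens[sample.int(length(lens), 1L, prob = w)]
}

# sample a planted mismatch count so the realized identity (L-m)/L falls
# exactly inside the requested identity range
draw_mismatches <- function(L, id_range) {
  mlo <- as.integer(ceiling((1 - id_range[2]) * L - 1e-9))
  mhi <- floor_eps((1 - id_range[1]) * L)
  ms <- mlo:mhi
  ms[sample.int(length(ms), 1L)]
}

#' Generate one host genome with CRISPR arrays
#'
#' Inserts 1 or more repeat-spacer arrays into a random background. Each
#' array uses one reference repeat (with probability `repeat_variant_prob`
#' carrying a single substitution, identical in every instance) and
#' alternates it with spacers; at least `frac_mge_derived` of the spacers
#' are drawn from the MGE pool with a controlled number of planted
#' mismatches, the remainder are random dark spacers.
#'
#' @param params a [sim_params()] object.
#' @param mge_pool list of members as produced by [generate_mge_family()]
#'   (flattened), each with `mge_id` and `sequence`.
#' @param reference_repeats named character vector from
#'   [generate_repeat_family()].
#' @param host_id label, e.g. `"host1"`.
#' @param seed optional seed; `NULL` uses the current RNG stream.
#' @return list with `host_id`, `sequence`, `arrays` (data.frame) and
#'   `spacers` (data.frame of per-spacer truth incl. protospacer records).
#' @export
generate_host_genome <- function(params, mge_pool, reference_repeats,
                                 host_id = "host1", seed = NULL) {
  if (!is.null(seed)) {
    return(withr::with_seed(
      seed, generate_host_genome(params, mge_pool, reference_repeats, host_id)))
  }
  stopifnot(length(mge_pool) >= 1L)
  ar <- params$arrays_per_host_range
  n_arr <- sample_range(ar[1], ar[2])

  arrays <- list(); spacer_rows <- list(); array_seqs <- character(n_arr)
  for (a in seq_len(n_arr)) {
    array_id <- sprintf("%s_arr%d", host_id, a)
    ridx <- sample.int(length(reference_repeats), 1L)
    rep_seq <- unname(reference_repeats[ridx])
    variant <- runif(1) < params$repeat_variant_prob
    if (variant) rep_seq <- mutate_positions(rep_seq, 1L)
    rr <- params$repeats_per_array_range
    n_rep <- sample_range(rr[1], rr[2])
    n_sp <- n_rep - 1L
    n_mge <- min(n_sp, as.integer(ceiling(params$frac_mge_derived * n_sp)))
    mge_slots <- sort(sample.int(n_sp, n_mge))

    sp_seqs <- character(n_sp)
    for (s in seq_len(n_sp)) {
      L <- draw_spacer_length(params)
      if (s %in% mge_slots) {
        mi <- sample.int(length(mge_pool), 1L)
        member <- mge_pool[[mi]]
        glen <- nchar(member$sequence)
        start0 <- sample.int(glen - L + 1L, 1L) - 1L
        window <- substr(member$sequence, start0 + 1L, start0 + L)
        strand <- c("+", "-")[sample.int(2L, 1L)]
        proto <- if (strand == "+") window else revcomp(window)
        m <- draw_mismatches(L, params$protospacer_identity_range)
        spacer <- mutate_positions(proto, m)
        # mutate_positions picks distinct positions, so the Hamming
        # distance between spacer and oriented protospacer is exactly m
        sp_seqs[s] <- spacer
        spacer_rows[[length(spacer_rows) + 1L]] <- data.frame(
          host_id = host_id, array_id = array_id, ordinal = s,
          sequence = spacer, length = L, origin = "mge",
          mge_id = member$mge_id, mge_start = start0, mge_end = start0 + L,
          strand = strand, mismatches = m, stringsAsFactors = FALSE)
      } else {
        sp_seqs[s] <- random_dna(L, params$gc_content)
        spacer_rows[[length(spacer_rows) + 1L]] <- data.frame(
          host_id = host_id, array_id = array_id, ordinal = s,
          sequence = sp_seqs[s], length = L, origin = "dark",
          mge_id = NA_character_, mge_start = NA_integer_,
          mge_end = NA_integer_, strand = NA_character_,
          mismatches = NA_integer_, stringsAsFactors = FALSE)
      }
    }
    inter <- c(rbind(rep(rep_seq, n_sp), sp_seqs))
    array_seqs[a] <- paste(c(inter, rep_seq), collapse = "")
    arrays[[a]] <- data.frame(
      host_id = host_id, array_id = array_id,
      ref_repeat_id = names(reference_repeats)[ridx],
      repeat_seq = rep_seq, repeat_variant = variant, n_repeats = n_rep,
      length = nchar(array_seqs[a]), stringsAsFactors = FALSE)
  }

  background <- random_dna(params$host_length, params$gc_content)
  # insertion points, kept >= 100 nt apart so arrays never touch
  repeat {
    ins <- sort(sample.int(params$host_length - 200L, n_arr) + 100L)
    if (n_arr == 1L || min(diff(ins)) > 100L) break
  }
  pieces <- character(0); prev <- 0L; coords <- integer(n_arr)
  shift <- 0L
  for (a in seq_len(n_arr)) {
    pieces <- c(pieces, substr(background, prev + 1L, ins[a]), array_seqs[a])
    coords[a] <- ins[a] + shift       # 0-based start of array in final genome
    shift <- shift + nchar(array_seqs[a])
    prev <- ins[a]
  }
  pieces <- c(pieces, substr(background, prev + 1L, params$host_length))
  genome <- paste(pieces, collapse = "")

  adf <- do.call(rbind, arrays)
  adf$start <- coords
  adf$end <- coords + adf$length
  adf$length <- NULL
  list(host_id = host_id, sequence = genome, arrays = adf,
       spacers = do.call(rbind, spacer_rows))
}

# tile [0, len) into fragments with given mean length; returns data.frame
# of 0-based half-open [start, end); breakpoints may be snapped to a set of
# permitted positions (gene-boundary-safe cutting for MGEs)
tile_fragments <- function(len, mean_len, snap = NULL) {
  n_frag <- max(1L, as.integer(round(len / mean_len)))
  if (n_frag == 1L) {
    return(data.frame(start = 0L, end = len))
  }
  cuts <- as.integer(round(seq_len(n_frag - 1L) * len / n_frag))
  if (!is.null(snap) && length(snap)) {
    cuts <- vapply(cuts, function(cu) snap[which.min(abs(snap - cu))], 0L)
    cuts <- sort(unique(cuts))
  } else {
    jit <- as.integer(round(runif(length(cuts), -0.1 * mean_len,
                                  0.1 * mean_len)))
    cuts <- sort(unique(pmin(pmax(cuts + jit, 1L), len - 1L)))
  }
  bounds <- c(0L, cuts, len)
  data.frame(start = bounds[-length(bounds)], end = bounds[-1])
}

#' Generate the metagenome contig set and truth manifest
#'
#' Emits host fragments, MGE sequences (complete genomes whole, incomplete
#' genomes tiled into fragments whose breakpoints are snapped into
#' intergenic gaps so gene content per contig is well defined) and i.i.d.
#' random decoys, in a seeded shuffled order under neutral contig ids.
#'
#' @param params a [sim_params()] object.
#' @param hosts list of host objects from [generate_host_genome()].
#' @param mge_pool flat list of MGE members.
#' @param seed optional seed; `NULL` uses the current RNG stream.
#' @return list: `contigs` (named character vector) and `manifest` (list of
#'   data.frames: `contigs`, `contig_protospacers`).
#' @export
generate_metagenome <- function(params, hosts, mge_pool, seed = NULL) {
  if (!is.null(seed)) {
    return(withr::with_seed(seed, generate_metagenome(params, hosts, mge_pool)))
  }
  stopifnot(length(hosts) >= 1L, length(mge_pool) >= 1L)
  seqs <- character(0)
  rows <- list()
  add <- function(seq, origin, source_id, s0, e0) {
    seqs[[length(seqs) + 1L]] <<- seq
    rows[[length(rows) + 1L]] <<- data.frame(
      origin = origin, source_id = source_id, source_start = s0,
      source_end = e0, length = nchar(seq), stringsAsFactors = FALSE)
  }

  for (m in mge_pool) {
    len <- nchar(m$sequence)
    if (m$completeness != "none") {
      add(m$sequence, "mge", m$mge_id, 0L, len)
    } else {
      # permitted cut points: inside intergenic gaps, insulator kept with
      # its downstream gene
      g <- m$genes[order(m$genes$start), ]
      snap <- integer(0)
      if (nrow(g) > 1L) {
        for (i in seq_len(nrow(g) - 1L)) {
          lo <- g$end[i] + 1L
          hi <- g$start[i + 1L] - nchar(ORF_INSULATOR)
          if (hi >= lo) snap <- c(snap, sample_range(lo, hi))
        }
      }
      fr <- tile_fragments(len, params$contig_fragmentation, snap = snap)
      for (i in seq_len(nrow(fr))) {
        add(substr(m$sequence, fr$start[i] + 1L, fr$end[i]),
            "mge", m$mge_id, fr$start[i], fr$end[i])
      }
    }
  }
  for (h in hosts) {
    len <- nchar(h$sequence)
    fr <- tile_fragments(len, params$contig_fragmentation)
    for (i in seq_len(nrow(fr))) {
      add(substr(h$sequence, fr$start[i] + 1L, fr$end[i]),
          "host", h$host_id, fr$start[i], fr$end[i])
    }
  }
  if (params$n_decoys > 0L) {
    dl <- params$decoy_length_range
    lens <- pmin(pmax(as.integer(round(stats::rlnorm(
      params$n_decoys, log(2200), 0.5))), dl[1]), dl[2])
    for (i in seq_len(params$n_decoys)) {
      add(random_dna(lens[i], params$gc_content), "decoy",
          sprintf("decoy%04d", i), 0L, lens[i])
    }
  }

  cdf <- do.call(rbind, rows)
  ord <- sample.int(nrow(cdf))
  cdf <- cdf[ord, , drop = FALSE]
  seqs <- unlist(seqs)[ord]
  cdf$contig_id <- sprintf("ctg%05d", seq_len(nrow(cdf)))
  rownames(cdf) <- NULL
  cdf <- cdf[, c("contig_id", "origin", "source_id", "source_start",
                 "source_end", "length")]
  names(seqs) <- cdf$contig_id

  # map planted protospacers onto emitted mge contigs (fully contained)
  sp <- do.call(rbind, lapply(hosts, `[[`, "spacers"))
  sp_mge <- sp[sp$origin == "mge", , drop = FALSE]
  proto <- list()
  mge_ctg <- cdf[cdf$origin == "mge", , drop = FALSE]
  if (nrow(sp_mge)) {
    sp_mge$spacer_key <- paste(sp_mge$array_id, sp_mge$ordinal, sep = ":")
    for (i in seq_len(nrow(sp_mge))) {
      hit_ctg <- mge_ctg[mge_ctg$source_id == sp_mge$mge_id[i] &
                         mge_ctg$source_start <= sp_mge$mge_start[i] &
                         mge_ctg$source_end >= sp_mge$mge_end[i], ,
                         drop = FALSE]
      for (j in seq_len(nrow(hit_ctg))) {
        proto[[length(proto) + 1L]] <- data.frame(
          spacer_key = sp_mge$spacer_key[i],
          sequence = sp_mge$sequence[i],
          contig_id = hit_ctg$contig_id[j],
          start = sp_mge$mge_start[i] - hit_ctg$source_start[j],
          end = sp_mge$mge_end[i] - hit_ctg$source_start[j],
          strand = sp_mge$strand[i],
          mismatches = sp_mge$mismatches[i], stringsAsFactors = FALSE)
      }
    }
  }
  proto <- if (length(proto)) do.call(rbind, proto) else data.frame(
    spacer_key = character(0), sequence = character(0),
    contig_id = character(0), start = integer(0), end = integer(0),
    strand = character(0), mismatches = integer(0))

  list(contigs = seqs,
       manifest = list(contigs = cdf, contig_protospacers = proto))
}

#' Simulate a complete synthetic vent metagenome scenario
#'
#' Runs the full generator under the single seed in `params`: reference
#' repeats, MGE families, host genomes with CRISPR arrays, and the shuffled
#' metagenome contig set, together with a machine-readable truth manifest
#' whose every claim (protospacer positions and mismatch counts, terminal
#' repeats, gene coordinates) is re-verifiable from the emitted sequences.
#'
#' @param params a [sim_params()] object.
#' @return list of class `vent_simulation`: `params`, `reference_repeats`,
#'   `families`, `mge_pool`, `hosts`, `host_seqs`, `contigs`, `manifest`.
#' @export
simulate_vent_metagenome <- function(params = sim_params()) {
  validate_sim_params(params)
  withr::with_seed(params$seed, {
    repeats <- generate_repeat_family(params$n_reference_repeats, params)
    families <- lapply(seq_len(params$n_mge_families), function(f) {
      generate_mge_family(params, sprintf("F%02d", f))
    })
    mge_pool <- do.call(c, lapply(families, `[[`, "members"))
    hosts <- lapply(seq_len(params$n_hosts), function(h) {
      generate_host_genome(params, mge_pool, repeats, sprintf("host%d", h))
    })
    meta <- generate_metagenome(params, hosts, mge_pool)

    mge_df <- do.call(rbind, lapply(mge_pool, function(m) {
      data.frame(mge_id = m$mge_id,
                 family = substr(m$mge_id, 1L, 3L),
                 length = nchar(m$sequence), completeness = m$completeness,
                 tr_length = m$tr_length, stringsAsFactors = FALSE)
    }))
    gene_df <- do.call(rbind, lapply(mge_pool, function(m) {
      cbind(data.frame(mge_id = m$mge_id, stringsAsFactors = FALSE), m$genes)
    }))
    arr_df <- do.call(rbind, lapply(hosts, `[[`, "arrays"))
    sp_df <- do.call(rbind, lapply(hosts, `[[`, "spacers"))

    manifest <- c(list(mges = mge_df, genes = gene_df, arrays = arr_df,
                       spacers = sp_df), meta$manifest)
    out <- list(params = params, reference_repeats = repeats,
                families = families, mge_pool = mge_pool, hosts = hosts,
                host_seqs = stats::setNames(
                  vapply(hosts, `[[`, "", "sequence"),
                  vapply(hosts, `[[`, "", "host_id")),
                contigs = meta$contigs, manifest = manifest)
    class(out) <- "vent_simulation"
    out
  })
}

#' @export
print.vent_simulation <- function(x, ...) {
  cat("Synthetic vent metagenome (seed ", x$params$seed, ")\n", sep = "")
  cat("  ", length(x$hosts), " hosts, ",
      length(x$families), " MGE families, ",
      length(x$contigs), " contigs (",
      sum(x$manifest$contigs$origin == "decoy"), " decoys)\n", sep = "")
  invisible(x)
}

#' Write a simulation to disk
#'
#' Emits `contigs.fasta`, `hosts.fasta`, `reference_repeats.fasta`, the
#' manifest as sectioned TSV plus a JSON mirror, and the parameters as a
#' flat key=value config.
#'
#' @param sim a [simulate_vent_metagenome()] result.
#' @param dir output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_simulation <- function(sim, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_fasta(sim$contigs, file.path(dir, "contigs.fasta"))
  write_fasta(sim$host_seqs, file.path(dir, "hosts.fasta"))
  write_fasta(sim$reference_repeats,
              file.path(dir, "reference_repeats.fasta"))
  write_manifest(sim$manifest, dir)
  p <- sim$params
  kv <- vapply(names(unclass(p)), function(k) {
    paste0(k, "=", paste(p[[k]], collapse = ","))
  }, character(1))
  writeLines(kv, file.path(dir, "sim_config.txt"))
  invisible(dir)
}

#' @rdname write_simulation
#' @param manifest a manifest list of data.frames.
#' @export
write_manifest <- function(manifest, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  con <- file(file.path(dir, "manifest.tsv"), "w")
  on.exit(close(con))
  for (section in names(manifest)) {
    df <- manifest[[section]]
    writeLines(paste0("## section=", section), con)
    utils::write.table(df, con, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       dataframe = "rows", auto_unbox = TRUE, digits = NA,
                       na = "null")
  invisible(dir)
}
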