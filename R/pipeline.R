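# Full pipeline orchestration: mine -> anchor -> search -> mask -> select
# -> dedup -> gene-sharing network -> communities -> reports. Every stage
# writes its intermediate, identical config + inputs give byte-identical
# output trees, and the run summary is recomputable from the emitted
# tables.

#' Pipeline configuration
#'
#' Defaults equal the published thresholds of the mining procedure:
#' repeat window 29-31 nt with a <= 1 mismatch reference anchor,
#' protospacer identity >= 0.90, candidate length >= 2000 nt with >= 2
#' hits (or >= 1 plus completeness), terminal repeats >= 20 bp at <= 10%
#' mismatches, dereplication at >= 98% ANI and >= 95% coverage, protein
#' clustering at >= 25% identity, gene-sharing edges at >= 5 shared
#' clusters, and representatives at >= 75% of the shortest complete
#' genome.
#'
#' @param ... overrides for any default listed by `run_config()`.
#' @return list of class `run_config`.
#' @export
run_config <- function(...) {
  cfg <- list(
    repeat_len = c(29L, 31L), spacer_len = c(20L, 60L), min_repeats = 3L,
    max_divergence = 2L, seed_k = 8L,
    anchor_max_mismatch = 1L,
    index_k = 7L, min_identity = 0.90,
    min_len = 2000L, min_hits = 2L,
    tr_min_len = 20L, tr_max_mismatch_frac = 0.10, tr_window = 2000L,
    dedup_min_ani = 0.98, dedup_min_cov = 0.95,
    cluster_min_identity = 0.25, cluster_min_cov = 0.80,
    orf_min_aa = 60L,
    min_shared = 5L, core_min_frac = 0.80, representative_frac = 0.75,
    host_screen_ani = 0.98, host_screen_cov = 0.50,
    seed = 42L,
    contigs = NULL, genomes = NULL, repeats = NULL, spacers = NULL,
    out_dir = NULL)
  over <- list(...)
  bad <- setdiff(names(over), names(cfg))
  if (length(bad)) stop("unknown config field(s): ", paste(bad, collapse = ", "))
  cfg[names(over)] <- over
  class(cfg) <- "run_config"
  validate_run_config(cfg)
  cfg
}

validate_run_config <- function(cfg) {
  stopifnot(
    cfg$min_identity > 0, cfg$min_identity <= 1,
    cfg$min_len >= 0, cfg$min_hits >= 1,
    cfg$tr_min_len >= 1, cfg$tr_max_mismatch_frac >= 0,
    cfg$tr_max_mismatch_frac <= 1,
    cfg$dedup_min_ani > 0, cfg$dedup_min_ani <= 1,
    cfg$dedup_min_cov > 0, cfg$dedup_min_cov <= 1,
    cfg$cluster_min_identity > 0, cfg$cluster_min_identity <= 1,
    cfg$min_shared >= 1, cfg$core_min_frac >= 0, cfg$core_min_frac <= 1,
    cfg$representative_frac >= 0, cfg$representative_frac <= 1,
    cfg$repeat_len[1] <= cfg$repeat_len[2])
  invisible(cfg)
}

as_seq_vector <- function(x, what) {
  if (is.null(x)) return(NULL)
  if (is.character(x) && length(x) == 1L && is.null(names(x)) &&
      file.exists(x)) {
    return(read_fasta(x))
  }
  if (is.character(x) && !is.null(names(x))) return(toupper(x))
  stop("cannot interpret '", what, "': give a named character vector or ",
       "a FASTA path")
}

serialize_config <- function(cfg, path) {
  flat <- unclass(cfg)
  flat <- flat[!vapply(flat, is.null, logical(1))]
  flat <- flat[!names(flat) %in% c("contigs", "genomes", "repeats",
                                   "spacers", "out_dir")]
  kv <- vapply(names(flat), function(k) {
    paste0(k, "=", paste(flat[[k]], collapse = ",")) }, character(1))
  writeLines(kv, path)
  invisible(path)
}

#' Run the full mining pipeline
#'
#' @param config a [run_config()]; `contigs` (required) and optionally
#'   `genomes` (isolate host genomes), `repeats` (reference repeat set,
#'   required to anchor metagenomic arrays) and `spacers` (precomputed
#'   spacer FASTA/vector) may be named character vectors or FASTA paths;
#'   `out_dir` enables file output.
#' @return list of class `run_result`: `summary` (a `run_summary`),
#'   `arrays`, `catalog`, `hits`, `completeness`, `candidates`,
#'   `clusters`, `orfs`, `protein_clusters`, `network`, `communities`,
#'   `community_table`.
#' @export
run_pipeline <- function(config = run_config()) {
  validate_run_config(config)
  contigs <- as_seq_vector(config$contigs, "contigs")
  if (is.null(contigs)) stop("config$contigs is required")
  genomes <- as_seq_vector(config$genomes, "genomes")
  repeats <- as_seq_vector(config$repeats, "repeats")
  extra_spacers <- as_seq_vector(config$spacers, "spacers")

  ap <- array_params(repeat_len = config$repeat_len,
                     spacer_len = config$spacer_len,
                     min_repeats = config$min_repeats,
                     max_divergence = config$max_divergence,
                     seed_k = config$seed_k)

  # -- mine CRISPR arrays -------------------------------------------------
  iso_arrays <- if (!is.null(genomes)) detect_arrays_set(genomes, ap)
                else list()
  meta_arrays <- detect_arrays_set(contigs, ap)
  if (!is.null(repeats)) {
    iso_arrays <- anchor_arrays(iso_arrays, repeats,
                                config$anchor_max_mismatch)
    meta_arrays <- anchor_arrays(meta_arrays, repeats,
                                 config$anchor_max_mismatch)
  }
  spacer_rows <- rbind(
    extract_spacers(iso_arrays, rep("isolate_genome",
                                    length(iso_arrays))),
    extract_spacers(meta_arrays, rep("metagenome", length(meta_arrays))))
  if (!is.null(extra_spacers)) {
    spacer_rows <- rbind(spacer_rows, data.frame(
      sequence = unname(extra_spacers), length = nchar(extra_spacers),
      contig_id = names(extra_spacers), array_start = NA_integer_,
      ordinal = NA_integer_, origin_class = "isolate_genome",
      stringsAsFactors = FALSE))
  }
  cat_res <- dedup_spacers(spacer_rows)
  catalog <- cat_res$catalog

  # -- protospacer search -------------------------------------------------
  hits_raw <- if (nrow(catalog) && length(contigs)) {
    idx <- index_contigs(contigs, k = config$index_k)
    search_spacers(catalog, idx, min_identity = config$min_identity)
  } else {
    data.frame(spacer_id = character(0), contig_id = character(0),
               start = integer(0), end = integer(0), strand = character(0),
               mismatches = integer(0), identity = numeric(0))
  }
  hits <- mask_array_hits(hits_raw, meta_arrays)

  # -- completeness + selection ------------------------------------------
  hit_ctg <- unique(hits$contig_id)
  completeness <- if (length(hit_ctg)) {
    call_completeness(contigs[hit_ctg], min_len = config$tr_min_len,
                      max_mismatch_frac = config$tr_max_mismatch_frac,
                      window = config$tr_window)
  } else {
    data.frame(contig_id = character(0), kind = character(0),
               repeat_length = integer(0), mismatches = integer(0),
               mismatch_fraction = numeric(0))
  }
  candidates <- select_candidates(contigs, hits, completeness,
                                  min_len = config$min_len,
                                  min_hits = config$min_hits)
  if (!is.null(genomes) && nrow(candidates)) {
    candidates <- screen_host_like(candidates, contigs, genomes,
                                   config$host_screen_ani,
                                   config$host_screen_cov)
  } else {
    candidates$host_like <- logical(nrow(candidates))
  }

  # -- dereplication ------------------------------------------------------
  clusters <- dedup_candidates(contigs[candidates$contig_id],
                               min_ani = config$dedup_min_ani,
                               min_cov = config$dedup_min_cov)
  reps <- unique(clusters$representative)

  # -- gene sharing -------------------------------------------------------
  orfs <- if (length(reps)) call_orfs_set(contigs[reps], config$orf_min_aa)
          else call_orfs_set(character(0))
  if (length(reps) && nrow(orfs)) {
    prot <- stats::setNames(orfs$protein, orfs$orf_id)
    pclust <- cluster_proteins(prot,
                               min_identity = config$cluster_min_identity,
                               min_cov = config$cluster_min_cov)
    orf_contig <- stats::setNames(orfs$contig_id, orfs$orf_id)
    contig_clusters <- data.frame(
      contig_id = unname(orf_contig[pclust$member]),
      cluster_id = pclust$cluster_id, stringsAsFactors = FALSE)
    # contigs whose every ORF failed min_aa still become singleton nodes
    missing <- setdiff(reps, unique(contig_clusters$contig_id))
    if (length(missing)) {
      contig_clusters <- rbind(contig_clusters, data.frame(
        contig_id = missing,
        cluster_id = paste0("none_", missing), stringsAsFactors = FALSE))
    }
    network <- build_network(contig_clusters,
                             min_shared = config$min_shared)
    communities <- detect_communities(network, seed = config$seed)
  } else {
    pclust <- cluster_proteins(character(0))
    network <- build_network(data.frame(contig_id = character(0),
                                        cluster_id = character(0)))
    communities <- stats::setNames(character(0), character(0))
  }

  # -- per-community report ----------------------------------------------
  lens <- stats::setNames(nchar(contigs), names(contigs))
  comm_rows <- list()
  for (cm in unique(communities)) {
    members <- names(communities)[communities == cm]
    rp <- select_representatives(members, lens, completeness,
                                 frac = config$representative_frac)
    core_members <- if (length(rp$representatives)) rp$representatives
                    else members
    core <- core_clusters(core_members, network$profiles,
                          min_frac = config$core_min_frac)
    dens <- vapply(members, function(id) {
      targeting_density(lens[[id]],
                        hits[hits$contig_id == id, , drop = FALSE])
    }, numeric(1))
    comp_members <- completeness$contig_id[
      completeness$kind != "none" & completeness$contig_id %in% members]
    comm_rows[[length(comm_rows) + 1L]] <- data.frame(
      community = cm, size = length(members),
      members = paste(members, collapse = ","),
      n_complete = length(comp_members),
      no_complete_flag = rp$no_complete,
      representatives = paste(rp$representatives, collapse = ","),
      n_core_clusters = nrow(core),
      core_clusters = paste(core$cluster_id, collapse = ","),
      mean_targeting_density = round(mean(dens), 4),
      stringsAsFactors = FALSE)
  }
  community_table <- if (length(comm_rows)) do.call(rbind, comm_rows)
    else data.frame(community = character(0), size = integer(0),
                    members = character(0), n_complete = integer(0),
                    no_complete_flag = logical(0),
                    representatives = character(0),
                    n_core_clusters = integer(0),
                    core_clusters = character(0),
                    mean_targeting_density = numeric(0))

  spacers_matched <- length(unique(hits$spacer_id))
  summary <- structure(list(
    n_contigs = length(contigs),
    arrays_found = length(iso_arrays) + length(meta_arrays),
    arrays_metagenome = length(meta_arrays),
    arrays_anchored = sum(vapply(c(iso_arrays, meta_arrays),
                                 function(a) isTRUE(a$anchored),
                                 logical(1))),
    unique_spacers = nrow(catalog),
    median_spacer_length = if (nrow(catalog))
      as.numeric(stats::median(catalog$length)) else NA_real_,
    spacers_matched = spacers_matched,
    spacer_match_fraction = if (nrow(catalog))
      spacers_matched / nrow(catalog) else NA_real_,
    hits_total = nrow(hits),
    hits_masked = attr(hits, "n_masked") %||% 0L,
    candidates_total = nrow(candidates),
    candidates_multi_hit = sum(candidates$selection_branch == "multi_hit"),
    candidates_single_hit_complete =
      sum(candidates$selection_branch == "single_hit_complete"),
    candidates_host_like = sum(candidates$host_like),
    complete_genomes = sum(candidates$completeness != "none"),
    mean_hits_per_candidate = if (nrow(candidates))
      mean(candidates$n_hits) else NA_real_,
    dedup_clusters = length(reps),
    network_nodes = igraph::vcount(network$graph),
    network_edges = igraph::ecount(network$graph),
    communities = length(unique(communities))),
    class = "run_summary")

  result <- structure(list(
    config = config, summary = summary,
    arrays = c(iso_arrays, meta_arrays), meta_arrays = meta_arrays,
    catalog = catalog, spacer_sources = cat_res$sources, hits = hits,
    completeness = completeness, candidates = candidates,
    clusters = clusters, representatives = reps, orfs = orfs,
    protein_clusters = pclust, network = network,
    communities = communities, community_table = community_table),
    class = "run_result")

  if (!is.null(config$out_dir)) {
    write_reports(result, config$out_dir, contigs = contigs)
  }
  result
}

#' @export
print.run_summary <- function(x, ...) {
  cat("Pipeline run summary\n")
  for (k in names(unclass(x))) {
    v <- x[[k]]
    if (is.numeric(v) && !is.na(v)) v <- signif(v, 5)
    cat(sprintf("  %-32s %s\n", k, v))
  }
  invisible(x)
}

#' @export
print.run_result <- function(x, ...) {
  print(x$summary)
  invisible(x)
}

#' Write pipeline reports to a directory
#'
#' Emits every intermediate as TSV/FASTA/GFF3/BED/GraphML plus the run
#' summary as TSV and JSON and a serialized copy of the configuration.
#' File contents are deterministic for identical inputs and config.
#'
#' @param result a [run_pipeline()] result.
#' @param out_dir output directory (created).
#' @param contigs named character vector used in the run (for FASTA
#'   output of representatives).
#' @return `out_dir`, invisibly.
#' @export
write_reports <- function(result, out_dir, contigs = NULL) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  f <- function(x) file.path(out_dir, x)
  serialize_config(result$config, f("config.txt"))

  write_arrays_gff3(result$arrays, f("arrays.gff3"))
  write_tsv(result$catalog, f("spacers.tsv"))
  if (nrow(result$catalog)) {
    write_fasta(stats::setNames(result$catalog$sequence,
                                result$catalog$spacer_id),
                f("spacers.fasta"))
  }
  hits <- result$hits
  attr(hits, "n_masked") <- NULL
  write_tsv(hits, f("hits.tsv"))
  write_hits_bed(result$hits, f("hits.bed"))
  write_tsv(result$completeness, f("completeness.tsv"))
  write_tsv(result$candidates, f("candidates.tsv"))
  write_tsv(result$clusters, f("dedup_clusters.tsv"))
  if (!is.null(contigs) && length(result$representatives)) {
    write_fasta(contigs[result$representatives],
                f("representatives.fasta"))
  }
  orfs <- result$orfs
  write_orfs_gff3(orfs, f("orfs.gff3"))
  if (nrow(orfs)) {
    write_fasta_aa(stats::setNames(orfs$protein, orfs$orf_id),
                   f("proteins.fasta"))
  }
  write_tsv(result$protein_clusters, f("protein_clusters.tsv"))

  g <- result$network$graph
  edges <- if (igraph::ecount(g)) {
    el <- igraph::as_edgelist(g)
    data.frame(contig_a = el[, 1], contig_b = el[, 2],
               shared_clusters = igraph::E(g)$shared,
               weight = igraph::E(g)$weight, stringsAsFactors = FALSE)
  } else {
    data.frame(contig_a = character(0), contig_b = character(0),
               shared_clusters = integer(0), weight = integer(0))
  }
  write_tsv(edges, f("network_edges.tsv"))
  igraph::write_graph(g, f("network.graphml"), format = "graphml")
  write_tsv(data.frame(contig_id = names(result$communities),
                       community = unname(result$communities),
                       stringsAsFactors = FALSE),
            f("communities.tsv"))
  write_tsv(result$community_table, f("community_report.tsv"))

  s <- unclass(result$summary)
  write_tsv(data.frame(statistic = names(s),
                       value = vapply(s, function(v)
                         as.character(v %||% NA), character(1))),
            f("summary.tsv"))
  jsonlite::write_json(s, f("summary.json"), auto_unbox = TRUE,
                       digits = NA, na = "null")
  invisible(out_dir)
}
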