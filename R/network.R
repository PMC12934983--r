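# Gene-sharing network: contigs are nodes, an edge connects two contigs
# sharing >= 5 protein clusters, weighted by total shared genes
# (sum over shared clusters of the smaller copy number). Communities come
# from weighted modularity optimization with a fixed seed.

#' Build the gene-sharing network
#'
#' @param contig_clusters data.frame with columns `contig_id` and
#'   `cluster_id`, one row per gene (so repeated rows encode copy number).
#' @param min_shared minimum distinct shared clusters for an edge
#'   (default 5).
#' @return object of class `gene_sharing_graph`: list with `graph`
#'   (igraph, weighted), `profiles` (contig x cluster count matrix) and
#'   `min_shared`.
#' @export
build_network <- function(contig_clusters, min_shared = 5L) {
  stopifnot(all(c("contig_id", "cluster_id") %in% names(contig_clusters)))
  contigs <- unique(contig_clusters$contig_id)
  clusters <- unique(contig_clusters$cluster_id)
  M <- table(factor(contig_clusters$contig_id, levels = contigs),
             factor(contig_clusters$cluster_id, levels = clusters))
  M <- matrix(as.integer(M), nrow = length(contigs),
              dimnames = list(contigs, clusters))
  nn <- length(contigs)
  ef <- integer(0); et <- integer(0); ew <- integer(0); es <- integer(0)
  if (nn > 1L) {
    for (i in seq_len(nn - 1L)) {
      for (j in (i + 1L):nn) {
        shared <- sum(M[i, ] > 0L & M[j, ] > 0L)
        if (shared >= min_shared) {
          ef <- c(ef, i); et <- c(et, j)
          es <- c(es, shared)
          ew <- c(ew, sum(pmin(M[i, ], M[j, ])))
        }
      }
    }
  }
  g <- igraph::make_empty_graph(n = nn, directed = FALSE)
  g <- igraph::set_vertex_attr(g, "name", value = contigs)
  if (length(ef)) {
    g <- igraph::add_edges(g, rbind(ef, et))
    g <- igraph::set_edge_attr(g, "shared", value = es)
    g <- igraph::set_edge_attr(g, "weight", value = ew)
  }
  structure(list(graph = g, profiles = M, min_shared = as.integer(min_shared)),
            class = "gene_sharing_graph")
}

#' @export
print.gene_sharing_graph <- function(x, ...) {
  cat(sprintf("Gene-sharing network: %d contigs, %d edges (>= %d shared clusters)\n",
              igraph::vcount(x$graph), igraph::ecount(x$graph), x$min_shared))
  invisible(x)
}

#' Detect communities by weighted modularity
#'
#' Louvain-style multilevel modularity optimization on the shared-gene
#' weights, under a fixed seed and the deterministic vertex order of the
#' input graph. Singleton nodes keep singleton communities. Labels are
#' renumbered by first node appearance so identical inputs give identical
#' labels.
#'
#' @param gsg a [build_network()] result (or an igraph graph).
#' @param seed RNG seed for the optimizer.
#' @return named character vector contig -> community label (`"C01"`...).
#' @export
detect_communities <- function(gsg, seed = 1L) {
  g <- if (inherits(gsg, "gene_sharing_graph")) gsg$graph else gsg
  if (igraph::vcount(g) == 0L) return(stats::setNames(character(0), character(0)))
  memb <- withr::with_seed(seed, {
    if (igraph::ecount(g) > 0L) {
      igraph::membership(igraph::cluster_louvain(
        g, weights = igraph::E(g)$weight))
    } else {
      stats::setNames(seq_len(igraph::vcount(g)), igraph::V(g)$name)
    }
  })
  first <- !duplicated(memb)
  relabel <- stats::setNames(sprintf("C%02d", seq_len(sum(first))),
                             memb[first])
  stats::setNames(unname(relabel[as.character(memb)]), names(memb))
}

#' Core protein clusters of a community
#'
#' Clusters present (count >= 1) in at least `min_frac` of the given
#' members, sorted by decreasing prevalence (ties by cluster id).
#'
#' @param members contig ids of the community (rows of `profiles`).
#' @param profiles contig x cluster count matrix (from
#'   [build_network()]`$profiles`).
#' @param min_frac prevalence threshold (default 0.80).
#' @return data.frame: `cluster_id`, `prevalence`.
#' @export
core_clusters <- function(members, profiles, min_frac = 0.80) {
  stopifnot(length(members) >= 1L, all(members %in% rownames(profiles)))
  sub <- profiles[members, , drop = FALSE]
  prev <- colMeans(sub > 0L)
  keep <- prev >= min_frac - 1e-9
  out <- data.frame(cluster_id = colnames(sub)[keep],
                    prevalence = unname(prev[keep]),
                    stringsAsFactors = FALSE)
  out[order(-out$prevalence, out$cluster_id, method = "radix"), ,
      drop = FALSE]
}

#' Representative contigs of a community
#'
#' A member is representative when its length reaches at least `frac` of
#' the shortest complete genome (completeness != "none") in the
#' community. Communities without any complete member return an empty set
#' with the `no_complete` flag.
#'
#' @param members community contig ids.
#' @param lengths named contig lengths.
#' @param completeness data.frame from [call_completeness()].
#' @param frac length fraction of the shortest complete genome
#'   (default 0.75).
#' @return list: `representatives` (character), `no_complete` (flag),
#'   `min_complete_length`.
#' @export
select_representatives <- function(members, lengths, completeness,
                                   frac = 0.75) {
  comp <- stats::setNames(completeness$kind, completeness$contig_id)
  kinds <- comp[members]
  kinds[is.na(kinds)] <- "none"
  complete <- members[kinds != "none"]
  if (!length(complete)) {
    return(list(representatives = character(0), no_complete = TRUE,
                min_complete_length = NA_integer_))
  }
  lstar <- min(lengths[complete])
  reps <- members[lengths[members] >= frac * lstar]
  list(representatives = reps, no_complete = FALSE,
       min_complete_length = as.integer(lstar))
}

#' Spacer targeting density of a contig
#'
#' Distinct spacers hitting the contig per kilobase.
#'
#' @param contig_length length in nt (> 0).
#' @param hits data.frame of hits on this contig (needs `spacer_id`).
#' @return numeric, spacers per kbp.
#' @export
targeting_density <- function(contig_length, hits) {
  if (contig_length <= 0) stop("contig_length must be positive")
  length(unique(hits$spacer_id)) / (contig_length / 1000)
}
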