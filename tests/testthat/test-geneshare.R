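# ORF calling, protein clustering, gene-sharing network and communities.

test_that("constructed ORFs are called exactly, with strand closure", {
  withr::with_seed(80, {
    ct <- spacermine:::codon_table()
    nonstop <- names(ct)[ct != "*"]
    cods <- sample(nonstop, 80, replace = TRUE)
    orf <- paste0("ATG", paste(cods, collapse = ""), "TAA")
    ctg <- paste0(random_dna(300, 0.45), "TAGATAGATAGA", orf,
                  random_dna(300, 0.45))
    o <- call_orfs(ctg, min_aa = 60)
    fwd <- o[o$strand == "+" & o$start == 312, ]
    expect_equal(nrow(fwd), 1)
    expect_equal(fwd$end - fwd$start, 3 * 82)
    expect_equal(fwd$length_aa, 81)
    expect_equal(substr(fwd$protein, 1, 1), "M")
    # reverse complement: same protein, strand -, mirrored coordinates
    o2 <- call_orfs(revcomp(ctg), min_aa = 60)
    rev <- o2[o2$protein == fwd$protein, ]
    expect_equal(rev$strand, "-")
    expect_equal(rev$start, nchar(ctg) - fwd$end)
    expect_equal(rev$end, nchar(ctg) - fwd$start)
  })
})

test_that("codons containing N translate to X and never start or stop", {
  ct <- spacermine:::codon_table()
  nonstop <- names(ct)[ct != "*"]
  withr::with_seed(81, {
    cods <- sample(nonstop, 70, replace = TRUE)
    cods[30] <- "ANA"
    ctg <- paste0("TAGATAGATAGA", "ATG", paste(cods, collapse = ""), "TAA")
    o <- call_orfs(ctg, min_aa = 60)
    o <- o[o$strand == "+" & o$start == 12, ]
    expect_equal(nrow(o), 1)
    expect_equal(substr(o$protein, 31, 31), "X")
  })
})

test_that("six-frame calls match the independent translation-based oracle", {
  for (sd in 1:6) {
    withr::with_seed(400 + sd, {
      ctg <- random_dna(10000, 0.45)
      got <- call_orfs(ctg, min_aa = 60)[, c("start", "end", "strand",
                                             "protein")]
      want <- oracle_orfs(ctg, min_aa = 60)
      rownames(got) <- rownames(want) <- NULL
      expect_equal(got, want)
      # every reported ORF re-verifiable: start codon, in-frame stop,
      # no internal stop
      for (i in seq_len(nrow(got))) {
        cds <- substr(ctg, got$start[i] + 1, got$end[i])
        if (got$strand[i] == "-") cds <- revcomp(cds)
        cods <- substring(cds, seq(1, nchar(cds), 3), seq(3, nchar(cds), 3))
        expect_true(cods[1] %in% c("ATG", "GTG", "TTG"))
        aa <- spacermine:::codon_table()[cods]
        expect_identical(unname(aa[length(aa)]), "*")
        expect_false(any(aa[-length(aa)] == "*"))
      }
    })
  }
})

test_that("protein clustering joins by identity and coverage, deterministically", {
  withr::with_seed(82, {
    anc <- spacermine:::random_protein(160)
    near1 <- spacermine:::mutate_protein(anc, 1 - sqrt(0.30))
    near2 <- spacermine:::mutate_protein(anc, 1 - sqrt(0.30))
    unrel <- spacermine:::random_protein(160)
    prot <- c(p1 = near1, p2 = near2, p3 = unrel, p4 = near1)
    cl <- cluster_proteins(prot)
    rep_of <- stats::setNames(cl$representative, cl$member)
    # identical pair together; ~30% pair together; unrelated separate
    expect_equal(rep_of[["p1"]], rep_of[["p4"]])
    expect_equal(rep_of[["p1"]], rep_of[["p2"]])
    expect_false(rep_of[["p3"]] == rep_of[["p1"]])
    # member-representative pairs re-verified by the independent aligner
    for (i in which(cl$member != cl$representative)) {
      o <- oracle_protein_identity(prot[[cl$representative[i]]],
                                   prot[[cl$member[i]]])
      expect_gte(o$identity, 0.25)
      expect_gte(o$cov_a, 0.80); expect_gte(o$cov_b, 0.80)
      expect_equal(cl$identity[i], o$identity, tolerance = 1e-6)
    }
    # a ~10% identity pair stays separate
    cl2 <- cluster_proteins(c(a = spacermine:::random_protein(150),
                              b = spacermine:::random_protein(150)))
    expect_equal(length(unique(cl2$cluster_id)), 2)
    # determinism
    expect_identical(cluster_proteins(prot), cl)
  })
})

test_that("network edges obey the shared-cluster threshold and weight rule", {
  cc <- rbind(
    data.frame(contig_id = "A", cluster_id = paste0("k", 1:5)),
    data.frame(contig_id = "B", cluster_id = paste0("k", 1:5)),
    data.frame(contig_id = "C", cluster_id = paste0("k", 1:4)),
    data.frame(contig_id = "D", cluster_id = paste0("k", 10:15)))
  net <- build_network(cc, min_shared = 5)
  g <- net$graph
  expect_equal(igraph::vcount(g), 4)
  expect_equal(igraph::ecount(g), 1)            # only A-B reaches 5
  expect_equal(igraph::E(g)$shared, 5)
  expect_equal(igraph::E(g)$weight, 5)
  # duplicated cluster contributes min(count) to weight, 1 to shared
  cc2 <- rbind(
    data.frame(contig_id = "A", cluster_id = c(paste0("k", 1:4), "k5", "k5")),
    data.frame(contig_id = "B", cluster_id = c(paste0("k", 1:4), "k5", "k5")))
  net2 <- build_network(cc2, min_shared = 5)
  expect_equal(igraph::E(net2$graph)$shared, 5)
  expect_equal(igraph::E(net2$graph)$weight, 6) # 4 x 1 + min(2, 2)
})

test_that("community detection recovers planted modules and matches exact modularity", {
  # two 6-cliques joined by one edge
  el <- c()
  for (off in c(0, 6)) {
    for (i in 1:5) for (j in (i + 1):6) el <- c(el, off + i, off + j)
  }
  el <- c(el, 6, 7)
  g <- igraph::make_graph(el, directed = FALSE)
  igraph::V(g)$name <- paste0("n", 1:12)
  igraph::E(g)$weight <- 1
  gsg <- structure(list(graph = g), class = "gene_sharing_graph")
  comm <- detect_communities(gsg, seed = 1)
  expect_equal(length(unique(comm)), 2)
  expect_equal(length(unique(comm[1:6])), 1)
  expect_equal(length(unique(comm[7:12])), 1)
  # agrees with exact modularity optimization
  opt <- igraph::membership(igraph::cluster_optimal(g))
  expect_equal(adjusted_rand(comm, opt), 1)
  # edgeless graph: every node its own community
  g0 <- igraph::make_empty_graph(5, directed = FALSE)
  igraph::V(g0)$name <- paste0("m", 1:5)
  comm0 <- detect_communities(structure(list(graph = g0),
                                        class = "gene_sharing_graph"))
  expect_equal(length(unique(comm0)), 5)
})

test_that("core clusters, representatives and targeting density follow their rules", {
  prof <- rbind(
    A = c(k1 = 1, k2 = 1, k3 = 1, k4 = 0),
    B = c(k1 = 2, k2 = 1, k3 = 0, k4 = 0),
    C = c(k1 = 1, k2 = 1, k3 = 1, k4 = 0),
    D = c(k1 = 1, k2 = 0, k3 = 1, k4 = 0),
    E = c(k1 = 1, k2 = 1, k3 = 1, k4 = 1))
  core <- core_clusters(rownames(prof), prof, min_frac = 0.80)
  expect_setequal(core$cluster_id, c("k1", "k2", "k3")) # k3 in 4/5 = 0.8
  expect_equal(core$cluster_id[1], "k1")                # sorted by prevalence
  expect_equal(nrow(core_clusters(rownames(prof), prof, min_frac = 0)), 4)
  # representatives: >= 75% of the shortest complete genome
  lens <- c(A = 20000, B = 24000, C = 15000, D = 14900, E = 5000)
  comp <- data.frame(contig_id = c("A", "B"), kind = c("DTR", "ITR"),
                     repeat_length = 30L, mismatches = 0L,
                     mismatch_fraction = 0)
  rp <- select_representatives(names(lens), lens, comp)
  expect_setequal(rp$representatives, c("A", "B", "C")) # 15000 >= 0.75*20000
  expect_false(rp$no_complete)
  # no complete member: empty with flag
  rp0 <- select_representatives(c("C", "D"), lens, comp[0, ])
  expect_equal(length(rp0$representatives), 0)
  expect_true(rp0$no_complete)
  # targeting density
  h <- data.frame(spacer_id = c("s1", "s2", "s3", "s4", "s5", "s6", "s7"))
  expect_equal(targeting_density(2000, h), 3.5)
  expect_equal(targeting_density(2000, h[c(1, 1, 2), , drop = FALSE]), 1)
  expect_equal(targeting_density(2000, h[0, , drop = FALSE]), 0)
  expect_error(targeting_density(0, h), "positive")
})
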