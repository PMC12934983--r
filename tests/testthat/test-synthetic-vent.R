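# Generator contracts: determinism, controllability of planted signals,
# and self-consistency of the truth manifest with the emitted sequences.

test_that("reference repeat families are deterministic, length-bounded and separated", {
  p <- sim_params(seed = 3)
  r1 <- generate_repeat_family(6, p, seed = 7)
  r2 <- generate_repeat_family(6, p, seed = 7)
  expect_identical(r1, r2)
  expect_true(all(nchar(r1) %in% 29:31))
  # exhaustive all-pairs Hamming check on equal-length pairs
  for (i in 1:5) for (j in (i + 1):6) {
    if (nchar(r1[i]) == nchar(r1[j])) {
      expect_gte(hamming(r1[[i]], r1[[j]]), 3)
    }
  }
  one <- generate_repeat_family(1, p, seed = 1)
  expect_match(one, "^[ACGT]{29,31}$")
})

test_that("MGE family members share diverged core modules as valid ORFs", {
  p <- sim_params(seed = 5, mges_per_family = 3, n_core_modules = 8)
  fam <- generate_mge_family(p, "F01", seed = 11)
  expect_length(fam$members, 3)
  for (m in fam$members) {
    g <- m$genes
    expect_true(all((g$end - g$start) %% 3 == 0))
    for (i in seq_len(nrow(g))) {
      cds <- substr(m$sequence, g$start[i] + 1, g$end[i])
      expect_identical(substr(cds, 1, 3), "ATG")
      ncod <- nchar(cds) / 3
      cods <- substring(cds, seq(1, nchar(cds), 3), seq(3, nchar(cds), 3))
      aa <- spacermine:::codon_table()[cods]
      expect_identical(unname(aa[ncod]), "*")        # terminal stop
      expect_false(any(aa[-ncod] == "*"))            # no internal stop
      expect_gte(ncod - 1, 60)                       # >= 60 codons
    }
  }
  # every member pair shares >= 6 core ORF pairs at >= 40% aa identity
  # (independent alignment oracle on the emitted proteins)
  core_ids <- unique(fam$members[[1]]$genes$module)
  core_ids <- core_ids[grepl("_core", core_ids)]
  for (a in 1:2) for (b in (a + 1):3) {
    ga <- fam$members[[a]]$genes; gb <- fam$members[[b]]$genes
    n_ok <- 0
    for (mod in core_ids) {
      pa <- ga$protein[ga$module == mod]
      pb <- gb$protein[gb$module == mod]
      if (oracle_protein_identity(pa, pb)$identity >= 0.40) n_ok <- n_ok + 1
    }
    expect_gte(n_ok, 6)
  }
})

test_that("frac_complete_mges = 1 forces verifiable terminal repeats", {
  p <- sim_params(seed = 2, mges_per_family = 4, frac_complete_mges = 1)
  fam <- generate_mge_family(p, "F01", seed = 4)
  for (m in fam$members) {
    expect_true(m$completeness %in% c("DTR", "ITR"))
    L <- m$tr_length
    expect_gte(L, 20)
    n <- nchar(m$sequence)
    pre <- substr(m$sequence, 1, L)
    suf <- substr(m$sequence, n - L + 1, n)
    if (m$completeness == "DTR") expect_identical(pre, suf)
    else expect_identical(pre, revcomp(suf))
  }
})

test_that("zero-divergence families have byte-identical shared modules", {
  p <- sim_params(seed = 9, mges_per_family = 3,
                  core_identity_range = c(1, 1))
  fam <- generate_mge_family(p, "F01", seed = 13)
  g1 <- fam$members[[1]]$genes
  for (mod in g1$module[grepl("_core", g1$module)]) {
    cds <- vapply(fam$members, function(m) {
      g <- m$genes
      i <- which(g$module == mod)
      substr(m$sequence, g$start[i] + 1, g$end[i] - 3L) # stop codon varies
    }, "")
    expect_length(unique(substr(cds, 1, min(nchar(cds)))), 1)
  }
})

test_that("host genomes carry arrays with fencepost spacer counts and planted truth", {
  p <- sim_params(seed = 21)
  fam <- generate_mge_family(p, "F01", seed = 3)
  reps <- generate_repeat_family(4, p, seed = 5)
  h <- generate_host_genome(p, fam$members, reps, "hostX", seed = 8)
  expect_gte(nrow(h$arrays), 1)
  for (i in seq_len(nrow(h$arrays))) {
    a <- h$arrays[i, ]
    sp <- h$spacers[h$spacers$array_id == a$array_id, ]
    expect_equal(nrow(sp), a$n_repeats - 1)            # fencepost
    # array sequence structure re-verifiable from the genome
    arr_seq <- substr(h$sequence, a$start + 1, a$end)
    expect_identical(substr(arr_seq, 1, nchar(a$repeat_seq)), a$repeat_seq)
    expect_identical(substr(arr_seq, nchar(arr_seq) - nchar(a$repeat_seq) + 1,
                            nchar(arr_seq)), a$repeat_seq)
    # at least 70% of spacers are MGE-derived
    expect_gte(mean(sp$origin == "mge"), 0.7)
  }
  # planted mismatches re-verifiable against MGE sequences
  mge_by_id <- stats::setNames(lapply(fam$members, `[[`, "sequence"),
                               vapply(fam$members, `[[`, "", "mge_id"))
  sp <- h$spacers[h$spacers$origin == "mge", ]
  for (i in seq_len(nrow(sp))) {
    w <- substr(mge_by_id[[sp$mge_id[i]]], sp$mge_start[i] + 1, sp$mge_end[i])
    proto <- if (sp$strand[i] == "+") w else revcomp(w)
    expect_equal(hamming(proto, sp$sequence[i]), sp$mismatches[i])
  }
  # determinism
  h2 <- generate_host_genome(p, fam$members, reps, "hostX", seed = 8)
  expect_identical(h$sequence, h2$sequence)
})

test_that("identity range (1,1) plants only exact protospacers", {
  p <- sim_params(seed = 6, protospacer_identity_range = c(1, 1),
                  frac_mge_derived = 1)
  fam <- generate_mge_family(p, "F01", seed = 2)
  reps <- generate_repeat_family(3, p, seed = 2)
  h <- generate_host_genome(p, fam$members, reps, "h", seed = 2)
  expect_true(all(h$spacers$origin == "mge"))
  expect_true(all(h$spacers$mismatches == 0))
})

test_that("planted protospacer identities respect the requested range exactly", {
  p <- sim_params(seed = 31, protospacer_identity_range = c(0.92, 0.97))
  fam <- generate_mge_family(p, "F01", seed = 3)
  reps <- generate_repeat_family(3, p, seed = 3)
  h <- generate_host_genome(p, fam$members, reps, "h", seed = 3)
  sp <- h$spacers[h$spacers$origin == "mge", ]
  ident <- (sp$length - sp$mismatches) / sp$length
  expect_true(all(ident >= 0.92 - 1e-12 & ident <= 0.97 + 1e-12))
})

test_that("metagenome tiles sources without gaps and manifests decoys honestly", {
  p <- sim_params(seed = 17, n_decoys = 40)
  sim <- simulate_vent_metagenome(p)
  m <- sim$manifest$contigs
  expect_false(any(duplicated(m$contig_id)))
  expect_setequal(unique(m$origin), c("host", "mge", "decoy"))
  # coordinate coverage: fragments of each source tile [0, len) exactly
  for (src in unique(m$source_id[m$origin != "decoy"])) {
    fr <- m[m$source_id == src, ]
    fr <- fr[order(fr$source_start), ]
    expect_equal(fr$source_start[1], 0)
    if (nrow(fr) > 1) {
      expect_equal(fr$source_start[-1], fr$source_end[-nrow(fr)])
    }
  }
  # emitted sequences equal the claimed source windows
  src_seqs <- c(stats::setNames(lapply(sim$mge_pool, `[[`, "sequence"),
                                vapply(sim$mge_pool, `[[`, "", "mge_id")),
                as.list(sim$host_seqs))
  nonde <- m[m$origin != "decoy", ]
  for (i in seq_len(nrow(nonde))) {
    expect_identical(
      sim$contigs[[nonde$contig_id[i]]],
      substr(src_seqs[[nonde$source_id[i]]], nonde$source_start[i] + 1,
             nonde$source_end[i]))
  }
  # decoys contain zero planted protospacers (brute-force scan)
  decoys <- sim$contigs[m$contig_id[m$origin == "decoy"]]
  spacers <- sim$manifest$spacers
  dec_cat <- data.frame(spacer_id = paste0("s", seq_len(nrow(spacers))),
                        sequence = spacers$sequence)
  dec_hits <- oracle_search(dec_cat, decoys, min_identity = 0.90)
  expect_equal(nrow(dec_hits), 0)
})

test_that("a single unfragmented complete MGE round-trips through the manifest", {
  p <- sim_params(seed = 8, n_hosts = 1, n_mge_families = 1,
                  mges_per_family = 1, frac_complete_mges = 1,
                  n_decoys = 0, contig_fragmentation = 100000L)
  sim <- simulate_vent_metagenome(p)
  m <- sim$manifest$contigs
  mge_rows <- m[m$origin == "mge", ]
  expect_equal(nrow(mge_rows), 1)
  expect_equal(mge_rows$source_start, 0)
  expect_equal(mge_rows$source_end, nchar(sim$mge_pool[[1]]$sequence))
})

test_that("simulation output is byte-identical under a fixed seed", {
  p <- sim_params(seed = 12, n_decoys = 20)
  s1 <- simulate_vent_metagenome(p)
  s2 <- simulate_vent_metagenome(p)
  expect_identical(s1$contigs, s2$contigs)
  expect_identical(s1$manifest, s2$manifest)
  s3 <- simulate_vent_metagenome(sim_params(seed = 13, n_decoys = 20))
  expect_false(identical(s1$contigs, s3$contigs))
})
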