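# Array detection, reference anchoring and the spacer catalog.

test_that("a planted array of identical repeats is recovered with exact boundaries", {
  withr::with_seed(42, {
    pg <- plant_array_genome(len = 50000, n_arrays = 1,
                             n_inst_range = c(4, 4))
    a <- detect_arrays(pg$genome)
    expect_length(a, 1)
    tr <- pg$truth[[1]]
    expect_equal(a[[1]]$start, tr$start)
    expect_equal(a[[1]]$end, tr$end)
    expect_identical(a[[1]]$repeat_consensus, tr$repeat_seq)
    expect_identical(a[[1]]$spacers$sequence, tr$spacers)
    expect_equal(nrow(a[[1]]$repeat_instances), tr$n_inst)
  })
})

test_that("repeats outside the 29-31 nt window are rejected", {
  withr::with_seed(5, {
    bg <- random_dna(20000, 0.45)
    r28 <- random_dna(28, 0.5)
    sps <- vapply(1:4, function(i) random_dna(38, 0.45), "")
    arr <- paste(c(rbind(rep(r28, 4), sps), r28), collapse = "")
    g <- paste0(substr(bg, 1, 10000), arr, substr(bg, 10001, 20000))
    expect_length(detect_arrays(g), 0)
    # same spacing with a 29-nt repeat is accepted
    r29 <- random_dna(29, 0.5)
    arr2 <- paste(c(rbind(rep(r29, 4), sps), r29), collapse = "")
    g2 <- paste0(substr(bg, 1, 10000), arr2, substr(bg, 10001, 20000))
    expect_length(detect_arrays(g2), 1)
  })
})

test_that("random sequence yields no arrays", {
  withr::with_seed(1, {
    expect_length(detect_arrays(random_dna(100000, 0.45)), 0)
  })
})

test_that("a diverged flanking repeat instance is walked in", {
  withr::with_seed(33, {
    bg <- random_dna(30000, 0.45)
    r <- random_dna(30, 0.5)
    r_div <- spacermine:::mutate_positions(r, 2) # terminal instance, 2 mm
    sps <- vapply(1:4, function(i) random_dna(40, 0.45), "")
    arr <- paste0(r, sps[1], r, sps[2], r, sps[3], r, sps[4], r_div)
    g <- paste0(substr(bg, 1, 15000), arr, substr(bg, 15001, 30000))
    a <- detect_arrays(g)
    expect_length(a, 1)
    expect_equal(nrow(a[[1]]$repeat_instances), 5)
    expect_equal(sum(a[[1]]$repeat_instances$mismatches), 2)
    expect_identical(a[[1]]$repeat_consensus, r)
    expect_equal(nrow(a[[1]]$spacers), 4)
  })
})

test_that("detection commutes with reverse complement", {
  for (sd in 1:6) {
    withr::with_seed(100 + sd, {
      pg <- plant_array_genome(len = 30000, n_arrays = 2,
                               n_inst_range = c(3, 6))
      n <- nchar(pg$genome)
      fwd <- detect_arrays(pg$genome)
      rev <- detect_arrays(revcomp(pg$genome))
      expect_length(rev, length(fwd))
      fwd_spans <- vapply(fwd, function(a) paste(a$start, a$end), "")
      rev_spans <- vapply(rev, function(a) paste(n - a$end, n - a$start), "")
      expect_setequal(rev_spans, fwd_spans)
      rc_cons <- vapply(rev, function(a) revcomp(a$repeat_consensus), "")
      expect_setequal(rc_cons, vapply(fwd, `[[`, "", "repeat_consensus"))
    })
  }
})

test_that("consensus repeat takes the column majority with alphabetical ties", {
  arr <- structure(list(repeat_instances = data.frame(
    start = c(0L, 60L, 120L),
    sequence = c("ACGTA", "ACGTA", "ACGTA"), mismatches = 0L)),
    class = "crispr_array")
  expect_identical(consensus_repeat(arr), "ACGTA")
  arr$repeat_instances <- data.frame(
    start = c(0L, 60L, 120L),
    sequence = c("ACGTA", "ACGTA", "ACCTA"), mismatches = 0L)
  expect_identical(consensus_repeat(arr), "ACGTA")  # majority forced
  arr$repeat_instances <- data.frame(
    start = c(0L, 60L), sequence = c("ACGTA", "ACCTA"), mismatches = 0L)
  expect_identical(consensus_repeat(arr), "ACCTA")  # C < G tie rule
})

test_that("repeat anchoring follows the <=1 mismatch either-strand contract", {
  withr::with_seed(9, {
    refs <- c(r1 = random_dna(30, 0.5), r2 = random_dna(30, 0.5),
              r3 = random_dna(29, 0.5))
    # exact forward
    m <- match_repeat_to_reference(refs[["r1"]], refs)
    expect_equal(m[c("ref_id", "orientation", "distance")],
                 list(ref_id = "r1", orientation = "forward", distance = 0L))
    # one substitution
    m1 <- match_repeat_to_reference(
      spacermine:::mutate_positions(refs[["r2"]], 1), refs)
    expect_equal(m1$ref_id, "r2"); expect_equal(m1$distance, 1L)
    # reverse complement with one substitution
    m2 <- match_repeat_to_reference(
      spacermine:::mutate_positions(revcomp(refs[["r3"]]), 1), refs)
    expect_equal(m2$ref_id, "r3")
    expect_equal(m2$orientation, "reverse")
    # two substitutions -> no match
    expect_null(match_repeat_to_reference(
      spacermine:::mutate_positions(refs[["r1"]], 2), refs))
    # length mismatch to every reference -> no match
    expect_null(match_repeat_to_reference(random_dna(31, 0.5),
                                          refs[c("r1", "r2")] ))
  })
})

test_that("anchoring agrees with exhaustive Hamming computation on random cases", {
  withr::with_seed(77, {
    for (case in 1:300) {
      refs <- vapply(1:4, function(i) random_dna(sample(29:31, 1), 0.5), "")
      names(refs) <- paste0("r", 1:4)
      base <- refs[[sample.int(4, 1)]]
      q <- spacermine:::mutate_positions(base, sample(0:3, 1))
      if (runif(1) < 0.5) q <- revcomp(q)
      got <- match_repeat_to_reference(q, refs)
      # oracle: plain exhaustive minimum over refs x orientations
      best_d <- Inf; best_i <- NA
      for (i in seq_along(refs)) {
        if (nchar(refs[[i]]) != nchar(q)) next
        d <- min(hamming(q, refs[[i]]), hamming(revcomp(q), refs[[i]]))
        if (d < best_d) { best_d <- d; best_i <- i }
      }
      if (best_d <= 1) {
        expect_equal(got$ref_id, names(refs)[best_i])
        expect_equal(got$distance, as.integer(best_d))
      } else {
        expect_null(got)
      }
    }
  })
})

test_that("spacer extraction honors anchoring, provenance and the N rule", {
  withr::with_seed(50, {
    pg <- plant_array_genome(len = 20000, n_arrays = 1,
                             n_inst_range = c(4, 4))
    arrays <- detect_arrays(pg$genome)
    arrays[[1]]$contig_id <- "c1"
    # unanchored metagenomic array contributes nothing
    expect_equal(nrow(extract_spacers(arrays, "metagenome")), 0)
    # isolate-genome arrays are kept regardless
    iso <- extract_spacers(arrays, "isolate_genome")
    expect_equal(nrow(iso), 3)
    expect_identical(iso$sequence, pg$truth[[1]]$spacers)
    # anchored metagenomic array contributes spacers
    anch <- anchor_arrays(arrays, pg$repeats)
    expect_true(anch[[1]]$anchored)
    expect_equal(nrow(extract_spacers(anch, "metagenome")), 3)
    # spacers containing N are dropped with a message
    arrN <- anch
    arrN[[1]]$spacers$sequence[2] <- sub("^.", "N",
                                         arrN[[1]]$spacers$sequence[2])
    expect_message(spN <- extract_spacers(arrN, "metagenome"), "dropped")
    expect_equal(nrow(spN), 2)
    expect_equal(attr(spN, "n_dropped"), 1L)
  })
})

test_that("spacer dedup is exact, orientation-sensitive and provenance-merging", {
  sp <- data.frame(
    sequence = c("ACGTACGTACGTACGTACGTA", "ACGTACGTACGTACGTACGTA",
                 revcomp("ACGTACGTACGTACGTACGTA"), "TTTTACGTACGTACGTACGTG"),
    length = 21L, contig_id = c("a", "b", "c", "d"),
    array_start = c(0L, 5L, 9L, 2L), ordinal = 1L,
    origin_class = c("metagenome", "isolate_genome", "metagenome",
                     "metagenome"), stringsAsFactors = FALSE)
  res <- dedup_spacers(sp)
  expect_equal(nrow(res$catalog), 3)            # rc stays distinct
  expect_equal(res$catalog$n_sources[1], 2)     # provenance merged
  expect_equal(res$catalog$origin_classes[1], "isolate_genome,metagenome")
  expect_identical(res$catalog$spacer_id, sprintf("sp%05d", 1:3))
  # empty input -> empty catalog
  empty <- dedup_spacers(sp[0, ])
  expect_equal(nrow(empty$catalog), 0)
})

test_that("every planted spacer of anchored arrays reaches the catalog", {
  for (sd in 1:5) {
    withr::with_seed(200 + sd, {
      pg <- plant_array_genome(len = 40000, n_arrays = 2,
                               variant = TRUE, n_inst_range = c(3, 7))
      arrays <- anchor_arrays(detect_arrays(pg$genome), pg$repeats)
      expect_true(all(vapply(arrays, `[[`, TRUE, "anchored")))
      cat <- dedup_spacers(extract_spacers(arrays, "metagenome"))$catalog
      planted <- unlist(lapply(pg$truth, `[[`, "spacers"))
      expect_true(all(planted %in% cat$sequence))
    })
  }
})
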