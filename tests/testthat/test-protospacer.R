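# Seeded protospacer search: indexing, pigeonhole guarantee, strand
# closure and the identity threshold boundary.

test_that("the k-mer index posts every in-bounds window", {
  idx <- index_contigs(c(c1 = "ACGTACGT"), k = 4)
  expect_equal(sum(lengths(idx$index)), 5)        # L - k + 1
  expect_equal(unname(idx$index[["ACGT"]]), c(1L, 5L)) # duplicate -> 2 postings
  # boundary-spanning k-mers excluded
  idx2 <- index_contigs(c(a = "ACGTACG", b = "TTTTTTT"), k = 4)
  expect_equal(sum(lengths(idx2$index)), 4 + 4)
  # contig shorter than k unindexed, logged
  expect_message(index_contigs(c(a = "ACGTACGT", b = "AC"), k = 4),
                 "unindexed")
})

test_that("the pigeonhole bound is enforced", {
  # Lmin = 30 at 10% mismatches -> m = 3 -> k must be <= 7
  expect_equal(30 %/% (floor(0.1 * 30) + 1), 7)
  withr::with_seed(2, {
    ctg <- c(c1 = random_dna(2000, 0.5))
    idx8 <- index_contigs(ctg, k = 8)
    sp <- c(s1 = random_dna(30, 0.5))
    expect_error(search_spacers(sp, idx8), "pigeonhole")
    idx7 <- index_contigs(ctg, k = 7)
    expect_silent(search_spacers(sp, idx7))
  })
})

test_that("planted matches are found exactly at the identity threshold", {
  withr::with_seed(14, {
    bg <- random_dna(30000, 0.45)
    sp <- random_dna(37, 0.5)
    p3 <- spacermine:::mutate_positions(sp, 3)  # 34/37 = 0.919 -> hit
    p4 <- spacermine:::mutate_positions(sp, 4)  # 33/37 = 0.892 -> no hit
    ctg <- paste0(substr(bg, 1, 5000), sp,
                  substr(bg, 5038, 12000), p3,
                  substr(bg, 12038, 20000), revcomp(sp),
                  substr(bg, 20038, 25000), p4,
                  substr(bg, 25038, 30000))
    h <- search_spacers(c(spA = sp), index_contigs(c(c1 = ctg)))
    expect_equal(nrow(h), 3)
    expect_equal(h$start, c(5000, 12000, 20000))
    expect_equal(h$strand, c("+", "+", "-"))
    expect_equal(h$mismatches, c(0L, 3L, 0L))
    expect_equal(h$identity[2], 34 / 37)
    # identity arithmetic holds exactly
    expect_equal(h$identity * 37 + h$mismatches, rep(37, 3))
    # end - start equals spacer length
    expect_true(all(h$end - h$start == 37))
  })
})

test_that("search equals the brute-force both-strand scan on random sets", {
  for (sd in 1:3) {
    withr::with_seed(300 + sd, {
      contigs <- stats::setNames(
        lapply(1:4, function(i) random_dna(15000, 0.45)),
        paste0("c", 1:4))
      contigs <- unlist(contigs)
      # spacers: some random, some planted with controlled mismatches
      spacers <- character(0)
      for (i in 1:6) spacers <- c(spacers, random_dna(sample(30:50, 1), 0.5))
      for (i in 1:6) {
        cid <- sample(names(contigs), 1)
        L <- sample(30:50, 1)
        s0 <- sample(nchar(contigs[[cid]]) - L, 1)
        w <- substr(contigs[[cid]], s0, s0 + L - 1)
        m <- sample(0:(floor(0.1 * L) + 1), 1)
        sp <- spacermine:::mutate_positions(
          if (runif(1) < 0.5) w else revcomp(w), m)
        spacers <- c(spacers, sp)
      }
      cat_df <- data.frame(spacer_id = sprintf("sp%02d", seq_along(spacers)),
                           sequence = spacers, stringsAsFactors = FALSE)
      got <- search_spacers(cat_df, index_contigs(contigs))
      attr(got, "n_skipped") <- NULL
      want <- oracle_search(cat_df, contigs)
      expect_equal(got, want)
    })
  }
})

test_that("array-overlapping hits are masked with half-open boundaries", {
  hits <- data.frame(
    spacer_id = c("s1", "s2", "s3", "s4"),
    contig_id = c("c1", "c1", "c1", "c2"),
    start = c(100L, 200L, 260L, 100L), end = c(137L, 237L, 297L, 137L),
    strand = "+", mismatches = 0L, identity = 1,
    stringsAsFactors = FALSE)
  arr <- structure(list(contig_id = "c1", start = 120L, end = 260L),
                   class = "crispr_array")
  out <- mask_array_hits(hits, list(arr))
  # s1 overlaps (100-137 vs 120-260): removed; s2 inside: removed;
  # s3 starts exactly at the half-open end 260: retained; c2 untouched
  expect_equal(out$spacer_id, c("s3", "s4"))
  expect_equal(attr(out, "n_masked"), 2L)
  # no arrays -> unchanged
  out2 <- mask_array_hits(hits, list())
  expect_equal(nrow(out2), 4)
})

test_that("spacers shorter than k are skipped with a log", {
  withr::with_seed(4, {
    idx <- index_contigs(c(c1 = random_dna(1000, 0.5)), k = 7)
    expect_message(
      h <- search_spacers(c(tiny = "ACGT"), idx, min_identity = 1),
      "skipped")
    expect_equal(nrow(h), 0)
    expect_equal(attr(h, "n_skipped"), 1L)
  })
})
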