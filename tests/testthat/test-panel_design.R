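test_that("probe windows center on the variant when unconstrained", {
  g <- test_genome(1000, seed = 5, gc = 0.5)
  w <- design_probe_window("c1", 500, g)
  expect_true(w$accepted)
  expect_equal(w$offset, 0)
  expect_equal(w$end0 - w$start0, 110L)
  expect_equal(w$start0, 500 - 1 - 55)
  # GC verified by direct computation over the slice
  slice <- panelsnp:::genome_slice(g, "c1", w$start0, w$end0)
  expect_equal(w$gc, 100 * lengths(regmatches(
    slice, gregexpr("[GC]", slice))) / 110)
  expect_true(w$gc >= 30 && w$gc <= 80)
})

test_that("probe windows shift away from a GC desert, nearer shifts first", {
  # SSR-free AT-only block (period-10 tile, no motif of length <= 6 repeats
  # enough) under the centered window, GC-balanced sequence after it
  left <- strrep("ATTAATATTA", 40)                  # 400 bp, gc 0
  set.seed(8)
  right <- random_seq(400, gc = 0.5)
  g <- Biostrings::DNAStringSet(paste0(left, right))
  names(g) <- "c1"
  pos <- 390                          # centered window is mostly the AT block
  w <- design_probe_window("c1", pos, g)
  expect_true(w$accepted)
  expect_true(w$offset > 0)                         # had to move right
  slice <- panelsnp:::genome_slice(g, "c1", w$start0, w$end0)
  gc_direct <- 100 * sum(strsplit(slice, "")[[1]] %in% c("G", "C")) / 110
  expect_equal(w$gc, gc_direct)
  expect_true(w$gc >= 30)
  # every window nearer the center must fail a constraint (re-derived
  # directly: the search is nearest-shift-first)
  for (sh in seq(0, w$offset - 1)) {
    for (sgn in c(-1, 1)) {
      s0 <- pos - 1 - 55 + sgn * sh
      sl <- panelsnp:::genome_slice(g, "c1", s0, s0 + 110)
      gc_sh <- 100 * sum(strsplit(sl, "")[[1]] %in% c("G", "C")) / 110
      expect_true(gc_sh < 30 || gc_sh > 80 || nrow(detect_ssr(sl)) > 0)
    }
  }
})

test_that("windows clip at contig edges with the variant kept inside", {
  g <- test_genome(500, seed = 6)
  w <- design_probe_window("c1", 30, g)
  expect_true(w$accepted)
  expect_equal(w$start0, 0L)
  expect_true(w$offset != 0)
  expect_true(30 - 1 >= w$start0 && 30 - 1 < w$end0)

  short <- Biostrings::DNAStringSet(strrep("ACGT", 10))
  names(short) <- "tiny"
  expect_equal(design_probe_window("tiny", 20, short)$reason,
               "contig_too_short")
})

test_that("single-copy test flags planted duplications, passes unique loci", {
  sim <- simulate_genome(
    c(c1 = 300000L, c2 = 150000L), gc_target = 0.45,
    duplications = data.frame(contig = "c1", src_start = 50000L,
                              length = 5000L, dest_contig = "c2",
                              dest_start = 60000L),
    seed = 31)
  g <- sim$genome
  expect_false(single_copy_check("c1", 52500, g))   # inside the source copy
  expect_false(single_copy_check("c2", 62500, g))   # inside the dest copy
  expect_true(single_copy_check("c1", 150000, g))   # 100 kb away
  expect_true(single_copy_check("c1", 40000, g))    # just outside
})

test_that("gap finding reports adjacent, leading and trailing intervals", {
  lens <- c(c1 = 250000L)
  sites <- data.frame(contig = "c1", pos = c(10000L, 50000L, 200000L))
  gaps <- find_gaps(sites, lens)
  expect_equal(nrow(gaps), 1)
  expect_equal(gaps$start, 50000L)
  expect_equal(gaps$end, 200000L)
  expect_equal(gaps$span, 150000L)

  empty <- find_gaps(sites[0, ], c(c1 = 100000L))
  expect_equal(empty$span, 99999L)

  dense <- data.frame(contig = "c1", pos = seq(1000L, 241000L, by = 60000L))
  expect_equal(nrow(find_gaps(dense, lens)), 0)
})

test_that("gap filling follows the greedy midpoint rule", {
  gaps <- data.frame(contig = "c1", start = 50000L, end = 200000L,
                     span = 150000L)
  pool <- data.frame(id = "m", contig = "c1", pos = 125000L)
  res <- fill_gaps(gaps, pool)
  expect_equal(res$added$id, "m")
  # both 75 kb sub-gaps remain >= 70 kb and are residual (pool exhausted)
  expect_equal(res$residual$span, c(75000L, 75000L))

  res2 <- fill_gaps(gaps, pool[0, ])
  expect_equal(nrow(res2$added), 0)
  expect_equal(res2$residual$span, 150000L)

  # nearest-to-midpoint with tie broken toward the lower coordinate
  pool3 <- data.frame(id = c("lo", "hi"), contig = "c1",
                      pos = c(120000L, 130000L))
  res3 <- fill_gaps(gaps, pool3)
  expect_equal(res3$added$id[1], "lo")
})

test_that("a dense pool drives the max adjacent spacing under threshold", {
  withr::with_seed(17, {
    pool <- data.frame(id = sprintf("b%04d", 1:1000), contig = "c1",
                       pos = sort(sample.int(3000000L, 1000)))
  })
  sites <- data.frame(contig = "c1", pos = c(1L, 3000000L))
  gaps <- find_gaps(sites, c(c1 = 3000000L), threshold = 70000)
  res <- fill_gaps(gaps, pool, threshold = 70000)
  all_pos <- sort(c(sites$pos, res$added$pos))
  expect_lt(max(diff(all_pos)), 70000)
  expect_equal(nrow(res$residual), 0)
  # filling never increases the max adjacent distance
  expect_lte(max(diff(all_pos)), max(diff(sites$pos)))
})

test_that("panel construction conserves roles and flags bad foreground", {
  sim <- simulate_genome(
    c(c1 = 400000L), gc_target = 0.45,
    ssrs = data.frame(contig = "c1", pos = 90000L, motif = "AT",
                      copies = 30L),
    seed = 41)
  g <- sim$genome
  catalog <- data.frame(
    trait = c("fruit_shape", "fruit_shape", "fruit_shape", "spice"),
    contig = "c1", pos = c(30000L, 85000L, 90010L, 140000L),
    ref = "A", alt = "G",
    role = c("foreground", "foreground", "foreground",
             "functional_segment"))
  withr::with_seed(3, {
    pool <- data.frame(id = sprintf("b%03d", 1:300), contig = "c1",
                       pos = sort(sample(1000:399000, 300)),
                       ref = "C", alt = "T")
  })
  cfg <- panel_config(check_single_copy = FALSE)
  panel <- build_panel(catalog, pool, g, cfg)

  cb <- panel$counts_by_role
  expect_equal(cb$foreground + cb$functional_segment + cb$background,
               cb$total)
  expect_equal(cb$foreground, 3L)            # never dropped
  expect_equal(cb$functional_segment, 1L)
  # the site inside the planted 60 bp SSR cannot get a window -> flagged
  fg_bad <- panel$probes[panel$probes$pos == 90010L, ]
  expect_true(fg_bad$flagged)
  expect_false(fg_bad$window_ok)
  expect_equal(fg_bad$role, "foreground")
  # accepted probes satisfy all window invariants
  acc <- panel$probes[panel$probes$window_ok, ]
  expect_true(all(acc$end0 - acc$start0 == 110))
  expect_true(all(acc$gc >= 30 & acc$gc <= 80))
  expect_true(all(acc$pos - 1 >= acc$start0 & acc$pos - 1 < acc$end0))
  # spacing is computed over unflagged sites and gaps shrink under 70 kb
  expect_true(all(panel$spacing$max_spacing < 70000, na.rm = TRUE))
  expect_equal(nrow(panel$residual_gaps), 0)
})

test_that("panel outputs are byte-identical across repeated runs", {
  g <- test_genome(2e5, seed = 51)
  catalog <- data.frame(trait = "t", contig = "c1", pos = 100000L,
                        ref = "A", alt = "T")
  withr::with_seed(4, {
    pool <- data.frame(id = sprintf("b%03d", 1:150), contig = "c1",
                       pos = sort(sample(200:199800, 150)),
                       ref = "C", alt = "T")
  })
  cfg <- panel_config(check_single_copy = FALSE)
  files <- replicate(2, {
    p <- build_panel(catalog, pool, g, cfg)
    bed <- tempfile(fileext = ".bed")
    fa <- tempfile(fileext = ".fa")
    write_probe_bed(p, bed)
    write_probe_fasta(p, g, fa)
    c(bed = bed, fa = fa)
  }, simplify = FALSE)
  expect_identical(readLines(files[[1]]["bed"]), readLines(files[[2]]["bed"]))
  expect_identical(readLines(files[[1]]["fa"]), readLines(files[[2]]["fa"]))
  file.remove(unlist(files))
})

test_that("trait catalog summaries count unique (trait, site) pairs", {
  cat1 <- data.frame(trait = c("a", "a", "b"), id = c("s1", "s2", "s1"))
  s <- summarize_trait_catalog(cat1)
  expect_equal(s$total, 3)
  expect_equal(s$counts$n_sites[s$counts$trait == "a"], 2L)

  expect_warning(s2 <- summarize_trait_catalog(
    data.frame(trait = c("a", "a"), id = c("s1", "s1"))), "duplicate")
  expect_equal(s2$total, 1)

  empty <- summarize_trait_catalog(data.frame(trait = character(0),
                                              id = character(0)))
  expect_equal(empty$total, 0)
})
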