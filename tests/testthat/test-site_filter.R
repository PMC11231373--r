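test_that("site statistics match hand-enumerated allele counts", {
  # 10 samples: 7 hom-ref, 2 het, 1 hom-alt
  gm <- gm_from_dosage(matrix(c(rep(0L, 7), 1L, 1L, 2L), nrow = 1))
  st <- compute_site_stats(gm)
  expect_equal(st$maf, 0.2)          # p = (2 + 2) / 20
  expect_equal(st$het_rate, 0.2)
  expect_equal(st$missing_rate, 0)

  gm2 <- gm_from_dosage(matrix(0L, 1, 10))
  expect_equal(compute_site_stats(gm2)$maf, 0)

  # 4 samples: 2 missing, 1 het, 1 hom-alt -> p = 3/4, maf = 1/4
  gm3 <- gm_from_dosage(matrix(c(NA, NA, 1L, 2L), nrow = 1))
  st3 <- compute_site_stats(gm3)
  expect_equal(st3$missing_rate, 0.5)
  expect_equal(st3$maf, 0.25)

  gm4 <- gm_from_dosage(matrix(NA_integer_, 1, 4))
  expect_false(compute_site_stats(gm4)$defined)
})

test_that("hard filters use the stated boundary semantics", {
  mk <- function(maf, het, miss, depth) {
    data.frame(id = "s", n_nonmissing = 10, maf = maf, missing_rate = miss,
               het_rate = het, mean_depth = depth, defined = TRUE)
  }
  expect_equal(apply_hard_filters(mk(0.04, 0, 0, 50))$reasons, "maf")
  expect_equal(apply_hard_filters(mk(0.2, 0.06, 0, 50))$reasons, "het")
  # boundaries: depth 10 exactly passes; maf 0.05, missing 0.20, het 0.05 fail
  expect_true(apply_hard_filters(mk(0.2, 0, 0, 10))$pass)
  expect_equal(apply_hard_filters(mk(0.05, 0, 0, 50))$reasons, "maf")
  expect_equal(apply_hard_filters(mk(0.2, 0, 0.20, 50))$reasons, "missing")
  expect_equal(apply_hard_filters(mk(0.2, 0.05, 0, 50))$reasons, "het")
  # a site with no data fails outright
  und <- mk(NA, NA, 1, NA)
  und$defined <- FALSE
  expect_equal(apply_hard_filters(und)$reasons, "no_data")
  # multiple violations are all reported
  expect_equal(apply_hard_filters(mk(0.01, 0.5, 0.9, 2))$reasons,
               "depth,maf,missing,het")
})

test_that("pairwise r2 equals an independent Pearson computation", {
  a <- c(0L, 0L, 1L, 1L, 2L, 2L)
  b <- c(0L, 1L, 0L, 1L, 2L, 2L)
  gm <- gm_from_dosage(rbind(a, b))
  ids <- gm$sites$id
  # independent oracle: explicit covariance formula
  ora <- (mean(a * b) - mean(a) * mean(b))^2 /
    (mean(a^2) - mean(a)^2) / (mean(b^2) - mean(b)^2)
  expect_equal(pairwise_r2(gm, ids[1], ids[2]), ora)
  expect_equal(pairwise_r2(gm, ids[1], ids[1]), 1)

  mono <- gm_from_dosage(rbind(a, rep(1L, 6)))
  expect_true(is.na(pairwise_r2(mono, mono$sites$id[1], mono$sites$id[2])))
  # fewer than 2 shared calls -> undefined
  sparse <- gm_from_dosage(rbind(c(0L, NA, NA), c(NA, 1L, 2L)))
  expect_true(is.na(pairwise_r2(sparse, sparse$sites$id[1],
                                sparse$sites$id[2])))
})

test_that("LD pruning keeps the higher-MAF member of a correlated pair", {
  # site1 maf 0.3, site2 maf 0.2, perfectly correlated pattern
  a <- c(rep(0L, 14), rep(2L, 6))                 # p = 0.3
  b <- c(rep(0L, 14), rep(2L, 4), rep(0L, 2))     # p = 0.2
  # make b a deterministic function of a on the first 18 samples only
  b <- a
  b[19:20] <- 0L                                   # maf drops to 0.2
  gm <- gm_from_dosage(rbind(a, b))
  expect_equal(ld_prune(gm), gm$sites$id[1])

  # independent sites all kept
  set.seed(42)
  d <- matrix(rbinom(5 * 200, 2, 0.4), nrow = 5)
  gm2 <- gm_from_dosage(d)
  r2max <- max(cor(t(d))[upper.tri(diag(5))]^2)
  skip_if(r2max >= 0.4)  # construction guard, not expected to trigger
  expect_equal(ld_prune(gm2), gm2$sites$id)
})

test_that("windowed pruner matches the brute-force single-window oracle", {
  g <- test_genome(1e5, seed = 2)
  for (seed in 1:10) {
    pop <- simulate_population(g, n_samples = 60, n_sites = 40,
                               maf = c(0.1, 0.2, 0.3, 0.4),
                               ld_block_size = 4, ld_r2_target = 0.8,
                               seed = seed)
    kept <- ld_prune(pop$gm, max_r2 = 0.4, window_sites = 40)
    expect_equal(kept, brute_ld_prune(pop$gm, max_r2 = 0.4))
  }
})

test_that("SSR detection handles thresholds, phase and primitive motifs", {
  hit <- detect_ssr("ACACACACAC")
  expect_equal(hit$motif, "AC")
  expect_equal(hit$copies, 5L)
  expect_equal(c(hit$start, hit$end), c(0L, 10L))

  expect_equal(nrow(detect_ssr("AAAAAAA")), 0)       # mono needs 8 copies
  expect_equal(nrow(detect_ssr(strrep("A", 8))), 1)

  # planted TTG x 4 inside a repeat-free 110-mer
  flank_l <- strrep("ACGGTACGTA", 5)
  flank_r <- strrep("CATGCATCGA", 4) ; flank_r <- substr(flank_r, 1, 48)
  seqv <- paste0(flank_l, strrep("TTG", 4), flank_r)
  hit2 <- detect_ssr(seqv)
  expect_equal(hit2$motif, "GTT")                    # canonical rotation
  expect_true(hit2$start <= 50 && hit2$end >= 62)
})

test_that("SSR detection agrees with the naive scanner on random 110-mers", {
  set.seed(7)
  for (i in 1:150) {
    s <- random_seq(110, gc = runif(1, 0.3, 0.7))
    expect_equal(detect_ssr(s), naive_ssr_scan(s), info = s)
  }
})

test_that("allele pairs classify by strand ambiguity; indels are safe", {
  expect_equal(classify_allele_pair("A", "T"),
               list(class = "strand_ambiguous", probes_required = 2L))
  expect_equal(classify_allele_pair("C", "G")$probes_required, 2L)
  expect_equal(classify_allele_pair("A", "G"),
               list(class = "strand_safe", probes_required = 1L))
  expect_equal(classify_allele_pair("AT", "A")$probes_required, 1L)
})

test_that("core-site selection rejects each engineered offender correctly", {
  g0 <- simulate_genome(
    c(c1 = 10000L), gc_target = 0.5,
    ssrs = data.frame(contig = "c1", pos = 3000L, motif = "AG",
                      copies = 12L),
    seed = 20)
  genome <- g0$genome
  # plant an N patch around position 5000 for the ambiguous-base offender
  chars <- strsplit(as.character(genome[["c1"]]), "")[[1]]
  chars[4990:5010] <- "N"
  genome <- Biostrings::DNAStringSet(paste(chars, collapse = ""))
  names(genome) <- "c1"

  n <- 40
  good <- function() c(rep(0L, 30), rep(2L, 10))     # maf 0.25, het 0
  calls <- rbind(
    depth_fail   = good(),
    maf_fail     = c(rep(0L, 39), 2L),               # maf 0.025
    missing_fail = c(rep(NA_integer_, 10), rep(0L, 20), rep(2L, 10)),
    het_fail     = c(rep(0L, 28), rep(1L, 4), rep(2L, 8)),  # het 0.10
    ssr_fail     = good(),
    n_fail       = good())
  depth <- matrix(50, nrow(calls), n)
  depth[1, ] <- 5
  pos <- c(1000L, 1500L, 2000L, 2500L, 3010L, 5000L)
  gm <- genotype_matrix(
    data.frame(contig = "c1", pos = pos, ref = "A", alt = "G"),
    sprintf("s%02d", 1:n), calls, depth)

  res <- select_core_sites(gm, genome)
  expect_equal(nrow(res$core), 0)
  led <- res$ledger[match(gm$sites$id, res$ledger$id), ]
  expect_equal(led$reasons,
               c("depth", "maf", "missing", "het", "ssr", "ambiguous_base"))
  expect_equal(led$stage, c(rep("hard_filter", 4), rep("probe_region", 2)))

  # same genotypes at clean positions pass everything
  gm_ok <- genotype_matrix(
    data.frame(contig = "c1", pos = c(7000L, 8000L), ref = "A", alt = "G"),
    sprintf("s%02d", 1:n), rbind(good(), c(rep(0L, 10), rep(2L, 30))),
    matrix(50, 2, n))
  res_ok <- select_core_sites(gm_ok, genome)
  expect_equal(res_ok$core$id, gm_ok$sites$id)
})

test_that("selection is idempotent and tier-demotes ambiguous SNPs", {
  g <- test_genome(5e4, seed = 9)
  pop <- simulate_population(g, n_samples = 80, n_sites = 30, maf = 0.3,
                             depth_mean = 40, seed = 13)
  res <- select_core_sites(pop$gm, g, window_sites = 30)
  expect_gt(nrow(res$core), 0)
  sub <- subset_genotypes(pop$gm, site_ids = res$core$id)
  res2 <- select_core_sites(sub, g, window_sites = 30)
  expect_equal(res2$core, res$core)
  expect_equal(nrow(res2$ledger), 0)
  # tier matches the allele-pair class
  amb <- with(pop$gm$sites[match(res$core$id, pop$gm$sites$id), ],
              (ref == "A" & alt == "T") | (ref == "T" & alt == "A") |
                (ref == "C" & alt == "G") | (ref == "G" & alt == "C"))
  expect_equal(res$core$tier, ifelse(amb, 2L, 1L))
  expect_equal(res$core$probes_required, ifelse(amb, 2L, 1L))
})

test_that("tightening any threshold never enlarges the pass set", {
  g <- test_genome(3e4, seed = 4)
  pop <- simulate_population(g, n_samples = 60, n_sites = 40,
                             maf = c(0.05, 0.1, 0.3), missing_rate = 0.1,
                             het_excess = 0.05, depth_mean = 15, seed = 21)
  st <- compute_site_stats(pop$gm)
  base <- apply_hard_filters(st)$pass
  tighter <- list(filter_thresholds(min_maf = 0.2),
                  filter_thresholds(max_missing = 0.05),
                  filter_thresholds(max_het = 0.01),
                  filter_thresholds(min_depth = 14))
  for (th in tighter) {
    expect_true(all(apply_hard_filters(st, th)$pass <= base))
  }
})

test_that("low-depth call masking converts thin calls to missing", {
  calls <- matrix(c(0L, 1L, 2L, 0L), nrow = 1)
  depth <- matrix(c(30, 9, 10, 2), nrow = 1)
  gm <- gm_from_dosage(calls, depth = depth)
  masked <- mask_low_depth_calls(gm, min_depth = 10)
  expect_equal(unname(masked$calls[1, ]), c(0L, NA, 2L, NA))
  expect_equal(compute_site_stats(masked)$missing_rate, 0.5)
  # no depth -> unchanged
  gm2 <- gm_from_dosage(calls)
  expect_identical(mask_low_depth_calls(gm2), gm2)
})
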