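#' Filtering thresholds for core polymorphic site selection
#'
#' Defaults are the panel's published selection criteria: per-site mean depth
#' of at least 10X, minor allele frequency above 0.05, missing-data ratio
#' below 20%, heterozygosity ratio below 5%, and pairwise linkage
#' disequilibrium (r-squared) below 0.4. Boundary semantics follow the
#' criteria wording exactly: depth is inclusive (>= 10), the others strict.
#'
#' @param min_depth minimum mean per-site depth (X-fold).
#' @param min_maf minor allele frequency must exceed this.
#' @param max_missing missing-call fraction must be below this.
#' @param max_het heterozygous fraction (of non-missing calls) must be below
#'   this.
#' @param max_r2 LD pruning threshold; pairs at or above it are thinned.
#' @return A list of class `filter_thresholds`.
#' @export
filter_thresholds <- function(min_depth = 10, min_maf = 0.05,
                              max_missing = 0.20, max_het = 0.05,
                              max_r2 = 0.4) {
  stopifnot(min_depth >= 0, min_maf >= 0, min_maf <= 0.5,
            max_missing >= 0, max_missing <= 1,
            max_het >= 0, max_het <= 1, max_r2 >= 0, max_r2 <= 1)
  structure(list(min_depth = min_depth, min_maf = min_maf,
                 max_missing = max_missing, max_het = max_het,
                 max_r2 = max_r2),
            class = "filter_thresholds")
}

#' Mask under-covered genotype calls as missing
#'
#' Optional pre-filtering step: individual calls whose read depth falls
#' below the threshold are set missing, so the depth requirement acts per
#' call rather than only on the per-site mean. Off by default in the
#' selection cascade; apply it explicitly before [compute_site_stats()]
#' when wanted. A matrix without depth is returned unchanged.
#'
#' @param gm a [genotype_matrix()].
#' @param min_depth calls below this depth become missing.
#' @return A new `genotype_matrix`.
#' @export
mask_low_depth_calls <- function(gm, min_depth = 10) {
  stopifnot(inherits(gm, "genotype_matrix"))
  if (is.null(gm$depth)) return(gm)
  calls <- gm$calls
  calls[!is.na(gm$depth) & gm$depth < min_depth] <- NA_integer_
  genotype_matrix(gm$sites, gm$samples, calls, gm$depth)
}

#' Per-site summary statistics
#'
#' Computes, over non-missing calls, the minor allele frequency
#' `maf = min(p, 1 - p)` with `p = (2 * hom_alt + het) / (2 * n_nonmissing)`,
#' the heterozygosity ratio `het / n_nonmissing`, the missing-call fraction
#' over all samples, and (when depth is present) the mean depth over
#' non-missing calls. Sites where every call is missing are flagged
#' `defined = FALSE`; their statistics are `NA` and they fail all filters.
#'
#' @param gm a [genotype_matrix()].
#' @return data.frame with columns `id`, `n_nonmissing`, `maf`,
#'   `missing_rate`, `het_rate`, `mean_depth`, `defined`.
#' @export
compute_site_stats <- function(gm) {
  stopifnot(inherits(gm, "genotype_matrix"))
  if (length(gm$samples) < 1) stop("at least one sample is required")
  calls <- gm$calls
  n <- ncol(calls)
  nm <- rowSums(!is.na(calls))
  het <- rowSums(calls == 1L, na.rm = TRUE)
  hom_alt <- rowSums(calls == 2L, na.rm = TRUE)
  p <- ifelse(nm > 0, (2 * hom_alt + het) / (2 * nm), NA_real_)
  maf <- pmin(p, 1 - p)
  het_rate <- ifelse(nm > 0, het / nm, NA_real_)
  missing_rate <- 1 - nm / n
  mean_depth <- if (is.null(gm$depth)) rep(NA_real_, nrow(calls)) else {
    d <- gm$depth
    d[is.na(calls)] <- NA
    rowMeans(d, na.rm = TRUE)
  }
  mean_depth[nm == 0] <- NA_real_
  data.frame(id = gm$sites$id, n_nonmissing = nm, maf = maf,
             missing_rate = missing_rate, het_rate = het_rate,
             mean_depth = mean_depth, defined = nm > 0,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Apply the hard per-site filters
#'
#' A site passes iff mean depth >= `min_depth` AND maf > `min_maf` AND
#' missing rate < `max_missing` AND het rate < `max_het`. Every failing site
#' lists all violated criteria as reason codes (`depth`, `maf`, `missing`,
#' `het`); a site with no non-missing call fails with reason `no_data`.
#' The depth criterion is only applied when the matrix carries depth
#' information.
#'
#' @param stats output of [compute_site_stats()].
#' @param thresholds a [filter_thresholds()].
#' @return data.frame with columns `id`, `pass`, `reasons` (comma-separated,
#'   empty when passing).
#' @export
apply_hard_filters <- function(stats, thresholds = filter_thresholds()) {
  stopifnot(is.data.frame(stats), inherits(thresholds, "filter_thresholds"))
  n <- nrow(stats)
  reasons <- vector("list", n)
  for (i in seq_len(n)) {
    if (!stats$defined[i]) {
      reasons[[i]] <- "no_data"
      next
    }
    r <- character(0)
    if (!is.na(stats$mean_depth[i]) &&
        stats$mean_depth[i] < thresholds$min_depth) r <- c(r, "depth")
    if (!(stats$maf[i] > thresholds$min_maf)) r <- c(r, "maf")
    if (!(stats$missing_rate[i] < thresholds$max_missing)) r <- c(r, "missing")
    if (!(stats$het_rate[i] < thresholds$max_het)) r <- c(r, "het")
    reasons[[i]] <- r
  }
  data.frame(id = stats$id,
             pass = lengths(reasons) == 0,
             reasons = vapply(reasons, paste, character(1), collapse = ","),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Genotype-based linkage disequilibrium between two sites
#'
#' Squared Pearson correlation of alternate-allele dosage vectors (0/1/2),
#' computed over samples with non-missing calls at both sites. Genotypes are
#' unphased, so this is the standard genotypic r-squared rather than a
#' haplotype EM estimate.
#'
#' @param gm a [genotype_matrix()].
#' @param id_a,id_b site ids.
#' @return r-squared in `[0, 1]`, or `NA` when fewer than two shared
#'   non-missing samples remain or either site is monomorphic among them.
#' @export
pairwise_r2 <- function(gm, id_a, id_b) {
  stopifnot(inherits(gm, "genotype_matrix"))
  i <- match(id_a, gm$sites$id)
  j <- match(id_b, gm$sites$id)
  if (is.na(i) || is.na(j)) stop("unknown site id")
  a <- gm$calls[i, ]
  b <- gm$calls[j, ]
  ok <- !is.na(a) & !is.na(b)
  if (sum(ok) < 2) return(NA_real_)
  a <- a[ok]; b <- b[ok]
  if (stats::sd(a) == 0 || stats::sd(b) == 0) return(NA_real_)
  stats::cor(a, b)^2
}

#' Windowed greedy LD pruning
#'
#' Sites are taken in (contig, pos) order. Within each sliding window (in
#' units of sites), while any pair of retained sites has r-squared at or
#' above `max_r2`, the worst pair (highest r-squared; ties broken by lowest
#' site indices) loses its lower-MAF member (MAF tie: the site at the larger
#' position is removed). Windows advance by `step_sites`; removals persist
#' across windows, so the procedure is deterministic. Pairs whose r-squared
#' is undefined (monomorphic or too few shared calls) are never pruned.
#'
#' @param gm a [genotype_matrix()].
#' @param max_r2 prune pairs with r-squared `>=` this value.
#' @param window_sites window width in sites.
#' @param step_sites window step in sites.
#' @return Character vector of retained site ids, in (contig, pos) order.
#' @export
ld_prune <- function(gm, max_r2 = 0.4, window_sites = 50, step_sites = 5) {
  stopifnot(inherits(gm, "genotype_matrix"), window_sites >= 2,
            step_sites >= 1)
  gm <- sort_sites(gm)
  st <- compute_site_stats(gm)
  maf <- st$maf
  pos <- gm$sites$pos
  keep <- rep(TRUE, nrow(gm$sites))
  for (ctg in unique(gm$sites$contig)) {
    idx <- which(gm$sites$contig == ctg)
    n <- length(idx)
    starts <- unique(pmin(seq(1L, max(1L, n), by = step_sites),
                          max(1L, n - window_sites + 1L)))
    for (s in starts) {
      w <- idx[s:min(s + window_sites - 1L, n)]
      w <- w[keep[w]]
      if (length(w) < 2) next
      repeat {
        d <- t(gm$calls[w, , drop = FALSE])
        r2 <- suppressWarnings(stats::cor(d, use = "pairwise.complete.obs")^2)
        r2[!is.finite(r2)] <- -1
        diag(r2) <- -1
        worst <- max(r2)
        if (worst < max_r2) break
        hit <- which(r2 == worst, arr.ind = TRUE)
        # upper triangle only, deterministic first pair in index order
        hit <- hit[hit[, 1] < hit[, 2], , drop = FALSE]
        hit <- hit[order(hit[, 1], hit[, 2]), , drop = FALSE]
        a <- w[hit[1, 1]]
        b <- w[hit[1, 2]]
        drop_site <- if (maf[a] < maf[b]) a
          else if (maf[b] < maf[a]) b
          else if (pos[a] >= pos[b]) a else b
        keep[drop_site] <- FALSE
        w <- setdiff(w, drop_site)
        if (length(w) < 2) break
      }
    }
  }
  gm$sites$id[keep]
}

#' Microsatellite (SSR) detection thresholds
#'
#' Minimum copy numbers for a perfect tandem repeat to count as an SSR, by
#' motif length 1-6. Defaults follow common microsatellite-survey
#' conventions: mononucleotide runs of 8+, dinucleotide 5+, tri- to
#' hexanucleotide 4+ copies.
#'
#' @param min_copies integer vector of length 6: minimum copies for motif
#'   lengths 1..6.
#' @return A list of class `ssr_spec`.
#' @export
ssr_spec <- function(min_copies = c(8L, 5L, 4L, 4L, 4L, 4L)) {
  min_copies <- as.integer(min_copies)
  stopifnot(length(min_copies) == 6, all(min_copies >= 2))
  structure(list(min_copies = min_copies), class = "ssr_spec")
}

#' Detect simple sequence repeats in a sequence
#'
#' Reports every maximal perfect tandem repeat whose primitive motif length
#' is 1-6 and whose full-copy count meets the spec. Intervals are 0-based
#' half-open and cover the whole periodic run (including a trailing partial
#' copy); `copies` counts full copies. The reported motif is the
#' lexicographically least rotation of the primitive repeat unit, so the
#' same run is never reported twice under different phases or motif
#' multiples. `N` never matches anything.
#'
#' @param sequence a nucleotide string (case-insensitive).
#' @param spec an [ssr_spec()].
#' @return data.frame with columns `start`, `end` (0-based half-open),
#'   `motif`, `copies`, ordered by `start`; zero rows when none found.
#' @export
detect_ssr <- function(sequence, spec = ssr_spec()) {
  stopifnot(inherits(spec, "ssr_spec"))
  s <- strsplit(toupper(sequence), "", fixed = TRUE)[[1]]
  n <- length(s)
  hits <- list()
  for (k in 1:6) {
    if (n < 2L * k) next
    i <- seq_len(n - k)
    eq <- s[i] == s[i + k] & s[i] != "N"
    r <- rle(eq)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    for (j in which(r$values)) {
      run_len <- r$lengths[j] + k          # bp covered by the periodic run
      copies <- run_len %/% k
      if (copies < spec$min_copies[k]) next
      motif <- paste(s[starts[j]:(starts[j] + k - 1L)], collapse = "")
      if (!is_primitive_motif(motif)) next
      hits[[length(hits) + 1L]] <- data.frame(
        start = starts[j] - 1L, end = starts[j] - 1L + run_len,
        motif = canonical_rotation(motif), copies = copies,
        stringsAsFactors = FALSE)
    }
  }
  if (!length(hits)) {
    return(data.frame(start = integer(0), end = integer(0),
                      motif = character(0), copies = integer(0)))
  }
  out <- do.call(rbind, hits)
  out <- out[order(out$start, out$end), , drop = FALSE]
  # drop intervals contained in a longer report of the same canonical motif
  keep <- rep(TRUE, nrow(out))
  for (i in seq_len(nrow(out))) {
    for (j in seq_len(nrow(out))) {
      if (i != j && keep[i] && keep[j] && out$motif[i] == out$motif[j] &&
          out$start[j] <= out$start[i] && out$end[i] <= out$end[j] &&
          (out$end[j] - out$start[j]) > (out$end[i] - out$start[i])) {
        keep[i] <- FALSE
      }
    }
  }
  out <- out[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

# TRUE when the motif is not a whole-number repetition of a shorter unit
is_primitive_motif <- function(motif) {
  k <- nchar(motif)
  if (k == 1L) return(TRUE)
  for (d in seq_len(k - 1L)) {
    if (k %% d == 0L &&
        motif == strrep(substr(motif, 1L, d), k %/% d)) return(FALSE)
  }
  TRUE
}

canonical_rotation <- function(motif) {
  k <- nchar(motif)
  if (k == 1L) return(motif)
  doubled <- paste0(motif, motif)
  min(vapply(seq_len(k), function(i) substr(doubled, i, i + k - 1L),
             character(1)))
}

#' Classify an allele pair for strand ambiguity
#'
#' A/T and C/G SNPs read the same on both strands, so a capture probe cannot
#' tell the strands apart and the site needs two oligos (one per strand).
#' Every other SNP, and every indel, is strand-safe and needs one.
#'
#' @param ref,alt allele strings of a biallelic site.
#' @return list with `class` (`"strand_safe"` or `"strand_ambiguous"`) and
#'   `probes_required` (1 or 2).
#' @export
classify_allele_pair <- function(ref, alt) {
  stopifnot(length(ref) == 1, length(alt) == 1, ref != alt)
  ambiguous <- nchar(ref) == 1 && nchar(alt) == 1 &&
    (all(c(ref, alt) %in% c("A", "T")) || all(c(ref, alt) %in% c("C", "G")))
  list(class = if (ambiguous) "strand_ambiguous" else "strand_safe",
       probes_required = if (ambiguous) 2L else 1L)
}

#' Select core polymorphic sites
#'
#' The full site-selection cascade: hard per-site filters (depth, MAF,
#' missingness, heterozygosity), then a probe-region screen (a valid
#' 110 bp window free of SSRs and N must exist, via
#' [design_probe_window()]), then windowed LD pruning. Strand-ambiguous
#' A/T and C/G SNPs are kept but demoted to priority tier 2 (they need two
#' oligos); all other sites are tier 1. Each rejected site is recorded once
#' in the ledger with the first stage at which it failed.
#'
#' @param gm a [genotype_matrix()].
#' @param genome the reference [Biostrings::DNAStringSet].
#' @param thresholds a [filter_thresholds()].
#' @param spec an [ssr_spec()] for the probe-region screen.
#' @param probe_length,gc_min,gc_max,max_shift probe-window design
#'   parameters, see [design_probe_window()].
#' @param window_sites,step_sites LD pruning window, see [ld_prune()].
#' @return list with `core` (data.frame: `id`, `tier`, `probes_required`)
#'   and `ledger` (data.frame: `id`, `stage` in
#'   `{hard_filter, probe_region, ld}`, `reasons`).
#' @export
select_core_sites <- function(gm, genome, thresholds = filter_thresholds(),
                              spec = ssr_spec(), probe_length = 110,
                              gc_min = 30, gc_max = 80, max_shift = 40,
                              window_sites = 50, step_sites = 5) {
  gm <- sort_sites(gm)
  stats <- compute_site_stats(gm)
  hard <- apply_hard_filters(stats, thresholds)
  ledger <- data.frame(id = character(0), stage = character(0),
                       reasons = character(0), stringsAsFactors = FALSE)
  failed <- !hard$pass
  if (any(failed)) {
    ledger <- rbind(ledger, data.frame(id = hard$id[failed],
                                       stage = "hard_filter",
                                       reasons = hard$reasons[failed]))
  }
  surv <- gm$sites$id[hard$pass]
  # probe-region screen: a window must exist
  win_ok <- logical(length(surv))
  win_reason <- character(length(surv))
  for (i in seq_along(surv)) {
    row <- gm$sites[match(surv[i], gm$sites$id), ]
    w <- design_probe_window(row$contig, row$pos, genome,
                             length = probe_length, gc_min = gc_min,
                             gc_max = gc_max, max_shift = max_shift,
                             spec = spec)
    win_ok[i] <- w$accepted
    if (!w$accepted) win_reason[i] <- w$reason
  }
  if (any(!win_ok)) {
    ledger <- rbind(ledger, data.frame(id = surv[!win_ok],
                                       stage = "probe_region",
                                       reasons = win_reason[!win_ok]))
  }
  surv <- surv[win_ok]
  if (length(surv) >= 2) {
    sub <- subset_genotypes(gm, site_ids = surv)
    kept <- ld_prune(sub, max_r2 = thresholds$max_r2,
                     window_sites = window_sites, step_sites = step_sites)
    pruned <- setdiff(surv, kept)
    if (length(pruned)) {
      ledger <- rbind(ledger, data.frame(id = pruned, stage = "ld",
                                         reasons = "r2_ge_max"))
    }
    surv <- surv[surv %in% kept]
  }
  cls <- lapply(match(surv, gm$sites$id), function(i) {
    classify_allele_pair(gm$sites$ref[i], gm$sites$alt[i])
  })
  core <- data.frame(
    id = surv,
    tier = vapply(cls, function(x)
      if (x$class == "strand_ambiguous") 2L else 1L, integer(1)),
    probes_required = vapply(cls, `[[`, integer(1), "probes_required"),
    stringsAsFactors = FALSE)
  rownames(ledger) <- NULL
  list(core = core, ledger = ledger)
}
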