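#' Panel design configuration
#'
#' Collects the probe and spacing parameters used by [build_panel()].
#' Defaults reproduce the published chip design: 110 bp probes with GC
#' content in 30-80% (inclusive), gaps of 70 kb or more between adjacent
#' selected sites trigger background fill, and candidate segments of
#' +/- 200 bp around each site must be single-copy in the genome.
#'
#' @param probe_length probe window length in bp.
#' @param gc_min,gc_max inclusive GC-content bounds in percent.
#' @param max_shift maximum window shift (bp) away from the centered
#'   placement when searching for a valid window.
#' @param gap_threshold adjacent-site distance (bp) at or above which an
#'   interval counts as a vacant region to fill.
#' @param flank bp of flanking sequence on each side of a site for the
#'   single-copy test.
#' @param min_identity,min_cov a secondary locus disqualifies a site when it
#'   aligns at `>= min_identity` over `>= min_cov` of the segment.
#' @param check_single_copy logical; run the single-copy test in
#'   [build_panel()].
#' @param spec an [ssr_spec()] for the probe-window SSR screen.
#' @return list of class `panel_config`.
#' @export
panel_config <- function(probe_length = 110, gc_min = 30, gc_max = 80,
                         max_shift = 40, gap_threshold = 70000,
                         flank = 200, min_identity = 0.80, min_cov = 0.50,
                         check_single_copy = TRUE, spec = ssr_spec()) {
  stopifnot(probe_length >= 20, gc_min >= 0, gc_max <= 100, gc_min <= gc_max,
            max_shift >= 0, gap_threshold > 0, flank > 0,
            min_identity > 0, min_identity <= 1, min_cov > 0, min_cov <= 1)
  structure(list(probe_length = probe_length, gc_min = gc_min,
                 gc_max = gc_max, max_shift = max_shift,
                 gap_threshold = gap_threshold, flank = flank,
                 min_identity = min_identity, min_cov = min_cov,
                 check_single_copy = check_single_copy, spec = spec),
            class = "panel_config")
}

gc_percent <- function(s) {
  chars <- strsplit(s, "", fixed = TRUE)[[1]]
  100 * sum(chars %in% c("G", "C")) / length(chars)
}

#' Design a probe window around a variant
#'
#' Starts from the centered placement (variant at 0-based offset 55 of a
#' 110 bp window) and, if that window violates a constraint (GC content
#' outside `[gc_min, gc_max]`, an ambiguous base N, or an SSR per `spec`),
#' scans alternative shifts in the order -1, +1, -2, +2, ... up to
#' `max_shift`, accepting the first valid window. Windows are clipped to the
#' contig, so near-edge variants get an off-center placement; the variant
#' must always lie strictly inside the window. A rejection records the
#' constraint that failed at every tried shift.
#'
#' @param contig,pos site location (1-based position).
#' @param genome a [Biostrings::DNAStringSet].
#' @param length window length (bp).
#' @param gc_min,gc_max inclusive GC bounds (percent).
#' @param max_shift maximum shift from the centered placement.
#' @param spec an [ssr_spec()].
#' @return list: `accepted` (logical); when accepted, `contig`, `start0`,
#'   `end0` (0-based half-open), `gc`, `offset` (signed shift of the window
#'   from the centered placement); when rejected, `reason` and `attempts`
#'   (data.frame of shift, start0, reason).
#' @export
design_probe_window <- function(contig, pos, genome, length = 110,
                                gc_min = 30, gc_max = 80, max_shift = 40,
                                spec = ssr_spec()) {
  if (!contig %in% names(genome)) stop("unknown contig: ", contig)
  clen <- length(genome[[contig]])
  if (clen < length) {
    return(list(accepted = FALSE, reason = "contig_too_short",
                attempts = data.frame(shift = integer(0), start0 = integer(0),
                                      reason = character(0))))
  }
  center_offset <- (length %/% 2)          # variant offset in window, 0-based
  base_start <- pos - 1L - center_offset   # 0-based window start
  shifts <- c(0L, as.vector(rbind(-seq_len(max_shift), seq_len(max_shift))))
  tried <- integer(0)
  attempts <- list()
  seq_chr <- as.character(genome[[contig]])
  for (sh in shifts) {
    start0 <- min(max(base_start + sh, 0L), clen - length)
    if (start0 %in% tried) next
    tried <- c(tried, start0)
    end0 <- start0 + length
    # variant strictly inside the window
    if (!(pos - 1L >= start0 && pos - 1L < end0)) {
      attempts[[length(attempts) + 1L]] <-
        data.frame(shift = sh, start0 = start0, reason = "variant_outside")
      next
    }
    win <- substr(seq_chr, start0 + 1L, end0)
    reason <- NULL
    if (grepl("N", win, fixed = TRUE)) {
      reason <- "ambiguous_base"
    } else {
      gc <- gc_percent(win)
      if (gc < gc_min || gc > gc_max) {
        reason <- "gc_out_of_range"
      } else if (nrow(detect_ssr(win, spec)) > 0) {
        reason <- "ssr"
      }
    }
    if (is.null(reason)) {
      return(list(accepted = TRUE, contig = contig, start0 = start0,
                  end0 = end0, gc = gc,
                  offset = (start0 + center_offset) - (pos - 1L)))
    }
    attempts[[length(attempts) + 1L]] <-
      data.frame(shift = sh, start0 = start0, reason = reason)
  }
  attempts <- do.call(rbind, attempts)
  list(accepted = FALSE, reason = attempts$reason[1], attempts = attempts)
}

#' Genome-wide single-copy test for a candidate segment
#'
#' Extracts the segment spanning `flank` bp up- and downstream of the site
#' (clipped at contig ends, so up to `2 * flank + 1` bp) and searches the
#' whole genome, both strands, for secondary occurrences by seeded
#' exact-match extension: exact k-mer seeds taken every `seed_stride` bp
#' along the segment are located genome-wide, and each hit is extended
#' without gaps to an implied full-segment alignment. The site fails
#' (returns `FALSE`) when any locus other than the source aligns at
#' `>= min_identity` over `>= min_cov` of the segment.
#'
#' @param contig,pos site location.
#' @param genome a [Biostrings::DNAStringSet].
#' @param flank flank length (bp) each side of the site.
#' @param min_identity,min_cov disqualification thresholds.
#' @param seed_k seed k-mer length.
#' @param seed_stride spacing between seed start positions.
#' @return `TRUE` when the segment is single-copy.
#' @export
single_copy_check <- function(contig, pos, genome, flank = 200,
                              min_identity = 0.80, min_cov = 0.50,
                              seed_k = 21, seed_stride = 10) {
  if (!contig %in% names(genome)) stop("unknown contig: ", contig)
  clen <- length(genome[[contig]])
  seg_start <- max(1L, pos - flank)        # 1-based inclusive
  seg_end <- min(clen, pos + flank)
  segment <- genome_slice(genome, contig, seg_start - 1L, seg_end)
  seg_len <- nchar(segment)
  if (seg_len < seed_k) return(TRUE)
  seed_offsets <- unique(c(seq(1L, seg_len - seed_k + 1L, by = seed_stride),
                           seg_len - seed_k + 1L))
  cand <- list()                            # (contig, start, strand)
  for (off in seed_offsets) {
    seed <- substr(segment, off, off + seed_k - 1L)
    if (grepl("N", seed, fixed = TRUE)) next
    pat <- Biostrings::DNAString(seed)
    for (strand in c("+", "-")) {
      p <- if (strand == "+") pat else Biostrings::reverseComplement(pat)
      hits <- Biostrings::vmatchPattern(p, genome)
      for (ci in seq_along(hits)) {
        st <- Biostrings::startIndex(hits)[[ci]]
        if (is.null(st)) next
        for (h in st) {
          aln_start <- if (strand == "+") h - (off - 1L)
            else h - (seg_len - (off + seed_k - 1L))
          cand[[length(cand) + 1L]] <-
            list(contig = names(genome)[ci], start = aln_start,
                 strand = strand)
        }
      }
    }
  }
  if (!length(cand)) return(TRUE)
  key <- vapply(cand, function(x)
    paste(x$contig, x$start, x$strand, sep = "|"), character(1))
  cand <- cand[!duplicated(key)]
  seg_chars <- strsplit(segment, "", fixed = TRUE)[[1]]
  for (x in cand) {
    # skip the source locus itself (any overlap on the forward strand)
    if (x$strand == "+" && x$contig == contig &&
        x$start < seg_end + 1L && x$start + seg_len - 1L >= seg_start) next
    tlen <- length(genome[[x$contig]])
    t_start <- max(1L, x$start)
    t_end <- min(tlen, x$start + seg_len - 1L)
    if (t_end < t_start) next
    tgt <- genome_slice(genome, x$contig, t_start - 1L, t_end)
    if (x$strand == "-") {
      tgt <- as.character(
        Biostrings::reverseComplement(Biostrings::DNAString(tgt)))
      # segment coordinates corresponding to the reverse-complemented slice
      q_from <- (x$start + seg_len - 1L - t_end) + 1L
      q_to <- q_from + (t_end - t_start)
    } else {
      q_from <- t_start - x$start + 1L
      q_to <- q_from + (t_end - t_start)
    }
    q <- seg_chars[q_from:q_to]
    t <- strsplit(tgt, "", fixed = TRUE)[[1]]
    compared <- length(q)
    ident <- sum(q == t & q != "N") / compared
    cov <- compared / seg_len
    if (ident >= min_identity && cov >= min_cov) return(FALSE)
  }
  TRUE
}

#' Find vacant intervals between selected sites
#'
#' Computes, per contig, the distance between adjacent selected sites (plus
#' the leading interval from the contig start and the trailing interval to
#' the contig end) and reports every interval whose span reaches the
#' threshold. A contig with no selected sites is one whole-contig gap.
#'
#' @param sites data.frame with columns `contig`, `pos` (1-based).
#' @param contig_lengths named vector of contig lengths (e.g.
#'   [genome_lengths()]); every contig in it is scanned.
#' @param threshold minimum span (bp) to report.
#' @return data.frame with columns `contig`, `start`, `end` (1-based
#'   positions of the flanking sites or contig ends), `span = end - start`.
#' @export
find_gaps <- function(sites, contig_lengths, threshold = 70000) {
  stopifnot(is.data.frame(sites), !is.null(names(contig_lengths)))
  out <- list()
  for (ctg in names(contig_lengths)) {
    pos <- sort(sites$pos[sites$contig == ctg])
    bounds <- c(1L, pos, as.integer(contig_lengths[[ctg]]))
    spans <- diff(bounds)
    hit <- which(spans >= threshold)
    if (length(hit)) {
      out[[length(out) + 1L]] <- data.frame(
        contig = ctg, start = bounds[hit], end = bounds[hit + 1L],
        span = spans[hit], stringsAsFactors = FALSE)
    }
  }
  if (!length(out)) {
    return(data.frame(contig = character(0), start = integer(0),
                      end = integer(0), span = integer(0)))
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Fill vacant intervals from a background site pool
#'
#' For each gap, repeatedly takes the largest remaining sub-gap at or above
#' the threshold and adds the unused pool site nearest its midpoint (ties:
#' lower coordinate), until every sub-gap is below the threshold or no pool
#' site remains inside any oversized sub-gap. Deterministic; sub-gaps that
#' cannot be filled are reported as residual.
#'
#' @param gaps a [find_gaps()] result.
#' @param pool data.frame of candidate background sites (`id`, `contig`,
#'   `pos`), already filtered and probe-checked.
#' @param threshold the gap threshold (bp).
#' @return list with `added` (pool rows chosen, in insertion order) and
#'   `residual` (data.frame of remaining gaps `>=` threshold).
#' @export
fill_gaps <- function(gaps, pool, threshold = 70000) {
  stopifnot(is.data.frame(gaps), is.data.frame(pool))
  used <- rep(FALSE, nrow(pool))
  added <- list()
  residual <- list()
  for (g in seq_len(nrow(gaps))) {
    ctg <- gaps$contig[g]
    bps <- c(gaps$start[g], gaps$end[g])
    closed <- logical(1)                   # sub-gaps with no usable candidate
    repeat {
      spans <- diff(bps)
      open <- which(spans >= threshold & !closed)
      if (!length(open)) break
      i <- open[which.max(spans[open])]    # ties: first = lower coordinate
      lo <- bps[i]; hi <- bps[i + 1L]
      cand <- which(!used & pool$contig == ctg &
                      pool$pos > lo & pool$pos < hi)
      if (!length(cand)) {
        closed[i] <- TRUE
        next
      }
      mid <- (lo + hi) / 2
      d <- abs(pool$pos[cand] - mid)
      pick <- cand[order(d, pool$pos[cand])][1]
      used[pick] <- TRUE
      added[[length(added) + 1L]] <- pool[pick, , drop = FALSE]
      bps <- append(bps, pool$pos[pick], after = i)
      closed <- append(closed, FALSE, after = i - 1L)
      closed[c(i, i + 1L)] <- FALSE
    }
    spans <- diff(bps)
    left <- which(spans >= threshold)
    if (length(left)) {
      residual[[length(residual) + 1L]] <- data.frame(
        contig = ctg, start = bps[left], end = bps[left + 1L],
        span = spans[left], stringsAsFactors = FALSE)
    }
  }
  added <- if (length(added)) do.call(rbind, added) else pool[0, , drop = FALSE]
  residual <- if (length(residual)) do.call(rbind, residual) else
    data.frame(contig = character(0), start = integer(0), end = integer(0),
               span = integer(0))
  rownames(added) <- NULL
  rownames(residual) <- NULL
  list(added = added, residual = residual)
}

#' Build a capture probe panel
#'
#' The complete panel construction pipeline: place the foreground /
#' functional-segment sites, detect vacant intervals of `gap_threshold` bp
#' or more, fill them from the background pool ([fill_gaps()]), then design
#' a probe window ([design_probe_window()]) and (optionally) run the
#' single-copy test ([single_copy_check()]) for every site. Background
#' sites with no valid window or a multi-copy flag are dropped; foreground
#' sites are never dropped, only flagged, because trait coverage takes
#' precedence over spacing. Spacing statistics are computed over all
#' retained, unflagged sites per contig.
#'
#' @param catalog data.frame of foreground sites: `contig`, `pos`, `ref`,
#'   `alt`, optional `trait`, optional `role` (`"foreground"` or
#'   `"functional_segment"`, default `"foreground"`), optional `id`.
#' @param pool background site pool (`contig`, `pos`, `ref`, `alt`,
#'   optional `id`), pre-filtered by [select_core_sites()].
#' @param genome a [Biostrings::DNAStringSet].
#' @param config a [panel_config()].
#' @return An object of class `probe_panel`: list with `probes` (one row per
#'   site: id, role, trait, contig, pos, ref, alt, window coordinates, gc,
#'   offset, probes_required, single_copy, window_ok, flagged, dropped
#'   reason), `counts_by_role`, `spacing` (per-contig mean / median / max
#'   adjacent distance), `residual_gaps`, `contig_lengths`.
#' @export
build_panel <- function(catalog, pool, genome, config = panel_config()) {
  stopifnot(is.data.frame(catalog), is.data.frame(pool),
            inherits(config, "panel_config"))
  lens <- genome_lengths(genome)
  fg <- catalog
  if (is.null(fg$role)) fg$role <- "foreground"
  if (is.null(fg$trait)) fg$trait <- NA_character_
  if (is.null(fg$id)) fg$id <- paste(fg$contig, fg$pos, sep = "_")
  stopifnot(all(fg$role %in% c("foreground", "functional_segment")))
  pool <- pool[!paste(pool$contig, pool$pos) %in%
                 paste(fg$contig, fg$pos), , drop = FALSE]
  if (is.null(pool$id)) pool$id <- paste(pool$contig, pool$pos, sep = "_")

  gaps <- find_gaps(fg, lens, config$gap_threshold)
  filled <- fill_gaps(gaps, pool, config$gap_threshold)
  bg <- filled$added
  if (nrow(bg)) {
    bg$role <- "background"
    bg$trait <- NA_character_
  }
  cols <- c("id", "role", "trait", "contig", "pos", "ref", "alt")
  for (cc in setdiff(cols, names(bg))) bg[[cc]] <- NA_character_
  sites <- rbind(fg[, cols, drop = FALSE], bg[, cols, drop = FALSE])
  sites <- sites[order(sites$contig, sites$pos), , drop = FALSE]

  n <- nrow(sites)
  start0 <- end0 <- rep(NA_integer_, n)
  gc <- offset <- rep(NA_real_, n)
  window_ok <- single_copy <- rep(NA, n)
  reject <- rep(NA_character_, n)
  probes_required <- rep(1L, n)
  for (i in seq_len(n)) {
    w <- design_probe_window(sites$contig[i], sites$pos[i], genome,
                             length = config$probe_length,
                             gc_min = config$gc_min, gc_max = config$gc_max,
                             max_shift = config$max_shift, spec = config$spec)
    window_ok[i] <- w$accepted
    if (w$accepted) {
      start0[i] <- w$start0; end0[i] <- w$end0
      gc[i] <- w$gc; offset[i] <- w$offset
    } else {
      reject[i] <- w$reason
    }
    single_copy[i] <- if (config$check_single_copy) {
      single_copy_check(sites$contig[i], sites$pos[i], genome,
                        flank = config$flank,
                        min_identity = config$min_identity,
                        min_cov = config$min_cov)
    } else TRUE
    if (!is.na(sites$ref[i]) && !is.na(sites$alt[i])) {
      probes_required[i] <-
        classify_allele_pair(sites$ref[i], sites$alt[i])$probes_required
    }
  }
  ok <- window_ok & single_copy
  foreground <- sites$role != "background"
  dropped <- !ok & !foreground
  flagged <- !ok & foreground
  probes <- data.frame(sites, start0 = start0, end0 = end0, gc = gc,
                       offset = offset, probes_required = probes_required,
                       window_ok = window_ok, single_copy = single_copy,
                       flagged = flagged,
                       reject_reason = ifelse(ok, NA_character_,
                         ifelse(window_ok, "multi_copy", reject)),
                       stringsAsFactors = FALSE)
  probes <- probes[!dropped, , drop = FALSE]
  rownames(probes) <- NULL

  counts <- table(factor(probes$role,
                         levels = c("foreground", "functional_segment",
                                    "background")))
  clean <- probes[!probes$flagged, , drop = FALSE]
  spacing <- do.call(rbind, lapply(names(lens), function(ctg) {
    p <- sort(clean$pos[clean$contig == ctg])
    if (length(p) < 2) {
      return(data.frame(contig = ctg, n_sites = length(p),
                        mean_spacing = NA_real_, median_spacing = NA_real_,
                        max_spacing = NA_real_))
    }
    d <- diff(p)
    data.frame(contig = ctg, n_sites = length(p), mean_spacing = mean(d),
               median_spacing = stats::median(d), max_spacing = max(d))
  }))
  residual <- find_gaps(clean, lens, config$gap_threshold)
  structure(list(probes = probes,
                 counts_by_role = c(as.list(counts),
                                    total = nrow(probes)),
                 spacing = spacing, residual_gaps = residual,
                 contig_lengths = lens, config = config),
            class = "probe_panel")
}

#' @export
print.probe_panel <- function(x, ...) {
  cb <- x$counts_by_role
  cat(sprintf(paste0("probe_panel: %d sites (%d foreground, %d functional",
                     " segments, %d background)\n"),
              cb$total, cb$foreground, cb$functional_segment, cb$background))
  cat(sprintf("  flagged foreground sites: %d; residual gaps: %d\n",
              sum(x$probes$flagged), nrow(x$residual_gaps)))
  invisible(x)
}

#' Read a foreground trait catalog from TSV
#'
#' Expected columns: `trait`, `contig`, `pos`, `ref`, `alt`, and optionally
#' `segment_tag` (a truthy value marks the site as a functional segment
#' rather than a plain foreground site).
#'
#' @param path TSV file.
#' @return data.frame with a `role` column added.
#' @export
read_trait_catalog <- function(path) {
  x <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("trait", "contig", "pos", "ref", "alt")
  miss <- setdiff(need, names(x))
  if (length(miss)) stop("catalog missing column(s): ",
                         paste(miss, collapse = ", "))
  x$role <- if (!is.null(x$segment_tag)) {
    ifelse(!is.na(x$segment_tag) & x$segment_tag != "" & x$segment_tag != 0,
           "functional_segment", "foreground")
  } else "foreground"
  x
}

#' Summarize a trait catalog
#'
#' Counts the registered sites per trait plus the grand total. A site listed
#' twice under the same trait is counted once, with a warning.
#'
#' @param catalog data.frame with columns `trait` and a site identifier
#'   (`id`, or `contig` + `pos`).
#' @return list with `counts` (data.frame `trait`, `n_sites`, sorted by
#'   trait) and `total`.
#' @export
summarize_trait_catalog <- function(catalog) {
  stopifnot(is.data.frame(catalog), "trait" %in% names(catalog))
  if (nrow(catalog) == 0) {
    return(list(counts = data.frame(trait = character(0),
                                    n_sites = integer(0)),
                total = 0L))
  }
  key <- if (!is.null(catalog$id)) catalog$id else {
    stopifnot(all(c("contig", "pos") %in% names(catalog)))
    paste(catalog$contig, catalog$pos, sep = "_")
  }
  pair <- paste(catalog$trait, key, sep = "\r")
  if (anyDuplicated(pair)) {
    warning("duplicate (trait, site) entries counted once")
    catalog <- catalog[!duplicated(pair), , drop = FALSE]
  }
  tab <- table(catalog$trait)
  counts <- data.frame(trait = names(tab), n_sites = as.integer(tab),
                       stringsAsFactors = FALSE)
  counts <- counts[order(counts$trait), , drop = FALSE]
  rownames(counts) <- NULL
  list(counts = counts, total = sum(counts$n_sites))
}
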