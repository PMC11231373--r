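#' VanRaden genomic kinship matrix
#'
#' The standard centered-dosage estimator:
#' `K = Z'Z / sum(2 p_j (1 - p_j))`, where `Z` is the site x sample dosage
#' matrix after per-site mean imputation of missing calls and centering by
#' `2 p_j` (alternate-allele frequency `p_j`). Monomorphic sites carry no
#' relatedness information and are excluded from both `Z` and the scaling
#' sum. Values are left on the VanRaden scale (unnormalized), so entries
#' above 1 are possible for close relatives and inbred lines.
#'
#' @param gm a [genotype_matrix()].
#' @return Symmetric samples x samples numeric matrix of class
#'   `kinship_matrix`.
#' @export
vanraden_kinship <- function(gm) {
  stopifnot(inherits(gm, "genotype_matrix"))
  d <- gm$calls
  storage.mode(d) <- "double"
  rm_ <- rowMeans(d, na.rm = TRUE)
  for (i in seq_len(nrow(d))) d[i, is.na(d[i, ])] <- rm_[i]
  p <- rm_ / 2
  poly <- is.finite(p) & p > 0 & p < 1
  if (!any(poly)) stop("no polymorphic markers")
  z <- d[poly, , drop = FALSE] - 2 * p[poly]
  denom <- sum(2 * p[poly] * (1 - p[poly]))
  k <- crossprod(z) / denom
  dimnames(k) <- list(gm$samples, gm$samples)
  class(k) <- c("kinship_matrix", class(k))
  k
}

#' Summarize a kinship matrix
#'
#' Statistics over the upper-triangle off-diagonal entries: the mean value,
#' the fraction lying in `[0, 0.5]`, and the fraction exceeding 1.
#'
#' @param k a square symmetric kinship matrix.
#' @return list: `mean`, `frac_0_05`, `frac_gt_1`, `n_pairs`.
#' @export
kinship_summary <- function(k) {
  k <- unclass(k)
  stopifnot(is.matrix(k), nrow(k) == ncol(k))
  if (nrow(k) < 2) stop("kinship summary needs at least two samples")
  v <- k[upper.tri(k)]
  list(mean = mean(v),
       frac_0_05 = mean(v >= 0 & v <= 0.5),
       frac_gt_1 = mean(v > 1),
       n_pairs = length(v))
}

#' Bonferroni significance threshold
#'
#' @param alpha family-wise error rate.
#' @param n_tests number of markers tested; must be at least 1.
#' @return `alpha / n_tests`.
#' @export
bonferroni_threshold <- function(alpha = 0.05, n_tests) {
  if (missing(n_tests) || length(n_tests) != 1 || n_tests < 1) {
    stop("n_tests must be a single value >= 1")
  }
  stopifnot(alpha > 0, alpha <= 1)
  alpha / n_tests
}

#' Simplified allelic chi-square association scan for a binary trait
#'
#' Per marker, alleles of the phenotyped, non-missing samples are tabulated
#' in a 2x2 allele-by-phenotype count table and tested with a Pearson
#' chi-square (1 df, no continuity correction). This is a deliberately
#' simplified single-marker scan: no mixed model, no structure or kinship
#' correction. Markers where any expected cell is below 5 are flagged
#' (`low_expected`), with an optional Fisher exact fallback for the p-value.
#' Monomorphic markers (or single-class tables) get statistic 0 and p = 1.
#'
#' @param gm a [genotype_matrix()], ideally post-filtered.
#' @param phenotype logical (or two-level factor) vector over `gm$samples`
#'   (`TRUE` = case), or a data.frame with columns `sample` and a two-level
#'   `category`.
#' @param fisher use Fisher's exact p for flagged markers.
#' @return data.frame, one row per marker: `id`, `contig`, `pos`,
#'   case/control alternate and reference allele counts, `chisq`, `p`,
#'   `af_diff` (case minus control alternate-allele frequency),
#'   `low_expected`.
#' @export
binary_assoc_scan <- function(gm, phenotype, fisher = FALSE) {
  stopifnot(inherits(gm, "genotype_matrix"))
  if (is.data.frame(phenotype)) {
    stopifnot(all(c("sample", "category") %in% names(phenotype)))
    m <- match(gm$samples, phenotype$sample)
    if (anyNA(m)) stop("sample(s) without phenotype")
    lv <- unique(as.character(phenotype$category))
    if (length(lv) != 2) stop("phenotype must have exactly two classes")
    phenotype <- as.character(phenotype$category[m]) == lv[1]
  }
  if (is.factor(phenotype)) {
    if (nlevels(droplevels(phenotype)) != 2) {
      stop("phenotype must have exactly two classes")
    }
    phenotype <- phenotype == levels(droplevels(phenotype))[1]
  }
  stopifnot(is.logical(phenotype), length(phenotype) == length(gm$samples))
  keep <- !is.na(phenotype)
  phenotype <- phenotype[keep]
  if (length(unique(phenotype)) < 2) {
    stop("phenotype must have exactly two classes")
  }
  d <- gm$calls[, keep, drop = FALSE]
  case <- which(phenotype)
  ctrl <- which(!phenotype)
  alt_case <- rowSums(d[, case, drop = FALSE], na.rm = TRUE)
  alt_ctrl <- rowSums(d[, ctrl, drop = FALSE], na.rm = TRUE)
  n_case <- 2 * rowSums(!is.na(d[, case, drop = FALSE]))
  n_ctrl <- 2 * rowSums(!is.na(d[, ctrl, drop = FALSE]))
  ref_case <- n_case - alt_case
  ref_ctrl <- n_ctrl - alt_ctrl
  n_tot <- n_case + n_ctrl
  alt_tot <- alt_case + alt_ctrl
  ref_tot <- ref_case + ref_ctrl
  # Pearson chi-square on the 2x2 allele table, closed form
  num <- n_tot * (alt_case * ref_ctrl - alt_ctrl * ref_case)^2
  den <- as.numeric(n_case) * n_ctrl * alt_tot * ref_tot
  chisq <- ifelse(den > 0, num / den, 0)
  p <- ifelse(chisq > 0, stats::pchisq(chisq, df = 1, lower.tail = FALSE), 1)
  expected <- outer_min_expected(alt_tot, ref_tot, n_case, n_ctrl, n_tot)
  low <- is.finite(expected) & expected < 5
  if (fisher && any(low)) {
    for (i in which(low)) {
      tb <- matrix(c(alt_case[i], ref_case[i], alt_ctrl[i], ref_ctrl[i]), 2)
      if (all(is.finite(tb)) && sum(tb) > 0) {
        p[i] <- stats::fisher.test(tb)$p.value
      }
    }
  }
  af_diff <- ifelse(n_case > 0, alt_case / n_case, NA) -
    ifelse(n_ctrl > 0, alt_ctrl / n_ctrl, NA)
  data.frame(id = gm$sites$id, contig = gm$sites$contig, pos = gm$sites$pos,
             alt_case = alt_case, ref_case = ref_case,
             alt_ctrl = alt_ctrl, ref_ctrl = ref_ctrl,
             chisq = chisq, p = p, af_diff = af_diff, low_expected = low,
             row.names = NULL, stringsAsFactors = FALSE)
}

# minimum expected cell of each marker's 2x2 allele table
outer_min_expected <- function(alt_tot, ref_tot, n_case, n_ctrl, n_tot) {
  e11 <- alt_tot * n_case / n_tot
  e12 <- alt_tot * n_ctrl / n_tot
  e21 <- ref_tot * n_case / n_tot
  e22 <- ref_tot * n_ctrl / n_tot
  pmin(e11, e12, e21, e22)
}

#' Group significant markers into QTLs
#'
#' Single-linkage clustering per contig: markers on the same contig whose
#' adjacent distance is at or below `merge_dist` join the same QTL. QTL
#' names follow the `<trait><chromosome>.<index>` convention (e.g.
#' `heli11.1`), with the chromosome number parsed from the contig name and
#' indices assigned in position order along each chromosome.
#'
#' @param markers data.frame of significant markers: `id`, `contig`, `pos`,
#'   optionally `p`.
#' @param merge_dist merge distance in bp.
#' @param trait trait prefix for QTL names.
#' @return data.frame, one row per QTL: `qtl`, `contig`, `start`, `end`,
#'   `span`, `n_markers`, `top_p` (NA when no p supplied), plus a
#'   `members` attribute (data.frame `qtl`, `id`, `pos`).
#' @export
group_qtls <- function(markers, merge_dist = 10e6, trait = "qtl") {
  stopifnot(is.data.frame(markers),
            all(c("contig", "pos") %in% names(markers)))
  if (!nrow(markers)) {
    out <- data.frame(qtl = character(0), contig = character(0),
                      start = integer(0), end = integer(0), span = integer(0),
                      n_markers = integer(0), top_p = numeric(0))
    attr(out, "members") <- data.frame(qtl = character(0), id = character(0),
                                       pos = integer(0))
    return(out)
  }
  if (is.null(markers$id)) {
    markers$id <- paste(markers$contig, markers$pos, sep = "_")
  }
  markers <- markers[order(markers$contig, markers$pos), , drop = FALSE]
  qtls <- list()
  members <- list()
  for (ctg in unique(markers$contig)) {
    mm <- markers[markers$contig == ctg, , drop = FALSE]
    brk <- which(diff(mm$pos) > merge_dist)
    grp <- cumsum(c(1L, seq_along(mm$pos)[-1] %in% (brk + 1L)))
    chrom <- gsub("[^0-9]", "", ctg)
    chrom <- if (nzchar(chrom)) as.integer(chrom) else ctg
    for (g in unique(grp)) {
      sel <- mm[grp == g, , drop = FALSE]
      name <- paste0(trait, chrom, ".", g)
      qtls[[length(qtls) + 1L]] <- data.frame(
        qtl = name, contig = ctg, start = min(sel$pos), end = max(sel$pos),
        span = max(sel$pos) - min(sel$pos), n_markers = nrow(sel),
        top_p = if (is.null(sel$p)) NA_real_ else min(sel$p),
        stringsAsFactors = FALSE)
      members[[length(members) + 1L]] <- data.frame(
        qtl = name, id = sel$id, pos = sel$pos, stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, qtls)
  rownames(out) <- NULL
  attr(out, "members") <- do.call(rbind, members)
  out
}

#' Candidate gene window around a QTL
#'
#' The QTL span extended by `flank` bp on each side, clipped to the contig.
#'
#' @param qtl one row of a [group_qtls()] result (or any list with `contig`,
#'   `start`, `end`).
#' @param contig_lengths named vector of contig lengths.
#' @param flank extension in bp on each side.
#' @return Named integer vector `c(start, end)` (1-based inclusive).
#' @export
candidate_window <- function(qtl, contig_lengths, flank = 2e6) {
  ctg <- qtl$contig
  if (!ctg %in% names(contig_lengths)) stop("unknown contig: ", ctg)
  c(start = max(1, qtl$start - flank),
    end = min(as.numeric(contig_lengths[[ctg]]), qtl$end + flank))
}

#' Genes overlapping a candidate window
#'
#' Plain interval overlap of the window against a gene table, with half-open
#' `[start, end)` semantics on both sides.
#'
#' @param window vector `c(start, end)` as from [candidate_window()], plus a
#'   `contig` argument.
#' @param contig contig of the window.
#' @param genes data.frame: `gene_id`, `contig`, `start`, `end`.
#' @return Character vector of overlapping gene ids, in table order.
#' @export
annotate_window <- function(window, contig, genes) {
  stopifnot(is.data.frame(genes),
            all(c("gene_id", "contig", "start", "end") %in% names(genes)))
  hit <- genes$contig == contig &
    genes$start < window[["end"]] & genes$end > window[["start"]]
  genes$gene_id[hit]
}
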