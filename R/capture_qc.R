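#' Post-capture marker filtering thresholds
#'
#' After hybridization capture and genotyping, background markers are
#' removed when MAF < 0.05, missing rate > 0.1, or heterozygosity ratio
#' > 0.8. The boundaries themselves are kept: removal requires strict
#' inequality, matching the stated criteria.
#'
#' @param min_maf remove markers with MAF strictly below this.
#' @param max_missing remove markers with missing rate strictly above this.
#' @param max_het remove markers with het ratio strictly above this.
#' @return list of class `post_filter_thresholds`.
#' @export
post_filter_thresholds <- function(min_maf = 0.05, max_missing = 0.10,
                                   max_het = 0.80) {
  stopifnot(min_maf >= 0, min_maf <= 0.5, max_missing >= 0, max_missing <= 1,
            max_het >= 0, max_het <= 1)
  structure(list(min_maf = min_maf, max_missing = max_missing,
                 max_het = max_het),
            class = "post_filter_thresholds")
}

#' Per-sample capture ratio
#'
#' Fraction of panel probes for which the sample has at least `min_reads`
#' on-target reads.
#'
#' @param counts probes x samples non-negative integer count matrix with
#'   dimnames.
#' @param sample sample (column) name.
#' @param min_reads a probe counts as captured at `>=` this many reads.
#' @return Ratio in `[0, 1]`.
#' @export
capture_ratio <- function(counts, sample, min_reads = 1) {
  counts <- as.matrix(counts)
  if (!sample %in% colnames(counts)) stop("unknown sample: ", sample)
  mean(counts[, sample] >= min_reads)
}

#' Capture QC report
#'
#' Per-sample capture ratios plus panel-level summaries: the mean capture
#' ratio and the fraction of samples at or above the retention threshold.
#'
#' @param counts probes x samples count matrix.
#' @param min_reads per-probe capture threshold in reads.
#' @param retain_threshold per-sample retention bound (inclusive).
#' @return list of class `capture_report`: `capture_ratio` (named vector),
#'   `retained` (sample names), `mean_capture_ratio`,
#'   `frac_ge_threshold`, `min_reads`, `retain_threshold`.
#' @export
capture_report <- function(counts, min_reads = 1, retain_threshold = 0.70) {
  counts <- as.matrix(counts)
  if (ncol(counts) > 0 && is.null(colnames(counts))) {
    stop("counts must have sample column names")
  }
  cr <- colMeans(counts >= min_reads)
  structure(list(capture_ratio = cr,
                 retained = as.character(names(cr)[cr >= retain_threshold]),
                 mean_capture_ratio = mean(cr),
                 frac_ge_threshold = mean(cr >= retain_threshold),
                 min_reads = min_reads,
                 retain_threshold = retain_threshold),
            class = "capture_report")
}

#' @export
print.capture_report <- function(x, ...) {
  cat(sprintf(paste0("capture_report: %d samples, mean capture ratio %.4f,",
                     " %d retained at >= %.0f%%\n"),
              length(x$capture_ratio), x$mean_capture_ratio,
              length(x$retained), 100 * x$retain_threshold))
  invisible(x)
}

#' Retain samples by capture ratio
#'
#' Keeps samples whose capture ratio is at or above the threshold
#' (inclusive: a sample at exactly the bound is retained).
#'
#' @param report a [capture_report()].
#' @param threshold retention bound.
#' @return Character vector of retained sample names.
#' @export
retain_samples <- function(report, threshold = 0.70) {
  stopifnot(inherits(report, "capture_report"))
  as.character(names(report$capture_ratio)[report$capture_ratio >= threshold])
}

#' Per-site detection ratio
#'
#' Fraction of samples with a non-missing genotype call at each site (or at
#' one named site).
#'
#' @param gm a [genotype_matrix()].
#' @param site_id optional single site id; default all sites.
#' @return Named numeric vector of detection ratios.
#' @export
detection_ratio <- function(gm, site_id = NULL) {
  stopifnot(inherits(gm, "genotype_matrix"))
  dr <- rowMeans(!is.na(gm$calls))
  names(dr) <- gm$sites$id
  if (is.null(site_id)) return(dr)
  if (!site_id %in% names(dr)) stop("unknown site id: ", site_id)
  dr[[site_id]]
}

#' Post-capture marker filter
#'
#' Removes markers with MAF < `min_maf` OR missing rate > `max_missing` OR
#' het ratio > `max_het` (strict inequalities; boundary values are kept).
#' Markers with no data at all are removed with reason `no_data`.
#'
#' @param gm a [genotype_matrix()].
#' @param thresholds a [post_filter_thresholds()].
#' @return list: `kept` (site ids), `ledger` (data.frame `id`, `removed`,
#'   `reasons`).
#' @export
post_capture_filter <- function(gm, thresholds = post_filter_thresholds()) {
  stopifnot(inherits(gm, "genotype_matrix"),
            inherits(thresholds, "post_filter_thresholds"))
  st <- compute_site_stats(gm)
  reasons <- vector("list", nrow(st))
  for (i in seq_len(nrow(st))) {
    if (!st$defined[i]) {
      reasons[[i]] <- "no_data"
      next
    }
    r <- character(0)
    if (st$maf[i] < thresholds$min_maf) r <- c(r, "maf")
    if (st$missing_rate[i] > thresholds$max_missing) r <- c(r, "missing")
    if (st$het_rate[i] > thresholds$max_het) r <- c(r, "het")
    reasons[[i]] <- r
  }
  removed <- lengths(reasons) > 0
  list(kept = st$id[!removed],
       ledger = data.frame(id = st$id, removed = removed,
                           reasons = vapply(reasons, paste, character(1),
                                            collapse = ","),
                           row.names = NULL, stringsAsFactors = FALSE))
}

#' Phenotype-stratified allele-presence table
#'
#' For each requested site and each phenotype category, the percentage of
#' the category's samples (with a non-missing call at the site) whose
#' genotype contains at least one copy of the tracked allele — a dominant
#' presence coding. An alternative mode reports the tracked-allele frequency
#' instead. Rows are ordered by (contig, pos); a category with no
#' non-missing sample at a site yields `NA`.
#'
#' @param gm a [genotype_matrix()].
#' @param phenotypes data.frame with columns `sample`, `category`; every
#'   sample of `gm` must appear exactly once.
#' @param site_ids sites to tabulate (default: all).
#' @param tracked `"alt"`, `"ref"`, or a per-site character vector of the
#'   two.
#' @param mode `"presence"` (percent of carriers, default) or
#'   `"frequency"` (percent allele frequency).
#' @return data.frame: `id`, `contig`, `pos`, `tracked_allele`, then one
#'   percentage column per category (categories in first-appearance order,
#'   with `n_<category>` attribute-free counts appended as an attribute
#'   `category_n`).
#' @export
allele_presence_table <- function(gm, phenotypes, site_ids = NULL,
                                  tracked = "alt",
                                  mode = c("presence", "frequency")) {
  mode <- match.arg(mode)
  stopifnot(inherits(gm, "genotype_matrix"), is.data.frame(phenotypes),
            all(c("sample", "category") %in% names(phenotypes)))
  m <- match(gm$samples, phenotypes$sample)
  if (anyNA(m)) {
    stop("sample(s) without phenotype category: ",
         paste(gm$samples[is.na(m)], collapse = ", "))
  }
  category <- as.character(phenotypes$category[m])
  # column order follows the phenotype table, so it is invariant to any
  # permutation of the genotype matrix's sample order
  cats <- unique(as.character(phenotypes$category))
  cats <- cats[cats %in% category]
  if (is.null(site_ids)) site_ids <- gm$sites$id
  ri <- match(site_ids, gm$sites$id)
  if (anyNA(ri)) stop("unknown site id(s): ",
                      paste(site_ids[is.na(ri)], collapse = ", "))
  if (length(tracked) == 1) tracked <- rep(tracked, length(site_ids))
  stopifnot(length(tracked) == length(site_ids),
            all(tracked %in% c("ref", "alt")))
  o <- order(gm$sites$contig[ri], gm$sites$pos[ri])
  ri <- ri[o]; tracked <- tracked[o]; site_ids <- site_ids[o]
  out <- data.frame(id = site_ids,
                    contig = gm$sites$contig[ri],
                    pos = gm$sites$pos[ri],
                    tracked_allele = ifelse(tracked == "alt",
                                            gm$sites$alt[ri],
                                            gm$sites$ref[ri]),
                    stringsAsFactors = FALSE)
  for (cat_ in cats) {
    cols <- which(category == cat_)
    vals <- numeric(length(ri))
    for (k in seq_along(ri)) {
      calls <- gm$calls[ri[k], cols]
      calls <- calls[!is.na(calls)]
      if (!length(calls)) {
        vals[k] <- NA_real_
        next
      }
      if (mode == "presence") {
        carrier <- if (tracked[k] == "alt") calls >= 1L else calls <= 1L
        vals[k] <- 100 * mean(carrier)
      } else {
        af <- mean(calls) / 2
        vals[k] <- 100 * (if (tracked[k] == "alt") af else 1 - af)
      }
    }
    out[[cat_]] <- vals
  }
  attr(out, "category_n") <- table(factor(category, levels = cats))
  out
}
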