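#' Construct a genotype matrix
#'
#' The central container of the package: a set of biallelic variant sites
#' (SNPs and small indels) together with diploid genotype calls for a sample
#' panel, and optionally per-call sequencing depth.
#'
#' Calls are coded as integer alternate-allele dosages: `0` (homozygous
#' reference), `1` (heterozygous), `2` (homozygous alternate), `NA` (missing).
#' Missing calls carry no allele information and are excluded from all allele
#' counting downstream.
#'
#' @param sites data.frame with columns `contig`, `pos` (1-based), `ref`,
#'   `alt` and optionally `id` and `vclass`. `id` defaults to
#'   `<contig>_<pos>` (with an allele suffix when several sites share a
#'   position); `vclass` is derived: `"indel"` when `nchar(ref) != nchar(alt)`,
#'   otherwise `"snp"`.
#' @param samples character vector of sample names.
#' @param calls integer matrix, sites x samples, values in `{0, 1, 2, NA}`.
#' @param depth optional numeric matrix of per-call read depth, same
#'   dimensions as `calls`.
#' @return An object of class `genotype_matrix`: a list with elements
#'   `sites`, `samples`, `calls`, `depth`.
#' @examples
#' sites <- data.frame(contig = "c1", pos = c(10L, 20L), ref = "A", alt = "G")
#' gm <- genotype_matrix(sites, c("s1", "s2"),
#'                       matrix(c(0L, 1L, 2L, NA), nrow = 2))
#' gm
#' @export
genotype_matrix <- function(sites, samples, calls, depth = NULL) {
  stopifnot(is.data.frame(sites),
            all(c("contig", "pos", "ref", "alt") %in% names(sites)))
  sites$contig <- as.character(sites$contig)
  sites$pos <- as.integer(sites$pos)
  sites$ref <- as.character(sites$ref)
  sites$alt <- as.character(sites$alt)
  if (any(sites$pos < 1L)) stop("site positions must be >= 1")
  if (any(sites$ref == sites$alt)) stop("ref and alt alleles must differ")
  if (is.null(sites$vclass)) {
    sites$vclass <- ifelse(nchar(sites$ref) != nchar(sites$alt),
                           "indel", "snp")
  }
  if (is.null(sites$id)) {
    id <- paste(sites$contig, sites$pos, sep = "_")
    dup <- id %in% id[duplicated(id)]
    id[dup] <- paste(id[dup], sites$alt[dup], sep = "_")
    sites$id <- id
  }
  if (anyDuplicated(sites$id)) stop("site ids must be unique")
  samples <- as.character(samples)
  if (anyDuplicated(samples)) stop("sample names must be unique")
  calls <- as.matrix(calls)
  storage.mode(calls) <- "integer"
  if (nrow(calls) != nrow(sites) || ncol(calls) != length(samples)) {
    stop("calls must be a sites x samples matrix")
  }
  bad <- calls[!is.na(calls)]
  if (length(bad) && !all(bad %in% 0:2)) {
    stop("calls must be coded 0/1/2/NA")
  }
  dimnames(calls) <- list(sites$id, samples)
  if (!is.null(depth)) {
    depth <- as.matrix(depth)
    if (!all(dim(depth) == dim(calls))) {
      stop("depth must have the same dimensions as calls")
    }
    if (any(depth < 0, na.rm = TRUE)) stop("depth must be non-negative")
    dimnames(depth) <- dimnames(calls)
  }
  structure(list(sites = sites, samples = samples,
                 calls = calls, depth = depth),
            class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf("genotype_matrix: %d sites x %d samples (%s depth)\n",
              nrow(x$sites), length(x$samples),
              if (is.null(x$depth)) "no" else "with"))
  cat(sprintf("  contigs: %s\n",
              paste(unique(x$sites$contig), collapse = ", ")))
  invisible(x)
}

#' @export
dim.genotype_matrix <- function(x) dim(x$calls)

#' Alternate-allele dosage matrix
#'
#' @param gm a [genotype_matrix()].
#' @return Integer matrix of dosages (0/1/2, `NA` for missing), sites x
#'   samples.
#' @export
dosage <- function(gm) {
  stopifnot(inherits(gm, "genotype_matrix"))
  gm$calls
}

#' Subset a genotype matrix by site id and/or sample
#'
#' @param gm a [genotype_matrix()].
#' @param site_ids site ids to keep (default all, original order preserved).
#' @param samples sample names to keep (default all).
#' @return A new `genotype_matrix`.
#' @export
subset_genotypes <- function(gm, site_ids = NULL, samples = NULL) {
  stopifnot(inherits(gm, "genotype_matrix"))
  ri <- if (is.null(site_ids)) seq_len(nrow(gm$sites)) else {
    m <- match(site_ids, gm$sites$id)
    if (anyNA(m)) stop("unknown site id(s): ",
                       paste(site_ids[is.na(m)], collapse = ", "))
    sort(m)
  }
  ci <- if (is.null(samples)) seq_along(gm$samples) else {
    m <- match(samples, gm$samples)
    if (anyNA(m)) stop("unknown sample(s): ",
                       paste(samples[is.na(m)], collapse = ", "))
    m
  }
  genotype_matrix(gm$sites[ri, , drop = FALSE], gm$samples[ci],
                  gm$calls[ri, ci, drop = FALSE],
                  if (is.null(gm$depth)) NULL else gm$depth[ri, ci, drop = FALSE])
}

# order sites by (contig, pos); used before any windowed or spacing operation
sort_sites <- function(gm) {
  o <- order(gm$sites$contig, gm$sites$pos)
  if (all(o == seq_along(o))) return(gm)
  genotype_matrix(gm$sites[o, , drop = FALSE], gm$samples,
                  gm$calls[o, , drop = FALSE],
                  if (is.null(gm$depth)) NULL else gm$depth[o, , drop = FALSE])
}
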