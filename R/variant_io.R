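#' Read a reference genome from FASTA
#'
#' Loads all contigs, normalizes to uppercase, and enforces a strict
#' `A/C/G/T/N` alphabet: capture probe design needs unambiguous target
#' sequence, so any other IUPAC code is rejected with the offending contig
#' and offset rather than silently carried along.
#'
#' @param path FASTA file.
#' @return A [Biostrings::DNAStringSet] with unique contig names.
#' @export
read_genome_fasta <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  genome <- Biostrings::readDNAStringSet(path)
  nm <- names(genome)
  # keep only the first whitespace-delimited token of each header
  nm <- sub("\\s.*$", "", nm)
  if (any(nm == "")) stop("FASTA record with empty name")
  if (anyDuplicated(nm)) {
    stop("duplicate contig name(s): ",
         paste(unique(nm[duplicated(nm)]), collapse = ", "))
  }
  names(genome) <- nm
  af <- Biostrings::alphabetFrequency(genome)
  extra <- rowSums(af) - rowSums(af[, c("A", "C", "G", "T", "N"), drop = FALSE])
  if (any(extra > 0)) {
    i <- which(extra > 0)[1]
    chars <- strsplit(as.character(genome[[i]]), "")[[1]]
    off <- which(!chars %in% c("A", "C", "G", "T", "N"))[1]
    stop(sprintf("non-ACGTN character '%s' in contig %s at offset %d",
                 chars[off], nm[i], off))
  }
  genome
}

#' Contig lengths of a genome
#'
#' @param genome a [Biostrings::DNAStringSet].
#' @return Named integer vector of contig lengths in bp.
#' @export
genome_lengths <- function(genome) {
  stats::setNames(Biostrings::width(genome), names(genome))
}

# extract genome[contig][(start0, end0)] as a character string;
# start0/end0 are 0-based half-open (BED convention)
genome_slice <- function(genome, contig, start0, end0) {
  if (!contig %in% names(genome)) stop("unknown contig: ", contig)
  len <- length(genome[[contig]])
  if (start0 < 0 || end0 > len || start0 >= end0) {
    stop(sprintf("window [%d,%d) outside contig %s (length %d)",
                 start0, end0, contig, len))
  }
  as.character(Biostrings::subseq(genome[[contig]], start0 + 1L, end0))
}

#' Read a multi-sample VCF into a genotype matrix
#'
#' Diploid `GT` is required; `DP` is captured when present in FORMAT.
#' Multiallelic records are split into one biallelic site per ALT allele,
#' with genotypes recoded against that ALT (any other allele counts as
#' non-ALT); split sites sharing a position get ids `<contig>_<pos>_<alt>`.
#' `./.` and `.|.` become missing calls. Phased separators are treated the
#' same as unphased.
#'
#' @param path VCF file (plain or bgzipped).
#' @param samples optional subset of sample names to load; unknown names are
#'   an error.
#' @return A [genotype_matrix()].
#' @export
read_vcf <- function(path, samples = NULL) {
  if (!file.exists(path)) stop("no such file: ", path)
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  if (nrow(v@gt) == 0) stop("VCF has no genotype records")
  fmt <- strsplit(v@gt[, "FORMAT"], ":", fixed = TRUE)
  if (!all(vapply(fmt, function(f) "GT" %in% f, logical(1)))) {
    stop("VCF records without a GT field")
  }
  gt <- vcfR::extract.gt(v, element = "GT", convertNA = FALSE)
  has_dp <- all(vapply(fmt, function(f) "DP" %in% f, logical(1)))
  dp <- if (has_dp) vcfR::extract.gt(v, element = "DP", as.numeric = TRUE) else NULL
  all_samples <- colnames(gt)
  if (!is.null(samples)) {
    miss <- setdiff(samples, all_samples)
    if (length(miss)) stop("sample(s) not in VCF: ", paste(miss, collapse = ", "))
    gt <- gt[, samples, drop = FALSE]
    if (!is.null(dp)) dp <- dp[, samples, drop = FALSE]
    all_samples <- samples
  }
  fix <- v@fix
  contig <- fix[, "CHROM"]
  pos <- as.integer(fix[, "POS"])
  ref <- fix[, "REF"]
  alt_list <- strsplit(fix[, "ALT"], ",", fixed = TRUE)

  out_sites <- vector("list", length(alt_list))
  out_calls <- vector("list", length(alt_list))
  out_depth <- vector("list", length(alt_list))
  for (r in seq_along(alt_list)) {
    alleles <- parse_gt_row(gt[r, ])
    alts <- alt_list[[r]]
    sites_r <- data.frame(contig = unname(contig[r]), pos = pos[r],
                          ref = unname(ref[r]), alt = alts,
                          row.names = NULL, stringsAsFactors = FALSE)
    calls_r <- matrix(NA_integer_, nrow = length(alts), ncol = length(all_samples))
    for (k in seq_along(alts)) {
      calls_r[k, ] <- ifelse(is.na(alleles$a1), NA_integer_,
                             (alleles$a1 == k) + (alleles$a2 == k))
    }
    out_sites[[r]] <- sites_r
    out_calls[[r]] <- calls_r
    if (!is.null(dp)) {
      out_depth[[r]] <- matrix(rep(dp[r, ], each = length(alts)),
                               nrow = length(alts))
    }
  }
  sites <- do.call(rbind, out_sites)
  calls <- do.call(rbind, out_calls)
  depth <- if (has_dp) do.call(rbind, out_depth) else NULL
  genotype_matrix(sites, all_samples, calls, depth)
}

# split diploid GT strings into two allele indices (NA for '.')
parse_gt_row <- function(g) {
  g[is.na(g)] <- "./."
  parts <- strsplit(g, "[/|]")
  n_alleles <- lengths(parts)
  if (any(n_alleles != 2)) {
    stop("non-diploid GT encountered (", g[which(n_alleles != 2)[1]],
         "); only diploid calls are supported")
  }
  m <- matrix(unlist(parts), nrow = 2)
  a1 <- suppressWarnings(as.integer(m[1, ]))
  a2 <- suppressWarnings(as.integer(m[2, ]))
  half <- xor(is.na(a1), is.na(a2))
  if (any(half)) stop("half-missing genotypes (e.g. './1') are not supported")
  list(a1 = a1, a2 = a2)
}

#' Write a genotype matrix as VCF
#'
#' Emits a minimal VCF 4.2 with `GT` (and `DP` when the matrix carries
#' depth), suitable for round-tripping through [read_vcf()]. Output is
#' bgzip-compressed when `path` ends in `.gz`, plain text otherwise.
#'
#' @param gm a [genotype_matrix()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(gm, path) {
  stopifnot(inherits(gm, "genotype_matrix"))
  s <- gm$sites
  gt_code <- c("0/0", "0/1", "1/1")
  gt <- matrix("./.", nrow = nrow(s), ncol = length(gm$samples))
  ok <- !is.na(gm$calls)
  gt[ok] <- gt_code[gm$calls[ok] + 1L]
  if (!is.null(gm$depth)) {
    dp <- gm$depth
    dp_chr <- ifelse(is.na(dp), ".", format(dp, trim = TRUE, scientific = FALSE))
    gt <- matrix(paste(gt, dp_chr, sep = ":"), nrow = nrow(s))
    fmt <- "GT:DP"
  } else {
    fmt <- "GT"
  }
  header <- c("##fileformat=VCFv4.2",
              '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
              if (!is.null(gm$depth))
                '##FORMAT=<ID=DP,Number=1,Type=Integer,Description="Read depth">',
              paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                      "INFO", "FORMAT", gm$samples), collapse = "\t"))
  body <- paste(s$contig, s$pos, s$id, s$ref, s$alt, ".", ".", ".", fmt,
                apply(gt, 1, paste, collapse = "\t"), sep = "\t")
  con <- if (grepl("\\.gz$", path)) gzfile(path, "w") else file(path, "w")
  on.exit(close(con))
  writeLines(c(header, body), con)
  invisible(path)
}

#' Write panel probe windows as BED6
#'
#' One line per probe window with 0-based half-open coordinates, the probe id
#' as name, the number of oligos the site needs (1, or 2 for strand-ambiguous
#' A/T and C/G SNPs) as score, and strand `+`. Lines are sorted by
#' (contig, start).
#'
#' @param panel a [build_panel()] result, or any data.frame with columns
#'   `id`, `contig`, `start0`, `end0`, `probes_required`.
#' @param path output BED file.
#' @return `path`, invisibly.
#' @export
write_probe_bed <- function(panel, path) {
  pr <- panel_probe_table(panel)
  if (nrow(pr)) {
    lens <- attr(pr, "contig_lengths")
    if (!is.null(lens)) {
      bad <- pr$start0 < 0 | pr$end0 > lens[pr$contig]
      if (any(bad)) {
        stop("probe window outside contig bounds: ",
             paste(pr$id[bad], collapse = ", "))
      }
    }
    pr <- pr[order(pr$contig, pr$start0), , drop = FALSE]
    lines <- paste(pr$contig, pr$start0, pr$end0, pr$id,
                   pr$probes_required, "+", sep = "\t")
  } else {
    lines <- character(0)
  }
  writeLines(lines, path)
  invisible(path)
}

#' Write probe sequences as FASTA
#'
#' Each probe record is the genome slice of its designed window (exactly the
#' probe length, 110 bp by default). Strand-ambiguous sites (A/T or C/G SNPs)
#' need a probe for each strand, so they emit two records with `_fw` / `_rc`
#' suffixes, the second being the reverse complement of the first.
#'
#' @param panel a [build_panel()] result or compatible probe data.frame.
#' @param genome the [Biostrings::DNAStringSet] the windows refer to.
#' @param path output FASTA file.
#' @return `path`, invisibly.
#' @export
write_probe_fasta <- function(panel, genome, path) {
  pr <- panel_probe_table(panel)
  ids <- character(0)
  seqs <- character(0)
  for (i in seq_len(nrow(pr))) {
    sq <- genome_slice(genome, pr$contig[i], pr$start0[i], pr$end0[i])
    if (grepl("N", sq, fixed = TRUE)) {
      stop("probe window for ", pr$id[i],
           " contains N; it should have been rejected at design time")
    }
    if (pr$probes_required[i] == 2L) {
      ids <- c(ids, paste0(pr$id[i], "_fw"), paste0(pr$id[i], "_rc"))
      seqs <- c(seqs, sq, as.character(
        Biostrings::reverseComplement(Biostrings::DNAString(sq))))
    } else {
      ids <- c(ids, pr$id[i])
      seqs <- c(seqs, sq)
    }
  }
  out <- Biostrings::DNAStringSet(seqs)
  names(out) <- ids
  Biostrings::writeXStringSet(out, path)
  invisible(path)
}

# accept either a panel object or a bare probe data.frame
panel_probe_table <- function(panel) {
  if (inherits(panel, "probe_panel")) {
    pr <- panel$probes[panel$probes$window_ok, , drop = FALSE]
    attr(pr, "contig_lengths") <- panel$contig_lengths
    return(pr)
  }
  stopifnot(is.data.frame(panel),
            all(c("id", "contig", "start0", "end0", "probes_required") %in%
                  names(panel)))
  panel
}

#' Write a site table as TSV
#'
#' @param sites data.frame of sites (`contig`, `pos`, `ref`, `alt`, ...).
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_site_tsv <- function(sites, path) {
  utils::write.table(sites, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
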