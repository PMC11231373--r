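#' Simulate a reference genome with planted features
#'
#' Bases are drawn i.i.d. at the target GC content, then the requested
#' microsatellites (SSRs) and duplicated segments are written over the
#' random background at recorded positions, so every planted feature is
#' recoverable by the corresponding pipeline stage ([detect_ssr()],
#' [single_copy_check()]). Fully reproducible per seed. Planted features
#' may not overlap one another.
#'
#' @param contig_lengths named integer vector of contig lengths (bp).
#' @param gc_target target GC fraction of the random background.
#' @param ssrs optional data.frame of SSRs to plant: `contig`, `pos`
#'   (1-based start), `motif`, `copies`.
#' @param duplications optional data.frame of segmental duplications:
#'   `contig`, `src_start` (1-based), `length`, `dest_contig`, `dest_start`;
#'   the source segment is copied over the destination.
#' @param seed RNG seed (mandatory).
#' @return list: `genome` (a [Biostrings::DNAStringSet]) and `truth` (the
#'   planted feature tables with realized coordinates).
#' @export
simulate_genome <- function(contig_lengths, gc_target = 0.40, ssrs = NULL,
                            duplications = NULL, seed) {
  stopifnot(!missing(seed), !is.null(names(contig_lengths)),
            gc_target > 0, gc_target < 1)
  withr::with_seed(seed, {
    probs <- c(A = (1 - gc_target) / 2, C = gc_target / 2,
               G = gc_target / 2, T = (1 - gc_target) / 2)
    seqs <- lapply(contig_lengths, function(len) {
      sample(names(probs), len, replace = TRUE, prob = probs)
    })
    planted <- list()
    plant <- function(contig, start, end) {
      iv <- data.frame(contig = contig, start = start, end = end)
      for (p in planted) {
        if (p$contig == contig && start <= p$end && end >= p$start) {
          stop("planted features overlap on ", contig)
        }
      }
      planted[[length(planted) + 1L]] <<- iv
    }
    if (!is.null(ssrs)) {
      for (i in seq_len(nrow(ssrs))) {
        ctg <- ssrs$contig[i]
        rep_str <- strrep(ssrs$motif[i], ssrs$copies[i])
        chars <- strsplit(rep_str, "", fixed = TRUE)[[1]]
        from <- ssrs$pos[i]
        to <- from + length(chars) - 1L
        if (to > contig_lengths[[ctg]]) stop("SSR extends past contig end")
        plant(ctg, from, to)
        seqs[[ctg]][from:to] <- chars
      }
    }
    if (!is.null(duplications)) {
      for (i in seq_len(nrow(duplications))) {
        d <- duplications[i, ]
        src <- seqs[[d$contig]][d$src_start:(d$src_start + d$length - 1L)]
        to <- d$dest_start + d$length - 1L
        if (to > contig_lengths[[d$dest_contig]]) {
          stop("duplication extends past contig end")
        }
        plant(d$contig, d$src_start, d$src_start + d$length - 1L)
        plant(d$dest_contig, d$dest_start, to)
        seqs[[d$dest_contig]][d$dest_start:to] <- src
      }
    }
    genome <- Biostrings::DNAStringSet(vapply(seqs, paste, character(1),
                                              collapse = ""))
    names(genome) <- names(contig_lengths)
    list(genome = genome,
         truth = list(ssrs = ssrs, duplications = duplications,
                      gc_target = gc_target, seed = seed))
  })
}

#' Simulate a genotyped population
#'
#' Variant positions are drawn uniformly over non-N genome positions (or
#' supplied). True minor allele frequencies come from `maf`; haplotypes are
#' drawn at those frequencies, optionally with linkage blocks (sites in a
#' block copy a latent block haplotype with fidelity `sqrt(r2_target)`,
#' giving dosage r-squared near the target). An `inbreeding` fraction of
#' samples are fully selfed lines (their second haplotype duplicates the
#' first), emulating the largely homozygous germplasm collections such
#' panels genotype; the remainder follow Hardy-Weinberg. A het-excess step
#' then converts a fraction of homozygous calls to heterozygous (emulating
#' paralog collapse), and finally independent missingness masks calls.
#' Per-call depth, when requested, is negative-binomial.
#'
#' @param genome a [Biostrings::DNAStringSet] (from [simulate_genome()] or
#'   [read_genome_fasta()]).
#' @param n_samples number of diploid samples.
#' @param n_sites number of biallelic SNP sites.
#' @param maf true minor allele frequencies: a single value, a vector to
#'   sample from, or a vector of length `n_sites` used as-is.
#' @param missing_rate per-call missing probability (scalar or per-site
#'   vector).
#' @param inbreeding fraction of samples that are fully selfed
#'   (homozygous) lines.
#' @param het_excess probability that a homozygous call is converted to a
#'   heterozygous one.
#' @param ld_block_size sites per linkage block (`NULL` or 1 = independent
#'   sites).
#' @param ld_r2_target within-block dosage r-squared target.
#' @param depth_mean mean per-call depth (`NULL` = no depth matrix).
#' @param depth_dispersion negative-binomial size parameter.
#' @param positions optional data.frame `contig`, `pos` to use instead of
#'   uniform placement.
#' @param seed RNG seed (mandatory).
#' @return list: `gm` (a [genotype_matrix()], sites sorted by contig and
#'   position) and `truth` (per-site true MAF and block index, sample
#'   names).
#' @export
simulate_population <- function(genome, n_samples, n_sites, maf = 0.25,
                                missing_rate = 0, inbreeding = 0.95,
                                het_excess = 0,
                                ld_block_size = NULL, ld_r2_target = 0.9,
                                depth_mean = NULL, depth_dispersion = 5,
                                positions = NULL, seed) {
  stopifnot(!missing(seed), n_samples >= 1, n_sites >= 1,
            inbreeding >= 0, inbreeding <= 1)
  withr::with_seed(seed, {
    if (is.null(positions)) {
      lens <- genome_lengths(genome)
      avail <- lapply(names(lens), function(ctg) {
        chars <- strsplit(as.character(genome[[ctg]]), "", fixed = TRUE)[[1]]
        which(chars != "N")
      })
      names(avail) <- names(lens)
      total <- sum(lengths(avail))
      if (n_sites > total) stop("n_sites exceeds available non-N positions")
      ctg_pick <- sample(rep(names(lens), lengths(avail)), n_sites)
      pos <- integer(n_sites)
      for (ctg in unique(ctg_pick)) {
        k <- sum(ctg_pick == ctg)
        pos[ctg_pick == ctg] <- sample(avail[[ctg]], k)
      }
      positions <- data.frame(contig = ctg_pick, pos = pos,
                              stringsAsFactors = FALSE)
    }
    stopifnot(nrow(positions) == n_sites)
    positions <- positions[order(positions$contig, positions$pos), ,
                           drop = FALSE]
    ref <- vapply(seq_len(n_sites), function(i) {
      genome_slice(genome, positions$contig[i], positions$pos[i] - 1L,
                   positions$pos[i])
    }, character(1))
    alt <- vapply(ref, function(r) {
      sample(setdiff(c("A", "C", "G", "T"), r), 1)
    }, character(1), USE.NAMES = FALSE)

    true_maf <- if (length(maf) == n_sites) maf else
      sample(maf, n_sites, replace = TRUE)
    stopifnot(all(true_maf >= 0 & true_maf <= 0.5))

    block <- if (is.null(ld_block_size) || ld_block_size <= 1) {
      seq_len(n_sites)
    } else {
      rep(seq_len(ceiling(n_sites / ld_block_size)),
          each = ld_block_size)[seq_len(n_sites)]
    }
    fidelity <- sqrt(ld_r2_target)
    selfed <- stats::runif(n_samples) < inbreeding
    calls <- matrix(NA_integer_, n_sites, n_samples)
    for (b in unique(block)) {
      idx <- which(block == b)
      # latent block haplotypes at the block's first site frequency
      tag1 <- stats::rbinom(n_samples, 1, true_maf[idx[1]])
      tag2 <- stats::rbinom(n_samples, 1, true_maf[idx[1]])
      for (i in idx) {
        p <- true_maf[i]
        if (length(idx) > 1) {
          cpy <- stats::runif(n_samples) < fidelity
          h1 <- ifelse(cpy, tag1, stats::rbinom(n_samples, 1, p))
          cpy <- stats::runif(n_samples) < fidelity
          h2 <- ifelse(cpy, tag2, stats::rbinom(n_samples, 1, p))
        } else {
          h1 <- stats::rbinom(n_samples, 1, p)
          h2 <- stats::rbinom(n_samples, 1, p)
        }
        h2[selfed] <- h1[selfed]
        calls[i, ] <- h1 + h2
      }
    }
    if (het_excess > 0) {
      hom <- calls %in% c(0L, 2L)
      flip <- hom & stats::runif(length(calls)) < het_excess
      calls[flip] <- 1L
    }
    if (any(missing_rate > 0)) {
      mr <- if (length(missing_rate) == n_sites) missing_rate else
        rep(missing_rate[1], n_sites)
      mask <- matrix(stats::runif(length(calls)), n_sites) < mr
      calls[mask] <- NA_integer_
    }
    depth <- NULL
    if (!is.null(depth_mean)) {
      depth <- matrix(stats::rnbinom(length(calls), mu = depth_mean,
                                     size = depth_dispersion),
                      n_sites, n_samples)
    }
    samples <- sprintf("S%03d", seq_len(n_samples))
    gm <- genotype_matrix(
      data.frame(contig = positions$contig, pos = positions$pos,
                 ref = ref, alt = alt, stringsAsFactors = FALSE),
      samples, calls, depth)
    list(gm = gm,
         truth = list(true_maf = stats::setNames(true_maf, gm$sites$id),
                      block = stats::setNames(block, gm$sites$id),
                      samples = samples, seed = seed))
  })
}

#' Simulate on-target capture read counts
#'
#' Per probe and sample the count is zero with the dropout probability,
#' otherwise a negative-binomial draw truncated below at one read (a
#' captured probe always yields at least one on-target read). Per-sample
#' dropout multipliers allow planting low-quality samples.
#'
#' @param probe_ids character vector of probe ids.
#' @param samples character vector of sample names.
#' @param dropout baseline per-probe dropout probability.
#' @param depth_mean mean on-target read count for captured probes.
#' @param depth_dispersion negative-binomial size parameter.
#' @param sample_dropout named vector of per-sample dropout probabilities
#'   overriding the baseline.
#' @param seed RNG seed (mandatory).
#' @return probes x samples integer count matrix with dimnames.
#' @export
simulate_capture <- function(probe_ids, samples, dropout = 0,
                             depth_mean = 100, depth_dispersion = 5,
                             sample_dropout = NULL, seed) {
  stopifnot(!missing(seed), dropout >= 0, dropout <= 1)
  withr::with_seed(seed, {
    np <- length(probe_ids)
    ns <- length(samples)
    drop_p <- rep(dropout, ns)
    names(drop_p) <- samples
    if (!is.null(sample_dropout)) {
      stopifnot(all(names(sample_dropout) %in% samples))
      drop_p[names(sample_dropout)] <- sample_dropout
    }
    counts <- matrix(0L, np, ns, dimnames = list(probe_ids, samples))
    for (j in seq_len(ns)) {
      dropped <- stats::runif(np) < drop_p[j]
      x <- stats::rnbinom(np, mu = depth_mean, size = depth_dispersion)
      x <- pmax(x, 1L)
      x[dropped] <- 0L
      counts[, j] <- x
    }
    counts
  })
}

#' Assign phenotypes from planted causal genotypes
#'
#' Binary trait: a sample carrying at least one alternate allele at the
#' causal site is a case with probability `penetrance_carrier`, otherwise
#' with probability `penetrance_noncarrier`. Categorical trait: the class is
#' `1 + (number of designated block sites at which the sample carries the
#' alternate allele)`, capped at `k`, then reassigned uniformly at random
#' with probability `noise`.
#'
#' @param gm a [genotype_matrix()].
#' @param causal_id causal site id (binary trait); must be polymorphic.
#' @param penetrance_carrier,penetrance_noncarrier case probabilities.
#' @param class_sites optional site ids defining a categorical trait.
#' @param k number of categorical classes (needed with `class_sites`).
#' @param noise class-confusion probability.
#' @param seed RNG seed (mandatory).
#' @return list: `phenotypes` (data.frame `sample`, `case` logical, and
#'   `class` when categorical) and `truth` (the generating parameters and
#'   per-sample carrier status).
#' @export
assign_phenotypes <- function(gm, causal_id, penetrance_carrier = 0.9,
                              penetrance_noncarrier = 0.1,
                              class_sites = NULL, k = NULL, noise = 0,
                              seed) {
  stopifnot(!missing(seed), inherits(gm, "genotype_matrix"))
  i <- match(causal_id, gm$sites$id)
  if (is.na(i)) stop("unknown causal site id: ", causal_id)
  g <- gm$calls[i, ]
  if (length(unique(g[!is.na(g)])) < 2) stop("causal site is monomorphic")
  withr::with_seed(seed, {
    carrier <- !is.na(g) & g >= 1L
    p_case <- ifelse(carrier, penetrance_carrier, penetrance_noncarrier)
    case <- stats::runif(length(g)) < p_case
    out <- data.frame(sample = gm$samples, case = case,
                      stringsAsFactors = FALSE)
    truth <- list(causal_id = causal_id, carrier = carrier,
                  penetrance_carrier = penetrance_carrier,
                  penetrance_noncarrier = penetrance_noncarrier, seed = seed)
    if (!is.null(class_sites)) {
      stopifnot(!is.null(k), k >= 2)
      ci <- match(class_sites, gm$sites$id)
      if (anyNA(ci)) stop("unknown class site id(s)")
      carriers <- colSums(gm$calls[ci, , drop = FALSE] >= 1L, na.rm = TRUE)
      cls <- pmin(1L + carriers, k)
      confuse <- stats::runif(length(cls)) < noise
      cls[confuse] <- sample.int(k, sum(confuse), replace = TRUE)
      out$class <- cls
      truth$class_sites <- class_sites
      truth$true_class <- pmin(1L + carriers, k)
    }
    list(phenotypes = out, truth = truth)
  })
}
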