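# Independent reference implementations used to cross-check the package's
# algorithmic primitives on small instances.

# Naive O(n^2 * 6) SSR scanner: for every motif length and start position,
# extend the periodic region base by base. Reports maximal runs of primitive
# motifs meeting the copy thresholds, with the same interval and motif
# conventions as detect_ssr (full run incl. partial copy, canonical motif).
naive_ssr_scan <- function(sequence, spec = ssr_spec()) {
  s <- strsplit(toupper(sequence), "", fixed = TRUE)[[1]]
  n <- length(s)
  rows <- list()
  for (k in 1:6) {
    a <- 1L
    while (a + 2L * k - 1L <= n) {
      # is a the start of a maximal k-periodic region?
      left_ext <- a > 1L && s[a - 1L] == safe_at(s, a - 1L + k) &&
        s[a - 1L] != "N"
      if (!left_ext) {
        b <- a + k - 1L
        while (b + 1L <= n && s[b + 1L] == s[b + 1L - k] &&
               s[b + 1L - k] != "N") {
          b <- b + 1L
        }
        run_len <- b - a + 1L
        copies <- run_len %/% k
        if (run_len >= 2L * k && copies >= spec$min_copies[k]) {
          motif <- paste(s[a:(a + k - 1L)], collapse = "")
          if (oracle_primitive(motif)) {
            rows[[length(rows) + 1L]] <- data.frame(
              start = a - 1L, end = a - 1L + run_len,
              motif = oracle_canonical(motif), copies = copies,
              stringsAsFactors = FALSE)
          }
        }
      }
      a <- a + 1L
    }
  }
  if (!length(rows)) {
    return(data.frame(start = integer(0), end = integer(0),
                      motif = character(0), copies = integer(0)))
  }
  out <- unique(do.call(rbind, rows))
  # drop intervals contained in a longer same-motif interval
  keep <- vapply(seq_len(nrow(out)), function(i) {
    !any(out$motif == out$motif[i] & out$start <= out$start[i] &
           out$end >= out$end[i] &
           (out$end - out$start) > (out$end[i] - out$start[i]))
  }, logical(1))
  out <- out[keep, , drop = FALSE]
  out <- out[order(out$start, out$end), , drop = FALSE]
  rownames(out) <- NULL
  out
}

safe_at <- function(s, i) if (i >= 1 && i <= length(s)) s[i] else ""

oracle_primitive <- function(motif) {
  k <- nchar(motif)
  if (k == 1) return(TRUE)
  !any(vapply(seq_len(k - 1), function(d) {
    k %% d == 0 && motif == strrep(substr(motif, 1, d), k / d)
  }, logical(1)))
}

oracle_canonical <- function(motif) {
  k <- nchar(motif)
  rot <- vapply(seq_len(k), function(i) {
    paste0(substr(motif, i, k), substr(motif, 1, i - 1))
  }, character(1))
  min(rot)
}

# Brute-force single-window LD pruner: full r2 matrix, repeatedly remove the
# lower-MAF member of the worst pair (same tie rules as ld_prune) until no
# pair reaches max_r2. Works directly on the dosage matrix.
brute_ld_prune <- function(gm, max_r2 = 0.4) {
  st <- compute_site_stats(gm)
  maf <- st$maf
  pos <- gm$sites$pos
  alive <- seq_len(nrow(gm$sites))
  repeat {
    if (length(alive) < 2) break
    worst <- -1
    worst_pair <- NULL
    for (ii in seq_along(alive)) {
      for (jj in seq_along(alive)) {
        if (ii >= jj) next
        a <- gm$calls[alive[ii], ]
        b <- gm$calls[alive[jj], ]
        ok <- !is.na(a) & !is.na(b)
        if (sum(ok) < 2) next
        if (sd(a[ok]) == 0 || sd(b[ok]) == 0) next
        r2 <- cor(a[ok], b[ok])^2
        if (r2 > worst + 1e-12 && r2 >= max_r2) {
          worst <- r2
          worst_pair <- c(alive[ii], alive[jj])
        }
      }
    }
    if (is.null(worst_pair)) break
    a <- worst_pair[1]
    b <- worst_pair[2]
    drop_site <- if (maf[a] < maf[b]) a
      else if (maf[b] < maf[a]) b
      else if (pos[a] >= pos[b]) a else b
    alive <- setdiff(alive, drop_site)
  }
  gm$sites$id[alive]
}

# Direct-formula VanRaden kinship: explicit loops, no matrix algebra.
direct_kinship <- function(d) {
  p <- rowMeans(d) / 2
  poly <- p > 0 & p < 1
  d <- d[poly, , drop = FALSE]
  p <- p[poly]
  denom <- sum(2 * p * (1 - p))
  ns <- ncol(d)
  k <- matrix(0, ns, ns)
  for (a in seq_len(ns)) {
    for (b in seq_len(ns)) {
      k[a, b] <- sum((d[, a] - 2 * p) * (d[, b] - 2 * p)) / denom
    }
  }
  k
}

# Naive window/gene overlap with half-open semantics.
naive_overlap <- function(win_start, win_end, genes, contig) {
  ids <- character(0)
  for (i in seq_len(nrow(genes))) {
    if (genes$contig[i] == contig &&
        genes$start[i] < win_end && genes$end[i] > win_start) {
      ids <- c(ids, genes$gene_id[i])
    }
  }
  ids
}
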