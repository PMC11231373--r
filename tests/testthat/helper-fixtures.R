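# Small fixture builders shared across test files.

# genotype_matrix from a bare dosage matrix (sites in rows)
gm_from_dosage <- function(d, contig = "c1", pos = NULL, ref = "A",
                           alt = "G", depth = NULL) {
  d <- as.matrix(d)
  if (is.null(pos)) pos <- seq_len(nrow(d)) * 100L
  sites <- data.frame(contig = contig, pos = pos,
                      ref = ref, alt = alt, stringsAsFactors = FALSE)
  genotype_matrix(sites, sprintf("s%02d", seq_len(ncol(d))), d, depth)
}

# uniform-ish random test genome without planted features
test_genome <- function(len = 5e4, seed = 1, gc = 0.5) {
  simulate_genome(c(c1 = as.integer(len)), gc_target = gc, seed = seed)$genome
}

random_seq <- function(n, gc = 0.5) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE,
               prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
        collapse = "")
}

write_fasta_lines <- function(lines) {
  f <- withr::local_tempfile(fileext = ".fa", .local_envir = parent.frame())
  writeLines(lines, f)
  f
}

write_vcf_lines <- function(body, samples = c("S1", "S2", "S3"),
                            format = "GT") {
  f <- withr::local_tempfile(fileext = ".vcf", .local_envir = parent.frame())
  writeLines(c("##fileformat=VCFv4.2",
               paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                       "INFO", "FORMAT", samples), collapse = "\t"),
               body), f)
  f
}
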