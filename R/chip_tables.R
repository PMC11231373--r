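#' Published 45K pepper chip reference tables
#'
#' The package ships the headline tables of the published 45K pepper GBTS
#' liquid-phase chip as plain-text data: the per-trait foreground site
#' counts, the panel role decomposition, and the significant helical-fruit
#' GWAS markers. They serve as worked inputs for the reporting functions
#' ([summarize_trait_catalog()], [group_qtls()], [candidate_window()]) and
#' as fixed points the test suite replays.
#'
#' @return
#' `pepper_trait_counts()`: data.frame `trait`, `n_sites` (43 traits).
#'
#' `pepper_panel_roles()`: data.frame `role`, `n_sites` (foreground,
#' functional_segment, background).
#'
#' `pepper_heli_markers()`: data.frame `qtl`, `contig`, `pos`,
#' `gene_context`, `p_value`, `contribution` (9 markers).
#' @name chip_tables
NULL

chip_table <- function(file) {
  path <- system.file("extdata", file, package = "panelsnp")
  if (path == "") path <- file.path("inst", "extdata", file)
  utils::read.delim(path, stringsAsFactors = FALSE)
}

#' @rdname chip_tables
#' @export
pepper_trait_counts <- function() chip_table("pepper45k_trait_counts.tsv")

#' @rdname chip_tables
#' @export
pepper_panel_roles <- function() chip_table("pepper45k_panel_roles.tsv")

#' @rdname chip_tables
#' @export
pepper_heli_markers <- function() chip_table("pepper45k_heli_markers.tsv")

#' Expand per-trait counts into a site-level trait catalog
#'
#' Builds a registry with one row per (trait, site) from a per-trait count
#' table, assigning synthetic site ids `<trait slug>_<k>`. Useful for
#' replaying published count tables through [summarize_trait_catalog()]
#' when the underlying site coordinates are not distributed.
#'
#' @param counts data.frame `trait`, `n_sites`.
#' @return data.frame `trait`, `id`.
#' @export
expand_trait_catalog <- function(counts) {
  stopifnot(is.data.frame(counts),
            all(c("trait", "n_sites") %in% names(counts)))
  trait <- rep(counts$trait, counts$n_sites)
  slug <- gsub("[^A-Za-z0-9]+", "_", trait)
  id <- paste0(slug, "_", unlist(lapply(counts$n_sites, seq_len)))
  data.frame(trait = trait, id = id, stringsAsFactors = FALSE)
}
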