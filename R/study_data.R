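#' Sample table of the lowland-tapir cytochrome-b survey
#'
#' The published sample inventory: 45 lowland tapirs (plus 3 mountain
#' tapirs) with sampling site, geographic group, ecogeographic unit and
#' haplotype assignment.  Haplotype labels follow the survey (`Hte` for
#' lowland, `Hpi` for mountain tapir); two haplotypes (Hte 2, Hte 13) are
#' shared between two sampling sites, and their per-site counts follow from
#' the sample rows.  This table alone supports the haplotype-frequency
#' statistics (gene diversity by any grouping); sequence-based statistics
#' need the deposited sequences.
#'
#' @return data frame with `sample_id`, `site_id`, `group`, `ecoregion`,
#'   `haplotype`, `species`.
#' @export
tapir_study_samples <- function() {
  row <- function(ids, site, group, eco, hap, sp = "T. terrestris") {
    data.frame(sample_id = ids, site_id = as.character(site), group = group,
               ecoregion = eco, haplotype = hap, species = sp,
               stringsAsFactors = FALSE)
  }
  ne <- "North-East Amazon rainforest"
  ua <- "Upper Amazon rainforest"
  rbind(
    row(c("TG01", "TG06", "TG29"), 1, "North Amazon", ne, "Hte 1"),
    row("TG28", 1, "North Amazon", ne, "Hte 2"),
    row("TG5", 1, "North Amazon", ne, "Hte 3"),
    row("TG24", 1, "North Amazon", ne, "Hte 7"),
    row("TC54", 2, "North Amazon", ne, "Hte 11"),
    row("TC186", 2, "North Amazon", ne, "Hte 19"),
    row("TB01", 3, "North Amazon", ne, "Hte 14"),
    row("TB02", 3, "North Amazon", ne, "Hte 15"),
    row(c("TE17", "TE22"), 4, "Andean Foothill", ua, "Hte 4"),
    row("TE14", 4, "Andean Foothill", ua, "Hte 5"),
    row("TE19", 4, "Andean Foothill", ua, "Hte 6"),
    row("TE20", 4, "Andean Foothill", ua, "Hte 8"),
    row("TE16", 4, "Andean Foothill", ua, "Hte 9"),
    row("TP104", 5, "West Amazon", ua, "Hte 12"),
    row("TP94", 5, "West Amazon", ua, "Hte 16"),
    row("TP14", 6, "Andean Foothill", ua, "Hte 13"),
    row("TP4", 6, "Andean Foothill", ua, "Hte 23"),
    row(c("TP12", "TP13"), 6, "Andean Foothill", ua, "Hte 24"),
    row("TP11", 6, "Andean Foothill", ua, "Hte 25"),
    row("TP9", 6, "Andean Foothill", ua, "Hte 26"),
    row(c("TP6", "TP7"), 6, "Andean Foothill", ua, "Hte 27"),
    row(c("TP5", "TP2"), 6, "Andean Foothill", ua, "Hte 28"),
    row("TP3", 6, "Andean Foothill", ua, "Hte 29"),
    row("TP1", 6, "Andean Foothill", ua, "Hte 30"),
    row("TP10", 6, "Andean Foothill", ua, "Hte 31"),
    row("TC88", 7, "West Amazon", ua, "Hte 18"),
    row("TC68", 7, "West Amazon", ua, "Hte 20"),
    row("TB69", 7, "West Amazon", ua, "Hte 13"),
    row(c("TV95", "TV48", "TV46"), 8, "North Amazon", "Llanos", "Hte 10"),
    row("TBo183", 9, "South Amazon", "\"Pastizal\" herbaceous habitat",
        "Hte 2"),
    row("TBo85", 9, "South Amazon", "\"Pastizal\" herbaceous habitat",
        "Hte 22"),
    row("TC100", 10, "West Amazon", "Choco Darien rainforest", "Hte 17"),
    row("TB29", 11, "South Amazon", "South East Amazon rainforest",
        "Hte 21"),
    row("TA10", 12, "South Amazon", "Dry tropical forest", "Hte 32"),
    row("TA11", 12, "South Amazon", "Dry tropical forest", "Hte 33"),
    row("TA12", 12, "South Amazon", "Dry tropical forest", "Hte 34"),
    row("TA13", 12, "South Amazon", "Dry tropical forest", "Hte 35"),
    row(c("TPI1", "TPI2"), "pi", NA_character_, NA_character_, "Hpi 1",
        "T. pinchaque"),
    row("TPI4", "pi", NA_character_, NA_character_, "Hpi 2", "T. pinchaque")
  )
}

#' Haplotype counts for a grouping of the survey samples
#'
#' Tabulates, within each level of a grouping column of
#' [tapir_study_samples()], how many samples carry each haplotype — the
#' within-group haplotype frequency spectra that drive gene diversity.
#' Mountain-tapir rows are excluded.
#'
#' @param by grouping column: `"group"`, `"ecoregion"`, or `"site_id"`; use
#'   `NULL` for the pooled spectrum over all 45 lowland samples.
#' @return named list of integer count vectors (one per group), or a single
#'   vector when `by` is NULL.
#' @export
tapir_haplotype_counts <- function(by = NULL) {
  tab <- tapir_study_samples()
  tab <- tab[tab$species == "T. terrestris", , drop = FALSE]
  if (is.null(by)) {
    return(as.integer(table(tab$haplotype)))
  }
  if (!by %in% names(tab)) stop("input error: unknown grouping column")
  lapply(split(tab$haplotype, tab[[by]]),
         function(h) as.integer(table(h)))
}

#' Load the cached survey alignment, if present
#'
#' The sequence-level statistics of the survey (segregating sites,
#' transition bias, nucleotide diversity) require the deposited cytochrome-b
#' sequences (GenBank GQ259910-GQ259957), which are not part of the
#' package.  A user who has fetched them once can place the aligned FASTA at
#' `inst/extdata/tapir_cytb_cached.fasta` (or pass a path); this loader
#' returns the alignment or, when the cache is absent, signals a
#' `missing_cache` condition explaining how to provide it.
#'
#' @param path optional explicit path to the cached FASTA.
#' @return a [seq_alignment()].
#' @export
read_cached_survey_alignment <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "tapir_cytb_cached.fasta",
                        package = "mtphylogeo")
  }
  if (is.null(path) || !nzchar(path) || !file.exists(path)) {
    stop(structure(class = c("missing_cache", "error", "condition"),
                   list(message = paste(
                     "cached survey alignment not found; download GenBank",
                     "accessions GQ259910-GQ259957, align/trim to the",
                     "shared 1,068-bp region and save as",
                     "inst/extdata/tapir_cytb_cached.fasta"),
                     call = NULL)))
  }
  read_fasta(path)
}
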