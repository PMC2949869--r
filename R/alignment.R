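#' @importFrom stats as.dist dist rbinom rexp runif rpois sd setNames quantile
#' @importFrom utils combn read.delim write.table
NULL

IUPAC_CODES <- c("A", "C", "G", "T", "N", "-", "R", "Y", "S", "W", "K", "M",
                 "B", "D", "H", "V", "?")

#' Construct an aligned sequence set
#'
#' An alignment is stored as a character matrix (samples x sites) over the
#' nucleotide alphabet plus IUPAC ambiguity codes, `N` and `-`.  All
#' sequences must have the same length and sample ids must be unique.
#'
#' @param sequences named character vector of equal-length sequence strings,
#'   or a character matrix with one row per sample and rownames as ids.
#' @return an object of class `seq_alignment`: a character matrix with
#'   attributes `L` (alignment length).
#' @export
seq_alignment <- function(sequences) {
  if (is.matrix(sequences)) {
    mat <- toupper(sequences)
    ids <- rownames(mat)
  } else {
    ids <- names(sequences)
    if (is.null(ids)) stop("sequences must be named by sample id")
    lens <- nchar(sequences)
    if (length(unique(lens)) > 1) {
      stop(sprintf("alignment error: ragged sequence lengths (%s)",
                   paste(unique(lens), collapse = ", ")))
    }
    mat <- do.call(rbind, strsplit(toupper(sequences), ""))
    rownames(mat) <- ids
  }
  if (is.null(ids) || anyNA(ids)) stop("sequences must be named by sample id")
  if (anyDuplicated(ids)) {
    stop(sprintf("input error: duplicate sample ids: %s",
                 paste(unique(ids[duplicated(ids)]), collapse = ", ")))
  }
  bad <- !(mat %in% IUPAC_CODES)
  if (any(bad)) {
    idx <- which(matrix(bad, nrow(mat)), arr.ind = TRUE)[1, ]
    stop(sprintf(
      "input error: illegal character '%s' in record '%s' at position %d",
      mat[idx[1], idx[2]], ids[idx[1]], idx[2]))
  }
  structure(mat, L = ncol(mat), class = "seq_alignment")
}

#' @export
print.seq_alignment <- function(x, ...) {
  cat(sprintf("seq_alignment: %d sequences, %d sites\n", nrow(x), ncol(x)))
  invisible(x)
}

#' Read an aligned FASTA file
#'
#' Thin wrapper around [ape::read.FASTA()] that validates the records as an
#' alignment (equal lengths, unique ids, legal alphabet) and preserves record
#' order.
#'
#' @param path path to a FASTA file (wrapped or unwrapped).
#' @return a [seq_alignment()].
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop(sprintf("input error: no such file: %s", path))
  dna <- ape::read.FASTA(path)
  if (length(dna) == 0) stop("input error: empty FASTA file")
  lens <- lengths(dna)
  if (length(unique(lens)) > 1) {
    stop(sprintf("alignment error: ragged sequence lengths in %s (%s)",
                 path, paste(unique(lens), collapse = ", ")))
  }
  seq_alignment(toupper(vapply(as.character(dna), paste0, "", collapse = "")))
}

#' Write an alignment to FASTA
#'
#' @param aln a [seq_alignment()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(aln, path) {
  lines <- character(2L * nrow(aln))
  lines[c(TRUE, FALSE)] <- paste0(">", rownames(aln))
  lines[c(FALSE, TRUE)] <- apply(unclass(aln), 1, paste0, collapse = "")
  writeLines(lines, path)
  invisible(path)
}

#' Read a sample-to-population map
#'
#' The map is a TSV with header
#' `sample_id site_id group ecoregion lat lon species`; extra columns are
#' kept and may be used as custom grouping schemes.
#'
#' @param path path to the TSV file.
#' @return a data frame, one row per sample.
#' @export
read_population_map <- function(path) {
  map <- read.delim(path, stringsAsFactors = FALSE)
  required <- c("sample_id", "site_id", "group", "ecoregion", "species")
  missing <- setdiff(required, names(map))
  if (length(missing)) {
    stop(sprintf("input error: population map lacks columns: %s",
                 paste(missing, collapse = ", ")))
  }
  if (anyDuplicated(map$sample_id)) {
    stop("input error: duplicate sample ids in population map")
  }
  map
}

#' Sites retained under complete deletion
#'
#' Columns in which any sequence carries something other than A, C, G or T
#' (gaps, N, ambiguity codes) are dropped from all site-based statistics and
#' from haplotype identity, so that reported counts refer to unambiguous
#' positions only.
#'
#' @param aln a [seq_alignment()].
#' @return integer vector of retained column indices.
#' @export
retained_sites <- function(aln) {
  which(apply(unclass(aln), 2, function(col) all(col %in% c("A", "C", "G", "T"))))
}

#' Collapse an alignment into haplotypes
#'
#' Haplotypes are equivalence classes of identical sequences on the retained
#' (complete-deletion) columns.  Counts are tabulated per deme, where a deme
#' is a level of `deme_col` in the population map (default: sampling site).
#'
#' @param aln a [seq_alignment()].
#' @param map population map data frame (see [read_population_map()]); every
#'   aligned sample must appear exactly once.
#' @param species_filter optional species label; samples whose `species`
#'   differs are dropped before collapsing.
#' @param deme_col map column defining demes (default `"site_id"`).
#' @return an object of class `haplotype_table`: a list with elements
#'   `haplotypes` (data frame of `hap_id`, `sequence` on retained columns),
#'   `counts` (haplotype x deme integer matrix), `n`, `p` (relative
#'   frequencies), `L` (number of retained sites), `retained` (column
#'   indices), and `membership` (named hap_id per sample).
#' @export
collapse_haplotypes <- function(aln, map, species_filter = NULL,
                                deme_col = "site_id") {
  if (nrow(aln) == 0) stop("input error: empty alignment")
  missing <- setdiff(rownames(aln), map$sample_id)
  if (length(missing)) {
    stop(sprintf("input error: samples missing from population map: %s",
                 paste(missing, collapse = ", ")))
  }
  map <- map[match(rownames(aln), map$sample_id), , drop = FALSE]
  keep <- rep(TRUE, nrow(aln))
  if (!is.null(species_filter)) keep <- map$species == species_filter
  if (!any(keep)) stop("input error: species filter removed every sample")
  sub <- unclass(aln)[keep, , drop = FALSE]
  map <- map[keep, , drop = FALSE]
  cols <- retained_sites(seq_alignment(sub))
  seqs <- apply(sub[, cols, drop = FALSE], 1, paste0, collapse = "")
  uniq <- unique(seqs)
  hap_id <- paste0("H", seq_along(uniq))
  member <- setNames(hap_id[match(seqs, uniq)], rownames(sub))
  demes <- as.character(map[[deme_col]])
  counts <- table(factor(member, levels = hap_id),
                  factor(demes, levels = unique(demes)))
  counts <- matrix(as.integer(counts), nrow = length(hap_id),
                   dimnames = dimnames(counts))
  n <- sum(counts)
  structure(list(
    haplotypes = data.frame(hap_id = hap_id, sequence = uniq,
                            stringsAsFactors = FALSE),
    counts = counts, n = n, p = rowSums(counts) / n,
    L = length(cols), retained = cols, membership = member
  ), class = "haplotype_table")
}

#' @export
print.haplotype_table <- function(x, ...) {
  cat(sprintf("haplotype_table: %d haplotypes, n = %d samples, %d demes, %d sites\n",
              nrow(x$haplotypes), x$n, ncol(x$counts), x$L))
  invisible(x)
}

#' Expand a haplotype table back to per-sample sequences
#'
#' Inverse of [collapse_haplotypes()] up to sample identity: returns the
#' multiset of sequences implied by the counts.
#'
#' @param haps a `haplotype_table`.
#' @return character vector of sequences, one per sample.
#' @export
expand_haplotypes <- function(haps) {
  rep(haps$haplotypes$sequence, times = rowSums(haps$counts))
}

#' Classify polymorphic sites
#'
#' Counts segregating sites on the retained (complete-deletion) columns and
#' classifies each biallelic site as a transition ({A,G} or {C,T}) or a
#' transversion; sites with three or more observed bases are reported in
#' `multiallelic`.  Base composition is pooled over all sequences and
#' retained sites.
#'
#' @param aln a [seq_alignment()].
#' @return an object of class `site_summary`: list with `S`, `transitions`,
#'   `transversions`, `multiallelic`, `base_composition` (named frequencies
#'   of A, C, G, T) and `retained` (number of retained sites).
#' @export
classify_sites <- function(aln) {
  if (nrow(aln) == 0) stop("input error: empty alignment")
  cols <- retained_sites(aln)
  mat <- unclass(aln)[, cols, drop = FALSE]
  alleles <- apply(mat, 2, function(col) sort(unique(col)), simplify = FALSE)
  n_alleles <- lengths(alleles)
  bi <- alleles[n_alleles == 2]
  is_ti <- vapply(bi, function(a) {
    identical(a, c("A", "G")) || identical(a, c("C", "T"))
  }, logical(1))
  counts <- table(factor(mat, levels = c("A", "C", "G", "T")))
  comp <- setNames(as.numeric(counts) / sum(counts), c("A", "C", "G", "T"))
  structure(list(
    S = sum(n_alleles > 1),
    transitions = sum(is_ti),
    transversions = sum(!is_ti),
    multiallelic = sum(n_alleles > 2),
    base_composition = comp,
    retained = length(cols)
  ), class = "site_summary")
}

#' @export
print.site_summary <- function(x, ...) {
  cat(sprintf("site_summary: S = %d (%d transitions, %d transversions, %d multiallelic) over %d sites\n",
              x$S, x$transitions, x$transversions, x$multiallelic, x$retained))
  comp <- sprintf("%s: %.2f%%", names(x$base_composition),
                  100 * x$base_composition)
  cat(" base composition:", paste(comp, collapse = ", "), "\n")
  invisible(x)
}
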