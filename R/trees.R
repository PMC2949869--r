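#' F84 pairwise distances
#'
#' Maximum-likelihood pairwise distances under the F84 substitution model
#' (unequal base frequencies, one transition/transversion parameter),
#' computed by [ape::dist.dna()] from the empirical base frequencies of the
#' alignment with complete deletion of ambiguous columns.  Saturated pairs,
#' for which the log arguments of the closed form are non-positive, come
#' back `NaN` from ape and are flagged: by default they are replaced by the
#' largest finite distance in the matrix (documented fallback) with a
#' warning.
#'
#' @param aln a [seq_alignment()] (or a `haplotype_table`, in which case the
#'   distances are between haplotypes).
#' @param saturated `"fallback"` (replace by max finite distance, warn) or
#'   `"NA"` (leave as NA).
#' @return symmetric numeric matrix of substitutions/site.
#' @export
f84_distance <- function(aln, saturated = c("fallback", "NA")) {
  saturated <- match.arg(saturated)
  if (inherits(aln, "haplotype_table")) {
    seqs <- setNames(aln$haplotypes$sequence, aln$haplotypes$hap_id)
    aln <- seq_alignment(seqs)
  }
  cols <- retained_sites(aln)
  mat <- unclass(aln)[, cols, drop = FALSE]
  if (nrow(mat) < 2) stop("input error: need at least 2 sequences")
  dna <- ape::as.DNAbin(tolower(mat))
  d <- as.matrix(ape::dist.dna(dna, model = "F84", pairwise.deletion = FALSE))
  bad <- !is.finite(d)
  diag(bad) <- FALSE
  if (any(bad)) {
    if (saturated == "fallback") {
      warning(sprintf("%d saturated pair(s): distance replaced by maximum finite value",
                      sum(bad) / 2))
      d[bad] <- max(d[!bad & row(d) != col(d)], 0)
    } else {
      d[bad] <- NA_real_
    }
  }
  d
}

#' UPGMA tree from a distance matrix
#'
#' Average-linkage agglomerative clustering rendered as a rooted ultrametric
#' tree with tips at height zero; the height of each internal node is half
#' the average distance between the clusters it joins.  Tied agglomerations
#' are broken deterministically by lexicographic label order (labels are
#' sorted before clustering, and `hclust` picks the first minimal pair).
#'
#' @param d symmetric distance matrix (or `dist`).
#' @return an [ape::phylo] rooted ultrametric tree.
#' @export
upgma_tree <- function(d) {
  m <- as.matrix(d)
  ord <- order(rownames(m))
  m <- m[ord, ord, drop = FALSE]
  hc <- stats::hclust(as.dist(m), method = "average")
  # as.phylo.hclust already places nodes at half the merge distance, so
  # root-to-tip depth is (max cluster distance)/2 and cophenetic distances
  # reproduce an ultrametric input exactly
  ape::as.phylo(hc)
}

#' Read and write newick trees
#'
#' Thin wrappers around [ape::read.tree()] / [ape::write.tree()] that
#' round-trip topology, labels and branch lengths.  `resolve_polytomies`
#' optionally converts a multifurcating tree to a random binary resolution
#' (zero-length internal branches) under a seed.
#'
#' @param path file path (`read_newick`) or tree/target (`write_newick`).
#' @return `read_newick`: an [ape::phylo]; `write_newick`: `path`,
#'   invisibly.
#' @export
read_newick <- function(path) {
  tr <- tryCatch(ape::read.tree(path),
                 error = function(e) stop(sprintf("parse error in %s: %s",
                                                  path, conditionMessage(e))))
  if (is.null(tr)) stop(sprintf("parse error: %s is not valid newick", path))
  tr
}

#' @param tree an [ape::phylo].
#' @rdname read_newick
#' @export
write_newick <- function(tree, path) {
  ape::write.tree(tree, file = path)
  invisible(path)
}

#' @param seed RNG seed for the random resolution.
#' @rdname read_newick
#' @export
resolve_polytomies <- function(tree, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  ape::multi2di(tree, random = TRUE)
}

#' Gene genealogy of site-associated haplotypes
#'
#' Builds the observed gene genealogy used by the migration-count test: a
#' UPGMA tree over F84 distances with one tip per (haplotype, site)
#' occurrence, so haplotypes shared between sampling sites contribute one
#' tip per site.  Each tip is tagged with its site and with the geographic
#' group of that site.
#'
#' @param aln a [seq_alignment()].
#' @param map population map (see [read_population_map()]).
#' @param species_filter optional species label.
#' @return an [ape::phylo] with attributes `tip_site` and `tip_group`
#'   (named by tip label).
#' @export
observed_gene_tree <- function(aln, map, species_filter = NULL) {
  haps <- collapse_haplotypes(aln, map, species_filter = species_filter)
  occ <- which(haps$counts > 0, arr.ind = TRUE)
  hap_ids <- rownames(haps$counts)[occ[, 1]]
  sites <- colnames(haps$counts)[occ[, 2]]
  tip_labels <- paste0(hap_ids, "@", sites)
  seqs <- setNames(
    haps$haplotypes$sequence[match(hap_ids, haps$haplotypes$hap_id)],
    tip_labels)
  d <- f84_distance(seq_alignment(seqs))
  phy <- upgma_tree(d)
  site_of <- setNames(sites, tip_labels)
  grp_of_site <- setNames(as.character(map$group), as.character(map$site_id))
  attr(phy, "tip_site") <- site_of[phy$tip.label]
  attr(phy, "tip_group") <- setNames(
    grp_of_site[site_of[phy$tip.label]], phy$tip.label)
  phy
}
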