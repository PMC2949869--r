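#' Nei's unbiased gene (haplotype) diversity
#'
#' \eqn{H_d = \frac{n}{n-1}\left(1 - \sum_i p_i^2\right)} with
#' \eqn{p_i = c_i/n}, the probability that two sequences drawn without
#' replacement carry different haplotypes.  The standard deviation follows
#' Nei (1987, eq. 8.12), the convention of DnaSP and Arlequin.
#'
#' @param counts integer vector of haplotype counts (zeros allowed).
#' @return list with `H_d`, `sd` and `n`.
#' @export
gene_diversity <- function(counts) {
  counts <- counts[counts > 0]
  n <- sum(counts)
  if (n < 2) stop("undefined error: gene diversity needs n >= 2")
  p <- counts / n
  sum_p2 <- sum(p^2)
  H <- n / (n - 1) * (1 - sum_p2)
  v <- 2 / (n * (n - 1)) *
    (2 * (n - 2) * (sum(p^3) - sum_p2^2) + sum_p2 - sum_p2^2)
  list(H_d = H, sd = sqrt(max(v, 0)), n = n)
}

#' Hamming distances between haplotype sequences
#'
#' @param seqs character vector of equal-length sequences.
#' @return symmetric integer matrix of pairwise differences.
#' @keywords internal
hamming_matrix <- function(seqs) {
  k <- length(seqs)
  mat <- do.call(rbind, strsplit(seqs, ""))
  d <- matrix(0L, k, k)
  if (k >= 2) {
    for (i in seq_len(k - 1)) {
      for (j in seq(i + 1, k)) {
        d[i, j] <- d[j, i] <- sum(mat[i, ] != mat[j, ])
      }
    }
  }
  d
}

#' Nucleotide diversity and mean pairwise difference
#'
#' \eqn{\bar k = \sum_{i<j} c_i c_j d_{ij} / \binom{n}{2}} over haplotype
#' pairs weighted by their counts, with \eqn{d_{ij}} the Hamming distance on
#' retained columns, and \eqn{\pi = \bar k / L}.  No multiple-hit correction
#' is applied: \eqn{\pi} is the uncorrected per-site mean, and the variance
#' is Nei (1987, eq. 10.7), which includes the coalescent (stochastic)
#' component.
#'
#' @param haps a `haplotype_table` from [collapse_haplotypes()].
#' @param L number of sites; defaults to the table's retained-site count.
#' @return list with `pi`, `sd`, `k_bar`, `k_bar_pct` (mean pairwise
#'   difference as percent of L), `n` and `L`.
#' @export
nucleotide_diversity <- function(haps, L = haps$L) {
  n <- haps$n
  if (n < 2) stop("undefined error: nucleotide diversity needs n >= 2")
  cnt <- rowSums(haps$counts)
  d <- hamming_matrix(haps$haplotypes$sequence)
  w <- outer(cnt, cnt)
  k_bar <- sum(w[upper.tri(w)] * d[upper.tri(d)]) / choose(n, 2)
  pi <- k_bar / L
  v <- (n + 1) / (3 * (n - 1) * L) * pi +
    2 * (n^2 + n + 3) / (9 * n * (n - 1)) * pi^2
  list(pi = pi, sd = sqrt(max(v, 0)), k_bar = k_bar,
       k_bar_pct = 100 * k_bar / L, n = n, L = L)
}

#' Diversity statistics per group of samples
#'
#' Splits the samples by a grouping scheme and reports gene diversity,
#' nucleotide diversity and mean pairwise differences per group.  Groups of
#' a single sample are flagged `undefined` (gene diversity has no unbiased
#' estimate at n = 1) with `pi = 0`, mirroring how survey tables print "-".
#'
#' @param aln a [seq_alignment()].
#' @param map population map covering every sample.
#' @param scheme either the name of a map column (e.g. `"group"` for the
#'   geographic regions, `"ecoregion"` for ecogeographic units) or a named
#'   character vector sample_id -> group ("custom" scheme).
#' @param species_filter optional species label passed through to
#'   [collapse_haplotypes()].
#' @return data frame with one row per group: `group`, `n`, `n_haplotypes`,
#'   `H_d`, `H_d_sd`, `pi`, `pi_sd`, `k_bar`, `undefined`.
#' @export
diversity_by_grouping <- function(aln, map, scheme = "group",
                                  species_filter = NULL) {
  if (is.character(scheme) && length(scheme) == 1) {
    if (!scheme %in% names(map)) {
      stop(sprintf("input error: unknown grouping scheme '%s'", scheme))
    }
    groups <- setNames(as.character(map[[scheme]]), map$sample_id)
  } else {
    if (is.null(names(scheme))) {
      stop("input error: custom scheme must be a named vector")
    }
    groups <- scheme
  }
  haps <- collapse_haplotypes(aln, map, species_filter = species_filter)
  ids <- names(haps$membership)
  groups <- groups[ids]
  if (anyNA(groups)) stop("input error: scheme does not assign every sample")
  out <- lapply(unique(groups), function(g) {
    sub_ids <- ids[groups == g]
    cnt <- table(haps$membership[sub_ids])
    if (length(sub_ids) < 2) {
      return(data.frame(group = g, n = length(sub_ids),
                        n_haplotypes = length(cnt), H_d = NA_real_,
                        H_d_sd = NA_real_, pi = 0, pi_sd = 0, k_bar = 0,
                        undefined = TRUE, stringsAsFactors = FALSE))
    }
    gd <- gene_diversity(as.integer(cnt))
    sub_haps <- subset_haplotypes(haps, sub_ids)
    nd <- nucleotide_diversity(sub_haps)
    data.frame(group = g, n = gd$n, n_haplotypes = length(cnt),
               H_d = gd$H_d, H_d_sd = gd$sd, pi = nd$pi, pi_sd = nd$sd,
               k_bar = nd$k_bar, undefined = FALSE, stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Restrict a haplotype table to a subset of samples
#'
#' @param haps a `haplotype_table`.
#' @param sample_ids samples to keep.
#' @return a `haplotype_table` over the kept samples (haplotypes with zero
#'   count dropped; demes collapse to a single column).
#' @keywords internal
subset_haplotypes <- function(haps, sample_ids) {
  member <- haps$membership[sample_ids]
  cnt <- table(factor(member, levels = haps$haplotypes$hap_id))
  keep <- cnt > 0
  counts <- matrix(as.integer(cnt[keep]), ncol = 1,
                   dimnames = list(haps$haplotypes$hap_id[keep], "all"))
  structure(list(
    haplotypes = haps$haplotypes[keep, , drop = FALSE],
    counts = counts, n = sum(counts), p = counts[, 1] / sum(counts),
    L = haps$L, retained = haps$retained, membership = member
  ), class = "haplotype_table")
}
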