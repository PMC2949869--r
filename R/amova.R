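#' Pairwise difference matrix between samples
#'
#' Expands a haplotype table back to samples and returns the sample-level
#' matrix of Hamming distances on the retained columns — the standard input
#' of molecular-variance analyses, in which the number of nucleotide
#' differences plays the role of a squared Euclidean distance.
#'
#' @param haps a `haplotype_table` from [collapse_haplotypes()].
#' @return symmetric matrix with sample ids as dimnames.
#' @export
pairwise_difference_matrix <- function(haps) {
  ids <- names(haps$membership)
  if (length(ids) < 2) stop("input error: need at least 2 samples")
  hd <- hamming_matrix(haps$haplotypes$sequence)
  idx <- match(haps$membership[ids], haps$haplotypes$hap_id)
  d <- hd[idx, idx, drop = FALSE]
  dimnames(d) <- list(ids, ids)
  d
}

# Sum over i<j in `members` of d2 (squared distances), divided by set size.
ss_within <- function(d2, members) {
  m <- d2[members, members, drop = FALSE]
  sum(m[upper.tri(m)]) / length(members)
}

# Variance components of a two-level hierarchy (groups / populations /
# samples) from squared distances, after Excoffier's sums of squared
# deviations. Returns NULL-free list; callers derive the Phi statistics.
amova_components <- function(d2, pops, groups_of_pop) {
  N <- nrow(d2)
  pop_ids <- unique(pops)
  P <- length(pop_ids)
  grp_of <- groups_of_pop[pop_ids]
  grp_ids <- unique(grp_of)
  G <- length(grp_ids)
  n_p <- vapply(pop_ids, function(p) sum(pops == p), 0L)
  N_g <- vapply(grp_ids, function(g) sum(n_p[grp_of == g]), 0)

  ssd_wp <- sum(vapply(pop_ids, function(p) ss_within(d2, which(pops == p)), 0))
  ssd_wg <- sum(vapply(grp_ids, function(g) {
    ss_within(d2, which(grp_of[match(pops, pop_ids)] == g))
  }, 0))
  ssd_tot <- ss_within(d2, seq_len(N))
  ssd_ap <- ssd_wg - ssd_wp
  ssd_ag <- ssd_tot - ssd_wg

  df_ag <- G - 1
  df_ap <- P - G
  df_wp <- N - P

  sum_npsq_over_Ng <- sum(vapply(grp_ids, function(g) {
    sum(n_p[grp_of == g]^2) / sum(n_p[grp_of == g])
  }, 0))
  n_c <- if (df_ap > 0) (N - sum_npsq_over_Ng) / df_ap else NA_real_
  n_cp <- if (df_ag > 0) {
    (sum_npsq_over_Ng - sum(n_p^2) / N) / df_ag
  } else NA_real_
  n_cpp <- if (df_ag > 0) (N - sum(N_g^2) / N) / df_ag else NA_real_

  sigma_c <- if (df_wp > 0) ssd_wp / df_wp else 0
  sigma_b <- if (df_ap > 0) (ssd_ap / df_ap - sigma_c) / n_c else 0
  sigma_a <- if (df_ag > 0) {
    (ssd_ag / df_ag - sigma_c - n_cp * sigma_b) / n_cpp
  } else NA_real_

  list(sigma_a = sigma_a, sigma_b = sigma_b, sigma_c = sigma_c,
       ssd = c(among_groups = ssd_ag, among_pops = ssd_ap, within = ssd_wp),
       df = c(df_ag, df_ap, df_wp), G = G, P = P, N = N)
}

phi_from_components <- function(cmp) {
  # one-level hierarchies have no among-group component
  a <- if (is.na(cmp$sigma_a)) 0 else cmp$sigma_a
  tot <- a + cmp$sigma_b + cmp$sigma_c
  list(
    phi_ST = if (tot > 0) (a + cmp$sigma_b) / tot else NA_real_,
    phi_SC = if ((cmp$sigma_b + cmp$sigma_c) != 0) {
      cmp$sigma_b / (cmp$sigma_b + cmp$sigma_c)
    } else NA_real_,
    phi_CT = if (!is.na(cmp$sigma_a) && tot > 0) cmp$sigma_a / tot else
      NA_real_
  )
}

#' Hierarchical analysis of molecular variance (AMOVA)
#'
#' Partitions molecular variance among groups, among populations within
#' groups, and within populations, from a matrix of pairwise differences
#' treated as squared distances, and estimates the fixation indices
#' \eqn{\Phi_{CT}}, \eqn{\Phi_{SC}} and \eqn{\Phi_{ST}}.  Significance is
#' assessed by permutation, with a different resampling scheme per
#' statistic: samples among populations (\eqn{\Phi_{ST}}), samples among
#' populations within groups (\eqn{\Phi_{SC}}), and whole populations among
#' groups (\eqn{\Phi_{CT}}); p-values carry the +1 pseudo-count.
#'
#' @param d sample-by-sample matrix of pairwise differences (squared
#'   distances), as from [pairwise_difference_matrix()].
#' @param populations named (by sample id) or positional vector assigning
#'   each sample to a population.
#' @param groups named vector assigning each population to a group; if NULL
#'   a single-level AMOVA (populations only) is run and only
#'   \eqn{\Phi_{ST}} is reported.
#' @param permutations number of permutations (default 10000).
#' @param seed optional RNG seed.
#' @return an object of class `amova_result`: variance components
#'   (`sigma_a`, `sigma_b`, `sigma_c`), `percent` variation per level,
#'   `phi_ST`, `phi_SC`, `phi_CT`, p-values `p_ST`, `p_SC`, `p_CT`, and the
#'   sums of squared deviations.  Phi statistics are reported unclamped
#'   (negative values are meaningful and kept).
#' @export
amova <- function(d, populations, groups = NULL, permutations = 10000,
                  seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  ids <- rownames(d)
  pops <- if (!is.null(names(populations))) {
    as.character(populations[ids])
  } else as.character(populations)
  if (anyNA(pops) || length(pops) != nrow(d)) {
    stop("input error: every sample needs exactly one population")
  }
  if (all(d[upper.tri(d)] == 0)) {
    stop("undefined error: total molecular variance is zero")
  }
  one_level <- is.null(groups)
  if (one_level) groups <- setNames(rep("all", length(unique(pops))),
                                    unique(pops))
  grp <- setNames(as.character(groups), names(groups))
  cmp <- amova_components(d, pops, grp)
  phi <- phi_from_components(cmp)

  perm_ge <- c(ST = 0L, SC = 0L, CT = 0L)
  for (b in seq_len(permutations)) {
    # Phi_ST: permute samples among populations, ignoring groups
    p1 <- sample(pops)
    phi1 <- phi_from_components(amova_components(d, p1, grp))
    if (!is.na(phi$phi_ST) && !is.na(phi1$phi_ST) &&
        phi1$phi_ST >= phi$phi_ST) perm_ge["ST"] <- perm_ge["ST"] + 1L
    if (!one_level) {
      # Phi_SC: permute samples among populations within each group
      p2 <- pops
      for (g in unique(grp)) {
        in_g <- grp[pops] == g
        p2[in_g] <- sample(pops[in_g])
      }
      phi2 <- phi_from_components(amova_components(d, p2, grp))
      if (!is.na(phi$phi_SC) && !is.na(phi2$phi_SC) &&
          phi2$phi_SC >= phi$phi_SC) perm_ge["SC"] <- perm_ge["SC"] + 1L
      # Phi_CT: permute whole populations among groups
      g3 <- setNames(sample(as.vector(grp)), names(grp))
      phi3 <- phi_from_components(amova_components(d, pops, g3))
      if (!is.na(phi$phi_CT) && !is.na(phi3$phi_CT) &&
          phi3$phi_CT >= phi$phi_CT) perm_ge["CT"] <- perm_ge["CT"] + 1L
    }
  }
  pvals <- (perm_ge + 1) / (permutations + 1)
  tot <- cmp$sigma_a + cmp$sigma_b + cmp$sigma_c
  pct <- if (one_level) {
    c(among_pops = 100 * cmp$sigma_b / (cmp$sigma_b + cmp$sigma_c),
      within = 100 * cmp$sigma_c / (cmp$sigma_b + cmp$sigma_c))
  } else {
    c(among_groups = 100 * cmp$sigma_a / tot,
      among_pops = 100 * cmp$sigma_b / tot,
      within = 100 * cmp$sigma_c / tot)
  }
  structure(list(
    sigma_a = if (one_level) NA_real_ else cmp$sigma_a,
    sigma_b = cmp$sigma_b, sigma_c = cmp$sigma_c, percent = pct,
    phi_ST = phi$phi_ST,
    phi_SC = if (one_level) NA_real_ else phi$phi_SC,
    phi_CT = if (one_level) NA_real_ else phi$phi_CT,
    p_ST = pvals[["ST"]],
    p_SC = if (one_level) NA_real_ else pvals[["SC"]],
    p_CT = if (one_level) NA_real_ else pvals[["CT"]],
    ssd = cmp$ssd, df = cmp$df, permutations = permutations,
    one_level = one_level
  ), class = "amova_result")
}

#' @export
print.amova_result <- function(x, ...) {
  cat("AMOVA\n")
  if (!x$one_level) {
    cat(sprintf(" among groups:              sigma2 = %8.4f (%5.1f%%)  Phi_CT = %6.3f (p = %.4g)\n",
                x$sigma_a, x$percent[["among_groups"]], x$phi_CT, x$p_CT))
    cat(sprintf(" among pops within groups:  sigma2 = %8.4f (%5.1f%%)  Phi_SC = %6.3f (p = %.4g)\n",
                x$sigma_b, x$percent[["among_pops"]], x$phi_SC, x$p_SC))
    cat(sprintf(" within pops:               sigma2 = %8.4f (%5.1f%%)  Phi_ST = %6.3f (p = %.4g)\n",
                x$sigma_c, x$percent[["within"]], x$phi_ST, x$p_ST))
  } else {
    cat(sprintf(" among pops: sigma2 = %8.4f (%5.1f%%)  Phi_ST = %6.3f (p = %.4g)\n",
                x$sigma_b, x$percent[["among_pops"]], x$phi_ST, x$p_ST))
    cat(sprintf(" within pops: sigma2 = %8.4f (%5.1f%%)\n",
                x$sigma_c, x$percent[["within"]]))
  }
  invisible(x)
}

#' Pairwise Phi statistics between demes
#'
#' Runs a single-level AMOVA for every pair of demes and reports the
#' unclamped \eqn{\Phi_{ST}} with a permutation p-value (samples permuted
#' between the two demes).
#'
#' @param d sample-by-sample difference matrix.
#' @param demes population assignment per sample (named by sample id or
#'   positional).
#' @param permutations permutations per pair (default 1000).
#' @param seed optional RNG seed.
#' @return list with matrices `phi` and `p` (demes x demes; NA diagonal).
#' @export
pairwise_phi <- function(d, demes, permutations = 1000, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  ids <- rownames(d)
  dm <- if (!is.null(names(demes))) as.character(demes[ids]) else
    as.character(demes)
  lev <- unique(dm)
  K <- length(lev)
  phi <- p <- matrix(NA_real_, K, K, dimnames = list(lev, lev))
  for (i in seq_len(K - 1)) {
    for (j in seq(i + 1, K)) {
      sel <- dm %in% c(lev[i], lev[j])
      dsub <- d[sel, sel, drop = FALSE]
      if (all(dsub[upper.tri(dsub)] == 0)) next
      res <- amova(dsub, dm[sel], permutations = permutations)
      phi[i, j] <- phi[j, i] <- res$phi_ST
      p[i, j] <- p[j, i] <- res$p_ST
    }
  }
  list(phi = phi, p = p)
}
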