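#' Tajima's D
#'
#' Compares the mean pairwise difference \eqn{\bar k} with Watterson's
#' \eqn{S/a_1}; under the standard neutral model both estimate \eqn{\theta}
#' and D is near zero.  Negative values indicate an excess of rare variants
#' (expansion or purifying selection).
#'
#' @param S number of segregating sites (>= 1).
#' @param k_bar mean number of pairwise differences.
#' @param n sample size (>= 4).
#' @return Tajima's D (numeric scalar).
#' @export
tajimas_d <- function(S, k_bar, n) {
  if (n < 4) stop("input error: Tajima's D needs n >= 4")
  if (S < 1) stop("undefined error: Tajima's D undefined when S = 0")
  i <- seq_len(n - 1)
  a1 <- sum(1 / i)
  a2 <- sum(1 / i^2)
  b1 <- (n + 1) / (3 * (n - 1))
  b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1
  c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
  e1 <- c1 / a1
  e2 <- c2 / (a1^2 + a2)
  (k_bar - S / a1) / sqrt(e1 * S + e2 * S * (S - 1))
}

#' Log unsigned Stirling numbers of the first kind
#'
#' Row `n` of the triangle, i.e. `log |s(n, k)|` for k = 1..n, computed by
#' the recurrence |s(n+1,k)| = n |s(n,k)| + |s(n,k-1)| in log space so that
#' rows up to n of a few hundred do not overflow.
#'
#' @param n row index (>= 1).
#' @return numeric vector of length n, `-Inf` where the number is zero.
#' @keywords internal
log_stirling1 <- function(n) {
  row <- 0 # log|s(1,1)|
  if (n == 1) return(row)
  for (m in seq_len(n - 1)) {
    # row holds log|s(m, 1..m)|
    up <- c(-Inf, row)                    # |s(m, k-1)|
    stay <- c(row, -Inf) + log(m)         # m * |s(m, k)|
    row <- pmax(up, stay) + log1p(exp(-abs(up - stay)))
    row[is.nan(row)] <- -Inf
  }
  row
}

#' Fu's Fs
#'
#' Based on the Ewens sampling formula: with \eqn{\theta} estimated by the
#' mean pairwise difference, \eqn{S' = P(K \ge k_{obs} \mid \theta, n)} is
#' the probability of observing at least as many distinct haplotypes as
#' seen, and \eqn{F_s = \ln(S' / (1 - S'))}.  Large negative values indicate
#' an excess of haplotypes, as after a population expansion.
#'
#' @param k_obs observed number of distinct haplotypes.
#' @param theta positive theta estimate (conventionally \eqn{\bar k}).
#' @param n sample size (>= 2).
#' @return Fu's Fs (numeric scalar).
#' @export
fus_fs <- function(k_obs, theta, n) {
  if (n < 2) stop("input error: Fu's Fs needs n >= 2")
  if (!is.finite(theta) || theta <= 0 || k_obs <= 1) {
    stop("undefined error: Fu's Fs undefined for monomorphic data")
  }
  ls <- log_stirling1(n)
  k <- seq_len(n)
  log_num <- ls + k * log(theta)
  log_den <- lse(log_num) # log theta^{(n)} = log sum_k |s(n,k)| theta^k
  log_Sp <- lse(log_num[k >= k_obs]) - log_den
  if (log_Sp >= 0) stop("undefined error: S' = 1, Fs undefined")
  # log(1 - S') computed stably
  log_1mSp <- log1p(-exp(log_Sp))
  log_Sp - log_1mSp
}

lse <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

#' Simulate one neutral constant-size genealogy with infinite-sites mutation
#'
#' Time is scaled in units of N generations (haploid coalescent): k lineages
#' coalesce at rate choose(k, 2), and mutations fall as a Poisson process at
#' rate theta/2 per unit branch length, so the expected pairwise difference
#' equals theta.
#'
#' @param n sample size.
#' @param theta scaled mutation rate (ignored when `fixed_S` is given).
#' @param fixed_S if non-NULL, place exactly this many mutations,
#'   multinomially along branches in proportion to length.
#' @return list with `S`, `k_bar`, `k_obs` (number of distinct haplotypes).
#' @keywords internal
sim_neutral_stats <- function(n, theta, fixed_S = NULL) {
  k <- n
  t_now <- 0
  node_time <- rep(0, 2 * n - 1)
  parent <- integer(2 * n - 1)
  active <- seq_len(n)
  nxt <- n + 1L
  while (k > 1) {
    t_now <- t_now + rexp(1, rate = k * (k - 1) / 2)
    pair <- sample(length(active), 2)
    node_time[nxt] <- t_now
    parent[active[pair]] <- nxt
    active <- c(active[-pair], nxt)
    nxt <- nxt + 1L
    k <- k - 1L
  }
  root <- 2L * n - 1L
  nonroot <- seq_len(root - 1L)
  blen <- node_time[parent[nonroot]] - node_time[nonroot]
  nmut <- if (is.null(fixed_S)) {
    c(rpois(length(blen), theta / 2 * blen), 0L)
  } else {
    c(as.integer(stats::rmultinom(1, fixed_S, prob = blen)), 0L)
  }
  S <- sum(nmut)
  # tips below each branch: parents are created after children, so a single
  # forward pass accumulates descendant counts
  ndesc <- c(rep(1L, n), rep(0L, n - 1L))
  for (v in nonroot) ndesc[parent[v]] <- ndesc[parent[v]] + ndesc[v]
  # sum of pairwise differences: a branch with i tips below separates
  # i * (n - i) pairs
  k_bar <- sum(nmut[nonroot] * ndesc[nonroot] * (n - ndesc[nonroot])) /
    choose(n, 2)
  list(S = S, k_bar = k_bar,
       k_obs = length(unique(hap_key(parent, nmut, n, root))))
}

hap_key <- function(parent, nmut, n, root) {
  vapply(seq_len(n), function(tip) {
    v <- tip
    ks <- character(0)
    while (v != root) {
      if (nmut[v] > 0) ks <- c(ks, paste0(v, ":", nmut[v]))
      v <- parent[v]
    }
    paste(ks, collapse = ";")
  }, "")
}

#' Neutrality tests for one group with simulated significance
#'
#' Computes Tajima's D and Fu's Fs for the samples of one group and obtains
#' one-tailed (lower) p-values from `reps` constant-size neutral coalescent
#' simulations conditioned on the sample size and on theta estimated by the
#' observed mean pairwise difference (the Arlequin-style
#' "simulate-given-theta" null; `conditional = "S"` instead fixes the
#' simulated segregating-site count to the observed S).
#'
#' @param haps a `haplotype_table` for the group (see
#'   [collapse_haplotypes()] / [subset_haplotypes()]), or NULL when passing
#'   `aln`/`map`.
#' @param reps number of null simulations (default 1000).
#' @param seed optional RNG seed.
#' @param conditional `"theta"` (default) or `"S"`.
#' @return an object of class `neutrality_stats`: list with `D`, `Fs`,
#'   `p_D`, `p_Fs`, `S`, `k_bar`, `k_obs`, `n`, `testable`.  Monomorphic
#'   groups return `testable = FALSE` with the statistics `NA`.
#' @export
neutrality_test <- function(haps, reps = 1000, seed = NULL,
                            conditional = c("theta", "S")) {
  conditional <- match.arg(conditional)
  if (!is.null(seed)) set.seed(seed)
  n <- haps$n
  cnt <- rowSums(haps$counts)
  ss <- classify_sites(seq_alignment(
    setNames(expand_haplotypes(haps), paste0("s", seq_len(n)))))
  S <- ss$S
  if (S == 0 || n < 4) {
    return(structure(list(D = NA_real_, Fs = NA_real_, p_D = NA_real_,
                          p_Fs = NA_real_, S = S, k_bar = 0,
                          k_obs = sum(cnt > 0), n = n, testable = FALSE),
                     class = "neutrality_stats"))
  }
  nd <- nucleotide_diversity(haps)
  k_bar <- nd$k_bar
  k_obs <- sum(cnt > 0)
  D_obs <- tajimas_d(S, k_bar, n)
  Fs_obs <- fus_fs(k_obs, k_bar, n)
  D_null <- Fs_null <- rep(NA_real_, reps)
  for (r in seq_len(reps)) {
    st <- if (conditional == "theta") {
      sim_neutral_stats(n, k_bar)
    } else {
      sim_neutral_stats(n, fixed_S = S)
    }
    if (st$S >= 1) D_null[r] <- tajimas_d(st$S, st$k_bar, n)
    if (st$k_obs > 1 && st$k_bar > 0) {
      Fs_null[r] <- fus_fs(st$k_obs, st$k_bar, n)
    }
  }
  p_D <- mean(D_null[!is.na(D_null)] <= D_obs)
  p_Fs <- mean(Fs_null[!is.na(Fs_null)] <= Fs_obs)
  structure(list(D = D_obs, Fs = Fs_obs, p_D = p_D, p_Fs = p_Fs, S = S,
                 k_bar = k_bar, k_obs = k_obs, n = n, testable = TRUE),
            class = "neutrality_stats")
}

#' @export
print.neutrality_stats <- function(x, ...) {
  if (!x$testable) {
    cat(sprintf("neutrality: not testable (n = %d, S = %d)\n", x$n, x$S))
  } else {
    cat(sprintf("Tajima's D = %.3f (p = %.4g), Fu's Fs = %.3f (p = %.4g)  [n = %d, S = %d, k = %d]\n",
                x$D, x$p_D, x$Fs, x$p_Fs, x$n, x$S, x$k_obs))
  }
  invisible(x)
}
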