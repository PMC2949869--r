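# Independent oracles used across tests.  These deliberately re-derive each
# quantity from first principles (loops over definitions, exhaustive
# enumeration) rather than reusing package internals.

# Brute-force AMOVA variance components straight from the sums-of-squared-
# deviations definitions, with explicit loops.
oracle_amova <- function(d2, pops, groups_of_pop) {
  N <- nrow(d2)
  ss_of <- function(idx) {
    tot <- 0
    for (i in idx) for (j in idx) if (i < j) tot <- tot + d2[i, j]
    tot / length(idx)
  }
  pop_ids <- unique(pops)
  P <- length(pop_ids)
  grp <- groups_of_pop[pop_ids]
  grp_ids <- unique(grp)
  G <- length(grp_ids)
  ssd_wp <- 0
  for (p in pop_ids) ssd_wp <- ssd_wp + ss_of(which(pops == p))
  ssd_wg <- 0
  for (g in grp_ids) {
    members <- which(pops %in% pop_ids[grp == g])
    ssd_wg <- ssd_wg + ss_of(members)
  }
  ssd_tot <- ss_of(seq_len(N))
  n_p <- sapply(pop_ids, function(p) sum(pops == p))
  N_g <- sapply(grp_ids, function(g) sum(n_p[grp == g]))
  df_ag <- G - 1; df_ap <- P - G; df_wp <- N - P
  s_npsq_Ng <- sum(sapply(grp_ids, function(g) {
    sum(n_p[grp == g]^2) / sum(n_p[grp == g])
  }))
  n_c <- (N - s_npsq_Ng) / df_ap
  n_cp <- (s_npsq_Ng - sum(n_p^2) / N) / df_ag
  n_cpp <- (N - sum(N_g^2) / N) / df_ag
  sigma_c <- ssd_wp / df_wp
  sigma_b <- ((ssd_wg - ssd_wp) / df_ap - sigma_c) / n_c
  sigma_a <- ((ssd_tot - ssd_wg) / df_ag - sigma_c - n_cp * sigma_b) / n_cpp
  list(sigma_a = sigma_a, sigma_b = sigma_b, sigma_c = sigma_c)
}

# Exhaustive parsimony: minimum number of edges with differing endpoint
# states over all assignments of states to internal nodes.
oracle_parsimony <- function(tree, tip_states, states = NULL,
                             costs = NULL) {
  ntip <- length(tree$tip.label)
  nnode <- tree$Nnode
  if (is.null(states)) states <- sort(unique(tip_states))
  K <- length(states)
  tip_idx <- match(tip_states[tree$tip.label], states)
  best <- Inf
  grid <- rep(list(seq_len(K)), nnode)
  assignments <- do.call(expand.grid, grid)
  for (r in seq_len(nrow(assignments))) {
    st <- c(tip_idx, as.integer(assignments[r, ]))
    tot <- 0
    for (e in seq_len(nrow(tree$edge))) {
      a <- st[tree$edge[e, 1]]
      b <- st[tree$edge[e, 2]]
      tot <- tot + if (is.null(costs)) (a != b) else costs[a, b]
    }
    if (tot < best) best <- tot
  }
  best
}

# Unsigned Stirling numbers of the first kind by brute-force cycle counting
# over all permutations of n elements.
oracle_stirling_row <- function(n) {
  perms <- function(v) {
    if (length(v) == 1) return(list(v))
    out <- list()
    for (i in seq_along(v)) {
      for (rest in perms(v[-i])) out[[length(out) + 1L]] <- c(v[i], rest)
    }
    out
  }
  count_cycles <- function(p) {
    seen <- rep(FALSE, length(p))
    k <- 0L
    for (i in seq_along(p)) {
      if (!seen[i]) {
        k <- k + 1L
        j <- i
        while (!seen[j]) { seen[j] <- TRUE; j <- p[j] }
      }
    }
    k
  }
  tab <- rep(0, n)
  for (p in perms(seq_len(n))) {
    k <- count_cycles(p)
    tab[k] <- tab[k] + 1
  }
  tab
}

# F84 pairwise distance evaluated directly from the closed form
# (Swofford et al. parameterization), independent of ape.
oracle_f84 <- function(P, Q, freq) {
  piA <- freq["A"]; piC <- freq["C"]; piG <- freq["G"]; piT <- freq["T"]
  piR <- piA + piG; piY <- piC + piT
  A <- piA * piG / piR + piC * piT / piY
  B <- piA * piG + piC * piT
  C <- piR * piY
  unname(-2 * A * log(1 - P / (2 * A) - (A - B) * Q / (2 * A * C)) +
           2 * (A - B - C) * log(1 - Q / (2 * C)))
}

# small random alignment over ACGT
random_alignment <- function(n, L, ids = paste0("s", seq_len(n))) {
  seqs <- vapply(seq_len(n), function(i) {
    paste0(sample(c("A", "C", "G", "T"), L, replace = TRUE), collapse = "")
  }, "")
  seq_alignment(setNames(seqs, ids))
}

# a minimal population map for ad-hoc alignments
toy_map <- function(ids, sites = rep("d1", length(ids)),
                    groups = rep("g1", length(ids))) {
  data.frame(sample_id = ids, site_id = sites, group = groups,
             ecoregion = groups, species = "toy",
             stringsAsFactors = FALSE)
}
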