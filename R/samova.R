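#' Delaunay adjacency between sampling sites
#'
#' Brute-force Delaunay triangulation on planar coordinates (longitude /
#' latitude treated as planar, the construction used to constrain spatial
#' partition searches): a triangle belongs to the triangulation when no
#' other site falls strictly inside its circumcircle.  Collinear degeneracies
#' fall back to a minimum-spanning-tree chain so the graph is always
#' connected.  Quadratic-to-quartic cost is irrelevant at survey scale
#' (a dozen sites).
#'
#' @param coords data frame or matrix with columns `lon` and `lat` (or two
#'   unnamed columns), one row per site; rownames or a `site_id` column give
#'   site labels.
#' @return two-column character matrix of adjacent site pairs.
#' @export
delaunay_adjacency <- function(coords) {
  if (is.data.frame(coords) && "site_id" %in% names(coords)) {
    labels <- as.character(coords$site_id)
    xy <- cbind(coords$lon, coords$lat)
  } else {
    xy <- as.matrix(coords[, 1:2])
    labels <- rownames(coords)
    if (is.null(labels)) labels <- as.character(seq_len(nrow(xy)))
  }
  n <- nrow(xy)
  if (n < 2) stop("input error: need at least 2 sites")
  edges <- matrix(character(0), ncol = 2)
  if (n == 2) {
    edges <- rbind(edges, labels)
  } else {
    for (i in seq_len(n - 2)) {
      for (j in seq(i + 1, n - 1)) {
        for (k in seq(j + 1, n)) {
          cc <- circumcircle(xy[i, ], xy[j, ], xy[k, ])
          if (is.null(cc)) next # collinear triple
          others <- setdiff(seq_len(n), c(i, j, k))
          d2 <- (xy[others, 1] - cc$x)^2 + (xy[others, 2] - cc$y)^2
          if (all(d2 >= cc$r2 * (1 - 1e-9))) {
            edges <- rbind(edges, labels[c(i, j)], labels[c(j, k)],
                           labels[c(i, k)])
          }
        }
      }
    }
  }
  if (nrow(edges)) edges <- unique(t(apply(edges, 1, sort)))
  # degenerate layouts (e.g. all collinear): connect via Euclidean MST
  g <- igraph::make_empty_graph(directed = FALSE) +
    igraph::vertices(labels)
  if (nrow(edges)) g <- igraph::add_edges(g, t(edges))
  if (igraph::components(g)$no > 1) {
    dmat <- as.matrix(dist(xy))
    dimnames(dmat) <- list(labels, labels)
    full <- igraph::graph_from_adjacency_matrix(dmat, mode = "undirected",
                                                weighted = TRUE)
    mst_edges <- igraph::as_edgelist(igraph::mst(full))
    edges <- unique(rbind(edges, t(apply(mst_edges, 1, sort))))
  }
  edges <- matrix(as.character(edges), ncol = 2,
                  dimnames = list(NULL, c("from", "to")))
  edges
}

circumcircle <- function(a, b, c) {
  d <- 2 * (a[1] * (b[2] - c[2]) + b[1] * (c[2] - a[2]) + c[1] * (a[2] - b[2]))
  if (abs(d) < 1e-12) return(NULL)
  ux <- ((a[1]^2 + a[2]^2) * (b[2] - c[2]) + (b[1]^2 + b[2]^2) * (c[2] - a[2]) +
           (c[1]^2 + c[2]^2) * (a[2] - b[2])) / d
  uy <- ((a[1]^2 + a[2]^2) * (c[1] - b[1]) + (b[1]^2 + b[2]^2) * (a[1] - c[1]) +
           (c[1]^2 + c[2]^2) * (b[1] - a[1])) / d
  list(x = ux, y = uy, r2 = (a[1] - ux)^2 + (a[2] - uy)^2)
}

# Precomputed per-deme sums of squared distances, so that Phi_CT of a
# candidate partition costs O(demes^2) instead of O(samples^2).
deme_ss_tables <- function(d, demes) {
  lev <- unique(demes)
  K <- length(lev)
  Tm <- matrix(0, K, K, dimnames = list(lev, lev))
  for (i in seq_len(K)) {
    for (j in seq(i, K)) {
      sel_i <- which(demes == lev[i])
      sel_j <- which(demes == lev[j])
      if (i == j) {
        m <- d[sel_i, sel_i, drop = FALSE]
        Tm[i, i] <- sum(m[upper.tri(m)])
      } else {
        Tm[i, j] <- Tm[j, i] <- sum(d[sel_i, sel_j])
      }
    }
  }
  list(T = Tm, n = vapply(lev, function(l) sum(demes == l), 0L), lev = lev)
}

# Phi_CT of a deme partition (named integer group index per deme), using the
# precomputed tables. Demes are the populations of the hierarchy.
phi_ct_partition <- function(tab, part) {
  lev <- tab$lev
  n_p <- tab$n
  N <- sum(n_p)
  gidx <- part[lev]
  G <- length(unique(gidx))
  P <- length(lev)
  ssd_wp <- sum(diag(tab$T) / n_p)
  ssd_wg <- 0
  sum_npsq_over_Ng <- 0
  for (g in unique(gidx)) {
    sel <- which(gidx == g)
    Ng <- sum(n_p[sel])
    ssd_wg <- ssd_wg +
      (sum(tab$T[sel, sel, drop = FALSE]) - sum(diag(tab$T)[sel])) / 2 / Ng +
      sum(diag(tab$T)[sel]) / Ng
    sum_npsq_over_Ng <- sum_npsq_over_Ng + sum(n_p[sel]^2) / Ng
  }
  ssd_tot <- (sum(tab$T) - sum(diag(tab$T))) / 2 / N + sum(diag(tab$T)) / N
  df_ag <- G - 1
  df_ap <- P - G
  df_wp <- N - P
  sigma_c <- if (df_wp > 0) ssd_wp / df_wp else 0
  sigma_b <- if (df_ap > 0) {
    ((ssd_wg - ssd_wp) / df_ap - sigma_c) / ((N - sum_npsq_over_Ng) / df_ap)
  } else 0
  n_cp <- (sum_npsq_over_Ng - sum(n_p^2) / N) / df_ag
  Ngs <- vapply(unique(gidx), function(g) sum(n_p[gidx == g]), 0)
  n_cpp <- (N - sum(Ngs^2) / N) / df_ag
  sigma_a <- ((ssd_tot - ssd_wg) / df_ag - sigma_c - n_cp * sigma_b) / n_cpp
  tot <- sigma_a + sigma_b + sigma_c
  if (tot <= 0) return(NA_real_)
  sigma_a / tot
}

connected_after <- function(adj_list, members) {
  if (length(members) <= 1) return(TRUE)
  seen <- members[1]
  frontier <- members[1]
  while (length(frontier)) {
    nb <- unique(unlist(adj_list[frontier], use.names = FALSE))
    frontier <- setdiff(intersect(nb, members), seen)
    seen <- c(seen, frontier)
  }
  length(seen) == length(members)
}

random_contiguous_partition <- function(lev, adj_list, K) {
  seeds <- sample(lev, K)
  part <- setNames(rep(NA_integer_, length(lev)), lev)
  part[seeds] <- seq_len(K)
  while (anyNA(part)) {
    # grow a random group through a random adjacent unassigned deme
    cand <- which(!is.na(part))
    grew <- FALSE
    for (v in sample(names(cand))) {
      nb <- setdiff(adj_list[[v]], names(part)[!is.na(part)])
      if (length(nb)) {
        pick <- if (length(nb) == 1) nb else sample(nb, 1)
        part[pick] <- part[v]
        grew <- TRUE
        break
      }
    }
    if (!grew) { # disconnected leftovers: assign to a random group
      left <- names(part)[is.na(part)]
      part[left[1]] <- sample.int(K, 1)
    }
  }
  part
}

#' SAMOVA: spatial search for maximally differentiated groups of sites
#'
#' Searches, by simulated annealing over geographically contiguous
#' partitions of the sampling sites into `K` groups, for the partition
#' maximizing the among-group fixation index \eqn{\Phi_{CT}}.  Contiguity is
#' enforced on the Delaunay graph of the site coordinates: every proposed
#' group must induce a connected subgraph.  The best partition across
#' independent annealing chains wins (ties to the first found), and its
#' \eqn{\Phi_{CT}} gets a permutation p-value (whole sites permuted among
#' groups).
#'
#' @param d sample-by-sample pairwise difference matrix.
#' @param demes site assignment per sample (named by sample id or
#'   positional).
#' @param coords site coordinates (see [delaunay_adjacency()]).
#' @param K number of groups, between 2 and the number of sites.
#' @param restarts independent annealing chains (default 100).
#' @param permutations permutations for the final p-value (default 1000).
#' @param seed optional RNG seed.
#' @param t0,cooling,moves_per_temp,t_min annealing schedule: geometric
#'   cooling from `t0` by factor `cooling`, `moves_per_temp` proposals per
#'   temperature, stopping below `t_min`.
#' @return an object of class `samova_result`: `K`, `partition` (named group
#'   index per site), `phi_CT`, `p`, and `trace` (best value per restart).
#' @export
samova <- function(d, demes, coords, K, restarts = 100, permutations = 1000,
                   seed = NULL, t0 = 1, cooling = 0.9, moves_per_temp = 10,
                   t_min = 1e-3) {
  if (!is.null(seed)) set.seed(seed)
  ids <- rownames(d)
  dm <- if (!is.null(names(demes))) as.character(demes[ids]) else
    as.character(demes)
  tab <- deme_ss_tables(d, dm)
  lev <- tab$lev
  if (K > length(lev)) stop("input error: K exceeds the number of sites")
  if (K < 2) stop("input error: K must be at least 2")
  edges <- delaunay_adjacency(coords)
  adj_list <- split(c(edges[, 2], edges[, 1]), c(edges[, 1], edges[, 2]))
  adj_list <- lapply(adj_list, unique)
  if (!all(lev %in% names(adj_list))) {
    stop("input error: coordinates missing for some sites")
  }

  best_part <- NULL
  best_phi <- -Inf
  trace <- numeric(restarts)
  for (chain in seq_len(restarts)) {
    part <- random_contiguous_partition(lev, adj_list, K)
    phi <- phi_ct_partition(tab, part)
    if (is.na(phi)) phi <- -Inf
    ch_best <- phi
    ch_best_part <- part
    temp <- t0
    while (temp >= t_min) {
      for (m in seq_len(moves_per_temp)) {
        cand <- propose_move(part, adj_list, K)
        if (is.null(cand)) next
        phi_new <- phi_ct_partition(tab, cand)
        if (is.na(phi_new)) next
        delta <- phi_new - phi
        if (delta > 0 || runif(1) < exp(delta / temp)) {
          part <- cand
          phi <- phi_new
          if (phi > ch_best) {
            ch_best <- phi
            ch_best_part <- part
          }
        }
      }
      temp <- temp * cooling
    }
    trace[chain] <- ch_best
    if (ch_best > best_phi) {
      best_phi <- ch_best
      best_part <- ch_best_part
    }
  }

  # permutation p: permute whole sites among groups (respecting group sizes)
  ge <- 0L
  sizes <- table(best_part)
  for (b in seq_len(permutations)) {
    perm <- setNames(sample(best_part), names(best_part))
    phi_b <- phi_ct_partition(tab, perm)
    if (!is.na(phi_b) && phi_b >= best_phi) ge <- ge + 1L
  }
  structure(list(K = K, partition = best_part, phi_CT = best_phi,
                 p = (ge + 1) / (permutations + 1), trace = trace),
            class = "samova_result")
}

# move one deme (adjacent to another group) into that group, keeping the
# source group non-empty and connected
propose_move <- function(part, adj_list, K) {
  lev <- names(part)
  movable <- lev[vapply(lev, function(v) {
    sum(part == part[v]) > 1 && any(part[adj_list[[v]]] != part[v])
  }, TRUE)]
  if (!length(movable)) return(NULL)
  v <- if (length(movable) == 1) movable else sample(movable, 1)
  targets <- unique(part[adj_list[[v]]])
  targets <- targets[targets != part[v]]
  g_new <- if (length(targets) == 1) targets else sample(targets, 1)
  cand <- part
  cand[v] <- g_new
  src_members <- names(cand)[cand == part[v]]
  if (!connected_after(adj_list, src_members)) return(NULL)
  cand
}

#' @export
print.samova_result <- function(x, ...) {
  cat(sprintf("SAMOVA: K = %d, Phi_CT = %.4f (p = %.4g)\n", x$K, x$phi_CT,
              x$p))
  for (g in sort(unique(x$partition))) {
    cat(sprintf("  group %d: %s\n", g,
                paste(names(x$partition)[x$partition == g], collapse = ", ")))
  }
  invisible(x)
}
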