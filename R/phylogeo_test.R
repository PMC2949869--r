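#' Slatkin-Maddison s: minimum migration events on a gene tree
#'
#' The minimum number of state changes of an unordered population-label
#' character on the genealogy (Fitch parsimony), an estimator of the number
#' of migration / incomplete-sorting events needed to explain the
#' geographic distribution of the tips.  Multifurcating trees are resolved
#' at random under the seed and the minimum count over resolutions is
#' reported.
#'
#' @param tree an [ape::phylo]; tips must all be labeled with a state.
#' @param tip_states named character vector (by tip label) of deme /
#'   population states.  Defaults to the tree's `tip_deme` attribute.
#' @param n_resolutions random binary resolutions tried when the tree has
#'   polytomies (default 10).
#' @param seed optional RNG seed for polytomy resolution.
#' @param costs optional symmetric state-by-state step-cost matrix; when
#'   given, the minimum total cost (Sankoff parsimony) is returned instead
#'   of the unordered change count.
#' @return integer (or numeric, under `costs`) minimum number of changes.
#' @export
slatkin_maddison_s <- function(tree, tip_states = attr(tree, "tip_deme"),
                               n_resolutions = 10, seed = NULL,
                               costs = NULL) {
  if (is.null(tip_states)) stop("input error: tip states required")
  miss <- setdiff(tree$tip.label, names(tip_states))
  if (length(miss)) {
    stop(sprintf("input error: unlabeled tips: %s",
                 paste(miss, collapse = ", ")))
  }
  states <- as.character(tip_states[tree$tip.label])
  if (anyNA(states)) stop("input error: unlabeled tip")
  if (ape::is.binary.phylo(tree) || !is.null(costs)) {
    return(count_changes(tree, states, costs))
  }
  if (!is.null(seed)) set.seed(seed)
  min(vapply(seq_len(n_resolutions), function(i) {
    count_changes(ape::multi2di(tree, random = TRUE), states, costs)
  }, 0))
}

# Fitch (unordered) or Sankoff (cost matrix) parsimony count of a single
# multistate character; works on binary or multifurcating rooted trees.
count_changes <- function(tree, states, costs = NULL) {
  ntip <- length(tree$tip.label)
  nnode <- tree$Nnode
  lev <- sort(unique(states))
  K <- length(lev)
  post <- ape::reorder.phylo(tree, "postorder")
  if (is.null(costs)) {
    sets <- vector("list", ntip + nnode)
    for (i in seq_len(ntip)) sets[[i]] <- states[i]
    changes <- 0L
    e <- post$edge
    kids <- split(e[, 2], e[, 1])
    # postorder guarantee: children appear before their parent in the edge
    # list, so sweeping parents in first-appearance order is bottom-up
    parents <- unique(e[, 1])
    for (p in parents) {
      ch <- kids[[as.character(p)]]
      # Fitch for (possibly) multifurcating node: greedy pairwise folding
      cur <- sets[[ch[1]]]
      for (c2 in ch[-1]) {
        inter <- intersect(cur, sets[[c2]])
        if (length(inter)) {
          cur <- inter
        } else {
          cur <- union(cur, sets[[c2]])
          changes <- changes + 1L
        }
      }
      sets[[p]] <- cur
    }
    changes
  } else {
    if (is.null(dimnames(costs))) dimnames(costs) <- list(lev, lev)
    cm <- costs[lev, lev, drop = FALSE]
    sc <- matrix(Inf, ntip + nnode, K)
    for (i in seq_len(ntip)) sc[i, match(states[i], lev)] <- 0
    e <- post$edge
    kids <- split(e[, 2], e[, 1])
    for (p in unique(e[, 1])) {
      acc <- rep(0, K)
      for (ch in kids[[as.character(p)]]) {
        acc <- acc + apply(cm + matrix(sc[ch, ], K, K, byrow = TRUE), 1, min)
      }
      sc[p, ] <- acc
    }
    min(sc[ntip + 1L, ])
  }
}

#' Test an observed s against a simulated allopatric null
#'
#' Simulates `reps` gene trees under a null population tree (typically
#' allopatric fragmentation: simultaneous isolation of the regional demes),
#' computes the Slatkin-Maddison s of each simulated genealogy under the
#' alternative grouping of demes into character states, and compares the
#' observed s with the resulting null distribution.  A small observed s
#' (fewer inferred migrations than isolation-with-sorting predicts) rejects
#' the null; the p-value is the lower-tail probability
#' \eqn{P(s_{null} \le s_{obs})} and the 99% CI is the empirical 0.5-99.5
#' percentile range of the null s values.
#'
#' @param null_ptree a [population_tree()] for the null scenario; its
#'   sample sizes drive the simulation.
#' @param s_observed the observed s (integer).
#' @param alt_grouping optional named map deme -> character state; default
#'   identity (states are the demes themselves).
#' @param reps simulated gene trees (default 1000; fewer than 100 warns).
#' @param seed optional RNG seed.
#' @param costs optional step-cost matrix passed to
#'   [slatkin_maddison_s()].
#' @return object of class `sm_test`: `s_observed`, `null_s`, `mean_s`,
#'   `ci99` (length-2), `p`, and scenario metadata.
#' @export
sm_hypothesis_test <- function(null_ptree, s_observed, alt_grouping = NULL,
                               reps = 1000, seed = NULL, costs = NULL) {
  if (reps < 100) warning("fewer than 100 replicates: null distribution is coarse")
  if (!is.null(seed)) set.seed(seed)
  demes <- null_ptree$phy$tip.label
  if (is.null(alt_grouping)) alt_grouping <- setNames(demes, demes)
  if (!all(demes[null_ptree$samples > 0] %in% names(alt_grouping))) {
    stop("input error: alternative grouping does not cover the sampled demes")
  }
  null_s <- vapply(seq_len(reps), function(r) {
    gt <- simulate_gene_tree(null_ptree)
    st <- setNames(as.character(alt_grouping[attr(gt, "tip_deme")]),
                   gt$tip.label)
    slatkin_maddison_s(gt, st, costs = costs)
  }, 0)
  structure(list(
    s_observed = s_observed, null_s = null_s, mean_s = mean(null_s),
    ci99 = unname(quantile(null_s, c(0.005, 0.995), type = 1)),
    p = mean(null_s <= s_observed), reps = reps,
    tmrca = max(null_ptree$times), Ne = null_ptree$Ne[1]
  ), class = "sm_test")
}

#' @export
print.sm_test <- function(x, ...) {
  cat(sprintf("Slatkin-Maddison test: observed s = %d, null mean s = %.2f (99%% CI %d - %d), p = %.4g\n",
              x$s_observed, x$mean_s, x$ci99[1], x$ci99[2], x$p))
  invisible(x)
}

#' Run a grid of Slatkin-Maddison null scenarios
#'
#' Crosses generations-to-tMRCA and effective-population-size values,
#' simulating the null s distribution for each scenario, and reports a
#' table in the familiar survey layout.
#'
#' @param generations vector of root times (generations).
#' @param Ne vector of haploid effective sizes.
#' @param s_observed observed s compared against every scenario.
#' @param samples named per-deme sample sizes.
#' @param hypothesis null topology passed to [hypothesis_tree()] (default
#'   `"null"` = allopatric fragmentation).
#' @param reps,seed simulation controls; each scenario is seeded
#'   deterministically from `seed`.
#' @return data frame with columns `generations`, `Ne`, `mean_s`,
#'   `ci99_low`, `ci99_high`, `p`, in the input grid order.
#' @export
run_scenarios <- function(generations, Ne, s_observed,
                          samples = c(West = 6, Andean = 19, North = 13,
                                      South = 7),
                          hypothesis = "null", reps = 1000, seed = NULL) {
  grid <- expand.grid(Ne = Ne, generations = generations)[, 2:1]
  grid <- grid[order(match(grid$generations, generations),
                     match(grid$Ne, Ne)), , drop = FALSE]
  rows <- lapply(seq_len(nrow(grid)), function(i) {
    pt <- hypothesis_tree(hypothesis, tmrca = grid$generations[i],
                          Ne = grid$Ne[i], samples = samples)
    res <- sm_hypothesis_test(pt, s_observed, reps = reps,
                              seed = if (is.null(seed)) NULL else seed + i)
    data.frame(generations = grid$generations[i], Ne = grid$Ne[i],
               mean_s = res$mean_s, ci99_low = res$ci99[1],
               ci99_high = res$ci99[2], p = res$p)
  })
  do.call(rbind, rows)
}
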