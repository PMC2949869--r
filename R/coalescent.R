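#' Population trees for the structured coalescent
#'
#' A population tree is a rooted (possibly multifurcating) tree over demes
#' with divergence times in generations before present, a haploid effective
#' size `Ne` for the population on the branch above every node (the root's
#' `Ne` extends indefinitely into the past), and a sample size per tip deme.
#' mtDNA is haploid and maternally inherited, so `Ne` throughout is the
#' haploid (female effective) size and k lineages coalesce at rate
#' k(k-1)/(2 Ne) per generation.
#'
#' @param phy an ultrametric [ape::phylo] (tips = demes), edge lengths in
#'   generations.  Multifurcations encode simultaneous splits.
#' @param Ne haploid effective sizes: single value recycled to all
#'   branches, or vector named by node label (tip labels and, optionally,
#'   `"root"` plus internal node labels).
#' @param samples named integer vector of sample sizes per tip deme.
#' @return an object of class `population_tree`.
#' @export
population_tree <- function(phy, Ne, samples) {
  if (!inherits(phy, "phylo")) stop("input error: phy must be an ape phylo")
  ntip <- length(phy$tip.label)
  nnode <- phy$Nnode
  total <- ntip + nnode
  depths <- ape::node.depth.edgelength(phy)
  height <- max(depths)
  times <- height - depths # tips at 0, root at height
  if (any(times[seq_len(ntip)] > 1e-6 * max(height, 1))) {
    stop("input error: population tree must be ultrametric (tips at present)")
  }
  internal_labels <- if (!is.null(phy$node.label)) phy$node.label else
    character(nnode)
  blank <- !nzchar(internal_labels)
  internal_labels[blank] <- paste0("anc", which(blank))
  node_labels <- c(phy$tip.label, internal_labels)
  root <- ntip + 1L
  if (length(Ne) == 1 && is.null(names(Ne))) {
    Ne_vec <- rep(as.numeric(Ne), total)
  } else {
    nm <- names(Ne)
    nm[nm == "root"] <- node_labels[root] # "root" aliases the root node
    Ne_vec <- rep(NA_real_, total)
    hit <- match(nm, node_labels)
    if (anyNA(hit)) stop("input error: Ne names do not match node labels")
    Ne_vec[hit] <- as.numeric(Ne)
    if (anyNA(Ne_vec)) stop("input error: Ne missing for some nodes")
  }
  if (any(Ne_vec <= 0)) stop("input error: Ne must be positive")
  if (is.null(names(samples)) ||
      !all(names(samples) %in% phy$tip.label)) {
    stop("input error: samples must be named by tip deme")
  }
  smp <- setNames(rep(0L, ntip), phy$tip.label)
  smp[names(samples)] <- as.integer(samples)
  if (any(smp < 0)) stop("input error: sample sizes must be >= 0")
  structure(list(phy = phy, times = times, Ne = Ne_vec,
                 node_labels = node_labels, samples = smp, ntip = ntip),
            class = "population_tree")
}

#' @export
print.population_tree <- function(x, ...) {
  cat(sprintf("population_tree: %d demes, height %.0f generations, %d samples\n",
              x$ntip, max(x$times), sum(x$samples)))
  cat(" demes:", paste(sprintf("%s (n=%d, Ne=%g)", x$phy$tip.label,
                               x$samples, x$Ne[seq_len(x$ntip)]),
                       collapse = ", "), "\n")
  invisible(x)
}

#' Single panmictic deme as a degenerate population tree
#'
#' Convenience constructor for the unstructured case (one deme, constant
#' size), used for calibration against closed-form coalescent expectations
#' such as E[TMRCA] = 2 Ne (1 - 1/n).
#'
#' @param Ne haploid effective size.
#' @param n sample size.
#' @param deme deme name.
#' @return a [population_tree()].
#' @export
single_deme_tree <- function(Ne, n, deme = "A") {
  phy <- structure(list(edge = matrix(c(2L, 1L), 1, 2), tip.label = deme,
                        edge.length = 0, Nnode = 1L), class = "phylo")
  population_tree(phy, Ne, setNames(n, deme))
}

#' Read a population tree from annotated newick
#'
#' The dialect carries per-branch effective sizes as `[&Ne=...]` comments
#' after node labels or branch lengths, e.g.
#' `((A[&Ne=1e4]:100,B[&Ne=1e4]:100)[&Ne=2e4]:50,C[&Ne=1e4]:150)[&Ne=2e4];`.
#'
#' @param text newick string (or `path` to a file).
#' @param samples named sample sizes per tip deme.
#' @param path optional file to read instead of `text`.
#' @return a [population_tree()].
#' @export
read_population_tree <- function(text = NULL, samples, path = NULL) {
  if (is.null(text)) text <- paste(readLines(path), collapse = "")
  ann_re <- "\\[&Ne=([0-9.eE+-]+)\\]"
  labs <- character(0)
  vals <- numeric(0)
  gen <- 0L
  repeat {
    m <- regexpr(ann_re, text)
    if (m == -1) break
    val <- as.numeric(sub(ann_re, "\\1", regmatches(text, m)))
    before <- substr(text, 1, m - 1)
    lab <- sub(".*?([A-Za-z0-9_.]*)$", "\\1", before)
    if (!nzchar(lab)) { # unlabeled node: insert a generated label
      gen <- gen + 1L
      lab <- paste0("nd", gen)
      before <- paste0(before, lab)
    }
    labs <- c(labs, lab)
    vals <- c(vals, val)
    text <- paste0(before, substr(text, m + attr(m, "match.length"),
                                  nchar(text)))
  }
  phy <- tryCatch(ape::read.tree(text = text), error = function(e) NULL)
  if (is.null(phy)) stop("parse error: invalid population-tree newick")
  Ne <- if (length(vals)) setNames(vals, labs) else
    stop("input error: no [&Ne=..] annotations found")
  population_tree(phy, Ne, samples)
}

#' Simulate a gene tree under the structured coalescent without migration
#'
#' Lineages coalesce only inside their current deme (or ancestral
#' population): within a population of haploid size Ne, k lineages coalesce
#' at exponential rate k(k-1)/(2 Ne) per generation.  At each divergence
#' time the lineage sets of the daughter populations merge into the
#' ancestral population.  The root population always coalesces the
#' remaining lineages.
#'
#' @param ptree a [population_tree()].
#' @param seed optional RNG seed (seeded runs are bit-reproducible).
#' @return an [ape::phylo] with branch lengths in generations, tip labels
#'   `<deme>_<i>`, and an attribute `tip_deme` (named deme per tip).
#' @export
simulate_gene_tree <- function(ptree, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  n_total <- sum(ptree$samples)
  if (n_total < 1) stop("input error: no samples to simulate")
  phy <- ptree$phy
  ntip <- ptree$ntip
  root <- ntip + 1L
  n_nodes_pop <- ntip + phy$Nnode
  children <- split(phy$edge[, 2], phy$edge[, 1])

  # gene-tree node bookkeeping
  tip_deme <- rep(phy$tip.label, times = ptree$samples)
  tip_labels <- unlist(lapply(seq_len(ntip), function(i) {
    k <- ptree$samples[i]
    if (k == 0) character(0) else paste0(phy$tip.label[i], "_", seq_len(k))
  }), use.names = FALSE)
  max_nodes <- 2L * max(n_total, 1L) - 1L
  g_time <- numeric(max_nodes)
  g_parent <- integer(max_nodes)
  nxt <- n_total + 1L

  # active lineages per population-tree node, processed in time order
  lineages <- vector("list", n_nodes_pop)
  idx <- 0L
  for (i in seq_len(ntip)) {
    k <- ptree$samples[i]
    lineages[[i]] <- if (k > 0) idx + seq_len(k) else integer(0)
    idx <- idx + k
  }

  # process populations tip-ward to root-ward by divergence time
  ord <- order(ptree$times[seq.int(ntip + 1L, n_nodes_pop)])
  internal_order <- (ntip + 1L):n_nodes_pop
  internal_order <- internal_order[ord]
  # first run each tip branch from 0 to its parent's time
  parent_of <- integer(n_nodes_pop)
  parent_of[phy$edge[, 2]] <- phy$edge[, 1]
  run_branch <- function(node) {
    act <- lineages[[node]]
    t_start <- ptree$times[node]
    t_end <- if (node == root) Inf else ptree$times[parent_of[node]]
    Ne <- ptree$Ne[node]
    t_now <- t_start
    while (length(act) > 1) {
      k <- length(act)
      wait <- rexp(1, rate = k * (k - 1) / (2 * Ne))
      if (t_now + wait > t_end) break
      t_now <- t_now + wait
      pair <- sample(k, 2)
      g_time[nxt] <<- t_now
      g_parent[act[pair]] <<- nxt
      act <- c(act[-pair], nxt)
      nxt <<- nxt + 1L
    }
    lineages[[node]] <<- act
  }
  for (i in seq_len(ntip)) run_branch(i)
  for (v in internal_order) {
    lineages[[v]] <- unlist(lineages[children[[as.character(v)]]],
                            use.names = FALSE)
    run_branch(v)
  }
  stopifnot(length(lineages[[root]]) == 1)

  if (n_total == 1) {
    tr <- structure(list(edge = matrix(c(2L, 1L), 1, 2), tip.label = tip_labels,
                         edge.length = 0, Nnode = 1L), class = "phylo")
    attr(tr, "tip_deme") <- setNames(tip_deme, tip_labels)
    return(tr)
  }
  # assemble phylo: internal gene nodes n_total+1 .. 2*n_total-1 exist;
  # ape wants the root to be node n_total+1
  n_internal <- n_total - 1L
  new_id <- integer(2L * n_total - 1L)
  new_id[seq_len(n_total)] <- seq_len(n_total)
  # renumber internal nodes in reverse creation order: the root (created
  # last) becomes n_total+1 and every parent gets a smaller id than its
  # children, as ape expects of a rooted tree
  internal <- seq.int(n_total + 1L, 2L * n_total - 1L)
  root_g <- 2L * n_total - 1L
  new_id[internal] <- n_total + 1L + (root_g - internal)
  edge <- cbind(new_id[g_parent[seq_len(2L * n_total - 2L)]],
                new_id[seq_len(2L * n_total - 2L)])
  edge_length <- g_time[g_parent[seq_len(2L * n_total - 2L)]] -
    g_time[seq_len(2L * n_total - 2L)]
  tr <- structure(list(edge = edge, tip.label = tip_labels,
                       edge.length = edge_length, Nnode = n_internal),
                  class = "phylo")
  tr <- ape::reorder.phylo(tr, "cladewise")
  attr(tr, "tip_deme") <- setNames(tip_deme, tip_labels)
  tr
}

#' Built-in phylogeographic hypothesis trees
#'
#' Population trees over the four geographic regions of a continent-wide
#' survey (`West`, `Andean`, `North`, `South`), encoding three divergence
#' hypotheses:
#' \describe{
#'   \item{`null`}{allopatric fragmentation: a simultaneous four-way split
#'     of all regional demes at `tmrca`; the ancestral population has the
#'     same Ne as each regional deme.}
#'   \item{`ii`}{gradient first: Andean foothills split from a western
#'     lowland ancestor at `tmrca`, then the northern and southern lineages
#'     (the two banks of the Amazon) split off the western lineage.}
#'   \item{`iii`}{river first: the north+south lineage leaves the western
#'     ancestral population at `tmrca` and splits across the river, with the
#'     Andean foothill divergence from the western lowlands coming later.}
#' }
#' Internal divergence times are evenly spaced fractions (2/3, 1/3) of
#' `tmrca`; the hypotheses fix branching order only, not times.
#'
#' @param hypothesis `"null"`, `"ii"` or `"iii"`.
#' @param tmrca root divergence time in generations.
#' @param Ne haploid effective size applied to every branch.
#' @param samples named sample sizes per region; defaults to the survey
#'   design (West 6, Andean 19, North 13, South 7).
#' @return a [population_tree()].
#' @export
hypothesis_tree <- function(hypothesis = c("null", "ii", "iii"), tmrca, Ne,
                            samples = c(West = 6, Andean = 19, North = 13,
                                        South = 7)) {
  hypothesis <- match.arg(hypothesis)
  t1 <- tmrca
  t2 <- tmrca * 2 / 3
  t3 <- tmrca / 3
  nwk <- switch(hypothesis,
    null = sprintf("(West:%.12g,Andean:%.12g,North:%.12g,South:%.12g);",
                   t1, t1, t1, t1),
    ii = sprintf("(Andean:%.12g,(West:%.12g,(North:%.12g,South:%.12g):%.12g):%.12g);",
                 t1, t2, t3, t3, t2 - t3, t1 - t2),
    iii = sprintf("((North:%.12g,South:%.12g):%.12g,(West:%.12g,Andean:%.12g):%.12g);",
                  t2, t2, t1 - t2, t3, t3, t1 - t3))
  phy <- ape::read.tree(text = nwk)
  population_tree(phy, Ne, samples)
}
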