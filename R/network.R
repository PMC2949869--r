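hap_seq_matrix <- function(seqs) do.call(rbind, strsplit(seqs, ""))

# pairwise Hamming distances between two sets of sequence strings
cross_hamming <- function(a, b) {
  ma <- hap_seq_matrix(a)
  mb <- hap_seq_matrix(b)
  out <- matrix(0L, length(a), length(b))
  for (i in seq_along(a)) {
    out[i, ] <- colSums(t(mb) != ma[i, ])
  }
  out
}

#' Minimum spanning network of haplotypes
#'
#' The union of all minimum spanning trees under Hamming distance, built by
#' merging components level by level: at each step all inter-component edges
#' within `epsilon` of the current minimum connecting distance are added.
#' With `epsilon = 0` this is exactly the union-of-MSTs network; a positive
#' `epsilon` relaxes the criterion as in the median-joining construction.
#'
#' @param haps a `haplotype_table`, or a named character vector of
#'   haplotype sequences.
#' @param epsilon relaxation parameter (default 0).
#' @return an object of class `haplotype_network`: list with `nodes` (data
#'   frame `id`, `sequence`, `median`, `count`), `edges` (data frame `from`,
#'   `to`, `weight`) and `epsilon`.
#' @export
minimum_spanning_network <- function(haps, epsilon = 0) {
  nd <- network_nodes(haps)
  build_msn(nd, epsilon)
}

network_nodes <- function(haps) {
  if (inherits(haps, "haplotype_table")) {
    # canonical order: by sequence, so output does not depend on input order
    ord <- order(haps$haplotypes$sequence)
    data.frame(id = haps$haplotypes$hap_id[ord],
               sequence = haps$haplotypes$sequence[ord],
               median = FALSE, count = rowSums(haps$counts)[ord],
               stringsAsFactors = FALSE)
  } else {
    if (is.null(names(haps))) names(haps) <- paste0("H", seq_along(haps))
    ord <- order(haps)
    data.frame(id = names(haps)[ord], sequence = unname(haps[ord]),
               median = FALSE, count = 1L, stringsAsFactors = FALSE)
  }
}

build_msn <- function(nodes, epsilon = 0) {
  k <- nrow(nodes)
  if (k < 2) stop("input error: need at least 2 haplotypes")
  d <- cross_hamming(nodes$sequence, nodes$sequence)
  comp <- seq_len(k)
  edges <- NULL
  while (length(unique(comp)) > 1) {
    inter <- outer(comp, comp, "!=") & upper.tri(d)
    m <- min(d[inter])
    take <- which(inter & d <= m + epsilon, arr.ind = TRUE)
    edges <- rbind(edges, data.frame(
      from = nodes$id[take[, 1]], to = nodes$id[take[, 2]],
      weight = d[take], stringsAsFactors = FALSE))
    for (r in seq_len(nrow(take))) {
      ci <- comp[take[r, 1]]
      cj <- comp[take[r, 2]]
      comp[comp == cj] <- ci
    }
  }
  structure(list(nodes = nodes, edges = edges, epsilon = epsilon),
            class = "haplotype_network")
}

#' @export
print.haplotype_network <- function(x, ...) {
  cat(sprintf("haplotype_network: %d nodes (%d median), %d edges, epsilon = %g\n",
              nrow(x$nodes), sum(x$nodes$median), nrow(x$edges), x$epsilon))
  invisible(x)
}

# consensus (median) sequences of three aligned haplotypes: per-column
# majority; columns with three distinct states yield one median per state
# (all tied medians, deduplicated by the caller)
triplet_medians <- function(a, b, c) {
  m <- rbind(strsplit(a, "")[[1]], strsplit(b, "")[[1]], strsplit(c, "")[[1]])
  cols <- lapply(seq_len(ncol(m)), function(j) {
    tb <- table(m[, j])
    if (max(tb) >= 2) names(tb)[which.max(tb)] else unique(m[, j])
  })
  grid <- expand.grid(cols, stringsAsFactors = FALSE)
  apply(grid, 1, paste0, collapse = "")
}

#' Median-joining haplotype network
#'
#' Iterative construction after Bandelt: build the minimum spanning network
#' at tolerance `epsilon`, consider every triple of mutually linked nodes,
#' add their majority-consensus median vectors when doing so lowers the
#' total edge length of the network, prune median vectors of degree below
#' three, and repeat to a fixed point.  Median vectors are flagged in the
#' node table; edge weights are Hamming distances.
#'
#' @inheritParams minimum_spanning_network
#' @param max_iter safety cap on construction rounds.
#' @return a `haplotype_network` whose `nodes$median` flags inferred
#'   (unsampled) intermediates.
#' @export
median_joining <- function(haps, epsilon = 0, max_iter = 20) {
  sampled <- network_nodes(haps)
  nodes <- sampled
  net <- build_msn(nodes, epsilon)
  for (iter in seq_len(max_iter)) {
    cost <- sum(net$edges$weight)
    adj <- edge_adjacency(net)
    cand <- character(0)
    ids <- nodes$id
    for (u in ids) {
      nb <- adj[[u]]
      if (length(nb) < 2) next
      pairs <- utils::combn(nb, 2)
      for (pp in seq_len(ncol(pairs))) {
        v <- pairs[1, pp]; w <- pairs[2, pp]
        meds <- triplet_medians(
          nodes$sequence[nodes$id == u],
          nodes$sequence[nodes$id == v],
          nodes$sequence[nodes$id == w])
        cand <- c(cand, meds)
      }
    }
    cand <- setdiff(unique(cand), nodes$sequence)
    if (!length(cand)) break
    # keep medians that reduce total network length when added
    added <- FALSE
    for (s in cand) {
      trial_nodes <- rbind(nodes, data.frame(
        id = paste0("mv", sum(nodes$median) + 1L), sequence = s,
        median = TRUE, count = 0L, stringsAsFactors = FALSE))
      trial_nodes <- trial_nodes[order(trial_nodes$sequence), , drop = FALSE]
      trial <- build_msn(trial_nodes, epsilon)
      if (sum(trial$edges$weight) < cost) {
        nodes <- trial_nodes
        net <- trial
        cost <- sum(trial$edges$weight)
        added <- TRUE
      }
    }
    # prune obsolete medians (degree < 3), then rebuild
    repeat {
      deg <- edge_degrees(net)
      drop <- nodes$id[nodes$median & deg[nodes$id] < 3]
      if (!length(drop)) break
      nodes <- nodes[!nodes$id %in% drop, , drop = FALSE]
      net <- build_msn(nodes, epsilon)
    }
    if (!added) break
  }
  # stable ids for medians after construction
  net$nodes$id[net$nodes$median] <-
    paste0("mv", seq_len(sum(net$nodes$median)))
  rebuilt <- build_msn(net$nodes, epsilon)
  rebuilt
}

edge_adjacency <- function(net) {
  adj <- split(c(net$edges$to, net$edges$from),
               c(net$edges$from, net$edges$to))
  adj <- lapply(adj, unique)
  for (id in setdiff(net$nodes$id, names(adj))) adj[[id]] <- character(0)
  adj
}

edge_degrees <- function(net) {
  deg <- table(factor(c(net$edges$from, net$edges$to),
                      levels = net$nodes$id))
  setNames(as.integer(deg), names(deg))
}

#' Convert a haplotype network to igraph
#'
#' @param net a `haplotype_network`.
#' @return an [igraph::graph] with node attributes `sequence`, `median`,
#'   `count` and edge attribute `weight`.
#' @export
as_igraph <- function(net) {
  g <- igraph::graph_from_data_frame(net$edges, directed = FALSE,
                                     vertices = net$nodes)
  g
}

#' Export a haplotype network to GraphML or DOT
#'
#' @param net a `haplotype_network`.
#' @param path output file.
#' @param format `"graphml"` or `"dot"`.
#' @return `path`, invisibly.
#' @export
write_network <- function(net, path, format = c("graphml", "dot")) {
  format <- match.arg(format)
  igraph::write_graph(as_igraph(net), path, format = format)
  invisible(path)
}
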