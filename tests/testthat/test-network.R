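test_that("minimum spanning network handles unique and tied MSTs", {
  # two haplotypes at distance 1: a single edge
  n2 <- minimum_spanning_network(c(a = "AT", b = "AA"))
  expect_equal(nrow(n2$edges), 1)
  expect_equal(n2$edges$weight, 1)

  # perfect three-way tie: all three edges belong to some MST
  tri <- minimum_spanning_network(c(a = "AAT", b = "ATA", c = "TAA"))
  expect_equal(nrow(tri$edges), 3)
  expect_equal(tri$edges$weight, rep(2, 3))

  # star data: unique MST
  star <- minimum_spanning_network(c(ctr = "AAAA", s1 = "AAAT",
                                     s2 = "AATA", s3 = "ATAA"))
  expect_equal(nrow(star$edges), 3)
  expect_true(all(star$edges$from == "ctr" | star$edges$to == "ctr"))
  expect_error(minimum_spanning_network(c(a = "A")), "at least 2")
})

test_that("union-of-MSTs property holds against exhaustive enumeration", {
  # enumerate all spanning trees of the complete graph on 4 sequences,
  # find the minimum total weight, and check edge-set equality with the MSN
  haps <- c(w = "AACC", x = "AATC", y = "TTCC", z = "TTTC")
  net <- minimum_spanning_network(haps)
  seqs <- strsplit(haps, "")
  d <- function(i, j) sum(seqs[[i]] != seqs[[j]])
  verts <- names(haps)
  all_edges <- t(combn(verts, 2))
  # spanning trees on 4 vertices: choose 3 edges that connect all
  combs <- combn(nrow(all_edges), 3)
  best <- Inf
  in_some_mst <- character(0)
  for (ci in seq_len(ncol(combs))) {
    es <- all_edges[combs[, ci], , drop = FALSE]
    g <- igraph::graph_from_edgelist(es, directed = FALSE)
    if (igraph::vcount(g) < 4 || igraph::components(g)$no != 1) next
    w <- sum(apply(es, 1, function(e) d(which(verts == e[1]),
                                        which(verts == e[2]))))
    if (w < best) {
      best <- w
      in_some_mst <- apply(es, 1, function(e) paste(sort(e), collapse = "-"))
    } else if (w == best) {
      in_some_mst <- union(in_some_mst,
                           apply(es, 1, function(e) paste(sort(e),
                                                          collapse = "-")))
    }
  }
  got <- sort(paste(pmin(net$edges$from, net$edges$to),
                    pmax(net$edges$from, net$edges$to), sep = "-"))
  expect_equal(got, sort(in_some_mst))
})

test_that("median joining adds the consensus vector on the worked triplet", {
  net <- median_joining(c(a = "AAA", b = "AGG", c = "GAG"))
  med <- net$nodes[net$nodes$median, ]
  expect_equal(nrow(med), 1)
  expect_equal(med$sequence, "AAG")
  # total length drops from the 6 of the pairwise triangle to 3
  expect_equal(sum(net$edges$weight), 3)
  # median vectors keep degree >= 3
  deg <- table(c(net$edges$from, net$edges$to))
  expect_gte(unname(deg[med$id]), 3)
})

test_that("median joining never adds medians for two haplotypes", {
  net <- median_joining(c(a = "AAAA", b = "TTAA"))
  expect_equal(sum(net$nodes$median), 0)
  expect_equal(nrow(net$edges), 1)
})

test_that("network construction is invariant to input order", {
  haps <- c(a = "AAA", b = "AGG", c = "GAG", d = "GGG")
  n1 <- median_joining(haps)
  n2 <- median_joining(rev(haps))
  canon <- function(net) {
    key <- net$nodes$sequence[match(c(net$edges$from, net$edges$to),
                                    net$nodes$id)]
    m <- matrix(key, ncol = 2)
    sort(paste(pmin(m[, 1], m[, 2]), pmax(m[, 1], m[, 2])))
  }
  expect_equal(canon(n1), canon(n2))
  expect_equal(sort(n1$nodes$sequence), sort(n2$nodes$sequence))
})

test_that("medians lie on shortest paths between sampled haplotypes", {
  set.seed(40)
  for (rep in 1:5) {
    k <- sample(3:5, 1)
    haps <- unique(vapply(seq_len(k), function(i) {
      paste0(sample(c("A", "T"), 5, replace = TRUE), collapse = "")
    }, ""))
    if (length(haps) < 3) next
    names(haps) <- paste0("h", seq_along(haps))
    net <- median_joining(haps)
    meds <- net$nodes$sequence[net$nodes$median]
    sampled <- net$nodes$sequence[!net$nodes$median]
    ham <- function(x, y) sum(strsplit(x, "")[[1]] != strsplit(y, "")[[1]])
    for (m in meds) {
      on_path <- FALSE
      for (i in seq_along(sampled)) {
        for (j in seq_along(sampled)) {
          if (i < j &&
              ham(sampled[i], m) + ham(m, sampled[j]) ==
              ham(sampled[i], sampled[j])) on_path <- TRUE
        }
      }
      expect_true(on_path)
    }
  }
})

test_that("MJ network with epsilon 0 spans all nodes via minimal links", {
  # the final network is the MSN of its own node set, hence contains a
  # minimum spanning tree of that node set and is connected
  haps <- c(a = "AAAAA", b = "AATTA", c = "TTAAA", d = "TTTTA", e = "AAAAT")
  net <- median_joining(haps)
  g <- igraph::graph_from_data_frame(net$edges, directed = FALSE,
                                     vertices = net$nodes$id)
  expect_equal(igraph::components(g)$no, 1)
  mst_w <- sum(igraph::E(igraph::mst(igraph::set_edge_attr(
    g, "weight", value = net$edges$weight)))$weight)
  # every MST of the node set is a subgraph of the network, so the network
  # total weight is at least the MST weight and each MST edge weight class
  # appears among the network edges
  expect_gte(sum(net$edges$weight), mst_w)
})

test_that("network export formats are written", {
  net <- median_joining(c(a = "AAA", b = "AGG", c = "GAG"))
  f1 <- withr::local_tempfile(fileext = ".graphml")
  f2 <- withr::local_tempfile(fileext = ".dot")
  write_network(net, f1, "graphml")
  write_network(net, f2, "dot")
  expect_gt(file.size(f1), 0)
  expect_gt(file.size(f2), 0)
})
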