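test_that("F84 distance matches the closed form evaluated independently", {
  # 100 sites, ten transitions between the two sequences, equal base use
  base <- paste(rep(c("A", "C", "G", "T"), 25), collapse = "")
  m <- rbind(x = strsplit(base, "")[[1]], y = strsplit(base, "")[[1]])
  ti <- c(A = "G", C = "T", G = "A", T = "C")
  m["y", 1:10] <- ti[m["y", 1:10]]
  aln <- seq_alignment(m)
  d <- f84_distance(aln)
  freq <- table(factor(m, levels = c("A", "C", "G", "T"))) / length(m)
  expected <- oracle_f84(P = 0.1, Q = 0, freq = c(A = 0.25, C = 0.25,
                                                  G = 0.25, T = 0.25))
  expect_equal(d["x", "y"], expected, tolerance = 1e-4)

  ident <- seq_alignment(c(u = "ACGTACGT", v = "ACGTACGT"))
  expect_equal(f84_distance(ident)["u", "v"], 0)
})

test_that("F84 approaches the observed proportion for small divergence", {
  L <- 2000
  base <- strsplit(paste(rep(c("A", "C", "G", "T"), L / 4), collapse = ""),
                   "")[[1]]
  y <- base
  y[1:4] <- c("G", "T", "C", "A") # 2 transitions + 2 transversions
  aln <- seq_alignment(rbind(x = base, y = y))
  d <- f84_distance(aln)["x", "y"]
  p_obs <- 4 / L
  expect_lt(abs(d - p_obs), 0.05 * p_obs)
})

test_that("F84 reduces to Jukes-Cantor under equal frequencies, collapsed ti/tv", {
  # with equal frequencies and the symmetric 1:2 ti:tv split (P = p/3,
  # Q = 2p/3) the F84 ML distance collapses to Jukes-Cantor
  L <- 300
  base <- strsplit(paste(rep(c("A", "C", "G", "T"), L / 4), collapse = ""),
                   "")[[1]]
  y <- base
  # 30 substitutions: 10 transitions, 20 transversions (the 1:2 JC ratio)
  ti <- c(A = "G", C = "T", G = "A", T = "C")
  tv <- c(A = "C", C = "A", G = "T", T = "G")
  y[1:10] <- ti[y[1:10]]
  y[11:30] <- tv[y[11:30]]
  aln <- seq_alignment(rbind(x = base, y = y))
  d <- f84_distance(aln)["x", "y"]
  p <- 30 / L
  jc <- -3 / 4 * log(1 - 4 * p / 3)
  expect_equal(d, jc, tolerance = 1e-5)
})

test_that("UPGMA reproduces a hand-computed agglomeration exactly", {
  dm <- matrix(c(0, 2, 6, 10,
                 2, 0, 6, 10,
                 6, 6, 0, 10,
                 10, 10, 10, 0), 4, 4,
               dimnames = list(letters[1:4], letters[1:4]))
  tr <- upgma_tree(dm)
  # hand agglomeration: (a,b) merge at distance 2 (height 1), ((a,b),c) at
  # 6 (height 3), root at 10 (height 5)
  expect_equal(ape::write.tree(tr), "(d:5,(c:3,(a:1,b:1):2):2);")
  depths <- ape::node.depth.edgelength(tr)[1:4]
  expect_true(all(abs(depths - depths[1]) < 1e-12)) # ultrametric
})

test_that("two taxa root at half their distance", {
  dm <- matrix(c(0, 3, 3, 0), 2, 2, dimnames = list(c("p", "q"), c("p", "q")))
  tr <- upgma_tree(dm)
  expect_equal(max(ape::node.depth.edgelength(tr)), 1.5)
  expect_equal(ape::cophenetic.phylo(tr)["p", "q"], 3)
})

test_that("UPGMA recovers the generating tree from its ultrametric matrix", {
  set.seed(60)
  for (rep in 1:5) {
    src <- ape::rcoal(6)
    dm <- ape::cophenetic.phylo(src)
    tr <- upgma_tree(dm)
    expect_equal(ape::dist.topo(ape::unroot(tr), ape::unroot(src)), 0,
                 ignore_attr = TRUE)
    expect_equal(ape::cophenetic.phylo(tr)[rownames(dm), colnames(dm)], dm,
                 tolerance = 1e-9)
  }
})

test_that("newick round-trips topology, labels and lengths", {
  f <- withr::local_tempfile(fileext = ".nwk")
  writeLines("(A:1,B:1):0;", f)
  tr <- read_newick(f)
  expect_equal(sort(tr$tip.label), c("A", "B"))
  write_newick(tr, f)
  tr2 <- read_newick(f)
  expect_equal(tr2$edge.length, tr$edge.length)

  set.seed(9)
  for (rep in 1:20) {
    src <- ape::rtree(sample(3:10, 1))
    write_newick(src, f)
    back <- read_newick(f)
    expect_equal(ape::dist.topo(ape::unroot(back), ape::unroot(src)), 0,
                 ignore_attr = TRUE)
    expect_equal(sort(back$edge.length), sort(src$edge.length),
                 tolerance = 1e-9)
  }
  bad <- withr::local_tempfile(fileext = ".nwk")
  writeLines("(A:1,B", bad)
  expect_error(read_newick(bad), "parse error")
})

test_that("polytomies are preserved and resolvable under a seed", {
  f <- withr::local_tempfile(fileext = ".nwk")
  writeLines("(A:1,B:1,C:1,D:1);", f)
  tr <- read_newick(f)
  expect_false(ape::is.binary.phylo(tr))
  r1 <- resolve_polytomies(tr, seed = 4)
  r2 <- resolve_polytomies(tr, seed = 4)
  expect_true(ape::is.binary.phylo(r1))
  expect_equal(ape::write.tree(r1), ape::write.tree(r2))
})

test_that("observed gene tree gives one tip per haplotype-site occurrence", {
  ids <- c("a1", "a2", "b1", "b2", "c1")
  # haplotype shared between sites d1 and d2 -> two tips
  aln <- seq_alignment(setNames(
    c("AAAA", "AATT", "AAAA", "TTTT", "TTAA"), ids))
  map <- toy_map(ids, sites = c("d1", "d1", "d2", "d2", "d3"),
                 groups = c("g1", "g1", "g2", "g2", "g3"))
  tr <- observed_gene_tree(aln, map)
  expect_equal(length(tr$tip.label), 4 + 1) # 4 haplotypes, one shared twice
  sites <- attr(tr, "tip_site")
  shared <- grep("@", names(sites)[duplicated(sub("@.*", "", names(sites)))],
                 value = TRUE)
  expect_equal(length(unique(sub("@.*", "", shared))), 1)
})
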