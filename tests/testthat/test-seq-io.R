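test_that("FASTA parsing preserves records and validates the alignment", {
  f <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c(">s1", "ACGT", ">s2", "acg-"), f)
  aln <- read_fasta(f)
  expect_s3_class(aln, "seq_alignment")
  expect_equal(nrow(aln), 2)
  expect_equal(attr(aln, "L"), 4)
  expect_equal(rownames(aln), c("s1", "s2"))
  expect_equal(unclass(aln)["s2", ], c("A", "C", "G", "-"),
               ignore_attr = TRUE)

  ragged <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c(">a", "ACGT", ">b", "ACGTT"), ragged)
  expect_error(read_fasta(ragged), "ragged")

  expect_error(seq_alignment(c(a = "ACGT", a = "ACGT")), "duplicate")
  expect_error(seq_alignment(c(a = "ACXT")), "illegal character")
  expect_error(read_fasta(file.path(tempdir(), "no-such-file.fa")),
               "no such file")
})

test_that("FASTA round-trips through write_fasta", {
  aln <- random_alignment(5, 30)
  f <- withr::local_tempfile(fileext = ".fasta")
  write_fasta(aln, f)
  back <- read_fasta(f)
  expect_identical(unclass(back), unclass(aln))
})

test_that("haplotype collapsing forms identity classes with per-deme counts", {
  ids <- paste0("s", 1:5)
  aln <- seq_alignment(setNames(rep("ACGT", 5), ids))
  h <- collapse_haplotypes(aln, toy_map(ids))
  expect_equal(nrow(h$haplotypes), 1)
  expect_equal(sum(h$counts), 5)

  ids3 <- c("x1", "x2", "x3")
  aln3 <- seq_alignment(setNames(c("AAA", "AAA", "AAT"), ids3))
  h3 <- collapse_haplotypes(aln3, toy_map(ids3, sites = c("d1", "d2", "d2")))
  expect_equal(nrow(h3$haplotypes), 2)
  expect_equal(dim(h3$counts), c(2, 2))
  # the AAA class has one copy in each deme; AAT is private to d2
  cnt_aaa <- h3$counts[h3$haplotypes$hap_id[h3$haplotypes$sequence == "AAA"], ]
  expect_equal(unname(cnt_aaa), c(1, 1))
  expect_equal(sum(h3$counts), 3)
  expect_equal(sum(h3$p), 1)
})

test_that("collapsing then expanding reproduces the input multiset", {
  set.seed(42)
  for (rep in 1:5) {
    n <- sample(4:12, 1)
    aln <- random_alignment(n, 8)
    h <- collapse_haplotypes(aln, toy_map(rownames(aln)))
    expanded <- expand_haplotypes(h)
    orig <- apply(unclass(aln), 1, paste0, collapse = "")
    expect_equal(sort(expanded), sort(unname(orig)))
  }
})

test_that("species filtering excludes mapped non-target samples", {
  ids <- c("a1", "a2", "b1")
  aln <- seq_alignment(setNames(c("AAAA", "AATA", "TTTT"), ids))
  map <- toy_map(ids)
  map$species <- c("target", "target", "other")
  h <- collapse_haplotypes(aln, map, species_filter = "target")
  expect_equal(h$n, 2)
  expect_false("TTTT" %in% h$haplotypes$sequence)
})

test_that("site classification counts transitions, transversions, composition", {
  ids <- c("u", "v", "w")
  # columns: {A,A,G} ti, {C,C,A} tv, {T,T,T} constant
  aln <- seq_alignment(setNames(c("ACT", "ACT", "GAT"), ids))
  ss <- classify_sites(aln)
  expect_equal(ss$S, 2)
  expect_equal(ss$transitions, 1)
  expect_equal(ss$transversions, 1)
  expect_equal(ss$multiallelic, 0)
  expect_equal(sum(ss$base_composition), 1)

  mono <- seq_alignment(setNames(rep("ACGT", 4), paste0("m", 1:4)))
  expect_equal(classify_sites(mono)$S, 0)

  # a {A,C,G} column is multiallelic, and S = ti + tv + multiallelic
  tri <- seq_alignment(setNames(c("A", "C", "G"), c("x", "y", "z")))
  st <- classify_sites(tri)
  expect_equal(st$S, 1)
  expect_equal(st$multiallelic, 1)
  expect_equal(st$S, st$transitions + st$transversions + st$multiallelic)
})

test_that("classification ignores row order and input case", {
  set.seed(7)
  aln <- random_alignment(6, 20)
  ss1 <- classify_sites(aln)
  perm <- sample(6)
  shuffled <- seq_alignment(unclass(aln)[perm, , drop = FALSE])
  ss2 <- classify_sites(shuffled)
  lower <- seq_alignment(setNames(
    tolower(apply(unclass(aln), 1, paste0, collapse = "")), rownames(aln)))
  ss3 <- classify_sites(lower)
  expect_equal(ss1[c("S", "transitions", "transversions")],
               ss2[c("S", "transitions", "transversions")])
  expect_equal(ss1$base_composition, ss3$base_composition)
})

test_that("ambiguous columns are excluded everywhere (complete deletion)", {
  ids <- c("p", "q")
  aln <- seq_alignment(setNames(c("ANGT", "ACGA"), ids))
  expect_equal(retained_sites(aln), c(1, 3, 4))
  ss <- classify_sites(aln)
  expect_equal(ss$retained, 3)
  expect_equal(ss$S, 1) # only the T/A column varies among retained sites
  h <- collapse_haplotypes(aln, toy_map(ids))
  expect_equal(nchar(h$haplotypes$sequence[1]), 3)
})

test_that("segregating sites agree between raw and collapsed representations", {
  set.seed(13)
  for (rep in 1:5) {
    aln <- random_alignment(10, 12)
    h <- collapse_haplotypes(aln, toy_map(rownames(aln)))
    exp_ids <- paste0("e", seq_along(expand_haplotypes(h)))
    expanded <- seq_alignment(setNames(expand_haplotypes(h), exp_ids))
    expect_equal(classify_sites(expanded)$S, classify_sites(aln)$S)
  }
})

test_that("population map reading enforces schema", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("sample_id\tsite_id\tgroup\tecoregion\tlat\tlon\tspecies",
               "s1\td1\tg1\te1\t1.5\t-60\tsp"), f)
  map <- read_population_map(f)
  expect_equal(map$sample_id, "s1")
  bad <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("sample_id\tsite_id", "s1\td1"), bad)
  expect_error(read_population_map(bad), "lacks columns")
})
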