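#' Default sampling design of the continent-wide survey
#'
#' Twelve sampling sites across four geographic regions with the sample
#' sizes of the lowland-tapir cytochrome-b survey (45 sequences in total),
#' and approximate site coordinates (decimal degrees) used for spatial
#' adjacency.
#'
#' @return data frame with `site_id`, `region`, `n`, `lat`, `lon`.
#' @export
survey_sites <- function() {
  data.frame(
    site_id = as.character(1:12),
    region = c("North", "North", "North", "Andean", "West", "Andean",
               "West", "North", "South", "West", "South", "South"),
    n = c(6L, 2L, 2L, 6L, 2L, 13L, 3L, 3L, 2L, 1L, 1L, 4L),
    lat = c(4.0, 1.0, -0.5, -1.5, -12.0, -8.0, -3.5, 7.5, -14.5, 5.0,
            -2.5, -25.5),
    lon = c(-53.0, -70.0, -63.0, -77.5, -70.5, -74.5, -70.0, -67.0, -62.5,
            -76.5, -49.5, -60.5),
    stringsAsFactors = FALSE
  )
}

#' Configuration of the study-shaped synthetic generator
#'
#' Bundles everything needed to simulate a survey-shaped dataset: the
#' population tree the genealogy is drawn on, the per-site sampling design,
#' and an HKY mutation process.  Defaults emulate the survey: 45 haploid
#' sequences of 1,068 sites over 12 sites in 4 regions; base frequencies
#' A 0.298, C 0.286, G 0.130, T 0.286 (the observed cytochrome-b
#' composition, with its bias against guanine); kappa = 20 (strong
#' transition bias, as in the observed 61:3 ti:tv ratio); mutation rate
#' 2.5e-7 substitutions/site/generation (2.5e-2 substitutions/site/My at a
#' 10-year generation time); and an allopatric four-way split 1,250
#' generations deep with Ne = 10,000 per deme.
#'
#' @param tree a [population_tree()] over the sampling sites, or NULL to
#'   build one from `hypothesis` applied at the region level and expanded
#'   to sites (each site is a deme; sites of a region split from their
#'   regional ancestor at `site_split` generations).
#' @param hypothesis `"null"`, `"ii"` or `"iii"` (used when `tree` is
#'   NULL).
#' @param sites sampling design data frame (see [survey_sites()]).
#' @param L sites in the alignment.
#' @param kappa HKY transition/transversion rate ratio.
#' @param base_freq named frequencies of A, C, G, T.
#' @param mu per-site per-generation mutation rate.
#' @param tmrca,Ne,site_split population-tree scalars used when `tree` is
#'   NULL (generations / haploid size / generations).
#' @return an object of class `synthetic_study_config`.
#' @export
synthetic_study_config <- function(tree = NULL, hypothesis = "null",
                                   sites = survey_sites(), L = 1068,
                                   kappa = 20,
                                   base_freq = c(A = 0.298, C = 0.286,
                                                 G = 0.130, T = 0.286),
                                   mu = 2.5e-7, tmrca = 1250, Ne = 10000,
                                   site_split = 250) {
  stopifnot(all(sites$n >= 0), kappa > 0, mu >= 0, L >= 1)
  base_freq <- base_freq / sum(base_freq)
  if (is.null(tree)) {
    tree <- site_level_tree(hypothesis, sites, tmrca, Ne, site_split)
  }
  structure(list(tree = tree, sites = sites, L = L, kappa = kappa,
                 base_freq = base_freq, mu = mu, hypothesis = hypothesis),
            class = "synthetic_study_config")
}

# expand a region-level hypothesis tree to the site level: each region's
# sites split simultaneously from the regional deme at `site_split`
# generations (single-site regions stay a plain tip)
site_level_tree <- function(hypothesis, sites, tmrca, Ne, site_split) {
  site_split <- min(site_split, tmrca / 3)
  clade <- function(region, stem) {
    ss <- sites$site_id[sites$region == region]
    if (!length(ss)) stop(sprintf("input error: no sites in region %s",
                                  region))
    if (length(ss) == 1) return(sprintf("s%s:%.12g", ss, stem))
    sprintf("(%s):%.12g",
            paste0("s", ss, ":", sprintf("%.12g", site_split),
                   collapse = ","),
            stem - site_split)
  }
  t1 <- tmrca; t2 <- tmrca * 2 / 3; t3 <- tmrca / 3
  regions <- unique(sites$region)
  if (hypothesis == "null") {
    nwk <- sprintf("(%s);",
                   paste(vapply(regions, clade, "", stem = t1),
                         collapse = ","))
  } else {
    if (!setequal(regions, c("West", "Andean", "North", "South"))) {
      stop("input error: hypotheses ii/iii need the four standard regions")
    }
    nwk <- switch(hypothesis,
      ii = sprintf("(%s,(%s,(%s,%s):%.12g):%.12g);",
                   clade("Andean", t1), clade("West", t2),
                   clade("North", t3), clade("South", t3), t2 - t3, t1 - t2),
      iii = sprintf("((%s,%s):%.12g,(%s,%s):%.12g);",
                    clade("North", t2), clade("South", t2), t1 - t2,
                    clade("West", t3), clade("Andean", t3), t1 - t3),
      stop("input error: unknown hypothesis"))
  }
  phy <- ape::read.tree(text = nwk)
  samples <- setNames(sites$n, paste0("s", sites$site_id))
  population_tree(phy, Ne, samples)
}

# HKY instantaneous rate matrix, scaled so the mean substitution rate at
# stationarity is `mu` per site per generation
hky_rate_matrix <- function(kappa, freqs, mu) {
  bases <- names(freqs)
  ti_partner <- c(A = "G", G = "A", C = "T", T = "C")
  Q <- matrix(0, 4, 4, dimnames = list(bases, bases))
  for (i in bases) {
    for (j in bases) {
      if (i == j) next
      Q[i, j] <- if (j == ti_partner[[i]]) kappa * freqs[[j]] else freqs[[j]]
    }
  }
  diag(Q) <- -rowSums(Q)
  scale <- -sum(freqs * diag(Q))
  Q * mu / scale
}

# transition probability matrix exp(Q t), via the symmetrized
# eigendecomposition available for any reversible rate matrix
hky_transition_matrix <- function(Q, freqs, t) {
  d <- sqrt(freqs)
  S <- diag(d) %*% Q %*% diag(1 / d)
  S <- (S + t(S)) / 2
  eig <- eigen(S, symmetric = TRUE)
  P <- diag(1 / d) %*% eig$vectors %*% diag(exp(eig$values * t)) %*%
    t(eig$vectors) %*% diag(d)
  P[P < 0] <- 0
  P <- P / rowSums(P)
  dimnames(P) <- dimnames(Q)
  P
}

#' Simulate sequences along a gene tree under HKY
#'
#' The root sequence is drawn from the stationary base frequencies; each
#' branch evolves every site independently under the HKY substitution
#' process (transitions upweighted by kappa, targets weighted by their
#' stationary frequency), by sampling the end base of the branch from the
#' exact transition probabilities exp(Q t).  The rate matrix is scaled so
#' that `mu` is the expected number of substitutions per site per
#' generation at stationarity.
#'
#' @param tree an [ape::phylo] with branch lengths in generations.
#' @param config a [synthetic_study_config()] (fields `L`, `kappa`,
#'   `base_freq`, `mu` are used).
#' @return a [seq_alignment()] with one record per tip.
#' @export
simulate_sequences <- function(tree, config) {
  L <- config$L
  freqs <- config$base_freq
  bases <- names(freqs)
  Q <- hky_rate_matrix(config$kappa, freqs, config$mu)
  ntip <- length(tree$tip.label)
  root <- ntip + 1L
  seqs <- vector("list", ntip + tree$Nnode)
  seqs[[root]] <- sample(bases, L, replace = TRUE, prob = freqs)
  pre <- ape::reorder.phylo(tree, "cladewise")
  for (e in seq_len(nrow(pre$edge))) {
    par <- pre$edge[e, 1]
    child <- pre$edge[e, 2]
    s0 <- seqs[[par]]
    s <- s0
    P <- hky_transition_matrix(Q, freqs, pre$edge.length[e])
    for (b in bases) {
      idx <- which(s0 == b) # index on the parent state, not updated in place
      if (length(idx)) {
        s[idx] <- sample(bases, length(idx), replace = TRUE,
                         prob = P[b, ])
      }
    }
    seqs[[child]] <- s
  }
  out <- vapply(seq_len(ntip), function(i) paste0(seqs[[i]], collapse = ""),
                "")
  seq_alignment(setNames(out, tree$tip.label))
}

#' Generate a complete study-shaped synthetic dataset
#'
#' One realization of the structured coalescent plus HKY mutation under the
#' configured population tree and sampling design, returned as the same
#' artifacts a field study would provide — an alignment and a population
#' map — plus a truth record (the latent gene tree, the true site
#' partition and all parameters) sufficient to recompute any downstream
#' expectation without re-simulation.
#'
#' @param config a [synthetic_study_config()].
#' @param seed RNG seed; identical seeds give byte-identical outputs.
#' @param dir optional directory; when given, writes `alignment.fasta`,
#'   `population_map.tsv` and `truth.json` (requires jsonlite) there.
#' @return list with `aln` (a [seq_alignment()]), `map` (population map
#'   data frame), `truth` (list: `gene_tree` newick, `partition`,
#'   `config`).
#' @export
generate_study <- function(config = synthetic_study_config(), seed = NULL,
                           dir = NULL) {
  if (!is.null(seed)) set.seed(seed)
  gt <- simulate_gene_tree(config$tree)
  aln <- simulate_sequences(gt, config)
  deme <- attr(gt, "tip_deme")
  site <- sub("^s", "", deme)
  sites <- config$sites
  map <- data.frame(
    sample_id = gt$tip.label,
    site_id = site,
    group = sites$region[match(site, sites$site_id)],
    ecoregion = sites$region[match(site, sites$site_id)],
    lat = sites$lat[match(site, sites$site_id)],
    lon = sites$lon[match(site, sites$site_id)],
    species = "synthetic",
    stringsAsFactors = FALSE
  )
  truth <- list(
    gene_tree = ape::write.tree(gt),
    partition = setNames(sites$region, sites$site_id),
    parameters = list(L = config$L, kappa = config$kappa,
                      base_freq = as.list(config$base_freq), mu = config$mu,
                      hypothesis = config$hypothesis,
                      tmrca = max(config$tree$times),
                      Ne = unname(config$tree$Ne[1]), seed = seed)
  )
  if (!is.null(dir)) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    write_fasta(aln, file.path(dir, "alignment.fasta"))
    write.table(map, file.path(dir, "population_map.tsv"), sep = "\t",
                row.names = FALSE, quote = FALSE)
    if (requireNamespace("jsonlite", quietly = TRUE)) {
      jsonlite::write_json(truth, file.path(dir, "truth.json"),
                           auto_unbox = TRUE, digits = NA)
    }
  }
  list(aln = aln, map = map, truth = truth)
}
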