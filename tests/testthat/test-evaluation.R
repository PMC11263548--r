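test_that("validity/uniqueness/novelty counts follow their definitions", {
  r <- validity_uniqueness_novelty(c("CCO", "CCO", "C1CC1", "C(C"), "CCO")
  expect_equal(r$n_generated, 4L)
  expect_equal(r$n_valid, 3L)
  expect_equal(r$n_unique, 2L)
  expect_equal(r$n_novel, 1L)
  # all invalid
  r0 <- validity_uniqueness_novelty(c("C(C", "C1CC"), "CCO")
  expect_equal(c(r0$n_valid, r0$n_unique, r0$n_novel), c(0L, 0L, 0L))
  # all valid, distinct, disjoint from training
  r1 <- validity_uniqueness_novelty(c("CCO", "CCN", "CCC"), "c1ccccc1")
  expect_equal(c(r1$n_valid, r1$n_unique, r1$n_novel), c(3L, 3L, 3L))
  # nesting invariant and taxonomy conservation
  expect_true(r$n_novel <= r$n_unique)
  expect_true(r$n_unique <= r$n_valid)
  expect_true(r$n_valid <= r$n_generated)
  expect_equal(sum(r$taxonomy), r$n_generated - r$n_valid)
})

test_that("error taxonomy labels and precedence", {
  expect_equal(classify_invalid_smiles("C(C"), "branching")
  expect_equal(classify_invalid_smiles("C1CC"), "ring")
  expect_equal(classify_invalid_smiles("F=F"), "bond")
  expect_equal(classify_invalid_smiles("CC="), "other")
  # branching takes precedence over a simultaneous ring defect
  expect_equal(classify_invalid_smiles("C1(CC"), "branching")
  # bracket contents never confuse the syntax checks
  expect_equal(classify_invalid_smiles("[C@H](C"), "branching")
  # a valid string is a contract violation
  expect_error(classify_invalid_smiles("CCO"), "valid")
})

test_that("property profile computes the structural descriptors", {
  pp <- property_profile(c("c1ccccc1", "C1CCCCC1", "C1CCC2(CC1)CCCC2"))
  expect_equal(pp$n_heavy_atoms, c(6, 6, 10))
  expect_equal(pp$n_aliphatic_rings[1:2], c(0, 1))
  expect_equal(pp$n_sp3_carbons[1:2], c(0, 6))
  expect_equal(pp$n_spiro_atoms, c(0, 0, 1))    # spiro[4.4]decane analogue
  expect_true(all(pp$molecular_weight > 0))
  sm <- property_summary(pp)
  expect_true("n_heavy_atoms" %in% sm$descriptor)
  expect_equal(sm$mean[sm$descriptor == "n_heavy_atoms"], mean(c(6, 6, 10)))
})

test_that("fragment scoring separates reference chemotypes", {
  aromatic <- c("c1ccccc1", "c1ccccc1C", "c1ccccc1O", "c1ccncc1",
                "c1ccccc1N", "Cc1ccccc1C")
  aliphatic <- c("CCCC", "CCCCC", "CCOCC", "CCNCC", "CCCCO", "CCCCN")
  mod <- fragment_score_model(aromatic, aliphatic, radius = 2)
  sc <- fragment_scores(c("c1ccccc1CC", "CCCCCC"), mod)
  expect_gt(sc[1], sc[2])
})

test_that("KS distance has its metric properties", {
  x <- rnorm(40)
  expect_equal(ks_distance(x, x), 0)
  expect_equal(ks_distance(1:5, 11:15), 100)
  # brute-force ECDF oracle on a small case: evaluate both ECDFs at every
  # sample point and take the sup by exhaustive enumeration
  a <- c(1, 2, 3); b <- c(1, 2, 4)
  pts <- sort(unique(c(a, b)))
  oracle <- 100 * max(abs(vapply(pts, function(t) mean(a <= t) - mean(b <= t),
                                 numeric(1))))
  expect_equal(ks_distance(a, b), oracle)
  expect_equal(oracle, 100 * 1 / 3)
  # symmetric, bounded, and matches the standard two-sample statistic
  s1 <- rnorm(30); s2 <- rnorm(25, mean = 1)
  expect_equal(ks_distance(s1, s2), ks_distance(s2, s1))
  expect_gte(ks_distance(s1, s2), 0); expect_lte(ks_distance(s1, s2), 100)
  expect_equal(ks_distance(s1, s2),
               100 * unname(suppressWarnings(
                 stats::ks.test(s1, s2)$statistic)))
})

test_that("rediscovery counts exact and similarity matches", {
  actives <- c("CCOc1ccccc1", "NCCCCN")
  # a design identical to an active counts in both modes
  designs <- c("CCOc1ccccc1", "CCCC")
  expect_equal(rediscovery_rate(designs, actives, mode = "exact"), 0.5)
  expect_equal(rediscovery_rate(designs, actives, mode = "relaxed"), 0.5)
  # relaxed >= exact always
  fx <- synthetic_smiles_corpus(grammar_spec(), 30, seed = 15)
  des <- fx[1:20]; act <- fx[11:30]
  expect_gte(rediscovery_rate(des, act, mode = "relaxed"),
             rediscovery_rate(des, act, mode = "exact"))
  # strict threshold: a constructed analog pair above/below the cut
  pair_a <- "CCOc1ccc(CC(=O)NCC)cc1"
  pair_b <- "CCOc1ccc(CC(=O)NCCC)cc1"       # one-atom homolog
  fp <- morgan_fingerprints(c(pair_a, pair_b))
  sim <- tanimoto_matrix(fp)[1, 2]
  expect_gt(sim, 0.6)                        # verified analog similarity
  expect_equal(rediscovery_rate(pair_b, pair_a, threshold = 0.6), 1)
  expect_equal(rediscovery_rate(pair_b, pair_a, threshold = sim), 0)
  expect_error(rediscovery_rate(pair_b, character(0)), "empty")
})

test_that("scaffold clustering groups by single linkage over the threshold graph", {
  # all designs share one scaffold -> 1 cluster
  one <- scaffold_cluster_count(c("c1ccccc1CC", "c1ccccc1CCC", "c1ccccc1N"))
  expect_equal(one$n_clusters, 1L)
  # k dissimilar scaffolds -> k clusters (pairwise similarity < 0.6 is
  # verified against the fingerprint oracle inside the expectation)
  dis <- c("c1ccccc1C", "C1CCCCC1C", "CC1CCOC1")
  sc <- murcko_scaffolds(dis)
  sim <- tanimoto_matrix(morgan_fingerprints(unique(sc)))
  expect_true(all(sim[upper.tri(sim)] < 0.6))
  expect_equal(scaffold_cluster_count(dis)$n_clusters, 3L)
  # independent oracle: connected components of the threshold graph by
  # union-find must equal the single-linkage cluster count
  probe <- c("c1ccccc1CC", "c1ccccc1CCC", "Cc1ccc(N)nc1", "C1CCCCC1C",
             "C1CCCC1N", "CC1CCOC1", "c1ccoc1CC(=O)O")
  sc2 <- murcko_scaffolds(probe)
  uq <- unique(sc2)
  sm <- tanimoto_matrix(morgan_fingerprints(uq))
  parent <- seq_along(uq)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  for (i in seq_along(uq)) for (j in seq_len(i - 1L)) {
    if (sm[i, j] > 0.6) parent[find(i)] <- find(j)
  }
  n_oracle <- length(unique(vapply(seq_along(uq), find, integer(1))))
  expect_equal(scaffold_cluster_count(probe)$n_clusters, n_oracle)
  # order invariance
  mix <- c("c1ccccc1CC", "CC1CCOC1", "C1CCCCC1C", "c1ccccc1N")
  l1 <- scaffold_cluster_count(mix)
  l2 <- scaffold_cluster_count(rev(mix))
  expect_equal(l1$n_clusters, l2$n_clusters)
  # acyclic designs get the dedicated no-scaffold cluster
  withno <- scaffold_cluster_count(c("c1ccccc1CC", "CCCC"))
  expect_equal(withno$n_clusters, 2L)
})

test_that("prospective selection applies the full shortlist protocol", {
  # constructed fixture: 6 designs, 2 fine-tuning actives; expected
  # shortlists derived by exhaustive application of the rules
  ft_set <- c("c1ccccc1CCNC(=O)C", "C1CCNCC1CCO")
  designs <- data.frame(
    smiles = c("c1ccccc1CCNC(=O)CC",   # scaffold = benzene, high sim
               "c1ccccc1CCNC(=O)N",    # scaffold = benzene, high sim
               "C1CCNCC1CCOC",         # scaffold = piperidine-like, high sim
               "CCCCCCCCN",            # acyclic: no scaffold, low sim
               "CC1COC1",              # oxetane scaffold, low sim
               ft_set[1]),             # not novel: must be dropped
    ll_ft = c(-10, -12, -11, -13, -14, -1),
    score = c(2.0, 3.5, 1.0, 0.5, 0.8, 9.9),
    stringsAsFactors = FALSE)
  # 5 novel candidates < top_n: all retained, with the documented warning
  expect_warning(sel <- select_prospective_designs(designs, ft_set,
                                                   top_n = 10),
                 "keeping all")
  expect_true(all(!grepl(paste0("^", ft_set[1], "$"), sel$high$smiles)))
  # benzene-scaffold designs share nearest_train = active 1 and only the
  # higher scorer (score 3.5) survives the per-group pick
  ben <- sel$high[sel$high$nearest_train == canonicalize_and_validate(ft_set[1])$canonical |
                    sel$high$nearest_train == ft_set[1], ]
  expect_equal(nrow(ben), 1L)
  expect_equal(ben$score, 3.5)
  # scaffold similarity 1.0 lands in the high list
  expect_true(all(sel$high$scaffold_similarity > 0.6))
  expect_true(all(sel$low$scaffold_similarity <= 0.6))
  # shortlists are ranked by score
  expect_true(all(diff(sel$high$score) <= 0))
  expect_true(all(diff(sel$low$score) <= 0))
  # fewer than top_n candidates: all retained with a warning
  expect_warning(select_prospective_designs(designs[1:3, ], ft_set,
                                            top_n = 500), "keeping all")
})
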