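# GO term depths, Wang-style similarity, profiles, best-match average

test_that("term levels follow the shortest-path convention", {
  dag <- chain_dag()
  d <- term_depths(dag)
  expect_equal(d[c("ROOT", "C", "A")], c(ROOT = 0L, C = 1L, A = 2L))
  expect_equal(term_depths(dag, root_level = 1)[["A"]], 3L)
})

test_that("diamond parents at different levels take the minimum rule", {
  # A's parents: P1 at level 1 and P2 at level 3 -> level(A) = 2
  dag <- go_dag(
    tibble::tibble(id = c("R", "P1", "M1", "M2", "P2", "A"),
                   name = id <- c("R", "P1", "M1", "M2", "P2", "A"),
                   namespace = "biological_process", obsolete = FALSE),
    tibble::tibble(
      child  = c("P1", "M1", "M2", "P2", "A", "A"),
      parent = c("R", "R", "M1", "M2", "P1", "P2"),
      type = "is_a"))
  d <- term_depths(dag)
  expect_equal(d[["P1"]], 1L)
  expect_equal(d[["P2"]], 3L)
  expect_equal(d[["A"]], 2L)
  expect_equal(term_depths(dag, rule = "longest")[["A"]], 4L)
})

test_that("levels equal an exhaustive relaxation oracle on random DAGs", {
  for (seed in c(2, 5)) {
    dag <- random_test_dag(60, seed = seed)
    d <- term_depths(dag)
    oracle <- bf_term_depths(dag)
    expect_equal(as.numeric(d[names(oracle)]), unname(oracle))
  }
})

test_that("chain similarity matches the hand recursion", {
  m <- term_sim_model(chain_dag())
  # S_A = {A:1, C:0.8, ROOT:0.64}; S_C = {C:1, ROOT:0.8}
  expect_equal(term_similarity("A", "C", m), 3.24 / 4.24, tolerance = 1e-12)
  expect_equal(term_similarity("C", "A", m), 3.24 / 4.24, tolerance = 1e-12)
})

test_that("self-similarity is exactly one and disjoint roots give zero", {
  m <- term_sim_model(chain_dag())
  for (t in c("A", "C", "ROOT")) expect_equal(term_similarity(t, t, m), 1)

  two_roots <- go_dag(
    tibble::tibble(id = c("R1", "R2", "X", "Y"), name = id <- c("R1", "R2", "X", "Y"),
                   namespace = "biological_process", obsolete = FALSE),
    tibble::tibble(child = c("X", "Y"), parent = c("R1", "R2"), type = "is_a"))
  expect_equal(term_similarity("X", "Y", term_sim_model(two_roots)), 0)
})

test_that("terms from different namespaces or unknown ids are rejected", {
  dag <- go_dag(
    tibble::tibble(id = c("R1", "R2"), name = c("bp root", "mf root"),
                   namespace = c("biological_process", "molecular_function"),
                   obsolete = FALSE),
    tibble::tibble(child = character(), parent = character(),
                   type = character()))
  m <- term_sim_model(dag)
  expect_error(term_similarity("R1", "R2", m), "namespaces")
  expect_error(term_similarity("R1", "NOPE", m), "unknown")
})

test_that("similarity decreases monotonically along a pure is_a chain", {
  n <- 8
  ids <- c("ROOT", sprintf("L%d", 1:n))
  dag <- go_dag(
    tibble::tibble(id = ids, name = ids, namespace = "biological_process",
                   obsolete = FALSE),
    tibble::tibble(child = ids[-1], parent = ids[-length(ids)], type = "is_a"))
  m <- term_sim_model(dag)
  sims <- vapply(ids[-length(ids)], function(anc) {
    term_similarity(ids[length(ids)], anc, m)
  }, numeric(1))
  expect_true(all(diff(rev(unname(sims))) < 0))
  expect_true(all(sims > 0 & sims < 1))
})

test_that("S-values equal brute-force path enumeration on random DAGs", {
  for (seed in c(3, 8, 12)) {
    dag <- random_test_dag(30, seed = seed)
    m <- term_sim_model(dag)
    for (t in sample(dag_terms(dag), 6)) {
      expected <- bf_s_values(dag, t)
      got <- netprox:::s_values(t, m)
      expect_equal(got[sort(names(got))], expected[sort(names(expected))],
                   tolerance = 1e-12)
    }
    # and full similarities against the oracle for a few pairs
    picks <- matrix(sample(dag_terms(dag), 6), ncol = 2)
    for (k in seq_len(nrow(picks))) {
      expect_equal(term_similarity(picks[k, 1], picks[k, 2], m),
                   bf_term_similarity(dag, picks[k, 1], picks[k, 2]),
                   tolerance = 1e-12)
    }
  }
})

test_that("profile BMA reduces to the single pair and the hand fixture", {
  m <- term_sim_model(chain_dag())
  expect_equal(profile_similarity("A", "C", m), 3.24 / 4.24,
               tolerance = 1e-12)
  expect_equal(profile_similarity(c("A", "C"), "C", m),
               (3.24 / 4.24 + 1 + 1) / 3, tolerance = 1e-12)
  expect_equal(profile_similarity(c("A", "C"), c("A", "C"), m), 1)
  # duplicating a term in a profile must not change the score
  expect_equal(profile_similarity(c("A", "C", "C"), c("A", "C"), m), 1)
  expect_error(profile_similarity(character(0), "C", m), "empty profile")
})

make_enrichment_fixture <- function() {
  # flat ontology: root with 2 children at level 1; "level" tests use 1
  dag <- go_dag(
    tibble::tibble(id = c("R", "T1", "T2"), name = c("R", "T1", "T2"),
                   namespace = "biological_process", obsolete = FALSE),
    tibble::tibble(child = c("T1", "T2"), parent = "R", type = "is_a"))
  genes <- sprintf("G%02d", 1:10)
  ann <- annotation_map(
    data.frame(gene = c(genes[1:5], genes[6:10]),
               term = rep(c("T1", "T2"), each = 5)), dag)
  list(dag = dag, ann = ann, genes = genes)
}

test_that("the hypergeometric profile matches the closed-form tail", {
  fx <- make_enrichment_fixture()
  # universe 10, term annotates 5, query = those same 5 -> p = 1/C(10,5)
  prof <- enrich_profile(gene_set(fx$genes[1:5]), fx$ann, level = 1)
  expect_equal(nrow(prof), 1)
  expect_equal(prof$term, "T1")
  expect_equal(prof$p_value, 1 / choose(10, 5), tolerance = 1e-12)

  # disjoint query: overlap 0 -> p = 1, term excluded
  prof2 <- enrich_profile(gene_set(fx$genes[6:10]), fx$ann, level = 1)
  expect_false("T1" %in% prof2$term)
})

test_that("profile construction validates level and background overlap", {
  fx <- make_enrichment_fixture()
  expect_error(enrich_profile(gene_set("NOT_THERE"), fx$ann, level = 1),
               "background")
  expect_error(enrich_profile(gene_set(fx$genes[1:5]), fx$ann, level = 9),
               "no terms at level")
})

test_that("profile p-values equal one-sided Fisher tests on the same table", {
  fx <- make_enrichment_fixture()
  # same counts pushed through the pathway-enrichment route
  pc <- pathway_collection(list(T1 = fx$genes[1:5], T2 = fx$genes[6:10]),
                           universe = fx$genes)
  fe <- fisher_enrichment(gene_set(fx$genes[1:5]), pc, alpha = 1)
  prof <- enrich_profile(gene_set(fx$genes[1:5]), fx$ann, level = 1,
                         alpha = 1.0000001)
  both <- merge(as.data.frame(prof)[, c("term", "p_value")],
                as.data.frame(fe)[, c("pathway", "p_value")],
                by.x = "term", by.y = "pathway")
  expect_gt(nrow(both), 1)
  expect_equal(both$p_value.x, both$p_value.y, tolerance = 1e-10)
})

test_that("a planted level-4 signal is recovered as the top profile term", {
  spec <- synthetic_spec(seed = 33, n_nodes = 400)
  genes <- sprintf("G%04d", 1:400)
  grp <- genes[1:59]
  onto <- gen_ontology_and_annotations(spec, genes, group_a = grp)
  prof <- enrich_profile(gene_set(grp), onto$annotations)
  expect_gt(nrow(prof), 0)
  # the profile's terms must be exactly at level 4
  d <- term_depths(onto$dag)
  expect_true(all(d[prof$term] == 4))
})

test_that("profile-similarity permutations detect planted overlap", {
  spec <- synthetic_spec(seed = 91, n_nodes = 400)
  genes <- sprintf("G%04d", 1:400)
  ga <- genes[1:40]; gb <- genes[350:400]
  onto <- gen_ontology_and_annotations(spec, genes, group_a = ga, group_b = gb)
  res <- permutation_test_profile_similarity(
    gene_set(ga), gene_set(gb), onto$annotations,
    randomized_side = "b", n_permutations = 200, seed = 17)
  expect_lt(res$p_empirical, 0.05)
  expect_gt(res$observed, 0)
  # determinism
  res2 <- permutation_test_profile_similarity(
    gene_set(ga), gene_set(gb), onto$annotations,
    randomized_side = "b", n_permutations = 200, seed = 17)
  expect_identical(glance(res), glance(res2))
})

test_that("a single-term ontology gives a degenerate, smoothed null", {
  dag <- go_dag(
    tibble::tibble(id = c("R", "T"), name = c("R", "T"),
                   namespace = "biological_process", obsolete = FALSE),
    tibble::tibble(child = "T", parent = "R", type = "is_a"))
  genes <- sprintf("G%d", 1:6)
  ann <- annotation_map(data.frame(gene = genes[1:3], term = "T"), dag)
  # query = the full 3-gene background, so every size-3 resample is the
  # same set; alpha > 1 admits the term despite p = 1, making every null
  # profile identical to the observed one
  expect_warning(
    res <- permutation_test_profile_similarity(
      gene_set(genes[1:3]), gene_set(genes[1:3]), ann,
      randomized_side = "b", n_permutations = 100, seed = 3, level = 1,
      alpha = 1.1),
    "zero spread")
  expect_equal(res$p_empirical, 1, tolerance = 1e-12)
})
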