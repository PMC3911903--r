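test_that("AND and EX scores reproduce hand-computed confidences", {
  perfect <- data.frame(f_a = 0.4, f_b = 0.4, f_ab = 0.4,
                        f_a_not_b = 0, f_b_not_a = 0)
  expect_equal(and_score(perfect), 1.0)
  expect_equal(ex_score(perfect), 0.0)
  never <- data.frame(f_a = 0.5, f_b = 0.5, f_ab = 0,
                      f_a_not_b = 0.5, f_b_not_a = 0.5)
  expect_equal(and_score(never), 0.0)
  expect_equal(ex_score(never), 1.0)
})

test_that("scores on an 8-network toy collection match the counting oracle", {
  # a in networks 1-4, b in networks 3-6: f_a = f_b = 0.5, f_ab = 0.25;
  # both rule confidences are 0.5, so AND = EX = 0.5 under min
  nets <- lapply(1:8, function(i) {
    keys <- "X->Y:+" # shared filler, HIGH
    if (i %in% 1:4) keys <- c(keys, "A->B:+")
    if (i %in% 3:6) keys <- c(keys, "C->D:-")
    keys
  })
  names(nets) <- paste0("n", 1:8)
  coll <- grn_collection(nets)
  tier <- classify_interactions(interaction_frequencies(coll), cutoff_config())
  st <- pair_stats(coll, tier)
  row <- st[st$a == "A->B:+" & st$b == "C->D:-", ]
  expect_equal(row$f_a, 0.5)
  expect_equal(row$f_ab, 0.25)
  expect_equal(and_score(row), 0.5)
  expect_equal(ex_score(row), 0.5)
})

test_that("scores error on zero marginals and are symmetric in a and b", {
  expect_error(and_score(data.frame(f_a = 0, f_b = 0.5, f_ab = 0)),
               "zero marginal")
  expect_error(ex_score(data.frame(f_a = 0.5, f_b = 0, f_ab = 0)),
               "zero marginal")
  set.seed(11)
  for (i in 1:50) {
    st <- random_pair_stats()
    swapped <- data.frame(f_a = st$f_b, f_b = st$f_a, f_ab = st$f_ab)
    expect_equal(and_score(st), and_score(swapped))
    expect_equal(ex_score(st), ex_score(swapped))
  }
})

test_that("alternative conjunctions are available and bounded by min", {
  st <- data.frame(f_a = 0.5, f_b = 0.4, f_ab = 0.2)
  # confidences: 0.4 and 0.5
  expect_equal(and_score(st, "min"), 0.4)
  expect_equal(and_score(st, "product"), 0.2)
  expect_equal(and_score(st, "bounded"), 0)
  expect_lte(and_score(st, "product"), and_score(st, "min"))
})

test_that("relation gating requires both score and evidence frequency", {
  cut <- cutoff_config() # joint 0.1, score 0.7
  strong <- data.frame(a = "a", b = "b", f_a = 1 / 3, f_b = 1 / 3,
                       f_ab = 0.3, f_a_not_b = 1 / 30, f_b_not_a = 1 / 30)
  expect_equal(pairwise_relations(strong, cut)$relation, "AND")
  weak_joint <- data.frame(a = "a", b = "b", f_a = 1 / 18, f_b = 1 / 18,
                           f_ab = 0.05, f_a_not_b = 1 / 180,
                           f_b_not_a = 1 / 180)
  # and_score 0.9 but joint 0.05 <= 0.1
  expect_equal(pairwise_relations(weak_joint, cut)$relation, "NONE")
  middling <- data.frame(a = "a", b = "b", f_a = 0.5, f_b = 0.5, f_ab = 0.3,
                         f_a_not_b = 0.2, f_b_not_a = 0.2)
  # and_score 0.6, ex_score 0.4
  expect_equal(pairwise_relations(middling, cut)$relation, "NONE")
})

test_that("EX relations are gated by the exclusive frequencies", {
  cut <- cutoff_config()
  ex_ok <- data.frame(a = "a", b = "b", f_a = 0.4, f_b = 0.4, f_ab = 0,
                      f_a_not_b = 0.4, f_b_not_a = 0.4)
  expect_equal(pairwise_relations(ex_ok, cut)$relation, "EX")
  ex_thin <- data.frame(a = "a", b = "b", f_a = 0.08, f_b = 0.08, f_ab = 0,
                        f_a_not_b = 0.08, f_b_not_a = 0.08)
  expect_equal(pairwise_relations(ex_thin, cut)$relation, "NONE")
})

test_that("AND-related pairs merge transitively into characteristic sets", {
  rel <- data.frame(
    a = c("e1", "e2"), b = c("e2", "e3"),
    f_a = 0.5, f_b = 0.5, f_ab = 0.5, f_a_not_b = 0, f_b_not_a = 0,
    and_score = 1, ex_score = 0, relation = "AND", stringsAsFactors = FALSE
  )
  # keys must be syntactically valid interactions
  rel$a <- c("A->B:+", "B->C:+")
  rel$b <- c("B->C:+", "C->D:+")
  sys <- build_characteristic_sets(rel)
  expect_length(sys$sets, 1)
  expect_equal(sys$sets$S1, c("A->B:+", "B->C:+", "C->D:+"))
})

test_that("EX links between sets become competitions; none leaves an empty system", {
  rel <- data.frame(
    a = c("A->B:+", "C->D:+", "A->B:+"),
    b = c("B->C:+", "D->A:+", "C->D:+"),
    f_a = 0.5, f_b = 0.5, f_ab = c(0.5, 0.5, 0),
    f_a_not_b = c(0, 0, 0.5), f_b_not_a = c(0, 0, 0.5),
    and_score = c(1, 1, 0), ex_score = c(0, 0, 1),
    relation = c("AND", "AND", "EX"), stringsAsFactors = FALSE
  )
  sys <- build_characteristic_sets(rel)
  expect_length(sys$sets, 2)
  expect_equal(sys$competitions$set1, "S1")
  expect_equal(sys$competitions$set2, "S2")
  empty <- build_characteristic_sets(rel[0, ])
  expect_length(empty$sets, 0)
  expect_equal(nrow(empty$competitions), 0)
})

test_that("intra-set EX edges are recorded as conflicts, never auto-resolved", {
  rel <- data.frame(
    a = c("A->B:+", "B->C:+", "A->B:+"),
    b = c("B->C:+", "C->D:+", "C->D:+"),
    f_a = 0.5, f_b = 0.5, f_ab = c(0.5, 0.5, 0),
    f_a_not_b = c(0, 0, 0.5), f_b_not_a = c(0, 0, 0.5),
    and_score = c(1, 1, 0), ex_score = c(0, 0, 1),
    relation = c("AND", "AND", "EX"), stringsAsFactors = FALSE
  )
  sys <- build_characteristic_sets(rel)
  expect_length(sys$sets, 1)
  expect_equal(nrow(sys$conflicts), 1)
  expect_equal(sys$conflicts$set_id, "S1")
  expect_error(enumerate_valid_signatures(sys), "conflict")
})

test_that("set support is the fraction of networks containing all members", {
  coll <- make_coll(
    n1 = c("A->B:+", "B->C:+"), n2 = c("A->B:+", "B->C:+"),
    n3 = "A->B:+", n4 = "D->A:-"
  )
  rel <- data.frame(
    a = "A->B:+", b = "B->C:+", f_a = 0.75, f_b = 0.5, f_ab = 0.5,
    f_a_not_b = 0.25, f_b_not_a = 0, and_score = 2 / 3, ex_score = 0,
    relation = "AND", stringsAsFactors = FALSE
  )
  sys <- build_characteristic_sets(rel, coll)
  expect_equal(unname(sys$support["S1"]), 0.5)
})

test_that("AND components equal brute-force partition refinement", {
  set.seed(202)
  for (rep in 1:30) {
    coll <- random_tiny_collection()
    ext <- extract_characteristic_sets(coll, cutoff_config())
    and_pairs <- ext$relations[ext$relations$relation == "AND",
                               c("a", "b"), drop = FALSE]
    expect_equal(unname(ext$system$sets), oracle_and_components(and_pairs))
  }
})

test_that("raising the score cutoff never creates relations or enlarges sets", {
  set.seed(303)
  for (rep in 1:20) {
    coll <- random_tiny_collection()
    ft <- interaction_frequencies(coll)
    tier <- classify_interactions(ft, cutoff_config())
    st <- pair_stats(coll, tier)
    lo <- pairwise_relations(st, cutoff_config(score = 0.6))
    hi <- pairwise_relations(st, cutoff_config(score = 0.9))
    related_hi <- hi$relation != "NONE"
    expect_true(all(lo$relation[related_hi] == hi$relation[related_hi]))
    sets_lo <- build_characteristic_sets(lo)$sets
    sets_hi <- build_characteristic_sets(hi)$sets
    for (s in sets_hi) {
      expect_true(any(vapply(sets_lo, function(x) all(s %in% x), logical(1))))
    }
  }
})
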