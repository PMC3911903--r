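# A reusable system with three sets (ids by smallest member):
# S1 = {A->B:+, B->C:+}, S2 = {B->D:-, D->C:-}, S3 = {C->D:+, D->A:+},
# with S2 and S3 competing.
three_set_system <- function() {
  rel <- data.frame(
    a = c("A->B:+", "C->D:+", "B->D:-", "C->D:+"),
    b = c("B->C:+", "D->A:+", "D->C:-", "B->D:-"),
    f_a = 0.4, f_b = 0.4, f_ab = c(0.4, 0.4, 0.4, 0),
    f_a_not_b = c(0, 0, 0, 0.4), f_b_not_a = c(0, 0, 0, 0.4),
    and_score = c(1, 1, 1, 0), ex_score = c(0, 0, 0, 1),
    relation = c("AND", "AND", "AND", "EX"), stringsAsFactors = FALSE
  )
  build_characteristic_sets(rel)
}

test_that("set containment is crisp: all members or nothing", {
  members <- c("A->B:+", "B->C:+", "C->D:+")
  expect_true(contains_set(c(members, "D->A:-"), members))
  expect_false(contains_set(members[1:2], members))
  expect_false(contains_set(character(0), members))
})

test_that("networks map to the signature of exactly the sets they contain", {
  sys <- three_set_system()
  coll <- make_coll(
    g1 = c("A->B:+", "B->C:+"),                     # S1 only
    g2 = c("A->B:+", "B->C:+", "C->D:+", "D->A:+"), # S1 and S3
    g3 = "A->B:+",                                  # no complete set
    g4 = c("C->D:+", "D->A:+", "B->D:-", "D->C:-")  # competing S2 + S3
  )
  grouping <- group_networks(coll, sys)
  expect_named(grouping$groups, c("S1", "S1+S3"))
  expect_equal(grouping$groups$S1$member_ids, "g1")
  expect_equal(grouping$groups[["S1+S3"]]$member_ids, "g2")
  expect_setequal(grouping$excluded, c("g3", "g4"))
  expect_equal(grouping$flagged, "g4")
  kept <- group_networks(coll, sys, keep_violations = TRUE)
  expect_true("g4" %in% kept$groups[["S2+S3"]]$member_ids)
})

test_that("every network lands in exactly one group or in excluded", {
  set.seed(404)
  for (rep in 1:15) {
    coll <- random_tiny_collection()
    ext <- extract_characteristic_sets(coll, cutoff_config(score = 0.6))
    grouping <- ext$grouping
    grouped <- unlist(lapply(grouping$groups, `[[`, "member_ids"),
                      use.names = FALSE)
    expect_setequal(c(grouped, grouping$excluded), names(coll$networks))
    expect_equal(anyDuplicated(c(grouped, grouping$excluded)), 0)
  }
})

test_that("valid signatures with one competing pair among three sets number five", {
  sys <- three_set_system()
  sigs <- enumerate_valid_signatures(sys)
  keys <- vapply(sigs, function(s) paste(s, collapse = "+"), character(1))
  expect_equal(keys, c("S1", "S2", "S3", "S1+S2", "S1+S3"))
})

test_that("signature enumeration handles degenerate systems", {
  one <- build_characteristic_sets(data.frame(
    a = "A->B:+", b = "B->C:+", f_a = 0.5, f_b = 0.5, f_ab = 0.5,
    f_a_not_b = 0, f_b_not_a = 0, and_score = 1, ex_score = 0,
    relation = "AND", stringsAsFactors = FALSE
  ))
  expect_length(enumerate_valid_signatures(one), 1)
  rel2 <- data.frame(
    a = c("A->B:+", "B->D:-", "A->B:+"),
    b = c("B->C:+", "D->C:-", "B->D:-"),
    f_a = 0.5, f_b = 0.5, f_ab = c(0.5, 0.5, 0),
    f_a_not_b = c(0, 0, 0.5), f_b_not_a = c(0, 0, 0.5),
    and_score = c(1, 1, 0), ex_score = c(0, 0, 1),
    relation = c("AND", "AND", "EX"), stringsAsFactors = FALSE
  )
  two_competing <- build_characteristic_sets(rel2)
  expect_length(enumerate_valid_signatures(two_competing), 2)
})

test_that("signed voting takes the net vote per gene pair", {
  nets <- c(
    rep(list(c("A->B:+")), 6),
    rep(list(c("C->D:-")), 4)
  )
  names(nets) <- paste0("n", 1:10)
  ens <- signed_vote(grn_collection(nets))
  expect_equal(ens$weights[["A->B:+"]], 0.6)
  # plain frequency voting agrees when only one sign occurs
  freq <- signed_vote(grn_collection(nets), scheme = "frequency")
  expect_equal(freq$weights[["A->B:+"]], 0.6)
})

test_that("opposite votes cancel and absent edges carry no entry", {
  nets <- c(rep(list("A->B:+"), 5), rep(list("A->B:-"), 5))
  names(nets) <- paste0("n", 1:10)
  ens <- signed_vote(grn_collection(nets, strict = TRUE))
  expect_false("A->B:+" %in% names(ens$weights))
  expect_false("A->B:-" %in% names(ens$weights))
  expect_false("C->D:+" %in% names(ens$weights))
  # under signed voting a gene pair never carries both signs
  mixed_nets <- stats::setNames(c(rep(list("A->B:+"), 7),
                                  rep(list("A->B:-"), 3)),
                                paste0("m", 1:10))
  mixed <- signed_vote(grn_collection(mixed_nets, genes = c("A", "B")))
  expect_equal(mixed$weights[["A->B:+"]], 0.4)
  expect_false("A->B:-" %in% names(mixed$weights))
})

test_that("ensemble weights stay in [0,1]; single networks vote 0/1", {
  set.seed(505)
  for (rep in 1:10) {
    coll <- random_tiny_collection()
    ens <- signed_vote(coll)
    expect_true(all(ens$weights >= 0 & ens$weights <= 1))
    single <- signed_vote(coll$networks[1])
    expect_true(all(single$weights == 1))
  }
})

test_that("group ensembles carry their signature's members at frequency 1", {
  sys <- three_set_system()
  coll <- make_coll(
    g1 = c("A->B:+", "B->C:+", "X->Y:+"),
    g2 = c("A->B:+", "B->C:+"),
    g3 = c("C->D:+", "D->A:+", "X->Y:+")
  )
  grouping <- group_networks(coll, sys)
  ens <- group_ensembles(grouping, coll)
  expect_named(ens, c("S1", "S3"))
  expect_equal(ens$S1$weights[["A->B:+"]], 1)
  expect_equal(ens$S1$weights[["B->C:+"]], 1)
  expect_equal(ens$S1$weights[["X->Y:+"]], 0.5)
  expect_equal(ens$S1$n_networks, 2)
  expect_equal(ens$S3$n_networks, 1)
})

test_that("high-confidence backbone edges stay near weight 1 in every group", {
  sim <- generate_collection(synthetic_spec(n_networks = 200, seed = 11))
  ext <- extract_characteristic_sets(sim$collection)
  ens <- group_ensembles(ext$grouping, sim$collection)
  high <- names(ext$classification)[ext$classification == "HIGH"]
  for (g in ens) {
    expect_true(all(g$weights[intersect(high, names(g$weights))] > 0.8))
  }
})

test_that("group score is the mean member score and requires scores", {
  coll <- make_coll(n1 = "A->B:+", n2 = "A->B:+", n3 = "B->C:-",
                    scores = c(0.1, 0.2, 0.3))
  expect_equal(group_score(c("n1", "n2"), coll), 0.15)
  expect_equal(group_score("n3", coll), 0.3)
  expect_equal(group_score(c("n1", "n2", "n3"), coll), 0.2)
  unscored <- make_coll(n1 = "A->B:+", n2 = "A->B:+")
  expect_error(group_score("n1", unscored), "without a score")
})
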