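#' Random signed reference networks
#'
#' Draws a reference gene regulatory network in which every gene receives an
#' in-degree drawn uniformly from `indegree_range` (the default 1-3 effectors
#' per gene), effectors sampled without replacement from the other genes, and
#' each interaction activating or inhibiting with equal probability.
#'
#' @param n_genes number of genes; must exceed the largest admissible
#'   in-degree (effectors are distinct and never the target itself).
#' @param indegree_range integer interval `c(lo, hi)` for per-gene in-degree.
#' @param seed optional integer seed; when given, the global RNG state is
#'   left untouched.
#' @param p_activating probability that an interaction is activating.
#' @return a `grn_network` with id `"reference"`.
#' @examples
#' ref <- random_reference(8, seed = 1)
#' length(ref$interactions)
#' @export
random_reference <- function(n_genes, indegree_range = c(1L, 3L), seed = NULL,
                             p_activating = 0.5) {
  stopifnot(n_genes >= 2, length(indegree_range) == 2L,
            indegree_range[1] >= 1, indegree_range[1] <= indegree_range[2])
  if (n_genes < indegree_range[2] + 1L) {
    stop("n_genes must be at least ", indegree_range[2] + 1L,
         " to draw ", indegree_range[2], " distinct non-self effectors")
  }
  genes <- gene_names(n_genes)
  with_rng_seed(seed, {
    edges <- do.call(rbind, lapply(genes, function(tgt) {
      k <- sample(seq.int(indegree_range[1], indegree_range[2]), 1L)
      eff <- sample(setdiff(genes, tgt), k)
      data.frame(effector = eff, target = tgt, stringsAsFactors = FALSE)
    }))
    edges$sign <- ifelse(stats::runif(nrow(edges)) < p_activating, "+", "-")
    grn_network("reference",
                interaction_key(edges$effector, edges$target, edges$sign))
  })
}

gene_names <- function(n_genes) {
  sprintf(paste0("G%0", max(2L, nchar(n_genes)), "d"), seq_len(n_genes))
}

# Run expr under a fixed seed without disturbing the caller's RNG stream.
with_rng_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

#' Specification of a synthetic network ensemble
#'
#' Describes the generative model used to emulate collections of predicted
#' networks produced by a non-deterministic reverse-engineering run: a
#' high-confidence backbone present in nearly every network, planted
#' characteristic sets realized as complete units (one alternative per
#' network, never a mixture of competing sets), unspecific variable edges
#' present independently, and random add/remove noise on every admissible
#' edge.
#'
#' By default two competing planted sets are derived from the reference: the
#' first consists of `set_size` true reference interactions, the second of
#' alternative-effector interactions absent from the reference that replace
#' them, so one planted hypothesis is correct and its competitor is not.
#' Explicit `planted_sets`/`planted_competitions` override this.
#'
#' @param n_genes genes in the reference (default 10).
#' @param n_networks networks in the collection (default 500).
#' @param indegree_range per-gene in-degree interval of the reference.
#' @param backbone_presence probability that a backbone (high-confidence)
#'   interaction appears in a given network (default 0.95).
#' @param set_size members per auto-derived planted set (default 3).
#' @param n_variable_edges number of unspecific variable edges (default 4).
#' @param variable_presence independent presence probability of each variable
#'   edge (default 0.4).
#' @param group_proportions probability vector over valid signatures (in the
#'   order of [enumerate_valid_signatures()]: by size, then lexicographic);
#'   default uniform, i.e. `c(0.5, 0.5)` for two competing sets.
#' @param noise_rate probability of flipping the presence of any admissible
#'   signed edge in a network (default 0.02); keep it below the
#'   non-interaction cutoff so noise alone cannot mimic low-confidence
#'   structure.
#' @param score_range range of the uniform synthetic per-network fit scores;
#'   these only exercise score-based selection and carry no dynamical
#'   meaning.
#' @param planted_sets optional named list of member-key vectors overriding
#'   the auto-derived sets.
#' @param planted_competitions optional two-column matrix/data.frame of
#'   competing planted-set name pairs.
#' @param seed optional integer seed for the whole generation.
#' @return an object of class `synthetic_spec`.
#' @export
synthetic_spec <- function(n_genes = 10L, n_networks = 500L,
                           indegree_range = c(1L, 3L),
                           backbone_presence = 0.95,
                           set_size = 3L, n_variable_edges = 4L,
                           variable_presence = 0.4,
                           group_proportions = NULL,
                           noise_rate = 0.02,
                           score_range = c(0.05, 0.15),
                           planted_sets = NULL,
                           planted_competitions = NULL,
                           seed = NULL) {
  stopifnot(n_networks >= 1, backbone_presence >= 0, backbone_presence <= 1,
            variable_presence >= 0, variable_presence <= 1,
            noise_rate >= 0, noise_rate < 1,
            length(score_range) == 2L, score_range[1] <= score_range[2])
  if (!is.null(group_proportions) &&
      abs(sum(group_proportions) - 1) > 1e-8) {
    stop("group_proportions must sum to 1")
  }
  structure(
    list(n_genes = as.integer(n_genes), n_networks = as.integer(n_networks),
         indegree_range = as.integer(indegree_range),
         backbone_presence = backbone_presence, set_size = as.integer(set_size),
         n_variable_edges = as.integer(n_variable_edges),
         variable_presence = variable_presence,
         group_proportions = group_proportions, noise_rate = noise_rate,
         score_range = score_range, planted_sets = planted_sets,
         planted_competitions = planted_competitions, seed = seed),
    class = "synthetic_spec"
  )
}

#' Generate a synthetic network collection with planted structure
#'
#' Each network is assigned a signature (combination of planted sets) by
#' `group_proportions` and receives: all member interactions of the sets in
#' its signature; each backbone interaction independently with probability
#' `backbone_presence`; each variable edge independently with probability
#' `variable_presence`; finally the presence of every admissible signed edge
#' is flipped with probability `noise_rate`.  A noise addition that would put
#' both signs on one gene pair is reverted, so strict-mode networks are
#' always produced.  Generation is fully reproducible given `spec$seed`.
#'
#' @param spec a [synthetic_spec()].
#' @return list with `collection` (a scored [grn_collection()]) and `truth`
#'   (class `planted_truth`): `reference` (`grn_network`), `true_sets` (named
#'   list of member keys), `true_competitions` (data.frame `set1`, `set2`),
#'   `group_assignment` (named character, network id -> pre-noise signature
#'   key), `backbone`, `variable_edges`, and the `spec` echo.
#' @examples
#' sim <- generate_collection(synthetic_spec(n_networks = 50, seed = 7))
#' sim$collection
#' sim$truth$true_sets
#' @export
generate_collection <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  with_rng_seed(spec$seed, generate_collection_impl(spec))
}

generate_collection_impl <- function(spec) {
  genes <- gene_names(spec$n_genes)
  reference <- random_reference(spec$n_genes, spec$indegree_range)
  universe <- candidate_universe(genes)

  if (is.null(spec$planted_sets)) {
    planted <- derive_planted_sets(reference, genes, spec$set_size)
    sets <- planted$sets
    competitions <- planted$competitions
  } else {
    sets <- lapply(spec$planted_sets, function(x) sort(unique(x)))
    competitions <- as.data.frame(spec$planted_competitions,
                                  stringsAsFactors = FALSE)
    if (is.null(competitions) || ncol(competitions) == 0L) {
      competitions <- data.frame(set1 = character(0), set2 = character(0))
    }
    names(competitions) <- c("set1", "set2")
  }
  all_members <- unique(unlist(sets, use.names = FALSE))
  backbone <- setdiff(reference$interactions, all_members)

  # unspecific variable edges on gene pairs untouched by reference or sets
  used_pairs <- unique(interaction_pair(c(reference$interactions, all_members)))
  free <- universe[!(interaction_pair(universe) %in% used_pairs)]
  free_pairs <- unique(interaction_pair(free))
  if (length(free_pairs) < spec$n_variable_edges) {
    stop("gene universe too small for ", spec$n_variable_edges,
         " variable edges")
  }
  var_pairs <- sample(free_pairs, spec$n_variable_edges)
  variable_edges <- vapply(var_pairs, function(p) {
    paste0(p, ":", sample(c("+", "-"), 1L))
  }, character(1))
  variable_edges <- sort(unname(variable_edges))

  # valid signatures over the planted sets, deterministic order
  signatures <- planted_signatures(names(sets), competitions)
  props <- spec$group_proportions
  if (is.null(props)) props <- rep(1 / length(signatures), length(signatures))
  if (length(props) != length(signatures)) {
    stop("group_proportions has ", length(props), " entries but there are ",
         length(signatures), " valid signatures")
  }

  n <- spec$n_networks
  sig_idx <- sample.int(length(signatures), n, replace = TRUE, prob = props)
  ids <- sprintf(paste0("net%0", max(3L, nchar(n)), "d"), seq_len(n))

  m <- matrix(FALSE, nrow = n, ncol = length(universe),
              dimnames = list(ids, universe))
  if (length(backbone)) {
    m[, backbone] <- stats::runif(n * length(backbone)) < spec$backbone_presence
  }
  if (length(variable_edges)) {
    m[, variable_edges] <-
      stats::runif(n * length(variable_edges)) < spec$variable_presence
  }
  for (k in seq_along(signatures)) {
    rows <- sig_idx == k
    for (s in signatures[[k]]) m[rows, sets[[s]]] <- TRUE
  }
  pre <- m
  if (spec$noise_rate > 0) {
    flip <- matrix(stats::runif(length(m)) < spec$noise_rate,
                   nrow = n, dimnames = dimnames(m))
    m <- xor(m, flip)
    # revert noise on gene pairs it left carrying both signs
    pairs <- interaction_pair(universe)
    plus_cols <- which(interaction_sign(universe) == "+")
    minus_cols <- match(paste0(pairs[plus_cols], ":-"), universe)
    both <- m[, plus_cols, drop = FALSE] & m[, minus_cols, drop = FALSE]
    if (any(both)) {
      idx <- which(both, arr.ind = TRUE)
      for (r in seq_len(nrow(idx))) {
        i <- idx[r, 1L]
        jp <- plus_cols[idx[r, 2L]]
        jm <- minus_cols[idx[r, 2L]]
        m[i, jp] <- pre[i, jp]
        m[i, jm] <- pre[i, jm]
      }
    }
  }
  networks <- lapply(seq_len(n), function(i) universe[m[i, ]])
  names(networks) <- ids
  scores <- stats::runif(n, spec$score_range[1], spec$score_range[2])
  collection <- grn_collection(networks, scores, genes = genes)

  assignment <- vapply(sig_idx, function(k) signature_key(signatures[[k]]),
                       character(1))
  names(assignment) <- ids
  truth <- structure(
    list(reference = reference, true_sets = sets,
         true_competitions = competitions, group_assignment = assignment,
         backbone = backbone, variable_edges = variable_edges, spec = spec),
    class = "planted_truth"
  )
  list(collection = collection, truth = truth)
}

# Two competing planted sets: set A = true reference edges, set B = the same
# targets rewired to alternative effectors absent from the reference.
derive_planted_sets <- function(reference, genes, set_size) {
  ref <- reference$interactions
  p <- parse_interactions(ref)
  ref_pairs <- interaction_pair(ref)
  # pick member targets with distinct targets so set B pairs stay distinct
  targets <- unique(p$target)
  if (length(targets) < set_size) {
    stop("reference has too few distinct targets for set_size ", set_size)
  }
  chosen_targets <- sample(targets, set_size)
  a_members <- character(set_size)
  b_members <- character(set_size)
  for (i in seq_along(chosen_targets)) {
    tgt <- chosen_targets[i]
    cand_rows <- which(p$target == tgt)
    row <- if (length(cand_rows) == 1L) cand_rows else sample(cand_rows, 1L)
    a_members[i] <- ref[row]
    alt_eff <- setdiff(genes, c(tgt, p$effector[p$target == tgt]))
    alt_eff <- alt_eff[!(paste0(alt_eff, "->", tgt) %in% ref_pairs)]
    if (length(alt_eff) == 0L) {
      stop("no alternative effector available for target ", tgt)
    }
    eff <- if (length(alt_eff) == 1L) alt_eff else sample(alt_eff, 1L)
    b_members[i] <- paste0(eff, "->", tgt, ":", sample(c("+", "-"), 1L))
  }
  list(
    sets = list(PS1 = sort(a_members), PS2 = sort(b_members)),
    competitions = data.frame(set1 = "PS1", set2 = "PS2",
                              stringsAsFactors = FALSE)
  )
}

# Non-empty subsets of planted-set names with no competing pair, ordered by
# size then lexicographically (mirrors enumerate_valid_signatures()).
planted_signatures <- function(ids, competitions) {
  subsets <- list()
  for (size in seq_along(ids)) {
    for (sub in utils::combn(ids, size, simplify = FALSE)) {
      sub <- sort(sub)
      competing <- nrow(competitions) > 0L && any(
        (competitions$set1 %in% sub & competitions$set2 %in% sub)
      )
      if (!competing) subsets[[length(subsets) + 1L]] <- sub
    }
  }
  keys <- vapply(subsets, signature_key, character(1))
  subsets[order(lengths(subsets), keys)]
}

#' Retain the best-scoring fraction of a collection
#'
#' Keeps the `ceiling(fraction * N)` networks with the smallest fit score
#' (mirroring selection of the best predictions by RMSD before extraction);
#' score ties are broken by network id so the result is deterministic.
#'
#' @param collection a fully scored [grn_collection()].
#' @param fraction fraction to retain, in (0, 1].
#' @return a `grn_collection` of the retained networks, in their original
#'   order.
#' @export
select_top_fraction <- function(collection, fraction) {
  stopifnot(inherits(collection, "grn_collection"),
            is.numeric(fraction), length(fraction) == 1L,
            fraction > 0, fraction <= 1)
  scores <- collection$scores
  if (anyNA(scores)) {
    stop("network(s) without a score: ",
         paste(names(scores)[is.na(scores)], collapse = ", "))
  }
  k <- ceiling(fraction * length(scores))
  keep_ids <- names(scores)[order(scores, names(scores))][seq_len(k)]
  keep_ids <- names(scores)[names(scores) %in% keep_ids] # original order
  subset_collection(collection, keep_ids)
}
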