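#' Ensemble entropy
#'
#' The total entropy of an ensemble, summed over the candidate interaction
#' universe: each interaction with weight (relative frequency) `f` contributes
#' the binary entropy `-f*log2(f) - (1-f)*log2(1-f)` (with `0*log 0 = 0`).
#' Interactions never predicted have frequency 0 and contribute nothing.  The
#' entropy is 0 iff all frequencies are 0 or 1 and is maximised by
#' frequencies of 0.5, so it measures the overall confidence of an ensemble:
#' a large proportion of intermediate-frequency (low-confidence) interactions
#' means high entropy.
#'
#' @param ensemble a [signed_vote()] result, or a named numeric weight
#'   vector.
#' @param universe optional candidate universe (see [candidate_universe()]);
#'   when supplied, ensemble interactions must lie inside it.  The universe
#'   only validates scope -- zero-frequency candidates contribute 0 bits.
#' @param base logarithm base; 2 (bits) by default.  Entropy *ratios* are
#'   independent of this choice.
#' @return non-negative numeric scalar.
#' @examples
#' ensemble_entropy(c("A->B:+" = 0.5)) # 1 bit
#' ensemble_entropy(c("A->B:+" = 1, "B->C:-" = 0.5, "C->A:+" = 0.5)) # 2 bits
#' @export
ensemble_entropy <- function(ensemble, universe = NULL, base = 2) {
  w <- ensemble_weights(ensemble)
  if (any(w < 0 | w > 1)) stop("ensemble weights must lie in [0, 1]")
  if (!is.null(universe)) {
    outside <- setdiff(names(w), universe)
    if (length(outside)) {
      stop("ensemble interaction(s) outside the candidate universe: ",
           paste(outside, collapse = ", "))
    }
  }
  h <- function(f) ifelse(f <= 0 | f >= 1, 0, -f * log(f, base) - (1 - f) * log(1 - f, base))
  sum(h(w))
}

#' Mean entropy reduction of group-ensembles
#'
#' The mean, over group-ensembles, of the ratio of each group-ensemble's
#' entropy to the full-ensemble entropy.  A ratio well below 1 means grouping
#' has converted low-confidence interactions into high-confidence ones within
#' each group.
#'
#' @param groups list of group ensembles ([signed_vote()] results).
#' @param full the ensemble voted over all networks.
#' @inheritParams ensemble_entropy
#' @return numeric scalar `>= 0`.
#' @export
entropy_ratio <- function(groups, full, universe = NULL, base = 2) {
  stopifnot(length(groups) >= 1L)
  h_full <- ensemble_entropy(full, universe, base)
  if (h_full == 0) {
    stop("full-ensemble entropy is zero; the entropy ratio is undefined")
  }
  ratios <- vapply(groups, function(g) {
    ensemble_entropy(g, universe, base) / h_full
  }, numeric(1))
  mean(ratios)
}

ensemble_weights <- function(ensemble) {
  if (inherits(ensemble, "grn_ensemble")) return(ensemble$weights)
  if (is.numeric(ensemble)) {
    if (length(ensemble) && is.null(names(ensemble))) {
      stop("weight vectors must be named by interaction key")
    }
    return(ensemble)
  }
  stop("ensemble must be a grn_ensemble or a named numeric weight vector")
}

#' Area under the precision-recall curve against a reference network
#'
#' Ensemble interactions are ranked by descending weight; at every distinct
#' positive weight `t` the prediction set is all interactions with weight
#' `>= t` (ties share one threshold), precision is `TP / |predicted|` and
#' recall `TP / |reference|`, a true positive being an exact
#' (effector, target, sign) match.  The area is the rectangular (step) sum
#' `sum_k (R_k - R_{k-1}) * P_k` over successive thresholds with `R_0 = 0`;
#' no interpolation is applied, so areas are bit-reproducible.  The AUPRC is
#' 1 when all reference interactions are ranked strictly above every other
#' interaction, and 0 when no reference interaction is present in the
#' ensemble.
#'
#' By default a predicted edge with the wrong sign is a false positive;
#' `unsigned = TRUE` collapses signs before matching.
#'
#' @inheritParams ensemble_entropy
#' @param reference a `grn_network` (or character key vector) of true
#'   interactions; must be non-empty and lie inside `universe`.
#' @param universe the admissible signed-interaction universe
#'   ([candidate_universe()] over the collection's genes).
#' @param unsigned collapse signs before matching?
#' @return an object of class `pr_curve`: list with `points` (data.frame
#'   `threshold`, `recall`, `precision`) and `auprc`.
#' @export
auprc <- function(ensemble, reference, universe, unsigned = FALSE) {
  w <- ensemble_weights(ensemble)
  ref <- reference_keys(reference)
  if (length(ref) == 0L) stop("reference network is empty")
  missing_ref <- setdiff(ref, universe)
  if (length(missing_ref)) {
    stop("reference interaction(s) outside the candidate universe: ",
         paste(missing_ref, collapse = ", "))
  }
  outside <- setdiff(names(w), universe)
  if (length(outside)) {
    stop("ensemble interaction(s) outside the candidate universe: ",
         paste(outside, collapse = ", "))
  }
  if (unsigned) {
    ref <- unique(interaction_pair(ref))
    pw <- interaction_pair(names(w))
    w <- vapply(split(w, pw), max, numeric(1))
  }
  w <- w[w > 0]
  points <- data.frame(threshold = numeric(0), recall = numeric(0),
                       precision = numeric(0))
  auc <- 0
  if (length(w)) {
    ord <- order(-w, names(w))
    w <- w[ord]
    hit <- as.numeric(names(w) %in% ref)
    tp <- cumsum(hit)
    npred <- seq_along(w)
    # ties share one threshold: keep the last index of each distinct weight
    last <- which(!duplicated(rev(w))) # positions from the end
    keep <- sort(length(w) + 1L - last)
    recall <- tp[keep] / length(ref)
    precision <- tp[keep] / npred[keep]
    auc <- sum(diff(c(0, recall)) * precision)
    points <- data.frame(threshold = unname(w[keep]), recall = recall,
                         precision = precision)
  }
  structure(list(points = points, auprc = auc), class = "pr_curve")
}

#' @export
print.pr_curve <- function(x, ...) {
  cat("pr_curve: AUPRC ", signif(x$auprc, 6), " over ",
      nrow(x$points), " thresholds\n", sep = "")
  invisible(x)
}

#' Precision of a characteristic set against a reference network
#'
#' The fraction of a set's member interactions found (exact signed match) in
#' the reference: 1 when all members are present, 0 when none is.
#'
#' @param members character vector of member interaction keys (one set of a
#'   `charset_system`).
#' @param reference a `grn_network` or character key vector.
#' @return numeric scalar in \[0, 1\].
#' @export
charset_precision <- function(members, reference) {
  stopifnot(length(members) >= 1L)
  ref <- reference_keys(reference)
  mean(members %in% ref)
}

#' Simulated experimental validation of a single interaction
#'
#' Emulates establishing the presence or absence of one tested interaction
#' by experiment: if the tested interaction is present in the reference, all
#' networks lacking it are rejected; otherwise all networks containing it
#' are rejected.  The ensemble is then re-voted over the retained networks.
#' Testing an interaction that is a member of a characteristic set rejects
#' entire alternative hypotheses at once, which is what makes co-occurring
#' interactions preferred targets for experimental verification.
#'
#' @param collection a [grn_collection()].
#' @param reference a `grn_network` or character key vector.
#' @param tested a single interaction key (typically LOW-confidence).
#' @inheritParams signed_vote
#' @return list with `retained` (a `grn_collection`) and `ensemble` (a
#'   `grn_ensemble` voted over the retained networks).
#' @export
validate_interaction <- function(collection, reference, tested,
                                 scheme = c("signed", "frequency")) {
  scheme <- match.arg(scheme)
  stopifnot(inherits(collection, "grn_collection"),
            is.character(tested), length(tested) == 1L)
  parse_interactions(tested)
  ref <- reference_keys(reference)
  has_it <- vapply(collection$networks, function(net) tested %in% net,
                   logical(1))
  keep <- if (tested %in% ref) has_it else !has_it
  if (!any(keep)) {
    stop("validation of '", tested, "' rejects every network; ",
         "the collection carries no surviving hypothesis")
  }
  retained <- subset_collection(collection, names(collection$networks)[keep])
  list(retained = retained, ensemble = signed_vote(retained, scheme = scheme))
}
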