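#' Does a network contain a characteristic set?
#'
#' Containment is crisp: every member interaction of the set must be present
#' in the network.
#'
#' @param interactions a `grn_network`, or a character vector of interaction
#'   keys.
#' @param members a characteristic set: character vector of member keys (or a
#'   single set entry of a `charset_system`).
#' @return logical scalar.
#' @export
contains_set <- function(interactions, members) {
  if (inherits(interactions, "grn_network")) {
    interactions <- interactions$interactions
  }
  length(members) > 0L && all(members %in% interactions)
}

# Canonical printable form of a signature (set of set ids).
signature_key <- function(set_ids) {
  paste(sort(set_ids), collapse = "+")
}

#' Group networks by the combination of characteristic sets they contain
#'
#' Each network is mapped to the signature of exactly the characteristic sets
#' it fully contains.  Networks containing no set are excluded from ensemble
#' creation.  Competing sets cannot validly co-occur in one network, so a
#' network exhibiting two competing sets simultaneously is flagged and, by
#' default, excluded (noise can produce such networks even though the
#' competition semantics forbid them); `keep_violations = TRUE` keeps it in
#' the group of all contained sets.  Sets carrying intra-set conflicts are
#' withheld from grouping unless `force = TRUE`.
#'
#' @param collection a [grn_collection()].
#' @param system a [build_characteristic_sets()] result.
#' @param keep_violations keep networks that contain competing sets?
#' @param force group on conflicted sets as well?
#' @return an object of class `network_grouping`: list with
#'   * `groups`: named list (signature key -> list with `signature` = sorted
#'     set ids, `member_ids`), only non-empty groups, deterministic order;
#'   * `excluded`: ids of networks containing no characteristic set;
#'   * `flagged`: ids of networks containing competing sets.
#' @export
group_networks <- function(collection, system, keep_violations = FALSE,
                           force = FALSE) {
  stopifnot(inherits(collection, "grn_collection"),
            inherits(system, "charset_system"))
  bad <- conflicted_sets(system)
  if (length(bad) && !force) {
    warning("set(s) with intra-set conflicts withheld from grouping: ",
            paste(bad, collapse = ", "), " (manual resolution required)")
  }
  usable <- if (force) names(system$sets) else setdiff(names(system$sets), bad)
  comp <- system$competitions
  groups <- list()
  excluded <- character(0)
  flagged <- character(0)
  for (id in names(collection$networks)) {
    net <- collection$networks[[id]]
    sig <- usable[vapply(usable, function(s) contains_set(net, system$sets[[s]]),
                         logical(1))]
    if (length(sig) == 0L) {
      excluded <- c(excluded, id)
      next
    }
    competing <- nrow(comp) > 0L &&
      any(comp$set1 %in% sig & comp$set2 %in% sig)
    if (competing) {
      flagged <- c(flagged, id)
      if (!keep_violations) {
        excluded <- c(excluded, id)
        next
      }
    }
    key <- signature_key(sig)
    if (is.null(groups[[key]])) {
      groups[[key]] <- list(signature = sort(sig), member_ids = character(0))
    }
    groups[[key]]$member_ids <- c(groups[[key]]$member_ids, id)
  }
  if (length(groups)) groups <- groups[order(names(groups))]
  structure(list(groups = groups, excluded = excluded, flagged = flagged),
            class = "network_grouping")
}

#' @export
print.network_grouping <- function(x, ...) {
  cat("network_grouping: ", length(x$groups), " groups, ",
      length(x$excluded), " excluded, ", length(x$flagged), " flagged\n",
      sep = "")
  for (key in names(x$groups)) {
    cat("  {", key, "}: ", length(x$groups[[key]]$member_ids),
        " networks\n", sep = "")
  }
  invisible(x)
}

#' All signatures a valid network can exhibit
#'
#' Enumerates every non-empty subset of characteristic sets that contains no
#' competing pair.  With three sets of which exactly one pair competes this
#' yields five signatures.  Order is deterministic: by subset size, then
#' lexicographically.
#'
#' @param system a [build_characteristic_sets()] result (conflict-free).
#' @return list of character vectors of set ids.
#' @export
enumerate_valid_signatures <- function(system) {
  stopifnot(inherits(system, "charset_system"))
  if (nrow(system$conflicts)) {
    stop("system has unresolved intra-set conflicts: ",
         paste(conflicted_sets(system), collapse = ", "))
  }
  ids <- names(system$sets)
  if (length(ids) == 0L) return(list())
  comp <- system$competitions
  subsets <- list()
  for (size in seq_along(ids)) {
    cols <- utils::combn(ids, size, simplify = FALSE)
    for (sub in cols) {
      sub <- sort(sub)
      competing <- nrow(comp) > 0L &&
        any(comp$set1 %in% sub & comp$set2 %in% sub)
      if (!competing) subsets[[length(subsets) + 1L]] <- sub
    }
  }
  keys <- vapply(subsets, signature_key, character(1))
  sizes <- lengths(subsets)
  subsets[order(sizes, keys)]
}

#' Signed ensemble voting
#'
#' For every (effector, target) gene pair let `n_plus` be the number of
#' networks containing the activating edge, `n_minus` the number containing
#' the inhibiting edge, and `N` the number of networks voted over.  The net
#' vote is `v = (n_plus - n_minus) / N`; the ensemble assigns weight `|v|` to
#' the interaction carrying the sign of `v` and no weight when `v = 0`, so
#' each gene pair carries at most one signed interaction.  Under the
#' alternative `"frequency"` scheme each signed edge is weighted by its plain
#' relative frequency `n / N` and both signs may coexist.
#'
#' @param networks a [grn_collection()], or a list of interaction-key
#'   character vectors (one per network).
#' @param scheme `"signed"` (default) or `"frequency"`.
#' @return an object of class `grn_ensemble`: list with `weights` (named
#'   numeric in \[0, 1\], interaction key -> weight; absent keys have weight
#'   0) and `n_networks`.
#' @examples
#' coll <- grn_collection(list(n1 = "A->B:+", n2 = "A->B:+", n3 = "A->B:-"))
#' signed_vote(coll)$weights # A->B:+ carries (2 - 1) / 3
#' @export
signed_vote <- function(networks, scheme = c("signed", "frequency")) {
  scheme <- match.arg(scheme)
  if (inherits(networks, "grn_collection")) networks <- networks$networks
  if (inherits(networks, "grn_network")) networks <- list(networks$interactions)
  stopifnot(is.list(networks), length(networks) >= 1L)
  n <- length(networks)
  counts <- table(unlist(networks, use.names = FALSE))
  if (length(counts) == 0L) {
    return(structure(list(weights = stats::setNames(numeric(0), character(0)),
                          n_networks = n), class = "grn_ensemble"))
  }
  freq <- stats::setNames(as.numeric(counts) / n, names(counts))
  if (scheme == "frequency") {
    weights <- freq
  } else {
    pairs <- interaction_pair(names(freq))
    signs <- interaction_sign(names(freq))
    plus <- stats::setNames(rep(0, length(unique(pairs))), unique(pairs))
    minus <- plus
    plus[pairs[signs == "+"]] <- freq[signs == "+"]
    minus[pairs[signs == "-"]] <- freq[signs == "-"]
    v <- plus - minus
    keep <- which(v != 0)
    weights <- if (length(keep)) {
      stats::setNames(
        abs(v[keep]),
        paste0(names(v)[keep], ":", ifelse(v[keep] > 0, "+", "-"))
      )
    } else {
      stats::setNames(numeric(0), character(0))
    }
  }
  weights <- weights[order(names(weights))]
  structure(list(weights = weights, n_networks = n), class = "grn_ensemble")
}

#' @export
print.grn_ensemble <- function(x, ...) {
  cat("grn_ensemble over ", x$n_networks, " networks: ",
      length(x$weights), " weighted interactions\n", sep = "")
  invisible(x)
}

#' Per-group ensembles
#'
#' Applies [signed_vote()] separately to each network group.  By the
#' containment definition, every member interaction of a set in a group's
#' signature has within-group frequency exactly 1; high-confidence backbone
#' interactions also carry near-1 weights in every group.
#'
#' @param grouping a [group_networks()] result.
#' @param collection the [grn_collection()] the grouping was derived from.
#' @inheritParams signed_vote
#' @return named list (signature key -> `grn_ensemble`), empty groups
#'   omitted.
#' @export
group_ensembles <- function(grouping, collection,
                            scheme = c("signed", "frequency")) {
  scheme <- match.arg(scheme)
  stopifnot(inherits(grouping, "network_grouping"),
            inherits(collection, "grn_collection"))
  out <- lapply(grouping$groups, function(g) {
    signed_vote(collection$networks[g$member_ids], scheme = scheme)
  })
  out[lengths(lapply(grouping$groups, `[[`, "member_ids")) > 0L]
}

#' Fit score of a network group
#'
#' The arithmetic mean of the member networks' fit scores (e.g. mean RMSD);
#' used to rank alternative group-ensembles by how well their networks
#' explain the data.
#'
#' @param group one entry of a [group_networks()] result's `groups` list (or
#'   a character vector of member ids).
#' @param collection the scored [grn_collection()].
#' @return numeric scalar.
#' @export
group_score <- function(group, collection) {
  stopifnot(inherits(collection, "grn_collection"))
  ids <- if (is.character(group)) group else group$member_ids
  scores <- collection$scores[ids]
  if (anyNA(scores)) {
    stop("network(s) without a score: ",
         paste(ids[is.na(scores)], collapse = ", "))
  }
  mean(scores)
}
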