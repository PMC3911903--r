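#' AND and EX relation scores for low-confidence interaction pairs
#'
#' Both scores are built from association-rule confidences.  For a pair of
#' interactions `a`, `b` with marginal frequencies `f_a`, `f_b` and joint
#' frequency `f_ab`:
#'
#' * co-occurrence: `AND(a, b) = conf(a -> b) (x) conf(b -> a)`
#'   with `conf(a -> b) = f_ab / f_a`;
#' * mutual exclusiveness: `EX(a, b) = conf(a -> not b) (x) conf(b -> not a)`
#'   with `conf(a -> not b) = (f_a - f_ab) / f_a`.
#'
#' The conjunction `(x)` is `min` by default; `product` and the bounded
#' product `max(0, x + y - 1)` are available alternatives.  Under the `min`
#' conjunction `AND + EX <= 1` for every pair, with equality iff the two
#' rule confidences coincide, so with a score cutoff above 0.5 at most one of
#' the two relations can qualify.
#'
#' @param stats a [pair_stats()] data.frame (or any list with numeric fields
#'   `f_a`, `f_b`, `f_ab`); scores are computed row-wise.
#' @param conjunction how to combine the two rule confidences: `"min"`
#'   (default), `"product"` or `"bounded"`.
#' @return numeric vector of scores in \[0, 1\], one per pair.
#' @examples
#' s <- data.frame(f_a = 0.5, f_b = 0.5, f_ab = 0.25)
#' and_score(s) # 0.5
#' ex_score(s)  # 0.5
#' @export
and_score <- function(stats, conjunction = c("min", "product", "bounded")) {
  conjunction <- match.arg(conjunction)
  check_marginals(stats)
  conjoin(stats$f_ab / stats$f_a, stats$f_ab / stats$f_b, conjunction)
}

#' @rdname and_score
#' @export
ex_score <- function(stats, conjunction = c("min", "product", "bounded")) {
  conjunction <- match.arg(conjunction)
  check_marginals(stats)
  conjoin((stats$f_a - stats$f_ab) / stats$f_a,
          (stats$f_b - stats$f_ab) / stats$f_b, conjunction)
}

check_marginals <- function(stats) {
  if (any(stats$f_a <= 0) || any(stats$f_b <= 0)) {
    stop("AND/EX scores are undefined for zero marginal frequencies")
  }
  invisible(stats)
}

conjoin <- function(x, y, conjunction) {
  switch(conjunction,
    min = pmin(x, y),
    product = x * y,
    bounded = pmax(0, x + y - 1)
  )
}

#' Classify interaction pairs as AND, EX or unrelated
#'
#' A pair is AND-related iff its AND score strictly exceeds the score cutoff
#' and its joint frequency strictly exceeds the joint cutoff; EX-related iff
#' its EX score strictly exceeds the score cutoff and both exclusive
#' frequencies strictly exceed the joint cutoff.  The evidence-frequency gate
#' rejects relations supported by too few networks to be distinguishable from
#' noise.  With a score cutoff above 0.5 and the `min` conjunction, AND and
#' EX can never both qualify for one pair.
#'
#' @inheritParams and_score
#' @param cutoffs a [cutoff_config()].
#' @return data.frame of class `pair_relations`: the input pairs with
#'   `and_score`, `ex_score` and `relation` (`"AND"`, `"EX"` or `"NONE"`)
#'   columns appended.
#' @export
pairwise_relations <- function(stats, cutoffs = cutoff_config(),
                               conjunction = c("min", "product", "bounded")) {
  conjunction <- match.arg(conjunction)
  stopifnot(inherits(cutoffs, "cutoff_config"))
  out <- as.data.frame(stats)
  if (nrow(out) == 0L) {
    out$and_score <- numeric(0)
    out$ex_score <- numeric(0)
    out$relation <- character(0)
    class(out) <- c("pair_relations", "data.frame")
    return(out)
  }
  out$and_score <- and_score(out, conjunction)
  out$ex_score <- ex_score(out, conjunction)
  is_and <- out$and_score > cutoffs$score & out$f_ab > cutoffs$joint
  is_ex <- out$ex_score > cutoffs$score &
    pmin(out$f_a_not_b, out$f_b_not_a) > cutoffs$joint
  if (any(is_and & is_ex)) {
    # unreachable for min conjunction with score cutoff > 0.5; possible for
    # permissive alternative conjunctions
    stop("pair(s) qualify as both AND and EX; raise the score cutoff")
  }
  out$relation <- ifelse(is_and, "AND", ifelse(is_ex, "EX", "NONE"))
  class(out) <- c("pair_relations", "data.frame")
  out
}

#' Assemble characteristic interaction sets from pairwise relations
#'
#' AND-related pairs are the initial two-element characteristic sets; sets are
#' merged whenever any cross-pair is AND-related, so the final sets are the
#' connected components (of size >= 2) of the AND graph.  Two sets linked by
#' at least one EX relation are *competing*: a valid predicted network can
#' contain one of them but not both.  An EX relation between two members of
#' the same AND component is a *conflict*; conflicts are reported, never
#' auto-resolved, and conflicted sets are excluded from automatic grouping
#' unless forced.
#'
#' Set identifiers `S1, S2, ...` are assigned by the lexicographically
#' smallest member interaction, so repeated runs are byte-identical.
#'
#' @param relations a [pairwise_relations()] data.frame.
#' @param collection optionally, the [grn_collection()] the relations were
#'   derived from; if given, each set's support (fraction of networks
#'   containing all members) is computed.
#' @return an object of class `charset_system`: list with
#'   * `sets`: named list, set id -> sorted member keys;
#'   * `support`: named numeric (NA when no collection given);
#'   * `competitions`: data.frame (`set1`, `set2`, `n_ex`) of competing pairs;
#'   * `conflicts`: data.frame (`set_id`, `a`, `b`) of intra-set EX edges;
#'   * `relations`: the input relations.
#' @examples
#' rel <- data.frame(
#'   a = c("A->B:+", "B->C:+"), b = c("B->C:+", "C->D:+"),
#'   f_a = 0.5, f_b = 0.5, f_ab = 0.5, f_a_not_b = 0, f_b_not_a = 0,
#'   and_score = 1, ex_score = 0, relation = "AND"
#' )
#' build_characteristic_sets(rel)$sets
#' @export
build_characteristic_sets <- function(relations, collection = NULL) {
  and_edges <- relations[relations$relation == "AND", c("a", "b"), drop = FALSE]
  ex_edges <- relations[relations$relation == "EX", c("a", "b"), drop = FALSE]
  if (nrow(and_edges) == 0L) {
    return(structure(
      list(
        sets = stats::setNames(list(), character(0)),
        support = stats::setNames(numeric(0), character(0)),
        competitions = data.frame(set1 = character(0), set2 = character(0),
                                  n_ex = integer(0), stringsAsFactors = FALSE),
        conflicts = data.frame(set_id = character(0), a = character(0),
                               b = character(0), stringsAsFactors = FALSE),
        relations = relations
      ),
      class = "charset_system"
    ))
  }
  g <- igraph::graph_from_data_frame(and_edges, directed = FALSE)
  comp <- igraph::components(g)
  members_by_comp <- split(igraph::V(g)$name, comp$membership)
  members_by_comp <- lapply(members_by_comp, sort)
  # deterministic ids: order components by smallest member key
  ord <- order(vapply(members_by_comp, `[`, character(1), 1L))
  members_by_comp <- members_by_comp[ord]
  ids <- paste0("S", seq_along(members_by_comp))
  sets <- stats::setNames(members_by_comp, ids)

  set_of <- stats::setNames(
    rep(ids, lengths(sets)), unlist(sets, use.names = FALSE)
  )
  competitions <- data.frame(set1 = character(0), set2 = character(0),
                             n_ex = integer(0), stringsAsFactors = FALSE)
  conflicts <- data.frame(set_id = character(0), a = character(0),
                          b = character(0), stringsAsFactors = FALSE)
  if (nrow(ex_edges)) {
    sa <- set_of[ex_edges$a]
    sb <- set_of[ex_edges$b]
    intra <- !is.na(sa) & !is.na(sb) & sa == sb
    if (any(intra)) {
      conflicts <- data.frame(set_id = unname(sa[intra]),
                              a = ex_edges$a[intra], b = ex_edges$b[intra],
                              stringsAsFactors = FALSE)
      conflicts <- conflicts[order(conflicts$set_id, conflicts$a, conflicts$b), ]
      rownames(conflicts) <- NULL
    }
    inter <- !is.na(sa) & !is.na(sb) & sa != sb
    if (any(inter)) {
      p1 <- pmin(sa[inter], sb[inter])
      p2 <- pmax(sa[inter], sb[inter])
      tab <- table(paste(p1, p2))
      parts <- strsplit(names(tab), " ", fixed = TRUE)
      competitions <- data.frame(
        set1 = vapply(parts, `[`, character(1), 1L),
        set2 = vapply(parts, `[`, character(1), 2L),
        n_ex = as.integer(tab),
        stringsAsFactors = FALSE
      )
      competitions <- competitions[order(competitions$set1, competitions$set2), ]
      rownames(competitions) <- NULL
    }
  }
  support <- stats::setNames(rep(NA_real_, length(sets)), ids)
  if (!is.null(collection)) {
    stopifnot(inherits(collection, "grn_collection"))
    nets <- collection$networks
    for (id in ids) {
      support[[id]] <- mean(vapply(
        nets, function(net) all(sets[[id]] %in% net), logical(1)
      ))
    }
  }
  structure(
    list(sets = sets, support = support, competitions = competitions,
         conflicts = conflicts, relations = relations),
    class = "charset_system"
  )
}

#' @export
print.charset_system <- function(x, ...) {
  cat("charset_system: ", length(x$sets), " characteristic sets, ",
      nrow(x$competitions), " competing pairs, ",
      nrow(x$conflicts), " conflicts\n", sep = "")
  for (id in names(x$sets)) {
    cat("  ", id, " {", paste(x$sets[[id]], collapse = ", "), "}", sep = "")
    if (!is.na(x$support[[id]])) cat(" support", signif(x$support[[id]], 3))
    cat("\n")
  }
  if (nrow(x$competitions)) {
    cat("  competing:",
        paste(x$competitions$set1, x$competitions$set2, sep = "<->"), "\n")
  }
  invisible(x)
}

# Set ids whose members carry an intra-set EX conflict.
conflicted_sets <- function(system) {
  unique(system$conflicts$set_id)
}
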