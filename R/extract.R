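#' Full characteristic-set extraction pipeline
#'
#' Runs the three extraction steps on a collection of predicted networks:
#' (1) relative interaction frequencies and confidence tiers, (2) AND/EX
#' scoring of low-confidence pairs and assembly of characteristic sets with
#' their competition structure, (3) grouping of networks by the combination
#' of sets they contain.
#'
#' @inheritParams pairwise_relations
#' @param collection a [grn_collection()].
#' @param keep_violations,force passed to [group_networks()].
#' @return an object of class `charset_extraction`: list with `cutoffs`,
#'   `frequencies`, `classification`, `pair_stats`, `relations`, `system`
#'   and `grouping`.
#' @examples
#' coll <- grn_collection(list(
#'   n1 = c("A->B:+", "B->C:+", "C->D:+"), n2 = c("A->B:+", "B->C:+", "C->D:+"),
#'   n3 = c("A->B:+", "B->D:-", "D->C:-"), n4 = c("A->B:+", "B->D:-", "D->C:-")
#' ))
#' ext <- extract_characteristic_sets(coll, cutoff_config(hc = 0.9))
#' ext$system$sets # two competing 2-member sets
#' @export
extract_characteristic_sets <- function(collection,
                                        cutoffs = cutoff_config(),
                                        conjunction = c("min", "product", "bounded"),
                                        keep_violations = FALSE,
                                        force = FALSE) {
  conjunction <- match.arg(conjunction)
  freqs <- interaction_frequencies(collection)
  classification <- classify_interactions(freqs, cutoffs)
  stats <- pair_stats(collection, classification)
  relations <- pairwise_relations(stats, cutoffs, conjunction)
  system <- build_characteristic_sets(relations, collection)
  grouping <- group_networks(collection, system,
                             keep_violations = keep_violations, force = force)
  structure(
    list(cutoffs = cutoffs, frequencies = freqs,
         classification = classification, pair_stats = stats,
         relations = relations, system = system, grouping = grouping),
    class = "charset_extraction"
  )
}

#' @export
print.charset_extraction <- function(x, ...) {
  tiers <- table(factor(x$classification, levels = c("HIGH", "LOW", "NON")))
  cat("charset_extraction over ", x$frequencies$n_networks, " networks\n",
      "  tiers: ", tiers[["HIGH"]], " HIGH, ", tiers[["LOW"]], " LOW, ",
      tiers[["NON"]], " NON\n", sep = "")
  print(x$system)
  print(x$grouping)
  invisible(x)
}
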