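#' Network and network-collection containers
#'
#' A `grn_network` is one predicted (or reference) network: an identifier, a
#' set of signed interactions (canonical keys, see [interaction_key()]) and an
#' optional non-negative fit score (lower is better, e.g. an RMSD to the
#' training data).  A `grn_collection` is an ordered list of such networks
#' over a common gene universe; it is the input of characteristic-set
#' extraction.
#'
#' In strict mode (the default) a network may carry at most one sign per gene
#' pair, matching dynamical frameworks that admit a single regulatory role per
#' edge; lenient mode keeps both signs as distinct interactions.
#'
#' @param network_id single string identifying the network.
#' @param interactions character vector of interaction keys; duplicates are
#'   removed.
#' @param score optional single non-negative fit score (`NA` for none).
#' @param strict reject both signs on one gene pair within the network?
#' @return `grn_network()`: an object of class `grn_network` with fields
#'   `network_id`, `interactions` (sorted unique keys) and `score`.
#' @examples
#' net <- grn_network("n1", interaction_key(c("A", "B"), c("B", "C"), c("+", "-")))
#' net$interactions
#' @export
grn_network <- function(network_id, interactions, score = NA_real_,
                        strict = TRUE) {
  stopifnot(is.character(network_id), length(network_id) == 1L)
  interactions <- sort(unique(as.character(interactions)))
  parse_interactions(interactions) # validates key syntax
  if (strict) {
    pairs <- interaction_pair(interactions)
    dup <- unique(pairs[duplicated(pairs)])
    if (length(dup)) {
      stop("network '", network_id, "' carries both signs on gene pair(s): ",
           paste(dup, collapse = ", "), " (strict mode)")
    }
  }
  score <- as.numeric(score)
  stopifnot(length(score) == 1L)
  if (!is.na(score) && score < 0) stop("network score must be non-negative")
  structure(
    list(network_id = network_id, interactions = interactions, score = score),
    class = "grn_network"
  )
}

#' @rdname grn_network
#' @param networks a named list mapping network ids to character vectors of
#'   interaction keys, or a list of `grn_network` objects.
#' @param scores optional numeric vector of fit scores, one per network
#'   (recycled `NA` if absent); ignored when `networks` holds `grn_network`
#'   objects.
#' @param genes gene universe; defaults to the genes appearing in any
#'   interaction.  Declaring extra genes widens the candidate universe used by
#'   entropy and AUPRC evaluation.
#' @return `grn_collection()`: an object of class `grn_collection` with fields
#'   `networks` (named list of sorted key vectors), `scores` (named numeric)
#'   and `genes` (sorted character).
#' @export
grn_collection <- function(networks, scores = NULL, genes = NULL,
                           strict = TRUE) {
  if (length(networks) == 0L) stop("a collection needs at least one network")
  if (all(vapply(networks, inherits, logical(1), "grn_network"))) {
    ids <- vapply(networks, `[[`, character(1), "network_id")
    scores <- vapply(networks, `[[`, numeric(1), "score")
    networks <- lapply(networks, `[[`, "interactions")
    names(networks) <- ids
  } else {
    ids <- names(networks)
    if (is.null(ids) || any(ids == "")) stop("networks must be named by id")
    networks <- lapply(networks, function(x) sort(unique(as.character(x))))
    if (is.null(scores)) scores <- rep(NA_real_, length(networks))
  }
  if (anyDuplicated(ids)) {
    stop("duplicate network_id(s): ", paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  scores <- as.numeric(scores)
  stopifnot(length(scores) == length(networks))
  names(scores) <- ids
  for (id in ids) {
    # revalidate per network (sign-pair invariant, key syntax)
    grn_network(id, networks[[id]], scores[[id]], strict = strict)
  }
  observed <- unique(unlist(networks, use.names = FALSE))
  obs_genes <- if (length(observed)) {
    p <- parse_interactions(observed)
    unique(c(p$effector, p$target))
  } else character(0)
  if (is.null(genes)) {
    genes <- obs_genes
  } else {
    check_gene_ids(genes)
    missing <- setdiff(obs_genes, genes)
    if (length(missing)) {
      stop("interactions use gene(s) outside the declared universe: ",
           paste(missing, collapse = ", "))
    }
  }
  structure(
    list(networks = networks, scores = scores, genes = sort(unique(genes))),
    class = "grn_collection"
  )
}

#' @export
print.grn_collection <- function(x, ...) {
  n_int <- lengths(x$networks)
  cat("grn_collection: ", length(x$networks), " networks over ",
      length(x$genes), " genes\n", sep = "")
  cat("  interactions per network: ", min(n_int), "-", max(n_int),
      " (median ", stats::median(n_int), ")\n", sep = "")
  if (any(!is.na(x$scores))) {
    cat("  scores: ", signif(min(x$scores, na.rm = TRUE), 3), "-",
        signif(max(x$scores, na.rm = TRUE), 3), "\n", sep = "")
  }
  invisible(x)
}

#' @export
print.grn_network <- function(x, ...) {
  cat("grn_network '", x$network_id, "': ", length(x$interactions),
      " interactions", sep = "")
  if (!is.na(x$score)) cat(", score ", signif(x$score, 4), sep = "")
  cat("\n")
  invisible(x)
}

#' Subset a collection by network id
#'
#' @param collection a [grn_collection()].
#' @param ids character vector of network ids to retain (order preserved).
#' @return a `grn_collection` over the same gene universe.
#' @export
subset_collection <- function(collection, ids) {
  stopifnot(inherits(collection, "grn_collection"))
  missing <- setdiff(ids, names(collection$networks))
  if (length(missing)) {
    stop("unknown network id(s): ", paste(missing, collapse = ", "))
  }
  if (length(ids) == 0L) stop("cannot subset a collection to zero networks")
  grn_collection(collection$networks[ids], collection$scores[ids],
                 genes = collection$genes)
}

# Logical membership matrix (networks x observed interactions); the workhorse
# behind frequency and joint-frequency counting.
membership_matrix <- function(collection) {
  keys <- sort(unique(unlist(collection$networks, use.names = FALSE)))
  ids <- names(collection$networks)
  m <- matrix(FALSE, nrow = length(ids), ncol = length(keys),
              dimnames = list(ids, keys))
  for (id in ids) m[id, collection$networks[[id]]] <- TRUE
  m
}

# Coerce a reference argument (grn_network or key vector) to a key vector.
reference_keys <- function(reference) {
  if (inherits(reference, "grn_network")) return(reference$interactions)
  if (is.character(reference)) {
    parse_interactions(reference)
    return(sort(unique(reference)))
  }
  stop("reference must be a grn_network or a character vector of interaction keys")
}
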