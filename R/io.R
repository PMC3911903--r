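#' Read a collection of predicted networks from a TSV edge list
#'
#' One row per interaction, tab-separated columns
#' `network_id, effector, target, sign` and an optional fifth `score`
#' column (the network's fit score, repeated on each of its rows).  Signs
#' may be written `+`/`-`, `activating`/`inhibiting` or `1`/`-1`.  Lines
#' starting with `#` are comments; the directive `#genes: A B C` declares
#' genes that belong to the universe without appearing in any edge (this
#' widens the candidate universe used for entropy and AUPRC).  Duplicate
#' identical rows are deduplicated with a warning; malformed rows and
#' unknown sign tokens raise an error naming the line.  Input row order is
#' irrelevant: permuted files parse to equal collections.
#'
#' @param path path to the TSV file.
#' @param strict reject both signs on one gene pair within one network?
#' @param allow_self_loops permit effector == target?
#' @return a [grn_collection()].
#' @export
read_network_collection <- function(path, strict = TRUE,
                                    allow_self_loops = FALSE) {
  rows <- read_edge_rows(path, n_min = 4L, n_max = 5L,
                         what = "collection")
  ids <- vapply(rows, `[[`, character(1), 1L)
  keys <- mapply(function(r, ln) {
    tryCatch(
      interaction_key(r[2L], r[3L], r[4L], allow_self_loops = allow_self_loops),
      error = function(e) stop("line ", ln, ": ", conditionMessage(e),
                               call. = FALSE)
    )
  }, rows, attr(rows, "lines"))
  scores <- vapply(seq_along(rows), function(i) {
    r <- rows[[i]]
    if (length(r) < 5L) return(NA_real_)
    s <- suppressWarnings(as.numeric(r[5L]))
    if (is.na(s)) {
      stop("line ", attr(rows, "lines")[i], ": non-numeric score '", r[5L], "'",
           call. = FALSE)
    }
    s
  }, numeric(1))

  dup <- duplicated(paste(ids, keys))
  if (any(dup)) {
    warning("deduplicated ", sum(dup), " repeated row(s) in ", path)
    ids <- ids[!dup]; keys <- keys[!dup]; scores <- scores[!dup]
  }
  order_ids <- unique(ids)
  networks <- split(keys, factor(ids, levels = order_ids))
  net_scores <- vapply(order_ids, function(id) {
    s <- unique(scores[ids == id & !is.na(scores)])
    if (length(s) == 0L) return(NA_real_)
    if (length(s) > 1L) {
      stop("network '", id, "' carries conflicting scores: ",
           paste(s, collapse = ", "), call. = FALSE)
    }
    s
  }, numeric(1))
  genes <- attr(rows, "declared_genes")
  coll_genes <- if (length(genes)) {
    p <- parse_interactions(keys)
    sort(unique(c(genes, p$effector, p$target)))
  } else NULL
  grn_collection(networks, net_scores, genes = coll_genes, strict = strict)
}

#' Read a reference network from a TSV edge list
#'
#' Columns `effector, target, sign` (no network id).  Other conventions are
#' as in [read_network_collection()].
#'
#' @inheritParams read_network_collection
#' @return a `grn_network` with id `"reference"`.
#' @export
read_reference <- function(path, strict = TRUE, allow_self_loops = FALSE) {
  rows <- read_edge_rows(path, n_min = 3L, n_max = 3L, what = "reference")
  keys <- mapply(function(r, ln) {
    tryCatch(
      interaction_key(r[1L], r[2L], r[3L], allow_self_loops = allow_self_loops),
      error = function(e) stop("line ", ln, ": ", conditionMessage(e),
                               call. = FALSE)
    )
  }, rows, attr(rows, "lines"))
  if (anyDuplicated(keys)) {
    warning("deduplicated ", sum(duplicated(keys)), " repeated row(s) in ",
            path)
    keys <- unique(keys)
  }
  grn_network("reference", keys, strict = strict)
}

# Shared line-level TSV reader: comments, #genes: directive, column-count
# checks with line numbers.
read_edge_rows <- function(path, n_min, n_max, what) {
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- readLines(path, encoding = "UTF-8", warn = FALSE)
  declared <- character(0)
  keep <- logical(length(raw))
  for (i in seq_along(raw)) {
    line <- raw[i]
    if (grepl("^#genes:", line)) {
      declared <- c(declared,
                    strsplit(trimws(sub("^#genes:", "", line)),
                             "[[:space:]]+")[[1]])
      next
    }
    keep[i] <- !grepl("^#", line) && nzchar(trimws(line))
  }
  lines <- which(keep)
  if (length(lines) == 0L) {
    stop("no data rows in ", what, " file: ", path)
  }
  rows <- strsplit(raw[lines], "\t", fixed = TRUE)
  rows <- lapply(rows, trimws)
  nc <- lengths(rows)
  bad <- nc < n_min | nc > n_max
  if (any(bad)) {
    stop("line ", lines[which(bad)[1]], ": expected ", n_min,
         if (n_max > n_min) paste0("-", n_max), " tab-separated columns, got ",
         nc[which(bad)[1]], call. = FALSE)
  }
  attr(rows, "lines") <- lines
  attr(rows, "declared_genes") <- declared
  rows
}

#' Write a network collection to the collection TSV dialect
#'
#' Inverse of [read_network_collection()]: emits a `#genes:` directive for
#' the full gene universe and one row per interaction, with a score column
#' when any network carries a score.  Reading the result back reproduces the
#' collection exactly.
#'
#' @param collection a [grn_collection()].
#' @param path output path.
#' @export
write_network_collection <- function(collection, path) {
  stopifnot(inherits(collection, "grn_collection"))
  lines <- paste0("#genes: ", paste(collection$genes, collapse = " "))
  with_scores <- any(!is.na(collection$scores))
  for (id in names(collection$networks)) {
    keys <- collection$networks[[id]]
    if (length(keys) == 0L) next
    p <- parse_interactions(keys)
    row <- paste(id, p$effector, p$target, p$sign, sep = "\t")
    if (with_scores) {
      row <- paste(row, format(collection$scores[[id]], digits = 15),
                   sep = "\t")
    }
    lines <- c(lines, row)
  }
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_network_collection
#' @param reference a `grn_network`.
#' @export
write_reference <- function(reference, path) {
  ref <- reference_keys(reference)
  p <- parse_interactions(ref)
  writeLines(paste(p$effector, p$target, p$sign, sep = "\t"), path)
  invisible(path)
}

#' Write an ensemble to TSV
#'
#' Columns `effector, target, sign, weight`, sorted by descending weight and
#' then lexicographically by (effector, target, sign); weights are printed
#' with six decimals.
#'
#' @param ensemble a `grn_ensemble` or named weight vector.
#' @param path output path.
#' @export
write_ensemble <- function(ensemble, path) {
  w <- ensemble_weights(ensemble)
  header <- "effector\ttarget\tsign\tweight"
  if (length(w) == 0L) {
    writeLines(header, path)
    return(invisible(path))
  }
  p <- parse_interactions(names(w))
  ord <- order(-w, p$effector, p$target, p$sign)
  writeLines(
    c(header,
      paste(p$effector[ord], p$target[ord], p$sign[ord],
            sprintf("%.6f", w[ord]), sep = "\t")),
    path
  )
  invisible(path)
}

#' @rdname write_ensemble
#' @return `read_ensemble()`: a `grn_ensemble` (with unknown `n_networks`,
#'   recorded as `NA`).
#' @export
read_ensemble <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  required <- c("effector", "target", "sign", "weight")
  if (!all(required %in% names(tab))) {
    stop("ensemble TSV must have columns: ", paste(required, collapse = ", "))
  }
  w <- stats::setNames(
    as.numeric(tab$weight),
    interaction_key(tab$effector, tab$target, tab$sign)
  )
  w <- w[order(names(w))]
  structure(list(weights = w, n_networks = NA_integer_),
            class = "grn_ensemble")
}

#' Write the extraction report
#'
#' Serializes a full [extract_characteristic_sets()] result to a
#' machine-readable JSON report: cutoffs, interaction confidence tiers,
#' characteristic sets with member interactions and pairwise AND/EX scores,
#' competing set pairs, conflicts (with a `manual_resolution_required` flag),
#' the network groups by signature, and excluded/flagged networks.
#'
#' @param extraction a `charset_extraction`.
#' @param path output path.
#' @export
write_extraction_report <- function(extraction, path) {
  stopifnot(inherits(extraction, "charset_extraction"))
  system <- extraction$system
  grouping <- extraction$grouping
  rel <- extraction$relations
  set_records <- lapply(names(system$sets), function(id) {
    members <- system$sets[[id]]
    inside <- rel$a %in% members & rel$b %in% members
    list(
      id = id,
      members = members,
      support = system$support[[id]],
      pairwise_scores = rel[inside, c("a", "b", "and_score", "ex_score",
                                      "relation")]
    )
  })
  groups <- lapply(grouping$groups, function(g) {
    list(signature = g$signature, network_ids = g$member_ids)
  })
  report <- list(
    cutoffs = unclass(extraction$cutoffs),
    interaction_classes = as.list(extraction$classification),
    frequencies = as.list(extraction$frequencies$freq),
    n_networks = extraction$frequencies$n_networks,
    characteristic_sets = set_records,
    competitions = system$competitions,
    conflicts = system$conflicts,
    manual_resolution_required = nrow(system$conflicts) > 0L,
    groups = groups,
    excluded_networks = grouping$excluded,
    flagged_networks = grouping$flagged
  )
  jsonlite::write_json(report, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, dataframe = "rows")
  invisible(path)
}
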