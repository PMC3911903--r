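#' Signed interaction identifiers
#'
#' A signed interaction is the identity of a directed regulatory edge: an
#' effector gene, a target gene and a regulation sign (activating `"+"` or
#' inhibiting `"-"`).  Throughout the package interactions are represented as
#' canonical string keys of the form `"effector->target:+"`, so that sets of
#' interactions are plain character vectors and set operations are cheap.
#' `(A->B,+)` and `(A->B,-)` are distinct interactions.
#'
#' @param effector character vector of effector gene identifiers.
#' @param target character vector of target gene identifiers.
#' @param sign regulation sign; one of `"+"`, `"-"` or an accepted alias
#'   (`"activating"`/`"inhibiting"`, `"1"`/`"-1"`).
#' @param allow_self_loops permit `effector == target`?  Autoregulation is
#'   rejected by default because the networks this package targets relate
#'   distinct genes.
#' @return `interaction_key()`: a character vector of canonical keys.
#' @examples
#' interaction_key("G1", "G2", "+")
#' parse_interactions(c("G1->G2:+", "G3->G1:-"))
#' @export
interaction_key <- function(effector, target, sign, allow_self_loops = FALSE) {
  sign <- normalize_sign(sign)
  check_gene_ids(c(effector, target))
  if (!allow_self_loops && any(effector == target)) {
    stop("self-loop interaction(s): ",
         paste(unique(effector[effector == target]), collapse = ", "),
         " (use allow_self_loops = TRUE to permit)")
  }
  paste0(effector, "->", target, ":", sign)
}

#' @rdname interaction_key
#' @param keys character vector of canonical interaction keys.
#' @return `parse_interactions()`: a data.frame with columns `effector`,
#'   `target`, `sign`, one row per key.
#' @export
parse_interactions <- function(keys) {
  m <- regmatches(keys, regexec("^(.+)->(.+):([+-])$", keys))
  bad <- vapply(m, length, integer(1)) != 4L
  if (any(bad)) {
    stop("malformed interaction key(s): ", paste(keys[bad], collapse = ", "))
  }
  data.frame(
    effector = vapply(m, `[`, character(1), 2L),
    target = vapply(m, `[`, character(1), 3L),
    sign = vapply(m, `[`, character(1), 4L),
    stringsAsFactors = FALSE
  )
}

# Map accepted sign tokens onto the canonical "+"/"-".
normalize_sign <- function(sign) {
  lut <- c(
    "+" = "+", "-" = "-",
    "activating" = "+", "inhibiting" = "-",
    "activation" = "+", "inhibition" = "-",
    "1" = "+", "-1" = "-"
  )
  out <- lut[as.character(sign)]
  if (anyNA(out)) {
    stop("unknown sign token(s): ",
         paste(unique(sign[is.na(out)]), collapse = ", "))
  }
  unname(out)
}

# Gene identifiers must survive embedding in interaction keys and TSV rows.
check_gene_ids <- function(genes) {
  bad <- grepl("[[:space:]:]|->", genes) | genes == ""
  if (any(bad)) {
    stop("invalid gene identifier(s): ",
         paste(unique(genes[bad]), collapse = ", "),
         " (whitespace, ':' and '->' are reserved)")
  }
  invisible(genes)
}

#' Enumerate the admissible signed-interaction universe over a gene set
#'
#' The candidate universe contains every ordered pair of distinct genes with
#' both signs (self-loops optionally included).  It is the denominator for
#' ensemble entropy and for precision-recall evaluation.
#'
#' @param genes character vector of gene identifiers.
#' @inheritParams interaction_key
#' @return character vector of interaction keys, lexicographically sorted.
#' @examples
#' candidate_universe(c("A", "B"))
#' @export
candidate_universe <- function(genes, allow_self_loops = FALSE) {
  check_gene_ids(genes)
  genes <- sort(unique(genes))
  grid <- expand.grid(
    effector = genes, target = genes, sign = c("+", "-"),
    KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE
  )
  if (!allow_self_loops) grid <- grid[grid$effector != grid$target, ]
  sort(paste0(grid$effector, "->", grid$target, ":", grid$sign))
}

# "G1->G2:+" and "G1->G2:-" share the gene pair "G1->G2".
interaction_pair <- function(keys) {
  sub(":[+-]$", "", keys)
}

interaction_sign <- function(keys) {
  substring(keys, nchar(keys))
}
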