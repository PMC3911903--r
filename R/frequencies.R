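#' Cutoff configuration for characteristic-set extraction
#'
#' Four cutoffs govern the extraction: interactions with relative frequency
#' strictly above `hc` are high-confidence (HIGH), strictly below `nc`
#' high-confidence non-interactions (NON), and low-confidence (LOW) otherwise;
#' `joint` is the minimum evidence frequency for a pairwise relation (the
#' joint frequency for AND, the smaller exclusive frequency for EX); `score`
#' is the minimum AND/EX relation score.  The defaults 0.8/0.1/0.1/0.7 are
#' the reference operating point for ensembles of a few hundred predictions.
#'
#' `score > 0.5` is required: since the AND and EX scores of a pair sum to at
#' most 1, it guarantees that at most one of the two relations can qualify.
#'
#' @param hc high-confidence frequency cutoff, in (0, 1].
#' @param nc non-interaction frequency cutoff, in [0, 1); must be `< hc`.
#' @param joint minimum evidence frequency for pairwise relations, in [0, 1].
#' @param score AND/EX relation score cutoff, in (0.5, 1].
#' @return an object of class `cutoff_config`.
#' @examples
#' cutoff_config()
#' cutoff_config(hc = 0.9, nc = 0.05)
#' @export
cutoff_config <- function(hc = 0.8, nc = 0.1, joint = 0.1, score = 0.7) {
  stopifnot(
    is.numeric(hc), length(hc) == 1L, hc > 0, hc <= 1,
    is.numeric(nc), length(nc) == 1L, nc >= 0, nc < 1,
    is.numeric(joint), length(joint) == 1L, joint >= 0, joint <= 1,
    is.numeric(score), length(score) == 1L, score <= 1
  )
  if (nc >= hc) stop("nc cutoff must be smaller than hc cutoff")
  if (score <= 0.5) {
    stop("score cutoff must exceed 0.5 so that AND and EX cannot both qualify")
  }
  structure(list(hc = hc, nc = nc, joint = joint, score = score),
            class = "cutoff_config")
}

#' @export
print.cutoff_config <- function(x, ...) {
  cat(sprintf("cutoffs: hc > %g, non < %g, joint evidence > %g, relation score > %g\n",
              x$hc, x$nc, x$joint, x$score))
  invisible(x)
}

#' Relative interaction frequencies across a collection
#'
#' For every signed interaction observed in at least one network, the exact
#' fraction of networks that contain it.  Interactions never observed have
#' frequency 0 and are omitted from the table.
#'
#' @param collection a [grn_collection()].
#' @return an object of class `freq_table`: list with `freq` (named numeric,
#'   interaction key to relative frequency) and `n_networks`.
#' @examples
#' coll <- grn_collection(list(n1 = "A->B:+", n2 = c("A->B:+", "B->C:-")))
#' interaction_frequencies(coll)$freq
#' @export
interaction_frequencies <- function(collection) {
  stopifnot(inherits(collection, "grn_collection"))
  n <- length(collection$networks)
  counts <- table(unlist(collection$networks, use.names = FALSE))
  freq <- as.numeric(counts) / n
  names(freq) <- names(counts)
  freq <- freq[order(names(freq))]
  structure(list(freq = freq, n_networks = n), class = "freq_table")
}

#' @export
print.freq_table <- function(x, ...) {
  cat("freq_table: ", length(x$freq), " observed interactions over ",
      x$n_networks, " networks\n", sep = "")
  invisible(x)
}

#' Classify interactions into confidence tiers
#'
#' An interaction is `HIGH` (high-confidence interaction) if its relative
#' frequency is strictly above the `hc` cutoff, `NON` (high-confidence
#' non-interaction) if strictly below the `nc` cutoff, and `LOW` otherwise.
#' Frequencies exactly at a cutoff are LOW, which keeps borderline
#' interactions available for dependency analysis.  Only LOW interactions
#' enter pairwise AND/EX scoring.
#'
#' @param freqs a [interaction_frequencies()] result.
#' @param cutoffs a [cutoff_config()].
#' @return named character vector mapping each observed interaction key to
#'   `"HIGH"`, `"LOW"` or `"NON"`.
#' @examples
#' coll <- grn_collection(list(n1 = "A->B:+", n2 = c("A->B:+", "B->C:-")))
#' classify_interactions(interaction_frequencies(coll), cutoff_config())
#' @export
classify_interactions <- function(freqs, cutoffs = cutoff_config()) {
  stopifnot(inherits(freqs, "freq_table"), inherits(cutoffs, "cutoff_config"))
  f <- freqs$freq
  tier <- rep("LOW", length(f))
  tier[f > cutoffs$hc] <- "HIGH"
  tier[f < cutoffs$nc] <- "NON"
  names(tier) <- names(f)
  tier
}

#' Marginal, joint and exclusive frequencies for low-confidence pairs
#'
#' For every unordered pair of distinct LOW interactions, the marginal
#' frequencies `f_a`, `f_b`, the joint frequency `f_ab` (both present in the
#' same network) and the exclusive frequencies `f_a_not_b = f_a - f_ab`,
#' `f_b_not_a = f_b - f_ab`, all computed over the full collection.  These are
#' the sufficient statistics for AND/EX scoring.  Pairs are enumerated over
#' LOW interactions only; HIGH and NON tiers never enter dependency scoring.
#'
#' Within each row `a < b` lexicographically, and rows are sorted by
#' `(a, b)`, so results are byte-reproducible.
#'
#' @param collection the [grn_collection()] the classification came from.
#' @param classification result of [classify_interactions()] on this
#'   collection.
#' @return data.frame of class `pair_stats` with columns `a`, `b`, `f_a`,
#'   `f_b`, `f_ab`, `f_a_not_b`, `f_b_not_a`.
#' @export
pair_stats <- function(collection, classification) {
  stopifnot(inherits(collection, "grn_collection"))
  low <- sort(names(classification)[classification == "LOW"])
  if (length(low) < 2L) {
    out <- data.frame(
      a = character(0), b = character(0),
      f_a = numeric(0), f_b = numeric(0), f_ab = numeric(0),
      f_a_not_b = numeric(0), f_b_not_a = numeric(0),
      stringsAsFactors = FALSE
    )
    class(out) <- c("pair_stats", "data.frame")
    return(out)
  }
  m <- membership_matrix(collection)[, low, drop = FALSE]
  n <- nrow(m)
  joint <- crossprod(m) / n # (i,j) = fraction of networks containing both
  marg <- diag(joint)
  idx <- which(upper.tri(joint), arr.ind = TRUE)
  out <- data.frame(
    a = low[idx[, 1L]],
    b = low[idx[, 2L]],
    f_a = marg[idx[, 1L]],
    f_b = marg[idx[, 2L]],
    f_ab = joint[idx],
    stringsAsFactors = FALSE
  )
  out$f_a_not_b <- out$f_a - out$f_ab
  out$f_b_not_a <- out$f_b - out$f_ab
  out <- out[order(out$a, out$b), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("pair_stats", "data.frame")
  out
}
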