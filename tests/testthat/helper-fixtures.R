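# Shared fixtures and independent brute-force oracles.  The oracles are
# deliberately naive (explicit loops over networks / thresholds) so they stay
# independent of the vectorised implementation paths they check.

make_coll <- function(..., scores = NULL, genes = NULL) {
  grn_collection(list(...), scores = scores, genes = genes)
}

# A small random collection on 4 genes with <= max_edges observed edges on
# distinct gene pairs (so strict mode always holds) and 2..max_networks
# networks.
random_tiny_collection <- function(max_networks = 8, max_edges = 10) {
  genes <- c("A", "B", "C", "D")
  pairs <- expand.grid(e = genes, t = genes, stringsAsFactors = FALSE)
  pairs <- pairs[pairs$e != pairs$t, ]
  n_edges <- sample(2:max_edges, 1)
  rows <- pairs[sample(nrow(pairs), n_edges), ]
  pool <- interaction_key(rows$e, rows$t, sample(c("+", "-"), n_edges, TRUE))
  n <- sample(2:max_networks, 1)
  nets <- lapply(seq_len(n), function(i) {
    k <- sample(seq_len(n_edges), 1)
    sort(sample(pool, k))
  })
  names(nets) <- sprintf("n%02d", seq_len(n))
  grn_collection(nets, genes = genes)
}

oracle_frequencies <- function(networks) {
  keys <- sort(unique(unlist(networks)))
  freq <- sapply(keys, function(k) {
    hits <- 0
    for (net in networks) if (k %in% net) hits <- hits + 1
    hits / length(networks)
  })
  stats::setNames(as.numeric(freq), keys)
}

oracle_pair_stats <- function(networks, low) {
  low <- sort(low)
  out <- NULL
  n <- length(networks)
  for (i in seq_along(low)) {
    for (j in seq_along(low)) {
      if (j <= i) next
      a <- low[i]; b <- low[j]
      ca <- cb <- cab <- 0
      for (net in networks) {
        ina <- a %in% net
        inb <- b %in% net
        if (ina) ca <- ca + 1
        if (inb) cb <- cb + 1
        if (ina && inb) cab <- cab + 1
      }
      out <- rbind(out, data.frame(
        a = a, b = b, f_a = ca / n, f_b = cb / n, f_ab = cab / n,
        f_a_not_b = (ca - cab) / n, f_b_not_a = (cb - cab) / n,
        stringsAsFactors = FALSE
      ))
    }
  }
  if (is.null(out)) return(out)
  out[order(out$a, out$b), , drop = FALSE]
}

# Partition refinement over AND pairs: start with singleton blocks and merge
# blocks that share an AND edge until a fixpoint; return sorted member lists
# of blocks of size >= 2, sorted by smallest member.
oracle_and_components <- function(and_pairs) {
  nodes <- unique(c(and_pairs$a, and_pairs$b))
  blocks <- as.list(nodes)
  repeat {
    merged <- FALSE
    for (r in seq_len(nrow(and_pairs))) {
      ia <- which(vapply(blocks, function(bl) and_pairs$a[r] %in% bl, logical(1)))
      ib <- which(vapply(blocks, function(bl) and_pairs$b[r] %in% bl, logical(1)))
      if (ia != ib) {
        blocks[[ia]] <- c(blocks[[ia]], blocks[[ib]])
        blocks[[ib]] <- NULL
        merged <- TRUE
        break
      }
    }
    if (!merged) break
  }
  blocks <- lapply(blocks, sort)
  blocks <- blocks[lengths(blocks) >= 2]
  blocks[order(vapply(blocks, `[`, character(1), 1))]
}

# Exhaustive threshold enumeration of the step-integrated PR area.
oracle_auprc <- function(weights, ref) {
  weights <- weights[weights > 0]
  if (length(weights) == 0) return(0)
  area <- 0
  prev_recall <- 0
  for (t in sort(unique(weights), decreasing = TRUE)) {
    pred <- names(weights)[weights >= t]
    tp <- length(intersect(pred, ref))
    precision <- tp / length(pred)
    recall <- tp / length(ref)
    area <- area + (recall - prev_recall) * precision
    prev_recall <- recall
  }
  area
}

# Random pair statistics realizable as exact counts over n networks.
random_pair_stats <- function() {
  n <- sample(2:60, 1)
  ca <- sample(1:n, 1)
  cb <- sample(1:n, 1)
  cab <- sample(0:min(ca, cb), 1)
  data.frame(f_a = ca / n, f_b = cb / n, f_ab = cab / n,
             f_a_not_b = (ca - cab) / n, f_b_not_a = (cb - cab) / n)
}
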