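# Independent brute-force oracles used to cross-check the implementation.

rand_seq <- function(n) {
  paste(sample(aa_alphabet(), n, replace = TRUE), collapse = "")
}

# sliding-window pattern scan: per-position residue-set membership check
oracle_scan <- function(sequence, pattern) {
  slots <- parse_box_pattern(pattern)
  k <- length(slots)
  chars <- strsplit(sequence, "")[[1]]
  starts <- integer(0)
  for (i in seq_len(max(0L, length(chars) - k + 1L))) {
    ok <- TRUE
    for (j in seq_len(k)) {
      if (!(chars[i + j - 1L] %in% slots[[j]])) { ok <- FALSE; break }
    }
    if (ok) starts <- c(starts, i - 1L)
  }
  starts
}

# exhaustive combination oracle for match_signature: nested loops over all
# per-slot matches, same candidate ordering as the documented contract
# (max score, spacing-legal preferred, min span, left-most starts)
oracle_match <- function(sequence, signature_row) {
  slots <- signature_row$slots[[1]]
  per_slot <- lapply(slots, function(alts) {
    hits <- NULL
    for (p in alts) {
      st <- oracle_scan(sequence, attr(p, "pattern"))
      if (length(st) > 0L) {
        hits <- rbind(hits, data.frame(
          start = st, end = st + attr(p, "npos"),
          score = attr(p, "literal_score")))
      }
    }
    hits
  })
  if (any(vapply(per_slot, is.null, logical(1)))) return(NULL)
  best <- NULL
  # lexicographic comparison on (-score, illegal-spacing, span, starts...)
  key_of <- function(starts, ends, score, legal, span) {
    c(-score, as.numeric(!legal), span, starts)
  }
  consider <- function(starts, ends, score) {
    gaps <- starts[-1] - ends[-length(ends)]
    legal <- all(gaps >= signature_row$gap_min &
                   gaps <= signature_row$gap_max)
    span <- ends[length(ends)] - starts[1]
    key <- key_of(starts, ends, score, legal, span)
    if (is.null(best)) {
      best <<- list(starts = starts, ends = ends, score = score,
                    legal = legal, span = span, key = key)
      return(invisible())
    }
    d <- key - best$key
    nz <- which(d != 0)
    if (length(nz) > 0L && d[nz[1]] < 0) {
      best <<- list(starts = starts, ends = ends, score = score,
                    legal = legal, span = span, key = key)
    }
    invisible()
  }
  rec <- function(slot, starts, ends, score) {
    if (slot > length(per_slot)) { consider(starts, ends, score); return(invisible()) }
    h <- per_slot[[slot]]
    for (r in seq_len(nrow(h))) {
      if (length(starts) == 0L || h$start[r] > starts[length(starts)]) {
        rec(slot + 1L, c(starts, h$start[r]), c(ends, h$end[r]),
            score + h$score[r])
      }
    }
    invisible()
  }
  rec(1L, integer(0), integer(0), 0)
  best
}

# score-only affine-gap Smith-Waterman (Gotoh), quadratic DP in plain R
oracle_sw_score <- function(a, b, gap_open = 11, gap_extend = 1) {
  S <- pufatyper:::blosum62_matrix()
  ca <- strsplit(a, "")[[1]]; cb <- strsplit(b, "")[[1]]
  n <- length(ca); m <- length(cb)
  H <- matrix(0, n + 1, m + 1)
  E <- matrix(-Inf, n + 1, m + 1)  # gap in a (left)
  F <- matrix(-Inf, n + 1, m + 1)  # gap in b (up)
  best <- 0
  for (i in 2:(n + 1)) {
    for (j in 2:(m + 1)) {
      E[i, j] <- max(E[i, j - 1] - gap_extend,
                     H[i, j - 1] - gap_open - gap_extend)
      F[i, j] <- max(F[i - 1, j] - gap_extend,
                     H[i - 1, j] - gap_open - gap_extend)
      H[i, j] <- max(0,
                     H[i - 1, j - 1] + S[ca[i - 1], cb[j - 1]],
                     E[i, j], F[i, j])
      if (H[i, j] > best) best <- H[i, j]
    }
  }
  best
}

# all tip bipartitions of an unrooted tree via igraph edge removal
oracle_splits <- function(tree) {
  g <- igraph::graph_from_edgelist(apply(tree$edge, 2, as.character),
                                   directed = FALSE)
  tips <- tree$tip.label
  lapply(seq_len(nrow(tree$edge)), function(e) {
    g2 <- igraph::delete_edges(g, e)
    comp <- igraph::components(g2)$membership
    side <- names(comp)[comp == comp[[as.character(tree$edge[e, 2])]]]
    tips[as.integer(side[as.integer(side) <= length(tips)])]
  })
}

# small default simulation config used across tests
test_cfg <- function(seed = 1, ...) sim_config(seed = seed, ...)
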