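#' Alignment-based distance trees with bootstrap and monophyly tests
#'
#' A minimal deterministic pipeline: progressive multiple alignment
#' (k-mer cosine guide distances, NJ guide tree, profile-profile global
#' merges under BLOSUM62 with a linear gap penalty), p-distances (with an
#' optional Poisson correction), neighbour-joining tree construction, a
#' classical column-resampling bootstrap, and an unrooted-bipartition
#' monophyly test.
#'
#' @name phylo
NULL

# ---- progressive alignment --------------------------------------------------

kmer_profile <- function(sequence, k = 3L) {
  n <- nchar(sequence)
  if (n < k) return(table(character(0)))
  kmers <- substring(sequence, seq_len(n - k + 1L),
                     seq_len(n - k + 1L) + k - 1L)
  table(kmers)
}

kmer_cosine_dist <- function(sequences, k = 3L) {
  profs <- lapply(sequences, kmer_profile, k = k)
  n <- length(sequences)
  D <- matrix(0, n, n, dimnames = list(names(sequences), names(sequences)))
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      a <- profs[[i]]; b <- profs[[j]]
      shared <- intersect(names(a), names(b))
      num <- sum(as.numeric(a[shared]) * as.numeric(b[shared]))
      den <- sqrt(sum(as.numeric(a)^2)) * sqrt(sum(as.numeric(b)^2))
      D[i, j] <- D[j, i] <- 1 - if (den > 0) num / den else 0
    }
  }
  D
}

# character matrix (rows = sequences) -> alphabet x columns frequency
# profile; gap characters contribute nothing, so low-occupancy columns
# score less against residue columns.
msa_profile <- function(chars) {
  alpha <- aa_alphabet()
  prof <- matrix(0, nrow = length(alpha), ncol = ncol(chars),
                 dimnames = list(alpha, NULL))
  for (a in alpha) {
    prof[a, ] <- colSums(chars == a) / nrow(chars)
  }
  prof
}

merge_profiles <- function(chars_a, chars_b, S, gap) {
  res <- profile_align_cpp(msa_profile(chars_a), msa_profile(chars_b),
                           S, gap)
  ncol_out <- length(res$a)
  take <- function(chars, idx) {
    out <- matrix("-", nrow = nrow(chars), ncol = ncol_out,
                  dimnames = list(rownames(chars), NULL))
    out[, idx > 0L] <- chars[, idx[idx > 0L], drop = FALSE]
    out
  }
  rbind(take(chars_a, res$a), take(chars_b, res$b))
}

#' Progressive multiple sequence alignment
#'
#' Deterministic: guide distances are cosine distances between 3-mer
#' count vectors, the guide tree is NJ (rooted canonically at the
#' alphabetically first id, children ordered by their smallest tip
#' label), and profiles merge by global profile-profile alignment with
#' BLOSUM62 expected column scores and a linear gap penalty.
#'
#' @param sequences Named character vector of at least two protein
#'   sequences.
#' @param gap Linear gap penalty per column (default 8).
#' @param k Guide k-mer size (default 3).
#' @return An `msa`: character matrix, rows named by sequence id (input
#'   order), columns = alignment columns.
#' @export
progressive_align <- function(sequences, gap = 8, k = 3L) {
  if (length(sequences) < 2L) {
    stop("input error: need at least two sequences", call. = FALSE)
  }
  if (is.null(names(sequences)) || anyDuplicated(names(sequences))) {
    stop("input error: sequences need unique names", call. = FALSE)
  }
  lapply(sequences, check_protein_sequence)
  alpha <- aa_alphabet()
  S <- blosum62_matrix()[alpha, alpha]
  one <- function(id) {
    matrix(strsplit(sequences[[id]], "")[[1]], nrow = 1,
           dimnames = list(id, NULL))
  }
  n <- length(sequences)
  if (n == 2L) {
    out <- merge_profiles(one(names(sequences)[1]), one(names(sequences)[2]),
                          S, gap)
    return(structure(out, class = c("msa", class(out))))
  }
  D <- kmer_cosine_dist(sequences, k = k)
  guide <- if (n == 3L) nj_three_taxa(D) else ape::nj(D)
  root_tip <- sort(guide$tip.label)[1]
  guide <- ape::root(guide, outgroup = root_tip, resolve.root = TRUE)
  # recursive post-order merge; children ordered by smallest tip label
  ntip <- length(guide$tip.label)
  children_of <- split(guide$edge[, 2], guide$edge[, 1])
  min_tip <- function(node) {
    if (node <= ntip) return(guide$tip.label[node])
    min(vapply(children_of[[as.character(node)]], min_tip, character(1)))
  }
  build <- function(node) {
    if (node <= ntip) return(one(guide$tip.label[node]))
    kids <- children_of[[as.character(node)]]
    kids <- kids[order(vapply(kids, min_tip, character(1)))]
    acc <- build(kids[1])
    for (kid in kids[-1]) {
      acc <- merge_profiles(acc, build(kid), S, gap)
    }
    acc
  }
  out <- build(ntip + 1L)
  out <- out[names(sequences), , drop = FALSE]
  structure(out, class = c("msa", class(out)))
}

#' Strip gaps from one MSA row
#' @param msa An `msa` matrix.
#' @param id Row name.
#' @return The ungapped sequence string.
#' @export
msa_sequence <- function(msa, id) {
  paste(msa[id, msa[id, ] != "-"], collapse = "")
}

# ---- distances --------------------------------------------------------------

#' Pairwise p-distance matrix from an alignment
#'
#' The p-distance of two rows is the fraction of mismatched residues over
#' columns where both rows are ungapped. Pairs with no comparable column
#' get distance 1 with a warning. An optional Poisson correction
#' `-ln(1 - p)` (p capped at 0.95) approximates multiple hits.
#'
#' @param msa An `msa` character matrix (or any rows x columns character
#'   matrix with `-` gaps).
#' @param correction `"none"` (default) or `"poisson"`.
#' @return Symmetric numeric matrix with zero diagonal.
#' @export
p_distance_matrix <- function(msa, correction = c("none", "poisson")) {
  correction <- match.arg(correction)
  n <- nrow(msa)
  ids <- rownames(msa)
  D <- matrix(0, n, n, dimnames = list(ids, ids))
  for (i in seq_len(max(0L, n - 1L))) {
    for (j in (i + 1L):n) {
      ok <- msa[i, ] != "-" & msa[j, ] != "-"
      if (!any(ok)) {
        warning("no comparable columns for ", ids[i], " vs ", ids[j],
                "; distance set to 1", call. = FALSE)
        p <- 1
      } else {
        p <- mean(msa[i, ok] != msa[j, ok])
      }
      if (correction == "poisson") p <- -log(1 - min(p, 0.95))
      D[i, j] <- D[j, i] <- p
    }
  }
  D
}

# ---- neighbour joining ------------------------------------------------------

# closed-form unrooted tree for exactly three taxa
nj_three_taxa <- function(D) {
  ids <- rownames(D)
  bl <- c((D[1, 2] + D[1, 3] - D[2, 3]) / 2,
          (D[1, 2] + D[2, 3] - D[1, 3]) / 2,
          (D[1, 3] + D[2, 3] - D[1, 2]) / 2)
  structure(list(edge = matrix(c(4L, 1L, 4L, 2L, 4L, 3L), ncol = 2,
                               byrow = TRUE),
                 edge.length = bl, tip.label = ids, Nnode = 1L),
            class = "phylo", order = "cladewise")
}

#' Neighbour-joining tree from a distance matrix
#'
#' Saitou-Nei Q-criterion agglomeration (via ape for four or more taxa;
#' the three-taxon case uses the closed form). Negative branch lengths
#' are clamped to zero with a warning; a non-symmetric matrix is an
#' input error.
#'
#' @param D Symmetric numeric matrix with row/column names.
#' @param tol Symmetry tolerance.
#' @return An unrooted `phylo` tree.
#' @export
nj_tree <- function(D, tol = 1e-8) {
  D <- as.matrix(D)
  if (nrow(D) != ncol(D) || max(abs(D - t(D))) > tol) {
    stop("input error: distance matrix must be symmetric", call. = FALSE)
  }
  if (is.null(rownames(D))) rownames(D) <- colnames(D) <- paste0("t", seq_len(nrow(D)))
  if (nrow(D) < 3L) stop("input error: need at least 3 taxa", call. = FALSE)
  tree <- if (nrow(D) == 3L) nj_three_taxa(D) else ape::nj(D)
  if (any(tree$edge.length < 0)) {
    warning("negative NJ branch length(s) clamped to 0", call. = FALSE)
    tree$edge.length[tree$edge.length < 0] <- 0
  }
  tree
}

# ---- bootstrap --------------------------------------------------------------

#' Classical bootstrap support for an NJ tree
#'
#' Felsenstein column bootstrap: alignment columns are resampled with
#' replacement, an NJ tree is rebuilt per replicate, and each internal
#' bipartition's support is the fraction of replicate trees containing
#' it. Seeded and reproducible.
#'
#' @param msa An `msa` character matrix.
#' @param n_reps Number of replicates (>= 1; default 1000).
#' @param seed Integer seed.
#' @param correction Distance correction, see [p_distance_matrix()].
#' @return The NJ tree of the full alignment with per-internal-node
#'   support in `node.label` (fractions in \[0, 1\]).
#' @export
bootstrap_support <- function(msa, n_reps = 1000L, seed = 1L,
                              correction = "none") {
  if (n_reps < 1L) stop("input error: n_reps must be >= 1", call. = FALSE)
  ref <- nj_tree(p_distance_matrix(msa, correction))
  nc <- ncol(msa)
  boots <- withr_seed(seed, {
    lapply(seq_len(n_reps), function(r) {
      cols <- sample.int(nc, nc, replace = TRUE)
      suppressWarnings(
        nj_tree(p_distance_matrix(msa[, cols, drop = FALSE], correction)))
    })
  })
  counts <- suppressWarnings(ape::prop.clades(ref, boots, rooted = FALSE))
  counts[is.na(counts)] <- 0
  ref$node.label <- counts / n_reps
  ref
}

# evaluate expr with a locally-set RNG seed, restoring the caller's state
withr_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()))
  }
  set.seed(seed)
  expr
}

# ---- monophyly --------------------------------------------------------------

# tip-label sets below each internal edge (child side), by recursion on
# the edge list
edge_tip_sets <- function(tree) {
  ntip <- length(tree$tip.label)
  children_of <- split(tree$edge[, 2], tree$edge[, 1])
  below <- function(node) {
    if (node <= ntip) return(tree$tip.label[node])
    unlist(lapply(children_of[[as.character(node)]], below))
  }
  internal_children <- tree$edge[, 2][tree$edge[, 2] > ntip]
  lapply(internal_children, below)
}

#' Does a tip subset form a clade of an unrooted tree?
#'
#' True iff some edge of the tree bipartitions exactly the subset against
#' the remaining tips. The full tip set and single tips are trivially
#' monophyletic.
#'
#' @param tree A `phylo` tree.
#' @param tip_subset Character vector of tip labels.
#' @return Logical.
#' @export
is_monophyletic_split <- function(tree, tip_subset) {
  tips <- tree$tip.label
  if (!all(tip_subset %in% tips)) {
    stop("input error: tip subset contains unknown tip(s)", call. = FALSE)
  }
  tip_subset <- unique(tip_subset)
  # tip edges make single tips (and their complements) trivial splits
  if (length(tip_subset) %in% c(1L, length(tips) - 1L, length(tips))) {
    return(TRUE)
  }
  for (set in edge_tip_sets(tree)) {
    if (setequal(set, tip_subset) ||
        setequal(setdiff(tips, set), tip_subset)) {
      return(TRUE)
    }
  }
  FALSE
}
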