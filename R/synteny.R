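#' Gene-neighborhood (microsynteny) conservation
#'
#' The neighborhood procedure extracts up to four genes on either side of
#' a target locus per strain, maps homologs between the flank sets of two
#' strains by reciprocal best local alignment, and counts conserved
#' upstream/downstream flank genes. Conservation is membership-based
#' (a homolog anywhere in the other strain's flank window counts); order
#' and strand agreement are reported as flags, not required.
#'
#' @name synteny
NULL

# ---- GFF-lite I/O -----------------------------------------------------------

#' Read a GFF-lite annotation table
#'
#' GFF-lite is the tab-separated 9-column dialect: contig, source, type
#' (`gene`), start, end, score, strand, frame, attributes
#' (`gene_id=...;protein_id=...`). On disk coordinates are 1-based
#' inclusive (GFF convention); in memory they are 0-based half-open.
#'
#' @param path Input path.
#' @return Data frame of gene features: `gene_id`, `contig_id`, `start`,
#'   `end` (0-based half-open), `strand`, `protein_id`, sorted by contig
#'   and start.
#' @export
read_gff_lite <- function(path) {
  lines <- readLines(path)
  lines <- lines[!grepl("^#", lines) & nzchar(lines)]
  if (length(lines) == 0L) {
    return(data.frame(gene_id = character(0), contig_id = character(0),
                      start = integer(0), end = integer(0),
                      strand = character(0), protein_id = character(0),
                      stringsAsFactors = FALSE))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  if (any(lengths(fields) != 9L)) {
    stop("parse error: GFF-lite rows must have 9 columns", call. = FALSE)
  }
  attr_get <- function(attrs, key) {
    m <- regmatches(attrs, regexec(paste0(key, "=([^;]+)"), attrs))
    vapply(m, function(x) if (length(x) == 2L) x[2] else NA_character_,
           character(1))
  }
  attrs <- vapply(fields, `[[`, character(1), 9L)
  out <- data.frame(
    gene_id = attr_get(attrs, "gene_id"),
    contig_id = vapply(fields, `[[`, character(1), 1L),
    start = as.integer(vapply(fields, `[[`, character(1), 4L)) - 1L,
    end = as.integer(vapply(fields, `[[`, character(1), 5L)),
    strand = vapply(fields, `[[`, character(1), 7L),
    protein_id = attr_get(attrs, "protein_id"),
    stringsAsFactors = FALSE
  )
  if (anyNA(out$gene_id)) {
    stop("parse error: feature without gene_id attribute", call. = FALSE)
  }
  if (any(out$start >= out$end)) {
    stop("parse error: feature with start >= end", call. = FALSE)
  }
  if (anyDuplicated(paste(out$contig_id, out$gene_id))) {
    stop("parse error: duplicate gene_id on one contig", call. = FALSE)
  }
  out[order(out$contig_id, out$start), , drop = FALSE]
}

#' Write gene features as GFF-lite
#'
#' @param features Feature data frame as returned by [read_gff_lite()]
#'   (0-based half-open coordinates).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gff_lite <- function(features, path) {
  rows <- sprintf("%s\tpufatyper\tgene\t%d\t%d\t.\t%s\t.\tgene_id=%s;protein_id=%s",
                  features$contig_id, features$start + 1L, features$end,
                  features$strand, features$gene_id, features$protein_id)
  writeLines(rows, path)
  invisible(path)
}

# ---- neighborhoods ----------------------------------------------------------

#' Extract the flanking-gene neighborhood of a target locus
#'
#' Upstream/downstream are defined in contig coordinate order (not
#' strand-relative); lists are nearest-first and truncate at contig edges.
#'
#' @param features Feature data frame (one strain).
#' @param target_gene_id Gene id of the target locus.
#' @param window Maximum flank genes per side (default 4).
#' @return List with `target` (one-row data frame), `upstream`,
#'   `downstream` (data frames, nearest first).
#' @export
extract_neighborhood <- function(features, target_gene_id, window = 4L) {
  i <- which(features$gene_id == target_gene_id)
  if (length(i) == 0L) {
    stop("input error: unknown target gene '", target_gene_id, "'",
         call. = FALSE)
  }
  i <- i[1]
  contig <- features$contig_id[i]
  on_contig <- features[features$contig_id == contig, , drop = FALSE]
  on_contig <- on_contig[order(on_contig$start), , drop = FALSE]
  pos <- which(on_contig$gene_id == target_gene_id)
  up_idx <- rev(seq_len(pos - 1L))
  up_idx <- up_idx[seq_len(min(window, length(up_idx)))]
  down_idx <- seq(pos + 1L, length.out = min(window, nrow(on_contig) - pos))
  list(
    target = on_contig[pos, , drop = FALSE],
    upstream = on_contig[up_idx, , drop = FALSE],
    downstream = on_contig[down_idx, , drop = FALSE]
  )
}

# ---- homolog mapping --------------------------------------------------------

#' Map homologous flank genes between two neighborhoods
#'
#' All flank proteins of one neighborhood are aligned against all flank
#' proteins of the other; pairs are kept when they are reciprocal best
#' hits with symmetric normalised score
#' `score / max(self-score a, self-score b)` at or above the threshold.
#' Each flank gene pairs at most once. Features whose protein is missing
#' from the proteome are skipped with a warning.
#'
#' @param nbr_a,nbr_b Neighborhoods from [extract_neighborhood()].
#' @param proteomes Named character vector (protein_id -> sequence)
#'   covering both strains, or a list of such vectors (merged).
#' @param min_norm_score Pair acceptance threshold (default 0.3).
#' @return Data frame of pairs: `gene_a`, `gene_b`, `side_a`, `side_b`,
#'   `normalized_score`, `same_strand`.
#' @export
map_homologs <- function(nbr_a, nbr_b, proteomes, min_norm_score = 0.3) {
  if (is.list(proteomes) && !is.character(proteomes)) {
    proteomes <- unlist(proteomes)
  }
  flank <- function(nbr) {
    f <- rbind(cbind(nbr$upstream, side = "upstream"),
               cbind(nbr$downstream, side = "downstream"))
    keep <- f$protein_id %in% names(proteomes)
    if (any(!keep)) {
      warning("no protein sequence for flank gene(s): ",
              paste(f$gene_id[!keep], collapse = ", "), call. = FALSE)
    }
    f[keep, , drop = FALSE]
  }
  fa <- flank(nbr_a); fb <- flank(nbr_b)
  empty <- data.frame(gene_a = character(0), gene_b = character(0),
                      side_a = character(0), side_b = character(0),
                      normalized_score = numeric(0),
                      same_strand = logical(0), stringsAsFactors = FALSE)
  if (nrow(fa) == 0L || nrow(fb) == 0L) return(empty)
  seq_a <- proteomes[fa$protein_id]; seq_b <- proteomes[fb$protein_id]
  self_a <- vapply(seq_a, function(s) local_align(s, s)$score, numeric(1))
  self_b <- vapply(seq_b, function(s) local_align(s, s)$score, numeric(1))
  raw <- vapply(seq_len(nrow(fb)), function(j) {
    local_align_scores(seq_a, seq_b[[j]])
  }, numeric(nrow(fa)))
  raw <- matrix(raw, nrow = nrow(fa))
  norm <- raw / outer(self_a, self_b, pmax)
  pairs <- empty
  for (i in seq_len(nrow(fa))) {
    j <- which.max(norm[i, ])
    if (norm[i, j] < min_norm_score) next
    if (which.max(norm[, j]) != i) next
    pairs <- rbind(pairs, data.frame(
      gene_a = fa$gene_id[i], gene_b = fb$gene_id[j],
      side_a = fa$side[i], side_b = fb$side[j],
      normalized_score = norm[i, j],
      same_strand = fa$strand[i] == fb$strand[j],
      stringsAsFactors = FALSE))
  }
  pairs
}

#' Pairwise synteny conservation of a target-gene neighborhood
#'
#' For a chosen reference strain, each other strain's neighborhood around
#' the same target family is compared; conserved flank counts are the
#' numbers of reference upstream/downstream genes with a reciprocal-best
#' homolog in the other strain's flank window. Strains lacking the target
#' are skipped with a note. When both PfaA and PfaB are annotated in a
#' strain, their adjacency (consecutive features on one contig) is
#' reported.
#'
#' @param target_gene_id Target gene id (shared across strains, e.g. the
#'   panel family name used by the synthetic generator).
#' @param annotations_by_strain Named list of feature data frames.
#' @param proteomes Named list (per strain) of named sequence vectors, or
#'   one merged named vector.
#' @param reference Reference strain id (default: first strain carrying
#'   the target).
#' @param window,min_norm_score See [extract_neighborhood()] and
#'   [map_homologs()].
#' @return A `synteny_result` list: `reference`, `results` (data frame:
#'   other_strain, conserved_upstream, conserved_downstream), `pairs`
#'   (list of pair tables), `adjacency` (named logical, PfaA-PfaB locus
#'   per strain), `skipped` (strains without the target).
#' @export
synteny_conservation <- function(target_gene_id, annotations_by_strain,
                                 proteomes, reference = NULL, window = 4L,
                                 min_norm_score = 0.3) {
  stopifnot(is.list(annotations_by_strain),
            !is.null(names(annotations_by_strain)))
  if (is.list(proteomes) && !is.character(proteomes)) {
    proteomes <- unlist(unname(proteomes))
  }
  has_target <- vapply(annotations_by_strain, function(f) {
    target_gene_id %in% f$gene_id
  }, logical(1))
  skipped <- names(annotations_by_strain)[!has_target]
  if (length(skipped) > 0L) {
    message("strains lacking target '", target_gene_id, "' skipped: ",
            paste(skipped, collapse = ", "))
  }
  with_target <- names(annotations_by_strain)[has_target]
  if (length(with_target) == 0L) {
    stop("input error: no strain carries target '", target_gene_id, "'",
         call. = FALSE)
  }
  if (is.null(reference)) reference <- with_target[1]
  stopifnot(reference %in% with_target)
  nbr_ref <- extract_neighborhood(annotations_by_strain[[reference]],
                                  target_gene_id, window)
  others <- setdiff(with_target, reference)
  pair_tables <- list()
  results <- data.frame(other_strain = character(0),
                        conserved_upstream = integer(0),
                        conserved_downstream = integer(0),
                        stringsAsFactors = FALSE)
  for (s in others) {
    nbr_s <- extract_neighborhood(annotations_by_strain[[s]],
                                  target_gene_id, window)
    pairs <- map_homologs(nbr_ref, nbr_s, proteomes, min_norm_score)
    pair_tables[[s]] <- pairs
    results <- rbind(results, data.frame(
      other_strain = s,
      conserved_upstream = sum(pairs$side_a == "upstream"),
      conserved_downstream = sum(pairs$side_a == "downstream"),
      stringsAsFactors = FALSE))
  }
  adjacency <- vapply(annotations_by_strain, pfa_locus_adjacent, logical(1))
  structure(list(reference = reference, results = results,
                 pairs = pair_tables, adjacency = adjacency,
                 skipped = skipped),
            class = "synteny_result")
}

#' Are PfaA and PfaB adjacent in a strain's annotation?
#'
#' Adjacency means consecutive gene features on the same contig, any
#' strand combination. `NA` when either gene is not annotated.
#'
#' @param features Feature data frame for one strain.
#' @param gene_a,gene_b Gene ids (defaults PfaA, PfaB).
#' @return Logical (or NA).
#' @export
pfa_locus_adjacent <- function(features, gene_a = "PfaA", gene_b = "PfaB") {
  ia <- which(features$gene_id == gene_a)
  ib <- which(features$gene_id == gene_b)
  if (length(ia) == 0L || length(ib) == 0L) return(NA)
  if (features$contig_id[ia[1]] != features$contig_id[ib[1]]) return(FALSE)
  contig <- features$contig_id[ia[1]]
  on_contig <- features[features$contig_id == contig, , drop = FALSE]
  on_contig <- on_contig[order(on_contig$start), , drop = FALSE]
  abs(which(on_contig$gene_id == gene_a) -
        which(on_contig$gene_id == gene_b)) == 1L
}
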