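#' Local alignment and best-hit family assignment
#'
#' Candidate proteins are assigned to panel families by exact
#' Smith-Waterman local alignment (BLOSUM62, affine gaps, open 11 /
#' extend 1 — the standard protein-search scoring) against a library of
#' per-family archetype sequences, with scores normalised by the
#' archetype's self-score. Motif evidence from the histidine-box scanner
#' corroborates desaturase/elongase calls; on conflict the alignment best
#' hit wins, because within-subfamily motif signatures are archetypal
#' placeholders.
#'
#' @name family_assign
NULL

blosum62_matrix <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      e <- new.env()
      utils::data("BLOSUM62", package = "Biostrings", envir = e)
      cache <<- e$BLOSUM62
    }
    cache
  }
})

#' Optimal local alignment of two protein sequences
#'
#' @param query,subject Protein sequence strings (non-empty).
#' @param substitution_matrix Scoring matrix name or matrix
#'   (default BLOSUM62).
#' @param gap_open,gap_extend Affine gap penalties (positive costs);
#'   a gap of length k costs `gap_open + k * gap_extend`.
#' @return List with `score` (>= 0), `identity_fraction` (identical
#'   positions over alignment columns), `query_range` and `subject_range`
#'   (0-based half-open aligned spans).
#' @export
local_align <- function(query, subject, substitution_matrix = "BLOSUM62",
                        gap_open = 11, gap_extend = 1) {
  if (!nzchar(query) || !nzchar(subject)) {
    stop("input error: empty sequence", call. = FALSE)
  }
  if (is.character(substitution_matrix)) {
    stopifnot(substitution_matrix == "BLOSUM62")
    substitution_matrix <- blosum62_matrix()
  }
  aln <- Biostrings::pairwiseAlignment(
    pattern = Biostrings::AAString(query),
    subject = Biostrings::AAString(subject),
    type = "local", substitutionMatrix = substitution_matrix,
    gapOpening = gap_open, gapExtension = gap_extend
  )
  pr <- Biostrings::pattern(aln)
  sr <- Biostrings::subject(aln)
  list(
    score = Biostrings::score(aln),
    identity_fraction = Biostrings::nmatch(aln) / Biostrings::nchar(aln),
    query_range = c(Biostrings::start(pr) - 1L, Biostrings::end(pr)),
    subject_range = c(Biostrings::start(sr) - 1L, Biostrings::end(sr))
  )
}

# Batch local-alignment scores of many queries vs one subject.
local_align_scores <- function(queries, subject, gap_open = 11,
                               gap_extend = 1) {
  Biostrings::pairwiseAlignment(
    pattern = Biostrings::AAStringSet(queries),
    subject = Biostrings::AAString(subject),
    type = "local", substitutionMatrix = blosum62_matrix(),
    gapOpening = gap_open, gapExtension = gap_extend, scoreOnly = TRUE
  )
}

#' Build/validate a reference archetype library
#'
#' @param entries Data frame with columns `family`, `protein_id`,
#'   `sequence`; one or more archetypes per family. Self-scores are
#'   computed and cached.
#' @param panel Gene panel the library must cover (every
#'   desaturase/elongase/accessory/PUFA-synthase family needs at least one
#'   archetype); `NULL` skips the coverage check.
#' @return A `reference_library` data frame with a `self_score` column.
#' @export
reference_library <- function(entries, panel = NULL) {
  stopifnot(is.data.frame(entries),
            all(c("family", "protein_id", "sequence") %in% names(entries)))
  if (nrow(entries) == 0L) {
    stop("config error: empty reference library", call. = FALSE)
  }
  if (!is.null(panel)) {
    missing <- setdiff(panel$name, entries$family)
    if (length(missing) > 0L) {
      stop("config error: library lacks archetype(s) for: ",
           paste(missing, collapse = ", "), call. = FALSE)
    }
  }
  entries$self_score <- vapply(entries$sequence, function(s) {
    local_align(s, s)$score
  }, numeric(1), USE.NAMES = FALSE)
  class(entries) <- c("reference_library", "data.frame")
  entries
}

#' Assign one query to the family of its best archetype hit
#'
#' The winning archetype maximises `score / archetype self-score`
#' (normalised score in \[0, 1\]); ties break by higher identity fraction,
#' then alphabetical family. Below `min_norm_score` the query is
#' unclassified.
#'
#' @param query Protein sequence string.
#' @param library A `reference_library`.
#' @param min_norm_score Acceptance threshold (default 0.3).
#' @return List with `family`, `normalized_score`, `identity_fraction`,
#'   `archetype_id`.
#' @export
best_hit_assign <- function(query, library, min_norm_score = 0.3) {
  if (!inherits(library, "reference_library") || nrow(library) == 0L) {
    stop("config error: invalid or empty reference library", call. = FALSE)
  }
  scores <- vapply(seq_len(nrow(library)), function(i) {
    local_align(query, library$sequence[i])$score
  }, numeric(1))
  norm <- scores / library$self_score
  top <- which(norm == max(norm))
  if (length(top) > 1L) {
    ident <- vapply(top, function(i) {
      local_align(query, library$sequence[i])$identity_fraction
    }, numeric(1))
    top <- top[order(-ident, library$family[top])]
  }
  best <- top[1]
  if (norm[best] < min_norm_score) {
    return(list(family = "unclassified", normalized_score = norm[best],
                identity_fraction = NA_real_, archetype_id = NA_character_))
  }
  list(family = library$family[best],
       normalized_score = unname(norm[best]),
       identity_fraction = local_align(
         query, library$sequence[best])$identity_fraction,
       archetype_id = library$protein_id[best])
}

#' Assign every protein of a proteome to a panel family
#'
#' Alignment best hits are computed in batch (all queries against each
#' archetype). For desaturase/elongase hits the motif scanner supplies
#' corroborating evidence; agreement records both evidence kinds, conflict
#' keeps the best hit and logs a warning. PUFA-synthase subunits and
#' accessory genes use best-hit evidence only.
#'
#' @param proteins Named character vector of sequences, or data frame with
#'   `protein_id`, `sequence`.
#' @param panel Gene panel.
#' @param library A `reference_library` covering the panel.
#' @param registry Signature registry for motif evidence.
#' @param min_norm_score Best-hit acceptance threshold.
#' @param quiet Suppress conflict warnings.
#' @return Data frame: `protein_id`, `family`, `evidence`
#'   (comma-separated), `normalized_score`, `motif_family`.
#' @export
assign_proteome <- function(proteins, panel = default_panel(),
                            library, registry = default_signature_registry(),
                            min_norm_score = 0.3, quiet = FALSE) {
  if (is.data.frame(proteins)) {
    seqs <- setNames(proteins$sequence, proteins$protein_id)
  } else {
    seqs <- proteins
  }
  if (length(seqs) == 0L) {
    return(data.frame(protein_id = character(0), family = character(0),
                      evidence = character(0), normalized_score = numeric(0),
                      motif_family = character(0), stringsAsFactors = FALSE))
  }
  stopifnot(!is.null(names(seqs)))
  # queries x archetypes normalised score matrix
  norm <- vapply(seq_len(nrow(library)), function(i) {
    local_align_scores(seqs, library$sequence[i]) / library$self_score[i]
  }, numeric(length(seqs)))
  norm <- matrix(norm, nrow = length(seqs),
                 dimnames = list(names(seqs), library$protein_id))

  out <- lapply(seq_along(seqs), function(q) {
    nq <- norm[q, ]
    best <- order(-nq, library$family)[1]
    hit_family <- if (nq[best] >= min_norm_score) library$family[best]
                  else "unclassified"
    cat_best <- if (hit_family == "unclassified") NA_character_
                else panel$category[match(hit_family, panel$name)]
    motif_family <- NA_character_
    evidence <- character(0)
    if (!is.na(cat_best) && cat_best == "desaturase") {
      cls <- classify_desaturase(seqs[[q]], registry)
      motif_family <- cls$family
      if (identical(cls$family, hit_family)) {
        evidence <- c("motif", "best_hit")
      } else {
        evidence <- "best_hit"
        if (!quiet && cls$family != "unclassified") {
          warning("motif/best-hit conflict for ", names(seqs)[q], ": motif ",
                  cls$family, " vs best hit ", hit_family,
                  "; keeping best hit", call. = FALSE)
        }
      }
    } else if (!is.na(cat_best) && cat_best == "elongase") {
      cls <- classify_elongase(seqs[[q]], registry)
      motif_family <- cls$group
      if (identical(cls$group, "ELO_C20")) {
        if (identical(hit_family, "ELO_C20")) {
          evidence <- c("motif", "best_hit")
        } else {
          evidence <- "best_hit"
          if (!quiet) {
            warning("motif/best-hit conflict for ", names(seqs)[q],
                    ": C20-type box vs best hit ", hit_family,
                    "; keeping best hit", call. = FALSE)
          }
        }
      } else if (identical(cls$group, "ELO_unresolved")) {
        # generic elongase box corroborates any elongase family
        evidence <- c("motif", "best_hit")
      } else {
        evidence <- "best_hit"
      }
    } else if (hit_family != "unclassified") {
      evidence <- "best_hit"
    }
    data.frame(protein_id = names(seqs)[q], family = hit_family,
               evidence = paste(evidence, collapse = ","),
               normalized_score = unname(nq[best]),
               motif_family = motif_family, stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Collapse per-strain assignments into a presence/absence matrix
#'
#' A cell is `present` iff at least one protein of the strain was assigned
#' to that family; otherwise `absent`.
#'
#' @param assignments Data frame with `strain_id` and `family` columns
#'   (unclassified rows are ignored).
#' @param panel Gene panel (matrix columns).
#' @param strains Strain table (matrix rows; all strains appear even with
#'   no assignments).
#' @return A `pa_matrix`.
#' @export
presence_matrix <- function(assignments, panel = default_panel(), strains) {
  stopifnot(is.data.frame(strains), "strain_id" %in% names(strains))
  cells <- matrix("absent", nrow = nrow(strains), ncol = nrow(panel),
                  dimnames = list(strains$strain_id, panel$name))
  if (nrow(assignments) > 0L) {
    hits <- assignments[assignments$family %in% panel$name, , drop = FALSE]
    bad <- setdiff(unique(hits$strain_id), strains$strain_id)
    if (length(bad) > 0L) {
      stop("input error: assignment references unknown strain(s): ",
           paste(bad, collapse = ", "), call. = FALSE)
    }
    if (nrow(hits) > 0L) {
      cells[cbind(hits$strain_id, hits$family)] <- "present"
    }
  }
  pa_matrix(strains, panel, cells)
}
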