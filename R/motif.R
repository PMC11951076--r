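#' Histidine-box motif scanning and subfamily classification
#'
#' Desaturases carry three short His-rich "histidine boxes" in their
#' catalytic region whose shapes differ between the First, Front-End and
#' Omega subfamilies; elongases carry a single box, canonically `HXXHH`,
#' with the C20 group showing the atypical `QXXHH` variant. Patterns are
#' written over residue letters, the wildcard `X` (any residue) and
#' bracketed alternatives such as `H[ED]CGH`.
#'
#' @name motif_scan
NULL

# ---- box patterns -----------------------------------------------------------

#' Parse a degenerate box pattern
#'
#' @param pattern Pattern string, e.g. `"H[ED]CGH"`. Positions are a single
#'   residue, `X` (any residue), or a bracketed residue set. Valid patterns
#'   span 5-6 positions and contain at least two literal H/Q positions.
#' @return An object of class `box_pattern`: a list of per-position allowed
#'   residue sets, with attributes `pattern`, `npos` and `literal_score`
#'   (number of non-wildcard positions, the score contribution of a match).
#' @export
parse_box_pattern <- function(pattern) {
  if (!is.character(pattern) || length(pattern) != 1L || is.na(pattern)) {
    stop("pattern error: pattern must be a single string", call. = FALSE)
  }
  chars <- strsplit(pattern, "")[[1]]
  slots <- list()
  i <- 1L
  while (i <= length(chars)) {
    ch <- chars[i]
    if (ch == "[") {
      j <- which(chars == "]" & seq_along(chars) > i)[1]
      if (is.na(j) || j == i + 1L) {
        stop("pattern error: malformed bracket in '", pattern, "'",
             call. = FALSE)
      }
      set <- chars[(i + 1L):(j - 1L)]
      if (!all(set %in% aa_alphabet())) {
        stop("pattern error: non-residue in bracket of '", pattern, "'",
             call. = FALSE)
      }
      slots[[length(slots) + 1L]] <- set
      i <- j + 1L
    } else if (ch == "X") {
      slots[[length(slots) + 1L]] <- aa_alphabet()
      i <- i + 1L
    } else if (ch %in% aa_alphabet()) {
      slots[[length(slots) + 1L]] <- ch
      i <- i + 1L
    } else {
      stop("pattern error: illegal character '", ch, "' in '", pattern, "'",
           call. = FALSE)
    }
  }
  npos <- length(slots)
  if (npos < 5L || npos > 6L) {
    stop("pattern error: '", pattern, "' spans ", npos,
         " positions; box patterns span 5-6", call. = FALSE)
  }
  n_hq <- sum(vapply(slots, function(s) identical(s, "H") || identical(s, "Q"),
                     logical(1)))
  if (n_hq < 2L) {
    stop("pattern error: '", pattern,
         "' needs at least two literal H/Q positions", call. = FALSE)
  }
  literal <- sum(vapply(slots, function(s) length(s) < 20L, logical(1)))
  structure(slots, pattern = pattern, npos = npos, literal_score = literal,
            class = "box_pattern")
}

box_pattern_regex <- function(parsed) {
  paste0(vapply(parsed, function(s) {
    if (length(s) == 1L) s else paste0("[", paste(s, collapse = ""), "]")
  }, character(1)), collapse = "")
}

#' Find all occurrences of a box pattern in a protein sequence
#'
#' Occurrences are reported left to right; overlapping matches are allowed.
#' Starts are 0-based residue indices.
#'
#' @param sequence Protein sequence string (20 residues + `X`; an `X` in the
#'   sequence matches no pattern position).
#' @param pattern Pattern string or a parsed `box_pattern`.
#' @return Data frame with columns `start` (0-based), `end` (half-open),
#'   `matched_text`, `pattern`.
#' @export
scan_boxes <- function(sequence, pattern) {
  check_protein_sequence(sequence)
  parsed <- if (inherits(pattern, "box_pattern")) pattern
            else parse_box_pattern(pattern)
  npos <- attr(parsed, "npos")
  rx <- sprintf("(?=(%s))", box_pattern_regex(parsed))
  m <- gregexpr(rx, sequence, perl = TRUE)[[1]]
  if (m[1] == -1L) {
    return(data.frame(start = integer(0), end = integer(0),
                      matched_text = character(0), pattern = character(0),
                      stringsAsFactors = FALSE))
  }
  start0 <- as.integer(m) - 1L
  data.frame(
    start = start0,
    end = start0 + npos,
    matched_text = substring(sequence, start0 + 1L, start0 + npos),
    pattern = attr(parsed, "pattern"),
    stringsAsFactors = FALSE
  )
}

# ---- signature registry -----------------------------------------------------

#' Read a motif signature registry
#'
#' The registry is a tab-separated table with columns `signature_id`,
#' `family`, `boxes` (ordered box slots separated by `;`, alternative
#' patterns for one slot separated by `|`), `gap_min`, `gap_max` (allowed
#' residue separation between consecutive boxes), `nterm` (one of `cytb5`,
#' `DUF3474`, `DUF1129`, `none`) and `nterm_window` (N-terminal search
#' window in residues). Desaturase signatures have three box slots,
#' elongase signatures one.
#'
#' @param path Path to the registry table; defaults to the packaged
#'   registry encoding the subfamily box shapes with family-specific
#'   archetypal instantiations.
#' @return A `signature_registry`: data frame with a parsed `slots`
#'   list-column.
#' @export
read_signature_registry <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "signatures_default.tsv",
                        package = "pufatyper")
  }
  reg <- read.delim(path, stringsAsFactors = FALSE)
  needed <- c("signature_id", "family", "boxes", "gap_min", "gap_max",
              "nterm", "nterm_window")
  if (!all(needed %in% names(reg))) {
    stop("registry config error: columns must be ",
         paste(needed, collapse = ", "), call. = FALSE)
  }
  if (anyDuplicated(reg$signature_id)) {
    stop("registry config error: duplicate signature id", call. = FALSE)
  }
  if (any(reg$gap_min > reg$gap_max)) {
    stop("registry config error: gap_min > gap_max", call. = FALSE)
  }
  bad_nterm <- setdiff(unique(reg$nterm), nterm_domain_tags())
  if (length(bad_nterm) > 0L) {
    stop("registry config error: unknown nterm tag: ",
         paste(bad_nterm, collapse = ", "), call. = FALSE)
  }
  reg$slots <- lapply(reg$boxes, function(spec) {
    slots <- strsplit(spec, ";", fixed = TRUE)[[1]]
    lapply(slots, function(slot) {
      lapply(strsplit(slot, "|", fixed = TRUE)[[1]], parse_box_pattern)
    })
  })
  n_slots <- vapply(reg$slots, length, integer(1))
  is_des <- grepl("^DES_", reg$family)
  is_elo <- grepl("^ELO_", reg$family)
  if (any(is_des & n_slots != 3L)) {
    stop("registry config error: desaturase signatures need 3 box slots",
         call. = FALSE)
  }
  if (any(is_elo & n_slots != 1L)) {
    stop("registry config error: elongase signatures need 1 box slot",
         call. = FALSE)
  }
  class(reg) <- c("signature_registry", "data.frame")
  reg
}

#' @rdname read_signature_registry
#' @export
default_signature_registry <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- read_signature_registry()
    cache
  }
})

registry_signature <- function(registry, id_or_family) {
  i <- match(id_or_family, registry$signature_id)
  if (is.na(i)) i <- match(id_or_family, registry$family)
  if (is.na(i)) {
    stop("config error: unknown signature or family '", id_or_family, "'",
         call. = FALSE)
  }
  as.list(registry[i, , drop = FALSE])
}

# Total literal positions of a signature, counting for each slot its
# highest-scoring alternative (used for classification tie-breaks).
signature_literal_total <- function(sig) {
  sum(vapply(sig$slots[[1]], function(alts) {
    max(vapply(alts, function(p) attr(p, "literal_score"), numeric(1)))
  }, numeric(1)))
}

# ---- N-terminal domain heuristics ------------------------------------------

nterm_domain_tags <- function() c("cytb5", "DUF3474", "DUF1129", "none")

#' Default N-terminal domain core patterns
#'
#' The cytochrome b5 domain is detected through its heme-pocket core
#' tetrapeptide `HPGG` (standard cytb5 knowledge, not a value measured
#' here). No default pattern ships for DUF3474/DUF1129; unconfigured tags
#' are skipped (treated as satisfied), since bundling real profile HMMs is
#' out of scope. Users may supply their own core patterns.
#'
#' @return Named character vector (NA = unconfigured).
#' @export
default_nterm_patterns <- function() {
  c(cytb5 = "HPGG", DUF3474 = NA_character_, DUF1129 = NA_character_)
}

#' Test for an N-terminal domain core motif
#'
#' @param sequence Protein sequence string.
#' @param domain_tag One of `"cytb5"`, `"DUF3474"`, `"DUF1129"`, `"none"`.
#' @param window N-terminal search window (residues); the match must start
#'   within the window.
#' @param patterns Named vector of core patterns per tag; NA entries are
#'   treated as unconfigured and return `TRUE`.
#' @return Logical.
#' @export
detect_nterm_domain <- function(sequence, domain_tag, window = 150,
                                patterns = default_nterm_patterns()) {
  if (!domain_tag %in% nterm_domain_tags()) {
    stop("config error: unknown N-terminal domain tag '", domain_tag, "'",
         call. = FALSE)
  }
  if (domain_tag == "none") return(TRUE)
  pat <- patterns[[domain_tag]]
  if (is.null(pat) || is.na(pat)) return(TRUE)
  check_protein_sequence(sequence)
  m <- regexpr(pat, sequence, fixed = TRUE)
  m[1] != -1L && (as.integer(m) - 1L) < window
}

# ---- signature matching -----------------------------------------------------

# Candidate matches for one box slot: all occurrences of all alternative
# patterns, each carrying the alternative's literal score.
slot_matches <- function(sequence, alternatives, max_per_box = 50L) {
  hits <- do.call(rbind, lapply(alternatives, function(p) {
    h <- scan_boxes(sequence, p)
    if (nrow(h) > 0L) h$score <- attr(p, "literal_score")
    h
  }))
  if (is.null(hits) || nrow(hits) == 0L) return(NULL)
  hits <- hits[order(hits$start, -hits$score), , drop = FALSE]
  if (nrow(hits) > max_per_box) {
    stop("candidate explosion: more than ", max_per_box,
         " matches for one box slot", call. = FALSE)
  }
  hits
}

#' Locate the best full-signature match in a protein
#'
#' Every combination of one match per box slot with strictly ascending
#' start positions is a candidate; the winner maximises the summed literal
#' score, then minimises the total span, then takes the left-most start
#' positions. `spacing_ok` is `TRUE` iff every inter-box gap (end of one
#' box to start of the next) lies within the signature's bounds;
#' `nterm_ok` applies the N-terminal domain heuristic. `NULL` is returned
#' when any slot has no match (absence is a valid result).
#'
#' @param sequence Protein sequence string.
#' @param signature One row of a signature registry (see
#'   [registry_signature()]), or a family/signature id plus `registry`.
#' @param registry Signature registry used when `signature` is an id.
#' @param max_per_box Cap on matches per box slot (error if exceeded).
#' @return A `signature_match` list: `signature_id`, `family`,
#'   `box_matches` (data frame), `spacing_ok`, `nterm_ok`, `score`, `span`;
#'   or `NULL`.
#' @export
match_signature <- function(sequence, signature,
                            registry = default_signature_registry(),
                            max_per_box = 50L) {
  if (is.character(signature)) {
    signature <- registry_signature(registry, signature)
  }
  slots <- signature$slots[[1]]
  per_slot <- lapply(slots, function(alts) {
    slot_matches(sequence, alts, max_per_box = max_per_box)
  })
  if (any(vapply(per_slot, is.null, logical(1)))) return(NULL)

  k <- length(per_slot)
  combo <- best_ascending_combo(per_slot, signature$gap_min,
                                signature$gap_max)
  if (is.null(combo)) return(NULL)
  boxes <- do.call(rbind, lapply(seq_len(k), function(i) {
    per_slot[[i]][combo[i], , drop = FALSE]
  }))
  boxes$slot <- seq_len(k)
  rownames(boxes) <- NULL
  gaps <- if (k > 1L) boxes$start[-1] - boxes$end[-k] else numeric(0)
  spacing_ok <- all(gaps >= signature$gap_min & gaps <= signature$gap_max)
  nterm_ok <- detect_nterm_domain(sequence, signature$nterm,
                                  window = signature$nterm_window)
  list(
    signature_id = signature$signature_id,
    family = signature$family,
    box_matches = boxes,
    gaps = gaps,
    spacing_ok = spacing_ok,
    nterm_ok = nterm_ok,
    score = sum(boxes$score),
    span = boxes$end[k] - boxes$start[1]
  )
}

# Pick, among all strictly-ascending one-match-per-slot combinations, the
# one maximising total score, then (at equal score) preferring
# spacing-legal combinations, then minimising span, then left-most
# starts. Full enumeration; slot match counts are capped upstream.
best_ascending_combo <- function(per_slot, gap_min, gap_max) {
  k <- length(per_slot)
  if (k == 1L) {
    h <- per_slot[[1]]
    return(order(-h$score, h$end - h$start, h$start)[1])
  }
  idx <- expand.grid(lapply(per_slot, function(h) seq_len(nrow(h))),
                     KEEP.OUT.ATTRS = FALSE)
  starts <- vapply(seq_len(k), function(i) per_slot[[i]]$start[idx[[i]]],
                   numeric(nrow(idx)))
  ends <- vapply(seq_len(k), function(i) per_slot[[i]]$end[idx[[i]]],
                 numeric(nrow(idx)))
  starts <- matrix(starts, ncol = k)
  ends <- matrix(ends, ncol = k)
  asc <- rep(TRUE, nrow(idx))
  for (i in seq_len(k - 1L)) asc <- asc & (starts[, i] < starts[, i + 1L])
  if (!any(asc)) return(NULL)
  idx <- idx[asc, , drop = FALSE]
  starts <- starts[asc, , drop = FALSE]
  ends <- ends[asc, , drop = FALSE]
  score <- rowSums(matrix(vapply(seq_len(k), function(i) {
    per_slot[[i]]$score[idx[[i]]]
  }, numeric(nrow(idx))), ncol = k))
  legal <- rep(TRUE, nrow(idx))
  for (i in seq_len(k - 1L)) {
    gap <- starts[, i + 1L] - ends[, i]
    legal <- legal & gap >= gap_min & gap <= gap_max
  }
  span <- ends[, k] - starts[, 1L]
  ord <- do.call(order, c(list(-score, !legal, span),
                          lapply(seq_len(k), function(i) starts[, i])))
  as.integer(idx[ord[1], ])
}

# ---- classification ---------------------------------------------------------

#' Classify a protein into a desaturase family by motif signature
#'
#' Every desaturase signature in the registry is evaluated; the family of
#' the highest-scoring match with acceptable box spacing wins. Ties break
#' by the signature with more literal positions, then alphabetically.
#'
#' @param sequence Protein sequence string.
#' @param registry Signature registry.
#' @return List with `family` (`"unclassified"` when nothing matches with
#'   legal spacing) and `match` (the winning `signature_match` or `NULL`).
#' @export
classify_desaturase <- function(sequence,
                                registry = default_signature_registry()) {
  des <- registry[grepl("^DES_", registry$family), , drop = FALSE]
  if (nrow(des) == 0L) stop("config error: registry has no desaturase ",
                            "signatures", call. = FALSE)
  cands <- list()
  for (i in seq_len(nrow(des))) {
    sig <- as.list(des[i, , drop = FALSE])
    m <- match_signature(sequence, sig, registry = registry)
    if (!is.null(m) && m$spacing_ok) {
      m$sig_literals <- signature_literal_total(sig)
      cands[[length(cands) + 1L]] <- m
    }
  }
  if (length(cands) == 0L) {
    return(list(family = "unclassified", match = NULL))
  }
  score <- vapply(cands, `[[`, numeric(1), "score")
  lits <- vapply(cands, `[[`, numeric(1), "sig_literals")
  fam <- vapply(cands, `[[`, character(1), "family")
  best <- order(-score, -lits, fam)[1]
  list(family = fam[best], match = cands[[best]])
}

#' Classify a protein as an elongase candidate by its single histidine box
#'
#' A `QXXHH` hit marks a C20-elongase candidate (the atypical
#' glutamine-substituted box); an `HXXHH` hit marks a generic elongase
#' candidate whose group is resolvable only with homology evidence; no
#' hit means unclassified.
#'
#' @param sequence Protein sequence string.
#' @param registry Signature registry (supplies the box shapes).
#' @return List with `group` (`"ELO_C20"`, `"ELO_unresolved"` or
#'   `"unclassified"`) and `match` (a `signature_match` or `NULL`).
#' @export
classify_elongase <- function(sequence,
                              registry = default_signature_registry()) {
  c20 <- match_signature(sequence, "ELO_C20", registry = registry)
  if (!is.null(c20)) {
    return(list(group = "ELO_C20", match = c20))
  }
  generic <- match_signature(sequence, "ELO_C16", registry = registry)
  if (!is.null(generic)) {
    generic$family <- NA_character_  # group not resolvable from the box
    return(list(group = "ELO_unresolved", match = generic))
  }
  list(group = "unclassified", match = NULL)
}
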