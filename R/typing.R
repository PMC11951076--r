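#' Four-lineage pathway typing
#'
#' Strains fall into four PUFA-biosynthetic lineages by which of the two
#' routes their gene repertoire completes: Type I carries only the full
#' elongase/desaturase (ELO/DES) route, Type II both routes, Type III the
#' PUFA synthase plus an ELO/DES route broken only at the canonical D9
#' desaturase, and Type IV the PUFA synthase with most elongases and
#' desaturases gone (no C18/C20 elongases). The cytosolic acetyl-CoA
#' supply is inferred from ACLY (citrate route) or cCrAT (carnitine
#' shuttle).
#'
#' @name pathway_typing
NULL

#' Derive pathway flags from one matrix row
#'
#' `elodes_complete` requires the canonical D9, D4, D5 and omega-3
#' desaturases, either the D6- or the D8-route desaturase (the two routes
#' are alternatives), and the C16, C18, C20 and D9 elongases.
#' `pufas_complete` requires all three PUFA-synthase subunits. Unknown
#' cells count as absent but are listed in `uncertain` so reports can flag
#' calls that extra evidence could flip.
#'
#' @param row Named character vector of cells (present/absent/unknown)
#'   covering all panel genes, or a `pa_matrix` plus `strain_id`.
#' @param panel Gene panel.
#' @param strain_id When `row` is a `pa_matrix`, the row to use.
#' @param strict Also require the omega-6/D9B desaturase for ELO/DES
#'   completeness (sensitivity option; default off, matching the
#'   main-route reading of the pathway).
#' @return List of logical flags plus `uncertain` (character vector of
#'   unknown driver genes).
#' @export
pathway_flags <- function(row, panel = default_panel(), strain_id = NULL,
                          strict = FALSE) {
  if (inherits(row, "pa_matrix")) {
    stopifnot(!is.null(strain_id))
    row <- row$cells[strain_id, ]
  }
  missing <- setdiff(panel$name, names(row))
  if (length(missing) > 0L) {
    stop("input error: row lacks gene column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  has <- function(g) row[[g]] == "present"
  elodes_required <- c("DES_D9A", "DES_D4", "DES_D5", "DES_w3",
                       "ELO_C16", "ELO_C18", "ELO_C20", "ELO_D9")
  if (strict) elodes_required <- c(elodes_required, "DES_w6D9B")
  drivers <- c("PfaA", "PfaB", "PfaC", elodes_required, "DES_D6", "DES_D8",
               "ACLY", "cCrAT", "CrtZ", "CrtO")
  flags <- list(
    pufas_complete = has("PfaA") && has("PfaB") && has("PfaC"),
    elodes_complete = all(vapply(elodes_required, has, logical(1))) &&
      (has("DES_D6") || has("DES_D8")),
    has_d9a = has("DES_D9A"),
    has_long_elos = has("ELO_C18") && has("ELO_C20"),
    has_acly = has("ACLY"),
    has_ccrat = has("cCrAT"),
    has_crtz = has("CrtZ"),
    has_crto = has("CrtO")
  )
  flags$uncertain <- intersect(drivers, names(row)[row == "unknown"])
  flags
}

#' Call the lineage from pathway flags
#'
#' Predicates, evaluated I through IV with first match winning:
#' I = complete ELO/DES without the PUFA synthase; II = both complete;
#' III = PUFA synthase, no canonical D9 desaturase, C18+C20 elongases
#' retained; IV = PUFA synthase, no canonical D9 desaturase, C18/C20
#' elongases lost. Anything else is unclassified. The rationale records
#' every clause evaluated.
#'
#' @param flags Flags from [pathway_flags()].
#' @return List with `lineage` (`"I"`, `"II"`, `"III"`, `"IV"` or
#'   `"unclassified"`) and `rationale` (character vector of fired/failed
#'   clauses; unknown driver genes are appended as uncertainty markers).
#' @export
call_type <- function(flags) {
  clauses <- list(
    I = flags$elodes_complete && !flags$pufas_complete,
    II = flags$elodes_complete && flags$pufas_complete,
    III = flags$pufas_complete && !flags$has_d9a && flags$has_long_elos,
    IV = flags$pufas_complete && !flags$has_d9a && !flags$has_long_elos
  )
  rationale <- character(0)
  lineage <- "unclassified"
  for (nm in names(clauses)) {
    rationale <- c(rationale,
                   sprintf("Type %s predicate: %s", nm,
                           if (clauses[[nm]]) "satisfied" else "failed"))
    if (clauses[[nm]]) {
      lineage <- nm
      break
    }
  }
  if (length(flags$uncertain) > 0L) {
    rationale <- c(rationale,
                   paste("uncertain: unknown cells treated as absent:",
                         paste(flags$uncertain, collapse = ", ")))
  }
  list(lineage = lineage, rationale = rationale)
}

#' Infer the cytosolic acetyl-CoA route
#'
#' ACLY present: citrate route (TCA-derived citrate cleaved in the
#' cytosol). Otherwise cCrAT present: acetyl-carnitine shuttle. Neither:
#' undetermined.
#'
#' @param flags Flags from [pathway_flags()].
#' @return `"citrate_ACLY"`, `"carnitine_cCrAT"` or `"undetermined"`.
#' @export
acetylcoa_route <- function(flags) {
  if (flags$has_acly) return("citrate_ACLY")
  if (flags$has_ccrat) return("carnitine_cCrAT")
  "undetermined"
}

#' Type every strain of a presence/absence matrix
#'
#' Thraustochytrid strains receive full lineage calls; relatives are typed
#' with the same rule but flagged as heuristic, since the lineage system
#' is defined within the thraustochytrids.
#'
#' @param matrix A `pa_matrix` whose strain table may carry `clade_group`
#'   and `evidence_source`.
#' @param panel Gene panel.
#' @param strict See [pathway_flags()].
#' @return A `typing_report`: list with `calls` (data frame: strain_id,
#'   clade_group, lineage, route, flags, caveat, rationale) and `counts`
#'   (pufas_complete, elodes_complete, per-lineage counts and distinct
#'   lineages among thraustochytrid rows).
#' @export
summarize_typing <- function(matrix, panel = default_panel(),
                             strict = FALSE) {
  stopifnot(inherits(matrix, "pa_matrix"))
  strains <- matrix$strains
  clade <- if ("clade_group" %in% names(strains)) strains$clade_group
           else rep("thraustochytrid", nrow(strains))
  calls <- lapply(seq_len(nrow(strains)), function(i) {
    fl <- pathway_flags(matrix$cells[strains$strain_id[i], ], panel,
                        strict = strict)
    ct <- call_type(fl)
    data.frame(
      strain_id = strains$strain_id[i],
      clade_group = clade[i],
      lineage = ct$lineage,
      acetylcoa_route = acetylcoa_route(fl),
      pufas_complete = fl$pufas_complete,
      elodes_complete = fl$elodes_complete,
      has_d9a = fl$has_d9a,
      has_long_elos = fl$has_long_elos,
      has_acly = fl$has_acly,
      has_ccrat = fl$has_ccrat,
      has_crtz = fl$has_crtz,
      has_crto = fl$has_crto,
      n_uncertain = length(fl$uncertain),
      caveat = if (clade[i] == "relative")
        "non-thraustochytrid; typing heuristic only" else "",
      rationale = paste(ct$rationale, collapse = "; "),
      stringsAsFactors = FALSE
    )
  })
  calls <- do.call(rbind, calls)
  thr <- calls[calls$clade_group == "thraustochytrid", , drop = FALSE]
  lineages <- c("I", "II", "III", "IV")
  counts <- list(
    n_thraustochytrid = nrow(thr),
    pufas_complete = sum(thr$pufas_complete),
    elodes_complete = sum(thr$elodes_complete),
    per_lineage = vapply(lineages, function(l) sum(thr$lineage == l),
                         integer(1)),
    unclassified = sum(thr$lineage == "unclassified"),
    distinct_lineages = length(unique(thr$lineage[thr$lineage %in%
                                                    lineages]))
  )
  structure(list(calls = calls, counts = counts), class = "typing_report")
}

#' @export
print.typing_report <- function(x, ...) {
  cat(sprintf(
    "typing_report: %d thraustochytrid strains | %d with complete PUFA-S, %d with complete ELO/DES\n",
    x$counts$n_thraustochytrid, x$counts$pufas_complete,
    x$counts$elodes_complete))
  tab <- x$counts$per_lineage
  cat("lineage counts:",
      paste(sprintf("%s=%d", names(tab), tab), collapse = ", "), "\n")
  invisible(x)
}
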