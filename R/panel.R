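#' The diagnostic gene panel
#'
#' The panel registers the genes whose presence/absence drives lineage
#' typing: the three PUFA synthase subunits (PfaA, PfaB, PfaC), ten
#' desaturase families, seven elongase groups (six major groups plus the
#' minor C16-like group), and four accessory genes (ACLY, cCrAT, CrtZ,
#' CrtO). Desaturase and elongase entries carry a link to a histidine-box
#' motif signature in the signature registry.
#'
#' @name gene_panel
NULL

panel_categories <- function() {
  c("pufa_synthase", "desaturase", "elongase", "accessory")
}

# Genes the four-lineage decision rule depends on; a valid panel must
# contain all of them.
panel_required_genes <- function() {
  c("PfaA", "PfaB", "PfaC",
    "DES_D4", "DES_D5", "DES_D6", "DES_D8", "DES_D9A", "DES_w3",
    "ELO_C16", "ELO_C18", "ELO_C20", "ELO_D9")
}

#' Load a gene panel from a config table
#'
#' The config is a tab-separated table with columns `name`, `category` and
#' `signature_id` (`.` for none). Validation enforces unique gene names,
#' known categories, a resolvable signature for every desaturase/elongase
#' entry, and the presence of all genes the lineage decision rule needs.
#'
#' @param path Path to the panel config. Defaults to the packaged panel.
#' @param registry A signature registry used to resolve signature links
#'   (default [default_signature_registry()]).
#' @return A `gene_panel` data frame with columns `name`, `category`,
#'   `signature_id`.
#' @export
load_panel <- function(path = NULL, registry = default_signature_registry()) {
  if (is.null(path)) {
    path <- system.file("extdata", "panel_default.tsv", package = "pufatyper")
  }
  cfg <- read.delim(path, stringsAsFactors = FALSE)
  required_cols <- c("name", "category", "signature_id")
  if (!all(required_cols %in% names(cfg))) {
    stop("panel config error: columns must be ",
         paste(required_cols, collapse = ", "), call. = FALSE)
  }
  cfg$signature_id[cfg$signature_id %in% c(".", "", NA)] <- NA_character_
  if (anyDuplicated(cfg$name)) {
    stop("panel config error: duplicate gene name(s): ",
         paste(unique(cfg$name[duplicated(cfg$name)]), collapse = ", "),
         call. = FALSE)
  }
  bad_cat <- setdiff(unique(cfg$category), panel_categories())
  if (length(bad_cat) > 0L) {
    stop("panel config error: unknown category: ",
         paste(bad_cat, collapse = ", "), call. = FALSE)
  }
  needs_sig <- cfg$category %in% c("desaturase", "elongase")
  if (any(needs_sig & is.na(cfg$signature_id))) {
    stop("panel config error: desaturase/elongase entries without signature: ",
         paste(cfg$name[needs_sig & is.na(cfg$signature_id)], collapse = ", "),
         call. = FALSE)
  }
  unresolved <- setdiff(cfg$signature_id[needs_sig], registry$signature_id)
  if (length(unresolved) > 0L) {
    stop("panel config error: unresolvable signature id(s): ",
         paste(unresolved, collapse = ", "), call. = FALSE)
  }
  missing <- setdiff(panel_required_genes(), cfg$name)
  if (length(missing) > 0L) {
    stop("panel config error: panel is missing gene(s) required for ",
         "lineage typing: ", paste(missing, collapse = ", "), call. = FALSE)
  }
  out <- cfg[, required_cols]
  class(out) <- c("gene_panel", "data.frame")
  out
}

#' @rdname load_panel
#' @export
default_panel <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- load_panel()
    cache
  }
})

#' Panel genes of one category
#'
#' @param panel A `gene_panel`.
#' @param category One of `"pufa_synthase"`, `"desaturase"`, `"elongase"`,
#'   `"accessory"`.
#' @return Character vector of gene names.
#' @export
panel_genes <- function(panel, category = NULL) {
  if (is.null(category)) return(panel$name)
  stopifnot(category %in% panel_categories())
  panel$name[panel$category == category]
}
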