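#' Presence/absence matrices
#'
#' A `pa_matrix` couples an ordered strain table, an ordered gene panel and
#' a strain x gene cell matrix over `present` / `absent` / `unknown`.
#' On disk the matrix is a TSV with a header row of gene names, a first
#' `strain_id` column, and cells `1` / `0` / `?`; the round trip is
#' lossless.
#'
#' @param strains Data frame with at least `strain_id` (unique); optional
#'   `genus`, `clade_group`, `evidence_source`, `lineage_reported`,
#'   `ploidy_note` columns are carried along.
#' @param genes A `gene_panel` or data frame with unique `name`.
#' @param cells Character matrix (strains x genes) over
#'   present/absent/unknown; dimnames must match `strain_id` and gene
#'   names.
#' @return An object of class `pa_matrix`.
#' @export
pa_matrix <- function(strains, genes, cells) {
  stopifnot(is.data.frame(strains), "strain_id" %in% names(strains),
            is.data.frame(genes), "name" %in% names(genes))
  if (anyDuplicated(strains$strain_id)) {
    stop("duplicate strain_id", call. = FALSE)
  }
  if (anyDuplicated(genes$name)) stop("duplicate gene name", call. = FALSE)
  if (!is.matrix(cells) || nrow(cells) != nrow(strains) ||
      ncol(cells) != nrow(genes)) {
    stop("cells must be a strains x genes matrix", call. = FALSE)
  }
  if (nrow(cells) > 0L && !identical(rownames(cells), strains$strain_id)) {
    stop("cell rownames must equal strain ids", call. = FALSE)
  }
  if (ncol(cells) > 0L && !identical(colnames(cells), genes$name)) {
    stop("cell colnames must equal gene names", call. = FALSE)
  }
  bad <- setdiff(unique(as.vector(cells)), c("present", "absent", "unknown"))
  if (length(bad) > 0L) {
    stop("illegal cell value(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  structure(list(strains = strains, genes = as.data.frame(genes),
                 cells = cells),
            class = "pa_matrix")
}

#' @export
print.pa_matrix <- function(x, ...) {
  cat(sprintf("pa_matrix: %d strains x %d genes (%d cells unknown)\n",
              nrow(x$strains), nrow(x$genes), sum(x$cells == "unknown")))
  invisible(x)
}

#' @export
dim.pa_matrix <- function(x) c(nrow(x$strains), nrow(x$genes))

cell_tokens <- c(present = "1", absent = "0", unknown = "?")

#' Write a presence/absence matrix to TSV
#'
#' @param matrix A `pa_matrix`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_matrix_tsv <- function(matrix, path) {
  stopifnot(inherits(matrix, "pa_matrix"))
  tok <- matrix(cell_tokens[matrix$cells], nrow = nrow(matrix$cells),
                ncol = ncol(matrix$cells), dimnames = dimnames(matrix$cells))
  df <- data.frame(strain_id = matrix$strains$strain_id,
                   tok, check.names = FALSE, stringsAsFactors = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a presence/absence matrix from TSV
#'
#' Strain metadata beyond `strain_id` is not stored in the TSV; strains
#' read back carry `strain_id` only unless a `strains` table is supplied.
#'
#' @param path Input path.
#' @param genes Optional gene table to validate/order columns against.
#' @param strains Optional strain table to attach (matched by
#'   `strain_id`).
#' @return A `pa_matrix`.
#' @export
read_matrix_tsv <- function(path, genes = NULL, strains = NULL) {
  lines <- readLines(path)
  if (length(lines) == 0L) stop("parse error: empty file", call. = FALSE)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  header <- fields[[1]]
  if (header[1] != "strain_id") {
    stop("parse error: first column must be strain_id", call. = FALSE)
  }
  gene_names <- header[-1]
  body <- fields[-1]
  nc <- lengths(body)
  if (any(nc != length(header))) {
    stop("parse error: ragged row(s) at line ",
         paste(which(nc != length(header)) + 1L, collapse = ", "),
         call. = FALSE)
  }
  ids <- vapply(body, `[[`, character(1), 1L)
  cells <- matrix("unknown", nrow = length(body), ncol = length(gene_names),
                  dimnames = list(ids, gene_names))
  rev_tok <- setNames(names(cell_tokens), cell_tokens)
  for (i in seq_along(body)) {
    vals <- body[[i]][-1]
    bad <- setdiff(unique(vals), names(rev_tok))
    if (length(bad) > 0L) {
      stop("parse error: illegal cell token '", bad[1], "' at line ", i + 1L,
           call. = FALSE)
    }
    cells[i, ] <- rev_tok[vals]
  }
  if (is.null(genes)) {
    genes <- data.frame(name = gene_names, stringsAsFactors = FALSE)
  } else {
    if (!setequal(genes$name, gene_names)) {
      stop("parse error: gene columns do not match the supplied panel",
           call. = FALSE)
    }
    cells <- cells[, genes$name, drop = FALSE]
  }
  if (is.null(strains)) {
    strains <- data.frame(strain_id = ids, stringsAsFactors = FALSE)
  } else {
    if (!setequal(strains$strain_id, ids)) {
      stop("parse error: strain rows do not match the supplied table",
           call. = FALSE)
    }
    strains <- strains[match(ids, strains$strain_id), , drop = FALSE]
    rownames(strains) <- NULL
  }
  pa_matrix(strains, genes, cells)
}
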