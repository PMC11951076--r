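#' Packaged presence/absence fixture for 19 thraustochytrids + 3 relatives
#'
#' The fixture transcribes, from the study's text statements only, the
#' distribution of the 24 panel genes across 19 thraustochytrid strains
#' (six genera) and three related Labyrinthulomycetes. Cells not fixed by
#' an explicit statement are `unknown`, never guessed from figure artwork.
#' Each filling statement is also available as a machine-checkable
#' predicate via [fixture_consistency()].
#'
#' @name fixture
NULL

#' Strain records underlying the fixture
#'
#' @return Data frame with columns `strain_id`, `genus`, `clade_group`
#'   (thraustochytrid/relative), `evidence_source` (genome/transcriptome),
#'   `lineage_reported` (the study's published lineage; NA for relatives)
#'   and `ploidy_note`.
#' @export
fixture_strains <- function() {
  df <- data.frame(
    strain_id = c(
      "B. sp. S-28", "P. sp. I65-24A", "S. aggregatum ATCC 28209",
      "T. striatum ATCC 24473",
      "T. aureum ATCC 34304", "T. aureum ssp. strugatskii",
      "A. sp. T66", "A. sp. KH105", "H. fermentalgiana FCC1311",
      "T. sp. ATCC 26185", "T. sp. TN22", "S. sp. CCTCC M209059",
      "S. sp. ATCC 20888",
      "A. acetophilum HS399", "A. limacinum ATCC MYA-1381",
      "A. limacinum SR21", "A. sp. R2", "S. sp. TIO01", "S. sp. x62-1",
      "O. sp. RT2316-13", "A. kerguelense PBS07", "L. sp. SR_Ha_C"
    ),
    genus = c(
      "Botryochytrium", "Parietichytrium", "Schizochytrium",
      "Thraustochytrium",
      "Thraustochytrium", "Thraustochytrium",
      "Aurantiochytrium", "Aurantiochytrium", "Hondaea",
      "Thraustochytrium", "Thraustochytrium", "Schizochytrium",
      "Schizochytrium",
      "Aurantiochytrium", "Aurantiochytrium",
      "Aurantiochytrium", "Aurantiochytrium", "Schizochytrium",
      "Schizochytrium",
      "Oblongichytrium", "Aplanochytrium", "Labyrinthula"
    ),
    clade_group = c(rep("thraustochytrid", 19L), rep("relative", 3L)),
    evidence_source = c(
      "transcriptome", "genome", "genome", "genome",
      "genome", "transcriptome",
      "genome", "genome", "genome", "genome", "genome", "genome",
      "transcriptome",
      "genome", "genome", "genome", "transcriptome", "genome",
      "transcriptome",
      "transcriptome", "genome", "genome"
    ),
    lineage_reported = c(
      rep("I", 4L), rep("II", 2L), rep("III", 7L), rep("IV", 6L),
      rep(NA_character_, 3L)
    ),
    stringsAsFactors = FALSE
  )
  df$ploidy_note <- ""
  df$ploidy_note[df$strain_id == "A. sp. KH105"] <- "diploid"
  df$ploidy_note[df$strain_id == "S. sp. CCTCC M209059"] <-
    paste("carries a truncated 422-residue ACLY lacking the N-terminal",
          "ATP/citrate/CoA binding domains; recorded absent for typing")
  df$ploidy_note[df$strain_id == "B. sp. S-28"] <-
    paste("RNA-seq evidence only; full Type-I gene set recorded present",
          "per the published lineage listing")
  df
}

# strains of one reported lineage (thraustochytrids only)
lineage_strains <- function(lineage) {
  s <- fixture_strains()
  s$strain_id[!is.na(s$lineage_reported) & s$lineage_reported == lineage]
}

# The text statements that fill (and check) fixture cells. Each entry has a
# description in the package's own words, a fill(cells) mutator and a
# check(cells) predicate. Cells are a strain x gene character matrix over
# {present, absent, unknown}.
fixture_statements <- function() {
  strains <- fixture_strains()
  thr <- strains$strain_id[strains$clade_group == "thraustochytrid"]
  tI <- lineage_strains("I"); tII <- lineage_strains("II")
  tIII <- lineage_strains("III"); tIV <- lineage_strains("IV")
  pfa <- c("PfaA", "PfaB", "PfaC")
  elodes_core <- c("DES_D4", "DES_D5", "DES_D6", "DES_D8", "DES_D9A",
                   "DES_w3", "ELO_C16", "ELO_C18", "ELO_C20", "ELO_D9")
  set_cells <- function(cells, rows, cols, value) {
    cells[rows, cols] <- value
    cells
  }
  all_are <- function(cells, rows, cols, value) {
    all(cells[rows, cols] == value)
  }

  list(
    list(
      desc = "Type I strains use only the ELO/DES route: no PUFA synthase subunits, full main-route elongase/desaturase set",
      fill = function(c) set_cells(set_cells(c, tI, pfa, "absent"),
                                   tI, elodes_core, "present"),
      check = function(c) all_are(c, tI, pfa, "absent") &&
        all_are(c, tI, elodes_core, "present")
    ),
    list(
      desc = "Type II strains carry both pathways: PUFA synthase subunits and the full main-route elongase/desaturase set",
      fill = function(c) set_cells(set_cells(c, tII, pfa, "present"),
                                   tII, elodes_core, "present"),
      check = function(c) all_are(c, tII, pfa, "present") &&
        all_are(c, tII, elodes_core, "present")
    ),
    list(
      desc = "Type III strains carry the PUFA synthase plus all route desaturases except the canonical D9 (D9DES-A), and all major elongase groups",
      fill = function(c) {
        c <- set_cells(c, tIII, pfa, "present")
        c <- set_cells(c, tIII, c("DES_D4", "DES_D5", "DES_D6", "DES_D8",
                                  "DES_w6D9B", "DES_w3", "DES_U3"),
                       "present")
        set_cells(c, tIII, c("ELO_C16", "ELO_C18", "ELO_C20", "ELO_D9"),
                  "present")
      },
      check = function(c) all_are(c, tIII, pfa, "present") &&
        all_are(c, tIII, c("DES_D4", "DES_D5", "DES_D6", "DES_D8",
                           "DES_w6D9B", "DES_w3", "DES_U3"), "present") &&
        all_are(c, tIII, c("ELO_C16", "ELO_C18", "ELO_C20", "ELO_D9"),
                "present")
    ),
    list(
      desc = "Type IV strains rely on the PUFA synthase and keep only the D8, omega-3 and U3 desaturases",
      fill = function(c) {
        c <- set_cells(c, tIV, pfa, "present")
        c <- set_cells(c, tIV, c("DES_D8", "DES_w3", "DES_U3"), "present")
        set_cells(c, tIV, c("DES_D4", "DES_D5", "DES_D6", "DES_w6D9B"),
                  "absent")
      },
      check = function(c) all_are(c, tIV, pfa, "present") &&
        all_are(c, tIV, c("DES_D8", "DES_w3", "DES_U3"), "present") &&
        all_are(c, tIV, c("DES_D4", "DES_D5", "DES_D6", "DES_w6D9B"),
                "absent")
    ),
    list(
      desc = "The canonical D9 desaturase (D9DES-A) and the U2 desaturase occur only in Type I and II strains",
      fill = function(c) {
        c <- set_cells(c, c(tI, tII), c("DES_D9A", "DES_U2"), "present")
        set_cells(c, c(tIII, tIV), c("DES_D9A", "DES_U2"), "absent")
      },
      check = function(c) all_are(c, c(tI, tII), c("DES_D9A", "DES_U2"),
                                  "present") &&
        all_are(c, c(tIII, tIV), c("DES_D9A", "DES_U2"), "absent")
    ),
    list(
      desc = "The U1 desaturase occurs solely in two Type I strains (P. sp. I65-24A and S. aggregatum)",
      fill = function(c) {
        u1 <- c("P. sp. I65-24A", "S. aggregatum ATCC 28209")
        c <- set_cells(c, u1, "DES_U1", "present")
        set_cells(c, setdiff(thr, u1), "DES_U1", "absent")
      },
      check = function(c) {
        u1 <- c("P. sp. I65-24A", "S. aggregatum ATCC 28209")
        all_are(c, u1, "DES_U1", "present") &&
          all_are(c, setdiff(thr, u1), "DES_U1", "absent")
      }
    ),
    list(
      desc = "Type IV strains lack the C18 and C20 elongases but retain the D9 elongase",
      fill = function(c) {
        c <- set_cells(c, tIV, c("ELO_C18", "ELO_C20"), "absent")
        set_cells(c, tIV, "ELO_D9", "present")
      },
      check = function(c) all_are(c, tIV, c("ELO_C18", "ELO_C20"),
                                  "absent") &&
        all_are(c, tIV, "ELO_D9", "present")
    ),
    list(
      desc = "The C16-like elongase occurs exclusively in Type I and II strains",
      fill = function(c) {
        c <- set_cells(c, c(tI, tII), "ELO_C16L", "present")
        set_cells(c, c(tIII, tIV), "ELO_C16L", "absent")
      },
      check = function(c) all_are(c, c(tI, tII), "ELO_C16L", "present") &&
        all_are(c, c(tIII, tIV), "ELO_C16L", "absent")
    ),
    list(
      desc = "The uncharacterised elongase groups U1 and U2 occur in all 19 thraustochytrids and in O. sp. RT2316-13, but no elongase at all was detected in L. sp. SR_Ha_C",
      fill = function(c) {
        c <- set_cells(c, c(thr, "O. sp. RT2316-13"),
                       c("ELO_U1", "ELO_U2"), "present")
        elos <- c("ELO_C16", "ELO_C16L", "ELO_C18", "ELO_C20", "ELO_D9",
                  "ELO_U1", "ELO_U2")
        set_cells(c, "L. sp. SR_Ha_C", elos, "absent")
      },
      check = function(c) {
        elos <- c("ELO_C16", "ELO_C16L", "ELO_C18", "ELO_C20", "ELO_D9",
                  "ELO_U1", "ELO_U2")
        all_are(c, c(thr, "O. sp. RT2316-13"), c("ELO_U1", "ELO_U2"),
                "present") &&
          all_are(c, "L. sp. SR_Ha_C", elos, "absent")
      }
    ),
    list(
      desc = "ACLY homologues occur only in Type I and II strains (the truncated, non-functional copy of S. sp. CCTCC M209059 is recorded absent)",
      fill = function(c) {
        c <- set_cells(c, c(tI, tII), "ACLY", "present")
        set_cells(c, c(tIII, tIV), "ACLY", "absent")
      },
      check = function(c) all_are(c, c(tI, tII), "ACLY", "present") &&
        all_are(c, c(tIII, tIV), "ACLY", "absent")
    ),
    list(
      desc = "Cytosolic carnitine acetyltransferase occurs in Types I-III and all three relatives but not in Type IV",
      fill = function(c) {
        c <- set_cells(c, c(tI, tII, tIII,
                            "O. sp. RT2316-13", "A. kerguelense PBS07",
                            "L. sp. SR_Ha_C"), "cCrAT", "present")
        set_cells(c, tIV, "cCrAT", "absent")
      },
      check = function(c) all_are(c, c(tI, tII, tIII), "cCrAT", "present") &&
        all_are(c, tIV, "cCrAT", "absent")
    ),
    list(
      desc = "Beta-carotene hydroxylase (CrtZ) occurs only in Types III and IV; it is absent from Types I and II and from all three relatives",
      fill = function(c) {
        c <- set_cells(c, c(tIII, tIV), "CrtZ", "present")
        set_cells(c, c(tI, tII, "O. sp. RT2316-13",
                       "A. kerguelense PBS07", "L. sp. SR_Ha_C"),
                  "CrtZ", "absent")
      },
      check = function(c) all_are(c, c(tIII, tIV), "CrtZ", "present") &&
        all_are(c, c(tI, tII), "CrtZ", "absent")
    ),
    list(
      desc = "Beta-carotene ketolase (CrtO) occurs in all thraustochytrids except T. striatum and the T. aureum strains",
      fill = function(c) {
        no_crto <- c("T. striatum ATCC 24473", "T. aureum ATCC 34304",
                     "T. aureum ssp. strugatskii")
        c <- set_cells(c, setdiff(thr, no_crto), "CrtO", "present")
        set_cells(c, no_crto, "CrtO", "absent")
      },
      check = function(c) {
        no_crto <- c("T. striatum ATCC 24473", "T. aureum ATCC 34304",
                     "T. aureum ssp. strugatskii")
        all_are(c, setdiff(thr, no_crto), "CrtO", "present") &&
          all_are(c, no_crto, "CrtO", "absent")
      }
    ),
    list(
      desc = "Among the relatives, O. sp. RT2316-13 lacks the PUFA synthase while A. kerguelense and L. sp. SR_Ha_C possess it",
      fill = function(c) {
        c <- set_cells(c, "O. sp. RT2316-13", pfa, "absent")
        set_cells(c, c("A. kerguelense PBS07", "L. sp. SR_Ha_C"), pfa,
                  "present")
      },
      check = function(c) all_are(c, "O. sp. RT2316-13", pfa, "absent") &&
        all_are(c, c("A. kerguelense PBS07", "L. sp. SR_Ha_C"), pfa,
                "present")
    )
  )
}

#' Build the packaged presence/absence fixture matrix
#'
#' @param panel The gene panel (defaults to the packaged 24-gene panel).
#' @return A `pa_matrix` (see [pa_matrix()]): 22 strains x 24 genes.
#' @export
build_fixture_matrix <- function(panel = default_panel()) {
  strains <- fixture_strains()
  cells <- matrix("unknown", nrow = nrow(strains), ncol = nrow(panel),
                  dimnames = list(strains$strain_id, panel$name))
  for (st in fixture_statements()) {
    cells <- st$fill(cells)
  }
  pa_matrix(strains, panel, cells)
}

#' Check the fixture against every encoded text statement
#'
#' @param matrix A `pa_matrix` (defaults to the freshly built fixture).
#' @return Named logical vector, one entry per statement.
#' @export
fixture_consistency <- function(matrix = build_fixture_matrix()) {
  sts <- fixture_statements()
  out <- vapply(sts, function(st) isTRUE(st$check(matrix$cells)), logical(1))
  names(out) <- vapply(sts, `[[`, character(1), "desc")
  out
}
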