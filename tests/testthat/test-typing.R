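fx <- build_fixture_matrix()

test_that("pathway flags derive correctly from fixture rows", {
  # Type I exemplar: complete ELO/DES, no PUFA synthase
  fl <- pathway_flags(fx, strain_id = "T. striatum ATCC 24473")
  expect_false(fl$pufas_complete)
  expect_true(fl$elodes_complete)
  # Type III exemplar: PUFA synthase, broken at the canonical D9
  fl3 <- pathway_flags(fx, strain_id = "H. fermentalgiana FCC1311")
  expect_true(fl3$pufas_complete)
  expect_false(fl3$has_d9a)
  expect_false(fl3$elodes_complete)
  expect_true(fl3$has_long_elos)
  # all-absent row: every flag false
  row <- setNames(rep("absent", 24), default_panel()$name)
  fl0 <- pathway_flags(row)
  expect_false(any(unlist(fl0[c("pufas_complete", "elodes_complete",
                                "has_d9a", "has_long_elos", "has_acly",
                                "has_ccrat")])))
  # missing gene column is an input error
  expect_error(pathway_flags(row[-1]), "lacks gene column")
})

test_that("lineage calls match the published assignments", {
  expect_equal(call_type(pathway_flags(
    fx, strain_id = "T. aureum ATCC 34304"))$lineage, "II")
  expect_equal(call_type(pathway_flags(
    fx, strain_id = "A. limacinum SR21"))$lineage, "IV")
  expect_equal(call_type(pathway_flags(
    fx, strain_id = "B. sp. S-28"))$lineage, "I")
  expect_equal(call_type(pathway_flags(
    fx, strain_id = "A. sp. T66"))$lineage, "III")
  row <- setNames(rep("absent", 24), default_panel()$name)
  expect_equal(call_type(pathway_flags(row))$lineage, "unclassified")
})

test_that("the four lineage predicates are mutually exclusive (64 cases)", {
  # six driver gene-groups toggle independently; flags derive through
  # pathway_flags, so impossible flag combinations never arise
  panel <- default_panel()
  groups <- list(
    pufas = c("PfaA", "PfaB", "PfaC"),
    d9a = "DES_D9A",
    core_des = c("DES_D4", "DES_D5", "DES_w3"),
    route_des = c("DES_D6", "DES_D8"),
    core_elo = c("ELO_C16", "ELO_D9"),
    long_elo = c("ELO_C18", "ELO_C20")
  )
  combos <- expand.grid(rep(list(c(FALSE, TRUE)), length(groups)))
  names(combos) <- names(groups)
  expect_equal(nrow(combos), 64L)
  for (i in seq_len(nrow(combos))) {
    row <- setNames(rep("absent", nrow(panel)), panel$name)
    for (g in names(groups)) {
      if (combos[i, g]) row[groups[[g]]] <- "present"
    }
    fl <- pathway_flags(row, panel)
    preds <- c(
      I = fl$elodes_complete && !fl$pufas_complete,
      II = fl$elodes_complete && fl$pufas_complete,
      III = fl$pufas_complete && !fl$has_d9a && fl$has_long_elos,
      IV = fl$pufas_complete && !fl$has_d9a && !fl$has_long_elos
    )
    expect_lte(sum(preds), 1L)
    # and the sequential call agrees with the unique true predicate
    ct <- call_type(fl)
    if (sum(preds) == 1L) {
      expect_equal(ct$lineage, names(preds)[preds])
    } else {
      expect_equal(ct$lineage, "unclassified")
    }
  }
})

test_that("acetyl-CoA route inference follows ACLY, then cCrAT", {
  route_of <- function(strain) {
    acetylcoa_route(pathway_flags(fx, strain_id = strain))
  }
  expect_equal(route_of("T. striatum ATCC 24473"), "citrate_ACLY")
  expect_equal(route_of("T. aureum ATCC 34304"), "citrate_ACLY")
  expect_equal(route_of("H. fermentalgiana FCC1311"), "carnitine_cCrAT")
  expect_equal(route_of("A. limacinum SR21"), "undetermined")
})

test_that("summarize reproduces the published counts and listings", {
  rep <- summarize_typing(fx)
  expect_equal(rep$counts$pufas_complete, 15L)
  expect_equal(rep$counts$elodes_complete, 6L)
  expect_equal(unname(rep$counts$per_lineage),
               c(4L, 2L, 7L, 6L))
  expect_equal(rep$counts$distinct_lineages, 4L)
  thr <- rep$calls[rep$calls$clade_group == "thraustochytrid", ]
  reported <- fx$strains$lineage_reported[
    fx$strains$clade_group == "thraustochytrid"]
  expect_identical(thr$lineage, reported)
  # relatives are typed but flagged as heuristic
  rel <- rep$calls[rep$calls$clade_group == "relative", ]
  expect_true(all(nzchar(rel$caveat)))
})

test_that("lineage calls ignore genes outside the driver set", {
  cells <- fx$cells
  cells[, "CrtO"] <- ifelse(cells[, "CrtO"] == "present", "absent",
                            "present")
  flipped <- pa_matrix(fx$strains, fx$genes, cells)
  expect_identical(summarize_typing(flipped)$calls$lineage,
                   summarize_typing(fx)$calls$lineage)
})

test_that("unknown driver cells are surfaced as uncertainty", {
  row <- fx$cells["O. sp. RT2316-13", ]
  fl <- pathway_flags(row)
  expect_gt(length(fl$uncertain), 0L)
  ct <- call_type(fl)
  expect_true(any(grepl("uncertain", ct$rationale)))
})

test_that("strict completeness additionally requires the omega-6/D9B gene", {
  # Type I rows leave that cell unknown, so strict mode withdraws
  # ELO/DES completeness there
  fl <- pathway_flags(fx, strain_id = "T. striatum ATCC 24473",
                      strict = TRUE)
  expect_false(fl$elodes_complete)
})
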