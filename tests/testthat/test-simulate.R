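test_that("generators are deterministic under a fixed config", {
  cfg <- test_cfg(161)
  a <- synth_family_protein("DES_w3", config = cfg)
  b <- synth_family_protein("DES_w3", config = cfg)
  expect_identical(as.character(a), as.character(b))
  lib <- make_reference_library(config = cfg)
  s1 <- synth_strain("III", lib, cfg, strain_id = "det")
  s2 <- synth_strain("III", lib, cfg, strain_id = "det")
  expect_identical(s1$proteome, s2$proteome)
  tr <- ape::read.tree(text = "((a:0.1,b:0.1):0.2,(c:0.1,d:0.1):0.2);")
  r <- paste(rep("ACDEFGHIKL", 20), collapse = "")
  expect_identical(evolve_along_tree(tr, r, 1, cfg),
                   evolve_along_tree(tr, r, 1, cfg))
})

test_that("family members carry their planted motifs", {
  cfg <- test_cfg(162)
  w3 <- synth_family_protein("DES_w3", config = cfg)
  expect_equal(classify_desaturase(as.character(w3))$family, "DES_w3")
  c20 <- synth_family_protein("ELO_C20", config = cfg)
  expect_gt(nrow(scan_boxes(as.character(c20), "QXXHH")), 0L)
  # U3 gets its long N-terminal extension before the domain motif
  u3 <- synth_family_protein("DES_U3", config = cfg)
  hp <- regexpr("HPGG", as.character(u3), fixed = TRUE)
  expect_gt(as.integer(hp), 450L)
  expect_error(synth_family_protein("NOT_A_FAMILY", config = cfg),
               "unknown family")
})

test_that("mutation follows its analytic expectations", {
  cfg <- test_cfg(163, box_preservation_prob = 0)
  s <- strrep("A", 2000)
  # rate 0 is the identity
  withr::with_seed(1, expect_identical(as.character(mutate_seq(s, 0, cfg)),
                                       s))
  # rate 1, no protection: residual identity = 1/20 (full resampling)
  ident <- withr::with_seed(2, {
    m <- strsplit(as.character(mutate_seq(s, 1, cfg)), "")[[1]]
    mean(m == "A")
  })
  ci <- stats::binom.test(round(ident * 2000), 2000, p = 1 / 20)$p.value
  expect_gt(ci, 0.001)
  # mean changed fraction at rate 0.1 is rate * 19/20 over many seeds
  frac <- withr::with_seed(3, vapply(1:200, function(i) {
    m <- strsplit(as.character(mutate_seq(s, 0.1, cfg)), "")[[1]]
    mean(m != "A")
  }, numeric(1)))
  se <- stats::sd(frac) / sqrt(length(frac))
  expect_lt(abs(mean(frac) - 0.1 * 19 / 20), 3 * se + 1e-4)
  expect_error(mutate_seq(s, 1.5, cfg), "rate")
})

test_that("box protection spares planted motifs preferentially", {
  cfg <- test_cfg(164, box_preservation_prob = 1)
  arch <- synth_family_protein("DES_w6D9B", config = cfg)
  mut <- withr::with_seed(4, mutate_seq(arch, 0.5, cfg))
  boxes <- attr(arch, "boxes")
  a <- strsplit(as.character(arch), "")[[1]]
  m <- strsplit(as.character(mut), "")[[1]]
  in_box <- logical(length(a))
  for (b in seq_len(nrow(boxes))) {
    in_box[(boxes$start[b] + 1):boxes$end[b]] <- TRUE
  }
  expect_identical(m[in_box], a[in_box])  # fully protected
  expect_gt(mean(m[!in_box] != a[!in_box]), 0.3)  # background mutated
})

test_that("strain truth tables are consistent with the emitted proteome", {
  cfg <- test_cfg(165)
  lib <- make_reference_library(config = cfg)
  for (prof in c("I", "IV")) {
    st <- synth_strain(prof, lib, cfg, strain_id = paste0("tt_", prof))
    expect_true(all(st$truth$protein_id %in% names(st$proteome)))
    expect_setequal(st$truth$family, type_profiles()[[prof]])
    decoys <- setdiff(names(st$proteome), st$truth$protein_id)
    expect_equal(length(decoys), cfg$decoys_per_strain)
    expect_false(any(decoys %in% st$truth$protein_id))
  }
  # profile IV omits the canonical D9 desaturase and long elongases
  p4 <- type_profiles()[["IV"]]
  expect_false(any(c("DES_D9A", "ELO_C18", "ELO_C20") %in% p4))
  # profiles I and II carry the canonical D9 desaturase
  expect_true(all(c("DES_D9A") %in% type_profiles()[["I"]]))
  expect_true(all(c("PfaA", "DES_D9A") %in% type_profiles()[["II"]]))
})

test_that("zero-length branches leave all tips identical", {
  tr <- ape::read.tree(text = "((a:0,b:0):0,(c:0,d:0):0);")
  root <- strrep("ACDEF", 40)
  tips <- evolve_along_tree(tr, root, 1, test_cfg(166))
  expect_true(all(tips == root))
})

test_that("end-to-end lineage recovery works on one seeded quartet", {
  cfg <- test_cfg(167, mutation_rate = 0.05)
  lib <- make_reference_library(config = cfg)
  panel <- default_panel()
  calls <- vapply(c("I", "II", "III", "IV"), function(prof) {
    st <- synth_strain(prof, lib, cfg, strain_id = paste0("e2e_", prof))
    asg <- assign_proteome(st$proteome, panel, lib, quiet = TRUE)
    asg$strain_id <- st$strain_id
    m <- presence_matrix(asg, panel, data.frame(strain_id = st$strain_id))
    summarize_typing(m)$calls$lineage
  }, character(1))
  expect_identical(unname(calls), c("I", "II", "III", "IV"))
})
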