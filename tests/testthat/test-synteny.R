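test_that("GFF-lite round trip preserves features and converts coordinates", {
  feats <- data.frame(
    gene_id = c("g1", "g2", "g3"),
    contig_id = "ctg1",
    start = c(0L, 1500L, 3200L),
    end = c(900L, 2400L, 4100L),
    strand = c("+", "-", "+"),
    protein_id = c("p1", "p2", "p3"),
    stringsAsFactors = FALSE
  )
  tmp <- tempfile(fileext = ".gff")
  write_gff_lite(feats, tmp)
  # on disk: 1-based inclusive
  line1 <- strsplit(readLines(tmp)[1], "\t")[[1]]
  expect_equal(as.integer(line1[4]), 1L)
  expect_equal(as.integer(line1[5]), 900L)
  back <- read_gff_lite(tmp)
  expect_equal(back[, names(feats)], feats)
  # malformed rows are rejected
  writeLines("ctg1\tx\tgene\t1\t10", tmp)
  expect_error(read_gff_lite(tmp), "9 columns")
})

test_that("neighborhood extraction truncates at contig edges", {
  feats <- data.frame(
    gene_id = paste0("g", 1:9), contig_id = "c",
    start = seq(0, 8000, by = 1000), end = seq(900, 8900, by = 1000),
    strand = "+", protein_id = paste0("p", 1:9),
    stringsAsFactors = FALSE
  )
  # target in the middle: full 4+4 flanks, nearest first
  nbr <- extract_neighborhood(feats, "g5")
  expect_equal(nbr$upstream$gene_id, c("g4", "g3", "g2", "g1"))
  expect_equal(nbr$downstream$gene_id, c("g6", "g7", "g8", "g9"))
  # target near the start: truncated upstream
  nbr2 <- extract_neighborhood(feats, "g3")
  expect_equal(nbr2$upstream$gene_id, c("g2", "g1"))
  expect_equal(nrow(nbr2$downstream), 4L)
  # determinism
  expect_identical(extract_neighborhood(feats, "g5"),
                   extract_neighborhood(feats, "g5"))
  expect_error(extract_neighborhood(feats, "nope"), "unknown target")
})

test_that("identical neighborhoods pair 8/8; random flanks pair 0", {
  cfg <- test_cfg(71, mutation_rate = 0)
  sc <- synth_contig(c("u", "v"), conserved_up = 1:4, conserved_down = 1:4,
                     config = cfg)
  nu <- extract_neighborhood(sc$u$features, "DES_D9A")
  nv <- extract_neighborhood(sc$v$features, "DES_D9A")
  prot <- c(sc$u$proteome, sc$v$proteome)
  pairs <- map_homologs(nu, nv, prot)
  expect_equal(nrow(pairs), 8L)
  # all-random flanks: nothing pairs at the default threshold
  sc0 <- synth_contig(c("w", "x"), config = test_cfg(72, mutation_rate = 0))
  nw <- extract_neighborhood(sc0$w$features, "DES_D9A")
  nx <- extract_neighborhood(sc0$x$features, "DES_D9A")
  expect_equal(nrow(map_homologs(nw, nx, c(sc0$w$proteome,
                                           sc0$x$proteome))), 0L)
})

test_that("planted 1-up/2-down conservation is recovered exactly", {
  for (seed in c(81, 82, 83)) {
    cfg <- test_cfg(seed, mutation_rate = 0.05)
    sc <- synth_contig(c("ref", "oth"), conserved_up = 1,
                       conserved_down = c(1, 2), config = cfg)
    res <- suppressMessages(synteny_conservation(
      "DES_D9A", lapply(sc, `[[`, "features"),
      lapply(sc, `[[`, "proteome")))
    expect_equal(res$results$conserved_upstream, 1L)
    expect_equal(res$results$conserved_downstream, 2L)
  }
})

test_that("conservation counts are symmetric in the strain pair", {
  cfg <- test_cfg(91, mutation_rate = 0.05)
  sc <- synth_contig(c("a", "b"), conserved_up = c(1, 3),
                     conserved_down = 2, config = cfg)
  ann <- lapply(sc, `[[`, "features")
  prot <- lapply(sc, `[[`, "proteome")
  fwd <- suppressMessages(synteny_conservation("DES_D9A", ann, prot,
                                               reference = "a"))
  rev <- suppressMessages(synteny_conservation("DES_D9A", ann, prot,
                                               reference = "b"))
  expect_equal(fwd$results$conserved_upstream,
               rev$results$conserved_upstream)
  expect_equal(fwd$results$conserved_downstream,
               rev$results$conserved_downstream)
})

test_that("PfaA-PfaB adjacency is detected per strain", {
  cfg <- test_cfg(95, mutation_rate = 0)
  sc <- synth_contig(c("s1", "s2", "s3"), config = cfg,
                     pfa_adjacent = c(TRUE, TRUE, FALSE))
  res <- suppressMessages(synteny_conservation(
    "DES_D9A", lapply(sc, `[[`, "features"),
    lapply(sc, `[[`, "proteome")))
  expect_identical(unname(res$adjacency), c(TRUE, TRUE, FALSE))
})

test_that("strains lacking the target are skipped with a note", {
  cfg <- test_cfg(97, mutation_rate = 0)
  sc <- synth_contig(c("y", "z"), conserved_up = 1, config = cfg)
  feats_no_target <- sc$z$features[sc$z$features$gene_id != "DES_D9A", ]
  ann <- list(y = sc$y$features, z = feats_no_target)
  prot <- lapply(sc, `[[`, "proteome")
  expect_message(res <- synteny_conservation("DES_D9A", ann, prot),
                 "skipped")
  expect_equal(res$skipped, "z")
  expect_equal(nrow(res$results), 0L)
})
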