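test_that("progressive alignment handles identity and single-gap cases", {
  m <- progressive_align(c(a = "ACDEFGHIK", b = "ACDEFGHIK"))
  expect_equal(ncol(m), 9L)
  expect_false(any(m == "-"))
  m2 <- progressive_align(c(a = "ACDEFG", b = "ACEFG"))
  expect_equal(ncol(m2), 6L)
  expect_equal(sum(m2 == "-"), 1L)
  expect_equal(msa_sequence(m2, "a"), "ACDEFG")
  expect_equal(msa_sequence(m2, "b"), "ACEFG")
  expect_error(progressive_align(c(a = "ACDEF")), "at least two")
})

test_that("alignment columns are invariant to input order", {
  withr::with_seed(111, {
    base <- rand_seq(120)
    cfg <- test_cfg(112)
    seqs <- setNames(vapply(1:5, function(i) {
      withr::with_seed(200 + i,
        as.character(mutate_seq(base, 0.15, cfg, boxes = NULL)))
    }, character(1)), paste0("s", 1:5))
    ref <- progressive_align(seqs)
    perm <- progressive_align(seqs[c(3, 1, 5, 2, 4)])
    expect_identical(unclass(ref),
                     unclass(perm)[rownames(ref), , drop = FALSE])
    # ungapping recovers every input
    for (id in names(seqs)) {
      expect_equal(msa_sequence(ref, id), unname(seqs[id]))
    }
  })
})

test_that("p-distances equal the brute-force column count", {
  m <- rbind(a = c("A", "C", "D", "-", "F"),
             b = c("A", "C", "E", "G", "F"))
  expect_equal(p_distance_matrix(m)["a", "b"], 0.25)  # 1 of 4 comparable
  # identical rows are at distance zero
  m2 <- rbind(x = c("A", "C"), y = c("A", "C"))
  expect_equal(p_distance_matrix(m2)["x", "y"], 0)
  # random alignments vs an independent loop
  withr::with_seed(121, {
    for (rep in 1:10) {
      chars <- matrix(sample(c(aa_alphabet(), "-"), 4 * 60, replace = TRUE),
                      nrow = 4, dimnames = list(paste0("t", 1:4), NULL))
      D <- suppressWarnings(p_distance_matrix(chars))
      for (i in 1:3) for (j in (i + 1):4) {
        ok <- chars[i, ] != "-" & chars[j, ] != "-"
        want <- if (any(ok)) mean(chars[i, ok] != chars[j, ok]) else 1
        expect_equal(D[i, j], want)
      }
    }
  })
  # zero comparable columns: distance 1 with a warning
  m3 <- rbind(p = c("A", "-"), q = c("-", "C"))
  expect_warning(D3 <- p_distance_matrix(m3), "no comparable")
  expect_equal(D3["p", "q"], 1)
  # Poisson correction applies -log(1-p)
  expect_equal(p_distance_matrix(m, "poisson")["a", "b"], -log(0.75))
})

test_that("NJ recovers additive matrices exactly", {
  # the worked 4-taxon case
  tr4 <- ape::read.tree(text = "((A:1,B:2):1,(C:3,D:4):0);")
  D4 <- ape::cophenetic.phylo(tr4)
  rec <- nj_tree(D4)
  expect_equal(ape::dist.topo(ape::unroot(tr4), rec), 0,
               ignore_attr = TRUE)
  expect_equal(ape::cophenetic.phylo(rec)[rownames(D4), colnames(D4)],
               D4, tolerance = 1e-10)
  # random additive matrices up to 8 taxa: path distances reproduce D
  withr::with_seed(131, {
    for (rep in 1:12) {
      n <- sample(4:8, 1)
      tr <- ape::rtree(n, br = function(k) runif(k, 0.05, 1))
      D <- ape::cophenetic.phylo(tr)
      rec <- nj_tree(D)
      expect_equal(ape::cophenetic.phylo(rec)[rownames(D), colnames(D)],
                   D, tolerance = 1e-8)
    }
  })
})

test_that("the 3-taxon case uses the closed form", {
  D3 <- matrix(c(0, 3, 5, 3, 0, 6, 5, 6, 0), 3,
               dimnames = list(c("a", "b", "c"), c("a", "b", "c")))
  t3 <- nj_tree(D3)
  expect_equal(sort(t3$edge.length), c(1, 2, 4))
  expect_equal(ape::cophenetic.phylo(t3)[rownames(D3), colnames(D3)], D3)
})

test_that("nj_tree validates symmetry and clamps negative branches", {
  D <- matrix(c(0, 1, 2, 0), 2, dimnames = list(c("a", "b"), c("a", "b")))
  expect_error(nj_tree(D), "symmetric")
  # a strongly non-additive matrix can force negative estimates
  Dn <- matrix(c(0, 1, 5, 5,
                 1, 0, 5, 5,
                 5, 5, 0, 0.1,
                 5, 5, 0.1, 0), 4,
               dimnames = list(letters[1:4], letters[1:4]))
  tr <- suppressWarnings(nj_tree(Dn))
  expect_true(all(tr$edge.length >= 0))
})

test_that("bootstrap support saturates, respects n_reps=1 and the seed", {
  # 4 tips, 200 perfectly clade-informative columns
  half <- 100
  msa <- rbind(A = c(rep("A", half), rep("C", half)),
               B = c(rep("A", half), rep("C", half)),
               C = c(rep("W", half), rep("Y", half)),
               D = c(rep("W", half), rep("Y", half)))
  msa[1, 1:3] <- "G"; msa[3, 1:3] <- "H"  # break exact ties
  bt <- bootstrap_support(msa, n_reps = 50, seed = 5)
  expect_true(all(bt$node.label >= 0 & bt$node.label <= 1))
  # the AB|CD split is present in every replicate
  expect_true(any(bt$node.label == 1))
  expect_true(is_monophyletic_split(bt, c("A", "B")))
  one <- bootstrap_support(msa, n_reps = 1, seed = 5)
  expect_true(all(one$node.label %in% c(0, 1)))
  expect_identical(bootstrap_support(msa, n_reps = 20, seed = 9)$node.label,
                   bootstrap_support(msa, n_reps = 20, seed = 9)$node.label)
  expect_error(bootstrap_support(msa, n_reps = 0), "n_reps")
})

test_that("monophyly test agrees with brute-force bipartition enumeration", {
  skip_if_not_installed("igraph")
  withr::with_seed(141, {
    for (rep in 1:8) {
      n <- sample(5:12, 1)
      tr <- ape::unroot(ape::rtree(n))
      splits <- oracle_splits(tr)
      tips <- tr$tip.label
      # every true split (and its complement) must test monophyletic
      for (s in splits) {
        expect_true(is_monophyletic_split(tr, s))
        expect_true(is_monophyletic_split(tr, setdiff(tips, s)))
      }
      # random subsets agree with membership in the split list
      for (k in 1:5) {
        sub <- sample(tips, sample(2:(n - 1), 1))
        in_splits <- any(vapply(splits, function(s) {
          setequal(s, sub) || setequal(setdiff(tips, s), sub)
        }, logical(1)))
        expect_equal(is_monophyletic_split(tr, sub), in_splits)
      }
    }
  })
  expect_error(is_monophyletic_split(ape::rtree(4), "ghost"),
               "unknown tip")
})

test_that("sequences evolved on a 4-clade tree recover per-clade monophyly", {
  newick <- paste0(
    "((a1:0.02,a2:0.02,a3:0.02,a4:0.02):0.5,",
    "(b1:0.02,b2:0.02,b3:0.02,b4:0.02):0.5,",
    "((c1:0.02,c2:0.02,c3:0.02,c4:0.02):0.5,",
    "(d1:0.02,d2:0.02,d3:0.02,d4:0.02):0.5):0.3);")
  clade_tree <- ape::read.tree(text = newick)
  withr::with_seed(151, {
    root <- rand_seq(400)
  })
  tips <- evolve_along_tree(clade_tree, root, rate_per_branch = 1,
                            config = test_cfg(152))
  msa <- progressive_align(tips)
  nj <- nj_tree(p_distance_matrix(msa))
  for (g in c("a", "b", "c", "d")) {
    expect_true(is_monophyletic_split(nj, paste0(g, 1:4)))
  }
  expect_false(is_monophyletic_split(nj, c("a1", "b1", "c1", "d1")))
})
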