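test_that("scan_boxes finds planted boxes at the right offsets", {
  hits <- scan_boxes("AAHDAGHAA", "HDXGH")
  expect_equal(nrow(hits), 1L)
  expect_equal(hits$start, 2L)
  expect_equal(hits$matched_text, "HDAGH")
  # two planted boxes, one per pattern
  seq2 <- "HQQHHXHQQHH"
  expect_equal(scan_boxes(seq2, "HQQHH")$start, c(0L, 6L))
  expect_equal(scan_boxes(seq2, "HXXHH")$start, c(0L, 6L))
  # overlapping occurrences are all reported
  expect_equal(scan_boxes("HHHHHH", "HXXHH")$start, c(0L, 1L))
})

test_that("pattern parsing validates shape and rejects junk", {
  p <- parse_box_pattern("H[ED]CGH")
  expect_equal(attr(p, "npos"), 5L)
  expect_equal(attr(p, "literal_score"), 5L)
  expect_equal(attr(parse_box_pattern("HXXHH"), "literal_score"), 3L)
  expect_error(parse_box_pattern("HXH"), "span")
  expect_error(parse_box_pattern("AXXXB"), "illegal character")
  expect_error(parse_box_pattern("AXXXA"), "literal H/Q")
  expect_error(parse_box_pattern("H[E"), "bracket")
})

test_that("scan_boxes equals the sliding-window oracle on random input", {
  patterns <- c("H[ED]CGH", "HXXHH", "HRLWSH", "QXXHH", "HXXXHH")
  withr::with_seed(101, {
    for (rep in 1:60) {
      s <- rand_seq(200)
      for (p in patterns) {
        expect_identical(scan_boxes(s, p)$start, oracle_scan(s, p))
      }
    }
  })
})

test_that("match_signature handles planted, spaced and violated layouts", {
  reg <- default_signature_registry()
  gap <- function(n) strrep("A", n)
  # First-desaturase boxes at legal gaps
  s <- paste0(gap(10), "HRLWSH", gap(40), "HRAHH", gap(40), "HNAHH",
              gap(20))
  m <- match_signature(s, "DES_D9A", reg)
  expect_false(is.null(m))
  expect_true(m$spacing_ok)
  expect_equal(m$box_matches$matched_text, c("HRLWSH", "HRAHH", "HNAHH"))
  # same boxes but a gap beyond the maximum: match with spacing flagged
  s2 <- paste0(gap(10), "HRLWSH", gap(500), "HRAHH", gap(40), "HNAHH")
  m2 <- match_signature(s2, "DES_D9A", reg)
  expect_false(is.null(m2))
  expect_false(m2$spacing_ok)
  # missing box: no match at all
  s3 <- paste0(gap(10), "HRLWSH", gap(40), "HRAHH", gap(200))
  expect_null(match_signature(s3, "DES_D9A", reg))
})

test_that("match_signature equals the exhaustive combination oracle", {
  reg <- default_signature_registry()
  sigs <- lapply(c("DES_w6D9B", "DES_D4", "ELO_C20"), function(f) {
    as.list(reg[match(f, reg$family), , drop = FALSE])
  })
  withr::with_seed(202, {
    n_checked <- 0L
    for (rep in 1:150) {
      s <- rand_seq(250)
      if (rep %% 2 == 0) {
        # plant two or three generic boxes so full-signature candidates
        # actually arise; positions (and thus combos) stay random
        for (b in sample(c("HAAHH", "HDCGH", "HAAAHH", "QAAHH"),
                         sample(2:3, 1))) {
          at <- sample(0:(nchar(s) - 8), 1)
          s <- paste0(substr(s, 1, at), b,
                      substr(s, at + nchar(b) + 1, nchar(s)))
        }
      }
      for (sig in sigs) {
        got <- match_signature(s, sig, reg)
        want <- oracle_match(s, sig)
        if (is.null(want)) {
          expect_null(got)
        } else {
          n_checked <- n_checked + 1L
          expect_equal(got$box_matches$start, want$starts)
          expect_equal(got$score, want$score)
          expect_equal(got$spacing_ok, want$legal)
        }
      }
    }
    # the generic patterns must actually have fired on random sequences
    expect_gt(n_checked, 20L)
  })
})

test_that("N-terminal domain detection respects the search window", {
  s <- paste0(strrep("A", 30), "HPGG", strrep("A", 300))
  expect_true(detect_nterm_domain(s, "cytb5", window = 150))
  s2 <- paste0(strrep("A", 400), "HPGG", strrep("A", 50))
  expect_false(detect_nterm_domain(s2, "cytb5", window = 150))
  expect_true(detect_nterm_domain(s2, "none"))
  # unconfigured tags are skipped rather than failed
  expect_true(detect_nterm_domain(s2, "DUF3474"))
  expect_error(detect_nterm_domain(s, "PF00173"), "unknown")
})

test_that("zero-mutation members of all 10 desaturase families self-classify", {
  reg <- default_signature_registry()
  fams <- reg$family[grepl("^DES_", reg$family)]
  for (seed in c(3, 17)) {
    got <- vapply(fams, function(f) {
      s <- synth_family_protein(f, reg, test_cfg(seed))
      classify_desaturase(as.character(s), reg)$family
    }, character(1))
    expect_identical(unname(got), fams)
  }
})

test_that("classification ignores appended C-terminal residues", {
  reg <- default_signature_registry()
  withr::with_seed(7, {
    for (f in c("DES_D9A", "DES_w3", "DES_D6")) {
      s <- as.character(synth_family_protein(f, reg, test_cfg(9)))
      extended <- paste0(s, rand_seq(150))
      expect_identical(classify_desaturase(extended, reg)$family, f)
    }
  })
})

test_that("expected signature score never increases with mutation rate", {
  reg <- default_signature_registry()
  rates <- seq(0, 0.9, by = 0.1)
  cfg0 <- test_cfg(5, box_preservation_prob = 0)
  arch <- synth_family_protein("DES_w6D9B", reg, cfg0)
  mean_scores <- vapply(rates, function(r) {
    withr::with_seed(1000 + round(r * 100), {
      mean(vapply(1:40, function(i) {
        m <- match_signature(as.character(
          mutate_seq(arch, r, cfg0)), "DES_w6D9B", reg)
        if (is.null(m)) 0 else m$score
      }, numeric(1)))
    })
  }, numeric(1))
  # expected score decays with rate: monotone up to Monte-Carlo wiggle
  expect_equal(which.max(mean_scores), 1L)
  expect_lt(mean_scores[length(mean_scores)], mean_scores[1])
  expect_true(all(mean_scores <= mean_scores[1] + 1e-9))
  expect_true(all(diff(mean_scores) <= 0.5))
})

test_that("elongase box classification distinguishes the C20 variant", {
  reg <- default_signature_registry()
  bg <- strrep("A", 120)
  s_c20 <- paste0(bg, "QAAHH", bg)
  expect_equal(classify_elongase(s_c20, reg)$group, "ELO_C20")
  s_gen <- paste0(bg, "HTLHH", bg)
  expect_equal(classify_elongase(s_gen, reg)$group, "ELO_unresolved")
  expect_equal(classify_elongase(strrep("ACDEF", 40), reg)$group,
               "unclassified")
})
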