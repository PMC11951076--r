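#' Seeded synthetic-data generators
#'
#' Generators emit proteomes, annotated contigs and tree-evolved
#' sequences with the structure the pipeline assumes: family members are
#' random backgrounds with the family's histidine boxes (and N-terminal
#' domain motif) planted at spacing-legal offsets, decoys are residue
#' shuffles of real members (same composition, no motif/homology), and
#' mutation is seeded per-site resampling that spares planted boxes with
#' a configurable preservation probability. Everything is deterministic
#' under a fixed config.
#'
#' @name synthetic_data
NULL

#' Simulation configuration
#'
#' @param seed Integer master seed; all generator randomness derives from
#'   it through stage-keyed substreams ([stage_seed()]).
#' @param background_length_range Min/max residues of random background.
#' @param mutation_rate Per-site substitution probability in \[0, 1\].
#' @param box_preservation_prob Probability that a site inside a planted
#'   box is spared when selected for mutation (default 0.9; catalytic
#'   histidines are strongly conserved).
#' @param decoys_per_strain Shuffled decoy proteins added per synthetic
#'   strain.
#' @param contig_gene_count Genes per synthetic contig (target + flanks).
#' @return A `sim_config` list.
#' @export
sim_config <- function(seed = 1L, background_length_range = c(250L, 420L),
                       mutation_rate = 0.05, box_preservation_prob = 0.9,
                       decoys_per_strain = 10L, contig_gene_count = 9L) {
  stopifnot(length(background_length_range) == 2L,
            background_length_range[1] >= 50L,
            background_length_range[1] <= background_length_range[2])
  if (mutation_rate < 0 || mutation_rate > 1) {
    stop("input error: mutation_rate outside [0, 1]", call. = FALSE)
  }
  if (box_preservation_prob < 0 || box_preservation_prob > 1) {
    stop("input error: box_preservation_prob outside [0, 1]", call. = FALSE)
  }
  structure(list(seed = as.integer(seed),
                 background_length_range = as.integer(background_length_range),
                 mutation_rate = mutation_rate,
                 box_preservation_prob = box_preservation_prob,
                 decoys_per_strain = as.integer(decoys_per_strain),
                 contig_gene_count = as.integer(contig_gene_count)),
            class = "sim_config")
}

random_protein <- function(n) {
  paste(sample(aa_alphabet(), n, replace = TRUE), collapse = "")
}

# concretize a parsed box pattern into a literal instance
instantiate_pattern <- function(parsed) {
  paste(vapply(parsed, function(set) {
    if (length(set) == 1L) set else sample(set, 1L)
  }, character(1)), collapse = "")
}

splice <- function(sequence, at0, insert) {
  # overwrite residues at 0-based offset at0 with `insert`
  paste0(substr(sequence, 1L, at0),
         insert,
         substr(sequence, at0 + nchar(insert) + 1L, nchar(sequence)))
}

#' Synthesize one family-member protein
#'
#' The family's boxes (first alternative pattern per slot, degenerate
#' positions drawn at random) are planted left to right at gaps legal for
#' the signature; families with an N-terminal cytb5 domain get the core
#' motif planted inside the search window, and the U3 desaturase receives
#' its long (~500 residue) N-terminal extension first. Families without a
#' signature (PUFA-synthase subunits, accessory genes) are plain random
#' backgrounds. The planted box coordinates are attached as the `boxes`
#' attribute so that [mutate_seq()] can protect them.
#'
#' @param family Panel family name.
#' @param registry Signature registry.
#' @param config A `sim_config`.
#' @param seed Optional seed override (default: derived from the config
#'   seed and the family name, so repeated calls are identical).
#' @return Sequence string with attributes `family` and `boxes`
#'   (data frame of 0-based start/end).
#' @export
synth_family_protein <- function(family, registry = default_signature_registry(),
                                 config = sim_config(), seed = NULL) {
  if (!family %in% c(registry$family, default_panel()$name)) {
    stop("config error: unknown family '", family, "'", call. = FALSE)
  }
  if (is.null(seed)) seed <- stage_seed(config$seed, paste0("arch_", family))
  withr_seed(seed, {
    len <- sample(seq(config$background_length_range[1],
                      config$background_length_range[2]), 1L)
    has_sig <- family %in% registry$family
    if (!has_sig) {
      # PUFA-synthase subunits are large multidomain proteins; give them
      # longer backgrounds so alignment scores dominate decoys clearly
      if (family %in% c("PfaA", "PfaB", "PfaC")) len <- len + 300L
      seq <- random_protein(len)
      attr(seq, "family") <- family
      attr(seq, "boxes") <- data.frame(start = integer(0), end = integer(0))
      return(seq)
    }
    sig <- registry_signature(registry, family)
    slots <- sig$slots[[1]]
    nterm_pat <- default_nterm_patterns()[sig$nterm]
    prefix <- 0L
    if (family == "DES_U3") prefix <- 500L  # long N-terminal extension
    len <- max(len, prefix + 250L)
    seq <- random_protein(len)
    boxes <- data.frame(start = integer(0), end = integer(0))
    cursor <- prefix
    if (!is.na(sig$nterm) && sig$nterm != "none" && !is.na(nterm_pat)) {
      at <- cursor + sample(10:40, 1L)
      seq <- splice(seq, at, nterm_pat)
      boxes <- rbind(boxes, data.frame(start = at,
                                       end = at + nchar(nterm_pat)))
      cursor <- at + nchar(nterm_pat)
    }
    gap_lo <- max(sig$gap_min, 20L)
    gap_hi <- min(sig$gap_max, 60L)
    for (alts in slots) {
      inst <- instantiate_pattern(alts[[1]])
      at <- cursor + sample(gap_lo:gap_hi, 1L)
      if (at + nchar(inst) > nchar(seq)) {
        seq <- paste0(seq, random_protein(at + nchar(inst) + 30L -
                                            nchar(seq)))
      }
      seq <- splice(seq, at, inst)
      boxes <- rbind(boxes, data.frame(start = at, end = at + nchar(inst)))
      cursor <- at + nchar(inst)
    }
    attr(seq, "family") <- family
    attr(seq, "boxes") <- boxes
    seq
  })
}

#' Mutate a sequence by per-site resampling
#'
#' Each site is selected with probability `rate`; selected sites inside
#' protected box intervals are spared with probability
#' `box_preservation_prob`; surviving selections are resampled uniformly
#' from the 20-letter alphabet (so at rate 1 with no protection the
#' expected residual identity is exactly 1/20).
#'
#' @param sequence Sequence string (box coordinates are read from its
#'   `boxes` attribute unless `boxes` is given).
#' @param rate Per-site substitution probability.
#' @param config A `sim_config` (supplies `box_preservation_prob`).
#' @param boxes Optional data frame of protected 0-based start/end
#'   intervals.
#' @return Mutated sequence string (attributes preserved).
#' @export
mutate_seq <- function(sequence, rate, config = sim_config(), boxes = NULL) {
  if (rate < 0 || rate > 1) {
    stop("input error: rate outside [0, 1]", call. = FALSE)
  }
  if (is.null(boxes)) boxes <- attr(sequence, "boxes")
  chars <- strsplit(as.character(sequence), "")[[1]]
  n <- length(chars)
  hit <- runif(n) < rate
  if (!is.null(boxes) && nrow(boxes) > 0L) {
    protected <- logical(n)
    for (b in seq_len(nrow(boxes))) {
      protected[(boxes$start[b] + 1L):boxes$end[b]] <- TRUE
    }
    spare <- protected & hit & (runif(n) < config$box_preservation_prob)
    hit <- hit & !spare
  }
  chars[hit] <- sample(aa_alphabet(), sum(hit), replace = TRUE)
  out <- paste(chars, collapse = "")
  attributes(out) <- attributes(sequence)
  out
}

shuffle_protein <- function(sequence) {
  paste(sample(strsplit(as.character(sequence), "")[[1]]), collapse = "")
}

#' Per-lineage gene profiles
#'
#' The gene set of each lineage, read off the fixture: a gene belongs to
#' a profile when every strain of that lineage has it present (so
#' strain-specific genes such as the U1 desaturase, and cells left
#' unknown, are excluded).
#'
#' @return Named list of character vectors (lineages I-IV).
#' @export
type_profiles <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      fx <- build_fixture_matrix()
      lin <- fx$strains$lineage_reported
      cache <<- setNames(lapply(c("I", "II", "III", "IV"), function(l) {
        rows <- fx$cells[which(!is.na(lin) & lin == l), , drop = FALSE]
        colnames(rows)[colSums(rows == "present") == nrow(rows)]
      }), c("I", "II", "III", "IV"))
    }
    cache
  }
})

#' Build the default synthetic archetype library
#'
#' One seeded archetype per panel family (see [synth_family_protein()]).
#' Intended for tests and synthetic runs; real analyses should supply
#' curated archetypes. The C16-like elongase archetype is derived from
#' the C16 archetype by 25% mutation, mirroring the high (>50%) identity
#' between those groups.
#'
#' @param registry Signature registry.
#' @param panel Gene panel.
#' @param config A `sim_config` (its seed keys the archetypes).
#' @return A `reference_library`.
#' @export
make_reference_library <- function(registry = default_signature_registry(),
                                   panel = default_panel(),
                                   config = sim_config()) {
  seqs <- lapply(panel$name, function(fam) {
    synth_family_protein(fam, registry, config)
  })
  names(seqs) <- panel$name
  # C16L stays homologous to C16 (same backbone, diverged)
  c16 <- seqs[["ELO_C16"]]
  seqs[["ELO_C16L"]] <- withr_seed(
    stage_seed(config$seed, "arch_ELO_C16L_derive"),
    mutate_seq(c16, 0.25, config))
  attr(seqs[["ELO_C16L"]], "family") <- "ELO_C16L"
  entries <- data.frame(
    family = panel$name,
    protein_id = paste0("arch_", panel$name),
    sequence = vapply(seqs, as.character, character(1)),
    stringsAsFactors = FALSE
  )
  lib <- reference_library(entries, panel)
  lib$boxes <- lapply(seqs, attr, "boxes")
  lib
}

#' Synthesize a strain proteome with its truth table
#'
#' One protein per gene in the lineage profile (a mutated copy of the
#' family archetype, boxes protected) plus shuffled decoys.
#'
#' @param profile Lineage label (`"I"`..`"IV"`) or explicit character
#'   vector of family names.
#' @param library Archetype library from [make_reference_library()].
#' @param config A `sim_config` (`mutation_rate`, `decoys_per_strain`,
#'   seed).
#' @param strain_id Strain identifier (keys the random substream).
#' @return List with `strain_id`, `proteome` (named character vector) and
#'   `truth` (data frame protein_id/family; decoys are absent from it).
#' @export
synth_strain <- function(profile, library, config = sim_config(),
                         strain_id = paste0("syn_", paste(profile,
                                                          collapse = ""))) {
  genes <- if (length(profile) == 1L && profile %in% names(type_profiles()))
    type_profiles()[[profile]] else profile
  stopifnot(all(genes %in% library$family))
  withr_seed(stage_seed(config$seed, paste0("strain_", strain_id)), {
    members <- lapply(genes, function(fam) {
      i <- match(fam, library$family)
      arch <- library$sequence[i]
      boxes <- if (!is.null(library$boxes)) library$boxes[[i]] else NULL
      mutate_seq(arch, config$mutation_rate, config, boxes = boxes)
    })
    names(members) <- paste0(strain_id, "|", genes)
    decoys <- character(0)
    if (config$decoys_per_strain > 0L) {
      src <- sample(seq_along(members), config$decoys_per_strain,
                    replace = TRUE)
      decoys <- vapply(src, function(i) shuffle_protein(members[[i]]),
                       character(1))
      names(decoys) <- paste0(strain_id, "|decoy_",
                              seq_len(config$decoys_per_strain))
    }
    proteome <- c(vapply(members, as.character, character(1)), decoys)
    list(strain_id = strain_id, proteome = proteome,
         truth = data.frame(protein_id = names(members), family = genes,
                            stringsAsFactors = FALSE))
  })
}

#' Synthesize annotated contigs for synteny tests
#'
#' Builds one linear contig per strain holding a shared target gene with
#' four upstream and four downstream flank genes. Flank positions listed
#' in `conserved_up` / `conserved_down` share a (optionally mutated)
#' protein across strains; all other flanks are independent random
#' proteins. Optionally plants a PfaA/PfaB pair, adjacent or separated.
#'
#' @param strain_ids Character vector of strain names.
#' @param conserved_up,conserved_down Integer flank positions (1 =
#'   nearest) shared across strains.
#' @param target_family Gene id used for the target locus in every strain.
#' @param config A `sim_config` (seed, mutation_rate applies to conserved
#'   flank copies in non-reference strains).
#' @param pfa_adjacent Optional logical vector per strain: plant
#'   PfaA/PfaB adjacent (`TRUE`) or separated by one gene (`FALSE`);
#'   `NULL` skips the pair.
#' @return Named list per strain: `features` (GFF-lite style data frame)
#'   and `proteome` (named character vector).
#' @export
synth_contig <- function(strain_ids, conserved_up = integer(0),
                         conserved_down = integer(0),
                         target_family = "DES_D9A",
                         config = sim_config(), pfa_adjacent = NULL) {
  window <- 4L
  stopifnot(all(conserved_up %in% seq_len(window)),
            all(conserved_down %in% seq_len(window)))
  withr_seed(stage_seed(config$seed, "contig_shared"), {
    shared_up <- lapply(seq_len(window), function(i) random_protein(220L))
    shared_down <- lapply(seq_len(window), function(i) random_protein(220L))
    target_seq <- random_protein(300L)
    pfa_seqs <- list(PfaA = random_protein(400L), PfaB = random_protein(400L))
  })
  out <- lapply(seq_along(strain_ids), function(si) {
    sid <- strain_ids[si]
    withr_seed(stage_seed(config$seed, paste0("contig_", sid)), {
      mut <- function(s) {
        if (si == 1L) s else mutate_seq(s, config$mutation_rate, config,
                                        boxes = NULL)
      }
      up_seqs <- lapply(seq_len(window), function(i) {
        if (i %in% conserved_up) mut(shared_up[[i]])
        else random_protein(220L)
      })
      down_seqs <- lapply(seq_len(window), function(i) {
        if (i %in% conserved_down) mut(shared_down[[i]])
        else random_protein(220L)
      })
      gene_ids <- c(paste0(sid, "_u", window:1), target_family,
                    paste0(sid, "_d", seq_len(window)))
      seqs <- c(rev(up_seqs), list(mut(target_seq)), down_seqs)
      if (!is.null(pfa_adjacent)) {
        adj <- pfa_adjacent[si]
        if (adj) {
          gene_ids <- c(gene_ids, "PfaA", "PfaB")
          seqs <- c(seqs, list(mut(pfa_seqs$PfaA), mut(pfa_seqs$PfaB)))
        } else {
          gene_ids <- c(gene_ids, "PfaA", paste0(sid, "_spacer"), "PfaB")
          seqs <- c(seqs, list(mut(pfa_seqs$PfaA), random_protein(200L),
                               mut(pfa_seqs$PfaB)))
        }
      }
      widths <- vapply(seqs, nchar, integer(1)) * 3L
      gaps <- sample(100:300, length(widths), replace = TRUE)
      starts <- cumsum(c(0L, head(widths + gaps, -1L)))
      features <- data.frame(
        gene_id = gene_ids,
        contig_id = paste0(sid, "_ctg1"),
        start = starts,
        end = starts + widths,
        strand = sample(c("+", "-"), length(widths), replace = TRUE),
        protein_id = paste0(sid, "|", gene_ids),
        stringsAsFactors = FALSE
      )
      proteome <- setNames(vapply(seqs, as.character, character(1)),
                           features$protein_id)
      list(features = features, proteome = proteome)
    })
  })
  names(out) <- strain_ids
  out
}

#' Evolve a sequence along a tree
#'
#' Each branch applies [mutate_seq()] with per-site probability
#' `min(1, rate_per_branch * branch length)`, independently per branch;
#' tips inherit the accumulated substitutions of their root path.
#'
#' @param tree A `phylo` tree with branch lengths.
#' @param root_sequence Sequence at the root.
#' @param rate_per_branch Substitution probability per unit branch length.
#' @param config A `sim_config` (seed).
#' @return Named character vector of tip sequences.
#' @export
evolve_along_tree <- function(tree, root_sequence, rate_per_branch = 1,
                              config = sim_config()) {
  tree <- ape::reorder.phylo(tree, "cladewise")  # parents precede children
  ntip <- length(tree$tip.label)
  root <- ntip + 1L
  seqs <- vector("list", ntip + tree$Nnode)
  seqs[[root]] <- as.character(root_sequence)
  withr_seed(stage_seed(config$seed, "evolve"), {
    for (e in seq_len(nrow(tree$edge))) {
      parent <- tree$edge[e, 1]; child <- tree$edge[e, 2]
      p <- min(1, rate_per_branch * tree$edge.length[e])
      seqs[[child]] <- mutate_seq(seqs[[parent]], p, config, boxes = NULL)
    }
  })
  setNames(unlist(seqs[seq_len(ntip)]), tree$tip.label)
}
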