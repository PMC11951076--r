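#' End-to-end pipeline orchestration
#'
#' `run_pipeline()` chains motif scan, best-hit assignment, matrix
#' construction, lineage typing, and (optionally) synteny and per-family
#' phylogeny over a set of proteomes, writing TSV/Newick outputs plus a
#' human-readable summary. Outputs are deterministic given config + seed;
#' every file carries a header comment with the tool version, a config
#' hash and the seed, and reruns are byte-identical.
#'
#' @name interface
NULL

#' Read / write protein FASTA
#'
#' Thin wrappers over Biostrings with named-character-vector semantics.
#'
#' @param path FASTA path.
#' @return `read_proteome`: named character vector of sequences.
#' @export
read_proteome <- function(path) {
  x <- Biostrings::readAAStringSet(path)
  setNames(as.character(x), names(x))
}

#' @rdname read_proteome
#' @param proteome Named character vector.
#' @export
write_proteome <- function(proteome, path) {
  Biostrings::writeXStringSet(Biostrings::AAStringSet(proteome), path)
  invisible(path)
}

pipeline_header <- function(config) {
  serial <- paste(deparse(config[order(names(config))]), collapse = "")
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(serial, tmp)
  hash <- unname(tools::md5sum(tmp))
  version <- as.character(utils::packageVersion("pufatyper"))
  sprintf("# pufatyper %s | config=%s | seed=%d", version, hash,
          config$seed)
}

write_tsv_with_header <- function(df, path, header) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(header, con)
  write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Run the full typing pipeline
#'
#' @param proteomes Named list (strain_id -> named character vector of
#'   protein sequences, or FASTA path). `NULL` with `simulate_profiles`
#'   set generates one synthetic strain per profile.
#' @param out_dir Output directory (created if missing).
#' @param seed Integer master seed.
#' @param simulate_profiles Optional character vector of lineage labels
#'   (e.g. `c("I","II","III","IV")`) to simulate when no proteomes are
#'   given.
#' @param matrix_tsv Optional path to a presence/absence TSV; when given,
#'   the scan/assign stages are skipped and only typing runs
#'   (matrix-only mode).
#' @param annotations Optional named list of feature tables for a synteny
#'   stage (see [synteny_conservation()]); requires `synteny_target`.
#' @param synteny_target Target gene id for the synteny stage.
#' @param phylo_family Optional panel family: member proteins across
#'   strains are aligned and an NJ tree (with `boot` bootstrap
#'   replicates) is written.
#' @param boot Bootstrap replicates for the phylo stage (0 = none).
#' @param min_norm_score Best-hit acceptance threshold.
#' @param mutation_rate Mutation rate for simulated strains.
#' @param quiet Suppress progress messages (never alters results).
#' @return Invisibly, a list with the typing report, assignment table,
#'   matrix, and paths of all written files.
#' @export
run_pipeline <- function(proteomes = NULL, out_dir, seed = 1L,
                         simulate_profiles = NULL, matrix_tsv = NULL,
                         annotations = NULL, synteny_target = NULL,
                         phylo_family = NULL, boot = 0L,
                         min_norm_score = 0.3, mutation_rate = 0.05,
                         quiet = FALSE) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  say <- function(...) if (!quiet) message(...)
  panel <- default_panel()
  registry <- default_signature_registry()
  config <- list(seed = as.integer(seed), min_norm_score = min_norm_score,
                 mutation_rate = mutation_rate,
                 simulate_profiles = simulate_profiles,
                 matrix_tsv = matrix_tsv, synteny_target = synteny_target,
                 phylo_family = phylo_family, boot = boot)
  header <- pipeline_header(config)
  paths <- list()
  cfg_path <- file.path(out_dir, "config.txt")
  writeLines(c(header, paste0(names(config), " = ",
                              vapply(config, function(x)
                                paste(deparse(x), collapse = ""),
                                character(1)))), cfg_path)
  paths$config <- cfg_path

  truth <- NULL
  if (!is.null(matrix_tsv)) {
    say("matrix-only mode: reading ", matrix_tsv)
    mat <- read_matrix_tsv(matrix_tsv, genes = panel)
    assignments <- NULL
  } else {
    if (is.null(proteomes)) {
      if (is.null(simulate_profiles)) {
        stop("input error: supply proteomes, simulate_profiles or ",
             "matrix_tsv", call. = FALSE)
      }
      say("simulating ", length(simulate_profiles), " strain(s)")
      cfg <- sim_config(seed = seed, mutation_rate = mutation_rate)
      lib <- make_reference_library(registry, panel, cfg)
      sims <- lapply(simulate_profiles, function(p) {
        synth_strain(p, lib, cfg, strain_id = paste0("syn_", p))
      })
      proteomes <- setNames(lapply(sims, `[[`, "proteome"),
                            vapply(sims, `[[`, character(1), "strain_id"))
      truth <- do.call(rbind, lapply(sims, `[[`, "truth"))
    } else {
      proteomes <- lapply(proteomes, function(p) {
        if (is.character(p) && length(p) == 1L && file.exists(p)) {
          read_proteome(p)
        } else p
      })
      cfg <- sim_config(seed = seed, mutation_rate = mutation_rate)
      lib <- make_reference_library(registry, panel, cfg)
    }
    say("assigning ", sum(lengths(proteomes)), " proteins across ",
        length(proteomes), " strain(s)")
    assignments <- do.call(rbind, lapply(names(proteomes), function(s) {
      a <- assign_proteome(proteomes[[s]], panel, lib, registry,
                           min_norm_score = min_norm_score, quiet = TRUE)
      if (nrow(a) > 0L) a$strain_id <- s
      a
    }))
    paths$assignments <- write_tsv_with_header(
      assignments, file.path(out_dir, "assignments.tsv"), header)
    strains <- data.frame(strain_id = names(proteomes),
                          stringsAsFactors = FALSE)
    mat <- presence_matrix(assignments, panel, strains)
  }
  paths$matrix <- file.path(out_dir, "matrix.tsv")
  tmp <- tempfile()
  write_matrix_tsv(mat, tmp)
  writeLines(c(header, readLines(tmp)), paths$matrix)
  unlink(tmp)

  say("typing ", nrow(mat$strains), " strain(s)")
  report <- summarize_typing(mat, panel)
  paths$typing <- write_tsv_with_header(
    report$calls, file.path(out_dir, "typing.tsv"), header)

  syn <- NULL
  if (!is.null(annotations)) {
    stopifnot(!is.null(synteny_target))
    say("synteny around ", synteny_target)
    syn <- synteny_conservation(synteny_target, annotations,
                                proteomes = proteomes,
                                min_norm_score = min_norm_score)
    paths$synteny <- write_tsv_with_header(
      syn$results, file.path(out_dir, "synteny.tsv"), header)
  }

  tree <- NULL
  if (!is.null(phylo_family) && !is.null(assignments)) {
    members <- assignments[assignments$family == phylo_family, ,
                           drop = FALSE]
    if (nrow(members) >= 2L) {
      say("tree for ", phylo_family, " (", nrow(members), " members)")
      seqs <- unlist(lapply(names(proteomes), function(s) {
        p <- proteomes[[s]]
        p[names(p) %in% members$protein_id[members$strain_id == s]]
      }))
      msa <- progressive_align(seqs)
      tree <- if (boot > 0L) {
        bootstrap_support(msa, n_reps = boot,
                          seed = stage_seed(seed, "bootstrap"))
      } else {
        nj_tree(p_distance_matrix(msa))
      }
      paths$tree <- file.path(out_dir, paste0(phylo_family, ".nwk"))
      con <- file(paths$tree, "w")
      writeLines(header, con)
      close(con)
      ape::write.tree(tree, paths$tree, append = TRUE)
    }
  }

  lineages <- report$calls$lineage[report$calls$clade_group ==
                                     "thraustochytrid"]
  summary_lines <- c(
    header,
    sprintf("strains typed: %d", nrow(report$calls)),
    sprintf("distinct lineages observed: %d",
            length(unique(lineages[lineages != "unclassified"]))),
    sprintf("complete PUFA-S: %d | complete ELO/DES: %d",
            report$counts$pufas_complete, report$counts$elodes_complete),
    sprintf("per-lineage: %s",
            paste(sprintf("%s=%d", names(report$counts$per_lineage),
                          report$counts$per_lineage), collapse = ", "))
  )
  paths$summary <- file.path(out_dir, "summary.txt")
  writeLines(summary_lines, paths$summary)

  invisible(list(report = report, assignments = assignments, matrix = mat,
                 truth = truth, synteny = syn, tree = tree, paths = paths))
}
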