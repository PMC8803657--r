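#' Pipeline configuration
#'
#' Assembles and checks the configuration driving [run_pipeline()]. Either
#' a sample sheet (TSV with columns sample_id, file, group, subset) or a
#' simulation block must be supplied. Round-trips through JSON unchanged.
#'
#' @param sample_sheet path to a sample-sheet TSV, or NULL to simulate
#' @param simulate named list for a simulated cohort: fields of
#'   [simulation_config()] plus `n_per_group`, `groups`, `effects`,
#'   `subset`
#' @param out_dir output directory (created if absent)
#' @param seed global seed
#' @param depths rarefaction depths; samples shallower than `min(depths)`
#'   are excluded from rarefied analyses (with a manifest warning)
#' @param replicates rarefaction replicates
#' @param indices diversity indices to rarefy
#' @param key_mode_oc,key_mode_frd clonotype species for overlap metrics
#' @param rarefied compute per-sample indices on repertoires subsampled to
#'   `min(depths)` (TRUE) or on full repertoires (FALSE); recorded in the
#'   manifest either way
#' @param test_method,p_adjust group-test settings
#' @param length_class CDR3 length class for positional amino-acid analyses
#' @param complexity_threshold spectratype complexity threshold
#' @return list of class `pipeline_config`
#' @export
pipeline_config <- function(sample_sheet = NULL, simulate = NULL,
                            out_dir = "repdiv_out", seed = 1L,
                            depths = c(4000L, 6000L, 8000L, 10000L, 12000L),
                            replicates = 3L,
                            indices = c("shannon", "simpson", "d50",
                                        "chao1", "top100"),
                            key_mode_oc = "nt", key_mode_frd = "nt_vj",
                            rarefied = FALSE,
                            test_method = "t_test", p_adjust = "BH",
                            length_class = 13L,
                            complexity_threshold = 0.01) {
  if (is.null(sample_sheet) && is.null(simulate)) {
    stop("pipeline_config needs a sample_sheet or a simulate block")
  }
  structure(list(
    sample_sheet = sample_sheet, simulate = simulate, out_dir = out_dir,
    seed = as.integer(seed), depths = as.integer(depths),
    replicates = as.integer(replicates), indices = indices,
    key_mode_oc = key_mode_oc, key_mode_frd = key_mode_frd,
    rarefied = isTRUE(rarefied), test_method = test_method,
    p_adjust = p_adjust, length_class = as.integer(length_class),
    complexity_threshold = complexity_threshold
  ), class = "pipeline_config")
}

#' Read a pipeline configuration from JSON
#' @param path JSON file with fields of [pipeline_config()]
#' @return a `pipeline_config`
#' @export
read_pipeline_config <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  do.call(pipeline_config, raw)
}

# Load cohort samples from a sample sheet.
.load_samples <- function(sheet_path) {
  sheet <- data.table::fread(sheet_path, sep = "\t", data.table = FALSE,
                             colClasses = "character")
  need <- c("sample_id", "file", "group", "subset")
  miss <- setdiff(need, names(sheet))
  if (length(miss)) {
    stop("sample sheet missing column(s): ", paste(miss, collapse = ", "))
  }
  base <- dirname(normalizePath(sheet_path))
  reps <- lapply(seq_len(nrow(sheet)), function(i) {
    f <- sheet$file[i]
    if (!file.exists(f)) f <- file.path(base, sheet$file[i])
    if (!file.exists(f)) stop("sample file not found: ", sheet$file[i])
    read_airr(f, sample_id = sheet$sample_id[i], group = sheet$group[i],
              subset = sheet$subset[i])
  })
  names(reps) <- sheet$sample_id
  reps
}

.write_tsv <- function(df, dir, name) {
  path <- file.path(dir, name)
  data.table::fwrite(df, path, sep = "\t", quote = FALSE)
  path
}

#' Run the full repertoire characterization pipeline
#'
#' Reads (or simulates) a cohort, then emits tidy TSV tables for every
#' analysis stage: per-sample diversity profiles, rarefaction curves,
#' V/D/J usage and V-J combination tables, pairwise overlap and distance
#' matrices, amino-acid composition and self-reactivity indices,
#' spectratype histograms and summaries, PCA scores/loadings, two-group
#' comparison tables, and a JSON manifest recording the seed, every
#' configurable decision in effect and any warnings. Deterministic:
#' reruns with the same configuration are byte-identical.
#'
#' @param cfg a [pipeline_config()] or path to its JSON serialization
#' @return invisibly, a named list of output file paths (plus the loaded
#'   repertoires in `$repertoires`)
#' @export
run_pipeline <- function(cfg) {
  if (is.character(cfg)) cfg <- read_pipeline_config(cfg)
  stopifnot(inherits(cfg, "pipeline_config"))
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  warnings_log <- character()
  note <- function(msg) warnings_log <<- c(warnings_log, msg)

  # --- load or simulate -----------------------------------------------
  if (!is.null(cfg$sample_sheet)) {
    reps <- .load_samples(cfg$sample_sheet)
  } else {
    sim <- cfg$simulate
    cfg_fields <- intersect(names(sim), names(formals(simulation_config)))
    base_cfg <- do.call(simulation_config,
                        c(sim[cfg_fields],
                          if (!"seed" %in% cfg_fields) list(seed = cfg$seed)))
    reps <- simulate_cohort(
      base_cfg,
      n_per_group = if (!is.null(sim$n_per_group)) sim$n_per_group else 4L,
      groups = if (!is.null(sim$groups)) sim$groups else c("WT", "KO"),
      effects = if (!is.null(sim$effects)) sim$effects else list(),
      subset = if (!is.null(sim$subset)) sim$subset else "CD4_TEM")
    for (id in names(reps)) {
      write_airr(reps[[id]], file.path(cfg$out_dir,
                                       paste0(id, ".airr.tsv")))
    }
  }
  outputs <- list()

  # --- depth handling --------------------------------------------------
  min_depth <- min(cfg$depths)
  deep_enough <- vapply(reps, function(r) r$total_count >= min_depth,
                        logical(1))
  if (!all(deep_enough)) {
    note(paste("excluded from rarefied analyses (total below",
               min_depth, "UMIs):",
               paste(names(reps)[!deep_enough], collapse = ", ")))
  }
  analysis_reps <- if (cfg$rarefied) {
    lapply(reps[deep_enough], function(r) {
      subsample(r, min_depth, seed = derive_seed(cfg$seed, 999L))
    })
  } else reps

  # --- per-sample diversity -------------------------------------------
  div <- do.call(rbind, lapply(analysis_reps, function(r) {
    row <- diversity_profile(r)$summary_row
    row$group <- r$group
    row$subset <- r$subset
    row
  }))
  outputs$diversity <- .write_tsv(div, cfg$out_dir, "diversity.tsv")

  hill <- do.call(rbind, lapply(analysis_reps, function(r) {
    h <- hill_curve(r)
    data.frame(sample_id = r$sample_id, h, stringsAsFactors = FALSE)
  }))
  outputs$hill <- .write_tsv(hill, cfg$out_dir, "hill_curves.tsv")

  # --- rarefaction -----------------------------------------------------
  raref <- do.call(rbind, lapply(reps[deep_enough], function(r) {
    do.call(rbind, lapply(cfg$indices, function(ix) {
      plan <- rarefaction_plan(cfg$depths[cfg$depths <= r$total_count],
                               replicates = cfg$replicates,
                               seed = derive_seed(cfg$seed, 7L))
      rarefy_index(r, plan, ix)
    }))
  }))
  if (!is.null(raref)) {
    outputs$rarefaction <- .write_tsv(raref, cfg$out_dir, "rarefaction.tsv")
  }

  # --- usage -----------------------------------------------------------
  usage_rows <- do.call(rbind, lapply(analysis_reps, function(r) {
    do.call(rbind, lapply(c("V", "D", "J"), function(ax) {
      do.call(rbind, lapply(c("total", "unique"), function(wt) {
        tab <- usage(r, ax, wt)
        data.frame(sample_id = r$sample_id, axis = ax, gene = names(tab),
                   weighting = wt, frequency = as.numeric(tab),
                   stringsAsFactors = FALSE)
      }))
    }))
  }))
  outputs$usage <- .write_tsv(usage_rows, cfg$out_dir, "usage.tsv")

  vj_rows <- do.call(rbind, lapply(analysis_reps, function(r) {
    tab <- combination_matrix(r, "VJ", "total")
    data.frame(sample_id = r$sample_id, combination = names(tab),
               frequency = as.numeric(tab), stringsAsFactors = FALSE)
  }))
  outputs$vj <- .write_tsv(vj_rows, cfg$out_dir, "vj_combinations.tsv")

  # --- overlap ---------------------------------------------------------
  rl <- unname(analysis_reps)
  if (length(rl) >= 2) {
    pairs <- do.call(rbind, lapply(seq_len(length(rl) - 1), function(i) {
      do.call(rbind, lapply((i + 1):length(rl), function(j) {
        repertoire_overlap(rl[[i]], rl[[j]], cfg$key_mode_oc,
                           cfg$key_mode_frd)
      }))
    }))
    outputs$overlap <- .write_tsv(pairs, cfg$out_dir, "overlap.tsv")
    dm <- distance_matrix(rl, "overlap", cfg$key_mode_oc)
    dm_df <- data.frame(sample_id = rownames(dm), as.data.frame(dm),
                        check.names = FALSE, stringsAsFactors = FALSE)
    outputs$distance <- .write_tsv(dm_df, cfg$out_dir,
                                   "distance_matrix.tsv")
  }

  # --- amino-acid features --------------------------------------------
  aa_rows <- do.call(rbind, lapply(analysis_reps, function(r) {
    comp <- aa_composition(r, "total")
    data.frame(sample_id = r$sample_id, residue = names(comp),
               frequency = as.numeric(comp), stringsAsFactors = FALSE)
  }))
  outputs$aa_composition <- .write_tsv(aa_rows, cfg$out_dir,
                                       "aa_composition.tsv")
  idx_rows <- do.call(rbind, lapply(analysis_reps, function(r) {
    has_class <- any(nchar(r$clonotypes$cdr3_aa[r$clonotypes$productive]) ==
                       cfg$length_class)
    if (!has_class) {
      note(paste0(r$sample_id, ": no CDR3 of length ", cfg$length_class,
                  "; hydrophobic index NA"))
    }
    data.frame(
      sample_id = r$sample_id, group = r$group,
      hydrophobic_index = if (has_class) {
        hydrophobic_index(r, cfg$length_class)
      } else NA_real_,
      cysteine_index = cysteine_index(r), stringsAsFactors = FALSE)
  }))
  outputs$aa_indices <- .write_tsv(idx_rows, cfg$out_dir, "aa_indices.tsv")

  # --- spectratype -----------------------------------------------------
  spec_rows <- do.call(rbind, lapply(analysis_reps, function(r) {
    do.call(rbind, lapply(c("total", "unique"), function(wt) {
      h <- length_distribution(r, wt)
      data.frame(sample_id = r$sample_id, length_nt = names(h),
                 weighting = wt, frequency = as.numeric(h),
                 stringsAsFactors = FALSE)
    }))
  }))
  outputs$spectratype <- .write_tsv(spec_rows, cfg$out_dir,
                                    "spectratype.tsv")
  spec_sum <- do.call(rbind, lapply(analysis_reps, function(r) {
    do.call(rbind, lapply(c("total", "unique"), function(wt) {
      p <- spectratype_profile(r, wt, cfg$complexity_threshold)
      data.frame(sample_id = r$sample_id, weighting = wt,
                 complexity = p$complexity, skewness = p$skewness,
                 stringsAsFactors = FALSE)
    }))
  }))
  outputs$spectratype_summary <- .write_tsv(spec_sum, cfg$out_dir,
                                            "spectratype_summary.tsv")

  # --- PCA and group comparisons --------------------------------------
  if (length(analysis_reps) >= 3) {
    fm <- assemble_features(unname(analysis_reps))
    if (ncol(fm) >= 2) {
      pca <- pca_segregation(fm, n_components = min(2L, ncol(fm)))
      sc <- data.frame(sample_id = rownames(pca$scores),
                       group = pca$groups, pca$scores,
                       stringsAsFactors = FALSE)
      outputs$pca_scores <- .write_tsv(sc, cfg$out_dir, "pca_scores.tsv")
    }
  }
  groups <- vapply(analysis_reps, function(r) r$group, character(1))
  glev <- unique(groups)
  if (length(glev) == 2 && all(table(groups) >= 2)) {
    a <- which(groups == glev[1])
    b <- which(groups == glev[2])
    feats <- c("shannon", "simpson_diversity", "simpson_dominance", "d50",
               "chao1", "top100", "richness", "total_count")
    cmp <- do.call(rbind, lapply(feats, function(f) {
      gt <- group_test(div[[f]][a], div[[f]][b],
                       method = cfg$test_method)
      data.frame(comparison = paste(glev, collapse = "_vs_"), feature = f,
                 statistic = gt$statistic, p = gt$p,
                 method = cfg$test_method, stringsAsFactors = FALSE)
    }))
    cmp$p_adjusted <- adjust_pvalues(cmp$p, cfg$p_adjust)
    outputs$comparisons <- .write_tsv(cmp, cfg$out_dir, "comparisons.tsv")

    ua <- lapply(analysis_reps[a], usage, "V", "total")
    ub <- lapply(analysis_reps[b], usage, "V", "total")
    if (length(ua) >= 2 && length(ub) >= 2) {
      cu <- compare_usage(ua, ub, method = cfg$test_method,
                          p_adjust = cfg$p_adjust,
                          seed = derive_seed(cfg$seed, 13L))
      outputs$usage_comparison <- .write_tsv(cu, cfg$out_dir,
                                             "usage_comparison.tsv")
    }
  }

  # --- manifest --------------------------------------------------------
  manifest <- list(
    package = "repdiv",
    seed = cfg$seed,
    settings = list(
      depths = cfg$depths, replicates = cfg$replicates,
      indices = cfg$indices, rarefied = cfg$rarefied,
      key_mode_overlap_coefficient = cfg$key_mode_oc,
      key_mode_f2_r_d = cfg$key_mode_frd,
      distance = "1 - overlap_coefficient",
      shannon_log_base = "e",
      d50_rule = "smallest k with cumulative frequency >= 0.5",
      chao1 = "classic, bias-corrected when f2 = 0",
      hydrophobic_doublet_set = "both residues in {A,C,F,I,L,M,V,W,Y}",
      cysteine_anchor = "midpoint, window 2, position-1 C excluded",
      complexity_threshold = cfg$complexity_threshold,
      length_class = cfg$length_class,
      test_method = cfg$test_method, p_adjust = cfg$p_adjust,
      pca = "z-scored features, largest loading forced positive"
    ),
    samples = data.frame(
      sample_id = vapply(reps, function(r) r$sample_id, character(1)),
      group = vapply(reps, function(r) r$group, character(1)),
      subset = vapply(reps, function(r) r$subset, character(1)),
      total_count = vapply(reps, function(r) r$total_count, integer(1)),
      richness = vapply(reps, function(r) richness(r), integer(1)),
      stringsAsFactors = FALSE),
    warnings = warnings_log
  )
  manifest_path <- file.path(cfg$out_dir, "manifest.json")
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)
  outputs$manifest <- manifest_path
  outputs$repertoires <- reps
  invisible(outputs)
}
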