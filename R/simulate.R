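# Synthetic germline-like nucleotide cores. These are stand-ins, NOT IMGT
# reference sequences: V cores open with the conserved cysteine codon
# (TGT) in the CASS-like frame, J cores close with a phenylalanine codon
# (TTC/TTT). Trimming never removes the protected conserved ends.
.SIM_V_STUBS <- c(
  "TRBV3"    = "TGTGCCAGCAGTTTAGC",
  "TRBV4"    = "TGTGCCAGCAGCCAAGA",
  "TRBV12-2" = "TGTGCCAGCAGTCTTGG",
  "TRBV15"   = "TGTGGTGCCAGCAGTGA",
  "TRBV20"   = "TGTGGAGCCAGAGATGA",
  "TRBV23"   = "TGTGCCAGCAGTGATGC",
  "TRBV30"   = "TGTGCCAGCAGCCGGGA",
  "TRBV31"   = "TGTGCCTGGAGTCTTGC"
)
.SIM_D_STUBS <- c(
  "TRBD1" = "GGGACAGGGGGC",
  "TRBD2" = "GGGACTGGGGGGGC"
)
.SIM_J_STUBS <- c(
  "TRBJ1-1" = "AACACAGAAGTCTTCTTT",
  "TRBJ1-3" = "TCTGGAAATACGCTCTATTTT",
  "TRBJ1-4" = "TCCAACGAAAGATTATTTT",
  "TRBJ1-5" = "AACCAGGCTCCGCTTTTT"
)
.SIM_V_PROTECT <- 6L   # keep TGTGCC (C-A) at the CDR3 start
.SIM_J_PROTECT <- 6L   # keep the terminal F codon region

#' Configuration for the synthetic TRB repertoire generator
#'
#' Parameterizes segment usage, junctional structure, the clone-size law
#' and sequencing depth. Defaults describe one realistic murine-like
#' sample: eight V genes with skewed usage, two D and four J genes,
#' geometric junctional trimming (mean 4 nt per end), Poisson N-region
#' insertions (mean 4 nt, GC-biased), productive-only output, a geometric
#' ("even", wild-type-like) clone-size law, and 12,000 UMIs — the deepest
#' standard rarefaction level.
#'
#' @param seed RNG seed (drives everything)
#' @param n_clonotypes number of distinct clonotypes to generate
#' @param depth total UMIs drawn across clonotypes
#' @param v_usage,d_usage,j_usage named nonnegative weight vectors
#'   (normalized internally); names must have stubs in
#'   `v_stubs`/`d_stubs`/`j_stubs`
#' @param v_stubs,d_stubs,j_stubs named nucleotide cores per segment
#' @param trim_mean mean geometric trim per junctional end (nt)
#' @param insert_mean mean Poisson N-region insertion length (nt)
#' @param insert_base_weights length-4 A/C/G/T weights for inserted bases
#' @param clone_size_law "uniform", "geometric", "powerlaw" or "lognormal"
#' @param clone_size_param law parameter: geometric success probability,
#'   power-law (Zipf) exponent, or lognormal sdlog
#' @param productive_only reject out-of-frame / stop-containing junctions
#' @param max_retries generation rounds before giving up
#' @return object of class `simulation_config`
#' @export
simulation_config <- function(seed = 1L,
                              n_clonotypes = 1000L,
                              depth = 12000L,
                              v_usage = c("TRBV4" = 0.18, "TRBV12-2" = 0.16,
                                          "TRBV15" = 0.13, "TRBV20" = 0.12,
                                          "TRBV23" = 0.11, "TRBV30" = 0.11,
                                          "TRBV31" = 0.10, "TRBV3" = 0.09),
                              d_usage = c("TRBD1" = 0.6, "TRBD2" = 0.4),
                              j_usage = c("TRBJ1-1" = 0.35, "TRBJ1-3" = 0.25,
                                          "TRBJ1-4" = 0.22, "TRBJ1-5" = 0.18),
                              v_stubs = .SIM_V_STUBS,
                              d_stubs = .SIM_D_STUBS,
                              j_stubs = .SIM_J_STUBS,
                              trim_mean = 4,
                              insert_mean = 4,
                              insert_base_weights = c(A = 0.2, C = 0.3,
                                                      G = 0.3, T = 0.2),
                              clone_size_law = c("geometric", "uniform",
                                                 "powerlaw", "lognormal"),
                              clone_size_param = NULL,
                              productive_only = TRUE,
                              max_retries = 50L) {
  clone_size_law <- match.arg(clone_size_law)
  if (is.null(clone_size_param)) {
    clone_size_param <- switch(clone_size_law,
      geometric = 0.5, powerlaw = 1.5, lognormal = 1, uniform = NA_real_)
  }
  norm_w <- function(w, stubs, what) {
    if (any(w < 0)) stop(what, " weights must be nonnegative")
    missing <- setdiff(names(w), names(stubs))
    if (length(missing)) {
      stop("no ", what, " stub for: ", paste(missing, collapse = ", "))
    }
    w / sum(w)
  }
  cfg <- list(
    seed = as.integer(seed),
    n_clonotypes = as.integer(n_clonotypes),
    depth = as.integer(depth),
    v_usage = norm_w(v_usage, v_stubs, "V"),
    d_usage = norm_w(d_usage, d_stubs, "D"),
    j_usage = norm_w(j_usage, j_stubs, "J"),
    v_stubs = v_stubs, d_stubs = d_stubs, j_stubs = j_stubs,
    trim_mean = trim_mean, insert_mean = insert_mean,
    insert_base_weights = insert_base_weights / sum(insert_base_weights),
    clone_size_law = clone_size_law,
    clone_size_param = clone_size_param,
    productive_only = isTRUE(productive_only),
    max_retries = as.integer(max_retries)
  )
  if (cfg$depth < 1 || cfg$n_clonotypes < 1) {
    stop("depth and n_clonotypes must be >= 1")
  }
  structure(cfg, class = "simulation_config")
}

# Random nucleotide strings of the given lengths.
.random_nt <- function(lens, base_weights) {
  total <- sum(lens)
  if (total == 0) return(rep("", length(lens)))
  bases <- sample(c("A", "C", "G", "T"), total, replace = TRUE,
                  prob = base_weights)
  out <- rep("", length(lens))
  idx <- rep.int(seq_along(lens), lens)
  nz <- lens > 0
  out[nz] <- vapply(split(bases, idx), paste, character(1), collapse = "")
  out
}

# One vectorized batch of candidate junctions.
.junction_batch <- function(cfg, n) {
  v <- sample(names(cfg$v_usage), n, replace = TRUE, prob = cfg$v_usage)
  d <- sample(names(cfg$d_usage), n, replace = TRUE, prob = cfg$d_usage)
  j <- sample(names(cfg$j_usage), n, replace = TRUE, prob = cfg$j_usage)
  p_trim <- 1 / (1 + cfg$trim_mean)
  vs <- unname(cfg$v_stubs[v])
  js <- unname(cfg$j_stubs[j])
  ds <- unname(cfg$d_stubs[d])
  tv <- pmin(rgeom(n, p_trim), nchar(vs) - .SIM_V_PROTECT)
  tj <- pmin(rgeom(n, p_trim), nchar(js) - .SIM_J_PROTECT)
  td5 <- rgeom(n, p_trim)
  td3 <- rgeom(n, p_trim)
  d_keep_from <- pmin(1 + td5, nchar(ds) + 1)
  d_keep_to <- pmax(nchar(ds) - td3, 0)
  d_part <- substr(ds, d_keep_from, d_keep_to)
  n1 <- .random_nt(rpois(n, cfg$insert_mean), cfg$insert_base_weights)
  n2 <- .random_nt(rpois(n, cfg$insert_mean), cfg$insert_base_weights)
  junction <- paste0(substr(vs, 1, nchar(vs) - tv), n1, d_part, n2,
                     substr(js, 1 + tj, nchar(js)))
  data.frame(cdr3_nt = junction, v_gene = v, d_gene = d, j_gene = j,
             stringsAsFactors = FALSE)
}

#' Simulate one TRB repertoire with known ground truth
#'
#' Generates `n_clonotypes` distinct clonotypes by sampling V/D/J segments
#' from the configured usage weights, trimming the synthetic germline
#' cores geometrically, inserting Poisson-length N-regions, and (when
#' `productive_only`) rejecting out-of-frame or stop-containing junctions.
#' Clone-size weights are drawn from the configured law and `depth` UMIs
#' are then allocated multinomially; clonotypes receiving zero UMIs are
#' absent from the observed repertoire but present in the ground truth.
#' Byte-reproducible from `cfg$seed`.
#'
#' @param cfg a [simulation_config()]
#' @param sample_id,group,subset metadata for the emitted repertoire
#' @return list with elements `repertoire` (a validated
#'   `tcr_repertoire`) and `ground_truth` (true richness, clone-size
#'   weights, usage weights, config)
#' @export
simulate_repertoire <- function(cfg, sample_id = "sim", group = "other",
                                subset = "other") {
  stopifnot(inherits(cfg, "simulation_config"))
  with_seed(cfg$seed, {
    pool <- NULL
    n_left <- cfg$n_clonotypes
    for (round in seq_len(cfg$max_retries)) {
      if (n_left <= 0) break
      batch_n <- max(50L, ceiling(n_left * if (cfg$productive_only) 6 else 1.5))
      cand <- .junction_batch(cfg, batch_n)
      if (cfg$productive_only) {
        inframe <- nchar(cand$cdr3_nt) %% 3 == 0
        cand <- cand[inframe, , drop = FALSE]
        if (nrow(cand)) {
          aa <- translate_cdr3(cand$cdr3_nt)
          cand <- cand[!grepl("*", aa, fixed = TRUE), , drop = FALSE]
        }
      }
      pool <- rbind(pool, cand)
      # enforce key-distinct clonotypes so ground-truth richness is exact
      pool <- pool[!duplicated(clonotype_key(pool, "nt_vj")), , drop = FALSE]
      n_left <- cfg$n_clonotypes - nrow(pool)
    }
    if (n_left > 0) {
      stop("junction generation failed to produce ", cfg$n_clonotypes,
           " productive distinct clonotypes within ", cfg$max_retries,
           " rounds; check stub/trim configuration")
    }
    pool <- pool[seq_len(cfg$n_clonotypes), , drop = FALSE]
    sizes <- switch(cfg$clone_size_law,
      uniform = rep(1, cfg$n_clonotypes),
      geometric = rgeom(cfg$n_clonotypes, cfg$clone_size_param) + 1,
      powerlaw = seq_len(cfg$n_clonotypes)^(-cfg$clone_size_param),
      lognormal = rlnorm(cfg$n_clonotypes, meanlog = 0,
                         sdlog = cfg$clone_size_param))
    counts <- as.integer(rmultinom(1, cfg$depth, prob = sizes))
    keep <- counts > 0L
    cl <- pool[keep, , drop = FALSE]
    cl$count <- counts[keep]
    cl$cdr3_aa <- translate_cdr3(cl$cdr3_nt)
    rep <- repertoire(cl, sample_id = sample_id, group = group,
                      subset = subset,
                      productive_only = cfg$productive_only)
    list(
      repertoire = rep,
      ground_truth = list(
        richness = cfg$n_clonotypes,
        clone_size_weights = sizes / sum(sizes),
        v_usage = cfg$v_usage, d_usage = cfg$d_usage, j_usage = cfg$j_usage,
        clone_size_law = cfg$clone_size_law,
        clone_size_param = cfg$clone_size_param,
        config = cfg
      )
    )
  })
}

#' Simulate a two-group cohort
#'
#' Draws `n_per_group` samples per group from a shared base configuration,
#' with deterministic per-sample seeds derived from the base seed. Group
#' effects perturb the base configuration: `v_usage_delta` (named additive
#' shifts to V-usage weights, renormalized), `clone_size_law` and
#' `clone_size_param` overrides emulate clonal expansion.
#'
#' @param base_cfg a [simulation_config()]
#' @param n_per_group samples per group
#' @param groups group labels (default WT and KO)
#' @param effects named list (by group label) of effect lists; groups
#'   without an entry use the base configuration
#' @param subset cell-subset label stamped on every sample
#' @param depth_cv lognormal coefficient of variation of the per-sample
#'   UMI depth around the base depth (default 0.15, emulating variable
#'   per-sample sequencing yield; 0 gives identical depths)
#' @return list of `tcr_repertoire`s with attributes `ground_truths` and
#'   `effects`
#' @export
simulate_cohort <- function(base_cfg, n_per_group = 8L,
                            groups = c("WT", "KO"), effects = list(),
                            subset = "CD4_TEM", depth_cv = 0.15) {
  stopifnot(inherits(base_cfg, "simulation_config"))
  unknown <- setdiff(names(effects), groups)
  if (length(unknown)) stop("effects for unknown group(s): ",
                            paste(unknown, collapse = ", "))
  reps <- list()
  truths <- list()
  i <- 0L
  for (g in groups) {
    cfg_g <- base_cfg
    eff <- effects[[g]]
    if (!is.null(eff)) {
      if (!is.null(eff$v_usage_delta)) {
        bad <- setdiff(names(eff$v_usage_delta), names(cfg_g$v_usage))
        if (length(bad)) {
          stop("usage effect references unknown gene(s): ",
               paste(bad, collapse = ", "))
        }
        w <- cfg_g$v_usage
        w[names(eff$v_usage_delta)] <- w[names(eff$v_usage_delta)] +
          eff$v_usage_delta
        if (any(w < 0)) stop("usage effect drives a weight negative")
        cfg_g$v_usage <- w / sum(w)
      }
      if (!is.null(eff$clone_size_law)) {
        cfg_g$clone_size_law <- eff$clone_size_law
        cfg_g$clone_size_param <- if (!is.null(eff$clone_size_param)) {
          eff$clone_size_param
        } else {
          switch(eff$clone_size_law, geometric = 0.5, powerlaw = 1.5,
                 lognormal = 1, uniform = NA_real_)
        }
      } else if (!is.null(eff$clone_size_param)) {
        cfg_g$clone_size_param <- eff$clone_size_param
      }
    }
    for (s in seq_len(n_per_group)) {
      i <- i + 1L
      cfg_i <- cfg_g
      cfg_i$seed <- derive_seed(base_cfg$seed, i)
      if (depth_cv > 0) {
        jitter <- with_seed(derive_seed(cfg_i$seed, 31L),
                            exp(rnorm(1, 0, depth_cv)))
        cfg_i$depth <- max(1L, as.integer(round(cfg_g$depth * jitter)))
      }
      id <- sprintf("%s_%s_%02d", g, subset, s)
      sim <- simulate_repertoire(cfg_i, sample_id = id, group = g,
                                 subset = subset)
      reps[[id]] <- sim$repertoire
      truths[[id]] <- sim$ground_truth
    }
  }
  structure(reps, ground_truths = truths, effects = effects)
}
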