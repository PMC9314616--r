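#' Run configuration for the end-to-end pipeline
#'
#' A single global seed fans out (by hashing) to per-stage seeds, so the
#' whole run is a pure function of its configuration.
#'
#' @param seed Global integer seed.
#' @param stages Character vector of stages to run, a subset of
#'   `c("simulate", "inherit", "features", "classify", "vision")`.
#' @param sim A [sim_config()] (its own seed is overridden by the derived
#'   stage seed).
#' @param app An [appearance_config()].
#' @param n_per_genotype Cohort sizes for the image stages.
#' @param cohort_sex Sex of the image cohort.
#' @return List of class `run_config`.
#' @export
run_config <- function(seed = 1L,
                       stages = c("simulate", "inherit", "features",
                                  "classify", "vision"),
                       sim = sim_config(),
                       app = appearance_config(),
                       n_per_genotype = c(WW = 37L, Wy = 88L, yy = 42L),
                       cohort_sex = "male") {
  stages <- match.arg(stages, c("simulate", "inherit", "features",
                                "classify", "vision"), several.ok = TRUE)
  structure(list(seed = check_count(seed, "seed", min = 0L), stages = stages,
                 sim = sim, app = app, n_per_genotype = n_per_genotype,
                 cohort_sex = cohort_sex),
            class = "run_config")
}

#' Read a run configuration from YAML or JSON
#'
#' Recognised top-level keys: `seed`, `stages`, `sim` (fields of
#' [sim_config()]), `n_per_genotype`, `cohort_sex`.
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` file.
#' @return A `run_config`.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  raw <- if (grepl("\\.ya?ml$", path)) {
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
  sim <- if (is.null(raw$sim)) sim_config() else do.call(sim_config, raw$sim)
  args <- list(sim = sim, app = appearance_config())
  for (k in c("seed", "stages", "cohort_sex")) {
    if (!is.null(raw[[k]])) args[[k]] <- raw[[k]]
  }
  if (!is.null(raw$n_per_genotype)) {
    args$n_per_genotype <- unlist(raw$n_per_genotype)
  }
  do.call(run_config, args)
}

#' Inheritance analysis over a pedigree
#'
#' Composes the Mendelian stage: tabulates family phenotype counts,
#' infers each family's cross by maximum likelihood, runs the pooled
#' segregation test against the inferred crosses, and (for components small
#' enough) back-traces individual genotype probabilities.
#'
#' @param pedigree Pedigree data frame or path to a pedigree CSV.
#' @param founder_prior_W Founder W frequency for the back-trace.
#' @param propagate Run the per-individual back-trace? (Enumeration is
#'   exponential in component size; disable for large linked pedigrees.)
#' @param cap Component size cap for the back-trace.
#' @return List: `families` (counts), `inference` (per-family ML crosses),
#'   `segregation` (pooled `chisq_gof`), `marginals` (per-individual, or
#'   `NULL`).
#' @export
run_inheritance <- function(pedigree, founder_prior_W = 0.5,
                            propagate = FALSE, cap = 12L) {
  if (is.character(pedigree)) pedigree <- read_pedigree(pedigree)
  fam <- family_phenotype_counts(pedigree)
  inference <- infer_families(fam)
  fam$cross <- vapply(seq_len(nrow(fam)), function(i) {
    ml <- inference$ml_set[i]
    if (is.na(ml)) return(NA_character_)
    strsplit(ml, ";", fixed = TRUE)[[1]][1]
  }, character(1))
  fam$excluded <- fam$excluded | is.na(fam$cross)
  seg <- pooled_segregation_test(fam)
  marginals <- if (propagate) {
    propagate_pedigree_genotypes(pedigree, founder_prior_W, cap = cap)
  }
  list(families = fam, inference = inference, segregation = seg,
       marginals = marginals)
}

#' Run the full pipeline and write an artifact bundle
#'
#' Stages in order: simulate (pedigree CSV + image cohort), inherit
#' (per-family inference CSV + segregation test JSON), features (feature
#' CSV + correlation-filter report), classify (LOO confusion CSV +
#' discriminant scores CSV + shadow importance CSV), vision (pairwise dS
#' CSV + summary CSV). A manifest JSON records the seeds, stage outputs and
#' their MD5 hashes; a fixed config reproduces the bundle byte-for-byte
#' (minus the manifest timestamp).
#'
#' @param config A [run_config()].
#' @param out_dir Output directory, created if needed.
#' @param shadow_iters Shadow-selection iterations (`0` skips the shadow
#'   screen, which dominates runtime).
#' @return Invisibly, the manifest list.
#' @export
run_full <- function(config = run_config(), out_dir, shadow_iters = 0L) {
  stopifnot(inherits(config, "run_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  outputs <- character(0)
  put <- function(df, name) {
    path <- file.path(out_dir, name)
    utils::write.csv(df, path, row.names = FALSE)
    outputs <<- c(outputs, path)
    path
  }
  cohort <- NULL
  features <- NULL

  if ("simulate" %in% config$stages) {
    sim <- config$sim
    sim$seed <- derive_seed(config$seed, 1L, 101L)
    fams <- simulate_families(sim)
    put(fams$pedigree, "pedigree.csv")
    put(fams$families, "families.csv")
    cohort <- generate_cohort(config$n_per_genotype, config$cohort_sex,
                              config$app,
                              seed = derive_seed(config$seed, 2L, 101L))
    put(cohort$truth, "cohort_truth.csv")
  }

  if ("inherit" %in% config$stages) {
    ped_path <- file.path(out_dir, "pedigree.csv")
    if (!file.exists(ped_path)) {
      stop("inherit stage needs pedigree.csv (run the simulate stage or ",
           "provide one in out_dir)", call. = FALSE)
    }
    inh <- run_inheritance(ped_path)
    put(inh$inference, "cross_inference.csv")
    seg_path <- file.path(out_dir, "segregation_test.json")
    jsonlite::write_json(
      list(statistic = inh$segregation$statistic, df = inh$segregation$df,
           p_value = inh$segregation$p_value),
      seg_path, auto_unbox = TRUE, digits = NA)
    outputs <- c(outputs, seg_path)
  }

  if ("features" %in% config$stages) {
    if (is.null(cohort)) stop("features stage needs the simulate stage",
                              call. = FALSE)
    features <- build_feature_table(cohort)
    put(features, "features.csv")
    filt <- drop_correlated_features(features)
    rep_path <- file.path(out_dir, "correlation_filter.json")
    jsonlite::write_json(list(retained = filt$retained,
                              dropped = filt$dropped),
                         rep_path, auto_unbox = TRUE, digits = NA)
    outputs <- c(outputs, rep_path)
  }

  if ("classify" %in% config$stages) {
    if (is.null(features)) stop("classify stage needs the features stage",
                                call. = FALSE)
    xnum <- features[!features$failed, ]
    loo <- evaluate_loo(xnum, xnum$genotype)
    conf <- as.data.frame(loo$confusion)
    conf$accuracy <- loo$accuracy
    put(conf, "confusion.csv")
    model <- fit_discriminant(xnum, xnum$genotype)
    scores <- as.data.frame(project(model, xnum))
    scores <- cbind(id = xnum$id, genotype = xnum$genotype, scores)
    put(scores, "scores.csv")
    if (shadow_iters >= 20L) {
      imp <- shadow_feature_selection(xnum, xnum$genotype,
                                      n_iter = shadow_iters,
                                      seed = derive_seed(config$seed, 3L, 101L))
      put(imp$decisions, "importance.csv")
    }
  }

  if ("vision" %in% config$stages) {
    if (is.null(features)) stop("vision stage needs the features stage",
                                call. = FALSE)
    contrasts <- pairwise_contrast_table(features[!features$failed, ])
    put(contrasts, "contrasts.csv")
    put(discriminability_summary(contrasts), "contrast_summary.csv")
  }

  manifest <- list(
    seed = config$seed,
    stages = config$stages,
    stage_seeds = list(simulate = derive_seed(config$seed, 1L, 101L),
                       cohort = derive_seed(config$seed, 2L, 101L),
                       shadow = derive_seed(config$seed, 3L, 101L)),
    outputs = stats::setNames(as.list(unname(tools::md5sum(outputs))),
                              basename(outputs))
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}

#' Summarise a pipeline bundle
#'
#' Reads a bundle directory written by [run_full()] and returns four
#' summary tables: offspring phenotype frequencies per inferred cross,
#' discriminant scores by genotype, classifier accuracy, and chromatic
#' contrast by genotype pair, ROI and receiver.
#'
#' @param bundle_dir Directory written by [run_full()].
#' @return Named list of data frames: `phenotype_frequencies`,
#'   `discriminant_scores`, `classifier_accuracy`, `contrast_summary`
#'   (entries present for the stages that ran).
#' @export
bundle_report <- function(bundle_dir) {
  if (!file.exists(file.path(bundle_dir, "manifest.json"))) {
    stop("not a pipeline bundle (no manifest.json): ", bundle_dir,
         call. = FALSE)
  }
  rd <- function(name) {
    path <- file.path(bundle_dir, name)
    if (file.exists(path)) utils::read.csv(path, stringsAsFactors = FALSE)
  }
  out <- list()

  fams <- rd("families.csv")
  inf <- rd("cross_inference.csv")
  if (!is.null(fams) && !is.null(inf)) {
    fams$inferred <- inf$identifiability_class[match(fams$family, inf$family)]
    keep <- !is.na(fams$inferred)
    agg <- stats::aggregate(
      cbind(white_males, yellow_males) ~ inferred, data = fams[keep, ], FUN = sum)
    agg$white_fraction <- agg$white_males /
      (agg$white_males + agg$yellow_males)
    out$phenotype_frequencies <- agg
  }

  scores <- rd("scores.csv")
  if (!is.null(scores)) {
    out$discriminant_scores <- stats::aggregate(
      cbind(LD1, LD2) ~ genotype, data = scores, FUN = mean)
  }

  conf <- rd("confusion.csv")
  if (!is.null(conf)) out$classifier_accuracy <- conf

  cs <- rd("contrast_summary.csv")
  if (!is.null(cs)) out$contrast_summary <- cs

  if (!length(out)) stop("bundle contains no summarisable outputs",
                         call. = FALSE)
  out
}
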