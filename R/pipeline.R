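#' Configuration for a full signature-discovery run
#'
#' Collects every stage parameter with defaults equal to the published
#' analysis values where one exists: missingness threshold 0.10, PRU
#' threshold 234, alpha 0.05, odds-ratio threshold 10, 100 bootstrap
#' iterations, 80/20 train/validation split. A single master `seed` is
#' fanned out to per-stage seeds.
#'
#' @param out_dir Directory for stage outputs and the manifest.
#' @param cohort A [cohort_spec()] describing the synthetic cohort to
#'   simulate, or `NULL` to read `genotypes_path`/`phenotypes_path` instead.
#' @param genotypes_path,phenotypes_path Input files used when `cohort` is
#'   `NULL`.
#' @param missing_threshold,pru_threshold,alpha,or_threshold,contrast QC and
#'   association parameters. The default contrast is `case_control` because
#'   the synthetic generator plants its odds ratios between the case and
#'   control arms; use `"resistance"` to contrast resistant vs non-resistant
#'   patients as in the published filter.
#' @param n_iterations,train_fraction,top_k,rank_methods Consensus-ranking
#'   parameters.
#' @param eval_models,max_features,tolerance Evaluation-sweep parameters.
#' @param annotation_filter Restrict the sweep to gene-annotated SNPs.
#' @param edges_path PPI edge list TSV (default: the packaged synthetic
#'   example network).
#' @param seed Master seed.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(out_dir,
                            cohort = cohort_spec(causal_genes = c("IQSEC1", "PSD3", "BTBD7", "GLIS3", "LRBA")),
                            genotypes_path = NULL, phenotypes_path = NULL,
                            missing_threshold = 0.10, pru_threshold = 234,
                            alpha = 0.05, or_threshold = 10,
                            contrast = c("case_control", "resistance"),
                            n_iterations = 100, train_fraction = 0.8,
                            top_k = 20,
                            rank_methods = c("forest", "svm", "lasso"),
                            eval_models = c("forest", "svm", "tree", "xgboost"),
                            max_features = 10, tolerance = 0.005,
                            annotation_filter = FALSE,
                            edges_path = system.file("extdata", "ppi_edges_synthetic.tsv",
                                                     package = "clopisig"),
                            seed = 1L) {
  if (is.null(cohort) && (is.null(genotypes_path) || is.null(phenotypes_path))) {
    abort("either `cohort` or both `genotypes_path` and `phenotypes_path` must be given.")
  }
  structure(
    list(out_dir = out_dir, cohort = cohort,
         genotypes_path = genotypes_path, phenotypes_path = phenotypes_path,
         missing_threshold = missing_threshold, pru_threshold = pru_threshold,
         alpha = alpha, or_threshold = or_threshold,
         contrast = match.arg(contrast),
         n_iterations = n_iterations, train_fraction = train_fraction,
         top_k = top_k, rank_methods = rank_methods,
         eval_models = eval_models, max_features = max_features,
         tolerance = tolerance, annotation_filter = annotation_filter,
         edges_path = edges_path, seed = as.integer(seed)),
    class = "pipeline_config"
  )
}

run_stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    abort(sprintf("pipeline stage '%s' failed: %s", name, conditionMessage(e)))
  })
}

#' Run the full signature-discovery pipeline
#'
#' Executes simulate (or load) -> qc -> association -> consensus ranking ->
#' evaluation -> network in order, writing each stage's outputs under
#' `config$out_dir` before the next stage starts, and finishes with a
#' machine-readable `manifest.json` recording the configuration, seed,
#' package version and per-stage record counts. Re-running with the same
#' configuration reproduces byte-identical analytic outputs. A stage
#' failure aborts with the stage name; outputs already written are kept.
#'
#' @param config A [pipeline_config()].
#' @return Invisibly, a list with all stage results and the manifest.
#' @export
run_pipeline <- function(config) {
  if (!inherits(config, "pipeline_config")) abort("`config` must be a pipeline_config.")
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  out <- function(f) file.path(config$out_dir, f)
  stage_seeds <- withr::with_seed(config$seed, sample.int(1e8, 4))
  stages <- list()

  # 1: cohort --------------------------------------------------------------
  if (!is.null(config$cohort)) {
    cspec <- config$cohort
    cspec$seed <- stage_seeds[1]
    sim <- run_stage("simulate", simulate_cohort(cspec))
    genotypes <- sim$genotypes
    phenotypes <- sim$phenotypes
    run_stage("simulate", {
      write_genotypes(genotypes, out("genotypes.tsv"))
      write_phenotypes(phenotypes, out("phenotypes.tsv"))
      readr::write_tsv(genotypes$snp_meta, out("annotation.tsv"), na = "NA")
      writeLines(sim$causal_snps, out("causal_snps.txt"))
    })
  } else {
    sim <- NULL
    genotypes <- run_stage("load", read_genotypes(config$genotypes_path))
    phenotypes <- run_stage("load", read_phenotypes(config$phenotypes_path))
  }
  stages$simulate <- c(n_subjects = nrow(genotypes$calls),
                       n_snps = ncol(genotypes$calls))

  # 2: qc -------------------------------------------------------------------
  qc <- run_stage("qc", {
    q <- filter_snps(genotypes, config$missing_threshold)
    phenotypes <- label_resistance(phenotypes, config$pru_threshold)
    readr::write_tsv(q$per_snp, out("qc_per_snp.tsv"), na = "NA")
    jsonlite::write_json(as.list(q$summary), out("qc_summary.json"),
                         auto_unbox = TRUE)
    q
  })
  stages$qc <- unlist(qc$summary)

  # 3: association ----------------------------------------------------------
  assoc <- run_stage("association", {
    a <- snp_association(qc$genotypes, phenotypes, contrast = config$contrast,
                         alpha = config$alpha, or_threshold = config$or_threshold)
    readr::write_tsv(a, out("association.tsv"), na = "NA")
    a
  })
  filtered_ids <- assoc$snp_id[assoc$pass]
  stages$association <- c(n_tested = sum(!assoc$untestable),
                          n_pass = length(filtered_ids))
  if (length(filtered_ids) < 2) {
    abort(sprintf("pipeline stage 'association' failed: only %d SNP(s) pass the p < %g & OR > %g filter.",
                  length(filtered_ids), config$alpha, config$or_threshold))
  }

  # 4: consensus ranking ----------------------------------------------------
  labels <- association_labels(phenotypes, config$contrast)
  top_k_eff <- min(config$top_k, length(filtered_ids))
  ranking <- run_stage("rank", {
    r <- consensus_rank(qc$genotypes[, filtered_ids], labels,
                        n_iterations = config$n_iterations,
                        train_fraction = config$train_fraction,
                        top_k = top_k_eff, methods = config$rank_methods,
                        seed = stage_seeds[2])
    readr::write_tsv(r$counts, out("ranking.tsv"))
    jsonlite::write_json(r$top_sets, out("ranking_log.json"))
    r
  })
  stages$rank <- c(n_ranked = nrow(ranking$counts),
                   total_count = sum(ranking$counts$count))

  # 5: evaluation -----------------------------------------------------------
  curve <- run_stage("evaluate", {
    ann <- if (config$annotation_filter) genotypes$snp_meta else NULL
    cv <- evaluate_curve(qc$genotypes, labels, ranking,
                         models = config$eval_models,
                         max_features = min(config$max_features, length(filtered_ids)),
                         seed = stage_seeds[3], tolerance = config$tolerance,
                         annotation = ann)
    readr::write_tsv(cv$curve, out("curve.tsv"))
    jsonlite::write_json(cv$selection, out("selection.json"),
                         auto_unbox = TRUE, digits = NA)
    gf <- test_genotype_frequencies(qc$genotypes, labels,
                                    snp_ids = cv$selection$snp_ids)
    readr::write_tsv(gf, out("genotype_frequencies.tsv"), na = "NA")
    cv
  })
  stages$evaluate <- c(n_models = length(config$eval_models),
                       selected_n_features = curve$selection$n_features)

  # 6: network --------------------------------------------------------------
  network <- run_stage("network", {
    meta <- genotypes$snp_meta
    genes <- meta$gene[match(curve$selection$snp_ids, meta$snp_id)]
    genes <- unique(genes[!is.na(genes) & genes != ""])
    if (length(genes) == 0) {
      warn("no selected SNP maps to an annotated gene; skipping network construction.")
      NULL
    } else {
      net <- build_subnetwork(read_edge_list(config$edges_path), genes)
      readr::write_tsv(net$nodes, out("network_nodes.tsv"))
      readr::write_tsv(net$edges, out("network_edges.tsv"))
      readr::write_tsv(component_summary(net), out("network_components.tsv"))
      net
    }
  })
  stages$network <- c(
    n_nodes = if (is.null(network)) 0L else nrow(network$nodes),
    n_edges = if (is.null(network)) 0L else nrow(network$edges)
  )

  manifest <- list(
    package = "clopisig",
    version = as.character(packageVersion("clopisig")),
    seed = config$seed,
    config = config[setdiff(names(config), c("cohort"))],
    cohort = if (!is.null(config$cohort)) unclass(config$cohort) else NULL,
    stages = lapply(stages, as.list)
  )
  jsonlite::write_json(manifest, out("manifest.json"), auto_unbox = TRUE,
                       null = "null", digits = NA)

  invisible(list(cohort = sim, genotypes = genotypes, phenotypes = phenotypes,
                 qc = qc, association = assoc, ranking = ranking,
                 curve = curve, network = network, manifest = manifest))
}
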