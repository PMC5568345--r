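## End-to-end orchestration: simulate (or load) -> DE scan -> sub-model
## classification -> parental model -> sPLS / Q2 / MSEP / network ->
## phenotype ANOVA -> enrichment -> qPCR validation.  Every stage writes its
## table under the run directory; a JSON manifest records the seed, the
## thresholds and the checksum of every artifact, so identical configs give
## identical runs.

#' Default pipeline configuration
#'
#' Thresholds mirror the study: DE scan FDR 0.01, parental-model FDR 0.05,
#' fold-change gate |log2FC| >= 0.5, Q2 retention > 0.09, network cutoff
#' 0.75, 5-fold cross-validation.
#'
#' @param seed master seed; all stage seeds derive from it.
#' @param out_dir run directory (created).
#' @return named list of configuration entries.
#' @export
pipelineConfig <- function(seed = 1L, out_dir = tempfile("maturix_run_")) {
  list(
    seed = as.integer(seed), out_dir = out_dir,
    # synthetic-data block (used when no expr/design paths are given)
    n_sows_per_breed = 8L, n_fetuses_per_sow = 4L, n_probes = 2000L,
    class_proportions = c(0.8, 0.05, 0.05, 0.05, 0.05),
    effect_size = 1, sow_sd = 0.15, resid_sd = 0.3,
    n_phenotypes = 23L, n_drivers = 20L, driver_weight = 1,
    pheno_noise_sd = 1,
    # input paths (override the simulation when all are set)
    expr_path = NULL, design_path = NULL, pheno_path = NULL,
    gmt_path = NULL,
    # thresholds
    alpha_fdr_de = 0.01, alpha_fdr_parental = 0.05,
    min_abs_log2fc = 0.5, q2_min = 0.09, network_cutoff = 0.75,
    n_folds = 5L, n_components = 4L, keepX = 50L)
}

.validateConfig <- function(config) {
  def <- pipelineConfig()
  config <- utils::modifyList(def, config[!vapply(config, is.null, TRUE)])
  with(config, {
    stopifnot(alpha_fdr_de >= 0, alpha_fdr_de <= 1,
              alpha_fdr_parental >= 0, alpha_fdr_parental <= 1,
              min_abs_log2fc >= 0, q2_min < 1,
              network_cutoff > 0, network_cutoff < 1,
              n_folds >= 2, n_components >= 1)
  })
  config
}

#' Read a pipeline configuration from YAML
#' @param path YAML file; entries override \code{\link{pipelineConfig}}
#'   defaults.
#' @return configuration list.
#' @export
readPipelineConfig <- function(path) {
  .validateConfig(yaml::read_yaml(path))
}

#' Run the full analysis pipeline
#'
#' Executes every stage in order and writes all intermediate tables, a
#' machine-readable manifest (package version, seed, config, artifact
#' checksums) and a summary (DEP counts per sub-model, best-predicted
#' phenotypes by MSEP, network size, and — for synthetic runs — the
#' sub-model confusion matrix against the planted truth).
#'
#' @param config list from \code{\link{pipelineConfig}} or
#'   \code{\link{readPipelineConfig}}; missing entries take defaults.
#' @return invisibly, a list with the stage results and the manifest.
#' @export
runPipeline <- function(config = pipelineConfig()) {
  config <- .validateConfig(config)
  out <- config$out_dir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  artifacts <- character(0)
  stage <- "init"
  manifest <- list(package = "maturix",
                   version = as.character(utils::packageVersion("maturix")),
                   seed = config$seed,
                   config = config[setdiff(names(config), "out_dir")])
  fail <- function(e) {
    manifest$failed_stage <- stage
    manifest$error <- conditionMessage(e)
    jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA,
                         force = TRUE)
    stop("pipeline failed at stage '", stage, "': ", conditionMessage(e),
         call. = FALSE)
  }
  res <- tryCatch({
    seeds <- .withSeed(config$seed, sample.int(2^31 - 2, 8))

    stage <- "data"
    external <- !is.null(config$expr_path) && !is.null(config$design_path)
    if (external) {
      expr <- readExpression(config$expr_path)
      design <- readDesign(config$design_path)
      ph <- if (!is.null(config$pheno_path))
        readPhenotypes(config$pheno_path) else NULL
      al <- alignSamples(expr, design, ph)
      me <- MaturityExperiment(al$expr, al$design, phenotypes = al$pheno)
    } else {
      design <- generateDesign(config$n_sows_per_breed,
                               config$n_fetuses_per_sow, seed = seeds[1])
      me <- simulateExpression(design, config$n_probes,
                               config$class_proportions,
                               config$effect_size, config$sow_sd,
                               config$resid_sd, seed = seeds[2])
      me <- simulatePhenotypes(me, config$n_phenotypes, config$n_drivers,
                               config$driver_weight, config$pheno_noise_sd,
                               seed = seeds[3])
      writeTruth(truthTable(me), file.path(out, "truth.tsv"))
      artifacts <- c(artifacts, "truth.tsv")
    }
    writeExpression(exprMatrix(me), file.path(out, "expression.tsv"))
    writeDesign(designTable(me), file.path(out, "design.tsv"))
    artifacts <- c(artifacts, "expression.tsv", "design.tsv")
    if (!is.null(phenotypes(me))) {
      writePhenotypes(phenotypes(me), file.path(out, "phenotypes.tsv"))
      artifacts <- c(artifacts, "phenotypes.tsv")
    }

    stage <- "de_scan"
    scan <- runDEScan(me, alpha_fdr = config$alpha_fdr_de)
    .writeTSV(scan$table, file.path(out, "de_table.tsv"))
    .writeTSV(scan$deps, file.path(out, "deps.tsv"))
    artifacts <- c(artifacts, "de_table.tsv", "deps.tsv")

    stage <- "submodel"
    cls <- classifyAll(scan$deps, me)
    .writeTSV(cls$labels, file.path(out, "submodel_labels.tsv"))
    .writeTSV(cls$summary, file.path(out, "submodel_summary.tsv"))
    artifacts <- c(artifacts, "submodel_labels.tsv", "submodel_summary.tsv")

    stage <- "parental"
    par <- fitParentalModel(me, alpha_fdr = config$alpha_fdr_parental)
    .writeTSV(par$maternal, file.path(out, "parental_maternal.tsv"))
    .writeTSV(par$paternal, file.path(out, "parental_paternal.tsv"))
    artifacts <- c(artifacts, "parental_maternal.tsv", "parental_paternal.tsv")

    stage <- "spls"
    spls <- NULL; q2 <- numeric(0); msep <- NULL; edges <- NULL
    ph <- phenotypes(me)
    if (!is.null(ph)) {
      X <- t(exprMatrix(me))
      strata <- paste(designTable(me)$gestational_age,
                      designTable(me)$fetal_genotype, sep = ":")
      keepX <- min(config$keepX, ncol(X))
      spls <- splsFit(X, ph, config$n_components, keepX)
      q2 <- q2CrossVal(X, ph, config$n_components, keepX,
                       config$n_folds, seed = seeds[4], strata = strata)
      spls@q2 <- q2
      retained <- which(q2 > config$q2_min)
      msep <- msepR2(X, ph, spls, config$n_folds, seed = seeds[5],
                     strata = strata)
      .writeTSV(msep, file.path(out, "msep_r2.tsv"))
      .writeTSV(data.frame(component = seq_along(q2), q2 = q2,
                           retained = q2 > config$q2_min),
                file.path(out, "q2.tsv"))
      comp_net <- if (length(retained)) retained else 1L
      edges <- relevanceNetwork(spls, X, ph, components = comp_net,
                                cutoff = config$network_cutoff)
      .writeTSV(edges, file.path(out, "network_edges.tsv"))
      writeNetworkSIF(edges, file.path(out, "network.sif"))
      sm_map <- stats::setNames(cls$labels$chosen, cls$labels$probe_id)
      writeNetworkGraphML(edges, file.path(out, "network.graphml"), sm_map)
      artifacts <- c(artifacts, "msep_r2.tsv", "q2.tsv", "network_edges.tsv",
                     "network.sif", "network.graphml")
    }

    stage <- "phenotype_anova"
    anova_tab <- NULL
    if (!is.null(ph)) {
      anova_tab <- analyzePhenotypes(me)
      .writeTSV(anova_tab, file.path(out, "phenotype_anova.tsv"))
      artifacts <- c(artifacts, "phenotype_anova.tsv")
    }

    stage <- "enrichment"
    enr <- NULL
    sets <- if (!is.null(config$gmt_path)) readGMT(config$gmt_path)
            else if (!is.null(truthTable(me))) {
              # synthetic annotation: one term per planted truth class
              tt <- truthTable(me)
              split(tt$probe_id, tt$true_class)
            } else NULL
    if (!is.null(sets) && nrow(scan$deps) > 0) {
      gated <- gateByFoldChange(scan$deps, config$min_abs_log2fc, "LW")
      if (nrow(gated) > 0) {
        enr <- hypergeomEnrich(gated$probe_id, sets, rownames(me),
                               alpha_fdr = config$alpha_fdr_de)
        .writeTSV(enr, file.path(out, "enrichment.tsv"))
        artifacts <- c(artifacts, "enrichment.tsv")
      }
    }

    stage <- "qpcr"
    qp <- NULL
    if (nrow(scan$deps) > 0) {
      targets <- utils::head(scan$deps$probe_id, 8)
      qpd <- simulateQPCR(me, targets, seed = seeds[6])
      rq <- relativeQuantities(qpd$cq, qpd$efficiency)
      gn <- geNormM(rq[qpd$reference_genes, , drop = FALSE])
      norm <- normalizeTargets(rq[qpd$target_genes, , drop = FALSE],
                               rq[gn$selected, , drop = FALSE])
      qp <- validateAgainstArray(norm, exprMatrix(me))
      .writeTSV(qp, file.path(out, "qpcr_validation.tsv"))
      artifacts <- c(artifacts, "qpcr_validation.tsv")
    }

    stage <- "summary"
    confusion <- NULL
    if (!is.null(truthTable(me)) && nrow(cls$labels) > 0) {
      tt <- truthTable(me)
      truth_cls <- tt$true_class[match(cls$labels$probe_id, tt$probe_id)]
      confusion <- table(truth = truth_cls, chosen = cls$labels$chosen)
    }
    summary <- list(
      n_samples = ncol(me), n_probes = nrow(me),
      n_deps = nrow(scan$deps),
      submodel_counts = stats::setNames(cls$summary$count,
                                        cls$summary$submodel),
      n_maternal_signif = sum(par$maternal$signif),
      n_paternal_signif = sum(par$paternal$signif),
      q2 = q2,
      best_predicted = if (!is.null(msep))
        msep$phenotype[order(msep$msep)][seq_len(min(3, nrow(msep)))]
        else character(0),
      network_edges = if (!is.null(edges)) nrow(edges) else 0L,
      qpcr_median_r = if (!is.null(qp) && nrow(qp)) stats::median(qp$r)
        else NA_real_)
    manifest$summary <- summary
    manifest$artifacts <- as.list(tools::md5sum(file.path(out, artifacts)))
    names(manifest$artifacts) <- artifacts
    jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA,
                         force = TRUE)
    list(data = me, scan = scan, submodels = cls, parental = par,
         spls = spls, q2 = q2, msep = msep, network = edges,
         phenotype_anova = anova_tab, enrichment = enr, qpcr = qp,
         confusion = confusion, summary = summary, manifest = manifest,
         out_dir = out)
  }, error = fail)
  invisible(res)
}
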