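## Synthetic factorial reciprocal-cross data with planted truth.
##
## The generator mirrors the study layout: sows of two breeds (LW, MS)
## inseminated with mixed semen, each litter holding purebred and crossbred
## fetuses, each sow sampled at exactly one gestational age (cross-sectional
## caesarean sampling).  Expression follows, per probe,
##   y = mu + a(age) + g(genotype) + i(age, genotype) + u(sow) + e
## with u ~ N(0, sow_sd^2) and e ~ N(0, resid_sd^2); the nonzero pattern of
## (a, g, i) is dictated by the probe's truth class.

TRUTH_CLASSES <- c("null", "complete", "additive", "age", "genotype")

# evaluate expr under a private RNG stream, restoring the caller's stream
.withSeed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

# per-probe sub-seeds: a prefix of the master stream, so growing n_probes
# never reshuffles the streams of earlier probes
.probeSeeds <- function(seed, n) {
  .withSeed(seed, sample.int(.Machine$integer.max - 1L, n))
}

#' Generate a reciprocal-cross factorial design
#'
#' Creates a sample design table for two sow breeds (LW, MS) mated with mixed
#' semen.  Sows are split evenly between gestational ages 90 and 110 days
#' (an odd count puts the extra sow at day 90); every sow carries fetuses of
#' its two possible genotypes (purebred + crossbred), with at least one of
#' each sire breed whenever \code{n_fetuses_per_sow >= 2}.
#'
#' @param n_sows_per_breed number of sows per breed (>= 1).
#' @param n_fetuses_per_sow fetuses sampled per sow (>= 1).
#' @param seed integer seed; the same seed reproduces the table exactly.
#' @param balanced_litters give every litter exactly half LW-sired and half
#'   MS-sired fetuses (requires an even litter size); with random sires
#'   (default) compositions vary as in a real insemination with mixed semen.
#' @return data.frame with columns sample_id, sow_id, maternal_genotype,
#'   paternal_genotype, fetal_genotype, gestational_age.
#' @examples
#' d <- generateDesign(9, 4, seed = 1)
#' table(d$gestational_age, d$fetal_genotype)
#' @export
generateDesign <- function(n_sows_per_breed, n_fetuses_per_sow, seed = 1L,
                           balanced_litters = FALSE) {
  if (n_sows_per_breed < 1 || n_fetuses_per_sow < 1)
    stop("n_sows_per_breed and n_fetuses_per_sow must be >= 1")
  if (balanced_litters && n_fetuses_per_sow %% 2 != 0)
    stop("balanced_litters requires an even litter size")
  .withSeed(seed, {
    rows <- list()
    for (breed in BREED_LEVELS) {
      n90 <- ceiling(n_sows_per_breed / 2)
      ages <- c(rep("90", n90), rep("110", n_sows_per_breed - n90))
      for (s in seq_len(n_sows_per_breed)) {
        sow <- sprintf("sow_%s_%02d", breed, s)
        if (balanced_litters) {
          sires <- sample(rep(BREED_LEVELS, n_fetuses_per_sow / 2))
        } else {
          sires <- sample(BREED_LEVELS, n_fetuses_per_sow, replace = TRUE)
          if (n_fetuses_per_sow >= 2) {
            # force both sire breeds into the litter, positions randomized
            pos <- sample.int(n_fetuses_per_sow, 2)
            sires[pos] <- sample(BREED_LEVELS)
          }
        }
        rows[[length(rows) + 1L]] <- data.frame(
          sample_id = sprintf("%s_f%02d", sow, seq_len(n_fetuses_per_sow)),
          sow_id = sow,
          maternal_genotype = breed,
          paternal_genotype = sires,
          fetal_genotype = crossGenotype(breed, sires),
          gestational_age = ages[s],
          stringsAsFactors = FALSE)
      }
    }
    do.call(rbind, c(rows, list(make.row.names = FALSE)))
  })
}

.checkDesign <- function(design) {
  design <- as.data.frame(design)
  need <- c("sample_id", "sow_id", "maternal_genotype", "paternal_genotype",
            "fetal_genotype", "gestational_age")
  miss <- setdiff(need, colnames(design))
  if (length(miss))
    stop("design lacks columns: ", paste(miss, collapse = ", "))
  design$gestational_age <- as.character(design$gestational_age)
  design
}

# fixed effect patterns per truth class, one magnitude `effect_size` per
# nonzero coefficient; signs are a fixed pattern so truth is identifiable
.classEffects <- function(true_class, effect_size) {
  a <- 0; g <- c(0, 0, 0); i <- c(0, 0, 0)
  if (true_class %in% c("age", "additive", "complete")) a <- effect_size
  if (true_class %in% c("genotype", "additive", "complete"))
    g <- effect_size * c(1, -1, 1)
  if (true_class == "complete") i <- effect_size * c(-1, 1, -1)
  list(age_effect = a, genotype_effects = g, interaction_effects = i)
}

#' Simulate per-probe expression with planted truth classes
#'
#' Each probe is assigned one of five truth classes — null, complete (age +
#' genotype + interaction), additive (age + genotype), age-only, genotype-only
#' — and its expression generated under the mixed model
#' \eqn{y = \mu + a + g + i + u_{sow} + \epsilon} with the nonzero pattern of
#' the fixed effects dictated by the class.  Genotype and interaction effects
#' are treatment contrasts against the LW reference level.  Per-probe RNG
#' streams derive from the master seed, so enlarging \code{n_probes} leaves
#' earlier probes unchanged.
#'
#' @param design design data.frame from \code{\link{generateDesign}}.
#' @param n_probes number of probes.
#' @param class_proportions length-5 nonnegative vector over
#'   (null, complete, additive, age, genotype); must sum to 1.
#' @param effect_size magnitude (log2 units) of every nonzero planted
#'   coefficient.
#' @param sow_sd,resid_sd standard deviations (log2 units) of the random sow
#'   effect and the residual.
#' @param mu_range range of the per-probe baseline, drawn uniformly;
#'   defaults to the typical microarray dynamic range.
#' @param seed master integer seed.
#' @return a \linkS4class{MaturityExperiment} carrying the truth table in
#'   \code{rowData} (probe class and planted coefficients).
#' @examples
#' d <- generateDesign(4, 3, seed = 1)
#' sim <- simulateExpression(d, n_probes = 50, seed = 2)
#' table(truthTable(sim)$true_class)
#' @export
simulateExpression <- function(design, n_probes,
                               class_proportions = c(0.8, 0.05, 0.05, 0.05, 0.05),
                               effect_size = 1, sow_sd = 0.15, resid_sd = 0.3,
                               mu_range = c(4, 14), seed = 1L) {
  design <- .checkDesign(design)
  if (nrow(design) < 2) stop("design must have at least 2 samples")
  if (abs(sum(class_proportions) - 1) > 1e-9)
    stop("class_proportions must sum to 1")
  if (sow_sd < 0 || resid_sd < 0) stop("sds must be >= 0")
  n <- nrow(design)
  sows <- design$sow_id
  usow <- unique(sows)
  age110 <- design$gestational_age == "110"
  geno <- factor(design$fetal_genotype, GENOTYPE_LEVELS)
  gidx <- as.integer(geno) - 1L            # 0 = LW reference
  seeds <- .probeSeeds(seed, n_probes)
  probe_ids <- sprintf("probe_%05d", seq_len(n_probes))

  expr <- matrix(0, n_probes, n, dimnames = list(probe_ids, design$sample_id))
  cls <- character(n_probes)
  tr_a <- numeric(n_probes)
  tr_g <- matrix(0, n_probes, 3)
  tr_i <- matrix(0, n_probes, 3)
  tr_mu <- numeric(n_probes)

  for (j in seq_len(n_probes)) {
    .withSeed(seeds[j], {
      cl <- sample(TRUTH_CLASSES, 1, prob = class_proportions)
      mu <- runif(1, mu_range[1], mu_range[2])
      ef <- .classEffects(cl, effect_size)
      u <- stats::rnorm(length(usow), 0, sow_sd)
      names(u) <- usow
      eps <- stats::rnorm(n, 0, resid_sd)
      fixed <- mu +
        ef$age_effect * age110 +
        ifelse(gidx > 0, ef$genotype_effects[pmax(gidx, 1L)], 0) +
        ifelse(gidx > 0 & age110, ef$interaction_effects[pmax(gidx, 1L)], 0)
      expr[j, ] <- fixed + u[sows] + eps
      cls[j] <- cl
      tr_a[j] <- ef$age_effect
      tr_g[j, ] <- ef$genotype_effects
      tr_i[j, ] <- ef$interaction_effects
      tr_mu[j] <- mu
    })
  }
  truth <- data.frame(
    probe_id = probe_ids, true_class = cls, mu = tr_mu, age_effect = tr_a,
    geno_MSLW = tr_g[, 1], geno_LWMS = tr_g[, 2], geno_MS = tr_g[, 3],
    int_MSLW = tr_i[, 1], int_LWMS = tr_i[, 2], int_MS = tr_i[, 3],
    sow_sd = sow_sd, resid_sd = resid_sd, stringsAsFactors = FALSE)
  me <- MaturityExperiment(expr, design, truth = truth)
  metadata(me)$seed <- seed
  me
}

#' Simulate phenotypic variables driven by known probe subsets
#'
#' Each phenotype is a weighted sum of a randomly drawn driver-probe set plus
#' Gaussian noise; the driver sets and weights are recorded in
#' \code{metadata(x)$phenotype_drivers} so recovery can be scored.
#'
#' @param x a \linkS4class{MaturityExperiment}.
#' @param n_phenotypes number of phenotype columns (the study recorded 23:
#'   7 morphometry, 2 enzyme activities, 14 blood parameters).
#' @param n_drivers probes driving each phenotype.
#' @param driver_weight weight applied to each driver probe's expression.
#' @param noise_sd standard deviation of the additive phenotype noise.
#' @param seed integer seed.
#' @return the input object with phenotype columns added to \code{colData}.
#' @examples
#' d <- generateDesign(3, 3, seed = 1)
#' sim <- simulateExpression(d, n_probes = 30, seed = 1)
#' sim <- simulatePhenotypes(sim, n_phenotypes = 4, n_drivers = 3, seed = 1)
#' colnames(phenotypes(sim))
#' @export
simulatePhenotypes <- function(x, n_phenotypes = 23, n_drivers = 20,
                               driver_weight = 1, noise_sd = 1, seed = 1L) {
  stopifnot(is(x, "MaturityExperiment"))
  if (n_phenotypes < 1) stop("n_phenotypes must be >= 1")
  expr <- exprMatrix(x)
  if (n_drivers > nrow(expr)) stop("n_drivers exceeds the number of probes")
  n <- ncol(expr)
  pnames <- sprintf("pheno_%02d", seq_len(n_phenotypes))
  drivers <- vector("list", n_phenotypes)
  names(drivers) <- pnames
  ph <- matrix(NA_real_, n, n_phenotypes,
               dimnames = list(colnames(expr), pnames))
  .withSeed(seed, {
    for (k in seq_len(n_phenotypes)) {
      idx <- sample.int(nrow(expr), n_drivers)
      w <- rep(driver_weight, n_drivers)
      signal <- if (n_drivers > 0) drop(w %*% expr[idx, , drop = FALSE]) else
        numeric(n)
      ph[, k] <- signal + stats::rnorm(n, 0, noise_sd)
      drivers[[k]] <- list(probes = rownames(expr)[idx], weights = w,
                           noise_sd = noise_sd)
    }
  })
  cd <- SummarizedExperiment::colData(x)
  for (v in pnames) cd[[v]] <- ph[, v]
  SummarizedExperiment::colData(x) <- cd
  x@phenotypeNames <- union(x@phenotypeNames, pnames)
  metadata(x)$phenotype_drivers <- drivers
  validObject(x)
  x
}

#' Simulate a qPCR dataset from planted expression
#'
#' Converts selected probes' log2 expression to quantification cycles under
#' per-gene amplification efficiencies (Cq decreases by one cycle per
#' efficiency-fold increase in template) with additive Cq noise, and appends
#' stable reference-gene candidates for geNorm selection.
#'
#' @param x a \linkS4class{MaturityExperiment}.
#' @param target_probes probe ids to assay; defaults to the first 8 probes.
#' @param n_references number of stable reference candidates to synthesize.
#' @param efficiency_range range of amplification efficiencies (1 = perfect
#'   doubling; the study's primers ran at 0.99-1.04).
#' @param cq_noise_sd per-well Cq noise, cycles (applied to reference genes,
#'   and to targets when \code{snr} is NULL).
#' @param reference_sd biological wobble of reference candidates, log2 units.
#' @param snr optional per-target signal-to-noise ratio: each target's Cq
#'   noise is scaled so the log2-scale noise sd equals (row sd)/snr,
#'   overriding \code{cq_noise_sd} for targets.
#' @param seed integer seed.
#' @return list with elements \code{cq} (genes x samples), \code{efficiency}
#'   (named vector), \code{reference_genes}, \code{target_genes}.
#' @export
simulateQPCR <- function(x, target_probes = NULL, n_references = 4,
                         efficiency_range = c(0.99, 1.04), cq_noise_sd = 0.1,
                         reference_sd = 0.05, snr = NULL, seed = 1L) {
  stopifnot(is(x, "MaturityExperiment"))
  expr <- exprMatrix(x)
  if (is.null(target_probes))
    target_probes <- head(rownames(expr), 8)
  stopifnot(all(target_probes %in% rownames(expr)))
  n <- ncol(expr)
  refs <- sprintf("ref_%02d", seq_len(n_references))
  genes <- c(target_probes, refs)
  .withSeed(seed, {
    eff <- stats::runif(length(genes), efficiency_range[1], efficiency_range[2])
    names(eff) <- genes
    cq <- matrix(NA_real_, length(genes), n,
                 dimnames = list(genes, colnames(expr)))
    for (g in target_probes) {
      # template quantity 2^expr; Cq relative to an arbitrary per-gene offset
      noise_cycles <- if (is.null(snr)) cq_noise_sd else
        (stats::sd(expr[g, ]) / snr) * log(2) / log(1 + eff[g])
      cq[g, ] <- 35 - expr[g, ] * log(2) / log(1 + eff[g]) +
        stats::rnorm(n, 0, noise_cycles)
    }
    for (g in refs) {
      base <- stats::runif(1, 6, 10)
      cq[g, ] <- 35 - (base + stats::rnorm(n, 0, reference_sd)) *
        log(2) / log(1 + eff[g]) + stats::rnorm(n, 0, cq_noise_sd)
    }
    list(cq = cq, efficiency = eff, reference_genes = refs,
         target_genes = target_probes)
  })
}
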