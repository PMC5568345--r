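## Two-way fixed-effects ANOVA of phenotypic variables (age x genotype) with
## Shapiro/Bartlett assumption checks and Box-Cox transformation when the
## residuals are non-normal.  Type-II sums of squares accommodate the
## unbalanced cell counts of the cross-sectional design.

#' Normality and homoscedasticity checks for a grouped variable
#'
#' Shapiro-Wilk on the residuals of the group-mean model and Bartlett's test
#' of equal variances across groups.
#'
#' @param y numeric values (NA dropped).
#' @param groups factor of group labels, same length as y.
#' @return list(shapiro_p, bartlett_p).
#' @export
checkAssumptions <- function(y, groups) {
  ok <- !is.na(y) & !is.na(groups)
  y <- y[ok]; groups <- droplevels(factor(groups[ok]))
  if (length(y) < 3) stop("need at least 3 observations")
  if (nlevels(groups) < 2) stop("need at least 2 groups for Bartlett")
  if (any(table(groups) < 2))
    stop("Bartlett requires >= 2 observations per group")
  resid <- y - stats::ave(y, groups)
  shapiro_p <- if (stats::sd(resid) < 1e-12) 1 else
    stats::shapiro.test(resid)$p.value
  bartlett_p <- stats::bartlett.test(y, groups)$p.value
  list(shapiro_p = shapiro_p, bartlett_p = bartlett_p)
}

.boxcoxLoglik <- function(y, lambda) {
  n <- length(y)
  z <- if (abs(lambda) < 1e-12) log(y) else (y^lambda - 1) / lambda
  s2 <- stats::var(z) * (n - 1) / n
  -n / 2 * log(s2) + (lambda - 1) * sum(log(y))
}

#' Box-Cox exponent by profile likelihood
#'
#' Maximizes the Box-Cox profile log-likelihood over a grid on [-2, 2]
#' followed by golden-section refinement.  The transform is
#' \eqn{(y^\lambda - 1)/\lambda} (natural log at \eqn{\lambda = 0}).
#' Non-positive values are shifted to positivity when \code{shift = TRUE},
#' and the applied offset is reported.
#'
#' @param y numeric values.
#' @param shift allow an additive offset to make all values positive.
#' @return list(lambda, shift, applied, loglik).
#' @examples
#' boxcoxLambda(exp(rnorm(100)))$lambda
#' @export
boxcoxLambda <- function(y, shift = TRUE) {
  y <- y[!is.na(y)]
  if (length(y) < 5) stop("need at least 5 observations")
  off <- 0
  if (min(y) <= 0) {
    if (!shift) stop("non-positive values; enable shift or offset the data")
    off <- -min(y) + 1e-3 * diff(range(y))
    if (off == 0) off <- 1
    y <- y + off
  }
  grid <- seq(-2, 2, by = 0.05)
  ll <- vapply(grid, function(l) .boxcoxLoglik(y, l), numeric(1))
  i <- which.max(ll)
  lo <- grid[max(1, i - 1)]; hi <- grid[min(length(grid), i + 1)]
  opt <- stats::optimize(function(l) .boxcoxLoglik(y, l),
                         interval = c(lo, hi), maximum = TRUE,
                         tol = 1e-8)
  list(lambda = opt$maximum, shift = off, applied = TRUE,
       loglik = opt$objective)
}

#' Apply a Box-Cox transform
#' @param y numeric values.
#' @param spec list from \code{\link{boxcoxLambda}}.
#' @return transformed values.
#' @export
boxcoxTransform <- function(y, spec) {
  z <- y + spec$shift
  if (any(z <= 0, na.rm = TRUE)) stop("non-positive values after shift")
  if (abs(spec$lambda) < 1e-12) log(z) else (z^spec$lambda - 1) / spec$lambda
}

#' Two-way ANOVA (age x genotype) with Type-II sums of squares
#'
#' @param y numeric response.
#' @param age,genotype factors (coerced; levels 90 < 110 and
#'   LW < MSLW < LWMS < MS when applicable).
#' @return list with per-term \code{F} and \code{p} (age, genotype,
#'   interaction) and \code{df_resid}.
#' @export
twowayAnova <- function(y, age, genotype) {
  ok <- !is.na(y)
  y <- y[ok]
  age <- droplevels(factor(as.character(age)[ok],
                           levels = intersect(AGE_LEVELS,
                                              as.character(age)[ok])))
  genotype <- droplevels(factor(as.character(genotype)[ok],
                                levels = intersect(GENOTYPE_LEVELS,
                                                   as.character(genotype)[ok])))
  if (nlevels(age) < 2 || nlevels(genotype) < 2)
    stop("both factors need at least 2 observed levels")
  if (any(table(age, genotype) == 0))
    stop("empty age x genotype cell: interaction not estimable")
  n_par <- nlevels(age) * nlevels(genotype)
  if (length(y) - n_par < 1) stop("no residual degrees of freedom")
  if (stats::var(y) < 1e-24) {
    z <- list(F = c(age = 0, genotype = 0, interaction = 0),
              p = c(age = 1, genotype = 1, interaction = 1),
              df_resid = length(y) - n_par)
    return(z)
  }
  fitlm <- stats::lm(y ~ age * genotype)
  a2 <- car::Anova(fitlm, type = 2)
  rn <- rownames(a2)
  pick <- function(term) {
    i <- match(term, rn)
    c(F = a2$`F value`[i], p = a2$`Pr(>F)`[i])
  }
  f <- c(age = unname(pick("age")["F"]),
         genotype = unname(pick("genotype")["F"]),
         interaction = unname(pick("age:genotype")["F"]))
  p <- c(age = unname(pick("age")["p"]),
         genotype = unname(pick("genotype")["p"]),
         interaction = unname(pick("age:genotype")["p"]))
  list(F = f, p = p, df_resid = a2$Df[match("Residuals", rn)])
}

# compact letter display from a symmetric p-value matrix (insertion order)
.compactLetters <- function(pmat, means, alpha = 0.05) {
  g <- names(means)[order(-means)]
  groups <- list()
  for (lev in g) {
    placed <- FALSE
    for (i in seq_along(groups)) {
      if (all(pmat[lev, groups[[i]]] > alpha, na.rm = TRUE)) {
        groups[[i]] <- c(groups[[i]], lev)
        placed <- TRUE
      }
    }
    if (!placed) groups[[length(groups) + 1L]] <- lev
  }
  letters_out <- stats::setNames(rep("", length(means)), names(means))
  for (i in seq_along(groups))
    for (lev in groups[[i]])
      letters_out[lev] <- paste0(letters_out[lev], letters[i])
  letters_out
}

#' Tukey HSD letter groupings over the age x genotype cells
#'
#' Pairwise Tukey comparisons of the eight cell means; cells not sharing a
#' letter differ at the chosen level.
#'
#' @param y numeric response.
#' @param age,genotype factors.
#' @param alpha family-wise level (default 0.05).
#' @return named character vector of letters, one per cell (named
#'   "age:genotype").
#' @export
tukeyLetters <- function(y, age, genotype, alpha = 0.05) {
  ok <- !is.na(y)
  cell <- factor(paste(as.character(age)[ok], as.character(genotype)[ok],
                       sep = ":"))
  y <- y[ok]
  fit <- stats::aov(y ~ cell)
  tk <- stats::TukeyHSD(fit)$cell
  levs <- levels(cell)
  pmat <- matrix(NA_real_, length(levs), length(levs),
                 dimnames = list(levs, levs))
  for (r in rownames(tk)) {
    pair <- strsplit(r, "-", fixed = TRUE)[[1]]
    pmat[pair[1], pair[2]] <- pmat[pair[2], pair[1]] <- tk[r, "p adj"]
  }
  means <- tapply(y, cell, mean)
  .compactLetters(pmat, means, alpha)
}

#' Phenotype-wide ANOVA workflow
#'
#' For every phenotype: check assumptions; in \code{auto} mode apply the
#' Box-Cox transform whenever the Shapiro p-value falls below
#' \code{alpha_normality} (the decision is recorded per variable); then run
#' the Type-II two-way ANOVA and the Tukey letter groupings.
#'
#' @param x a \linkS4class{MaturityExperiment} with phenotypes, or a samples
#'   x variables matrix plus a design.
#' @param design design data.frame (ignored for a MaturityExperiment).
#' @param transform "auto" (Box-Cox when non-normal), "never", or "always".
#' @param alpha_normality Shapiro threshold triggering the transform.
#' @return data.frame, one row per phenotype: shapiro_p, bartlett_p,
#'   transformed flag, lambda, per-term F and p, df_resid.
#' @export
analyzePhenotypes <- function(x, design = NULL,
                              transform = c("auto", "never", "always"),
                              alpha_normality = 0.05) {
  transform <- match.arg(transform)
  if (is(x, "MaturityExperiment")) {
    ph <- phenotypes(x)
    design <- designTable(x)
  } else ph <- as.matrix(x)
  if (is.null(ph) || !ncol(ph)) stop("no phenotype variables found")
  design <- .checkDesign(design)
  ph <- ph[match(design$sample_id, rownames(ph)), , drop = FALSE]
  age <- design$gestational_age
  geno <- design$fetal_genotype
  cell <- paste(age, geno, sep = ":")
  rows <- lapply(colnames(ph), function(v) {
    y <- ph[, v]
    chk <- checkAssumptions(y, cell)
    use_bc <- switch(transform,
                     auto = chk$shapiro_p < alpha_normality,
                     never = FALSE, always = TRUE)
    lambda <- NA_real_
    if (use_bc) {
      spec <- boxcoxLambda(y)
      lambda <- spec$lambda
      y <- boxcoxTransform(y, spec)
    }
    an <- twowayAnova(y, age, geno)
    data.frame(phenotype = v, shapiro_p = chk$shapiro_p,
               bartlett_p = chk$bartlett_p, transformed = use_bc,
               lambda = lambda,
               F_age = an$F["age"], p_age = an$p["age"],
               F_genotype = an$F["genotype"], p_genotype = an$p["genotype"],
               F_interaction = an$F["interaction"],
               p_interaction = an$p["interaction"],
               df_resid = an$df_resid,
               stringsAsFactors = FALSE, row.names = NULL)
  })
  do.call(rbind, rows)
}
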