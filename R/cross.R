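#' Nested growth-curve mixed-model ladder for a reciprocal cross
#'
#' Fits a series of nested linear mixed models for longitudinal body weight
#' in an F1 reciprocal cross, dissecting the effects of sex, parental
#' genotype (which parent carried the mutant allele — a purely parental
#' effect), offspring genotype, and their interaction (the parent-of-origin
#' effect), on top of a quadratic growth curve with a per-animal random
#' intercept.  Consecutive models are compared by likelihood-ratio tests on
#' maximum-likelihood fits, the standard way to test nested fixed effects in
#' mixed models.
#'
#' The default ladder (heterozygous x WT design) is:
#' `w ~ a + a^2`, `+ sex`, `+ parent`, `+ genotype`, `+ genotype:parent`,
#' `+ (a + a^2):(sex + parent)`, always with `(1 | id)`.  When the cross has
#' a single offspring genotype (homozygous KO x WT), the genotype terms are
#' dropped and the transmitting-parent main effect *is* the
#' parent-of-origin term.
#'
#' @param cross A `cross_table` in long format with repeated ages per
#'   animal (columns `id`, `sex`, `f1_genotype`, `ko_parent`, `age_weeks`,
#'   `phenotype`).
#' @param formulas Optional list of model formulas (terms on the right of
#'   `~`, excluding the random intercept, which is always added) overriding
#'   the default ladder.  Each must nest the previous one.
#' @return Object of class `growth_ladder`: `fits` (ML `lmerMod` objects),
#'   `anova` (sequential comparison table: model, npar, logLik, Chisq, df,
#'   p), and `terms` naming which row tests the parental and
#'   parent-of-origin effects.
#' @export
fit_growth_ladder <- function(cross, formulas = NULL) {
  cross <- as.data.frame(cross)
  if (all(is.na(cross$age_weeks)) || max(table(cross$id)) < 2)
    stop("single-age data: use fit_poe_anova() for single-timepoint phenotypes")
  if (length(unique(cross$ko_parent)) < 2)
    stop("both transmitting-parent classes must be present")
  single_geno <- length(unique(cross$f1_genotype)) < 2
  dat <- data.frame(w = cross$phenotype, a = cross$age_weeks,
                    s = factor(cross$sex), p = factor(cross$ko_parent),
                    g = factor(cross$f1_genotype), m = factor(cross$id))
  if (is.null(formulas)) {
    formulas <- if (single_geno) {
      list(base = "a + I(a^2)", sex = ". + s", parent_poe = ". + p",
           growth_mod = ". + (a + I(a^2)):(s + p)")
    } else {
      list(base = "a + I(a^2)", sex = ". + s", parent = ". + p",
           genotype = ". + g", poe = ". + g:p",
           growth_mod = ". + (a + I(a^2)):(s + p)")
    }
  }
  fits <- vector("list", length(formulas))
  names(fits) <- names(formulas)
  rhs <- character(length(formulas))
  for (i in seq_along(formulas)) {
    rhs[i] <- if (grepl("^\\.", formulas[[i]]) && i > 1)
      sub("^\\.", paste0("(", rhs[i - 1], ")"), formulas[[i]])
    else formulas[[i]]
    f <- stats::as.formula(paste("w ~", rhs[i], "+ (1 | m)"))
    fits[[i]] <- lme4::lmer(f, data = dat, REML = FALSE)
  }
  av <- do.call(stats::anova, c(unname(fits),
                                list(model.names = names(fits))))
  tab <- data.frame(model = names(formulas), npar = av$npar,
                    logLik = av$logLik, Chisq = av$Chisq, df = av$Df,
                    p = av$`Pr(>Chisq)`)
  terms <- list(parental = if (single_geno) NA_character_ else "parent",
                poe = if (single_geno) "parent_poe" else "poe")
  structure(list(fits = fits, anova = tab, terms = terms,
                 single_genotype = single_geno), class = "growth_ladder")
}

#' @export
print.growth_ladder <- function(x, ...) {
  cat("<growth_ladder> sequential mixed-model comparisons\n")
  print(transform(x$anova, p = signif(p, 3)))
  invisible(x)
}

#' Sequential ANOVA for single-timepoint parent-of-origin effects
#'
#' Fixed-effects linear-model ANOVA (sequential, type-I sums of squares) for
#' a single phenotype measured once per F1 animal.  In the heterozygous x WT
#' design the parent-of-origin effect is the interaction between F1 genotype
#' and transmitting parent; in the homozygous design (all offspring
#' heterozygous) it is the transmitting-parent main effect.
#'
#' @param cross A `cross_table` (one row per animal, or a single age).
#' @param phenotype Column name holding the response (default
#'   `"phenotype"`).
#' @param sex_interaction Also test the sex-by-parent-of-origin interaction.
#' @return Object of class `poe_anova`: `anova` (term, df, sum sq, F, p),
#'   `poe_term` naming the parent-of-origin row, `fit` (the `lm`), and
#'   `degenerate` (TRUE when the response is constant).
#' @export
fit_poe_anova <- function(cross, phenotype = "phenotype",
                          sex_interaction = TRUE) {
  cross <- as.data.frame(cross)
  y <- cross[[phenotype]]
  if (is.null(y)) stop("no column '", phenotype, "' in the cross table")
  single_geno <- length(unique(cross$f1_genotype)) < 2
  dat <- data.frame(y = y, s = factor(cross$sex),
                    p = factor(cross$ko_parent),
                    g = factor(cross$f1_genotype))
  if (length(unique(dat$p)) < 2)
    stop("term 'p' (transmitting parent) is inestimable: only one class present")
  if (single_geno) {
    rhs <- c("s", "p", if (sex_interaction) "s:p")
    poe_term <- "p"
  } else {
    rhs <- c("s", "g", "p", "g:p", if (sex_interaction) "s:g:p")
    poe_term <- "g:p"
  }
  fml <- stats::reformulate(rhs, response = "y")
  fit <- stats::lm(fml, data = dat)
  degenerate <- stats::var(y) < .Machine$double.eps
  av <- if (degenerate) suppressWarnings(stats::anova(fit)) else stats::anova(fit)
  tab <- data.frame(term = rownames(av), df = av$Df, sumsq = av$`Sum Sq`,
                    F = av$`F value`, p = av$`Pr(>F)`)
  structure(list(anova = tab, poe_term = poe_term, fit = fit,
                 degenerate = degenerate), class = "poe_anova")
}

#' @export
print.poe_anova <- function(x, ...) {
  cat("<poe_anova> parent-of-origin term: ", x$poe_term,
      if (x$degenerate) " [constant response]" else "", "\n", sep = "")
  print(transform(x$anova, p = signif(p, 3)))
  invisible(x)
}

#' Fisher's exact test for a 2x2 table
#'
#' Two-sided exact test for association in a 2x2 contingency table (the sum
#' over tables with fixed margins whose hypergeometric probability does not
#' exceed the observed one), plus the sample odds ratio.
#'
#' @param tab 2x2 matrix of non-negative integer counts, or a length-4
#'   vector filled column-wise.
#' @return List: `p_value`, `odds_ratio` (sample), `estimate` (conditional
#'   MLE from the exact test).
#' @export
fisher_exact_2x2 <- function(tab) {
  if (is.vector(tab)) tab <- matrix(tab, 2, 2)
  if (!all(dim(tab) == c(2, 2))) stop("a 2x2 table is required")
  if (any(tab < 0) || any(tab != round(tab))) stop("counts must be non-negative integers")
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0))
    stop("a margin of the table is zero")
  ft <- stats::fisher.test(tab)
  or <- (tab[1, 1] * tab[2, 2]) / (tab[1, 2] * tab[2, 1])
  list(p_value = ft$p.value, odds_ratio = or,
       estimate = unname(ft$estimate))
}

#' Per-gene count dispersion within replicate groups
#'
#' For replicate count data (e.g. RNA-seq read counts across animals that
#' share sex, genotype and transmitting parent), computes for every gene and
#' group the mean `mu`, variance `sigma2` and the dispersion
#' `s = sigma2 / (mu + 1)` of library-size-normalized counts — a
#' mean-scaled variance suited to approximately negative-binomial counts.
#' Groups of fewer than 2 animals are skipped with a warning.
#'
#' @param counts Genes x animals matrix of non-negative counts (rownames =
#'   genes).
#' @param groups Factor of length `ncol(counts)` assigning animals to
#'   replicate groups.
#' @param normalize Divide each column by its library-size factor (total
#'   count over mean total count) first.
#' @param gene_sets Optional named list of gene-id vectors; when given, the
#'   result carries an `ecdf` element with the empirical cumulative
#'   distribution of mean per-gene dispersion for each set (plus
#'   `"all"`), for enrichment-style comparisons.
#' @return Data frame of class `dispersion_table`: `gene`, `group`, `n`,
#'   `mu`, `sigma2`, `s`.
#' @export
dispersion_table <- function(counts, groups, normalize = TRUE,
                             gene_sets = NULL) {
  counts <- as.matrix(counts)
  groups <- as.factor(groups)
  if (length(groups) != ncol(counts))
    stop("groups must have one entry per animal (column)")
  if (normalize) {
    lib <- colSums(counts)
    counts <- sweep(counts, 2, lib / mean(lib), "/")
  }
  keep <- levels(groups)[table(groups) >= 2]
  if (length(keep) < length(levels(groups)))
    warning("skipping group(s) of size 1: ",
            paste(setdiff(levels(groups), keep), collapse = ", "), call. = FALSE)
  out <- do.call(rbind, lapply(keep, function(g) {
    sub <- counts[, groups == g, drop = FALSE]
    mu <- rowMeans(sub)
    s2 <- apply(sub, 1, stats::var)
    data.frame(gene = rownames(counts), group = g, n = ncol(sub),
               mu = mu, sigma2 = s2, s = s2 / (mu + 1), row.names = NULL)
  }))
  class(out) <- c("dispersion_table", "data.frame")
  if (!is.null(gene_sets)) {
    per_gene <- tapply(out$s, out$gene, mean)
    sets <- c(list(all = names(per_gene)), gene_sets)
    attr(out, "ecdf") <- lapply(sets, function(gs)
      stats::ecdf(per_gene[names(per_gene) %in% gs]))
  }
  out
}
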