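#' Simulate a reciprocal F1 cross
#'
#' Emulates reciprocal crosses between a knockout (KO) line and wild-type
#' (WT): in half the matings the KO allele is carried by the father, in half
#' by the mother.  With `design = "hom_x_wt"` the KO parent is homozygous so
#' every F1 animal is heterozygous; with `"het_x_wt"` offspring are WT or
#' heterozygous with Mendelian probability 1/2.  Phenotypes are either a
#' longitudinal weight series (quadratic in age, with a per-animal random
#' intercept) or a single measurement.
#'
#' The mean model for animal \eqn{i} at age \eqn{a} is
#' \deqn{\mu = \beta_0 + \beta_1 a + \beta_2 a^2 + s\,[sex=M] + d\,[KO parent = father]
#'       + g\,[het] + m\,[het\ \&\ KO\ paternal]}
#' where `d` is a purely parental effect (depends only on which parent
#' carried the KO), `g` a genotype effect, and `m` the additive
#' parent-of-origin effect (paternal vs maternal transmission of the KO
#' allele in heterozygotes).
#'
#' @param design `"hom_x_wt"` or `"het_x_wt"`.
#' @param n_offspring Number of F1 animals.
#' @param effects Named list with entries `intercept`, `age` (length-2:
#'   linear, quadratic), `sex`, `parental`, `genotype`, `poe`; missing
#'   entries default to 0 (intercept 20, age c(3, -0.15) for a plausible
#'   murine growth curve).
#' @param ages Vector of ages (weeks) at which weights are recorded; `NULL`
#'   gives one phenotype per animal at `age = NA`.
#' @param sd_animal SD of the per-animal random intercept.
#' @param sd_resid Residual SD per observation.
#' @param seed Optional integer seed.
#'
#' @return A data frame of class `cross_table` in long format with columns
#'   `id`, `sex`, `f1_genotype` ("wt"/"het"), `ko_parent` ("father"/"mother"),
#'   `age_weeks`, `phenotype`.
#' @export
simulate_cross <- function(design = c("het_x_wt", "hom_x_wt"), n_offspring = 100,
                           effects = list(), ages = 4:11,
                           sd_animal = 1, sd_resid = 1, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  design <- match.arg(design)
  if (n_offspring < 2) stop("n_offspring must be >= 2")
  if (!is.null(ages) && any(ages <= 0)) stop("ages must be positive")
  ef <- list(intercept = 20, age = c(3, -0.15), sex = 0, parental = 0,
             genotype = 0, poe = 0)
  ef[names(effects)] <- effects

  sex <- sample(c("M", "F"), n_offspring, replace = TRUE)
  ko_parent <- rep(c("father", "mother"), length.out = n_offspring)
  f1 <- if (design == "hom_x_wt") rep("het", n_offspring)
        else ifelse(stats::runif(n_offspring) < 0.5, "het", "wt")
  u <- stats::rnorm(n_offspring, sd = sd_animal)

  base <- ef$intercept + ef$sex * (sex == "M") +
    ef$parental * (ko_parent == "father") +
    ef$genotype * (f1 == "het") +
    ef$poe * (f1 == "het" & ko_parent == "father") + u

  if (is.null(ages)) {
    out <- data.frame(id = sprintf("F1_%03d", seq_len(n_offspring)),
                      sex = sex, f1_genotype = f1, ko_parent = ko_parent,
                      age_weeks = NA_real_,
                      phenotype = base + stats::rnorm(n_offspring, sd = sd_resid),
                      stringsAsFactors = FALSE)
  } else {
    k <- length(ages)
    out <- data.frame(
      id = rep(sprintf("F1_%03d", seq_len(n_offspring)), each = k),
      sex = rep(sex, each = k), f1_genotype = rep(f1, each = k),
      ko_parent = rep(ko_parent, each = k),
      age_weeks = rep(ages, n_offspring),
      stringsAsFactors = FALSE)
    out$phenotype <- rep(base, each = k) +
      ef$age[1] * out$age_weeks + ef$age[2] * out$age_weeks^2 +
      stats::rnorm(nrow(out), sd = sd_resid)
  }
  class(out) <- c("cross_table", "data.frame")
  out
}
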