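#' Simulate a pedigreed outbred population
#'
#' Builds a multi-generation pedigree in the style of a heterogeneous stock
#' maintained by pseudo-random mating: generation 0 consists of the inbred
#' founder strains themselves; intermediate generations are produced by
#' random non-sibling matings; the final generation is organised into
#' full-sib families so that downstream analyses see both sibling and
#' non-sibling pairs.
#'
#' @param n_families Number of full-sib families in the final generation.
#' @param sibs_per_family Number of offspring per final-generation family.
#' @param n_generations Number of generations bred from the founders (>= 1).
#'   With `n_generations = 1` the founders themselves are the parents of the
#'   final generation.
#' @param n_founders Number of founder strains in generation 0 (even, so both
#'   sexes are present).
#' @param n_mid Size of each intermediate generation; defaults to enough
#'   animals that every final family can have distinct parents.
#' @param seed Optional integer seed.
#'
#' @return A data frame of class `hs_pedigree` with columns `id`, `sire`,
#'   `dam`, `sex` ("M"/"F"), `generation`, and `family` (NA except in the
#'   final generation).  Sires and dams always belong to the immediately
#'   preceding generation.
#' @export
simulate_pedigree <- function(n_families = 50, sibs_per_family = 4,
                              n_generations = 3, n_founders = 8,
                              n_mid = NULL, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (n_families < 1 || sibs_per_family < 1 || n_generations < 1)
    stop("counts must be >= 1")
  if (n_founders < 4 || n_founders %% 2 != 0)
    stop("n_founders must be an even number >= 4")
  if (is.null(n_mid)) n_mid <- max(2L * n_families, 2L * n_founders)
  if (n_mid %% 2 != 0) n_mid <- n_mid + 1L

  ped <- data.frame(
    id = paste0("G0_", seq_len(n_founders)),
    sire = NA_character_, dam = NA_character_,
    sex = rep(c("M", "F"), length.out = n_founders),
    generation = 0L, family = NA_integer_,
    stringsAsFactors = FALSE
  )

  make_generation <- function(ped, gen, sizes, fam_ids) {
    prev <- ped[ped$generation == gen - 1L, ]
    males <- prev$id[prev$sex == "M"]
    females <- prev$id[prev$sex == "F"]
    n_fam <- length(sizes)
    if (length(males) < 1L || length(females) < 1L)
      stop("previous generation lacks one sex; population too small")
    # pair distinct parents where possible; full-sib matings are repaired
    # pairwise by re-drawing the dam of each offending couple
    sibkey <- function(ids) {
      i <- match(ids, ped$id)
      ifelse(is.na(ped$sire[i]), paste("f", ids), paste(ped$sire[i], ped$dam[i]))
    }
    s <- sample(males, n_fam, replace = n_fam > length(males))
    d <- sample(females, n_fam, replace = n_fam > length(females))
    pr <- cbind(s, d)
    is_sib <- function(pr) !is.na(ped$sire[match(pr[, 1], ped$id)]) &
      sibkey(pr[, 1]) == sibkey(pr[, 2])
    ok <- FALSE
    for (try in 1:500) {
      bad <- which(is_sib(pr))
      if (!length(bad)) { ok <- TRUE; break }
      pr[bad, 2] <- sample(females, length(bad), replace = TRUE)
    }
    if (!ok) stop("could not form non-sibling matings; population too small")
    off <- data.frame(
      id = paste0("G", gen, "_", seq_len(sum(sizes))),
      sire = rep(pr[, 1], sizes), dam = rep(pr[, 2], sizes),
      sex = sample(c("M", "F"), sum(sizes), replace = TRUE),
      generation = gen,
      family = rep(fam_ids, sizes),
      stringsAsFactors = FALSE
    )
    rbind(ped, off)
  }

  if (n_generations > 1) {
    for (gen in seq_len(n_generations - 1L)) {
      n_fam_mid <- n_mid %/% 2L
      ped <- make_generation(ped, gen, rep(2L, n_fam_mid), rep(NA_integer_, n_fam_mid))
    }
  }
  ped <- make_generation(ped, n_generations,
                         rep(sibs_per_family, n_families), seq_len(n_families))
  # guarantee both sexes in every non-final generation that must breed
  class(ped) <- c("hs_pedigree", "data.frame")
  ped
}

#' Validate a pedigree table
#'
#' Checks column presence, acyclicity via generation ordering, parental sex,
#' and that every named parent exists.
#'
#' @param ped A pedigree data frame (`id`, `sire`, `dam`, `sex`, `generation`).
#' @return The pedigree, invisibly, or an error describing the first problem.
#' @export
validate_pedigree <- function(ped) {
  need <- c("id", "sire", "dam", "sex", "generation")
  miss <- setdiff(need, names(ped))
  if (length(miss)) stop("pedigree missing columns: ", paste(miss, collapse = ", "))
  if (anyDuplicated(ped$id)) stop("duplicate individual ids in pedigree")
  idx <- match(ped$sire, ped$id)
  bad <- which(!is.na(ped$sire) & is.na(idx))
  if (length(bad)) stop("unknown sire for individual ", ped$id[bad[1]])
  jdx <- match(ped$dam, ped$id)
  bad <- which(!is.na(ped$dam) & is.na(jdx))
  if (length(bad)) stop("unknown dam for individual ", ped$id[bad[1]])
  ok <- is.na(idx) | ped$generation[idx] < ped$generation
  if (!all(ok)) stop("sire does not precede offspring in generation order")
  ok <- is.na(jdx) | ped$generation[jdx] < ped$generation
  if (!all(ok)) stop("dam does not precede offspring in generation order")
  if (any(ped$sex[idx[!is.na(idx)]] != "M")) stop("a named sire is not male")
  if (any(ped$sex[jdx[!is.na(jdx)]] != "F")) stop("a named dam is not female")
  invisible(ped)
}

#' Enumerate full-sibling, half-sibling and unrelated pairs in one generation
#'
#' @param ped Pedigree data frame.
#' @param generation Generation to classify (default: the last one).
#' @return List with integer matrices `sibs` (both parents shared),
#'   `halfsibs` (exactly one shared) and `nonsibs` (no shared parent), each
#'   two columns of row indices into the ids of that generation, plus the
#'   ids themselves.
#' @export
sib_pairs <- function(ped, generation = max(ped$generation)) {
  g <- ped[ped$generation == generation, ]
  n <- nrow(g)
  if (n < 2) stop("fewer than two individuals in generation ", generation)
  pr <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  shared <- (!is.na(g$sire[pr[, 1]]) & g$sire[pr[, 1]] == g$sire[pr[, 2]]) +
    (!is.na(g$dam[pr[, 1]]) & g$dam[pr[, 1]] == g$dam[pr[, 2]])
  list(ids = g$id, sibs = pr[shared == 2, , drop = FALSE],
       halfsibs = pr[shared == 1, , drop = FALSE],
       nonsibs = pr[shared == 0, , drop = FALSE])
}
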