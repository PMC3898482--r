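#' File formats
#'
#' Plain-text table readers and writers with schema validation and
#' round-trip fidelity: pedigree CSV (`id, sire, dam, sex, generation`),
#' genotype TSV (rows = individuals, columns = markers, dosages 0/1/2 or
#' NA), marker-map TSV (`marker, chr, bp, cM`), phenotype CSV, region BED
#' (0-based half-open), and square kinship TSV with ids in the header and
#' first column.
#'
#' @param path File path.
#' @param x Object to write.
#' @name poehs_io
NULL

#' @rdname poehs_io
#' @export
write_pedigree <- function(x, path) {
  utils::write.csv(x[, c("id", "sire", "dam", "sex", "generation",
                         intersect("family", names(x)))],
                   path, row.names = FALSE, quote = FALSE, na = "")
}

#' @rdname poehs_io
#' @export
read_pedigree <- function(path) {
  x <- utils::read.csv(path, stringsAsFactors = FALSE, na.strings = "")
  need <- c("id", "sire", "dam", "sex", "generation")
  miss <- setdiff(need, names(x))
  if (length(miss)) stop("pedigree file missing column(s): ",
                         paste(miss, collapse = ", "))
  bad <- which(!x$sex %in% c("M", "F"))
  if (length(bad)) stop("invalid sex code at data row ", bad[1])
  validate_pedigree(x)
  class(x) <- c("hs_pedigree", "data.frame")
  x
}

#' @rdname poehs_io
#' @export
write_genotypes <- function(x, path) {
  df <- data.frame(id = rownames(x), x, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE,
                     na = "NA")
}

#' @rdname poehs_io
#' @export
read_genotypes <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (names(df)[1] != "id") stop("genotype file must start with an 'id' column")
  g <- as.matrix(df[, -1, drop = FALSE])
  mode(g) <- "integer"
  rownames(g) <- df$id
  bad <- which(!is.na(g) & !(g %in% 0:2), arr.ind = TRUE)
  if (nrow(bad) > 0)
    stop("invalid genotype value at row ", rownames(g)[bad[1, 1]],
         ", marker ", colnames(g)[bad[1, 2]], " (must be 0/1/2/NA)")
  g
}

#' @rdname poehs_io
#' @export
write_map <- function(x, path) {
  utils::write.table(x[, c("marker", "chr", "bp", "cM")], path, sep = "\t",
                     row.names = FALSE, quote = FALSE)
}

#' @rdname poehs_io
#' @export
read_map <- function(path) {
  x <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("marker", "chr", "bp", "cM")
  miss <- setdiff(need, names(x))
  if (length(miss)) stop("map file missing column(s): ", paste(miss, collapse = ", "))
  for (cc in unique(x$chr)) {
    bp <- x$bp[x$chr == cc]
    if (is.unsorted(bp, strictly = TRUE))
      stop("marker positions not strictly increasing on chromosome ", cc)
  }
  x
}

#' @rdname poehs_io
#' @export
write_phenotypes <- function(x, path) {
  utils::write.csv(x, path, row.names = FALSE, quote = FALSE)
}

#' @rdname poehs_io
#' @export
read_phenotypes <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' @rdname poehs_io
#' @export
write_regions <- function(x, path) {
  bed <- data.frame(chr = x$chr, start = format(x$start, scientific = FALSE, trim = TRUE),
                    end = format(x$end, scientific = FALSE, trim = TRUE),
                    name = if ("name" %in% names(x)) x$name else ".")
  utils::write.table(bed, path, sep = "\t", row.names = FALSE,
                     col.names = FALSE, quote = FALSE)
}

#' @rdname poehs_io
#' @export
read_regions <- function(path) {
  x <- utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE)
  if (ncol(x) < 3) stop("BED file needs at least 3 columns")
  names(x)[1:3] <- c("chr", "start", "end")
  if (ncol(x) >= 4) names(x)[4] <- "name"
  if (any(x$end <= x$start))
    stop("empty or inverted interval at line ", which(x$end <= x$start)[1])
  x
}

#' @rdname poehs_io
#' @export
write_kinship <- function(x, path) {
  K <- if (inherits(x, "kinship_set")) x$K_pm else x
  df <- data.frame(id = rownames(K), K, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
}

#' @rdname poehs_io
#' @export
read_kinship <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  K <- as.matrix(df[, -1, drop = FALSE])
  rownames(K) <- df$id
  if (nrow(K) != ncol(K)) stop("kinship matrix is not square")
  K
}

#' @rdname poehs_io
#' @export
write_cross_table <- function(x, path) {
  utils::write.csv(x, path, row.names = FALSE, quote = FALSE)
}

#' @rdname poehs_io
#' @export
read_cross_table <- function(path) {
  x <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("id", "sex", "f1_genotype", "ko_parent", "phenotype")
  miss <- setdiff(need, names(x))
  if (length(miss)) stop("cross table missing column(s): ",
                         paste(miss, collapse = ", "))
  if (!"age_weeks" %in% names(x)) x$age_weeks <- NA_real_
  if (any(!is.na(x$age_weeks) & x$age_weeks <= 0))
    stop("non-positive age at data row ",
         which(!is.na(x$age_weeks) & x$age_weeks <= 0)[1])
  class(x) <- c("cross_table", "data.frame")
  x
}

#' Run configuration
#'
#' A `run_config` collects the tunables of the pipeline (HMM parameters,
#' simulation sizes, scan window, FDR threshold) together with an explicit
#' seed for every stochastic stage, and round-trips losslessly through
#' YAML.
#'
#' @param ... Named fields overriding the defaults.
#' @return List of class `run_config`.
#' @export
run_config <- function(...) {
  cfg <- list(
    hmm = list(error = 0.01, lambda = 0.05),
    population = list(n_families = 50, sibs_per_family = 4, n_generations = 3,
                      n_founders = 8, markers_per_chr = 100, n_chr = 1),
    trait = list(n_qtls = 7, variance_per_qtl = 0.05),
    scan = list(window = 10, fdr_threshold = 0.2, n_null_traits = 100),
    seeds = list(population = 1, traits = 2, null = 3)
  )
  dots <- list(...)
  for (nm in names(dots)) {
    cfg[[nm]] <- if (is.list(dots[[nm]]) && is.list(cfg[[nm]]))
      utils::modifyList(cfg[[nm]], dots[[nm]]) else dots[[nm]]
  }
  structure(cfg, class = "run_config")
}

#' @rdname run_config
#' @param path File path for the YAML serialization.
#' @export
write_run_config <- function(x, path) {
  yaml::write_yaml(unclass(x), path)
}

#' @rdname run_config
#' @export
read_run_config <- function(path) {
  structure(yaml::read_yaml(path), class = "run_config")
}
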