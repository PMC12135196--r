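# Tabular input/output: genotype and phenotype TSVs (including PLINK
# .raw-compatible genotype layout), simulator output bundles, run
# configuration files (YAML/JSON) and provenance records.

#' Write a genotype dosage matrix as TSV
#'
#' Header row of marker ids; one row per individual, first column `id`.
#'
#' @param genotypes Dosage matrix with row names (individual ids).
#' @param path Output file.
#' @export
write_genotypes_tsv <- function(genotypes, path) {
  if (is.null(colnames(genotypes)))
    colnames(genotypes) <- sprintf("M%d", seq_len(ncol(genotypes)))
  df <- data.frame(id = rownames(genotypes), genotypes,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a genotype dosage matrix from TSV or PLINK .raw
#'
#' Accepts either the package's TSV layout (first column `id`, remaining
#' columns marker dosages) or a PLINK `.raw` layout (columns FID IID PAT MAT
#' SEX PHENOTYPE followed by per-marker dosages; IID is used as the
#' individual id).  Dosages must be complete and in \{0, 1, 2\}; missing
#' values are rejected (pre-impute or drop markers).
#'
#' @param path Input file.
#' @return Integer dosage matrix with individual ids as row names.
#' @export
read_genotypes_tsv <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE,
                          stringsAsFactors = FALSE, sep = "")
  cn <- names(df)
  if (length(cn) >= 6 && all(toupper(cn[1:6]) ==
                             c("FID", "IID", "PAT", "MAT", "SEX", "PHENOTYPE"))) {
    ids <- as.character(df[[2]])
    M <- as.matrix(df[, -(1:6), drop = FALSE])
  } else {
    ids <- as.character(df[[1]])
    M <- as.matrix(df[, -1, drop = FALSE])
  }
  storage.mode(M) <- "integer"
  if (anyNA(M))
    stop("missing genotypes in ", path, "; impute or drop markers",
         call. = FALSE)
  rownames(M) <- ids
  M
}

#' Write a phenotype table as TSV
#'
#' Columns: `id`, `generation`, `sex`, then one column per trait.
#'
#' @param phenotypes Data frame.
#' @param path Output file.
#' @export
write_phenotypes_tsv <- function(phenotypes, path) {
  utils::write.table(phenotypes, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read a phenotype table from TSV
#'
#' @param path Input file with columns `id`, `generation`, `sex`, then trait
#'   columns.
#' @return Data frame.
#' @export
read_phenotypes_tsv <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("id", "generation")
  if (!all(need %in% names(df)))
    stop("phenotype table must have columns `id` and `generation`",
         call. = FALSE)
  df$id <- as.character(df$id)
  df
}

#' Write the simulator output bundle
#'
#' Writes, into `dir`: `genotypes.tsv`, `phenotypes.tsv` (id, generation, sex,
#' y1..y3), `true_values.tsv` (id, generation, sire, dam, u1..u3),
#' `realized_parameters.tsv`, and `provenance.json` (configuration, seed,
#' package version) — the exact inputs the time-slice estimation consumes plus
#' the true values needed for validation.
#'
#' @param sim A `"sim_population"`.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the directory.
#' @export
write_sim_outputs <- function(sim, dir) {
  stopifnot(inherits(sim, "sim_population"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  ind <- sim$individuals
  write_genotypes_tsv(sim$genotypes, file.path(dir, "genotypes.tsv"))
  write_phenotypes_tsv(ind[, c("id", "generation", "sex", "y1", "y2", "y3")],
                       file.path(dir, "phenotypes.tsv"))
  utils::write.table(ind[, c("id", "generation", "sire", "dam",
                             "u1", "u2", "u3")],
                     file.path(dir, "true_values.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(sim$realized, file.path(dir, "realized_parameters.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  write_provenance(file.path(dir, "provenance.json"),
                   config = unclass_config(sim$config), seed = sim$seed)
  invisible(dir)
}

# sim_config with classed components flattened to plain lists for JSON
unclass_config <- function(config) {
  if (is.list(config)) lapply(unclass(config), unclass_config)
  else config
}

#' Write a provenance record
#'
#' A JSON block with the full configuration, the seed, and the package
#' version — sufficient to reproduce a run byte-for-byte.
#'
#' @param path Output file.
#' @param config Configuration list.
#' @param seed Seed used.
#' @export
write_provenance <- function(path, config, seed) {
  rec <- list(package = "predslice",
              version = as.character(utils::packageVersion("predslice")),
              seed = seed, config = config,
              r_version = as.character(getRversion()))
  jsonlite::write_json(rec, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA, null = "null")
  invisible(path)
}

#' Read a run-configuration file
#'
#' YAML (`.yml`/`.yaml`) or JSON (`.json`), returned as a plain list.
#'
#' @param path Configuration file.
#' @return List.
#' @export
read_run_config <- function(path) {
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("yml", "yaml")) yaml::read_yaml(path)
  else if (ext == "json") jsonlite::read_json(path, simplifyVector = TRUE)
  else stop("unsupported config format: ", ext, call. = FALSE)
}
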