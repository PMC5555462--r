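# Tab-separated readers and writers for the three core tables, plus run
# configuration and the region report. All files are UTF-8 TSV with a
# header row; missing genotypes are written as NA.

read_tsv_checked <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  utils::read.delim(path, sep = "\t", header = TRUE, check.names = FALSE,
                    stringsAsFactors = FALSE, na.strings = "NA")
}

#' Write / read a marker map
#'
#' TSV columns: `id`, `chr`, `pos_mbp`, `pos_cm`. The reader validates
#' ordering, uniqueness and positivity via [marker_map()].
#'
#' @param map a [marker_map()].
#' @param path file path.
#' @return `read_map` returns a [marker_map()]; `write_map` its path,
#'   invisibly.
#' @export
write_map <- function(map, path) {
  utils::write.table(as.data.frame(map), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_map
#' @export
read_map <- function(path) {
  df <- read_tsv_checked(path)
  need <- c("id", "chr", "pos_mbp", "pos_cm")
  if (!all(need %in% names(df)))
    stop("map file ", path, " must have columns: ", paste(need, collapse = ", "))
  dup <- which(duplicated(df$id))
  if (length(dup))
    stop("duplicate marker id at line ", dup[1] + 1L, ": ", df$id[dup[1]])
  tryCatch(marker_map(df$id, df$chr, df$pos_mbp, df$pos_cm),
           error = function(e) stop("invalid map in ", path, ": ",
                                    conditionMessage(e), call. = FALSE))
}

#' Write / read a genotype panel
#'
#' TSV with one row per strain: columns `strain`, `family`, then one
#' column per marker with values A, B, H or NA.
#'
#' @param panel a [genotype_panel()].
#' @param path file path.
#' @return `read_genotypes` returns a [genotype_panel()];
#'   `write_genotypes` its path, invisibly.
#' @export
write_genotypes <- function(panel, path) {
  df <- data.frame(strain = rownames(panel$geno),
                   family = unname(panel$family),
                   panel$geno, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_genotypes
#' @export
read_genotypes <- function(path) {
  df <- read_tsv_checked(path)
  if (!all(c("strain", "family") %in% names(df)))
    stop("genotype file ", path, " must start with columns strain, family")
  markers <- setdiff(names(df), c("strain", "family"))
  dupm <- markers[duplicated(markers)]
  if (length(dupm))
    stop("duplicate marker column(s): ", paste(unique(dupm), collapse = ", "))
  geno <- as.matrix(df[, markers, drop = FALSE])
  mode(geno) <- "character"
  rownames(geno) <- df$strain
  bad <- which(!(geno %in% c("A", "B", "H") | is.na(geno)), arr.ind = TRUE)
  if (nrow(bad))
    stop("unknown allele symbol '", geno[bad[1, , drop = FALSE]],
         "' at line ", bad[1, 1] + 1L, " (strain ", df$strain[bad[1, 1]],
         ", marker ", markers[bad[1, 2]], ")")
  genotype_panel(geno, df$family)
}

#' Write / read an animal-level phenotype panel
#'
#' TSV columns: `animal_id`, `strain`, `condition`, `ige_ng_ml`.
#'
#' @param panel a [phenotype_panel()].
#' @param path file path.
#' @return `read_phenotypes` returns a [phenotype_panel()];
#'   `write_phenotypes` its path, invisibly.
#' @export
write_phenotypes <- function(panel, path) {
  df <- data.frame(animal_id = panel$animal_id, strain = panel$strain,
                   condition = panel$condition, ige_ng_ml = panel$ige,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_phenotypes
#' @export
read_phenotypes <- function(path) {
  df <- read_tsv_checked(path)
  need <- c("animal_id", "strain", "condition", "ige_ng_ml")
  if (!all(need %in% names(df)))
    stop("phenotype file ", path, " must have columns: ",
         paste(need, collapse = ", "))
  bad <- which(!df$condition %in% CONDITIONS)
  if (length(bad))
    stop("unknown condition '", df$condition[bad[1]], "' at line ",
         bad[1] + 1L)
  badi <- which(!is.finite(df$ige_ng_ml) | df$ige_ng_ml <= 0)
  if (length(badi))
    stop("non-positive IgE at line ", badi[1] + 1L, " (animal ",
         df$animal_id[badi[1]], ")")
  phenotype_panel(df$animal_id, df$strain, df$condition, df$ige_ng_ml)
}

#' Run configuration
#'
#' Bundles all settings for a simulate-to-report pipeline run; round-trips
#' losslessly through YAML. A seed is mandatory because every stochastic
#' stage (breeding, phenotypes, permutations) must be reproducible.
#'
#' @param seed integer seed (required).
#' @param conditions conditions to analyze (default all three).
#' @param alpha genome-wide significance level.
#' @param n_perm permutations for the threshold.
#' @param n_acb,n_bca,n_backcrosses breeding settings (used when
#'   simulating).
#' @param n_per_strain animals per strain per condition.
#' @param n_markers markers in the default map (used when simulating).
#' @param genotypes,phenotypes,map optional input paths; when all are NULL
#'   the pipeline simulates its inputs.
#' @param out_dir output directory.
#' @return A `run_config` list.
#' @export
run_config <- function(seed, conditions = CONDITIONS, alpha = 0.05,
                       n_perm = 10000L, n_acb = 10L, n_bca = 21L,
                       n_backcrosses = 2L, n_per_strain = 10L,
                       n_markers = 1215L, genotypes = NULL,
                       phenotypes = NULL, map = NULL, out_dir = ".") {
  if (missing(seed) || is.null(seed)) stop("seed is required")
  structure(list(seed = as.integer(seed), conditions = conditions,
                 alpha = alpha, n_perm = as.integer(n_perm),
                 n_acb = as.integer(n_acb), n_bca = as.integer(n_bca),
                 n_backcrosses = as.integer(n_backcrosses),
                 n_per_strain = as.integer(n_per_strain),
                 n_markers = as.integer(n_markers),
                 genotypes = genotypes, phenotypes = phenotypes, map = map,
                 out_dir = out_dir),
            class = "run_config")
}

#' @rdname run_config
#' @param path YAML file path.
#' @export
write_run_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname run_config
#' @param config a `run_config` (for `write_run_config`).
#' @export
read_run_config <- function(path) {
  x <- yaml::read_yaml(path)
  if (is.null(x$seed)) stop("config ", path, " lacks a seed")
  do.call(run_config, x)
}

#' Write a region report
#'
#' Tab-separated table of called regions — chromosome, region bounds in
#' Mbp (2 decimals, as genome coordinates are conventionally printed for
#' such tables), peak p in scientific notation — followed by comment-line
#' footers recording alpha, permutation count and each condition's
#' threshold on both the -log10 and p scales.
#'
#' @param regions a `region_call` data frame (possibly from several
#'   conditions row-bound together).
#' @param thresholds a `threshold_set` or list of them.
#' @param path output file.
#' @return The formatted table, invisibly.
#' @export
report_regions <- function(regions, thresholds, path) {
  if (inherits(thresholds, "threshold_set")) thresholds <- list(thresholds)
  tab <- data.frame(
    condition = regions$condition, chr = regions$chr,
    region_mbp = sprintf("%.2f-%.2f", regions$start_mbp, regions$end_mbp),
    n_markers = regions$n_markers, peak_marker = regions$peak_marker,
    peak_p = sprintf("%.3g", regions$peak_p), stringsAsFactors = FALSE)
  con <- file(path, "w")
  on.exit(close(con))
  utils::write.table(tab, con, sep = "\t", quote = FALSE, row.names = FALSE)
  for (th in thresholds)
    writeLines(sprintf(
      "# threshold condition=%s alpha=%g n_perm=%s neg_log10=%.4f p=%.3g",
      th$condition, th$alpha, format(th$n_perm), th$threshold_neg_log10,
      th$threshold_p), con)
  invisible(tab)
}

#' Write a scan result table
#' @param scan a `scan_result`.
#' @param path output TSV path.
#' @return The path, invisibly.
#' @export
write_scan <- function(scan, path) {
  utils::write.table(as.data.frame(scan), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
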