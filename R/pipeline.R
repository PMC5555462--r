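#' Run the full simulate-to-report pipeline
#'
#' Chains the package's stages under one seeded configuration: obtain
#' genotypes, phenotypes and map (reading them from the configured paths,
#' or simulating a panel when none are given), compute strain summaries
#' and informative-strain calls, then per condition run the genome scan,
#' the permutation threshold and region delimitation, writing all tables
#' (and a Manhattan plot per condition when `plots = TRUE`) to the output
#' directory together with a run log recording the seed and settings.
#'
#' @param config a [run_config()].
#' @param plots write Manhattan plots (default FALSE; tables only).
#' @return Invisibly, a list with `scan`, `thresholds`, `regions`,
#'   `summaries`, `informative` and the inputs used.
#' @export
run_pipeline <- function(config, plots = FALSE) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  logf <- file.path(config$out_dir, "run_log.txt")
  log_line <- function(...) cat(sprintf(...), "\n", file = logf,
                                append = TRUE, sep = "")
  cat(sprintf("seed=%d alpha=%g n_perm=%d conditions=%s\n", config$seed,
              config$alpha, config$n_perm,
              paste(config$conditions, collapse = ",")), file = logf)
  if (!is.null(config$genotypes)) {
    map <- read_map(config$map)
    panel <- read_genotypes(config$genotypes)
    phenos <- read_phenotypes(config$phenotypes)
    log_line("inputs: %s (%d strains), %s (%d animals), %s (%d markers)",
             config$genotypes, nrow(panel$geno), config$phenotypes,
             nrow(phenos), config$map, nrow(map))
  } else {
    map <- default_marker_map(config$n_markers)
    panel <- breed_rcs_panel(
      breeding_config(n_acb = config$n_acb, n_bca = config$n_bca,
                      n_backcrosses = config$n_backcrosses,
                      seed = config$seed), map)
    phenos <- simulate_phenotypes(panel, qtl_spec(),
                                  n_per_strain = config$n_per_strain,
                                  conditions = config$conditions,
                                  seed = config$seed + 1L)
    write_map(map, file.path(config$out_dir, "map.tsv"))
    write_genotypes(panel, file.path(config$out_dir, "genotypes.tsv"))
    write_phenotypes(phenos, file.path(config$out_dir, "phenotypes.tsv"))
    log_line("simulated %d strains x %d markers, %d animals",
             nrow(panel$geno), nrow(map), nrow(phenos))
  }
  summaries <- summarize_strains(phenos)
  utils::write.table(summaries,
                     file.path(config$out_dir, "strain_summaries.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  informative <- do.call(rbind, lapply(config$conditions, function(cond)
    informative_strains(phenos, cond, seed = config$seed + 2L)))
  if (!is.null(informative))
    utils::write.table(informative,
                       file.path(config$out_dir, "informative_strains.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  scans <- list(); thresholds <- list(); regions <- list()
  for (cond in config$conditions) {
    y <- strain_means(phenos, cond)
    sc <- scan_genome(y, panel, map)
    thr <- permutation_threshold(y, panel, map, alpha = config$alpha,
                                 n_perm = config$n_perm,
                                 seed = config$seed + 3L, condition = cond)
    reg <- call_regions(sc, thr)
    scans[[cond]] <- sc; thresholds[[cond]] <- thr; regions[[cond]] <- reg
    tag <- gsub("[^A-Za-z0-9]", "_", cond)
    write_scan(sc, file.path(config$out_dir,
                             sprintf("scan_results_%s.tsv", tag)))
    log_line("%s: threshold -log10(p)=%.4f (p=%.3g), %d region(s)", cond,
             thr$threshold_neg_log10, thr$threshold_p, nrow(reg))
    if (plots)
      manhattan_plot(sc, thr, out_path = file.path(
        config$out_dir, sprintf("manhattan_%s.png", tag)))
  }
  all_regions <- do.call(rbind, regions)
  report_regions(all_regions, thresholds,
                 file.path(config$out_dir, "regions.tsv"))
  thr_tab <- do.call(rbind, lapply(thresholds, function(th) data.frame(
    condition = th$condition, alpha = th$alpha, n_perm = th$n_perm,
    threshold_neg_log10 = th$threshold_neg_log10,
    threshold_p = th$threshold_p, stringsAsFactors = FALSE)))
  utils::write.table(thr_tab, file.path(config$out_dir, "thresholds.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(list(scan = scans, thresholds = thresholds,
                 regions = all_regions, summaries = summaries,
                 informative = informative, panel = panel, map = map,
                 phenotypes = phenos))
}
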