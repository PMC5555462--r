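# Simulation-based calibration of the scan: family-wise error under the
# null and power to recover a planted QTL. These drive the package's own
# validation and are reusable for study design.

#' Family-wise error rate of the permutation-threshold scan under the null
#'
#' Simulates independent RCS panels with no QTL effects (strain and
#' residual variance only), runs the permutation-threshold genome scan on
#' each, and reports the fraction of panels in which any marker reaches
#' its own panel's threshold. With a well-calibrated threshold this
#' fraction estimates alpha.
#'
#' @param n_panels number of null panels (default 200).
#' @param config a [breeding_config()] (default: study-sized panel of
#'   10 AcB + 21 BcA strains).
#' @param map a [marker_map()] (default [default_marker_map()]).
#' @param qtl a [qtl_spec()] with no effects; its variances set the null
#'   phenotype distribution.
#' @param condition condition simulated and scanned (default baseline).
#' @param n_per_strain animals per strain per condition (default 10).
#' @param alpha,n_perm threshold settings (defaults 0.05 and 1000).
#' @param seed integer seed; panel i uses seed + i for breeding, phenotype
#'   generation and permutations.
#' @return List: `fwer` (fraction of panels with any significant marker),
#'   `hits` (per-panel logical), `n_panels`.
#' @export
null_fwer_calibration <- function(n_panels = 200L, config = breeding_config(),
                                  map = default_marker_map(),
                                  qtl = qtl_spec(), condition = "baseline",
                                  n_per_strain = 10L, alpha = 0.05,
                                  n_perm = 1000L, seed = 1L) {
  stopifnot(nrow(qtl$effects) == 0L)
  hits <- logical(n_panels)
  for (i in seq_len(n_panels)) {
    cfg <- config; cfg$seed <- seed + i
    panel <- breed_rcs_panel(cfg, map)
    ph <- simulate_phenotypes(panel, qtl, n_per_strain = n_per_strain,
                              conditions = condition, seed = seed + i)
    y <- strain_means(ph, condition)
    sc <- scan_genome(y, panel, map)
    thr <- permutation_threshold(y, panel, map, alpha = alpha,
                                 n_perm = n_perm, seed = seed + i,
                                 condition = condition)
    hits[i] <- any(sc$p[!sc$skipped] <= thr$threshold_p)
  }
  list(fwer = mean(hits), hits = hits, n_panels = n_panels)
}

#' Detection rate for a planted QTL
#'
#' Repeatedly breeds a panel, plants a single additive QTL at a chosen
#' marker, runs the permutation-threshold scan, and asks whether a called
#' region contains the planted marker.
#'
#' @param effect QTL effect in log2 units per A allele.
#' @param marker_id marker carrying the QTL; default the marker nearest
#'   84 Mbp on chromosome 4 (the centre of the region the scan design is
#'   aimed at).
#' @param n_reps simulation replicates (default 100).
#' @param config,map,condition,n_per_strain,alpha,n_perm,seed as in
#'   [null_fwer_calibration()].
#' @param strain_variance,residual_variance phenotype variance components.
#' @return List: `rate` (fraction of replicates recovering the marker),
#'   `hits` (per-replicate logical), `marker_id`.
#' @export
qtl_detection_rate <- function(effect, marker_id = NULL, n_reps = 100L,
                               config = breeding_config(),
                               map = default_marker_map(),
                               condition = "baseline", n_per_strain = 10L,
                               strain_variance = 0.25,
                               residual_variance = 0.5,
                               alpha = 0.05, n_perm = 1000L, seed = 1L) {
  if (is.null(marker_id)) {
    chr4 <- map[map$chr == "4", ]
    marker_id <- chr4$id[which.min(abs(chr4$pos_mbp - 84))]
  }
  qtl <- qtl_spec(effects = data.frame(marker_id = marker_id,
                                       effect = effect),
                  strain_variance = strain_variance,
                  residual_variance = residual_variance)
  chr <- map$chr[map$id == marker_id]
  pos <- map$pos_mbp[map$id == marker_id]
  hits <- logical(n_reps)
  for (i in seq_len(n_reps)) {
    cfg <- config; cfg$seed <- seed + i
    panel <- breed_rcs_panel(cfg, map)
    ph <- simulate_phenotypes(panel, qtl, n_per_strain = n_per_strain,
                              conditions = condition, seed = seed + i)
    y <- strain_means(ph, condition)
    sc <- scan_genome(y, panel, map)
    thr <- permutation_threshold(y, panel, map, alpha = alpha,
                                 n_perm = n_perm, seed = seed + i,
                                 condition = condition)
    reg <- call_regions(sc, thr)
    hits[i] <- any(reg$chr == chr & reg$start_mbp <= pos & reg$end_mbp >= pos)
  }
  list(rate = mean(hits), hits = hits, marker_id = marker_id)
}
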