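#' Experimental conditions
#'
#' The three allergen-exposure conditions under which plasma IgE is
#' measured: unsensitized baseline, ovalbumin-sensitized with mock PBS
#' challenge (OVA-PBS), and ovalbumin-sensitized with ovalbumin aerosol
#' challenge (OVA-OVA).
#' @export
CONDITIONS <- c("baseline", "OVA-PBS", "OVA-OVA")

#' QTL specification for phenotype simulation
#'
#' Describes the genetic architecture driving simulated log2 plasma IgE:
#' additive per-locus effects (log2 units added when a strain carries the
#' A/J allele), a strain-level random effect shared across conditions, and
#' an animal-level residual, around per-condition baseline means.
#'
#' @param effects data frame with columns `marker_id`, `effect` (log2
#'   units per A allele) and optionally `conditions` (comma-separated
#'   condition names, or `"all"`); default no QTL.
#' @param strain_variance variance of the strain random effect, log2-units^2
#'   (default 0.25).
#' @param residual_variance animal-level residual variance, log2-units^2
#'   (default 0.5).
#' @param baseline_mean named per-condition mean of log2(IgE in ng/ml).
#'   Defaults place baseline IgE around 2^7 = 128 ng/ml, rising with
#'   sensitization and challenge.
#' @return A `qtl_spec` list.
#' @export
qtl_spec <- function(effects = data.frame(marker_id = character(),
                                          effect = numeric()),
                     strain_variance = 0.25, residual_variance = 0.5,
                     baseline_mean = c("baseline" = 7, "OVA-PBS" = 9,
                                       "OVA-OVA" = 11)) {
  stopifnot(is.data.frame(effects),
            all(c("marker_id", "effect") %in% names(effects)))
  if (strain_variance < 0 || residual_variance < 0)
    stop("variances must be non-negative")
  if (is.null(effects$conditions))
    effects$conditions <- rep("all", nrow(effects))
  stopifnot(all(CONDITIONS %in% names(baseline_mean)))
  structure(list(effects = effects, strain_variance = strain_variance,
                 residual_variance = residual_variance,
                 baseline_mean = baseline_mean),
            class = "qtl_spec")
}

#' Construct a phenotype panel
#'
#' One record per animal: strain, condition and plasma IgE concentration
#' (ng/ml, strictly positive so the log2 transform is defined).
#'
#' @param animal_id,strain,condition,ige equal-length vectors.
#' @return A `phenotype_panel` data frame.
#' @export
phenotype_panel <- function(animal_id, strain, condition, ige) {
  pan <- data.frame(animal_id = as.character(animal_id),
                    strain = as.character(strain),
                    condition = as.character(condition),
                    ige = as.numeric(ige), stringsAsFactors = FALSE)
  bad_cond <- setdiff(unique(pan$condition), CONDITIONS)
  if (length(bad_cond))
    stop("unknown condition(s): ", paste(bad_cond, collapse = ", "))
  bad <- which(!is.finite(pan$ige) | pan$ige <= 0)
  if (length(bad))
    stop("non-positive IgE for animal(s): ",
         paste(pan$animal_id[utils::head(bad, 5)], collapse = ", "))
  class(pan) <- c("phenotype_panel", "data.frame")
  pan
}

# Per-strain additive QTL contribution for one condition, from allele
# dosage (A = 1, H = 0.5, B = 0, missing contributes nothing).
qtl_contribution <- function(panel, qtl, condition) {
  out <- stats::setNames(numeric(nrow(panel$geno)), rownames(panel$geno))
  eff <- qtl$effects
  if (!nrow(eff)) return(out)
  for (j in seq_len(nrow(eff))) {
    conds <- trimws(strsplit(eff$conditions[j], ",")[[1]])
    if (!("all" %in% conds || condition %in% conds)) next
    mk <- eff$marker_id[j]
    if (!mk %in% colnames(panel$geno))
      stop("QTL marker not in panel: ", mk)
    a <- panel$geno[, mk]
    dose <- ifelse(is.na(a), 0, ifelse(a == "A", 1, ifelse(a == "H", 0.5, 0)))
    out <- out + dose * eff$effect[j]
  }
  out
}

#' Simulate animal-level IgE phenotypes for a strain panel
#'
#' Generates plasma IgE on the scale the assay reports (ng/ml) from an
#' additive model on the log2 scale: per-condition baseline mean + sum of
#' QTL effects carried by the strain + a strain random effect (shared
#' across conditions) + an animal residual, then exponentiates, so IgE is
#' log-normal and strictly positive. Group sizes per strain and condition
#' are drawn uniformly from `n_per_strain` (default 5-20 animals, the
#' typical per-strain sample size in RCS phenotyping studies).
#'
#' @param panel a [genotype_panel()].
#' @param qtl a [qtl_spec()].
#' @param n_per_strain integer vector of admissible group sizes (a single
#'   value fixes the size).
#' @param conditions subset of [CONDITIONS] to simulate.
#' @param seed integer seed.
#' @return A [phenotype_panel()].
#' @examples
#' map <- default_marker_map(60)
#' panel <- breed_rcs_panel(breeding_config(n_acb = 2, n_bca = 2, seed = 3), map)
#' ph <- simulate_phenotypes(panel, qtl_spec(), n_per_strain = 6, seed = 4)
#' head(ph)
#' @export
simulate_phenotypes <- function(panel, qtl, n_per_strain = 5:20,
                                conditions = CONDITIONS, seed = NULL) {
  stopifnot(inherits(panel, "genotype_panel"), inherits(qtl, "qtl_spec"))
  if (any(n_per_strain < 1)) stop("n_per_strain must be >= 1")
  if (!is.null(seed)) set.seed(seed)
  strains <- rownames(panel$geno)
  strain_eff <- stats::rnorm(length(strains), 0, sqrt(qtl$strain_variance))
  names(strain_eff) <- strains
  recs <- list()
  for (cond in conditions) {
    gshift <- qtl_contribution(panel, qtl, cond)
    for (s in strains) {
      n <- if (length(n_per_strain) > 1L) sample(n_per_strain, 1L) else n_per_strain
      log2ige <- qtl$baseline_mean[[cond]] + gshift[[s]] + strain_eff[[s]] +
        stats::rnorm(n, 0, sqrt(qtl$residual_variance))
      recs[[length(recs) + 1L]] <- data.frame(
        animal_id = sprintf("%s_%s_%02d", s, gsub("[^A-Za-z0-9]", "", cond),
                            seq_len(n)),
        strain = s, condition = cond, ige = 2^log2ige,
        stringsAsFactors = FALSE)
    }
  }
  all <- do.call(rbind, recs)
  phenotype_panel(all$animal_id, all$strain, all$condition, all$ige)
}

#' Infer strain family from strain names
#'
#' `AcB*` and `BcA*` prefixes name the two RCS families, `CSS*` a
#' chromosome substitution strain, and `A/J` / `C57BL/6J` the parentals.
#'
#' @param strains character vector of strain names.
#' @return Character vector in `AcB`, `BcA`, `CSS`, `parental` (NA if
#'   unrecognized).
#' @export
strain_family <- function(strains) {
  out <- rep(NA_character_, length(strains))
  out[startsWith(strains, "AcB")] <- "AcB"
  out[startsWith(strains, "BcA")] <- "BcA"
  out[startsWith(strains, "CSS")] <- "CSS"
  out[strains %in% c("A/J", "C57BL/6J")] <- "parental"
  out
}
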