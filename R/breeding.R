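# Haplotypes are integer vectors over the marker map: 1 = A/J-derived allele
# ("A"), 0 = C57BL/6J-derived allele ("B").

#' Breeding configuration for a recombinant congenic panel
#'
#' Fixes the breeding scheme used by [breed_rcs_panel()]: an F1 between the
#' two parental strains, `n_backcrosses` backcrosses to the recurrent
#' (major-donor) parent, then brother-sister mating until every marker is
#' fixed. With the default two backcrosses (N3 generation) the expected
#' minor-donor genome fraction is (1/2)^3 = 12.5%, the composition of
#' AcB/BcA-style panels.
#'
#' @param n_acb number of AcB strains (A/J recurrent parent; default 10).
#' @param n_bca number of BcA strains (C57BL/6J recurrent; default 21).
#' @param n_backcrosses backcross generations before sib-mating (>= 1;
#'   default 2).
#' @param max_inbreeding_generations sib-mating generations before residual
#'   heterozygous segments are force-fixed by a fair coin per segment
#'   (default 20).
#' @param seed integer seed; identical configurations reproduce identical
#'   panels.
#' @return A `breeding_config` list.
#' @export
breeding_config <- function(n_acb = 10, n_bca = 21, n_backcrosses = 2,
                            max_inbreeding_generations = 20, seed = 1L) {
  if (n_acb < 0 || n_bca < 0 || n_acb + n_bca < 1)
    stop("config error: need a positive number of strains")
  if (n_backcrosses < 1)
    stop("config error: n_backcrosses must be >= 1")
  structure(
    list(n_acb = as.integer(n_acb), n_bca = as.integer(n_bca),
         n_backcrosses = as.integer(n_backcrosses),
         max_inbreeding_generations = as.integer(max_inbreeding_generations),
         seed = as.integer(seed)),
    class = "breeding_config"
  )
}

# Precompute a genome-wide meiosis layout: marker cM positions laid out on
# one cumulative axis with a large spacer between chromosomes, so a single
# findInterval over all crossover positions resolves every marker's phase.
meiosis_layout <- function(map) {
  idx <- chromosome_index(map)
  n_chr <- length(idx)
  lo <- vapply(idx, function(i) map$pos_cm[i[1]], 0)
  hi <- vapply(idx, function(i) map$pos_cm[i[length(i)]], 0)
  spacer <- 10 * (sum(hi - lo) + 100)
  offset <- spacer * (seq_len(n_chr) - 1L) - lo
  sizes <- lengths(idx)
  list(order = unlist(idx, use.names = FALSE),
       global_cm = map$pos_cm[unlist(idx, use.names = FALSE)] +
         rep(offset, sizes),
       sizes = sizes,
       span_lo = lo + offset, span_hi = hi + offset,
       morgans = (hi - lo) / 100, n_chr = n_chr)
}

# One gamete from a diploid parent. No crossover interference: the number of
# crossovers per chromosome is Poisson in the chromosome's length in
# Morgans, positions uniform on the cM scale; adjacent markers therefore
# recombine with Haldane's probability (1 - exp(-2d))/2. Each chromosome
# starts from a random parental haplotype and crossovers flip the phase.
meiosis_engine <- function(hap1, hap2, layout) {
  n_xo <- stats::rpois(layout$n_chr, layout$morgans)
  start <- rep(sample(c(0L, 1L), layout$n_chr, replace = TRUE),
               layout$sizes)
  if (sum(n_xo) > 0L) {
    xo <- stats::runif(sum(n_xo)) *
      rep(layout$span_hi - layout$span_lo, n_xo) +
      rep(layout$span_lo, n_xo)
    flips <- findInterval(layout$global_cm, sort(xo))
    phase <- (start + flips) %% 2L
  } else {
    phase <- start
  }
  gamete <- hap1
  i <- layout$order[phase == 1L]
  gamete[i] <- hap2[i]
  gamete
}

#' Simulate one meiosis
#'
#' Draws a single gamete from a parent carrying haplotypes `hap1` and `hap2`
#' over the markers of `map`, under a no-interference crossover model:
#' crossover counts per chromosome are Poisson in the chromosome's genetic
#' length (Morgans) and crossover positions are uniform on the cM scale.
#' Adjacent markers at map distance d Morgans consequently recombine with
#' Haldane's map-function probability c = (1 - exp(-2d))/2.
#'
#' @param hap1,hap2 integer haplotypes (1 = A allele, 0 = B allele), one
#'   entry per marker of `map`.
#' @param map a [marker_map()].
#' @return An integer gamete haplotype of the same length.
#' @examples
#' map <- default_marker_map(40)
#' g <- simulate_meiosis(rep(1L, 40), rep(0L, 40), map)
#' @export
simulate_meiosis <- function(hap1, hap2, map) {
  if (length(hap1) != nrow(map) || length(hap2) != nrow(map))
    stop("haplotype length does not match marker count of the map")
  meiosis_engine(as.integer(hap1), as.integer(hap2), meiosis_layout(map))
}

# Force fixation of residual heterozygous segments: each maximal run of
# heterozygous markers inherits hap1 or hap2 with a fair coin, preserving
# the expected donor fraction.
force_fixation <- function(hap1, hap2) {
  het <- hap1 != hap2
  if (!any(het)) return(hap1)
  runs <- rle(het)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  out <- hap1
  for (j in which(runs$values)) {
    if (stats::rbinom(1L, 1L, 0.5) == 1L) {
      i <- starts[j]:ends[j]
      out[i] <- hap2[i]
    }
  }
  out
}

# Breed a single fully inbred RCS strain; returns its fixed haplotype.
# recurrent_allele: 1 for AcB (A/J recurrent), 0 for BcA.
breed_one_strain <- function(layout, n_markers, recurrent_allele,
                             n_backcrosses, max_gen) {
  pure_rec <- rep(as.integer(recurrent_allele), n_markers)
  pure_don <- 1L - pure_rec
  # F1 carries one haplotype from each parent
  ind <- list(pure_rec, pure_don)
  if (n_backcrosses > 1L) {
    for (b in seq_len(n_backcrosses - 1L))
      ind <- list(meiosis_engine(ind[[1]], ind[[2]], layout), pure_rec)
  }
  # final backcross yields two full siblings that found the inbreeding line
  p1 <- list(meiosis_engine(ind[[1]], ind[[2]], layout), pure_rec)
  p2 <- list(meiosis_engine(ind[[1]], ind[[2]], layout), pure_rec)
  for (g in seq_len(max_gen)) {
    o1 <- list(meiosis_engine(p1[[1]], p1[[2]], layout),
               meiosis_engine(p2[[1]], p2[[2]], layout))
    o2 <- list(meiosis_engine(p1[[1]], p1[[2]], layout),
               meiosis_engine(p2[[1]], p2[[2]], layout))
    p1 <- o1; p2 <- o2
    if (identical(p1[[1]], p1[[2]]) && identical(p2[[1]], p2[[2]]) &&
        identical(p1[[1]], p2[[1]]))
      return(p1[[1]])
  }
  force_fixation(p1[[1]], p1[[2]])
}

#' Construct a genotype panel
#'
#' @param geno character matrix, strains x markers, entries in
#'   `A`, `B`, `H` or `NA`; rownames are strain ids, colnames marker ids.
#' @param family character vector, one of `AcB`, `BcA`, `parental`, `CSS`
#'   per strain.
#' @param minor_fraction optional per-strain fraction of markers carrying
#'   the minor-donor allele (NA for parentals).
#' @return A `genotype_panel` object.
#' @export
genotype_panel <- function(geno, family, minor_fraction = NULL) {
  stopifnot(is.matrix(geno), !is.null(rownames(geno)), !is.null(colnames(geno)),
            length(family) == nrow(geno))
  bad <- setdiff(unique(as.vector(geno)), c("A", "B", "H", NA))
  if (length(bad))
    stop("unknown allele symbol(s): ", paste(bad, collapse = ", "))
  bad_fam <- setdiff(unique(family), c("AcB", "BcA", "parental", "CSS"))
  if (length(bad_fam))
    stop("unknown strain family: ", paste(bad_fam, collapse = ", "))
  if (is.null(minor_fraction)) minor_fraction <- rep(NA_real_, nrow(geno))
  structure(
    list(geno = geno, family = stats::setNames(family, rownames(geno)),
         minor_fraction = stats::setNames(minor_fraction, rownames(geno))),
    class = "genotype_panel"
  )
}

#' @export
print.genotype_panel <- function(x, ...) {
  cat("genotype_panel:", nrow(x$geno), "strains x", ncol(x$geno), "markers\n")
  print(table(x$family))
  invisible(x)
}

#' Strain identifiers of a genotype panel
#' @param panel a [genotype_panel()].
#' @return Character vector of strain ids.
#' @export
strain_ids <- function(panel) rownames(panel$geno)

#' Numeric genotype matrix
#'
#' Codes parental-origin alleles numerically for regression: A (A/J allele)
#' = 1, B (C57BL/6J allele) = 0, heterozygous or missing = NA.
#'
#' @param panel a [genotype_panel()].
#' @return Numeric strains x markers matrix.
#' @export
as_genotype_matrix <- function(panel) {
  g <- matrix(NA_real_, nrow(panel$geno), ncol(panel$geno),
              dimnames = dimnames(panel$geno))
  g[panel$geno == "A"] <- 1
  g[panel$geno == "B"] <- 0
  g
}

#' Simulate a recombinant congenic strain panel
#'
#' Breeds each strain through an explicit pedigree simulation: F1 between
#' A/J and C57BL/6J, `n_backcrosses` backcrosses to the recurrent parent
#' (A/J for the AcB family, C57BL/6J for BcA), then brother-sister mating
#' until all markers are homozygous, with residual heterozygous segments
#' force-fixed after `max_inbreeding_generations`. Meiosis follows the
#' Haldane no-interference model on the map's cM positions. All returned
#' strains are fully inbred (no heterozygous calls).
#'
#' @param config a [breeding_config()].
#' @param map a [marker_map()].
#' @param include_parentals also include constant rows for the parental
#'   strains `A/J` (all A) and `C57BL/6J` (all B); default TRUE.
#' @return A [genotype_panel()] with per-strain minor-donor fractions.
#' @examples
#' map <- default_marker_map(120)
#' panel <- breed_rcs_panel(breeding_config(n_acb = 2, n_bca = 3, seed = 7), map)
#' panel$minor_fraction
#' @export
breed_rcs_panel <- function(config, map, include_parentals = TRUE) {
  stopifnot(inherits(config, "breeding_config"))
  validate_marker_map(map)
  set.seed(config$seed)
  layout <- meiosis_layout(map)
  m <- nrow(map)
  ids <- c(sprintf("AcB%02d", seq_len(config$n_acb)),
           sprintf("BcA%02d", seq_len(config$n_bca)))
  fam <- c(rep("AcB", config$n_acb), rep("BcA", config$n_bca))
  haps <- matrix(NA_integer_, length(ids), m)
  for (i in seq_along(ids)) {
    rec <- if (fam[i] == "AcB") 1L else 0L
    haps[i, ] <- breed_one_strain(layout, m, rec, config$n_backcrosses,
                                  config$max_inbreeding_generations)
  }
  # minor donor is the non-recurrent parent
  minor <- ifelse(fam == "AcB", rowMeans(haps == 0L), rowMeans(haps == 1L))
  geno <- matrix(ifelse(haps == 1L, "A", "B"), length(ids), m,
                 dimnames = list(ids, map$id))
  if (include_parentals) {
    geno <- rbind(geno,
                  "A/J" = rep("A", m),
                  "C57BL/6J" = rep("B", m))
    fam <- c(fam, "parental", "parental")
    minor <- c(minor, NA_real_, NA_real_)
  }
  genotype_panel(geno, fam, minor)
}

#' Construct a chromosome substitution (consomic) strain
#'
#' A CSS strain carries one complete chromosome from the A/J donor on an
#' otherwise pure C57BL/6J background (e.g. CSS4 = A/J chromosome 4 on
#' C57BL/6J).
#'
#' @param donor_chromosome chromosome label (`1`..`19` or `"X"`).
#' @param map a [marker_map()].
#' @return A one-strain [genotype_panel()] named `CSS<chromosome>`.
#' @export
make_css_strain <- function(donor_chromosome, map) {
  donor_chromosome <- as.character(donor_chromosome)
  if (!donor_chromosome %in% map$chr)
    stop("chromosome not in map: ", donor_chromosome)
  alleles <- ifelse(map$chr == donor_chromosome, "A", "B")
  geno <- matrix(alleles, 1L, nrow(map),
                 dimnames = list(paste0("CSS", donor_chromosome), map$id))
  genotype_panel(geno, "CSS", mean(alleles == "A"))
}

#' Combine genotype panels over the same markers
#' @param ... [genotype_panel()] objects sharing identical marker columns.
#' @return A single [genotype_panel()].
#' @export
combine_panels <- function(...) {
  panels <- list(...)
  cols <- colnames(panels[[1]]$geno)
  for (p in panels) stopifnot(identical(colnames(p$geno), cols))
  genotype_panel(do.call(rbind, lapply(panels, function(p) p$geno)),
                 unlist(lapply(panels, function(p) unname(p$family))),
                 unlist(lapply(panels, function(p) unname(p$minor_fraction))))
}
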