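# Marker-by-marker linear regression of log2 strain phenotypes on
# parental-origin genotype, permutation-derived genome-wide thresholds, and
# delimitation of significant regions.

#' Per-strain mean log2 phenotype for one condition
#'
#' The response vector of the genome scan: one mean log2(IgE) per RCS
#' strain. Parental and CSS strains are excluded by default — their
#' genotypes are constant (or single-chromosome) across the genome, so
#' single-marker effects would be confounded with whole-genome background.
#'
#' @param panel a [phenotype_panel()].
#' @param condition one of [CONDITIONS].
#' @param exclude_families families dropped from the response (default
#'   `parental` and `CSS`).
#' @return Named numeric vector of per-strain means (empty, with a
#'   warning, when the condition has no records).
#' @export
strain_means <- function(panel, condition,
                         exclude_families = c("parental", "CSS")) {
  sub <- panel[panel$condition == condition, , drop = FALSE]
  if (!nrow(sub)) {
    warning("no records for condition ", condition)
    return(stats::setNames(numeric(0), character(0)))
  }
  fam <- strain_family(unique(sub$strain))
  keep <- unique(sub$strain)[!(fam %in% exclude_families)]
  dropped_empty <- setdiff(unique(panel$strain), unique(sub$strain))
  if (length(dropped_empty))
    warning("strain(s) with no animals in ", condition, " dropped: ",
            paste(dropped_empty, collapse = ", "))
  sub <- sub[sub$strain %in% keep, , drop = FALSE]
  m <- tapply(log2(sub$ige), sub$strain, mean)
  stats::setNames(as.numeric(m), names(m))
}

# Vectorized scan statistics. Y: n_rep x n matrix of response vectors
# (each row one phenotype vector over the same n strains); G: n x m
# genotype matrix coded 1 = A allele, 0 = B allele, NA = dropped (H or
# missing). For binary genotype the OLS slope t-test is algebraically the
# pooled two-sample t-test comparing A-strains with B-strains.
marker_scan_stats <- function(Y, G, min_class = 3L, with_p = TRUE) {
  if (is.null(dim(Y))) Y <- matrix(Y, nrow = 1L)
  n <- ncol(Y); m <- ncol(G)
  stopifnot(nrow(G) == n)
  M <- !is.na(G)
  complete <- all(M)
  G0 <- G; G0[!M] <- 0
  n1 <- colSums(G0)
  nm <- if (complete) rep(n, m) else colSums(M)
  n0 <- nm - n1
  skipped <- n1 < min_class | n0 < min_class
  reason <- rep(NA_character_, m)
  reason[skipped & (n1 == 0 | n0 == 0)] <- "monomorphic"
  reason[skipped & is.na(reason)] <- "insufficient class size"
  S1 <- Y %*% G0
  if (complete) {
    St <- matrix(rowSums(Y), nrow(Y), m)
    SS <- matrix(rowSums(Y^2), nrow(Y), m)
  } else {
    St <- Y %*% M
    SS <- Y^2 %*% M
  }
  NM <- matrix(nm, nrow(Y), m, byrow = TRUE)
  N1 <- matrix(n1, nrow(Y), m, byrow = TRUE)
  N0 <- NM - N1
  beta <- S1 / N1 - (St - S1) / N0
  syy <- SS - St^2 / NM
  ssr <- beta^2 * N1 * N0 / NM
  dfm <- NM - 2
  sigma2 <- pmax(syy - ssr, 0) / dfm
  se <- sqrt(sigma2 * NM / (N1 * N0))
  tstat <- beta / se
  if (with_p) {
    p <- 2 * stats::pt(-abs(tstat), dfm)
    p <- pmax(p, .Machine$double.xmin)  # keep p in (0, 1] for the log scale
  } else {
    p <- NULL
  }
  if (any(skipped)) {
    beta[, skipped] <- NA; se[, skipped] <- NA
    tstat[, skipped] <- NA
    if (with_p) p[, skipped] <- NA
  }
  list(beta = beta, se = se, t = tstat, p = p, df = dfm[1, ],
       n_used = nm, skipped = skipped, reason = reason)
}

#' Single-marker regression fit
#'
#' Ordinary least-squares regression of a strain-mean phenotype vector on
#' one binary genotype column (0 = B/C57BL/6J allele, 1 = A/A-J allele),
#' with a two-sided t-test on the slope. For binary genotype this equals
#' the pooled two-sample t-test comparing A-carrying with B-carrying
#' strains; a positive slope means the A/J allele raises the phenotype.
#' Markers with fewer than `min_class` strains in either genotype class
#' (after dropping heterozygous/missing calls) are skipped.
#'
#' @param y numeric response vector (strain means of log2 IgE).
#' @param g genotype column: numeric 0/1/NA, or characters A/B/H/NA.
#' @param min_class minimum strains per genotype class (default 3).
#' @return One-row data frame: `beta`, `se`, `t_stat`, `p`,
#'   `neg_log10_p`, `n_used`, `skipped`, `reason`.
#' @export
fit_marker <- function(y, g, min_class = 3L) {
  if (is.character(g)) {
    gc <- rep(NA_real_, length(g))
    gc[g == "A"] <- 1; gc[g == "B"] <- 0
    g <- gc
  }
  stopifnot(length(y) == length(g))
  st <- marker_scan_stats(matrix(y, 1L), matrix(g, ncol = 1L), min_class)
  data.frame(beta = st$beta[1, 1], se = st$se[1, 1], t_stat = st$t[1, 1],
             p = st$p[1, 1], neg_log10_p = -log10(st$p[1, 1]),
             n_used = st$n_used[1], skipped = st$skipped[1],
             reason = st$reason[1], stringsAsFactors = FALSE)
}

#' Genome-wide marker-by-marker regression scan
#'
#' Fits [fit_marker()] at every marker of the map, one row per marker in
#' map order. The response is a named vector of per-strain mean log2
#' phenotypes (see [strain_means()]); genotypes are taken from the panel
#' rows matching those names.
#'
#' @param y named numeric vector of strain-mean log2 phenotypes.
#' @param panel a [genotype_panel()].
#' @param map a [marker_map()] matching the panel's marker columns.
#' @param min_class minimum strains per genotype class (default 3).
#' @return A `scan_result` data frame: `marker_id`, `chr`, `pos_mbp`,
#'   `beta`, `se`, `t_stat`, `p`, `neg_log10_p`, `n_used`, `skipped`,
#'   `reason`.
#' @examples
#' map <- default_marker_map(80)
#' panel <- breed_rcs_panel(breeding_config(n_acb = 4, n_bca = 8, seed = 11), map)
#' ph <- simulate_phenotypes(panel, qtl_spec(), n_per_strain = 8, seed = 2)
#' sc <- scan_genome(strain_means(ph, "baseline"), panel, map)
#' head(sc)
#' @export
scan_genome <- function(y, panel, map, min_class = 3L) {
  stopifnot(inherits(panel, "genotype_panel"))
  validate_marker_map(map)
  if (!identical(colnames(panel$geno), map$id))
    stop("panel markers do not match map")
  if (is.null(names(y))) stop("y must be named by strain")
  missing <- setdiff(names(y), rownames(panel$geno))
  if (length(missing))
    stop("strain(s) in y absent from genotype panel: ",
         paste(missing, collapse = ", "))
  G <- as_genotype_matrix(panel)[names(y), , drop = FALSE]
  st <- marker_scan_stats(matrix(y, 1L), G, min_class)
  out <- data.frame(marker_id = map$id, chr = map$chr, pos_mbp = map$pos_mbp,
                    beta = st$beta[1, ], se = st$se[1, ], t_stat = st$t[1, ],
                    p = st$p[1, ], neg_log10_p = -log10(st$p[1, ]),
                    n_used = st$n_used, skipped = st$skipped,
                    reason = st$reason, stringsAsFactors = FALSE)
  class(out) <- c("scan_result", "data.frame")
  out
}

#' Empirical order-statistic quantile (ceiling rule)
#'
#' Type-1 empirical quantile: the k-th order statistic with
#' k = ceiling(q * n) (k = 1 when q = 0). Used for the permutation
#' threshold so that, e.g., the 0.95 quantile of 10,000 permutation maxima
#' is exactly the 9500th sorted value.
#'
#' @param values non-empty numeric vector.
#' @param q probability in `[0, 1]`.
#' @return The selected order statistic.
#' @export
quantile_rule <- function(values, q) {
  if (!length(values)) stop("empty values")
  if (!is.finite(q) || q < 0 || q > 1) stop("q must be in [0, 1]")
  k <- max(1L, ceiling(q * length(values)))
  sort(values)[k]
}

#' Permutation-derived genome-wide significance threshold
#'
#' The family-wise threshold construction of Churchill and Doerge: for
#' each of `n_perm` permutations the strain labels of the response are
#' shuffled, the full genome scan re-run, and the genome-wide maximum of
#' -log10(p) recorded; the threshold is the empirical (1 - alpha) quantile
#' (ceiling rule, [quantile_rule()]) of those maxima. Permuting strains —
#' the exchangeable units — preserves the within-strain correlation
#' structure.
#'
#' @param y named numeric vector of strain-mean log2 phenotypes.
#' @param panel a [genotype_panel()].
#' @param map a [marker_map()].
#' @param alpha genome-wide significance level (default 0.05).
#' @param n_perm number of permutations (>= 100; default 10000).
#' @param seed integer seed for the permutations.
#' @param condition optional condition label carried into the result.
#' @param min_class passed to the scan.
#' @return A `threshold_set` list: `condition`, `alpha`, `n_perm`,
#'   `threshold_neg_log10`, `threshold_p` (= 10^-threshold_neg_log10),
#'   `seed`.
#' @export
permutation_threshold <- function(y, panel, map, alpha = 0.05,
                                  n_perm = 10000L, seed = NULL,
                                  condition = NA_character_,
                                  min_class = 3L) {
  if (!is.finite(alpha) || alpha <= 0 || alpha > 1)
    stop("alpha must be in (0, 1]")
  if (n_perm < 100) stop("n_perm must be >= 100")
  stopifnot(inherits(panel, "genotype_panel"))
  if (!is.null(seed)) set.seed(seed)
  G <- as_genotype_matrix(panel)[names(y), , drop = FALSE]
  n <- length(y)
  Yperm <- t(vapply(seq_len(n_perm), function(i) y[sample.int(n)],
                    numeric(n)))
  st <- marker_scan_stats(Yperm, G, min_class, with_p = FALSE)
  if (all(st$skipped)) stop("all markers skipped; cannot form a threshold")
  dfs <- st$df[!st$skipped]
  if (all(dfs == dfs[1])) {
    # constant df: max -log10(p) is attained at max |t|, so p is only
    # needed for the n_perm per-permutation maxima
    at <- abs(st$t[, !st$skipped, drop = FALSE])
    tmax <- at[cbind(seq_len(nrow(at)), max.col(at, ties.method = "first"))]
    maxima <- -log10(pmax(2 * stats::pt(-tmax, dfs[1]),
                          .Machine$double.xmin))
  } else {
    P <- 2 * stats::pt(-abs(st$t[, !st$skipped, drop = FALSE]),
                       matrix(dfs, nrow(Yperm), length(dfs), byrow = TRUE))
    maxima <- -log10(pmax(apply(P, 1L, min), .Machine$double.xmin))
  }
  thr <- quantile_rule(maxima, 1 - alpha)
  threshold_set(condition = condition, alpha = alpha, n_perm = n_perm,
                threshold_neg_log10 = thr, seed = seed)
}

#' Construct a threshold set
#'
#' Holds a genome-wide significance threshold on both reporting scales;
#' `threshold_p` is 10^(-threshold_neg_log10) exactly.
#'
#' @param threshold_neg_log10 threshold on the -log10(p) scale.
#' @param condition,alpha,n_perm,seed provenance fields.
#' @return A `threshold_set` list.
#' @export
threshold_set <- function(threshold_neg_log10, condition = NA_character_,
                          alpha = 0.05, n_perm = NA_integer_, seed = NULL) {
  stopifnot(is.finite(threshold_neg_log10), threshold_neg_log10 > 0)
  structure(list(condition = condition, alpha = alpha,
                 n_perm = n_perm,
                 threshold_neg_log10 = threshold_neg_log10,
                 threshold_p = 10^(-threshold_neg_log10),
                 seed = if (is.null(seed)) NA_integer_ else seed),
            class = "threshold_set")
}

#' @export
print.threshold_set <- function(x, ...) {
  cat(sprintf(
    "threshold_set: %s alpha=%.3g n_perm=%s  -log10(p)=%.3f  p=%.3g\n",
    ifelse(is.na(x$condition), "(no condition)", x$condition), x$alpha,
    format(x$n_perm), x$threshold_neg_log10, x$threshold_p))
  invisible(x)
}

#' Delimit significant regions from a genome scan
#'
#' A region is a maximal run of consecutive non-skipped markers on one
#' chromosome whose p-values all fall at or below the threshold; its
#' bounds are the outermost markers' physical positions (single-marker
#' regions have start = end) and its peak is the smallest p in the run
#' (ties broken by lowest position). Skipped markers are transparent; by
#' default a single non-significant marker splits a region (`gap = 0`),
#' but up to `gap` consecutive non-significant markers may be bridged.
#'
#' @param scan a `scan_result` from [scan_genome()].
#' @param thr a `threshold_set` (or a bare p-value threshold).
#' @param gap maximum run of interior non-significant markers bridged
#'   inside a region (default 0).
#' @return A `region_call` data frame: `condition`, `chr`, `start_mbp`,
#'   `end_mbp`, `n_markers`, `peak_marker`, `peak_p`.
#' @export
call_regions <- function(scan, thr, gap = 0L) {
  p_thr <- if (inherits(thr, "threshold_set")) thr$threshold_p else thr
  cond <- if (inherits(thr, "threshold_set")) thr$condition else NA_character_
  empty <- data.frame(condition = character(), chr = character(),
                      start_mbp = numeric(), end_mbp = numeric(),
                      n_markers = integer(), peak_marker = character(),
                      peak_p = numeric(), stringsAsFactors = FALSE)
  out <- list()
  for (ch in unique(scan$chr)) {
    sub <- scan[scan$chr == ch & !scan$skipped, , drop = FALSE]
    if (!nrow(sub)) next
    sig <- sub$p <= p_thr
    if (!any(sig)) next
    # group significant markers, bridging runs of <= gap non-significant ones
    grp <- integer(nrow(sub)); cur <- 0L; miss <- Inf
    for (i in seq_len(nrow(sub))) {
      if (sig[i]) {
        if (miss > gap) cur <- cur + 1L
        grp[i] <- cur; miss <- 0L
      } else {
        miss <- miss + 1L
      }
    }
    for (g in seq_len(max(grp))) {
      i <- which(grp == g)
      i <- seq(min(i), max(i))       # include bridged interior markers
      run <- sub[i, , drop = FALSE]
      peak <- run[order(run$p, run$pos_mbp), ][1, ]
      out[[length(out) + 1L]] <- data.frame(
        condition = cond, chr = ch, start_mbp = min(run$pos_mbp),
        end_mbp = max(run$pos_mbp), n_markers = nrow(run),
        peak_marker = peak$marker_id, peak_p = peak$p,
        stringsAsFactors = FALSE)
    }
  }
  res <- if (length(out)) do.call(rbind, out) else empty
  rownames(res) <- NULL
  class(res) <- c("region_call", "data.frame")
  res
}
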