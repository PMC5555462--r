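# Strain-level phenotype statistics on the log2 scale: group summaries,
# parental contrasts, and many-to-one (Dunnett) comparisons that flag
# informative strains.

signif_stars <- function(p) {
  ifelse(is.na(p), "",
         ifelse(p <= 0.001, "***",
                ifelse(p <= 0.01, "**", ifelse(p <= 0.05, "*", ""))))
}

log2_values <- function(panel, strain, condition) {
  v <- panel$ige[panel$strain == strain & panel$condition == condition]
  log2(v)
}

#' Per-strain phenotype summaries
#'
#' Mean and standard error of log2-transformed IgE for every (strain,
#' condition) group present in the panel, the quantities plotted as
#' "mean of log2 values +/- SEM" in strain-distribution figures.
#'
#' @param panel a [phenotype_panel()].
#' @return Data frame with columns `strain`, `condition`, `n`, `mean_log2`,
#'   `sem_log2` (NA when n = 1). Strain x condition combinations with no
#'   animals are absent, with a warning.
#' @export
summarize_strains <- function(panel) {
  stopifnot(is.data.frame(panel), all(c("strain", "condition", "ige") %in%
                                        names(panel)))
  bad <- which(!is.finite(panel$ige) | panel$ige <= 0)
  if (length(bad))
    stop("non-positive IgE for record(s): ",
         paste(rownames(panel)[utils::head(bad, 5)], collapse = ", "))
  grp <- interaction(panel$strain, panel$condition, drop = TRUE, sep = "\r")
  lv <- log2(panel$ige)
  n <- tapply(lv, grp, length)
  m <- tapply(lv, grp, mean)
  s <- tapply(lv, grp, stats::sd) / sqrt(n)
  keys <- do.call(rbind, strsplit(names(n), "\r", fixed = TRUE))
  out <- data.frame(strain = keys[, 1], condition = keys[, 2],
                    n = as.integer(n), mean_log2 = as.numeric(m),
                    sem_log2 = as.numeric(s), stringsAsFactors = FALSE)
  out <- out[order(match(out$condition, CONDITIONS), out$strain), ]
  rownames(out) <- NULL
  n_missing <- length(unique(panel$strain)) * length(unique(panel$condition)) -
    nrow(out)
  if (n_missing > 0)
    warning(n_missing, " strain x condition group(s) have no animals and are omitted")
  out
}

#' Two-strain contrast by t-test on log2 values
#'
#' Two-sided two-sample t-test of log2(IgE) between two strains in one
#' condition; pooled-variance by default, Welch via `var_equal = FALSE`.
#' This is the parental A/J vs C57BL/6J comparison.
#'
#' @param panel a [phenotype_panel()].
#' @param strain_a,strain_b strain names.
#' @param condition one of [CONDITIONS].
#' @param var_equal pooled-variance t-test (default TRUE).
#' @return List with `mean_diff` (log2 units, a - b), `t`, `df`, `p_value`,
#'   `n` (per-group sizes).
#' @export
parental_contrast <- function(panel, strain_a, strain_b, condition,
                              var_equal = TRUE) {
  xa <- log2_values(panel, strain_a, condition)
  xb <- log2_values(panel, strain_b, condition)
  if (length(xa) < 2 || length(xb) < 2)
    stop("need >= 2 animals per strain; got ", length(xa), " for ", strain_a,
         " and ", length(xb), " for ", strain_b, " in ", condition)
  if (stats::sd(c(xa, xb)) == 0)
    return(list(mean_diff = 0, t = 0, df = length(xa) + length(xb) - 2,
                p_value = 1, n = c(length(xa), length(xb))))
  ht <- stats::t.test(xa, xb, var.equal = var_equal)
  list(mean_diff = unname(diff(rev(ht$estimate))), t = unname(ht$statistic),
       df = unname(ht$parameter), p_value = ht$p.value,
       n = c(length(xa), length(xb)))
}

#' Dunnett many-to-one comparisons against a reference strain
#'
#' One-way ANOVA followed by Dunnett's procedure: each test strain is
#' compared to the reference (major parental) strain by a t statistic on
#' the pooled ANOVA error, and p-values are adjusted for the family of k
#' comparisons under the equicorrelated multivariate-t distribution
#' (correlation 1/2 when balanced; per-pairwise sample sizes otherwise).
#' The multivariate-t probabilities are computed by quasi-Monte-Carlo
#' integration (Genz-Bretz, absolute tolerance ~1e-4).
#'
#' @param panel a [phenotype_panel()].
#' @param reference_strain the major parental strain (A/J for AcB strains,
#'   C57BL/6J for BcA).
#' @param test_strains character vector of strains to compare.
#' @param condition one of [CONDITIONS].
#' @param alpha familywise significance level (default 0.05).
#' @param correlation `"unbalanced"` (default, correlation from pairwise n)
#'   or `"balanced"` (fixed 1/2).
#' @param seed optional seed for the quasi-Monte-Carlo integration.
#' @return Data frame (one row per test strain): `strain`, `condition`,
#'   `n`, `mean_log2`, `direction` (sign of strain mean - reference mean),
#'   `raw_p`, `adjusted_p`, `significant` (adjusted_p <= alpha), `stars`,
#'   `degenerate` (TRUE when the pooled variance is zero, in which case no
#'   p-values are emitted).
#' @export
dunnett_many_to_one <- function(panel, reference_strain, test_strains,
                                condition, alpha = 0.05,
                                correlation = c("unbalanced", "balanced"),
                                seed = NULL) {
  correlation <- match.arg(correlation)
  k <- length(test_strains)
  empty <- data.frame(strain = character(), condition = character(),
                      n = integer(), mean_log2 = numeric(),
                      direction = numeric(), raw_p = numeric(),
                      adjusted_p = numeric(), significant = logical(),
                      stars = character(), degenerate = logical(),
                      stringsAsFactors = FALSE)
  if (k == 0) return(empty)
  if (!is.null(seed)) set.seed(seed)
  groups <- lapply(c(reference_strain, test_strains), log2_values,
                   panel = panel, condition = condition)
  ns <- lengths(groups)
  if (any(ns < 2))
    stop("need >= 2 animals per strain in ", condition, "; offending: ",
         paste(c(reference_strain, test_strains)[ns < 2], collapse = ", "))
  means <- vapply(groups, mean, 0)
  N <- sum(ns)
  df <- N - (k + 1L)
  mse <- sum(vapply(seq_along(groups),
                    function(i) sum((groups[[i]] - means[i])^2), 0)) / df
  n0 <- ns[1]
  ni <- ns[-1]
  diff <- means[-1] - means[1]
  degenerate <- mse <= 0
  if (degenerate) {
    return(data.frame(strain = test_strains, condition = condition,
                      n = as.integer(ni), mean_log2 = means[-1],
                      direction = sign(diff), raw_p = NA_real_,
                      adjusted_p = NA_real_, significant = NA,
                      stars = "", degenerate = TRUE,
                      stringsAsFactors = FALSE))
  }
  tstat <- diff / sqrt(mse * (1 / ni + 1 / n0))
  raw_p <- 2 * stats::pt(-abs(tstat), df)
  if (correlation == "balanced") {
    R <- matrix(0.5, k, k); diag(R) <- 1
  } else {
    lam <- sqrt(ni / (ni + n0))
    R <- tcrossprod(lam); diag(R) <- 1
  }
  adj <- vapply(abs(tstat), function(q) {
    if (k == 1L) return(2 * stats::pt(-q, df))
    pr <- mvtnorm::pmvt(lower = rep(-q, k), upper = rep(q, k), df = df,
                        corr = R, algorithm = mvtnorm::GenzBretz(abseps = 1e-4))
    1 - as.numeric(pr)
  }, 0)
  adj <- pmin(1, pmax(adj, raw_p))  # multiplicity can only increase p
  data.frame(strain = test_strains, condition = condition,
             n = as.integer(ni), mean_log2 = means[-1],
             direction = sign(diff), raw_p = raw_p, adjusted_p = adj,
             significant = adj <= alpha, stars = signif_stars(adj),
             degenerate = FALSE, stringsAsFactors = FALSE)
}

#' Flag informative strains across both RCS families
#'
#' Convenience wrapper running [dunnett_many_to_one()] per family with the
#' appropriate major parental reference: AcB strains against A/J, BcA
#' strains against C57BL/6J. A strain is informative when its phenotype
#' differs significantly from its major parental strain, implying it
#' carries segregating alleles for the trait.
#'
#' @param panel a [phenotype_panel()] containing RCS and parental strains.
#' @param condition one of [CONDITIONS].
#' @param ... passed to [dunnett_many_to_one()].
#' @return Row-bound data frame of both families' calls.
#' @export
informative_strains <- function(panel, condition, ...) {
  strains <- unique(panel$strain)
  fam <- strain_family(strains)
  out <- list()
  for (f in c("AcB", "BcA")) {
    ref <- if (f == "AcB") "A/J" else "C57BL/6J"
    test <- sort(strains[!is.na(fam) & fam == f])
    if (length(test) && ref %in% strains)
      out[[f]] <- dunnett_many_to_one(panel, ref, test, condition, ...)
  }
  do.call(rbind, c(out, list(make.row.names = FALSE)))
}

#' Three-group pairwise comparisons with Bonferroni correction
#'
#' One-way ANOVA over exactly three strains followed by all three pairwise
#' contrasts on the pooled error, each p-value multiplied by 3 and capped
#' at 1 — the comparison used for CSS strains against both parentals.
#'
#' @param panel a [phenotype_panel()].
#' @param strains exactly three strain names.
#' @param condition one of [CONDITIONS].
#' @return Data frame with `strain_1`, `strain_2`, `mean_diff` (log2),
#'   `raw_p`, `adjusted_p`, `stars`.
#' @export
bonferroni_three_group <- function(panel, strains, condition) {
  if (length(strains) != 3)
    stop("exactly three strains required, got ", length(strains))
  groups <- lapply(strains, log2_values, panel = panel, condition = condition)
  ns <- lengths(groups)
  if (any(ns < 2))
    stop("need >= 2 animals per strain; offending: ",
         paste(strains[ns < 2], collapse = ", "))
  means <- vapply(groups, mean, 0)
  df <- sum(ns) - 3L
  mse <- sum(vapply(seq_along(groups),
                    function(i) sum((groups[[i]] - means[i])^2), 0)) / df
  pairs <- utils::combn(3, 2)
  res <- apply(pairs, 2, function(ij) {
    i <- ij[1]; j <- ij[2]
    d <- means[i] - means[j]
    if (mse <= 0) {
      p <- if (d == 0) 1 else 0
    } else {
      t <- d / sqrt(mse * (1 / ns[i] + 1 / ns[j]))
      p <- 2 * stats::pt(-abs(t), df)
    }
    c(d = d, p = p)
  })
  raw_p <- res["p", ]
  adj <- pmin(1, 3 * raw_p)
  data.frame(strain_1 = strains[pairs[1, ]], strain_2 = strains[pairs[2, ]],
             mean_diff = res["d", ], raw_p = raw_p, adjusted_p = adj,
             stars = signif_stars(adj), stringsAsFactors = FALSE)
}
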