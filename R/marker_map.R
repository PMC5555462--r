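# Canonical chromosome ordering for the mouse genome: autosomes 1-19, then X.
CHROMOSOMES <- c(as.character(1:19), "X")

# Approximate mm10 chromosome lengths in Mbp, used by the default marker map.
MM10_CHR_MBP <- c(
  "1" = 195.47, "2" = 182.11, "3" = 160.04, "4" = 156.51, "5" = 151.83,
  "6" = 149.74, "7" = 145.44, "8" = 129.40, "9" = 124.60, "10" = 130.69,
  "11" = 122.08, "12" = 120.13, "13" = 120.42, "14" = 124.90, "15" = 104.04,
  "16" = 98.21, "17" = 94.99, "18" = 90.70, "19" = 61.43, "X" = 171.03
)

#' Construct a marker map
#'
#' A marker map is an ordered table of genetic markers with a chromosome
#' label, a physical position in megabase pairs (Mbp, GRCm38/mm10
#' coordinates) and a genetic position in centimorgans (cM). Markers must be
#' strictly ordered by chromosome (1-19 then X) and physical position, with
#' non-decreasing genetic position within each chromosome.
#'
#' @param id character vector of unique marker identifiers.
#' @param chr chromosome labels, each one of `1..19` or `"X"`.
#' @param pos_mbp physical positions in Mbp, strictly positive and strictly
#'   increasing within a chromosome.
#' @param pos_cm genetic positions in cM, non-decreasing within a chromosome.
#' @return A `marker_map` data frame with columns `id`, `chr`, `pos_mbp`,
#'   `pos_cm`, one row per marker in genome order.
#' @seealso [default_marker_map()]
#' @export
marker_map <- function(id, chr, pos_mbp, pos_cm) {
  chr <- as.character(chr)
  map <- data.frame(
    id = as.character(id), chr = chr,
    pos_mbp = as.numeric(pos_mbp), pos_cm = as.numeric(pos_cm),
    stringsAsFactors = FALSE
  )
  validate_marker_map(map)
  class(map) <- c("marker_map", "data.frame")
  map
}

validate_marker_map <- function(map) {
  stopifnot(is.data.frame(map),
            all(c("id", "chr", "pos_mbp", "pos_cm") %in% names(map)))
  if (anyDuplicated(map$id))
    stop("duplicate marker id(s): ",
         paste(unique(map$id[duplicated(map$id)]), collapse = ", "))
  bad_chr <- setdiff(unique(map$chr), CHROMOSOMES)
  if (length(bad_chr))
    stop("unknown chromosome label(s): ", paste(bad_chr, collapse = ", "))
  if (any(!is.finite(map$pos_mbp)) || any(map$pos_mbp <= 0))
    stop("pos_mbp must be finite and > 0")
  ord <- order(match(map$chr, CHROMOSOMES), map$pos_mbp)
  if (!identical(ord, seq_len(nrow(map))))
    stop("markers must be ordered by (chromosome, pos_mbp)")
  for (ch in unique(map$chr)) {
    i <- map$chr == ch
    if (any(diff(map$pos_mbp[i]) <= 0))
      stop("pos_mbp must be strictly increasing within chromosome ", ch)
    if (any(diff(map$pos_cm[i]) < 0))
      stop("pos_cm must be non-decreasing within chromosome ", ch)
  }
  invisible(map)
}

#' Default genome-wide marker map
#'
#' Builds a synthetic marker map mirroring the density of the 1215-marker
#' SNP/microsatellite panel used for AcB/BcA genome scans: markers are
#' spread over the 19 autosomes and the X chromosome proportionally to mm10
#' chromosome length, evenly spaced within each chromosome. Genetic
#' positions use a uniform expansion of `cm_per_mbp` centimorgans per
#' megabase (default 0.5, giving a genome of roughly 13 Morgans).
#'
#' @param n_markers total number of markers (default 1215).
#' @param cm_per_mbp genetic map expansion, cM per Mbp (default 0.5).
#' @return A [marker_map()] with `n_markers` rows.
#' @examples
#' map <- default_marker_map()
#' nrow(map)            # 1215
#' table(map$chr)["19"] # fewest markers on the shortest autosome
#' @export
default_marker_map <- function(n_markers = 1215, cm_per_mbp = 0.5) {
  stopifnot(n_markers >= length(MM10_CHR_MBP))
  len <- MM10_CHR_MBP
  # largest-remainder apportionment so counts sum exactly to n_markers
  quota <- n_markers * len / sum(len)
  k <- floor(quota)
  rem <- n_markers - sum(k)
  if (rem > 0) {
    top <- order(quota - k, decreasing = TRUE)[seq_len(rem)]
    k[top] <- k[top] + 1
  }
  k[k < 1] <- 1
  pieces <- lapply(names(len), function(ch) {
    n <- k[[ch]]
    pos <- len[[ch]] * (seq_len(n) - 0.5) / n
    data.frame(
      id = sprintf("m%s_%03d", ch, seq_len(n)),
      chr = ch, pos_mbp = pos, pos_cm = pos * cm_per_mbp,
      stringsAsFactors = FALSE
    )
  })
  map <- do.call(rbind, pieces)
  marker_map(map$id, map$chr, map$pos_mbp, map$pos_cm)
}

# Per-chromosome row indices of a map, in map order.
chromosome_index <- function(map) {
  split(seq_len(nrow(map)), factor(map$chr, levels = CHROMOSOMES), drop = TRUE)
}
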