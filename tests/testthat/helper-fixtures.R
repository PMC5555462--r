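# Shared fixtures, built in code.

# Small three-chromosome map: 5 + 4 + 3 markers, 10 Mbp apart, 0.5 cM/Mbp.
toy_map <- function() {
  chr <- rep(c("1", "2", "3"), c(5, 4, 3))
  pos <- unlist(lapply(c(5, 4, 3), function(k) seq(10, by = 10, length.out = k)))
  marker_map(sprintf("mk%02d", seq_along(chr)), chr, pos, pos * 0.5)
}

# Phenotype panel from explicit per-group IgE values.
# groups: named list, names "strain|condition", values IgE vectors.
make_phenos <- function(groups) {
  recs <- lapply(names(groups), function(key) {
    parts <- strsplit(key, "|", fixed = TRUE)[[1]]
    v <- groups[[key]]
    data.frame(animal_id = paste0(parts[1], "_", seq_along(v)),
               strain = parts[1], condition = parts[2], ige = v,
               stringsAsFactors = FALSE)
  })
  df <- do.call(rbind, recs)
  phenotype_panel(df$animal_id, df$strain, df$condition, df$ige)
}

# Hand-built genotype panel from a strains x markers character matrix.
make_panel <- function(geno_mat, family = NULL) {
  if (is.null(family)) family <- strain_family(rownames(geno_mat))
  genotype_panel(geno_mat, family)
}

# A small bred panel + map shared by several tests (computed once).
shared_small <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      map <- default_marker_map(180)
      panel <- breed_rcs_panel(breeding_config(n_acb = 4, n_bca = 8,
                                               seed = 424), map)
      cache <<- list(map = map, panel = panel)
    }
    cache
  }
})
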