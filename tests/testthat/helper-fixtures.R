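# Small in-code fixtures shared across test files.

# A counts matrix with named samples/ASVs.
mk_counts <- function(m, samples = NULL, asvs = NULL) {
  m <- as.matrix(m)
  rownames(m) <- samples %||% paste0("s", seq_len(nrow(m)))
  colnames(m) <- asvs %||% paste0("ASV", seq_len(ncol(m)))
  m
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Minimal valid metadata for arbitrary tissue/month/replicate slots.
mk_metadata <- function(tissue, month, replicate = 1, dna = 5,
                        sample_id = NULL) {
  n <- max(length(tissue), length(month), length(replicate))
  df <- data.frame(
    sample_id = sample_id %||% paste0("s", seq_len(n)),
    tissue = rep_len(tissue, n),
    month = rep_len(month, n),
    replicate = rep_len(replicate, n),
    dna_conc = rep_len(dna, n),
    is_negative_control = FALSE,
    stringsAsFactors = FALSE
  )
  validate_metadata(df)
}

# Taxonomy rows for given ASVs with a single rank filled.
mk_taxonomy <- function(asv_ids, genus = "", class = "Gammaproteobacteria",
                        order = "OrderX") {
  data.frame(
    asv_id = asv_ids,
    domain = "Bacteria", phylum = "Proteobacteria", class = class,
    order = order, family = "FamX",
    genus = rep_len(genus, length(asv_ids)),
    species = "",
    stringsAsFactors = FALSE
  )
}

# Metadata for one tissue sampled over months with r replicates, sample ids
# <tissue>_<month>_r<k> to match the matrix construction helpers.
mk_tissue_metadata <- function(tissue = "Fser", months = qmp_months, r = 3) {
  grid <- expand.grid(month = months, replicate = seq_len(r),
                      stringsAsFactors = FALSE)
  mk_metadata(tissue, grid$month, grid$replicate,
              sample_id = sprintf("%s_%s_r%d", tissue, grid$month,
                                  grid$replicate))
}

# Exhaustive pseudo-F enumeration over all distinct two-group label
# assignments (independent of the package's permutation machinery).
exhaustive_p <- function(d, groups) {
  d2 <- as.matrix(d)^2
  n <- nrow(d2)
  lev <- unique(groups)
  f_of <- function(g) {
    ss_tot <- sum(d2) / (2 * n)
    ss_w <- 0
    for (l in lev) {
      s <- which(g == l)
      ss_w <- ss_w + sum(d2[s, s]) / (2 * length(s))
    }
    ((ss_tot - ss_w) / (length(lev) - 1)) / (ss_w / (n - length(lev)))
  }
  f_obs <- f_of(groups)
  idx_a <- utils::combn(n, sum(groups == lev[1]))
  fs <- apply(idx_a, 2, function(s) {
    g <- rep(lev[2], n)
    g[s] <- lev[1]
    f_of(g)
  })
  mean(fs >= f_obs - 1e-12)
}

# Independent brute-force occupancy-redundancy index: loops over months of
# a [taxon, month, replicate] cube, no shared code with the implementation.
brute_force_index <- function(cube, taxon) {
  months <- dimnames(cube)[[2]]
  total <- 0
  for (m in months) {
    x <- cube[taxon, m, ]
    x <- x[!is.na(x)]
    occ <- sum(x) / length(x)
    red <- if (all(x == 1)) 1 else 0
    total <- total + occ + red
  }
  total / (2 * length(months))
}
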