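# Host-specificity set analysis: upset-style exclusive intersection counts
# and shared-ASV comparisons between phylogenetic pair classes.

#' Exclusive host-subset intersection counts
#'
#' For every non-empty subset of hosts, counts the taxa detected on exactly
#' that subset (detection = abundance at or above `detection_threshold` in
#' at least one sample of the host). The three Ldig blade parts collapse to
#' the single host `Ldig`. These are the numbers behind an upset plot.
#'
#' @param matrix Samples-by-taxa matrix (counts or absolute abundances;
#'   control samples excluded).
#' @param metadata Validated metadata covering the rows of `matrix`.
#' @param detection_threshold Minimum abundance counted as detection
#'   (default 1 read; use any positive value for absolute matrices).
#' @return List with `counts` (data frame: `subset` as `+`-joined host
#'   labels, `degree`, `n_taxa`), `per_host` (named vector of per-host set
#'   sizes), `n_detected` (total taxa detected anywhere) and `membership`
#'   (taxa x hosts logical matrix).
#' @export
intersection_counts <- function(matrix, metadata, detection_threshold = 1) {
  md <- metadata[!metadata$is_negative_control, , drop = FALSE]
  hosts <- intersect(qmp_hosts, unique(md$host))
  if (length(hosts) < 2) stop("need at least two hosts", call. = FALSE)
  membership <- base::matrix(FALSE, ncol(matrix), length(hosts),
                             dimnames = list(colnames(matrix), hosts))
  for (h in hosts) {
    ids <- md$sample_id[md$host == h]
    sub <- matrix[rownames(matrix) %in% ids, , drop = FALSE]
    membership[, h] <- colSums(sub >= detection_threshold) > 0
  }
  detected <- rowSums(membership) > 0
  key <- apply(membership, 1, function(x) paste(hosts[x], collapse = "+"))
  key <- key[detected]
  masks <- unlist(lapply(seq_along(hosts), function(k) {
    utils::combn(hosts, k, FUN = paste, collapse = "+")
  }))
  counts <- data.frame(
    subset = masks,
    degree = lengths(strsplit(masks, "+", fixed = TRUE)),
    n_taxa = as.integer(table(factor(key, levels = masks))),
    stringsAsFactors = FALSE
  )
  list(counts = counts,
       per_host = colSums(membership),
       n_detected = sum(detected),
       membership = membership)
}

#' Whole-percent share
#'
#' Percentage rounded to the nearest whole percent, the convention used for
#' reporting shares of detected taxa (e.g. 93 of 331 genera -> 28).
#'
#' @param k Numerator count.
#' @param n Denominator count.
#' @return Integer percentage.
#' @export
whole_percent <- function(k, n) {
  as.integer(round(100 * k / n))
}

#' Pairwise shared-taxon counts between samples
#'
#' For every unordered pair of non-control samples, counts the taxa with
#' nonzero abundance in both, and classifies the pair: `intra-species`
#' (same brown-algal host), `intra-phylum` (two different brown hosts),
#' `inter-phylum` (a brown host vs Ulva or Ppal) or `other` (pairs within
#' or between the non-brown hosts, which fall outside the three classes and
#' are excluded from the group comparison).
#'
#' @param matrix Samples-by-taxa matrix.
#' @param metadata Validated metadata.
#' @return Data frame with one row per pair: `sample_a`, `sample_b`,
#'   `shared`, `class`.
#' @export
pairwise_shared <- function(matrix, metadata) {
  md <- metadata[!metadata$is_negative_control, , drop = FALSE]
  md <- md[md$sample_id %in% rownames(matrix), , drop = FALSE]
  if (nrow(md) < 2) stop("need at least two samples", call. = FALSE)
  m <- matrix[md$sample_id, , drop = FALSE] > 0
  shared <- m %*% t(m)
  idx <- which(upper.tri(shared), arr.ind = TRUE)
  host_a <- md$host[idx[, 1]]
  host_b <- md$host[idx[, 2]]
  brown_a <- host_a %in% qmp_brown_hosts
  brown_b <- host_b %in% qmp_brown_hosts
  cls <- ifelse(brown_a & brown_b & host_a == host_b, "intra-species",
         ifelse(brown_a & brown_b, "intra-phylum",
         ifelse(xor(brown_a, brown_b), "inter-phylum", "other")))
  data.frame(
    sample_a = md$sample_id[idx[, 1]],
    sample_b = md$sample_id[idx[, 2]],
    shared = shared[idx],
    class = cls,
    stringsAsFactors = FALSE
  )
}

#' Rank-based comparison of shared-taxon counts between pair classes
#'
#' Kruskal-Wallis omnibus test (with ties correction) on the shared counts
#' across pair classes, followed by post hoc pairwise Wilcoxon rank-sum
#' tests with Benjamini-Hochberg adjustment, plus per-class medians as the
#' effect direction.
#'
#' @param pair_table Data frame from [pairwise_shared]; rows with class
#'   `other` are dropped.
#' @param value,group Column names holding the response and the class.
#' @return List with `omnibus` (`statistic`, `df`, `p_value`), `pairwise`
#'   (data frame `class_a`, `class_b`, `p_raw`, `p_adj`) and `medians`.
#' @export
group_comparison <- function(pair_table, value = "shared", group = "class") {
  df <- pair_table[pair_table[[group]] != "other", , drop = FALSE]
  df[[group]] <- factor(df[[group]])
  sizes <- table(df[[group]])
  if (length(sizes) < 2 || any(sizes < 2)) {
    stop("each pair class needs at least 2 observations", call. = FALSE)
  }
  kw <- stats::kruskal.test(df[[value]], df[[group]])
  pw <- stats::pairwise.wilcox.test(df[[value]], df[[group]],
                                    p.adjust.method = "BH", exact = FALSE)
  raw <- stats::pairwise.wilcox.test(df[[value]], df[[group]],
                                     p.adjust.method = "none", exact = FALSE)
  idx <- which(!is.na(pw$p.value), arr.ind = TRUE)
  pairwise <- data.frame(
    class_a = rownames(pw$p.value)[idx[, 1]],
    class_b = colnames(pw$p.value)[idx[, 2]],
    p_raw = raw$p.value[idx],
    p_adj = pw$p.value[idx],
    stringsAsFactors = FALSE
  )
  list(
    omnibus = list(statistic = unname(kw$statistic),
                   df = unname(kw$parameter),
                   p_value = kw$p.value),
    pairwise = pairwise,
    medians = tapply(df[[value]], df[[group]], stats::median)
  )
}
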