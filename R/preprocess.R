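# Filtering, contaminant removal, absolute rescaling and rank pooling.

#' Remove organellar and non-bacterial ASVs
#'
#' Drops every ASV whose lineage contains (case-insensitively, at any rank)
#' one of the configured labels — by default cyanobacteria (including
#' chloroplast 16S), mitochondria and Eukaryota.
#'
#' @param table An [asv_table].
#' @param taxonomy Taxonomy data frame covering all ASVs of `table`.
#' @param labels Character vector of lineage labels to purge.
#' @return List with `table` (filtered [asv_table]) and `removed`
#'   (character vector of dropped ASV ids; possibly empty).
#' @export
remove_organellar <- function(table, taxonomy,
                              labels = c("Cyanobacteria", "Chloroplast",
                                         "Mitochondria", "Eukaryota")) {
  hit <- match(colnames(table), taxonomy$asv_id)
  if (anyNA(hit)) {
    stop("ASV(s) missing from taxonomy: ",
         paste(colnames(table)[is.na(hit)], collapse = ", "), call. = FALSE)
  }
  lin <- taxonomy[hit, qmp_ranks, drop = FALSE]
  flat <- tolower(do.call(paste, c(lin, sep = ";")))
  pat <- paste(tolower(labels), collapse = "|")
  bad <- grepl(pat, flat)
  removed <- colnames(table)[bad]
  kept <- table[, !bad, drop = FALSE]
  if (ncol(kept) == 0) stop("all ASVs removed by organellar filter",
                            call. = FALSE)
  list(table = asv_table(kept), removed = removed)
}

#' Flag and remove reagent contaminants using negative controls
#'
#' An ASV is flagged as a contaminant iff all three clauses hold:
#' it has nonzero reads in at least one negative control, its frequency
#' (number of non-control samples where it is detected) is at most
#' `max_freq`, and its maximum per-sample relative abundance among
#' non-control samples is at most `max_relab`. Relative abundance is
#' reads-based (controls have no qPCR load, so the filter runs before
#' absolute rescaling). Flagged ASVs are removed and the control samples
#' are dropped from the returned table.
#'
#' @param table An [asv_table] containing control and non-control samples.
#' @param control_ids Sample ids of the negative controls (non-empty).
#' @param max_freq Maximum prevalence among non-control samples
#'   (default 11).
#' @param max_relab Maximum per-sample relative abundance among non-control
#'   samples (default 0.015, i.e. 1.5 percent).
#' @param reference Optional [asv_table] on which the frequency and
#'   relative-abundance clauses are evaluated (defaults to `table`). Fixing
#'   it to the post-organellar-filter table makes the contaminant predicate
#'   a pure column predicate, so the organellar and contaminant filters
#'   commute.
#' @return List with `table` (non-control samples, flagged ASVs removed),
#'   `report` (one row per flagged ASV: `asv_id`, `in_controls`,
#'   `frequency`, `max_relab`) and `flagged` (character vector).
#' @export
flag_contaminants <- function(table, control_ids,
                              max_freq = 11, max_relab = 0.015,
                              reference = table) {
  if (length(control_ids) == 0) {
    stop("contaminant filtering requested without negative controls",
         call. = FALSE)
  }
  miss <- setdiff(control_ids, rownames(table))
  if (length(miss)) stop("control sample(s) not in table: ",
                         paste(miss, collapse = ", "), call. = FALSE)
  is_ctrl <- rownames(table) %in% control_ids
  samp <- table[!is_ctrl, , drop = FALSE]
  ref_ctrl <- reference[rownames(reference) %in% control_ids, , drop = FALSE]
  ref_samp <- reference[!rownames(reference) %in% control_ids, , drop = FALSE]
  in_controls <- colSums(ref_ctrl > 0) > 0
  freq <- colSums(ref_samp > 0)
  tot <- rowSums(ref_samp)
  relab <- sweep(ref_samp, 1, pmax(tot, 1), "/")
  max_ra <- apply(relab, 2, max)
  pred <- in_controls & freq <= max_freq & max_ra <= max_relab
  ## ASVs outside the reference (e.g. organellar ones evaluated before
  ## that filter ran) are not contaminant candidates
  hit <- match(colnames(table), colnames(reference))
  flagged <- ifelse(is.na(hit), FALSE, pred[hit])
  freq <- ifelse(is.na(hit), NA, freq[hit])
  max_ra <- ifelse(is.na(hit), NA, max_ra[hit])
  report <- data.frame(
    asv_id = colnames(table)[flagged],
    in_controls = rep(TRUE, sum(flagged)),
    frequency = unname(freq[flagged]),
    max_relab = unname(max_ra[flagged]),
    stringsAsFactors = FALSE
  )
  kept <- samp[, !flagged, drop = FALSE]
  list(table = asv_table(kept), report = report,
       flagged = colnames(table)[flagged])
}

#' Rescale relative read abundances to absolute copy densities
#'
#' Quantitative microbiome profiling: each sample's relative ASV abundances
#' (reads divided by the sample's read total) are multiplied by that
#' sample's total 16S load N (copies per cm2) from qPCR, so row sums equal
#' N. The result is invariant to jointly rescaling a sample's reads.
#'
#' @param table An [asv_table] (controls removed).
#' @param loads Named numeric vector of N per sample (copies per cm2), or
#'   the data frame returned by [attach_loads] (its `N` column is used).
#' @return Numeric matrix (samples x ASVs) of copies per cm2 with attribute
#'   `provenance = "ASV"`.
#' @export
scale_to_absolute <- function(table, loads) {
  if (is.data.frame(loads)) {
    loads <- stats::setNames(loads$N, loads$sample_id)
  }
  hit <- match(rownames(table), names(loads))
  if (anyNA(hit)) {
    stop("missing load N for sample(s): ",
         paste(rownames(table)[is.na(hit)], collapse = ", "), call. = FALSE)
  }
  N <- unname(loads[hit])
  if (any(is.na(N) | N < 0)) stop("loads must be non-negative", call. = FALSE)
  tot <- rowSums(table)
  dead <- tot == 0 & N > 0
  if (any(dead)) {
    stop("unresolvable sample(s) with zero reads but positive load: ",
         paste(rownames(table)[dead], collapse = ", "), call. = FALSE)
  }
  out <- sweep(unclass(table), 1, pmax(tot, 1), "/") * N
  attr(out, "provenance") <- "ASV"
  out
}

#' Pool taxa by a taxonomic rank
#'
#' Sums columns over ASVs sharing the same label at `rank`. ASVs with an
#' empty label at that rank are excluded from the pooled matrix and
#' reported separately (their mass is dropped, mirroring default rank
#' agglomeration of amplicon toolchains).
#'
#' @param matrix Samples-by-ASVs numeric matrix (counts or absolute).
#' @param taxonomy Taxonomy data frame covering all columns.
#' @param rank One of the seven ranks (default `"genus"`).
#' @return List with `matrix` (samples x rank labels), `excluded`
#'   (ASV ids with empty label) and `excluded_mass` (their total).
#' @export
pool_by_rank <- function(matrix, taxonomy, rank = "genus") {
  rank <- match.arg(rank, qmp_ranks)
  hit <- match(colnames(matrix), taxonomy$asv_id)
  if (anyNA(hit)) {
    stop("ASV(s) missing from taxonomy: ",
         paste(colnames(matrix)[is.na(hit)], collapse = ", "), call. = FALSE)
  }
  lab <- taxonomy[[rank]][hit]
  empty <- is.na(lab) | lab == ""
  kept <- matrix[, !empty, drop = FALSE]
  lab <- lab[!empty]
  pooled <- t(rowsum(t(kept), group = lab))
  pooled <- pooled[, order(colnames(pooled)), drop = FALSE]
  attr(pooled, "provenance") <- rank
  list(matrix = pooled,
       excluded = colnames(matrix)[empty],
       excluded_mass = sum(matrix[, empty, drop = FALSE]))
}

#' Convert 16S gene copies to cell densities
#'
#' Divides a copy density by the rRNA operon copy number per genome
#' (default 3, the count in the reference *Granulosicoccus antarcticus*
#' genome).
#'
#' @param copies Copies per cm2 (any non-negative numeric).
#' @param operons_per_cell Operons per genome (> 0, default 3).
#' @return Cells per cm2.
#' @examples
#' copies_to_cells(7.7e6)  # ~2.57e6 cells per cm2
#' @export
copies_to_cells <- function(copies, operons_per_cell = 3) {
  if (operons_per_cell <= 0) stop("operons_per_cell must be > 0",
                                  call. = FALSE)
  copies / operons_per_cell
}
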