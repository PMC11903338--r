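# Occupancy-redundancy core index.
#
# Per tissue, each taxon gets, for each sampled month, an occupancy term
# (fraction of replicates where it is detected) and a redundancy term (1 if
# detected in every replicate of that month, else 0). The index is the sum
# of both terms over months, scaled by the theoretical maximum 2 * n_months,
# so an always-present taxon scores exactly 1 and an always-absent one 0.

#' Build a presence/absence cube for one tissue
#'
#' Arranges detection calls as a taxon x month x replicate binary array for
#' the samples of a single tissue. Replicate slots absent from the design
#' (e.g. a month with only two swabs) are `NA`, never 0 — a missing swab is
#' not an absence.
#'
#' @param matrix Samples-by-taxa numeric matrix (reads or copies per cm2).
#' @param metadata Validated metadata covering the rows of `matrix`.
#' @param tissue Tissue label to subset on.
#' @param detection_threshold Minimum abundance counted as presence
#'   (default 1; use any positive value for real-valued absolute matrices).
#' @return 3-d array `[taxon, month, replicate]` with entries in
#'   `{0, 1, NA}` and class `presence_cube`.
#' @export
presence_cube <- function(matrix, metadata, tissue, detection_threshold = 1) {
  md <- metadata[!metadata$is_negative_control &
                   metadata$tissue == tissue, , drop = FALSE]
  if (nrow(md) == 0) stop("no samples for tissue ", tissue, call. = FALSE)
  hit <- match(md$sample_id, rownames(matrix))
  if (anyNA(hit)) {
    stop("sample(s) of tissue ", tissue, " missing from matrix: ",
         paste(md$sample_id[is.na(hit)], collapse = ", "), call. = FALSE)
  }
  months <- intersect(qmp_months, unique(md$month))
  if (length(months) == 0) months <- unique(md$month)
  reps <- sort(unique(md$replicate))
  cube <- array(NA_real_,
                dim = c(ncol(matrix), length(months), length(reps)),
                dimnames = list(colnames(matrix), months,
                                paste0("r", reps)))
  for (i in seq_len(nrow(md))) {
    m <- md$month[i]
    r <- match(md$replicate[i], reps)
    cube[, m, r] <- as.numeric(matrix[hit[i], ] >= detection_threshold)
  }
  structure(cube, class = c("presence_cube", "array"))
}

#' Monthly occupancy term
#'
#' Mean presence over the non-missing replicates of a month: the fraction
#' of that month's swabs where the taxon was detected.
#'
#' @param cube A [presence_cube].
#' @param taxon Taxon identifier (row of the cube).
#' @param month Month label (column of the cube).
#' @return Value in `[0, 1]`.
#' @export
occupancy_term <- function(cube, taxon, month) {
  x <- cube[taxon, month, ]
  if (all(is.na(x))) stop("month ", month, " has no replicates",
                          call. = FALSE)
  mean(x, na.rm = TRUE)
}

#' Monthly redundancy term
#'
#' 1 iff the taxon is present in every non-missing replicate of the month,
#' else 0. In a deficit month (two swabs instead of three) presence in both
#' available swabs earns the redundancy point: a missing swab should not cap
#' a consistently present taxon below index 1.
#'
#' @inheritParams occupancy_term
#' @return 0 or 1.
#' @export
redundancy_term <- function(cube, taxon, month) {
  x <- cube[taxon, month, ]
  if (all(is.na(x))) stop("month ", month, " has no replicates",
                          call. = FALSE)
  as.numeric(all(x[!is.na(x)] == 1))
}

#' Occupancy-redundancy index
#'
#' Sum over months of (occupancy + redundancy), scaled by the theoretical
#' maximum `2 * n_months` so the index lives in `[0, 1]` and equals 1
#' exactly when the taxon is present in every non-missing replicate of
#' every month.
#'
#' @param cube A [presence_cube].
#' @param taxon Optional taxon id(s); default all taxa of the cube.
#' @return Named numeric vector of indices in `[0, 1]`.
#' @export
occupancy_redundancy_index <- function(cube, taxon = NULL) {
  if (is.null(dim(cube)) || dim(cube)[2] == 0) stop("empty presence cube",
                                                    call. = FALSE)
  if (is.null(taxon)) taxon <- dimnames(cube)[[1]]
  months <- dimnames(cube)[[2]]
  occ <- apply(cube[taxon, , , drop = FALSE], c(1, 2), mean, na.rm = TRUE)
  red <- apply(cube[taxon, , , drop = FALSE], c(1, 2),
               function(x) as.numeric(all(x[!is.na(x)] == 1)))
  idx <- rowSums(occ + red) / (2 * length(months))
  stats::setNames(as.numeric(idx), taxon)
}

#' Per-tissue core-index table
#'
#' Computes the occupancy-redundancy index of every taxon on every tissue.
#'
#' @inheritParams presence_cube
#' @param tissues Tissue labels to include (default: all tissues present in
#'   the metadata).
#' @return Numeric matrix, taxa in rows and tissues in columns, entries in
#'   `[0, 1]`.
#' @export
core_index_table <- function(matrix, metadata, tissues = NULL,
                             detection_threshold = 1) {
  if (is.null(tissues)) {
    tissues <- intersect(qmp_tissues,
                         unique(metadata$tissue[!metadata$is_negative_control]))
  }
  out <- base::matrix(NA_real_, ncol(matrix), length(tissues),
                      dimnames = list(colnames(matrix), tissues))
  for (tt in tissues) {
    out[, tt] <- occupancy_redundancy_index(
      presence_cube(matrix, metadata, tt, detection_threshold))
  }
  out
}

#' Classify core taxa from a core-index table
#'
#' Aggregates tissue columns to host-species columns (by default the three
#' Ldig blade parts average into one `Ldig` column) and calls a taxon core
#' iff its aggregated index strictly exceeds `threshold` on every species
#' column. Ties at the threshold are non-core.
#'
#' @param index_table Taxa-by-tissues matrix from [core_index_table].
#' @param threshold Core cutoff in `(0, 1]` (default 0.65).
#' @param tissue_aggregation Named list mapping display columns to the
#'   tissue columns averaged into them; defaults to the five host species
#'   with `Ldig = mean(LdigB, LdigM, LdigO)`.
#' @return List with `core` (character vector of core taxa), `aggregated`
#'   (taxa x species index matrix) and `is_core` (logical vector).
#' @export
classify_core <- function(index_table, threshold = 0.65,
                          tissue_aggregation = NULL) {
  if (threshold <= 0 || threshold > 1) {
    stop("core threshold must lie in (0, 1]", call. = FALSE)
  }
  if (is.null(tissue_aggregation)) {
    tissue_aggregation <- split(names(qmp_tissue_host),
                                unname(qmp_tissue_host))
    tissue_aggregation <- lapply(tissue_aggregation,
                                 intersect, x = colnames(index_table))
    tissue_aggregation <- tissue_aggregation[
      lengths(tissue_aggregation) > 0]
  }
  agg <- base::matrix(NA_real_, nrow(index_table),
                      length(tissue_aggregation),
                      dimnames = list(rownames(index_table),
                                      names(tissue_aggregation)))
  for (sp in names(tissue_aggregation)) {
    agg[, sp] <- rowMeans(
      index_table[, tissue_aggregation[[sp]], drop = FALSE])
  }
  is_core <- apply(agg > threshold, 1, all)
  list(core = rownames(agg)[is_core], aggregated = agg, is_core = is_core)
}
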