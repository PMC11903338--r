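# Study-design vocabulary and tabular I/O.
#
# All tables are tab-separated UTF-8 with a header row; samples are always in
# rows and taxa in columns. Floats are serialised with "." as decimal
# separator and 12 significant digits so that write/read round-trips are
# stable; integer counts round-trip bit-exactly.

#' Study-design vocabulary
#'
#' Controlled vocabularies for the seven algal tissue types, the five host
#' species, the ten sampled months and the month-to-season grouping used
#' throughout the pipeline. The three *Laminaria digitata* blade parts
#' (`LdigB`, `LdigM`, `LdigO`) belong to the single host `Ldig`; `Anod`,
#' `Fser` and `Ldig` are brown algae (Phaeophyceae), `Ppal` is red and
#' `Ulva` green.
#'
#' @format Character vectors (`qmp_tissues`, `qmp_hosts`, `qmp_months`,
#'   `qmp_brown_hosts`) and named character vectors mapping tissue to host
#'   (`qmp_tissue_host`) and month to season (`qmp_season_map`).
#' @name design-vocab
NULL

#' @rdname design-vocab
#' @export
qmp_tissues <- c("Anod", "Fser", "LdigB", "LdigM", "LdigO", "Ppal", "Ulva")

#' @rdname design-vocab
#' @export
qmp_tissue_host <- c(
  Anod = "Anod", Fser = "Fser",
  LdigB = "Ldig", LdigM = "Ldig", LdigO = "Ldig",
  Ppal = "Ppal", Ulva = "Ulva"
)

#' @rdname design-vocab
#' @export
qmp_hosts <- c("Anod", "Fser", "Ldig", "Ppal", "Ulva")

#' @rdname design-vocab
#' @export
qmp_brown_hosts <- c("Anod", "Fser", "Ldig")

#' @rdname design-vocab
#' @export
qmp_months <- c("Jan", "Feb", "Mar", "Jun", "Jul", "Aug",
                "Sep", "Oct", "Nov", "Dec")

#' @rdname design-vocab
#' @export
qmp_season_map <- c(
  Jan = "winter", Feb = "winter", Mar = "winter",
  Jun = "summer", Jul = "summer", Aug = "summer",
  Sep = "autumn", Oct = "autumn", Nov = "autumn", Dec = "autumn"
)

#' Taxonomic ranks recognised by the pipeline, coarsest first.
#' @export
qmp_ranks <- c("domain", "phylum", "class", "order", "family",
               "genus", "species")

.canon_month <- function(month) {
  m <- paste0(toupper(substr(month, 1, 1)), tolower(substr(month, 2, 3)))
  m
}

#' Map a calendar month to its season
#'
#' The ten sampled months are grouped into three seasons: winter (Jan, Feb,
#' Mar), summer (Jun, Jul, Aug) and autumn (Sep, Oct, Nov, Dec). April and
#' May were not sampled and are deliberately unmapped; asking for them (or
#' any unknown label) is an error rather than an NA, so that a malformed
#' metadata table fails loudly.
#'
#' @param month Character vector of three-letter month abbreviations
#'   (case-insensitive).
#' @return Character vector of seasons (`"winter"`, `"summer"`, `"autumn"`).
#' @examples
#' month_to_season(c("Feb", "dec"))
#' @export
month_to_season <- function(month) {
  m <- .canon_month(as.character(month))
  s <- unname(qmp_season_map[m])
  if (anyNA(s)) {
    bad <- unique(m[is.na(s)])
    stop("unmapped month(s): ", paste(bad, collapse = ", "),
         " (Apr and May are outside the sampled design)", call. = FALSE)
  }
  s
}

#' Enumerate the expected sample slots of a swab study design
#'
#' Expands a full-factorial tissue-by-month design with a fixed number of
#' replicates per condition, minus explicit replicate deficits. The default
#' vocabulary (7 tissues, 10 months, 3 replicates, with only 2 replicates
#' for LdigB in February and for Ulva in March) yields 70 conditions and 208
#' samples. Deficits are recorded, never imputed.
#'
#' @param tissues,months Character vectors of tissue and month labels.
#' @param replicates Default replicate count per condition.
#' @param exceptions `NULL` or a data frame with columns `tissue`, `month`,
#'   `replicates` overriding the replicate count of individual conditions.
#' @return A data frame with one row per expected sample (`tissue`, `month`,
#'   `replicate`, `sample_id`) plus attributes `n_conditions` and
#'   `n_samples`.
#' @examples
#' d <- enumerate_design()
#' attr(d, "n_conditions")  # 70
#' attr(d, "n_samples")     # 208
#' @export
enumerate_design <- function(tissues = qmp_tissues,
                             months = qmp_months,
                             replicates = 3,
                             exceptions = qmp_design_deficits()) {
  stopifnot(length(tissues) > 0, length(months) > 0, replicates >= 1)
  months <- .canon_month(months)
  grid <- expand.grid(month = months, tissue = tissues,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  grid$replicates <- replicates
  if (!is.null(exceptions) && nrow(exceptions) > 0) {
    exceptions$month <- .canon_month(exceptions$month)
    bad_t <- setdiff(exceptions$tissue, tissues)
    bad_m <- setdiff(exceptions$month, months)
    if (length(bad_t) || length(bad_m)) {
      stop("design exception refers to unknown tissue/month: ",
           paste(c(bad_t, bad_m), collapse = ", "), call. = FALSE)
    }
    for (i in seq_len(nrow(exceptions))) {
      hit <- grid$tissue == exceptions$tissue[i] &
        grid$month == exceptions$month[i]
      grid$replicates[hit] <- exceptions$replicates[i]
    }
  }
  out <- grid[rep(seq_len(nrow(grid)), grid$replicates), c("tissue", "month")]
  out$replicate <- unlist(lapply(grid$replicates, seq_len))
  out$sample_id <- sprintf("%s_%s_r%d", out$tissue, out$month, out$replicate)
  rownames(out) <- NULL
  attr(out, "n_conditions") <- length(tissues) * length(months)
  attr(out, "n_samples") <- nrow(out)
  out
}

#' The two known replicate deficits of the default design
#'
#' Only two replicates were retrieved for LdigB in February and for Ulva in
#' March; all other conditions have three.
#'
#' @return Data frame with columns `tissue`, `month`, `replicates`.
#' @export
qmp_design_deficits <- function() {
  data.frame(
    tissue = c("LdigB", "Ulva"),
    month = c("Feb", "Mar"),
    replicates = c(2L, 2L),
    stringsAsFactors = FALSE
  )
}

## ---- ASV count table ------------------------------------------------------

#' Construct an ASV count table
#'
#' A validated samples-by-ASVs matrix of non-negative integer read counts.
#'
#' @param counts Numeric matrix, samples in rows, with unique row and column
#'   names (sample and ASV identifiers).
#' @return An object of class `asv_table` (a matrix with validated dimnames).
#' @export
asv_table <- function(counts) {
  counts <- as.matrix(counts)
  if (nrow(counts) == 0 || ncol(counts) == 0) {
    stop("no samples or no ASVs in count table", call. = FALSE)
  }
  if (is.null(rownames(counts)) || is.null(colnames(counts))) {
    stop("count table needs sample (row) and ASV (column) identifiers",
         call. = FALSE)
  }
  if (anyDuplicated(rownames(counts))) {
    stop("duplicate sample identifiers", call. = FALSE)
  }
  if (anyDuplicated(colnames(counts))) {
    stop("duplicate ASV identifiers", call. = FALSE)
  }
  if (anyNA(counts) || any(counts < 0)) {
    stop("counts must be non-negative and non-missing", call. = FALSE)
  }
  if (any(counts != round(counts))) {
    stop("counts must be integers (reads)", call. = FALSE)
  }
  storage.mode(counts) <- "double"
  structure(counts, class = c("asv_table", "matrix", "array"))
}

#' @export
print.asv_table <- function(x, ...) {
  cat(sprintf("ASV count table: %d samples x %d ASVs, %s reads total\n",
              nrow(x), ncol(x), format(sum(x), big.mark = ",")))
  invisible(x)
}

#' Read an ASV count table
#'
#' @param path Path to the file.
#' @param dialect `"tsv"` for a dense samples-by-ASVs table whose first
#'   column holds sample identifiers, or `"triplet"` for a sparse
#'   three-column table (`sample_id`, `asv_id`, `count`) in the style of a
#'   sparse BIOM export; absent triplets are zero.
#' @return An [asv_table].
#' @export
read_asv_table <- function(path, dialect = c("tsv", "triplet")) {
  dialect <- match.arg(dialect)
  stopifnot(file.exists(path))
  df <- utils::read.delim(path, check.names = FALSE,
                          stringsAsFactors = FALSE)
  if (nrow(df) == 0) stop("no samples in ", path, call. = FALSE)
  if (dialect == "tsv") {
    if (ncol(df) < 2) stop("no ASV columns in ", path, call. = FALSE)
    m <- as.matrix(df[, -1, drop = FALSE])
    rownames(m) <- as.character(df[[1]])
  } else {
    need <- c("sample_id", "asv_id", "count")
    if (!all(need %in% names(df))) {
      stop("triplet dialect needs columns sample_id, asv_id, count",
           call. = FALSE)
    }
    if (anyDuplicated(df[c("sample_id", "asv_id")])) {
      stop("duplicate (sample, ASV) triplets", call. = FALSE)
    }
    samples <- unique(df$sample_id)
    asvs <- unique(df$asv_id)
    m <- matrix(0, length(samples), length(asvs),
                dimnames = list(samples, asvs))
    m[cbind(match(df$sample_id, samples), match(df$asv_id, asvs))] <- df$count
  }
  asv_table(m)
}

#' Write an ASV count table as dense TSV
#'
#' Round-trips bit-exactly with [read_asv_table] for integer counts.
#'
#' @param x An [asv_table] (or plain matrix with dimnames).
#' @param path Output path.
#' @export
write_asv_table <- function(x, path) {
  .write_matrix_tsv(x, path, id_col = "sample_id")
}

.write_matrix_tsv <- function(x, path, id_col = "sample_id") {
  old <- options(OutDec = ".")
  on.exit(options(old))
  df <- data.frame(rownames(x), as.data.frame(unclass(x)),
                   check.names = FALSE, stringsAsFactors = FALSE)
  names(df)[1] <- id_col
  is_int <- vapply(df[-1], function(col) all(col == round(col)), logical(1))
  for (j in which(!is_int) + 1L) {
    df[[j]] <- formatC(df[[j]], digits = 12, format = "g")
  }
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read/write a numeric samples-or-months by variables matrix
#'
#' Generic helpers for the absolute-abundance, distance and environmental
#' tables: first column is the row identifier, remaining columns numeric.
#'
#' @param path File path.
#' @param id_col Name of the identifier column on write.
#' @return A numeric matrix with row names.
#' @keywords internal
#' @export
read_matrix_tsv <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE,
                          stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- as.character(df[[1]])
  m
}

#' @rdname read_matrix_tsv
#' @param x Matrix to write.
#' @export
write_matrix_tsv <- function(x, path, id_col = "id") {
  .write_matrix_tsv(x, path, id_col = id_col)
}

## ---- taxonomy -------------------------------------------------------------

#' Read a taxonomy table
#'
#' Expects a TSV with an `asv_id` column and up to seven rank columns
#' (domain, phylum, class, order, family, genus, species). Missing ranks are
#' encoded as empty strings (not the text "NA", which is a legitimate genus
#' name fragment).
#'
#' @param path File path.
#' @return Data frame with `asv_id` plus the seven rank columns (missing
#'   ranks filled with `""`).
#' @export
read_taxonomy <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, na.strings = NULL,
                          colClasses = "character")
  if (!"asv_id" %in% names(df)) stop("taxonomy needs an asv_id column",
                                     call. = FALSE)
  for (r in qmp_ranks) if (!r %in% names(df)) df[[r]] <- ""
  df <- df[, c("asv_id", qmp_ranks)]
  df[is.na(df)] <- ""
  if (anyDuplicated(df$asv_id)) stop("duplicate ASV in taxonomy",
                                     call. = FALSE)
  df
}

#' Write a taxonomy table
#' @param taxonomy Data frame as returned by [read_taxonomy].
#' @param path Output path.
#' @export
write_taxonomy <- function(taxonomy, path) {
  utils::write.table(taxonomy, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

## ---- sample metadata ------------------------------------------------------

#' Read and validate sample metadata
#'
#' Columns: `sample_id`, `tissue`, `month`, `replicate`, `dna_conc`
#' (ng per uL), `is_negative_control` (logical). `host` and `season` are
#' derived from tissue and month; negative controls carry no tissue/month.
#'
#' @param path File path.
#' @return Validated data frame with derived `host` and `season` columns.
#' @export
read_metadata <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  validate_metadata(df)
}

#' @rdname read_metadata
#' @param metadata Data frame to validate in place of reading a file.
#' @export
validate_metadata <- function(metadata) {
  need <- c("sample_id", "tissue", "month", "replicate", "dna_conc",
            "is_negative_control")
  miss <- setdiff(need, names(metadata))
  if (length(miss)) stop("metadata missing column(s): ",
                         paste(miss, collapse = ", "), call. = FALSE)
  if (anyDuplicated(metadata$sample_id)) {
    stop("duplicate sample identifiers in metadata", call. = FALSE)
  }
  metadata$is_negative_control <- as.logical(metadata$is_negative_control)
  real <- !metadata$is_negative_control
  bad <- setdiff(metadata$tissue[real], qmp_tissues)
  if (length(bad)) stop("unknown tissue(s): ", paste(bad, collapse = ", "),
                        call. = FALSE)
  metadata$month[real] <- .canon_month(metadata$month[real])
  metadata$host <- NA_character_
  metadata$host[real] <- unname(qmp_tissue_host[metadata$tissue[real]])
  metadata$season <- NA_character_
  metadata$season[real] <- month_to_season(metadata$month[real])
  if (any(real & (is.na(metadata$dna_conc) | metadata$dna_conc <= 0))) {
    stop("dna_conc must be > 0 for non-control samples", call. = FALSE)
  }
  metadata
}

#' Write sample metadata
#' @param metadata Metadata data frame.
#' @param path Output path.
#' @export
write_metadata <- function(metadata, path) {
  old <- options(OutDec = ".")
  on.exit(options(old))
  utils::write.table(metadata, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

## ---- qPCR and environmental tables ---------------------------------------

#' Read a qPCR measurement table
#'
#' One row per sample (or per well when a `well` column is present) with
#' either a `copies` column (16S copies detected in the reaction) or a `cq`
#' column to be converted through a standard curve.
#'
#' @param path File path.
#' @return Data frame.
#' @export
read_qpcr <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!"sample_id" %in% names(df)) stop("qPCR table needs sample_id",
                                        call. = FALSE)
  if (!any(c("copies", "cq") %in% names(df))) {
    stop("qPCR table needs a copies or cq column", call. = FALSE)
  }
  df
}

#' Read the monthly environmental parameter table
#'
#' @param path File path. First column `month`, remaining columns numeric
#'   environmental variables; missing values are explicit `NA`.
#' @return Numeric matrix, months in rows.
#' @export
read_env_table <- function(path) {
  m <- read_matrix_tsv(path)
  rownames(m) <- .canon_month(rownames(m))
  if (anyDuplicated(rownames(m))) stop("duplicate months in env table",
                                       call. = FALSE)
  m
}
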