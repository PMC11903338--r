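# qPCR quantification: from copies detected in a reaction to total 16S rRNA
# gene copies per cm2 of swabbed surface.

#' Total 16S copies per cm2 of swabbed surface
#'
#' Converts the number of gene copies detected in a qPCR reaction back to a
#' surface density, undoing the extract normalisation:
#' \deqn{N = \frac{n \cdot C \cdot V}{c \cdot v \cdot S}}
#' where `n` is the copies detected in the reaction, `C` the original extract
#' concentration (ng/uL) before normalisation, `V` the extract volume (uL),
#' `c` the normalised input concentration in the reaction (ng/uL), `v` the
#' input volume (uL) and `S` the swabbed surface (cm2). The defaults are the
#' assay constants of a 50 uL extract normalised to 0.5 ng/uL, 1.5 uL input
#' and a 50 cm2 swab. `N` is linear in `n` and in `C`.
#'
#' @param n Copies detected in the reaction (>= 0).
#' @param C Original extract concentration, ng/uL (>= 0).
#' @param V Extract volume, uL (default 50).
#' @param c Input DNA concentration in the reaction, ng/uL (default 0.5).
#' @param v Input volume, uL (default 1.5).
#' @param S Swabbed surface, cm2 (default 50).
#' @return Copies per cm2 (vectorised over its arguments).
#' @examples
#' copies_per_cm2(n = 1875, C = 0.5)  # 1250
#' @export
copies_per_cm2 <- function(n, C, V = 50, c = 0.5, v = 1.5, S = 50) {
  if (any(c <= 0)) stop("input concentration c must be > 0", call. = FALSE)
  if (any(v <= 0)) stop("input volume v must be > 0", call. = FALSE)
  if (any(S <= 0)) stop("swabbed surface S must be > 0", call. = FALSE)
  if (any(n < 0)) stop("copies n must be >= 0", call. = FALSE)
  if (any(C < 0)) stop("extract concentration C must be >= 0", call. = FALSE)
  if (any(V < 0)) stop("extract volume V must be >= 0", call. = FALSE)
  n * C * V / (c * v * S)
}

#' qPCR standard curve
#'
#' A linear calibration Cq = slope * log10(copies) + intercept. Slope must
#' be negative; amplification efficiency is E = 10^(-1/slope) - 1 (a slope
#' of -3.3219 gives E = 1, i.e. perfect doubling per cycle). Efficiencies
#' outside (0, 1.1] trigger a warning, not an error.
#'
#' @param slope Cq change per decade of template (negative).
#' @param intercept Cq at one copy.
#' @return Object of class `standard_curve` with fields `slope`, `intercept`,
#'   `efficiency`.
#' @export
standard_curve <- function(slope, intercept) {
  if (!is.finite(slope) || slope >= 0) {
    stop("standard-curve slope must be negative", call. = FALSE)
  }
  eff <- 10^(-1 / slope) - 1
  if (eff <= 0 || eff > 1.1) {
    warning(sprintf("amplification efficiency %.2f outside (0, 1.1]", eff))
  }
  structure(list(slope = slope, intercept = intercept, efficiency = eff),
            class = "standard_curve")
}

#' Convert quantification cycles to template copies
#'
#' Inverts the standard curve: copies = 10^((cq - intercept) / slope).
#' Monotonically decreasing in `cq`.
#'
#' @param cq Quantification cycle values.
#' @param curve A [standard_curve].
#' @return Copies in the reaction.
#' @export
cq_to_copies <- function(cq, curve) {
  stopifnot(inherits(curve, "standard_curve"))
  10^((cq - curve$intercept) / curve$slope)
}

#' Inverse of [cq_to_copies] (for simulation and round-trip checks).
#' @inheritParams cq_to_copies
#' @param copies Template copies in the reaction (> 0).
#' @export
copies_to_cq <- function(copies, curve) {
  stopifnot(inherits(curve, "standard_curve"), all(copies > 0))
  curve$slope * log10(copies) + curve$intercept
}

#' Attach per-sample total loads to the metadata
#'
#' Joins qPCR measurements to the sample metadata and computes N, the total
#' 16S copies per cm2, for every non-control sample. Samples whose extract
#' concentration was already below the normalisation target `c` were used
#' undiluted; for those the effective input concentration equals the extract
#' concentration (so N = n*V/(v*S)) and an `undiluted` flag is raised.
#' Loads outside a plausibility window are flagged, not rejected. Replicate
#' qPCR wells, when present, are aggregated by the arithmetic mean of copies
#' (copies, not Cq, being the linear-scale quantity entering N).
#'
#' @param metadata Validated metadata (see [read_metadata]).
#' @param measurements qPCR table with `sample_id` and `copies` (or `cq`
#'   plus `curve`); optional `well` column for replicate wells.
#' @param curve Optional [standard_curve] used when only `cq` is supplied.
#' @param V,c,v,S Assay constants, as in [copies_per_cm2].
#' @param window Plausibility window for N in copies per cm2
#'   (default `c(1e3, 1e9)`).
#' @return Data frame with one row per non-control sample: `sample_id`,
#'   `copies` (mean copies in reaction), `C`, `c_eff`, `N`, `undiluted`,
#'   `implausible`.
#' @export
attach_loads <- function(metadata, measurements, curve = NULL,
                         V = 50, c = 0.5, v = 1.5, S = 50,
                         window = c(1e3, 1e9)) {
  metadata <- validate_metadata(metadata)
  real <- metadata[!metadata$is_negative_control, , drop = FALSE]
  if (!"copies" %in% names(measurements)) {
    if (is.null(curve)) {
      stop("measurements carry only cq; a standard curve is required",
           call. = FALSE)
    }
    measurements$copies <- cq_to_copies(measurements$cq, curve)
  }
  agg <- stats::aggregate(copies ~ sample_id, data = measurements, FUN = mean)
  hit <- match(real$sample_id, agg$sample_id)
  if (anyNA(hit)) {
    stop("missing qPCR measurement for sample(s): ",
         paste(real$sample_id[is.na(hit)], collapse = ", "), call. = FALSE)
  }
  n <- agg$copies[hit]
  C <- real$dna_conc
  undiluted <- C < c
  c_eff <- ifelse(undiluted, C, c)
  N <- copies_per_cm2(n, C, V = V, c = c_eff, v = v, S = S)
  data.frame(
    sample_id = real$sample_id,
    copies = n,
    C = C,
    c_eff = c_eff,
    N = N,
    undiluted = undiluted,
    implausible = N < window[1] | N > window[2],
    stringsAsFactors = FALSE
  )
}
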