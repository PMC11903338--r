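# End-to-end orchestration: read -> quantify -> filter -> scale -> pool ->
# (core index | specificity | community stats), file-based so stages can be
# rerun or replaced from the shell, with a manifest of outputs and hashes.

#' Default pipeline parameters
#'
#' @param ... Named overrides.
#' @return Named list: qPCR assay constants, filter thresholds, core
#'   threshold, permutation settings and seed.
#' @export
pipeline_params <- function(...) {
  p <- list(
    V = 50, c = 0.5, v = 1.5, S = 50,
    load_window = c(1e3, 1e9),
    organellar_labels = c("Cyanobacteria", "Chloroplast", "Mitochondria",
                          "Eukaryota"),
    contam_max_freq = 11,
    contam_max_relab = 0.015,
    core_threshold = 0.65,
    detection_copies = 1e-9,  # any positive copy density counts as present
    n_perm = 999,
    env_alpha = 0.05,
    env_r_threshold = 0.8,
    seed = 1
  )
  dots <- list(...)
  p[names(dots)] <- dots
  p
}

#' Validate a pipeline configuration
#'
#' A configuration is a list (or YAML file) with `inputs` (paths named
#' `asv`, `taxonomy`, `metadata`, `qpcr` and optionally `env`), `out_dir`
#' and optional `params` overriding [pipeline_params]. Validation runs
#' before any stage: all referenced files must exist and numeric
#' parameters must be in range.
#'
#' @param config List or path to a YAML file.
#' @return Normalised config list (with full `params`).
#' @export
validate_config <- function(config) {
  if (is.character(config) && length(config) == 1) {
    config <- yaml::read_yaml(config)
  }
  need <- c("asv", "taxonomy", "metadata", "qpcr")
  miss <- setdiff(need, names(config$inputs))
  if (length(miss)) {
    stop("config validation: missing input path(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  for (nm in names(config$inputs)) {
    if (!file.exists(config$inputs[[nm]])) {
      stop("config validation: input file not found: ",
           config$inputs[[nm]], call. = FALSE)
    }
  }
  if (is.null(config$out_dir)) {
    stop("config validation: out_dir required", call. = FALSE)
  }
  config$params <- do.call(pipeline_params,
                           if (is.null(config$params)) list()
                           else config$params)
  p <- config$params
  if (p$core_threshold <= 0 || p$core_threshold > 1) {
    stop("config validation: core_threshold outside (0, 1]", call. = FALSE)
  }
  if (p$n_perm < 1) stop("config validation: n_perm must be >= 1",
                         call. = FALSE)
  config
}

.stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    stop(sprintf("stage %s: %s", name, conditionMessage(e)), call. = FALSE)
  })
}

#' Run the full quantitative profiling pipeline
#'
#' Executes, in order: input reading and validation; qPCR quantification
#' (total 16S copies per cm2 per sample); organellar/eukaryote removal;
#' negative-control contaminant filtering; rescaling to absolute
#' abundances; genus pooling; core-index computation and core
#' classification; host-specificity analyses (upset intersection counts at
#' ASV and genus level, shared-pair comparison); and community statistics
#' (Bray-Curtis, PERMANOVA by tissue and season with pairwise comparisons,
#' dispersion, richness, optional environmental pruning). All outputs are
#' written as TSV under `out_dir`, together with a manifest recording each
#' file's MD5 hash, the parameters and the seed. Any stage error aborts
#' with the stage name.
#'
#' @param config See [validate_config].
#' @return The manifest data frame (invisibly); all results are also
#'   returned in the `results` attribute.
#' @export
run_pipeline <- function(config) {
  config <- validate_config(config)
  p <- config$params
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  res <- list()

  inp <- .stage("read", {
    list(asv = read_asv_table(config$inputs$asv),
         taxonomy = read_taxonomy(config$inputs$taxonomy),
         metadata = read_metadata(config$inputs$metadata),
         qpcr = read_qpcr(config$inputs$qpcr),
         env = if (!is.null(config$inputs$env)) {
           read_env_table(config$inputs$env)
         })
  })
  md <- inp$metadata
  controls <- md$sample_id[md$is_negative_control]

  loads <- .stage("quantify", {
    attach_loads(md, inp$qpcr, V = p$V, c = p$c, v = p$v, S = p$S,
                 window = p$load_window)
  })

  filt <- .stage("filter", {
    org <- remove_organellar(inp$asv, inp$taxonomy, p$organellar_labels)
    if (length(controls)) {
      con <- flag_contaminants(org$table, controls,
                               max_freq = p$contam_max_freq,
                               max_relab = p$contam_max_relab)
    } else {
      con <- list(table = org$table, flagged = character(0),
                  report = data.frame())
    }
    list(org = org, con = con)
  })
  tab <- filt$con$table

  absmat <- .stage("scale", scale_to_absolute(tab, loads))
  pooled <- .stage("pool", pool_by_rank(absmat, inp$taxonomy, "genus"))
  relmat <- sweep(unclass(tab), 1, rowSums(tab), "/")
  rel_pooled <- pool_by_rank(relmat, inp$taxonomy, "genus")

  core <- .stage("core", {
    idx <- core_index_table(pooled$matrix, md,
                            detection_threshold = p$detection_copies)
    cls <- classify_core(idx, threshold = p$core_threshold)
    list(index = idx, classified = cls)
  })

  sets <- .stage("sets", {
    list(asv = intersection_counts(absmat, md,
                                   detection_threshold = p$detection_copies),
         genus = intersection_counts(pooled$matrix, md,
                                     detection_threshold = p$detection_copies),
         pairs = pairwise_shared(absmat, md))
  })
  comparison <- .stage("sets", group_comparison(sets$pairs))

  stats_res <- .stage("stats", {
    d <- bray_curtis(absmat)
    grp_t <- md$tissue[match(rownames(absmat), md$sample_id)]
    grp_s <- md$season[match(rownames(absmat), md$sample_id)]
    list(
      dist = d,
      permanova_tissue = permanova(d, grp_t, n_perm = p$n_perm,
                                   seed = p$seed),
      permanova_season = permanova(d, grp_s, n_perm = p$n_perm,
                                   seed = p$seed + 1),
      pairwise_season = pairwise_permanova(d, grp_s, n_perm = p$n_perm,
                                           seed = p$seed + 2),
      dispersion_tissue = dispersion(d, grp_t, n_perm = p$n_perm,
                                     seed = p$seed + 3),
      richness = observed_richness(absmat, groupby = grp_t,
                                   detection_threshold = p$detection_copies),
      env = if (!is.null(inp$env)) {
        env_prune(inp$env, alpha = p$env_alpha,
                  r_threshold = p$env_r_threshold)
      }
    )
  })

  res <- list(loads = loads, filter = filt, abs = absmat, pooled = pooled,
              rel_pooled = rel_pooled, core = core, sets = sets,
              comparison = comparison, stats = stats_res)

  out <- function(name) file.path(config$out_dir, name)
  .stage("write", {
    old <- options(OutDec = ".")
    on.exit(options(old))
    utils::write.table(loads, out("loads.tsv"), sep = "\t", quote = FALSE,
                       row.names = FALSE)
    utils::write.table(filt$con$report, out("contaminant_report.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    writeLines(c("# contaminant clauses evaluated on the",
                 "# post-organellar-filter read table",
                 filt$org$removed), out("removed_organellar.txt"))
    write_matrix_tsv(absmat, out("absolute_asv.tsv"), id_col = "sample_id")
    write_matrix_tsv(pooled$matrix, out("absolute_genus.tsv"),
                     id_col = "sample_id")
    write_matrix_tsv(core$index, out("core_index.tsv"), id_col = "genus")
    agg <- data.frame(genus = rownames(core$classified$aggregated),
                      core$classified$aggregated,
                      core = core$classified$is_core,
                      check.names = FALSE)
    utils::write.table(agg, out("core_classification.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    utils::write.table(sets$genus$counts, out("upset_genus.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(sets$asv$counts, out("upset_asv.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(sets$pairs, out("shared_pairs.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    write_matrix_tsv(stats_res$dist, out("bray_curtis.tsv"),
                     id_col = "sample_id")
    pt <- stats_res$permanova_tissue
    ps <- stats_res$permanova_season
    utils::write.table(
      data.frame(factor = c("tissue", "season"),
                 f = c(pt$f, ps$f),
                 df1 = c(pt$df[1], ps$df[1]),
                 df2 = c(pt$df[2], ps$df[2]),
                 r2 = c(pt$r2, ps$r2),
                 p_value = c(pt$p_value, ps$p_value),
                 n_perm = p$n_perm, seed = c(p$seed, p$seed + 1)),
      out("permanova.tsv"), sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(stats_res$pairwise_season,
                       out("pairwise_permanova_season.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(stats_res$richness$summary, out("richness.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    if (!is.null(stats_res$env)) {
      utils::write.table(stats_res$env$report, out("env_correlations.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      writeLines(stats_res$env$retained, out("env_retained.txt"))
    }
  })

  files <- list.files(config$out_dir, full.names = TRUE)
  files <- setdiff(files, out("manifest.tsv"))
  manifest <- data.frame(
    file = basename(files),
    md5 = unname(tools::md5sum(files)),
    seed = p$seed,
    n_perm = p$n_perm,
    core_threshold = p$core_threshold,
    stringsAsFactors = FALSE
  )
  utils::write.table(manifest, out("manifest.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  attr(manifest, "results") <- res
  invisible(manifest)
}
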