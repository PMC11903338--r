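# Distance-based community statistics: Bray-Curtis, PERMANOVA with
# permutation p-values, pairwise PERMANOVA, multivariate dispersion,
# observed richness and environmental-variable pruning.

#' Bray-Curtis dissimilarity matrix
#'
#' d(x, y) = sum|x_i - y_i| / sum(x_i + y_i) between all sample pairs of a
#' non-negative abundance matrix (reads or copies per cm2). Zero for
#' identical samples, one for disjoint supports; invariant under jointly
#' rescaling both samples of a pair.
#'
#' @param matrix Samples-by-taxa non-negative matrix; every sample must
#'   have a positive total.
#' @return Square symmetric matrix of dissimilarities in `[0, 1]` with the
#'   sample ids as dimnames.
#' @export
bray_curtis <- function(matrix) {
  if (any(matrix < 0)) stop("abundances must be non-negative", call. = FALSE)
  tot <- rowSums(matrix)
  if (any(tot == 0)) {
    stop("sample(s) with zero total abundance: ",
         paste(rownames(matrix)[tot == 0], collapse = ", "), call. = FALSE)
  }
  num <- as.matrix(stats::dist(matrix, method = "manhattan"))
  den <- outer(tot, tot, "+")
  d <- num / den
  diag(d) <- 0
  dimnames(d) <- list(rownames(matrix), rownames(matrix))
  d
}

# Pseudo-F from a squared-distance matrix and a grouping, via the
# sums-of-squares decomposition SS_total = (1/N) sum_{i<j} d2_ij and
# SS_within = sum_g (1/n_g) sum_{i<j in g} d2_ij.
.pseudo_f <- function(d2, groups, lev) {
  n <- nrow(d2)
  k <- length(lev)
  ss_tot <- sum(d2) / (2 * n)
  ss_w <- 0
  for (g in lev) {
    s <- which(groups == g)
    ss_w <- ss_w + sum(d2[s, s]) / (2 * length(s))
  }
  ss_b <- ss_tot - ss_w
  list(f = (ss_b / (k - 1)) / (ss_w / (n - k)),
       r2 = ss_b / ss_tot, ss_b = ss_b, ss_w = ss_w)
}

#' Permutational multivariate analysis of variance (PERMANOVA)
#'
#' Single-factor PERMANOVA on a distance matrix: partitions the squared
#' dissimilarities into between- and within-group components, forms the
#' pseudo-F statistic `F = (SS_b / (k-1)) / (SS_w / (N-k))`, and assesses it
#' by permuting the group labels over whole samples. The p-value uses the
#' add-one convention `p = (1 + #(F_perm >= F_obs)) / (1 + n_perm)`, so it
#' never returns zero and its lower bound is `1/(n_perm + 1)`.
#'
#' @param dist Square symmetric distance matrix (or `dist` object).
#' @param groups Factor-like group labels, one per sample.
#' @param n_perm Number of permutations (default 999).
#' @param seed Integer seed making the permutation draw reproducible.
#' @return Object of class `permanova`: list with `f`, `df` (`k-1`, `N-k`),
#'   `r2`, `p_value`, `n_perm`, `seed`.
#' @export
permanova <- function(dist, groups, n_perm = 999, seed = 1) {
  d <- as.matrix(dist)
  groups <- as.character(groups)
  n <- nrow(d)
  stopifnot(length(groups) == n, n_perm >= 1)
  lev <- unique(groups)
  k <- length(lev)
  if (k < 2) stop("need at least two groups", call. = FALSE)
  if (n - k <= 0) stop("no residual degrees of freedom", call. = FALSE)
  d2 <- d^2
  obs <- .pseudo_f(d2, groups, lev)
  if (obs$ss_w == 0) {
    warning("zero within-group sum of squares; F is infinite")
  }
  set.seed(seed)
  hits <- 0L
  for (b in seq_len(n_perm)) {
    fp <- .pseudo_f(d2, sample(groups), lev)$f
    if (fp >= obs$f) hits <- hits + 1L
  }
  structure(list(
    f = obs$f,
    df = c(k - 1L, n - k),
    r2 = obs$r2,
    p_value = (1 + hits) / (1 + n_perm),
    n_perm = n_perm,
    seed = seed
  ), class = "permanova")
}

#' @export
print.permanova <- function(x, ...) {
  cat(sprintf("PERMANOVA: F(%d,%d) = %.3f, R2 = %.3f, p = %.4g (%d perms)\n",
              x$df[1], x$df[2], x$f, x$r2, x$p_value, x$n_perm))
  invisible(x)
}

#' Pairwise PERMANOVA with Benjamini-Hochberg adjustment
#'
#' Runs [permanova] on the submatrix of every pair of groups and adjusts
#' the permutation p-values across pairs with BH.
#'
#' @inheritParams permanova
#' @return Data frame with `group_a`, `group_b`, `f`, `p_raw`, `p_adj`.
#' @export
pairwise_permanova <- function(dist, groups, n_perm = 999, seed = 1) {
  d <- as.matrix(dist)
  groups <- as.character(groups)
  lev <- unique(groups)
  pairs <- utils::combn(lev, 2)
  out <- data.frame(group_a = pairs[1, ], group_b = pairs[2, ],
                    f = NA_real_, p_raw = NA_real_,
                    stringsAsFactors = FALSE)
  for (j in seq_len(ncol(pairs))) {
    s <- groups %in% pairs[, j]
    res <- permanova(d[s, s, drop = FALSE], groups[s],
                     n_perm = n_perm, seed = seed + j)
    out$f[j] <- res$f
    out$p_raw[j] <- res$p_value
  }
  out$p_adj <- stats::p.adjust(out$p_raw, method = "BH")
  out
}

#' Multivariate dispersion (distance to group centroid)
#'
#' Embeds the distance matrix by principal-coordinate analysis, keeping
#' negative-eigenvalue axes as imaginary coordinates: a sample's squared
#' distance to its group centroid is the contribution from the
#' positive-eigenvalue axes minus the contribution from the negative ones
#' (truncated at zero before the square root). Reports per-group mean
#' distances and a permutation test of an ANOVA-type F over the per-sample
#' distances under group-label permutation.
#'
#' @inheritParams permanova
#' @return List with `distances` (per-sample distance to own-group
#'   centroid), `group_means`, `f`, `p_value`, `n_perm`, `seed`.
#' @export
dispersion <- function(dist, groups, n_perm = 999, seed = 1) {
  d <- as.matrix(dist)
  groups <- as.character(groups)
  n <- nrow(d)
  stopifnot(length(groups) == n)
  sizes <- table(groups)
  if (any(sizes < 2)) stop("each group needs at least 2 samples",
                           call. = FALSE)
  ctr <- diag(n) - 1 / n
  G <- -0.5 * ctr %*% (d^2) %*% ctr
  G <- (G + t(G)) / 2
  e <- eigen(G, symmetric = TRUE)
  tol <- max(abs(e$values)) * 1e-10
  if (!is.finite(tol) || tol == 0) tol <- 1e-12
  pos <- e$values > tol
  neg <- e$values < -tol
  xp <- e$vectors[, pos, drop = FALSE] %*%
    diag(sqrt(e$values[pos]), sum(pos))
  xn <- e$vectors[, neg, drop = FALSE] %*%
    diag(sqrt(-e$values[neg]), sum(neg))
  dist2 <- numeric(n)
  for (g in unique(groups)) {
    s <- groups == g
    cp <- colMeans(xp[s, , drop = FALSE])
    cn <- colMeans(xn[s, , drop = FALSE])
    d2p <- rowSums(sweep(xp[s, , drop = FALSE], 2, cp)^2)
    d2n <- rowSums(sweep(xn[s, , drop = FALSE], 2, cn)^2)
    dist2[s] <- pmax(d2p - d2n, 0)
  }
  z <- sqrt(dist2)
  f_of <- function(lab) {
    m <- tapply(z, lab, mean)
    nb <- table(lab)
    gm <- mean(z)
    ss_b <- sum(nb * (m - gm)^2)
    ss_w <- sum((z - m[lab])^2)
    (ss_b / (length(nb) - 1)) / (ss_w / (length(z) - length(nb)))
  }
  if (stats::sd(z) == 0) {
    # all distances equal (e.g. every sample identical): F undefined
    warning("constant distances to centroid; dispersion test undefined")
    f_obs <- NA_real_
    p_val <- NA_real_
  } else {
    f_obs <- f_of(groups)
    set.seed(seed)
    hits <- 0L
    for (b in seq_len(n_perm)) if (f_of(sample(groups)) >= f_obs) {
      hits <- hits + 1L
    }
    p_val <- (1 + hits) / (1 + n_perm)
  }
  list(
    distances = stats::setNames(z, rownames(d)),
    group_means = tapply(z, groups, mean),
    f = f_obs,
    p_value = p_val,
    n_perm = n_perm,
    seed = seed
  )
}

#' Observed richness per sample, with optional group summaries
#'
#' Counts the taxa at or above a detection threshold in each sample.
#'
#' @param matrix Samples-by-taxa matrix.
#' @param groupby Optional vector of group labels (one per sample) for a
#'   summary table.
#' @param detection_threshold Minimum abundance counted as present
#'   (default 1).
#' @return Named vector of per-sample richness; when `groupby` is given, a
#'   list with `per_sample` and `summary` (group, n, mean, sd).
#' @export
observed_richness <- function(matrix, groupby = NULL,
                              detection_threshold = 1) {
  rich <- rowSums(matrix >= detection_threshold)
  if (is.null(groupby)) return(rich)
  groupby <- as.character(groupby)
  summary <- data.frame(
    group = sort(unique(groupby)),
    stringsAsFactors = FALSE
  )
  summary$n <- as.integer(table(groupby)[summary$group])
  summary$mean <- tapply(rich, groupby, mean)[summary$group]
  summary$sd <- tapply(rich, groupby, stats::sd)[summary$group]
  list(per_sample = rich, summary = summary)
}

#' Prune highly correlated environmental variables
#'
#' Computes all pairwise Pearson correlations between environmental
#' variables (across months), BH-adjusts the correlation-test p-values,
#' and removes variables greedily — the variable with the highest maximum
#' absolute correlation among offending pairs first — until no retained
#' pair has adjusted p below `alpha` and `|r|` at or above `r_threshold`.
#' Constant variables (undefined r) are flagged and treated as
#' uncorrelated. The full correlation report is returned for audit, since
#' any automated rule is one of several defensible choices.
#'
#' @param env_table Months-by-variables numeric matrix.
#' @param alpha Adjusted-p cutoff (default 0.05).
#' @param r_threshold Absolute-correlation cutoff (default 0.8).
#' @return List with `retained`, `removed` (in removal order), `constant`
#'   and `report` (data frame `var_a`, `var_b`, `r`, `p_raw`, `p_adj`).
#' @export
env_prune <- function(env_table, alpha = 0.05, r_threshold = 0.8) {
  m <- as.matrix(env_table)
  vars <- colnames(m)
  if (length(vars) < 2 || nrow(m) < 3) {
    stop("need at least 2 variables and 3 months", call. = FALSE)
  }
  constant <- vars[apply(m, 2, function(x) {
    all(is.na(x)) || isTRUE(stats::var(x, na.rm = TRUE) == 0)
  })]
  pairs <- utils::combn(vars, 2)
  r <- p <- numeric(ncol(pairs))
  for (j in seq_len(ncol(pairs))) {
    a <- m[, pairs[1, j]]
    b <- m[, pairs[2, j]]
    if (pairs[1, j] %in% constant || pairs[2, j] %in% constant) {
      r[j] <- 0
      p[j] <- 1
    } else {
      ct <- stats::cor.test(a, b, method = "pearson")
      r[j] <- unname(ct$estimate)
      p[j] <- ct$p.value
    }
  }
  report <- data.frame(var_a = pairs[1, ], var_b = pairs[2, ],
                       r = r, p_raw = p,
                       p_adj = stats::p.adjust(p, method = "BH"),
                       stringsAsFactors = FALSE)
  retained <- vars
  removed <- character(0)
  repeat {
    live <- report$var_a %in% retained & report$var_b %in% retained
    bad <- live & report$p_adj < alpha & abs(report$r) >= r_threshold
    if (!any(bad)) break
    cand <- unique(c(report$var_a[bad], report$var_b[bad]))
    worst <- vapply(cand, function(v) {
      max(abs(report$r[bad & (report$var_a == v | report$var_b == v)]))
    }, numeric(1))
    drop <- cand[which.max(worst)]
    removed <- c(removed, drop)
    retained <- setdiff(retained, drop)
  }
  list(retained = retained, removed = removed, constant = constant,
       report = report)
}
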