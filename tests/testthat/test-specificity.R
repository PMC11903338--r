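# Metadata with one sample per tissue (7 tissues over 5 hosts).
mk_host_metadata <- function() {
  mk_metadata(qmp_tissues, "Jan", 1, sample_id = qmp_tissues)
}

test_that("exclusive intersection counts partition the detected taxa", {
  md <- mk_host_metadata()
  m <- matrix(0, 7, 5, dimnames = list(qmp_tissues, paste0("G", 1:5)))
  m[, "G1"] <- 1                                   # on all 5 hosts
  m["Anod", "G2"] <- 3                             # private taxa
  m["Ulva", "G3"] <- 2
  m["LdigM", "G4"] <- 1                            # private to host Ldig
  out <- intersection_counts(m, md)
  counts <- setNames(out$counts$n_taxa, out$counts$subset)
  expect_equal(unname(counts["Anod+Fser+Ldig+Ppal+Ulva"]), 1)
  expect_equal(unname(counts["Anod"]), 1)
  expect_equal(unname(counts["Ulva"]), 1)
  expect_equal(unname(counts["Ldig"]), 1)
  expect_equal(out$n_detected, 4)                  # G5 never detected
  expect_equal(sum(out$counts$n_taxa), out$n_detected)
})

test_that("intersection counts agree with brute-force subset enumeration", {
  md <- mk_host_metadata()
  set.seed(10)
  for (rep in 1:5) {
    m <- matrix(rbinom(7 * 30, 1, 0.3) * rpois(7 * 30, 4), 7, 30,
                dimnames = list(qmp_tissues, paste0("G", 1:30)))
    out <- intersection_counts(m, md)
    # oracle: loop every taxon, build its exclusive host set independently
    hosts <- unname(qmp_tissue_host[rownames(m)])
    keys <- character(0)
    for (g in colnames(m)) {
      on <- unique(hosts[m[, g] >= 1])
      if (length(on) == 0) next
      keys <- c(keys, paste(intersect(qmp_hosts, on), collapse = "+"))
    }
    oracle_counts <- table(keys)
    for (key in out$counts$subset) {
      want <- if (key %in% names(oracle_counts)) {
        as.integer(oracle_counts[[key]])
      } else 0L
      expect_equal(out$counts$n_taxa[out$counts$subset == key], want)
    }
    oracle_total <- sum(colSums(m >= 1) > 0)
    expect_equal(sum(out$counts$n_taxa), oracle_total)
    expect_equal(out$n_detected, oracle_total)
    # per-host sizes
    for (h in qmp_hosts) {
      expect_equal(unname(out$per_host[h]),
                   sum(colSums(m[hosts == h, , drop = FALSE] >= 1) > 0))
    }
  }
})

test_that("whole-percent shares round as reported", {
  expect_equal(whole_percent(103, 10243), 1L)
  expect_equal(whole_percent(6801, 10243), 66L)
  expect_equal(whole_percent(93, 331), 28L)
  expect_equal(whole_percent(10, 331), 3L)
})

test_that("pairwise shared counts match the elementwise oracle", {
  md <- mk_metadata(c("Fser", "Fser", "Anod", "Ulva"), "Jan", 1:4)
  m <- mk_counts(rbind(c(1, 1, 0, 2),
                       c(1, 1, 0, 2),
                       c(0, 0, 3, 0),
                       c(1, 0, 1, 0)),
                 samples = md$sample_id)
  out <- pairwise_shared(m, md)
  s12 <- out$shared[out$sample_a == "s1" & out$sample_b == "s2"]
  expect_equal(s12, sum(m["s1", ] > 0))          # identical samples
  s13 <- out$shared[out$sample_a == "s1" & out$sample_b == "s3"]
  expect_equal(s13, 0)                           # disjoint supports
  # classes
  cls <- function(a, b) out$class[out$sample_a == a & out$sample_b == b]
  expect_equal(cls("s1", "s2"), "intra-species")
  expect_equal(cls("s1", "s3"), "intra-phylum")
  expect_equal(cls("s1", "s4"), "inter-phylum")

  set.seed(11)
  m2 <- mk_counts(matrix(rbinom(4 * 40, 1, 0.4), 4, 40),
                  samples = md$sample_id)
  out2 <- pairwise_shared(m2, md)
  for (i in seq_len(nrow(out2))) {
    a <- m2[out2$sample_a[i], ] > 0
    b <- m2[out2$sample_b[i], ] > 0
    expect_equal(out2$shared[i], sum(a & b))
  }
})

test_that("group comparison detects a shifted class and applies BH", {
  set.seed(12)
  pairs <- data.frame(
    shared = c(rpois(30, 20), rpois(30, 20), rpois(30, 60)),
    class = rep(c("intra-species", "intra-phylum", "inter-phylum"),
                each = 30)
  )
  out <- group_comparison(pairs)
  expect_lt(out$omnibus$p_value, 0.01)
  expect_equal(out$omnibus$df, 2)
  # BH step-up oracle on the raw pairwise p-values
  p <- out$pairwise$p_raw
  n <- length(p)
  o <- order(p)
  stepped <- rev(cummin(rev(p[o] * n / seq_len(n))))
  bh <- pmin(1, stepped)[order(o)]
  expect_equal(out$pairwise$p_adj, bh)
  expect_true(all(out$pairwise$p_adj >= out$pairwise$p_raw - 1e-12))
  expect_true(all(out$pairwise$p_adj <= 1))
  expect_error(group_comparison(data.frame(shared = 1:3,
                                           class = c("a", "a", "b"))),
               "at least 2")
})

test_that("planted host-specific taxa share more within than across hosts", {
  tr <- generate_truth(seed = 21)
  reads <- simulate_reads(tr, seed = 22)
  md <- tr$metadata
  real <- unclass(reads)[!rownames(reads) %in%
                           md$sample_id[md$is_negative_control], ]
  set.seed(23)
  pairs <- pairwise_shared(real[sample(nrow(real), 60), ], md)
  med <- tapply(pairs$shared, pairs$class, median)
  expect_gte(med["intra-species"], med["inter-phylum"])
})
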