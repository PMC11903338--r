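test_that("organellar and eukaryote lineages are removed at any rank", {
  m <- mk_counts(matrix(1:10, 2, 5))
  tax <- mk_taxonomy(colnames(m), genus = "Granulosicoccus")
  tax$order[2] <- "Chloroplast"
  tax$domain[4] <- "Eukaryota"
  out <- remove_organellar(asv_table(m), tax)
  expect_setequal(out$removed, c("ASV2", "ASV4"))
  expect_equal(ncol(out$table), 3)
  # retained columns untouched
  expect_equal(unclass(out$table)[, "ASV1"], m[, "ASV1"])
  # case-insensitive
  tax$order[2] <- "chloroplast"
  expect_setequal(remove_organellar(asv_table(m), tax)$removed,
                  c("ASV2", "ASV4"))
  expect_error(remove_organellar(asv_table(m), tax[-1, ]), "missing")
})

test_that("contaminant rule needs all three clauses", {
  # 20 real samples + 1 control; ASV1 satisfies all clauses, ASV2 is absent
  # from controls, ASV3 is too prevalent
  set.seed(2)
  m <- mk_counts(matrix(0, 21, 4),
                 samples = c(paste0("s", 1:20), "NC1"))
  m[, 4] <- rpois(21, 300) + 1          # abundant backbone taxon
  m[c(1, 3, 19), 1] <- 1                # rare: freq 3, relab < 1.5%
  m["NC1", 1] <- 40
  m[c(2, 5), 2] <- 1                    # never in a control
  m[1:15, 3] <- 2                       # freq 15 > 11
  m["NC1", 3] <- 10
  out <- flag_contaminants(asv_table(m), "NC1", max_freq = 11,
                           max_relab = 0.015)
  expect_equal(out$flagged, "ASV1")
  expect_equal(out$report$frequency, 3)
  expect_false("NC1" %in% rownames(out$table))
  expect_false("ASV1" %in% colnames(out$table))
  expect_true(all(c("ASV2", "ASV3") %in% colnames(out$table)))
  expect_error(flag_contaminants(asv_table(m), character(0)),
               "without negative controls")
})

test_that("organellar and contaminant filters commute on a fixed reference", {
  set.seed(3)
  m <- mk_counts(matrix(rpois(25 * 12, 2), 25, 12),
                 samples = c(paste0("s", 1:23), "NC1", "NC2"))
  m[24:25, ] <- 0
  m[24, c(2, 7)] <- 25                   # control-borne ASVs
  m[25, 7] <- 10
  m[, 2] <- 0; m[c(1, 4), 2] <- 1; m[24, 2] <- 25
  tab <- asv_table(m)
  tax <- mk_taxonomy(colnames(m), genus = "G")
  tax$class[c(3, 7)] <- "Cyanobacteria"
  ctrl <- c("NC1", "NC2")

  a <- remove_organellar(tab, tax)
  a2 <- flag_contaminants(a$table, ctrl, reference = a$table)
  kept_a <- colnames(a2$table)

  b <- flag_contaminants(tab, ctrl, reference = a$table)
  b2 <- remove_organellar(b$table, tax)
  kept_b <- colnames(b2$table)
  expect_setequal(kept_a, kept_b)
})

test_that("scaling to absolute abundance preserves per-sample loads", {
  m <- mk_counts(rbind(c(20, 80), c(10, 0)))
  loads <- c(s1 = 1e6, s2 = 0)
  out <- scale_to_absolute(asv_table(m), loads)
  expect_equal(out["s1", ], c(ASV1 = 2e5, ASV2 = 8e5))
  expect_equal(unname(out["s2", ]), c(0, 0))

  set.seed(4)
  m2 <- mk_counts(matrix(rpois(10 * 8, 5) + 1, 10, 8))
  loads2 <- setNames(10^runif(10, 5, 7.7), rownames(m2))
  out2 <- scale_to_absolute(asv_table(m2), loads2)
  expect_equal(rowSums(out2), loads2, tolerance = 1e-6)
  # scale-equivariance: multiplying a sample's reads leaves its row alone
  m3 <- m2; m3[1, ] <- m3[1, ] * 7
  expect_equal(scale_to_absolute(asv_table(m3), loads2)[1, ], out2[1, ])

  bad <- m2; bad[1, ] <- 0
  expect_error(scale_to_absolute(asv_table(bad), loads2), "unresolvable")
  expect_error(scale_to_absolute(asv_table(m2), loads2[-1]), "missing load")
})

test_that("rank pooling matches an independent group-by and conserves mass", {
  m <- mk_counts(rbind(c(100, 50, 7), c(1, 2, 3)))
  tax <- mk_taxonomy(colnames(m), genus = c("X", "X", "Y"))
  out <- pool_by_rank(m, tax, "genus")
  expect_equal(out$matrix["s1", "X"], 150)

  set.seed(5)
  m2 <- mk_counts(matrix(rpois(6 * 20, 4), 6, 20))
  gen <- sample(c("A", "B", "C", ""), 20, replace = TRUE)
  tax2 <- mk_taxonomy(colnames(m2), genus = gen)
  out2 <- pool_by_rank(m2, tax2, "genus")
  # oracle: per-sample tapply over genus labels
  for (s in rownames(m2)) {
    oracle <- tapply(m2[s, gen != ""], gen[gen != ""], sum)
    expect_equal(unname(out2$matrix[s, names(oracle)]),
                 unname(as.numeric(oracle)))
  }
  expect_setequal(out2$excluded, colnames(m2)[gen == ""])
  expect_equal(sum(out2$matrix) + out2$excluded_mass, sum(m2))
})

test_that("copy-to-cell conversion divides by the operon number", {
  expect_equal(copies_to_cells(7.7e6), 7.7e6 / 3)
  expect_equal(copies_to_cells(7.7e6), 2.566667e6, tolerance = 1e-6)
  expect_equal(copies_to_cells(6e6), 2e6)
  expect_equal(copies_to_cells(0), 0)
  expect_error(copies_to_cells(1, 0), "operons")
})
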