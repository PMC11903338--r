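# Build a samples-by-taxa matrix for one tissue from a taxon x month x
# replicate presence specification (counts 0/7 reads).
cube_matrix <- function(presence, tissue = "Fser") {
  dn <- dimnames(presence)
  samples <- as.vector(outer(dn[[2]], seq_len(dim(presence)[3]),
                             function(m, r) sprintf("%s_%s_r%d", tissue, m, r)))
  m <- matrix(0, length(samples), dim(presence)[1],
              dimnames = list(samples, dn[[1]]))
  for (tx in dn[[1]]) for (mo in dn[[2]]) for (r in seq_len(dim(presence)[3])) {
    v <- presence[tx, mo, r]
    if (!is.na(v)) {
      m[sprintf("%s_%s_r%d", tissue, mo, r), tx] <- 7 * v
    }
  }
  m
}

mk_cube_spec <- function(n_taxa = 1, months = qmp_months, r = 3) {
  array(0, dim = c(n_taxa, length(months), r),
        dimnames = list(paste0("G", seq_len(n_taxa)), months,
                        paste0("r", seq_len(r))))
}

test_that("presence cube thresholds abundances and honours missing slots", {
  md <- mk_tissue_metadata("Fser", months = c("Jan", "Feb"), r = 3)
  m <- matrix(0, nrow(md), 2,
              dimnames = list(md$sample_id, c("G1", "G2")))
  m["Fser_Jan_r1", "G1"] <- 0
  m["Fser_Jan_r2", "G1"] <- 3
  m["Fser_Jan_r3", "G1"] <- 7
  cube <- presence_cube(m, md, "Fser")
  expect_equal(unname(cube["G1", "Jan", ]), c(0, 1, 1))
  expect_equal(unname(cube["G2", , ]), matrix(0, 2, 3), ignore_attr = TRUE)
  expect_error(presence_cube(m, md, "Ppal"), "no samples")

  # deficit month: missing replicate slot is NA, not 0
  md2 <- md[md$sample_id != "Fser_Feb_r3", ]
  cube2 <- presence_cube(m[md2$sample_id, ], md2, "Fser")
  expect_true(is.na(cube2["G1", "Feb", "r3"]))

  # brute-force elementwise agreement on a random matrix and threshold
  set.seed(6)
  m3 <- matrix(rpois(nrow(md) * 4, 2), nrow(md), 4,
               dimnames = list(md$sample_id, paste0("G", 1:4)))
  thr <- 2
  cube3 <- presence_cube(m3, md, "Fser", detection_threshold = thr)
  for (i in seq_len(nrow(md))) {
    expect_equal(unname(cube3[, md$month[i], md$replicate[i]]),
                 unname(as.numeric(m3[md$sample_id[i], ] >= thr)))
  }
})

test_that("occupancy and redundancy terms follow the replicate rules", {
  spec <- mk_cube_spec()
  spec["G1", "Jan", ] <- c(1, 1, 1)
  spec["G1", "Feb", ] <- c(1, 1, 0)
  spec["G1", "Mar", ] <- c(1, 0, NA)   # deficit month, 1 of 2 present
  spec["G1", "Jun", ] <- c(1, 1, NA)   # deficit month, all available present
  md <- mk_tissue_metadata("Fser")
  md <- md[!(md$month %in% c("Mar", "Jun") & md$replicate == 3), ]
  cube <- presence_cube(cube_matrix(spec)[md$sample_id, , drop = FALSE],
                        md, "Fser")
  expect_equal(occupancy_term(cube, "G1", "Jan"), 1)
  expect_equal(occupancy_term(cube, "G1", "Feb"), 2 / 3)
  expect_equal(occupancy_term(cube, "G1", "Mar"), 1 / 2)
  expect_equal(redundancy_term(cube, "G1", "Jan"), 1)
  expect_equal(redundancy_term(cube, "G1", "Feb"), 0)
  expect_equal(redundancy_term(cube, "G1", "Jun"), 1)
})

test_that("index hand-arithmetic cases", {
  md <- mk_tissue_metadata("Fser")

  all_present <- mk_cube_spec(); all_present["G1", , ] <- 1
  m <- cube_matrix(all_present)
  cube <- presence_cube(m, md, "Fser")
  expect_equal(unname(occupancy_redundancy_index(cube, "G1")), 1)

  absent <- mk_cube_spec()
  cube0 <- presence_cube(cube_matrix(absent), md, "Fser")
  expect_equal(unname(occupancy_redundancy_index(cube0, "G1")), 0)

  # 2 of 3 replicates in each of 10 months: (10 * (2/3 + 0)) / 20 = 1/3
  two3 <- mk_cube_spec(); two3["G1", , c(1, 2)] <- 1
  cube23 <- presence_cube(cube_matrix(two3), md, "Fser")
  expect_equal(unname(occupancy_redundancy_index(cube23, "G1")), 1 / 3)

  # all replicates in 5 months, absent in 5: (5 * 2) / 20 = 1/2
  half <- mk_cube_spec(); half["G1", 1:5, ] <- 1
  cube5 <- presence_cube(cube_matrix(half), md, "Fser")
  expect_equal(unname(occupancy_redundancy_index(cube5, "G1")), 0.5)
})

test_that("index is bounded, equals brute force, and is monotone", {
  md <- mk_tissue_metadata("Fser")
  set.seed(8)
  for (rep in 1:10) {
    spec <- mk_cube_spec(n_taxa = 3)
    spec[] <- rbinom(length(spec), 1, 0.5)
    cube <- presence_cube(cube_matrix(spec), md, "Fser")
    idx <- occupancy_redundancy_index(cube)
    expect_true(all(idx >= 0 & idx <= 1))
    for (tx in names(idx)) {
      expect_equal(unname(idx[tx]), brute_force_index(cube, tx))
    }
    # flip one absent slot to present: index never decreases
    zero <- which(spec == 0)
    if (length(zero)) {
      spec2 <- spec
      spec2[sample(zero, 1)] <- 1
      cube2 <- presence_cube(cube_matrix(spec2), md, "Fser")
      idx2 <- occupancy_redundancy_index(cube2)
      expect_true(all(idx2 >= idx - 1e-12))
    }
  }
  # index 1 iff present in every non-missing slot
  full <- mk_cube_spec(); full["G1", , ] <- 1
  cube <- presence_cube(cube_matrix(full), md, "Fser")
  expect_equal(unname(occupancy_redundancy_index(cube, "G1")), 1)
  almost <- full; almost["G1", "Dec", 3] <- 0
  cube2 <- presence_cube(cube_matrix(almost), md, "Fser")
  expect_lt(occupancy_redundancy_index(cube2, "G1"), 1)
})

test_that("core classification is strict and averages the Ldig blade parts", {
  idx <- rbind(
    G1 = c(Anod = 1, Fser = 0.9, LdigB = 0.8, LdigM = 0.8, LdigO = 0.8,
           Ppal = 0.7, Ulva = 0.66),
    G2 = c(Anod = 1, Fser = 0.5, LdigB = 1, LdigM = 1, LdigO = 1,
           Ppal = 1, Ulva = 1),
    G3 = c(Anod = 0.66, Fser = 0.66, LdigB = 0.9, LdigM = 0.6, LdigO = 0.6,
           Ppal = 0.66, Ulva = 0.66)
  )
  out <- classify_core(idx, threshold = 0.65)
  expect_true("G1" %in% out$core)        # all species above 0.65
  expect_false("G2" %in% out$core)       # one species at 0.5
  # Ldig aggregate of G3: mean(0.9, 0.6, 0.6) = 0.7
  expect_equal(unname(out$aggregated["G3", "Ldig"]), 0.7)
  expect_true("G3" %in% out$core)
  # ties at the threshold are non-core
  idx2 <- rbind(G1 = c(Anod = 0.65, Fser = 1, LdigB = 1, LdigM = 1,
                       LdigO = 1, Ppal = 1, Ulva = 1))
  expect_length(classify_core(idx2, 0.65)$core, 0)
  expect_error(classify_core(idx, threshold = 0), "threshold")
})

test_that("core-index table covers tissues and planted cores are recovered", {
  # two tissues, one always-present genus, one sporadic genus
  md <- rbind(mk_tissue_metadata("Fser"), mk_tissue_metadata("Ulva"))
  set.seed(9)
  m <- matrix(0, nrow(md), 2, dimnames = list(md$sample_id, c("Core", "Bg")))
  m[, "Core"] <- 5
  m[, "Bg"] <- rbinom(nrow(md), 1, 0.4) * 3
  idx <- core_index_table(m, md)
  expect_equal(colnames(idx), c("Fser", "Ulva"))
  expect_equal(unname(idx["Core", ]), c(1, 1))
  expect_true(all(idx["Bg", ] < 0.65))
})
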