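test_that("allele frequencies are per-population alternate-allele fractions", {
  m <- rbind(matrix(c(1, 1, 1, 1, 0, 0, 0, 0), ncol = 1),
             matrix(0, nrow = 4, ncol = 1))
  panel <- matrix_panel(cbind(m, 0), pops = rep(c("X", "Y"), c(8, 4)))
  f <- allele_frequency(panel, 1)
  expect_equal(unname(f["X"]), 0.5)  # 4 of 8 haplotypes
  expect_equal(unname(f["Y"]), 0)
  expect_equal(unname(f["overall"]), 4 / 12)
  # all-zero column is 0 in every population
  expect_true(all(allele_frequency(panel, 2) == 0))

  # simulated panel: focal-site frequencies equal carrier fractions exactly
  sim <- demo_sim()
  f <- allele_frequency(sim$panel, sim$truth$focal_site_index)
  for (pop in unique(sim$panel$pop_of_haplotype)) {
    ids <- sim$panel$haplotype_ids[sim$panel$pop_of_haplotype == pop]
    expect_equal(
      unname(f[pop]),
      length(intersect(sim$truth$introgressed_haplotype_ids, ids)) /
        length(ids))
  }
})

test_that("ld_r2 matches hand-computed gamete-count cases", {
  expect_equal(ld_r2(two_locus_panel(
    c("AB", "AB", "AB", "ab", "ab", "ab")), 1, 2)$r2, 1)
  expect_equal(ld_r2(two_locus_panel(
    c("AB", "Ab", "aB", "ab")), 1, 2)$r2, 0)
  res <- ld_r2(two_locus_panel(
    c("AB", "AB", "Ab", "aB", "ab", "ab")), 1, 2)
  expect_equal(res$r2, 1 / 9)
  expect_equal(sum(res$haplotype_counts), 6)
  expect_equal(unname(res$haplotype_counts["1", "1"]), 2)

  mono <- two_locus_panel(c("AB", "AB", "Ab", "Ab"))
  expect_error(ld_r2(mono, 1, 2), "monomorphic")
})

test_that("ld_r2 properties: oracle agreement, symmetry, label invariance", {
  set.seed(42)
  checked <- 0L
  while (checked < 60L) {
    m <- matrix(rbinom(40, 1, runif(1, 0.2, 0.8)), ncol = 2)
    if (any(colMeans(m) %in% c(0, 1))) next
    panel <- matrix_panel(m, pops = rep("P", 20))
    r2 <- ld_r2(panel, 1, 2)$r2
    expect_equal(r2, ld_r2_oracle(m[, 1], m[, 2]))
    expect_equal(r2, ld_r2(panel, 2, 1)$r2)           # symmetric
    flipped <- matrix_panel(cbind(1L - m[, 1], m[, 2]), rep("P", 20))
    expect_equal(r2, ld_r2(flipped, 1, 2)$r2)         # label swap
    expect_gte(r2, 0)
    expect_lte(r2, 1)
    checked <- checked + 1L
  }
})

test_that("ld_r2 works on pseudo-markers and haplotype subsets", {
  sim <- demo_sim()
  alu <- insertion_pseudo_marker(sim$panel,
                                 sim$truth$alu_carrier_haplotype_ids)
  res <- ld_r2(sim$panel, sim$truth$focal_site_index, alu)
  # insertion carriers are a subset of segment carriers: r2 in (0, 1)
  expect_gt(res$r2, 0.3)
  expect_lt(res$r2, 1)
  # restricted to carriers of the segment the insertion is monomorphic-free
  sub <- c(sim$truth$introgressed_haplotype_ids,
           setdiff(sim$panel$haplotype_ids,
                   sim$truth$introgressed_haplotype_ids)[1:50])
  res_sub <- ld_r2(sim$panel, sim$truth$focal_site_index, alu,
                   haplotype_subset = sub)
  expect_gte(res_sub$r2, 0)
})

test_that("private archaic sites require strict absence in the outgroup", {
  # 6 haplotypes: 4 outgroup, 2 other; 3 sites
  m <- cbind(c(0, 0, 0, 0, 1, 1),   # absent in outgroup -> private
             c(1, 0, 0, 0, 1, 1),   # 1 outgroup copy -> excluded
             c(0, 0, 0, 0, 1, 0))   # absent, but archaic all-missing
  panel <- matrix_panel(m, pops = rep(c("OUT", "POP"), c(4, 2)))
  arch <- ArchaicGenotypes("arch1", matrix(c(2, 2, NA), nrow = 1))
  idx <- private_archaic_sites(panel, "OUT", arch)
  expect_equal(as.integer(idx), 1L)
  expect_equal(attr(idx, "private_allele"), "alt")

  # reference allele can be the private one (outgroup fixed for alt)
  m2 <- cbind(c(1, 1, 1, 1, 0, 0))
  panel2 <- matrix_panel(m2, pops = rep(c("OUT", "POP"), c(4, 2)))
  arch2 <- ArchaicGenotypes("arch1", matrix(0, nrow = 1))
  idx2 <- private_archaic_sites(panel2, "OUT", arch2)
  expect_equal(attr(idx2, "private_allele"), "ref")

  expect_error(private_archaic_sites(panel, "NOPE", arch), "outgroup")
})

test_that("segment extension follows the r2 threshold over consecutive sites", {
  # 8 haplotypes, 5 sites: sites 2-4 in perfect LD, flanked by noise sites
  seg_col <- c(1, 1, 1, 1, 0, 0, 0, 0)
  set.seed(9)
  noise <- rbinom(8, 1, 0.5)
  while (mean(noise) %in% c(0, 1) ||
         ld_r2_oracle(noise, seg_col) > 0.6) noise <- rbinom(8, 1, 0.5)
  m <- cbind(noise, seg_col, seg_col, seg_col, noise[c(2:8, 1)])
  panel <- matrix_panel(m, pops = rep("P", 8),
                        positions = c(10L, 100L, 150L, 220L, 400L))
  seg <- introgression_segment(panel, 3, r2_threshold = 0.8)
  expect_equal(seg$member_sites, 2:4)
  expect_equal(seg$start_bp, 100L)
  expect_equal(seg$end_bp, 220L)
  expect_equal(seg$length_bp, 120L)

  # impossible threshold: the focal site alone, length 0
  alone <- introgression_segment(panel, 3, r2_threshold = 1.01)
  expect_equal(alone$member_sites, 3L)
  expect_equal(alone$length_bp, 0L)

  # all sites in perfect LD with the focal span first to last
  m3 <- cbind(seg_col, seg_col, seg_col)
  panel3 <- matrix_panel(m3, rep("P", 8), positions = c(5L, 50L, 500L))
  seg3 <- introgression_segment(panel3, 2)
  expect_equal(seg3$length_bp, 495L)

  # monomorphic focal site is rejected
  m4 <- cbind(rep(0L, 8), seg_col)
  expect_error(introgression_segment(matrix_panel(m4, rep("P", 8)), 1),
               "monomorphic")
})

test_that("raising the r2 threshold never lengthens the segment", {
  sim <- demo_sim()
  lens <- vapply(c(0.2, 0.5, 0.8, 0.95), function(thr) {
    introgression_segment(sim$panel, sim$truth$focal_site_index,
                          r2_threshold = thr)$length_bp
  }, numeric(1))
  expect_true(all(diff(lens) <= 0))
})

test_that("archaic match matrix selects and labels sites per the rules", {
  # 8 haplotypes: 4 outgroup, 2 carriers, 2 noncarriers
  pops <- rep(c("OUT", "CAR", "NON"), c(4, 2, 2))
  m <- cbind(
    c(0, 0, 0, 0, 1, 1, 1, 1),  # absent in outgroup, archaic dosage 6
    c(1, 0, 0, 0, 1, 1, 0, 0),  # minor in outgroup (0.25), dosage 3
    c(0, 0, 0, 0, 1, 1, 0, 0),  # absent, archaic dosage 2 -> not selected
    c(0, 0, 0, 0, 1, 0, 1, 0)   # tie in both subsets (freq 0.5)
  )
  panel <- matrix_panel(m, pops = pops)
  arch <- ArchaicGenotypes(
    c("a1", "a2", "a3"),
    rbind(c(2, 1, 1, 2), c(2, 1, 1, 2), c(2, 1, 0, 2))
  )
  ids <- panel$haplotype_ids
  mm <- archaic_match_matrix(panel, carrier_subset = ids[5:6],
                             noncarrier_subset = ids[7:8],
                             outgroup_pop = "OUT", archaic = arch)
  expect_setequal(mm$site_index, c(1L, 2L, 4L))
  r1 <- mm[mm$site_index == 1, ]
  expect_equal(r1$carrier_match, "match")      # carriers fixed for archaic
  expect_equal(r1$noncarrier_match, "match")
  r2 <- mm[mm$site_index == 2, ]
  expect_equal(r2$carrier_match, "match")
  expect_equal(r2$noncarrier_match, "mismatch")
  r4 <- mm[mm$site_index == 4, ]
  expect_equal(r4$carrier_match, "tie")
  expect_equal(r4$noncarrier_match, "tie")

  expect_error(archaic_match_matrix(panel, character(0), ids[7:8],
                                    "OUT", arch), "non-empty")
})
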