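test_that("fragment simulation is deterministic and noise-free by default", {
  rp <- sim_ref_pair()
  cfg <- sim_fragment_config(seed = 5)
  f1 <- simulate_ancient_fragments(rp, "het", cfg)
  f2 <- simulate_ancient_fragments(rp, "het", cfg)
  expect_identical(f1, f2)

  # zero noise: every fragment is an exact substring of its donor chromosome
  frags <- f1$fragments
  donor <- c(ref_with = rp$ref_with, ref_without = rp$ref_without)
  expect_true(all(nchar(frags$sequence) >= cfg$fragment_length_min_bp))
  on_plus <- ifelse(frags$strand == "+", frags$sequence,
                    introscan:::revcomp(frags$sequence))
  extracted <- substr(donor[frags$ref_name], frags$start + 1, frags$end)
  expect_identical(unname(extracted), on_plus)
})

test_that("genotype controls which chromosomes fragments come from", {
  rp <- sim_ref_pair()
  cfg <- sim_fragment_config(target_coverage = 40, seed = 9)
  hom_abs <- simulate_ancient_fragments(rp, "hom_absent", cfg)
  expect_true(all(hom_abs$fragments$ref_name == "ref_without"))
  # no fragment contains the insertion junction 22-mer
  expect_equal(count_junction_fragments(hom_abs$fragments, rp), 0L)

  het <- simulate_ancient_fragments(rp, "het", cfg)
  expect_setequal(unique(het$fragments$ref_name),
                  c("ref_with", "ref_without"))
  # at 40x both evidence classes are present with overwhelming probability
  aligned <- align_fragments(het$fragments, rp$ref_without, "ref_without")
  expect_gt(count_junction_fragments(het$fragments, rp), 0L)
  expect_gt(count_spanning_fragments(aligned, rp$insertion_point), 0L)
})

test_that("realized coverage calibrates to the target", {
  rp <- sim_ref_pair()
  for (cov in c(10, 30)) {
    sf <- simulate_ancient_fragments(
      rp, "hom_absent", sim_fragment_config(target_coverage = cov, seed = 21))
    al <- align_fragments(sf$fragments, rp$ref_without, "ref_without")
    # exclude one fragment-length margin at the edges
    margin <- 2L * max(nchar(sf$fragments$sequence))
    win <- c(margin, nchar(rp$ref_without) - margin)
    prof <- depth_profile(al, win)
    expect_lt(abs(mean(prof$depth) - cov) / cov, 0.10)
  }
})

test_that("terminal deamination rewrites fragment ends as configured", {
  rp <- sim_ref_pair()
  sf <- simulate_ancient_fragments(
    rp, "hom_absent",
    sim_fragment_config(deamination_rate = 1, seed = 13))
  s <- sf$fragments$sequence
  expect_false(any(grepl("C", substr(s, 1, 3))))
  expect_false(any(grepl("G", substr(s, nchar(s) - 2, nchar(s)))))
})

test_that("invalid fragment configs are rejected", {
  expect_error(sim_fragment_config(target_coverage = 0), "positive")
  expect_error(sim_fragment_config(fragment_length_mean_bp = 25,
                                   fragment_length_min_bp = 30),
               "mean fragment length")
  expect_error(sim_fragment_config(fragment_length_min_bp = 10), ">= 22")
  rp <- sim_ref_pair()
  expect_error(
    simulate_ancient_fragments(rp, "hemizygous", sim_fragment_config()),
    "arg")
})

test_that("align_fragments round-trips true coordinates and flags failures", {
  rp <- sim_ref_pair()
  sf <- simulate_ancient_fragments(
    rp, "hom_absent", sim_fragment_config(target_coverage = 5, seed = 31))
  al <- align_fragments(sf$fragments, rp$ref_without, "ref_without")
  # a random 3 kb reference: every fragment is uniquely placeable
  expect_true(all(al$placed))
  expect_identical(al$start, sf$fragments$start)
  expect_identical(al$end, sf$fragments$end)
  expect_identical(al$strand, sf$fragments$strand)

  # a junction-crossing fragment has no exact match on ref_without
  ip_with <- rp$insertion_point  # insertion starts here in ref_with
  junc_frag <- substr(rp$ref_with, ip_with - 10, ip_with + 30)
  # a sequence occurring twice is ambiguous
  dup_ref <- paste0(rp$ref_without, rp$ref_without)
  dup_frag <- substr(rp$ref_without, 101, 140)
  al2 <- align_fragments(junc_frag, rp$ref_without)
  expect_false(al2$placed)
  expect_equal(al2$reason, "no_exact_match")
  al3 <- align_fragments(dup_frag, dup_ref)
  expect_false(al3$placed)
  expect_equal(al3$reason, "ambiguous")

  expect_error(align_fragments("ACGT", ""), "non-empty|nchar")
})
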