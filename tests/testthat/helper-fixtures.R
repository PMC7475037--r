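# Fixtures are built in code; heavyweight simulation sweeps are memoized so
# several test files can share one run.

.fixture_cache <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (is.null(.fixture_cache[[key]])) .fixture_cache[[key]] <- force(expr)
  .fixture_cache[[key]]
}

# panel from two-locus haplotype strings, e.g. c("AB","Ab","aB","ab"):
# uppercase = allele 1 at that locus
two_locus_panel <- function(haps, pop = "P1") {
  m <- t(vapply(strsplit(haps, ""), function(h) {
    as.integer(h %in% c("A", "B"))
  }, integer(2)))
  ids <- sprintf("h%02d", seq_along(haps))
  HaplotypePanel(
    sites = data.frame(position_bp = c(100L, 200L),
                       ref_allele = c("C", "C"), alt_allele = c("T", "T")),
    alleles = m, haplotype_ids = ids,
    pop_of_haplotype = setNames(rep(pop, length(haps)), ids)
  )
}

# panel from an explicit allele matrix
matrix_panel <- function(alleles, pops, positions = NULL) {
  alleles <- as.matrix(alleles)
  storage.mode(alleles) <- "integer"
  if (is.null(positions)) positions <- seq_len(ncol(alleles)) * 100L
  ids <- sprintf("h%02d", seq_len(nrow(alleles)))
  HaplotypePanel(
    sites = data.frame(position_bp = positions,
                       ref_allele = rep("C", ncol(alleles)),
                       alt_allele = rep("T", ncol(alleles))),
    alleles = alleles, haplotype_ids = ids,
    pop_of_haplotype = setNames(pops, ids)
  )
}

# independent brute-force LD oracle: explicit gamete enumeration over the
# four two-locus haplotype classes
ld_r2_oracle <- function(a, b) {
  n <- length(a)
  n_ab <- n_aB <- n_Ab <- n_AB <- 0L
  for (i in seq_len(n)) {
    if (a[i] == 1 && b[i] == 1) n_AB <- n_AB + 1L
    else if (a[i] == 1 && b[i] == 0) n_Ab <- n_Ab + 1L
    else if (a[i] == 0 && b[i] == 1) n_aB <- n_aB + 1L
    else n_ab <- n_ab + 1L
  }
  pA <- (n_AB + n_Ab) / n
  pB <- (n_AB + n_aB) / n
  d <- n_AB / n - pA * pB
  d^2 / (pA * (1 - pA) * pB * (1 - pB))
}

# shared reference pair for genotyping simulations
sim_ref_pair <- function() memo("ref_pair", random_reference_pair(seed = 42))

# one seeded simulate -> genotype run; returns evidence + alignment
sim_genotype_once <- function(genotype, seed, coverage = 30) {
  rp <- sim_ref_pair()
  sf <- simulate_ancient_fragments(
    rp, genotype, sim_fragment_config(target_coverage = coverage, seed = seed))
  ev <- genotype_insertion(sf$fragments, rp)
  list(evidence = ev, fragments = sf$fragments)
}

# memoized 100-seed-per-genotype sweep at 30x (the heavyweight fixture;
# shared by the genotyper property tests and the acceptance criteria)
genotype_sweep <- function(n_seeds = 100L) {
  memo(paste0("sweep", n_seeds), {
    out <- list()
    for (g in c("hom_present", "het", "hom_absent")) {
      res <- lapply(seq_len(n_seeds), function(s) {
        ev <- sim_genotype_once(g, seed = s)$evidence
        data.frame(true = g, call = ev$call, drop_ratio = ev$drop_ratio,
                   n_junction = ev$n_junction, n_spanning = ev$n_spanning,
                   stringsAsFactors = FALSE)
      })
      out[[g]] <- do.call(rbind, res)
    }
    out
  })
}

# memoized demo panel simulation
demo_sim <- function() memo("demo_sim", simulate_panel(sim_panel_config(seed = 7)))

# independent conservation oracle: sum of clipped fragment lengths
clipped_length_sum <- function(fragments, window) {
  if ("placed" %in% names(fragments)) {
    fragments <- fragments[fragments$placed %in% TRUE, , drop = FALSE]
  }
  sum(pmax(0, pmin(fragments$end, window[2]) - pmax(fragments$start, window[1])))
}
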