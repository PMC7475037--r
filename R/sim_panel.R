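## Synthetic phased panels with a planted introgressed archaic segment.
##
## The generator uses a copying model rather than a coalescent: a shared
## ancestral background with independently drawn site frequencies, plus an
## archaic segment with hard boundaries pasted onto designated carrier
## haplotypes.  The downstream analyses need LD structure between the
## planted segment and its tag sites, not genealogies.

#' Configuration for the panel simulator
#'
#' Defaults describe the study system the package emulates: a 1000
#' Genomes-style panel where an archaic (Neandertal-derived) segment of
#' 56.2 kb, tagged by 28 lineage-private SNPs, segregates at moderate
#' frequency in non-African populations and is absent from an African
#' outgroup.  Two archaic sub-haplotypes exist; a fraction of introgressed
#' haplotypes additionally carries a mobile-element (Alu) insertion flag
#' (256 of 345 carrier chromosomes, i.e. 0.742, in the emulated data).
#'
#' @param n_haplotypes_per_pop haplotypes simulated per population.
#' @param pop_labels population labels; must include `outgroup_pop`.
#' @param outgroup_pop label of the outgroup population (introgression
#'   frequency forced to 0, used to define lineage-private sites).
#' @param n_sites total number of segregating sites; `NULL` derives it from
#'   `mutation_density`.
#' @param region_length_bp simulated region length.
#' @param introgressed_freq_per_pop named numeric vector, per-population
#'   probability that a haplotype carries the archaic segment; the outgroup
#'   entry must be 0.
#' @param n_private_archaic_snps number of archaic-lineage private SNPs
#'   planted inside the segment.
#' @param segment_bounds_bp half-open interval `c(start, end)` of the
#'   archaic segment within the region.
#' @param alu_subhaplotype_fraction fraction of introgressed haplotypes that
#'   carry the insertion flag (the insertion-bearing archaic sub-haplotype).
#' @param mutation_density expected segregating sites per kb (used when
#'   `n_sites` is `NULL`).
#' @param seed integer seed; all randomness derives from it.
#' @return a validated list of class `SimPanelConfig`.
#' @export
sim_panel_config <- function(n_haplotypes_per_pop = 100L,
                             pop_labels = c("AFR-out", "EUR-like", "EAS-like"),
                             outgroup_pop = "AFR-out",
                             n_sites = NULL,
                             region_length_bp = 150000L,
                             introgressed_freq_per_pop = c(
                               "AFR-out" = 0, "EUR-like" = 0.17,
                               "EAS-like" = 0.10),
                             n_private_archaic_snps = 28L,
                             segment_bounds_bp = c(45000L, 101200L),
                             alu_subhaplotype_fraction = 256 / 345,
                             mutation_density = 1.0,
                             seed = 1L) {
  if (length(pop_labels) < 1L) stop("empty population list", call. = FALSE)
  if (!outgroup_pop %in% pop_labels) {
    stop("'outgroup_pop' must be one of 'pop_labels'", call. = FALSE)
  }
  if (!all(pop_labels %in% names(introgressed_freq_per_pop))) {
    stop("introgressed_freq_per_pop must name every population",
         call. = FALSE)
  }
  for (p in pop_labels) {
    stopifnot_scalar_prob(introgressed_freq_per_pop[[p]],
                          paste0("introgressed_freq_per_pop[", p, "]"))
  }
  if (introgressed_freq_per_pop[[outgroup_pop]] != 0) {
    stop("outgroup introgressed frequency must be 0", call. = FALSE)
  }
  stopifnot_positive(n_haplotypes_per_pop, "n_haplotypes_per_pop")
  stopifnot_positive(region_length_bp, "region_length_bp")
  stopifnot_positive(mutation_density, "mutation_density")
  stopifnot_scalar_prob(alu_subhaplotype_fraction, "alu_subhaplotype_fraction")
  if (n_private_archaic_snps < 0) {
    stop("'n_private_archaic_snps' must be non-negative", call. = FALSE)
  }
  if (length(segment_bounds_bp) != 2L ||
      segment_bounds_bp[1] < 0 || segment_bounds_bp[2] > region_length_bp ||
      segment_bounds_bp[1] >= segment_bounds_bp[2]) {
    stop("segment_bounds_bp must be a half-open interval inside the region",
         call. = FALSE)
  }
  if (is.null(n_sites)) {
    n_sites <- max(n_private_archaic_snps,
                   round(mutation_density * region_length_bp / 1000))
  }
  if (n_sites < n_private_archaic_snps) {
    stop("n_sites must be >= n_private_archaic_snps", call. = FALSE)
  }
  structure(
    list(
      n_haplotypes_per_pop = as.integer(n_haplotypes_per_pop),
      pop_labels = pop_labels,
      outgroup_pop = outgroup_pop,
      n_sites = as.integer(n_sites),
      region_length_bp = as.integer(region_length_bp),
      introgressed_freq_per_pop = introgressed_freq_per_pop,
      n_private_archaic_snps = as.integer(n_private_archaic_snps),
      segment_bounds_bp = as.integer(segment_bounds_bp),
      alu_subhaplotype_fraction = alu_subhaplotype_fraction,
      mutation_density = mutation_density,
      seed = as.integer(seed)
    ),
    class = "SimPanelConfig"
  )
}

#' Simulate a phased panel with a planted introgressed segment
#'
#' Generates (i) a phased biallelic [HaplotypePanel] across labelled
#' populations in which a contiguous archaic segment, tagged by
#' lineage-private SNPs, is carried by a per-population random subset of
#' haplotypes (never by the outgroup); (ii) diploid genotypes for three
#' archaic individuals that are mosaics of the two archaic sub-haplotypes
#' (one carrying the mobile-element insertion flag, one not), with insertion
#' genotypes homozygous-present, heterozygous and homozygous-absent; and
#' (iii) a `GroundTruth` record of every planted feature.
#'
#' Sites inside `segment_bounds_bp` are exactly the private archaic SNPs:
#' the alternate allele is carried by every introgressed haplotype and by
#' no other modern haplotype, and by all archaic chromosomes.  Background
#' sites (outside the segment) are either cosmopolitan (i.i.d. alleles at a
#' shared frequency, also genotyped in the archaics) or private to one
#' modern population (absent from the archaics).
#'
#' @param config a [sim_panel_config()] object.
#' @return list with elements `panel` ([HaplotypePanel]), `archaic`
#'   ([ArchaicGenotypes]) and `truth` (class `GroundTruth`: segment bounds,
#'   carrier haplotype ids, insertion-carrier ids, archaic insertion
#'   genotypes, private site indices, focal site index, seed).
#' @examples
#' sim <- simulate_panel(sim_panel_config(seed = 7))
#' sim$panel
#' length(sim$truth$private_site_indices)
#' @export
simulate_panel <- function(config) {
  stopifnot(inherits(config, "SimPanelConfig"))
  with_seed(config$seed, simulate_panel_impl(config))
}

simulate_panel_impl <- function(config) {
  pops <- config$pop_labels
  nh_pop <- config$n_haplotypes_per_pop
  nh <- nh_pop * length(pops)
  ns <- config$n_sites
  npriv <- config$n_private_archaic_snps
  seg <- config$segment_bounds_bp

  hap_ids <- unlist(lapply(pops, function(p) {
    sprintf("%s_h%03d", p, seq_len(nh_pop))
  }))
  pop_of <- setNames(rep(pops, each = nh_pop), hap_ids)

  ## positions: private sites inside the segment, background outside.
  ## The outermost private sites sit exactly at the segment bounds — the
  ## emulated haplotype's coordinates are themselves defined by the span of
  ## its private SNPs — so segment recovery from LD is exact up to the
  ## half-open right bound.
  priv_pos <- if (npriv == 0L) integer(0) else if (npriv == 1L) seg[1] else {
    sort(c(seg[1], seg[2] - 1L,
           sample(seq.int(seg[1] + 1L, seg[2] - 2L), npriv - 2L)))
  }
  n_bg <- ns - npriv
  bg_candidates <- c(seq_len(seg[1]) - 1L,
                     seq.int(seg[2], config$region_length_bp - 1L))
  bg_pos <- sort(sample(bg_candidates, n_bg))
  positions <- sort(c(priv_pos, bg_pos))
  private_idx <- which(positions %in% priv_pos)
  bg_idx <- setdiff(seq_len(ns), private_idx)

  base_pairs <- matrix(c("A", "G", "C", "T", "G", "A", "T", "C"),
                       ncol = 2, byrow = TRUE)
  pick <- sample(nrow(base_pairs), ns, replace = TRUE)
  sites <- data.frame(
    position_bp = positions,
    ref_allele = base_pairs[pick, 1],
    alt_allele = base_pairs[pick, 2],
    stringsAsFactors = FALSE
  )

  ## carrier status per haplotype (Bernoulli per haplotype within pop)
  carrier <- vapply(hap_ids, function(h) {
    f <- config$introgressed_freq_per_pop[[pop_of[[h]]]]
    rbinom(1L, 1L, f) == 1L
  }, logical(1))
  carriers <- hap_ids[carrier]
  alu_carrier <- carriers[
    rbinom(length(carriers), 1L, config$alu_subhaplotype_fraction) == 1L]

  alleles <- matrix(0L, nrow = nh, ncol = ns,
                    dimnames = list(hap_ids, NULL))
  ## private archaic sites: alternate allele = archaic allele, carried by
  ## exactly the introgressed haplotypes (hard segment bounds, no erosion)
  alleles[carrier, private_idx] <- 1L

  ## background sites: cosmopolitan (70%) or private to one modern pop
  arch_freq <- rep(NA_real_, ns)  # NA = allele absent from archaic lineage
  for (j in bg_idx) {
    if (runif(1) < 0.7) {
      p <- runif(1, 0.05, 0.95)
      alleles[, j] <- rbinom(nh, 1L, p)
      arch_freq[j] <- p
    } else {
      pop <- sample(pops, 1L)
      p <- runif(1, 0.01, 0.30)
      in_pop <- pop_of[hap_ids] == pop
      alleles[in_pop, j] <- rbinom(sum(in_pop), 1L, p)
    }
  }

  ## three archaic individuals: mosaics of sub-haplotype A (insertion) and
  ## B (no insertion); both sub-haplotypes carry the full archaic segment
  arch_ids <- c("archaicA", "archaicB", "archaicC")
  ins_geno <- setNames(c("hom_present", "het", "hom_absent"), arch_ids)
  geno <- matrix(NA_real_, nrow = 3L, ncol = ns,
                 dimnames = list(arch_ids, NULL))
  geno[, private_idx] <- 2
  for (j in bg_idx) {
    if (is.na(arch_freq[j])) {
      geno[, j] <- 0           # modern-private allele: absent in archaics
    } else {
      geno[, j] <- rbinom(3L, 2L, arch_freq[j])
    }
  }
  ## light missingness on background sites only (ancient-DNA reality);
  ## private sites stay fully observed so planted truth is recoverable
  miss <- matrix(runif(3L * ns) < 0.01, nrow = 3L)
  miss[, private_idx] <- FALSE
  geno[miss] <- NA_real_

  panel <- HaplotypePanel(sites, alleles, hap_ids, pop_of)
  archaic <- ArchaicGenotypes(arch_ids, geno)

  ## focal tag site: the private SNP nearest the segment midpoint
  mid <- mean(seg)
  focal <- private_idx[which.min(abs(positions[private_idx] - mid))]

  truth <- structure(
    list(
      segment_bounds_bp = seg,
      introgressed_haplotype_ids = carriers,
      alu_carrier_haplotype_ids = alu_carrier,
      archaic_insertion_genotypes = ins_geno,
      private_site_indices = private_idx,
      focal_site_index = focal,
      seed = config$seed
    ),
    class = "GroundTruth"
  )
  list(panel = panel, archaic = archaic, truth = truth)
}

#' 0/1 insertion-carriage pseudo-marker over panel haplotypes
#'
#' Encodes carriage of the mobile-element insertion as a biallelic
#' pseudo-SNP column, for LD analyses that treat the insertion as a marker.
#'
#' @param panel a [HaplotypePanel].
#' @param carrier_ids haplotype ids carrying the insertion.
#' @return integer 0/1 vector over `panel$haplotype_ids`.
#' @export
insertion_pseudo_marker <- function(panel, carrier_ids) {
  as.integer(panel$haplotype_ids %in% carrier_ids)
}
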