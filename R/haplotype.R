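## Characterization of introgressed haplotypes in phased panels:
## per-population allele frequencies, pairwise LD (r-squared), lineage
## private SNPs, the r-squared-defined segment extent around a focal site,
## and the archaic-match matrix comparing carrier/non-carrier chromosomes
## with archaic genomes.

#' Per-population alternate-allele frequency at a site
#'
#' @param panel a [HaplotypePanel].
#' @param site site index, or a 0/1 pseudo-marker vector (see
#'   [site_column()]).
#' @return named numeric vector: one frequency per population plus
#'   `"overall"`.
#' @export
allele_frequency <- function(panel, site) {
  col <- site_column(panel, site)
  pops <- panel$pop_of_haplotype
  if (any(table(pops) == 0L)) stop("empty population", call. = FALSE)
  by_pop <- tapply(col, pops, mean)
  c(by_pop, overall = mean(col))
}

#' Linkage disequilibrium r-squared between two markers
#'
#' Gamete (two-locus haplotype) counts are taken directly from the phased
#' panel; `D = p_AB - p_A p_B` and `r2 = D^2 / (p_A q_A p_B q_B)`.  Either
#' marker may be a panel site index or a 0/1 pseudo-marker vector, so the
#' presence/absence of a structural variant (e.g. an Alu insertion) can be
#' treated as a biallelic marker.
#'
#' @param panel a [HaplotypePanel].
#' @param site_a,site_b site indices or 0/1 pseudo-marker vectors.
#' @param haplotype_subset optional haplotype ids (or logical/integer index
#'   over haplotypes) restricting the computation.
#' @return object of class `LDResult`: `r2`, `d`, and `haplotype_counts`
#'   (2x2 gamete count table).
#' @examples
#' \dontrun{ld_r2(panel, 3, 7)$r2}
#' @export
ld_r2 <- function(panel, site_a, site_b, haplotype_subset = NULL) {
  a <- site_column(panel, site_a)
  b <- site_column(panel, site_b)
  if (!is.null(haplotype_subset)) {
    idx <- if (is.character(haplotype_subset)) {
      match(haplotype_subset, panel$haplotype_ids)
    } else haplotype_subset
    a <- a[idx]
    b <- b[idx]
  }
  keep <- !is.na(a) & !is.na(b)
  a <- a[keep]
  b <- b[keep]
  pa <- mean(a)
  pb <- mean(b)
  if (pa %in% c(0, 1) || pb %in% c(0, 1)) {
    stop("LD undefined: monomorphic marker in the chosen haplotype subset",
         call. = FALSE)
  }
  pab <- mean(a == 1L & b == 1L)
  d <- pab - pa * pb
  counts <- table(factor(a, levels = c(1, 0)), factor(b, levels = c(1, 0)),
                  dnn = c("site_a", "site_b"))
  structure(
    list(r2 = d^2 / (pa * (1 - pa) * pb * (1 - pb)), d = d,
         haplotype_counts = counts),
    class = "LDResult"
  )
}

#' @export
print.LDResult <- function(x, ...) {
  cat(sprintf("LDResult: r2 = %.4f (D = %.4f)\n", x$r2, x$d))
  print(x$haplotype_counts)
  invisible(x)
}

#' Sites private to the archaic lineage
#'
#' A site is private when an allele carried by the archaic individuals
#' (summed dosage at least `min_archaic_dosage_total`, missing genotypes
#' ignored) has frequency exactly 0 among the outgroup haplotypes.  Both the
#' alternate and the reference allele are tested; all-missing archaic sites
#' are excluded.
#'
#' @param panel a [HaplotypePanel].
#' @param outgroup_pop outgroup population label (e.g. the Yoruba-like
#'   panel).
#' @param archaic an [ArchaicGenotypes].
#' @param min_archaic_dosage_total minimum summed archaic dosage for an
#'   allele to count as archaic-carried (default 1).
#' @return integer vector of site indices, with attribute
#'   `private_allele` ("alt" or "ref" per returned site).
#' @export
private_archaic_sites <- function(panel, outgroup_pop, archaic,
                                  min_archaic_dosage_total = 1L) {
  stopifnot(inherits(archaic, "ArchaicGenotypes"))
  if (!outgroup_pop %in% panel$pop_of_haplotype) {
    stop("outgroup population not present in panel", call. = FALSE)
  }
  if (ncol(archaic$genotypes) != n_sites(panel)) {
    stop("archaic genotypes and panel must share sites", call. = FALSE)
  }
  out_rows <- panel$pop_of_haplotype == outgroup_pop
  out_alt_freq <- colMeans(panel$alleles[out_rows, , drop = FALSE])
  g <- archaic$genotypes
  n_obs <- colSums(!is.na(g))
  alt_dose <- colSums(g, na.rm = TRUE)
  ref_dose <- 2 * n_obs - alt_dose
  alt_private <- n_obs > 0 & alt_dose >= min_archaic_dosage_total &
    out_alt_freq == 0
  ref_private <- n_obs > 0 & ref_dose >= min_archaic_dosage_total &
    out_alt_freq == 1
  idx <- which(alt_private | ref_private)
  structure(idx,
            private_allele = ifelse(alt_private[idx], "alt", "ref"))
}

#' r-squared-defined introgressed segment around a focal site
#'
#' Starting from a focal polymorphic site, extends left and right over
#' consecutive polymorphic panel sites while `r2(site, focal)` exceeds
#' `r2_threshold`; a site failing the threshold terminates extension in that
#' direction (monomorphic sites carry no LD information and are skipped,
#' not counted as failures).  The segment is reported both as a member-site
#' run and as a bp span between the outermost members.
#'
#' @param panel a [HaplotypePanel].
#' @param focal_site focal site index (must be polymorphic).
#' @param r2_threshold LD threshold (default 0.8).
#' @param private_sites optional site indices of lineage-private SNPs; used
#'   to report how many fall inside the segment.
#' @return object of class `IntrogressionSegment`: `focal_site`,
#'   `member_sites`, `start_bp`, `end_bp`, `length_bp`, `n_private`.
#' @export
introgression_segment <- function(panel, focal_site, r2_threshold = 0.8,
                                  private_sites = NULL) {
  col_f <- site_column(panel, focal_site)
  pf <- mean(col_f)
  if (pf %in% c(0, 1)) {
    stop("focal site is monomorphic", call. = FALSE)
  }
  poly <- unname(which(apply(panel$alleles, 2L, function(x) {
    m <- mean(x)
    m > 0 && m < 1
  })))
  focal_site <- unname(focal_site)
  fpos <- match(focal_site, poly)
  r2_with_focal <- function(j) ld_r2(panel, j, focal_site)$r2
  members <- focal_site
  i <- fpos - 1L
  while (i >= 1L && r2_with_focal(poly[i]) > r2_threshold) {
    members <- c(poly[i], members)
    i <- i - 1L
  }
  i <- fpos + 1L
  while (i <= length(poly) && r2_with_focal(poly[i]) > r2_threshold) {
    members <- c(members, poly[i])
    i <- i + 1L
  }
  pos <- panel$sites$position_bp[members]
  n_private <- if (is.null(private_sites)) NA_integer_ else {
    sum(private_sites %in% members)
  }
  structure(
    list(focal_site = focal_site, member_sites = members,
         start_bp = min(pos), end_bp = max(pos),
         length_bp = max(pos) - min(pos), n_private = n_private),
    class = "IntrogressionSegment"
  )
}

#' @export
print.IntrogressionSegment <- function(x, ...) {
  cat(sprintf(
    "IntrogressionSegment: %d sites, %d-%d bp (%.1f kb)%s\n",
    length(x$member_sites), x$start_bp, x$end_bp, x$length_bp / 1000,
    if (is.na(x$n_private)) "" else sprintf(", %d private SNPs", x$n_private)
  ))
  invisible(x)
}

#' Archaic-match matrix for carrier and non-carrier chromosomes
#'
#' Selects sites where an allele that is minor (frequency < 0.5) or absent
#' among outgroup haplotypes is carried by the archaic individuals with
#' summed dosage at least `min_archaic_count`; then, for each of two
#' haplotype subsets (typically introgressed chromosomes with and without
#' the mobile-element insertion), reports whether the subset's major allele
#' matches the archaic allele.  An exact 0.5 frequency in a subset is
#' reported as `"tie"`, not a match.
#'
#' @param panel a [HaplotypePanel].
#' @param carrier_subset,noncarrier_subset haplotype ids of the two subsets
#'   (non-empty).
#' @param outgroup_pop outgroup population label.
#' @param archaic an [ArchaicGenotypes].
#' @param min_archaic_count minimum summed archaic dosage (default 3).
#' @return data.frame (long format, one row per selected site): site index,
#'   position, archaic allele, archaic dosage, outgroup frequency of that
#'   allele, and `carrier_match` / `noncarrier_match` in
#'   `{"match", "mismatch", "tie"}`.
#' @export
archaic_match_matrix <- function(panel, carrier_subset, noncarrier_subset,
                                 outgroup_pop, archaic,
                                 min_archaic_count = 3L) {
  stopifnot(inherits(archaic, "ArchaicGenotypes"))
  if (length(carrier_subset) == 0L || length(noncarrier_subset) == 0L) {
    stop("haplotype subsets must be non-empty", call. = FALSE)
  }
  out_rows <- panel$pop_of_haplotype == outgroup_pop
  if (!any(out_rows)) stop("outgroup population not present", call. = FALSE)
  out_alt <- colMeans(panel$alleles[out_rows, , drop = FALSE])
  g <- archaic$genotypes
  n_obs <- colSums(!is.na(g))
  alt_dose <- colSums(g, na.rm = TRUE)
  ref_dose <- 2 * n_obs - alt_dose

  ## candidate archaic allele per site: the allele that is minor or absent
  ## in the outgroup and sufficiently often seen in the archaics
  alt_ok <- out_alt < 0.5 & alt_dose >= min_archaic_count
  ref_ok <- (1 - out_alt) < 0.5 & ref_dose >= min_archaic_count
  sel <- which(alt_ok | ref_ok)
  if (length(sel) == 0L) {
    return(data.frame(site_index = integer(0), position_bp = integer(0),
                      archaic_allele = character(0),
                      archaic_dosage = numeric(0),
                      outgroup_freq = numeric(0),
                      carrier_match = character(0),
                      noncarrier_match = character(0)))
  }
  archaic_is_alt <- alt_ok[sel]
  subset_status <- function(ids) {
    rows <- panel$haplotype_ids %in% ids
    f_alt <- colMeans(panel$alleles[rows, sel, drop = FALSE])
    f_arch <- ifelse(archaic_is_alt, f_alt, 1 - f_alt)
    ifelse(f_arch == 0.5, "tie",
           ifelse(f_arch > 0.5, "match", "mismatch"))
  }
  data.frame(
    site_index = sel,
    position_bp = panel$sites$position_bp[sel],
    archaic_allele = ifelse(archaic_is_alt, "alt", "ref"),
    archaic_dosage = ifelse(archaic_is_alt, alt_dose[sel], ref_dose[sel]),
    outgroup_freq = ifelse(archaic_is_alt, out_alt[sel], 1 - out_alt[sel]),
    carrier_match = subset_status(carrier_subset),
    noncarrier_match = subset_status(noncarrier_subset),
    stringsAsFactors = FALSE
  )
}
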