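## Containers for phased haplotype panels and archaic diploid genotypes.
## These are deliberately lightweight S3 objects (a matrix plus site and
## sample annotation), in the spirit of scikit-allel / plink-style tables.

#' Construct a phased haplotype panel
#'
#' A `HaplotypePanel` holds a phased biallelic allele matrix (haplotypes in
#' rows, sites in columns, entries 0 = reference allele, 1 = alternate
#' allele), site coordinates/alleles, and a population label per haplotype.
#'
#' @param sites data.frame with columns `position_bp` (strictly increasing
#'   integer coordinates), `ref_allele`, `alt_allele` (single bases).
#' @param alleles integer matrix of 0/1, `length(haplotype_ids)` rows and
#'   `nrow(sites)` columns.
#' @param haplotype_ids character vector of unique haplotype identifiers.
#' @param pop_of_haplotype named character vector mapping haplotype id to
#'   population label.
#' @return an object of class `HaplotypePanel`.
#' @export
HaplotypePanel <- function(sites, alleles, haplotype_ids, pop_of_haplotype) {
  stopifnot(
    is.data.frame(sites),
    all(c("position_bp", "ref_allele", "alt_allele") %in% names(sites)),
    is.matrix(alleles)
  )
  if (nrow(sites) > 1L && any(diff(sites$position_bp) <= 0)) {
    stop("site positions must be strictly increasing", call. = FALSE)
  }
  if (!all(alleles %in% c(0L, 1L))) {
    stop("allele matrix must contain only 0 and 1 (biallelic, phased)",
         call. = FALSE)
  }
  if (nrow(alleles) != length(haplotype_ids) ||
      ncol(alleles) != nrow(sites)) {
    stop("allele matrix dimensions inconsistent with sites/haplotype_ids",
         call. = FALSE)
  }
  if (anyDuplicated(haplotype_ids)) {
    stop("haplotype ids must be unique", call. = FALSE)
  }
  if (!all(haplotype_ids %in% names(pop_of_haplotype))) {
    stop("every haplotype must have a population label", call. = FALSE)
  }
  rownames(alleles) <- haplotype_ids
  structure(
    list(
      sites = sites,
      alleles = alleles,
      haplotype_ids = haplotype_ids,
      pop_of_haplotype = pop_of_haplotype[haplotype_ids]
    ),
    class = "HaplotypePanel"
  )
}

#' @export
print.HaplotypePanel <- function(x, ...) {
  pops <- table(x$pop_of_haplotype)
  cat(sprintf(
    "HaplotypePanel: %d haplotypes x %d sites, span %d-%d bp\n",
    length(x$haplotype_ids), nrow(x$sites),
    min(x$sites$position_bp), max(x$sites$position_bp)
  ))
  cat("populations:",
      paste(sprintf("%s (%d)", names(pops), pops), collapse = ", "), "\n")
  invisible(x)
}

#' Number of haplotypes / sites in a panel
#' @param panel a [HaplotypePanel].
#' @return integer count.
#' @export
n_haplotypes <- function(panel) length(panel$haplotype_ids)

#' @rdname n_haplotypes
#' @export
n_sites <- function(panel) nrow(panel$sites)

#' Construct archaic diploid genotypes at panel sites
#'
#' Alternate-allele dosages (0/1/2, `NA` for missing) for a small set of
#' archaic individuals at the same sites as a companion [HaplotypePanel].
#'
#' @param individuals character vector of individual ids.
#' @param genotypes numeric matrix, individuals in rows, sites in columns,
#'   entries in `{0, 1, 2, NA}`.
#' @return an object of class `ArchaicGenotypes`.
#' @export
ArchaicGenotypes <- function(individuals, genotypes) {
  stopifnot(is.matrix(genotypes), nrow(genotypes) == length(individuals))
  ok <- is.na(genotypes) | genotypes %in% c(0, 1, 2)
  if (!all(ok)) stop("dosages must be 0, 1, 2 or NA", call. = FALSE)
  rownames(genotypes) <- individuals
  structure(list(individuals = individuals, genotypes = genotypes),
            class = "ArchaicGenotypes")
}

#' @export
print.ArchaicGenotypes <- function(x, ...) {
  cat(sprintf("ArchaicGenotypes: %d individuals x %d sites (%s)\n",
              length(x$individuals), ncol(x$genotypes),
              paste(x$individuals, collapse = ", ")))
  invisible(x)
}

#' Extract the haplotype allele column for a site or pseudo-marker
#'
#' Several analyses (notably LD against the Alu insertion treated as a
#' presence/absence marker) accept either a site index into the panel or a
#' full 0/1 vector over haplotypes.  This helper normalizes both.
#'
#' @param panel a [HaplotypePanel].
#' @param site a single site index, or a 0/1 vector of length
#'   `n_haplotypes(panel)` (a pseudo-marker such as insertion carriage).
#' @return integer vector of 0/1 over haplotypes.
#' @keywords internal
#' @export
site_column <- function(panel, site) {
  nh <- n_haplotypes(panel)
  if (length(site) == 1L && is.numeric(site)) {
    if (site < 1 || site > n_sites(panel)) {
      stop("site index out of range", call. = FALSE)
    }
    return(as.integer(panel$alleles[, site]))
  }
  if (length(site) == nh && all(site %in% c(0L, 1L))) {
    return(as.integer(site))
  }
  stop("'site' must be a site index or a 0/1 vector over haplotypes",
       call. = FALSE)
}
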