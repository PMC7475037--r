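## Readers and writers for the plain-text interchange formats the pipeline
## uses: FASTA references/fragments, a minimal phased VCF for panels, TSV
## tables (placements, population map, archaic dosages, associations), and
## JSON (ground truth, run reports).

#' Write / read sequences as FASTA
#'
#' @param sequences named character vector of DNA sequences.
#' @param path file path.
#' @return `read_fasta` returns a named character vector.
#' @export
write_fasta <- function(sequences, path) {
  x <- Biostrings::DNAStringSet(sequences)
  names(x) <- names(sequences)
  Biostrings::writeXStringSet(x, filepath = path)
  invisible(path)
}

#' @rdname write_fasta
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  setNames(as.character(x), names(x))
}

#' Write / read a fragment set (FASTA + placement TSV)
#'
#' Sequences go to `<prefix>.fasta` (true coordinates in the description
#' line) and placements to `<prefix>.placements.tsv` with columns
#' fragment_id, ref_name, start, end, strand (0-based half-open).
#'
#' @param fragments fragment data.frame (see
#'   [simulate_ancient_fragments()]).
#' @param prefix output path prefix.
#' @return `read_fragments` returns the fragment data.frame.
#' @export
write_fragments <- function(fragments, prefix) {
  fa <- setNames(
    fragments$sequence,
    sprintf("%s %s:%d-%d(%s)", fragments$fragment_id, fragments$ref_name,
            fragments$start, fragments$end, fragments$strand)
  )
  write_fasta(fa, paste0(prefix, ".fasta"))
  write.table(
    fragments[, c("fragment_id", "ref_name", "start", "end", "strand")],
    paste0(prefix, ".placements.tsv"),
    sep = "\t", quote = FALSE, row.names = FALSE
  )
  invisible(prefix)
}

#' @rdname write_fragments
#' @export
read_fragments <- function(prefix) {
  fa <- read_fasta(paste0(prefix, ".fasta"))
  tab <- read.delim(paste0(prefix, ".placements.tsv"),
                    stringsAsFactors = FALSE)
  tab$sequence <- unname(fa[match(tab$fragment_id,
                                  sub(" .*", "", names(fa)))])
  tab
}

#' Write a haplotype panel as a minimal phased VCF plus population map
#'
#' One diploid VCF sample is emitted per haplotype pair (consecutive
#' haplotypes are paired; GT phased with `|`), which keeps the file a valid
#' standard VCF while preserving haplotype order.  The population map TSV
#' (haplotype_id, sample, population) records the haplotype-level labels.
#'
#' @param panel a [HaplotypePanel].
#' @param prefix output path prefix (`<prefix>.vcf`, `<prefix>.pops.tsv`).
#' @param chrom contig name written in the VCF.
#' @return invisibly, the prefix.
#' @export
write_panel_vcf <- function(panel, prefix, chrom = "sim1") {
  nh <- n_haplotypes(panel)
  if (nh %% 2L != 0L) {
    stop("need an even number of haplotypes to emit diploid VCF samples",
         call. = FALSE)
  }
  ids <- panel$haplotype_ids
  sample_names <- sprintf("S%04d", seq_len(nh / 2L))
  gt <- matrix("", nrow = n_sites(panel), ncol = nh / 2L)
  for (s in seq_len(nh / 2L)) {
    h1 <- panel$alleles[2L * s - 1L, ]
    h2 <- panel$alleles[2L * s, ]
    gt[, s] <- paste(h1, h2, sep = "|")
  }
  header <- c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    sprintf("##contig=<ID=%s>", chrom),
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", sample_names), collapse = "\t")
  )
  body <- paste(
    chrom, panel$sites$position_bp + 1L,  # VCF is 1-based
    sprintf("site%04d", seq_len(n_sites(panel))),
    panel$sites$ref_allele, panel$sites$alt_allele,
    ".", "PASS", ".", "GT",
    apply(gt, 1L, paste, collapse = "\t"),
    sep = "\t"
  )
  writeLines(c(header, body), paste0(prefix, ".vcf"))
  pops <- data.frame(
    haplotype_id = ids,
    sample = rep(sample_names, each = 2L),
    population = unname(panel$pop_of_haplotype),
    stringsAsFactors = FALSE
  )
  write.table(pops, paste0(prefix, ".pops.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(prefix)
}

#' Read a phased panel from VCF plus population map
#'
#' Uses \pkg{VariantAnnotation} to parse the VCF; haplotypes are the two
#' phased alleles of each sample in file order, labelled per the population
#' map written by [write_panel_vcf()].
#'
#' @param prefix path prefix used by [write_panel_vcf()].
#' @return a [HaplotypePanel].
#' @export
read_panel_vcf <- function(prefix) {
  if (!requireNamespace("VariantAnnotation", quietly = TRUE)) {
    stop("read_panel_vcf() requires the VariantAnnotation package",
         call. = FALSE)
  }
  vcf <- VariantAnnotation::readVcf(paste0(prefix, ".vcf"))
  gt <- VariantAnnotation::geno(vcf)$GT
  rr <- SummarizedExperiment::rowRanges(vcf)
  sites <- data.frame(
    position_bp = BiocGenerics::start(rr) - 1L,
    ref_allele = as.character(rr$REF),
    alt_allele = vapply(rr$ALT, function(a) as.character(a)[1],
                        character(1)),
    stringsAsFactors = FALSE
  )
  pops <- read.delim(paste0(prefix, ".pops.tsv"), stringsAsFactors = FALSE)
  split_gt <- strsplit(as.vector(gt), "|", fixed = TRUE)
  h1 <- matrix(as.integer(vapply(split_gt, `[`, character(1), 1L)),
               nrow = nrow(gt))
  h2 <- matrix(as.integer(vapply(split_gt, `[`, character(1), 2L)),
               nrow = nrow(gt))
  nh <- 2L * ncol(gt)
  alleles <- matrix(0L, nrow = nh, ncol = nrow(gt))
  alleles[seq(1L, nh, by = 2L), ] <- t(h1)
  alleles[seq(2L, nh, by = 2L), ] <- t(h2)
  HaplotypePanel(sites, alleles, pops$haplotype_id,
                 setNames(pops$population, pops$haplotype_id))
}

#' Write / read archaic dosages as TSV
#'
#' Long-format TSV: individual, site index, position, dosage (NA for
#' missing).
#'
#' @param archaic an [ArchaicGenotypes].
#' @param panel the companion [HaplotypePanel] (for positions).
#' @param path file path.
#' @return `read_archaic_tsv` returns an [ArchaicGenotypes].
#' @export
write_archaic_tsv <- function(archaic, panel, path) {
  g <- archaic$genotypes
  tab <- data.frame(
    individual = rep(archaic$individuals, times = ncol(g)),
    site_index = rep(seq_len(ncol(g)), each = nrow(g)),
    position_bp = rep(panel$sites$position_bp, each = nrow(g)),
    dosage = as.vector(g),
    stringsAsFactors = FALSE
  )
  write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_archaic_tsv
#' @export
read_archaic_tsv <- function(path) {
  tab <- read.delim(path, stringsAsFactors = FALSE)
  inds <- unique(tab$individual)
  ns <- max(tab$site_index)
  g <- matrix(NA_real_, nrow = length(inds), ncol = ns,
              dimnames = list(inds, NULL))
  g[cbind(match(tab$individual, inds), tab$site_index)] <- tab$dosage
  ArchaicGenotypes(inds, g)
}

#' Write / read planted ground truth as JSON
#'
#' @param truth a `GroundTruth` object.
#' @param path file path.
#' @return `read_ground_truth` returns the `GroundTruth` list.
#' @export
write_ground_truth <- function(truth, path) {
  jsonlite::write_json(unclass(truth), path, auto_unbox = TRUE,
                       digits = NA, null = "null", pretty = TRUE)
  invisible(path)
}

#' @rdname write_ground_truth
#' @export
read_ground_truth <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(x, class = "GroundTruth")
}

#' Read / write an association summary table (TSV)
#'
#' Columns: phenotype_id, group, a, b, c, d (optional 2x2 counts), or,
#' p, and after processing p_adjusted, ci_low, ci_high.
#'
#' @param table data.frame.
#' @param path file path.
#' @return `read_assoc_table` returns a data.frame.
#' @export
write_assoc_table <- function(table, path) {
  write.table(table, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_assoc_table
#' @export
read_assoc_table <- function(path) {
  read.delim(path, stringsAsFactors = FALSE)
}
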