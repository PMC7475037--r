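## Ancient-DNA shotgun fragment simulation around a mobile-element
## insertion, plus an exact-match "aligner" for the synthetic references.

#' Construct a with/without-insertion reference pair
#'
#' `ref_with` is `ref_without` with the mobile element (and an optional
#' target-site-duplication copy of the bases immediately 5' of the
#' insertion point) inserted between positions `insertion_point - 1` and
#' `insertion_point` (0-based).
#'
#' @param ref_without reference sequence lacking the insertion.
#' @param insertion_seq the inserted element (e.g. an Alu, ~300 bp); must be
#'   longer than 22 bp so junction 22-mers lie within it.
#' @param insertion_point 0-based index into `ref_without` of the first base
#'   after the insertion site.
#' @param tsd_length target-site duplication length (default 0; the
#'   emulated locus is analysed without one).
#' @return an object of class `ReferencePair`.
#' @export
reference_pair <- function(ref_without, insertion_seq, insertion_point,
                           tsd_length = 0L) {
  stopifnot(is.character(ref_without), length(ref_without) == 1L,
            is.character(insertion_seq), length(insertion_seq) == 1L)
  n <- nchar(ref_without)
  if (nchar(insertion_seq) <= 22L) {
    stop("insertion_seq must be longer than 22 bp", call. = FALSE)
  }
  if (insertion_point < tsd_length || insertion_point > n) {
    stop("insertion_point out of range", call. = FALSE)
  }
  left <- substr(ref_without, 1L, insertion_point)
  right <- substr(ref_without, insertion_point + 1L, n)
  tsd <- if (tsd_length > 0L) {
    substr(ref_without, insertion_point - tsd_length + 1L, insertion_point)
  } else ""
  structure(
    list(
      ref_without = ref_without,
      ref_with = paste0(left, tsd, insertion_seq, right),
      insertion_point = as.integer(insertion_point),
      insertion_seq = insertion_seq,
      tsd_length = as.integer(tsd_length)
    ),
    class = "ReferencePair"
  )
}

#' Random reference pair for simulation studies
#'
#' @param region_length_bp length of the insertion-free reference.
#' @param insertion_point 0-based insertion site (default: region midpoint).
#' @param insertion_length_bp mobile-element length (default 300, Alu-like).
#' @param tsd_length target-site duplication length.
#' @param seed integer seed.
#' @return a [reference_pair()].
#' @export
random_reference_pair <- function(region_length_bp = 3000L,
                                  insertion_point = NULL,
                                  insertion_length_bp = 300L,
                                  tsd_length = 0L,
                                  seed = 1L) {
  if (is.null(insertion_point)) insertion_point <- region_length_bp %/% 2L
  with_seed(seed, {
    reference_pair(random_dna(region_length_bp),
                   random_dna(insertion_length_bp),
                   insertion_point, tsd_length)
  })
}

#' Configuration for the ancient-DNA fragment simulator
#'
#' Fragment lengths follow a truncated normal (mean 55, sd 15, min 30 by
#' default), matching typical ancient-DNA size distributions.  Post-mortem
#' deamination (terminal C->T / G->A) and sequencing error default to 0.
#'
#' @param target_coverage expected total fold-coverage (summed over both
#'   chromosomes of the diploid donor).
#' @param fragment_length_mean_bp,fragment_length_sd_bp truncated-normal
#'   parameters.
#' @param fragment_length_min_bp minimum fragment length; must be at least
#'   22 bp so insertion junctions remain detectable.
#' @param deamination_rate per-position C->T probability within 3 bp of the
#'   5' end (and G->A within 3 bp of the 3' end).
#' @param sequencing_error_rate per-base substitution probability.
#' @param seed integer seed.
#' @return a validated list of class `SimFragmentConfig`.
#' @export
sim_fragment_config <- function(target_coverage = 30,
                                fragment_length_mean_bp = 55,
                                fragment_length_sd_bp = 15,
                                fragment_length_min_bp = 30L,
                                deamination_rate = 0,
                                sequencing_error_rate = 0,
                                seed = 1L) {
  stopifnot_positive(target_coverage, "target_coverage")
  stopifnot_positive(fragment_length_mean_bp, "fragment_length_mean_bp")
  stopifnot_positive(fragment_length_sd_bp, "fragment_length_sd_bp")
  stopifnot_scalar_prob(deamination_rate, "deamination_rate")
  stopifnot_scalar_prob(sequencing_error_rate, "sequencing_error_rate")
  if (fragment_length_min_bp < 22L) {
    stop("fragment_length_min_bp must be >= 22 (junction 2k-mer length)",
         call. = FALSE)
  }
  if (fragment_length_mean_bp < fragment_length_min_bp) {
    stop("mean fragment length must be >= minimum length", call. = FALSE)
  }
  structure(
    list(
      target_coverage = target_coverage,
      fragment_length_mean_bp = fragment_length_mean_bp,
      fragment_length_sd_bp = fragment_length_sd_bp,
      fragment_length_min_bp = as.integer(fragment_length_min_bp),
      deamination_rate = deamination_rate,
      sequencing_error_rate = sequencing_error_rate,
      seed = as.integer(seed)
    ),
    class = "SimFragmentConfig"
  )
}

rtruncnorm_len <- function(n, mean, sd, min) {
  out <- integer(0)
  while (length(out) < n) {
    x <- round(rnorm(n, mean, sd))
    out <- c(out, x[x >= min])
  }
  out[seq_len(n)]
}

#' Simulate ancient-DNA shotgun fragments from a diploid donor
#'
#' Draws fragments uniformly from the two donor chromosomes implied by the
#' insertion genotype (`hom_present`: both carry the element; `het`: one
#' each; `hom_absent`: neither), with truncated-normal lengths and optional
#' terminal deamination and sequencing error.  Half the fragments are drawn
#' from the minus strand; sequences are reported read-orientation, while
#' coordinates always refer to the plus strand of the donor reference the
#' fragment came from (`ref_with` or `ref_without`).
#'
#' @param ref_pair a [reference_pair()].
#' @param genotype one of `"hom_present"`, `"het"`, `"hom_absent"`.
#' @param config a [sim_fragment_config()].
#' @return list with `fragments` (data.frame: fragment_id, ref_name, start,
#'   end, strand, sequence; 0-based half-open coordinates) and `truth`
#'   (class `GroundTruth`: genotype, per-fragment donor, seed).
#' @export
simulate_ancient_fragments <- function(ref_pair, genotype, config) {
  stopifnot(inherits(ref_pair, "ReferencePair"),
            inherits(config, "SimFragmentConfig"))
  genotype <- match.arg(genotype, c("hom_present", "het", "hom_absent"))
  with_seed(config$seed, {
    donors <- switch(genotype,
      hom_present = c("ref_with", "ref_with"),
      het         = c("ref_with", "ref_without"),
      hom_absent  = c("ref_without", "ref_without")
    )
    seqs <- c(ref_with = ref_pair$ref_with,
              ref_without = ref_pair$ref_without)
    donor_len <- nchar(seqs[donors])
    ## total bases so that single-copy depth ~ target_coverage:
    ## each chromosome contributes ~ coverage/2
    total_target <- config$target_coverage * sum(donor_len) / 2
    n_guess <- ceiling(1.2 * total_target / config$fragment_length_mean_bp)
    lens <- rtruncnorm_len(n_guess, config$fragment_length_mean_bp,
                           config$fragment_length_sd_bp,
                           config$fragment_length_min_bp)
    n <- which(cumsum(lens) >= total_target)[1]
    if (is.na(n)) n <- n_guess  # pathological config; keep what we have
    lens <- lens[seq_len(n)]
    chrom <- sample(1:2, n, replace = TRUE,
                    prob = donor_len / sum(donor_len))
    ref_name <- donors[chrom]
    L <- donor_len[chrom]
    lens <- pmin(lens, L)
    start <- floor(runif(n) * (L - lens + 1))  # 0-based
    end <- start + lens
    strand <- ifelse(runif(n) < 0.5, "+", "-")
    sequence <- stringi::stri_sub(seqs[ref_name], start + 1, end)
    minus <- strand == "-"
    if (any(minus)) sequence[minus] <- revcomp(sequence[minus])
    sequence <- apply_ancient_noise(sequence, config)
    frags <- data.frame(
      fragment_id = sprintf("frag%06d", seq_len(n)),
      ref_name = unname(ref_name),
      start = as.integer(start),
      end = as.integer(end),
      strand = strand,
      sequence = sequence,
      stringsAsFactors = FALSE
    )
    truth <- structure(
      list(insertion_genotype = genotype,
           donor_of_fragment = setNames(unname(ref_name), frags$fragment_id),
           seed = config$seed),
      class = "GroundTruth"
    )
    list(fragments = frags, truth = truth)
  })
}

## terminal deamination (C->T at 5', G->A at 3', first/last 3 bp) and
## uniform sequencing error, both applied in read orientation
apply_ancient_noise <- function(sequence, config) {
  d <- config$deamination_rate
  e <- config$sequencing_error_rate
  if (d == 0 && e == 0) return(sequence)
  vapply(sequence, function(s) {
    b <- strsplit(s, "")[[1]]
    n <- length(b)
    if (d > 0) {
      i5 <- seq_len(min(3L, n))
      hit <- i5[b[i5] == "C" & runif(length(i5)) < d]
      b[hit] <- "T"
      i3 <- seq.int(max(1L, n - 2L), n)
      hit <- i3[b[i3] == "G" & runif(length(i3)) < d]
      b[hit] <- "A"
    }
    if (e > 0) {
      hit <- which(runif(n) < e)
      for (i in hit) b[i] <- sample(setdiff(c("A", "C", "G", "T"), b[i]), 1L)
    }
    paste(b, collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

#' Place fragments on a reference by exact match
#'
#' Ungapped placement by exact substring match on either strand.  A
#' fragment is placed only if its sequence (or reverse complement) occurs
#' exactly once in the reference; otherwise it is returned unplaced with a
#' reason code (`no_exact_match` or `ambiguous`).  Occurrence counting is
#' overlap-aware.
#'
#' @param sequences character vector of fragment sequences (read
#'   orientation), or a fragment data.frame with a `sequence` column.
#' @param reference reference sequence (single string).
#' @param ref_name name recorded for placed fragments.
#' @return data.frame: fragment_id, ref_name, start, end (0-based
#'   half-open), strand, sequence, placed (logical), reason.
#' @export
align_fragments <- function(sequences, reference, ref_name = "ref") {
  ids <- NULL
  if (is.data.frame(sequences)) {
    ids <- sequences$fragment_id
    sequences <- sequences$sequence
  }
  stopifnot(is.character(reference), length(reference) == 1L,
            nchar(reference) > 0L)
  n <- length(sequences)
  if (is.null(ids)) ids <- sprintf("frag%06d", seq_len(n))
  out <- data.frame(
    fragment_id = ids, ref_name = ref_name,
    start = NA_integer_, end = NA_integer_, strand = NA_character_,
    sequence = sequences, placed = FALSE, reason = NA_character_,
    stringsAsFactors = FALSE
  )
  if (n == 0L) return(out)
  fwd <- stringi::stri_locate_all_fixed(reference, sequences, overlap = TRUE)
  rev <- stringi::stri_locate_all_fixed(reference, revcomp(sequences),
                                        overlap = TRUE)
  nhit <- function(m) sum(!is.na(m[, 1L]))
  cf <- vapply(fwd, nhit, integer(1))
  cr <- vapply(rev, nhit, integer(1))
  ## palindromic fragments match both strands at the same locus: count once
  pal <- sequences == revcomp(sequences)
  total <- ifelse(pal, cf, cf + cr)
  out$reason[total == 0L] <- "no_exact_match"
  out$reason[total > 1L] <- "ambiguous"
  ok <- total == 1L
  if (any(ok)) {
    use_fwd <- cf[ok] == 1L
    pos <- integer(sum(ok))
    pos[use_fwd] <- vapply(fwd[ok][use_fwd], function(m) m[1, 1L], integer(1))
    pos[!use_fwd] <- vapply(rev[ok][!use_fwd], function(m) m[1, 1L],
                            integer(1))
    out$start[ok] <- pos - 1L
    out$end[ok] <- pos - 1L + nchar(sequences[ok])
    out$strand[ok] <- ifelse(use_fwd, "+", "-")
    out$placed[ok] <- TRUE
  }
  out
}
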