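## Mobile-element insertion genotyping from short aligned fragments:
## coverage-drop statistics around the insertion point plus exact-match
## junction / spanning fragment counts, combined into a diploid call.

#' Per-base read depth over a window
#'
#' `depth[i]` is the number of fragments whose half-open interval
#' `[start, end)` contains base `i`.  Only placed fragments contribute.
#'
#' @param fragments data.frame of aligned fragments (columns `start`, `end`,
#'   0-based half-open; rows with `placed == FALSE` are ignored if the
#'   column is present).
#' @param window half-open interval `c(start, end)` (0-based) on the
#'   reference.
#' @return object of class `DepthProfile`: list with `window` and integer
#'   `depth` of length `window[2] - window[1]`.
#' @examples
#' f <- data.frame(start = c(0L, 5L), end = c(10L, 15L))
#' depth_profile(f, c(0L, 15L))$depth
#' @export
depth_profile <- function(fragments, window) {
  if (length(window) != 2L || window[2] <= window[1] || window[1] < 0) {
    stop("'window' must be a non-empty half-open interval c(start, end)",
         call. = FALSE)
  }
  if ("placed" %in% names(fragments)) {
    fragments <- fragments[fragments$placed %in% TRUE, , drop = FALSE]
  }
  w <- as.integer(window)
  width <- w[2] - w[1]
  if (nrow(fragments) == 0L) {
    depth <- integer(width)
  } else {
    ir <- IRanges::IRanges(start = fragments$start + 1L,
                           end = fragments$end)
    cov <- IRanges::coverage(ir, width = max(w[2], max(fragments$end)))
    depth <- as.integer(cov)[(w[1] + 1L):w[2]]
  }
  structure(list(window = w, depth = depth), class = "DepthProfile")
}

#' @export
print.DepthProfile <- function(x, ...) {
  cat(sprintf("DepthProfile over [%d, %d): mean depth %.2f\n",
              x$window[1], x$window[2], mean(x$depth)))
  invisible(x)
}

#' Coverage drop and flank asymmetry at an insertion point
#'
#' A homozygous insertion absent from the alignment reference produces a
#' symmetrical drop of read depth to zero around the insertion point; a
#' heterozygous one, a drop to roughly half.  `drop_ratio` is the mean depth
#' over the inner window `[point - inner, point + inner)` divided by the
#' mean depth over two flanking windows of width `flank_width_bp` placed
#' immediately outside the inner window; `asymmetry` is the absolute
#' relative difference of the two flank means.
#'
#' The default inner half-width is small (5 bp) because depth ramps down
#' over one fragment length on each side of the insertion point; a wide
#' inner window would average the ramp into the drop and inflate the ratio
#' for true homozygous insertions.
#'
#' @param profile a [depth_profile()] covering all windows.
#' @param insertion_point 0-based insertion point.
#' @param inner_halfwidth_bp half-width of the inner window (default 5).
#' @param flank_width_bp width of each flanking window (default 500).
#' @return list with `drop_ratio` (NA with `no_data = TRUE` if both flank
#'   means are 0) and `asymmetry`.
#' @export
coverage_drop <- function(profile, insertion_point,
                          inner_halfwidth_bp = 5L, flank_width_bp = 500L) {
  stopifnot(inherits(profile, "DepthProfile"))
  if (inner_halfwidth_bp <= 0L || flank_width_bp <= 0L) {
    stop("window widths must be positive", call. = FALSE)
  }
  w <- profile$window
  lo <- insertion_point - inner_halfwidth_bp - flank_width_bp
  hi <- insertion_point + inner_halfwidth_bp + flank_width_bp
  if (lo < w[1] || hi > w[2]) {
    stop("inner and flank windows must fit inside the profile window",
         call. = FALSE)
  }
  at <- function(a, b) profile$depth[(a - w[1] + 1L):(b - w[1])]  # [a, b)
  inner <- at(insertion_point - inner_halfwidth_bp,
              insertion_point + inner_halfwidth_bp)
  left <- at(lo, insertion_point - inner_halfwidth_bp)
  right <- at(insertion_point + inner_halfwidth_bp, hi)
  flank_mean <- mean(c(left, right))
  if (flank_mean == 0) {
    return(list(drop_ratio = NA_real_, asymmetry = NA_real_, no_data = TRUE))
  }
  list(
    drop_ratio = mean(inner) / flank_mean,
    asymmetry = abs(mean(left) - mean(right)) / flank_mean,
    no_data = FALSE
  )
}

#' The insertion junction 2k-mer of a reference pair
#'
#' The k bases immediately 5' of the inserted element in `ref_with`
#' concatenated with the first k bases of the element.  Verified to occur
#' exactly once in `ref_with` and never in `ref_without` (both strands,
#' overlap-aware); non-uniqueness is a hard error naming the sequence,
#' since every downstream count would be uninterpretable.
#'
#' @param ref_pair a [reference_pair()].
#' @param k bases on each side of the junction (default 11).
#' @return the junction 2k-mer (character scalar).
#' @export
junction_kmer <- function(ref_pair, k = 11L) {
  stopifnot(inherits(ref_pair, "ReferencePair"))
  if (k < 1L) stop("'k' must be >= 1", call. = FALSE)
  ins_start0 <- ref_pair$insertion_point + ref_pair$tsd_length  # 0-based
  if (ins_start0 < k) stop("not enough 5' flank for k", call. = FALSE)
  jmer <- substr(ref_pair$ref_with, ins_start0 - k + 1L, ins_start0 + k)
  if (nchar(jmer) != 2L * k) {
    stop("insertion too short for k", call. = FALSE)
  }
  n_with <- count_occurrences(jmer, ref_pair$ref_with)
  n_without <- count_occurrences(jmer, ref_pair$ref_without)
  if (n_with != 1L || n_without != 0L) {
    stop(sprintf(
      "junction %d-mer '%s' is not unique (%d occurrence(s) in ref_with, %d in ref_without)",
      2L * k, jmer, n_with, n_without), call. = FALSE)
  }
  jmer
}

#' Count insertion-supporting (junction) fragments
#'
#' A fragment supports the insertion if it contains, on either strand, the
#' exact junction 2k-mer of [junction_kmer()].  Only the 5' junction is
#' used by default; `use_3prime = TRUE` additionally returns the 3'-junction
#' count separately.  Fragments shorter than 2k are skipped.  Detection is
#' exact-substring, so heavily deaminated fragments may be missed.
#'
#' @param sequences character vector of fragment sequences (read
#'   orientation), or a fragment data.frame with a `sequence` column.
#' @param ref_pair a [reference_pair()].
#' @param k bases on each side of the junction (default 11).
#' @param use_3prime also count 3'-junction fragments (reported separately).
#' @return integer count (with attribute `n_junction_3prime` when
#'   `use_3prime = TRUE`).
#' @export
count_junction_fragments <- function(sequences, ref_pair, k = 11L,
                                     use_3prime = FALSE) {
  if (is.data.frame(sequences)) sequences <- sequences$sequence
  jmer <- junction_kmer(ref_pair, k)
  n5 <- count_fragments_with(sequences, jmer, 2L * k)
  if (!use_3prime) return(n5)
  ## 3' junction: last k bases of the element + k bases of 3' flank
  ins_end0 <- ref_pair$insertion_point + ref_pair$tsd_length +
    nchar(ref_pair$insertion_seq)
  jmer3 <- substr(ref_pair$ref_with, ins_end0 - k + 1L, ins_end0 + k)
  n_with <- count_occurrences(jmer3, ref_pair$ref_with)
  n_without <- count_occurrences(jmer3, ref_pair$ref_without)
  if (n_with != 1L || n_without != 0L) {
    stop(sprintf("3' junction %d-mer '%s' is not unique", 2L * k, jmer3),
         call. = FALSE)
  }
  structure(n5, n_junction_3prime = count_fragments_with(sequences, jmer3,
                                                         2L * k))
}

count_fragments_with <- function(sequences, kmer, min_len) {
  eligible <- nchar(sequences) >= min_len
  s <- sequences[eligible]
  if (length(s) == 0L) return(0L)
  hit <- stringi::stri_detect_fixed(s, kmer) |
    stringi::stri_detect_fixed(s, revcomp(kmer))
  sum(hit)
}

#' Count insertion-site-spanning fragments
#'
#' Fragments aligned to the insertion-free reference that cross the
#' insertion point with at least `min_anchor_bp` aligned bases on each side
#' (`start <= point - anchor` and `end >= point + anchor`); these evidence
#' the insertion-free allele.
#'
#' @param fragments data.frame of aligned fragments on the insertion-free
#'   reference (`start`/`end` 0-based half-open; unplaced rows ignored).
#' @param insertion_point 0-based insertion point.
#' @param min_anchor_bp minimum anchor on each side (default 11, symmetric
#'   with the junction k).
#' @return integer count.
#' @export
count_spanning_fragments <- function(fragments, insertion_point,
                                     min_anchor_bp = 11L) {
  if (min_anchor_bp < 1L) stop("'min_anchor_bp' must be >= 1", call. = FALSE)
  if ("placed" %in% names(fragments)) {
    fragments <- fragments[fragments$placed %in% TRUE, , drop = FALSE]
  }
  sum(fragments$start <= insertion_point - min_anchor_bp &
        fragments$end >= insertion_point + min_anchor_bp)
}

#' Call an insertion genotype from junction and spanning counts
#'
#' Decision rule: with `total = n_junction + n_spanning`, fewer than
#' `min_support` informative fragments gives `no_call`; otherwise zero
#' spanning fragments gives `hom_present`, zero junction fragments gives
#' `hom_absent`, and mixed evidence gives `het`.  For mixed evidence a
#' two-sided exact binomial test of `n_junction` against 0.5 is reported;
#' the het call is downgraded to `no_call` when that test rejects
#' (`p < het_alpha`) and the minority count is below `min_support`, i.e.
#' when the imbalance looks more like contamination than heterozygosity.
#'
#' @param n_junction,n_spanning non-negative fragment counts.
#' @param min_support minimum informative fragments for any call (default 5).
#' @param het_alpha significance level of the heterozygote balance guard.
#' @return object of class `InsertionEvidence` fields `n_junction`,
#'   `n_spanning`, `call`, `het_pvalue`.
#' @examples
#' call_genotype(20, 0)$call   # "hom_present"
#' call_genotype(25, 40)$call  # "het"
#' call_genotype(0, 36)$call   # "hom_absent"
#' @export
call_genotype <- function(n_junction, n_spanning, min_support = 5L,
                          het_alpha = 0.05) {
  if (n_junction < 0 || n_spanning < 0) {
    stop("counts must be non-negative", call. = FALSE)
  }
  total <- n_junction + n_spanning
  het_pvalue <- NA_real_
  if (total < min_support) {
    call <- "no_call"
  } else if (n_spanning == 0L) {
    call <- "hom_present"
  } else if (n_junction == 0L) {
    call <- "hom_absent"
  } else {
    het_pvalue <- binom.test(n_junction, total, p = 0.5)$p.value
    call <- "het"
    if (het_pvalue < het_alpha && min(n_junction, n_spanning) < min_support) {
      call <- "no_call"
    }
  }
  structure(
    list(n_junction = as.integer(n_junction),
         n_spanning = as.integer(n_spanning),
         call = call, het_pvalue = het_pvalue),
    class = "InsertionEvidence"
  )
}

#' @export
print.InsertionEvidence <- function(x, ...) {
  cat(sprintf("InsertionEvidence: %d junction / %d spanning -> %s",
              x$n_junction, x$n_spanning, x$call))
  if (!is.na(x$het_pvalue)) cat(sprintf(" (het p = %.3g)", x$het_pvalue))
  if (!is.null(x$drop_ratio)) {
    cat(sprintf("; drop_ratio = %.3f, asymmetry = %.3f",
                x$drop_ratio, x$asymmetry))
  }
  cat("\n")
  invisible(x)
}

#' Genotype an insertion from raw fragments end to end
#'
#' Convenience wrapper: aligns fragments to the insertion-free reference,
#' computes the depth profile and coverage-drop statistics around the
#' insertion point, counts junction (on raw sequences) and spanning
#' fragments, and calls the genotype.
#'
#' @param sequences character vector of fragment sequences, or a fragment
#'   data.frame with a `sequence` column.
#' @param ref_pair a [reference_pair()].
#' @param k junction half-length (default 11).
#' @param min_anchor_bp spanning-fragment anchor (default 11).
#' @param min_support minimum informative fragments (default 5).
#' @param het_alpha heterozygote balance guard level (default 0.05).
#' @param inner_halfwidth_bp,flank_width_bp [coverage_drop()] windows; the
#'   flank width is shrunk automatically if the reference is short.
#' @return an `InsertionEvidence` with `drop_ratio` and `asymmetry` added.
#' @export
genotype_insertion <- function(sequences, ref_pair, k = 11L,
                               min_anchor_bp = 11L, min_support = 5L,
                               het_alpha = 0.05,
                               inner_halfwidth_bp = 5L,
                               flank_width_bp = 500L) {
  if (is.data.frame(sequences)) sequences <- sequences$sequence
  aligned <- align_fragments(sequences, ref_pair$ref_without,
                             ref_name = "ref_without")
  ip <- ref_pair$insertion_point
  reflen <- nchar(ref_pair$ref_without)
  flank_width_bp <- min(flank_width_bp,
                        ip - inner_halfwidth_bp,
                        reflen - ip - inner_halfwidth_bp)
  win <- c(ip - inner_halfwidth_bp - flank_width_bp,
           ip + inner_halfwidth_bp + flank_width_bp)
  prof <- depth_profile(aligned, win)
  drop <- coverage_drop(prof, ip, inner_halfwidth_bp, flank_width_bp)
  n_j <- count_junction_fragments(sequences, ref_pair, k)
  n_s <- count_spanning_fragments(aligned, ip, min_anchor_bp)
  ev <- call_genotype(n_j, n_s, min_support, het_alpha)
  ev$drop_ratio <- drop$drop_ratio
  ev$asymmetry <- drop$asymmetry
  ev
}
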