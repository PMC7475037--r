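## End-to-end synthetic study: simulate a panel and three archaic
## individuals' fragment sets, genotype the insertion in each, characterize
## the introgressed haplotype, run the ILS length test, and post-process an
## association table, emitting one structured report.

#' Default demo run configuration
#'
#' A fixed-seed synthetic study sized to run in seconds: a three-population
#' panel with a planted 56.2 kb archaic segment (28 private SNPs, insertion
#' sub-haplotype fraction 256/345), three 30x archaic fragment sets with
#' insertion genotypes hom_present / het / hom_absent, the ILS test at the
#' emulated locus parameters, and a bundled 22-phenotype association family.
#'
#' @param seed master seed; per-stage seeds are derived from it.
#' @param assoc_table_path TSV of association summary statistics; defaults
#'   to the synthetic table bundled with the package.
#' @return a list of class `RunConfig`.
#' @export
demo_config <- function(seed = 2020L, assoc_table_path = NULL) {
  if (is.null(assoc_table_path)) {
    assoc_table_path <- system.file("extdata",
                                    "synthetic_pregnancy_associations.tsv",
                                    package = "introscan")
  }
  structure(
    list(
      seed = as.integer(seed),
      panel = sim_panel_config(seed = seed),
      reference = list(region_length_bp = 3000L, insertion_length_bp = 300L,
                       tsd_length = 0L, seed = seed + 1L),
      fragments = list(
        archaicA = list(genotype = "hom_present",
                        config = sim_fragment_config(seed = seed + 11L)),
        archaicB = list(genotype = "het",
                        config = sim_fragment_config(seed = seed + 12L)),
        archaicC = list(genotype = "hom_absent",
                        config = sim_fragment_config(seed = seed + 13L))
      ),
      genotyper = list(k = 11L, min_anchor_bp = 11L, min_support = 5L,
                       het_alpha = 0.05),
      haplotype = list(r2_threshold = 0.8, min_archaic_count = 3L),
      ils = ils_params(),
      assoc = list(table_path = assoc_table_path, family_column = "group",
                   method = "bonferroni")
    ),
    class = "RunConfig"
  )
}

run_stage <- function(report, name, fun) {
  t0 <- proc.time()[["elapsed"]]
  res <- tryCatch(list(status = "ok", result = fun()),
                  error = function(e) list(status = "error",
                                           result = conditionMessage(e)))
  message(sprintf("[introscan] stage %-12s %-5s (%.2f s)", name, res$status,
                  proc.time()[["elapsed"]] - t0))
  report$stages[[name]] <- res
  report
}

#' Run the full synthetic pipeline
#'
#' Executes the stages in dependency order (simulate panel; build reference
#' pair; simulate + genotype fragments per archaic individual; haplotype
#' characterization; ILS test; association post-processing).  A failing
#' stage is recorded with its error message and downstream stages that
#' depend on it are skipped; independent stages still run.  The report
#' payload is deterministic under the configured seeds.
#'
#' @param config a [demo_config()]-style `RunConfig`.
#' @param output_dir optional directory; when given, the panel VCF, ground
#'   truth JSON, fragment FASTA/TSV sets and the JSON report are written
#'   there.
#' @return a list of class `RunReport`: `schema_version`, `config_echo`,
#'   `stages` (per-stage status + result), `truth_comparison`, `timing`.
#' @export
run_pipeline <- function(config, output_dir = NULL) {
  stopifnot(inherits(config, "RunConfig"))
  t_start <- proc.time()[["elapsed"]]
  report <- list(schema_version = "1.0", config_echo = config,
                 stages = list())

  report <- run_stage(report, "simulate", function() {
    simulate_panel(config$panel)
  })
  sim <- if (report$stages$simulate$status == "ok") {
    report$stages$simulate$result
  } else NULL

  report <- run_stage(report, "reference", function() {
    do.call(random_reference_pair, config$reference)
  })
  ref_pair <- if (report$stages$reference$status == "ok") {
    report$stages$reference$result
  } else NULL

  report <- run_stage(report, "genotype", function() {
    if (is.null(ref_pair)) stop("reference stage failed")
    lapply(config$fragments, function(spec) {
      sim_frag <- simulate_ancient_fragments(ref_pair, spec$genotype,
                                             spec$config)
      ev <- genotype_insertion(
        sim_frag$fragments, ref_pair,
        k = config$genotyper$k,
        min_anchor_bp = config$genotyper$min_anchor_bp,
        min_support = config$genotyper$min_support,
        het_alpha = config$genotyper$het_alpha
      )
      list(true_genotype = spec$genotype, n_fragments = nrow(sim_frag$fragments),
           evidence = unclass(ev), fragments = sim_frag$fragments)
    })
  })

  report <- run_stage(report, "haplotype", function() {
    if (is.null(sim)) stop("simulate stage failed")
    panel <- sim$panel
    truth <- sim$truth
    focal <- truth$focal_site_index
    alu_col <- insertion_pseudo_marker(panel, truth$alu_carrier_haplotype_ids)
    priv <- private_archaic_sites(panel, config$panel$outgroup_pop,
                                  sim$archaic)
    seg <- introgression_segment(panel, focal,
                                 r2_threshold = config$haplotype$r2_threshold,
                                 private_sites = as.integer(priv))
    carriers <- truth$alu_carrier_haplotype_ids
    noncarriers <- setdiff(truth$introgressed_haplotype_ids, carriers)
    mm <- archaic_match_matrix(panel, carriers, noncarriers,
                               config$panel$outgroup_pop, sim$archaic,
                               config$haplotype$min_archaic_count)
    list(
      focal_site = focal,
      focal_frequency = as.list(allele_frequency(panel, focal)),
      ld_focal_vs_insertion = unclass(ld_r2(panel, focal, alu_col))[
        c("r2", "d")],
      n_private_sites = length(priv),
      segment = unclass(seg),
      match_matrix = mm
    )
  })

  report <- run_stage(report, "ils", function() {
    list(params = unclass(config$ils),
         expected_length_bp = expected_tract_length(config$ils),
         probability = ils_probability(config$ils))
  })

  report <- run_stage(report, "assoc", function() {
    tab <- read_assoc_table(config$assoc$table_path)
    process_assoc_table(tab, family_column = config$assoc$family_column,
                        method = config$assoc$method)
  })

  report$truth_comparison <- if (!is.null(sim) &&
                                 report$stages$genotype$status == "ok" &&
                                 report$stages$haplotype$status == "ok") {
    calls <- vapply(report$stages$genotype$result,
                    function(x) x$evidence$call, character(1))
    truth_geno <- vapply(report$stages$genotype$result,
                         function(x) x$true_genotype, character(1))
    hap <- report$stages$haplotype$result
    list(
      insertion_calls_correct = unname(calls == truth_geno),
      private_sites_recovered =
        hap$n_private_sites == length(sim$truth$private_site_indices),
      segment_length_bp = hap$segment$length_bp,
      planted_segment_length_bp = diff(sim$truth$segment_bounds_bp)
    )
  } else NULL

  report$timing <- list(elapsed_s = proc.time()[["elapsed"]] - t_start)
  class(report) <- "RunReport"

  if (!is.null(output_dir)) write_run_outputs(report, sim, output_dir)
  report
}

#' @export
print.RunReport <- function(x, ...) {
  cat("introscan RunReport (schema", x$schema_version, ")\n")
  for (nm in names(x$stages)) {
    cat(sprintf("  %-12s %s\n", nm, x$stages[[nm]]$status))
  }
  if (x$stages$genotype$status == "ok") {
    for (ind in names(x$stages$genotype$result)) {
      r <- x$stages$genotype$result[[ind]]
      cat(sprintf(
        "  %s: true %s -> called %s (%d junction / %d spanning, drop %.3f)\n",
        ind, r$true_genotype, r$evidence$call, r$evidence$n_junction,
        r$evidence$n_spanning, r$evidence$drop_ratio))
    }
  }
  if (x$stages$ils$status == "ok") {
    cat(sprintf("  ILS: expected tract %.1f bp, P = %.4f\n",
                x$stages$ils$result$expected_length_bp,
                x$stages$ils$result$probability))
  }
  invisible(x)
}

#' Serializable payload of a run report (timestamps excluded)
#'
#' Everything in the report except wall-clock timing, for determinism
#' checks and JSON export.
#'
#' @param report a `RunReport`.
#' @return a list.
#' @export
report_payload <- function(report) {
  x <- unclass(report)
  x$timing <- NULL
  ## drop bulky per-fragment tables from the payload; calls remain
  if (!is.null(x$stages$genotype) && x$stages$genotype$status == "ok") {
    x$stages$genotype$result <- lapply(x$stages$genotype$result, function(r) {
      r$fragments <- NULL
      r
    })
  }
  x
}

write_run_outputs <- function(report, sim, output_dir) {
  dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)
  jsonlite::write_json(report_payload(report),
                       file.path(output_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, null = "null",
                       pretty = TRUE, force = TRUE)
  if (!is.null(sim)) {
    write_panel_vcf(sim$panel, file.path(output_dir, "panel"))
    write_archaic_tsv(sim$archaic, sim$panel,
                      file.path(output_dir, "archaic_dosage.tsv"))
    write_ground_truth(sim$truth, file.path(output_dir, "ground_truth.json"))
  }
  if (report$stages$genotype$status == "ok") {
    for (ind in names(report$stages$genotype$result)) {
      write_fragments(report$stages$genotype$result[[ind]]$fragments,
                      file.path(output_dir, paste0("fragments_", ind)))
    }
  }
  if (report$stages$assoc$status == "ok") {
    write_assoc_table(report$stages$assoc$result,
                      file.path(output_dir, "associations.tsv"))
  }
  invisible(output_dir)
}
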