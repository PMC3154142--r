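#' Run the full imprinted-DMR screen
#'
#' Sequences the analysis end to end: detection-p quality filter, group
#' mean profiles, two-class SAM between diandric and digynic samples,
#' candidate thresholding with parental-origin assignment, reference
#' consistency filtering, DMR aggregation, optional CNV-overlap
#' annotation, and — when the tissue panel groups are present — the
#' tissue/gestation classification. Probe counts in and out of every
#' filter are logged via `message()` and collected in a manifest.
#'
#' @param bm a [BetaMatrix].
#' @param annotation probe annotation data.frame (see
#'   [validate_probe_annotation()]).
#' @param sheet sample sheet covering the samples of `bm`.
#' @param out_dir optional output directory; when given, writes the DML
#'   table, eliminated-probe table, DMR BED, classification table,
#'   cluster outputs (Newick + distance TSV) and a JSON manifest.
#' @param detection_alpha detection p-value threshold (default 0.05);
#'   skipped with a note when `bm` has no detection p-values.
#' @param fdr_target SAM q-value cutoff (default 0.001).
#' @param delta_threshold minimum |delta beta| (default 0.15).
#' @param placenta_margin placenta-specificity margin (default 0.15).
#' @param cfg a [sam_config()]; its `fdr_target` is overridden by
#'   `fdr_target`.
#' @param cnv_intervals optional data.frame of 0-based half-open intervals
#'   (e.g. [read_bed()]) for CNV-overlap annotation.
#' @param known_imprinted character vector of known-imprinted gene
#'   symbols for the classification table.
#' @param cluster run the sample clustering stage (default TRUE).
#' @return the manifest: a list with counts (`n_candidates`,
#'   `n_eliminated`, `n_final_dml`, `n_dmrs`, `n_genes`, `n_maternal`,
#'   `n_paternal`, ...), seed/version provenance, and the result tables
#'   under `$results`.
#' @export
run_imprint_pipeline <- function(bm, annotation, sheet, out_dir = NULL,
                                 detection_alpha = 0.05, fdr_target = 0.001,
                                 delta_threshold = 0.15, placenta_margin = 0.15,
                                 cfg = sam_config(), cnv_intervals = NULL,
                                 known_imprinted = character(0),
                                 cluster = TRUE) {
  stopifnot(inherits(bm, "BetaMatrix"))
  annotation <- validate_probe_annotation(annotation)
  sheet <- validate_sample_sheet(sheet)
  cfg$fdr_target <- fdr_target
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("[stage %s] %s", name, conditionMessage(e)), call. = FALSE))
  }

  n_input <- nrow(bm$beta)
  message(sprintf("input: %d probes x %d samples", n_input, ncol(bm$beta)))

  bm <- stage("detection_filter", {
    if (is.null(bm$detection_p)) {
      message("no detection p-values supplied: detection filter skipped")
      bm
    } else {
      out <- filter_by_detection(bm, detection_alpha)
      message(sprintf("detection filter (p <= %g in every sample): %d -> %d probes",
                      detection_alpha, n_input, nrow(out$beta)))
      out
    }
  })

  profiles <- stage("group_means", group_means(bm, sheet))

  hc <- NULL
  if (cluster) hc <- stage("cluster", cluster_samples(bm))

  groups_present <- unique(sheet$group[sheet$sample_id %in% colnames(bm$beta)])
  for (g in c("diandric", "digynic", "normal_placenta", "chm"))
    if (!g %in% groups_present)
      stop("[stage screen] required group absent from sample sheet: ", g)

  triploid <- sheet$sample_id[sheet$group %in% c("diandric", "digynic")]
  sub <- subset_beta(bm, samples = intersect(colnames(bm$beta), triploid))
  labs <- sheet$group[match(colnames(sub$beta), sheet$sample_id)]
  sam <- stage("sam", sam_two_class(sub, labs, cfg))
  message(sprintf("SAM diandric vs digynic: %d permutations, s0 = %.4g, pi0 = %.3f",
                  sam$n_permutations, sam$s0, sam$pi0))

  candidates <- stage("screen",
    call_candidate_dml(sam, profiles, fdr_target, delta_threshold))
  message(sprintf("candidates at q <= %g and |delta beta| > %g: %d probes",
                  fdr_target, delta_threshold, nrow(candidates)))

  flagged <- stage("consistency", consistency_filter(candidates))
  final <- flagged[flagged$consistent, , drop = FALSE]
  eliminated <- flagged[!flagged$consistent, , drop = FALSE]
  message(sprintf("consistency filter: %d eliminated, %d final DML",
                  nrow(eliminated), nrow(final)))

  if (!is.null(cnv_intervals))
    final <- stage("cnv", annotate_cnv_overlap(final, annotation, cnv_intervals))

  dmrs <- stage("aggregate", aggregate_dml_to_dmrs(final, annotation))
  genes <- unique(dmrs$gene_symbol[dmrs$gene_symbol != ""])
  n_genes <- length(genes) + sum(dmrs$gene_symbol == "")
  message(sprintf("aggregation: %d DML -> %d DMRs from %d genes (%d maternal, %d paternal)",
                  nrow(final), nrow(dmrs), n_genes,
                  sum(dmrs$origin == "maternal"), sum(dmrs$origin == "paternal")))

  classification <- NULL
  tissue_panel <- c("brain", "kidney", "muscle", "placenta_mid", "maternal_blood")
  if (all(tissue_panel %in% groups_present) &&
      all(c("placenta_mid", "placenta_term") %in% groups_present) &&
      nrow(final) > 0) {
    classification <- stage("classify", {
      dml_bm <- subset_beta(bm, probes = final$probe_id)
      tis <- tissue_differential_probes(dml_bm, sheet, cfg)
      tmeans <- group_means(dml_bm, sheet, groups = tissue_panel)
      pla <- names(which(is_placenta_specific(tmeans, margin = placenta_margin)))
      ges <- gestation_change_probes(dml_bm, sheet, cfg)
      classify_dmrs(dmrs, tis, pla, ges, known_imprinted,
                    analyzed_probes = rownames(dml_bm$beta))
    })
    message(sprintf(
      "classification: %d tissue-differential, %d placenta-specific, %d gestation-change, %d stable DMRs",
      sum(classification$tissue_differential, na.rm = TRUE),
      sum(classification$placenta_specific, na.rm = TRUE),
      sum(classification$gestation_change, na.rm = TRUE),
      sum(classification$stable, na.rm = TRUE)))
  }

  manifest <- list(
    package = "imprintscan",
    version = as.character(utils::packageVersion("imprintscan")),
    seed = cfg$seed,
    n_permutations = sam$n_permutations,
    thresholds = list(detection_alpha = detection_alpha,
                      fdr_target = fdr_target,
                      delta_threshold = delta_threshold,
                      placenta_margin = placenta_margin),
    n_probes_input = n_input,
    n_probes_analyzed = nrow(bm$beta),
    n_candidates = nrow(candidates),
    n_eliminated = nrow(eliminated),
    n_final_dml = nrow(final),
    n_dmrs = nrow(dmrs),
    n_genes = n_genes,
    n_maternal = sum(dmrs$origin == "maternal"),
    n_paternal = sum(dmrs$origin == "paternal"),
    sam_s0 = sam$s0,
    sam_pi0 = sam$pi0)

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_dml_table(final, file.path(out_dir, "dml_final.tsv"))
    write_dml_table(eliminated, file.path(out_dir, "dml_eliminated.tsv"))
    if (nrow(dmrs) > 0) write_dmr_bed(dmrs, file.path(out_dir, "dmrs.bed"))
    if (!is.null(classification))
      write_classification_table(classification,
                                 file.path(out_dir, "dmr_classification.tsv"))
    if (!is.null(hc)) {
      dendrogram_newick(hc, file.path(out_dir, "cluster.nwk"))
      utils::write.table(correlation_distances(bm),
                         file.path(out_dir, "cluster_distances.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    }
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }

  manifest$results <- list(dml = final, eliminated = eliminated, dmrs = dmrs,
                           classification = classification, sam = sam,
                           profiles = profiles, dendrogram = hc)
  invisible(manifest)
}
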