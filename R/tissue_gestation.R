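#' Probes with tissue-differential methylation
#'
#' Multiclass SAM across the five-tissue panel (brain, kidney, muscle,
#' midgestation placenta, maternal blood by default), returning the probe
#' set called at the configured FDR target.
#'
#' @param bm a [BetaMatrix], typically restricted to the identified DML
#'   probes.
#' @param sheet sample sheet covering the panel samples.
#' @param cfg a [sam_config()].
#' @param tissue_groups the panel group labels (each needs >= 2 samples).
#' @return character vector of called probe ids.
#' @export
tissue_differential_probes <- function(bm, sheet, cfg = sam_config(),
                                       tissue_groups = c("brain", "kidney",
                                                         "muscle", "placenta_mid",
                                                         "maternal_blood")) {
  stopifnot(inherits(bm, "BetaMatrix"))
  sheet <- validate_sample_sheet(sheet)
  sheet <- sheet[sheet$group %in% tissue_groups, , drop = FALSE]
  missing_groups <- setdiff(tissue_groups, unique(sheet$group))
  if (length(missing_groups))
    stop("missing tissue group(s): ", paste(missing_groups, collapse = ", "))
  samples <- intersect(colnames(bm$beta), sheet$sample_id)
  sub <- subset_beta(bm, samples = samples)
  labs <- sheet$group[match(samples, sheet$sample_id)]
  res <- sam_multiclass(sub, labs, cfg)
  res$called
}

#' Placenta-specific methylation rule
#'
#' TRUE for probes whose placental mean exceeds the maximum mean of every
#' non-placental tissue by strictly more than `margin` (default 0.15, the
#' >15 percent rule). Evaluated on raw group means.
#'
#' @param tissue_means probes x tissue-groups matrix of mean beta values
#'   (e.g. from [group_means()] on the tissue panel).
#' @param placenta_group column holding the placental means (default
#'   `"placenta_mid"`).
#' @param margin required beta margin in (0,1); default 0.15.
#' @return named logical vector over probes.
#' @export
is_placenta_specific <- function(tissue_means, placenta_group = "placenta_mid",
                                 margin = 0.15) {
  if (!placenta_group %in% colnames(tissue_means))
    stop("placenta group '", placenta_group, "' not in tissue means")
  others <- setdiff(colnames(tissue_means), placenta_group)
  if (length(others) == 0) stop("need at least one non-placental tissue")
  maxo <- apply(tissue_means[, others, drop = FALSE], 1, max)
  out <- tissue_means[, placenta_group] - maxo > margin
  names(out) <- rownames(tissue_means)
  out
}

#' Probes whose placental methylation changes with gestational age
#'
#' Two-class SAM between midgestation and term placentas at the
#' configured FDR target.
#'
#' @inheritParams tissue_differential_probes
#' @param groups the two placental-age group labels.
#' @return character vector of called probe ids.
#' @export
gestation_change_probes <- function(bm, sheet, cfg = sam_config(),
                                    groups = c("placenta_mid", "placenta_term")) {
  stopifnot(inherits(bm, "BetaMatrix"), length(groups) == 2)
  sheet <- validate_sample_sheet(sheet)
  sheet <- sheet[sheet$group %in% groups, , drop = FALSE]
  missing_groups <- setdiff(groups, unique(sheet$group))
  if (length(missing_groups))
    stop("missing placental group(s): ", paste(missing_groups, collapse = ", "))
  samples <- intersect(colnames(bm$beta), sheet$sample_id)
  sub <- subset_beta(bm, samples = samples)
  labs <- sheet$group[match(samples, sheet$sample_id)]
  res <- sam_two_class(sub, labs, cfg)
  res$called
}

#' Classify DMRs by tissue and gestational-age specificity
#'
#' A DMR is tissue-differential (or gestation-changed) if ANY member probe
#' is in the respective called set; placenta-specific if additionally any
#' member probe passes the placental-margin rule; stable iff neither
#' tissue-differential nor gestation-changed. DMRs whose probes are all
#' absent from the analyzed matrix are classified unknown (NA flags) with
#' a warning.
#'
#' @param dmrs data.frame from [aggregate_dml_to_dmrs()] (needs `dmr_id`,
#'   `gene_symbol`, `probe_ids`).
#' @param tissue_probes probe ids called tissue-differential.
#' @param placenta_specific_probes probe ids passing the placental margin
#'   rule.
#' @param gestation_probes probe ids called for gestational change.
#' @param known_imprinted character vector of known-imprinted gene
#'   symbols (user-supplied list).
#' @param analyzed_probes optional probe universe actually present in the
#'   classification matrix, used to detect unclassifiable DMRs.
#' @return data.frame: `dmr_id`, `gene_symbol`, `origin` (when present),
#'   `tissue_differential`, `placenta_specific`, `gestation_change`,
#'   `stable`, `known_imprinted`.
#' @export
classify_dmrs <- function(dmrs, tissue_probes, placenta_specific_probes,
                          gestation_probes, known_imprinted = character(0),
                          analyzed_probes = NULL) {
  stopifnot(is.data.frame(dmrs), "probe_ids" %in% names(dmrs))
  tis <- ges <- pla <- logical(nrow(dmrs))
  unknown <- logical(nrow(dmrs))
  for (i in seq_len(nrow(dmrs))) {
    probes <- dmrs$probe_ids[[i]]
    if (!is.null(analyzed_probes) && !any(probes %in% analyzed_probes)) {
      unknown[i] <- TRUE
      next
    }
    tis[i] <- any(probes %in% tissue_probes)
    pla[i] <- any(probes %in% placenta_specific_probes)
    ges[i] <- any(probes %in% gestation_probes)
  }
  pla <- pla & tis   # placenta-specific is a refinement of tissue-differential
  out <- data.frame(dmr_id = dmrs$dmr_id,
                    gene_symbol = dmrs$gene_symbol,
                    stringsAsFactors = FALSE)
  if (!is.null(dmrs$origin)) out$origin <- dmrs$origin
  out$tissue_differential <- tis
  out$placenta_specific <- pla
  out$gestation_change <- ges
  out$stable <- !tis & !ges
  out$known_imprinted <- dmrs$gene_symbol %in% known_imprinted
  if (any(unknown)) {
    warning("DMR(s) with no probes in the analyzed matrix classified unknown: ",
            paste(utils::head(dmrs$dmr_id[unknown], 5), collapse = ", "))
    out$tissue_differential[unknown] <- NA
    out$placenta_specific[unknown] <- NA
    out$gestation_change[unknown] <- NA
    out$stable[unknown] <- NA
  }
  out
}
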