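# Synthetic beta-matrix generator. Probes carry the allele-dosage
# structure the screen assumes: imprinted probes follow the
# haploid-genome-dosage model (diandric = 1 maternal + 2 paternal genomes,
# digynic = 2 + 1, biparental tissues = 1 + 1, CHM = 0 + 2), background
# probes share a bimodal promoter-methylation level across groups, and
# optional tissue-specific / gestational-drift probes mirror the
# classification panel. Noise is logit-normal.

.GROUP_DOSAGE <- list(
  diandric       = c(maternal = 1, paternal = 2),
  digynic        = c(maternal = 2, paternal = 1),
  chm            = c(maternal = 0, paternal = 2),
  normal_placenta = c(maternal = 1, paternal = 1),
  maternal_blood = c(maternal = 1, paternal = 1),
  brain          = c(maternal = 1, paternal = 1),
  kidney         = c(maternal = 1, paternal = 1),
  muscle         = c(maternal = 1, paternal = 1),
  placenta_mid   = c(maternal = 1, paternal = 1),
  placenta_term  = c(maternal = 1, paternal = 1))

.PLACENTAL_GROUPS <- c("diandric", "digynic", "chm", "normal_placenta",
                       "placenta_mid", "placenta_term")

#' Expected beta under the haploid-genome-dosage model
#'
#' At an imprinted locus each haploid genome contributes its parental
#' methylation level: `m1` on the methylated-origin allele, `m0` on the
#' other. With full imprinting fidelity the expected beta is the
#' genome-dosage-weighted mean, e.g. a maternally methylated DMR gives
#' 1/3 in diandric (1 maternal + 2 paternal genomes), 2/3 in digynic
#' (2 + 1), 1/2 in biparental tissue and 0 in CHM (0 + 2) — hence the
#' theoretical 33.3 percent diandry-digyny difference. `fidelity` mixes in
#' a non-imprinted cell fraction at the biparental mean (m1 + m0)/2,
#' modelling incomplete methylation of the silenced allele or cell-type
#' mixture.
#'
#' @param origin `"maternal"` or `"paternal"` (which parental allele is
#'   methylated).
#' @param n_maternal_genomes,n_paternal_genomes haploid genome counts
#'   (total >= 1).
#' @param m1 methylation level of the methylated-origin allele (default 1).
#' @param m0 methylation level of the opposite allele (default 0).
#' @param fidelity fraction of cells carrying the imprint, in \[0,1\].
#' @return expected beta in \[0,1\].
#' @examples
#' expected_beta("maternal", 1, 2)  # diandric: 1/3
#' expected_beta("maternal", 2, 1)  # digynic: 2/3
#' expected_beta("maternal", 0, 2)  # CHM: 0
#' @export
expected_beta <- function(origin = c("maternal", "paternal"),
                          n_maternal_genomes, n_paternal_genomes,
                          m1 = 1, m0 = 0, fidelity = 1) {
  origin <- match.arg(origin)
  ntot <- n_maternal_genomes + n_paternal_genomes
  if (any(ntot < 1)) stop("at least one haploid genome is required")
  if (any(c(m1, m0, fidelity) < 0) || any(c(m1, m0, fidelity) > 1))
    stop("m1, m0 and fidelity must lie in [0,1]")
  imprint <- if (origin == "maternal")
    (n_maternal_genomes * m1 + n_paternal_genomes * m0) / ntot
  else
    (n_maternal_genomes * m0 + n_paternal_genomes * m1) / ntot
  fidelity * imprint + (1 - fidelity) * (m1 + m0) / 2
}

#' Configuration of the synthetic beta-matrix generator
#'
#' Defaults reproduce the study design: 10 diandric, 10 digynic, 10
#' normal-placenta, 6 CHM and 10 maternal-blood arrays (plus the optional
#' tissue panel of 8 brain, 12 kidney, 11 muscle, 10 midgestation and 10
#' term placentas when tissue/gestation probes are requested), 5,000
#' shared bimodal background probes, 50 maternal and 50 paternal fully
#' imprinted probes at allele levels 1/0, and logit-scale noise of sd
#' 0.05.
#'
#' @param n_background count of background probes (shared bimodal level).
#' @param n_maternal_dmr,n_paternal_dmr counts of imprinted probes per
#'   origin.
#' @param n_tissue_specific count of placenta-vs-soma probes.
#' @param n_gestation_drift count of probes drifting between midgestation
#'   and term placenta.
#' @param n_blood_divergent count of background-like probes shifted in
#'   maternal blood (gives the blood/placenta cluster split).
#' @param samples_per_group named integer vector, group -> sample count;
#'   groups must come from [group_levels()].
#' @param m_methylated,m_unmethylated allele methylation levels in \[0,1\].
#' @param fidelity fraction of cells carrying the imprint.
#' @param noise_sd logit-scale noise standard deviation (0 = noise-free).
#' @param background_mix list(low, high, weight_low, logit_sd): the
#'   two-component promoter-methylation mixture for background probes.
#' @param tissue_low,tissue_high expected beta of tissue-specific probes
#'   in somatic vs placental groups.
#' @param gestation_mid,gestation_term expected beta of drift probes in
#'   midgestation vs term placenta.
#' @param blood_logit_shift logit shift applied to blood-divergent probes
#'   in maternal blood.
#' @param seed integer seed.
#' @return an object of class `SimConfig`.
#' @export
sim_config <- function(n_background = 5000, n_maternal_dmr = 50,
                       n_paternal_dmr = 50, n_tissue_specific = 0,
                       n_gestation_drift = 0, n_blood_divergent = 0,
                       samples_per_group = c(diandric = 10, digynic = 10,
                                             normal_placenta = 10, chm = 6,
                                             maternal_blood = 10),
                       m_methylated = 1, m_unmethylated = 0, fidelity = 1,
                       noise_sd = 0.05,
                       background_mix = list(low = 0.10, high = 0.85,
                                             weight_low = 0.7, logit_sd = 0.6),
                       tissue_low = 0.2, tissue_high = 0.5,
                       gestation_mid = 0.3, gestation_term = 0.6,
                       blood_logit_shift = 1.5, seed = 1) {
  counts <- c(n_background, n_maternal_dmr, n_paternal_dmr,
              n_tissue_specific, n_gestation_drift, n_blood_divergent)
  if (any(counts < 0)) stop("probe counts must be >= 0")
  if (sum(counts) < 1) stop("need at least one probe")
  if (is.null(names(samples_per_group)) || any(names(samples_per_group) == ""))
    stop("samples_per_group must be a named vector")
  unknown <- setdiff(names(samples_per_group), names(.GROUP_DOSAGE))
  if (length(unknown))
    stop("group(s) without a dosage definition: ", paste(unknown, collapse = ", "))
  if (any(samples_per_group < 1)) stop("sample counts must be >= 1")
  if (any(c(m_methylated, m_unmethylated, fidelity) < 0) ||
      any(c(m_methylated, m_unmethylated, fidelity) > 1))
    stop("levels and fidelity must lie in [0,1]")
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  structure(list(n_background = n_background, n_maternal_dmr = n_maternal_dmr,
                 n_paternal_dmr = n_paternal_dmr,
                 n_tissue_specific = n_tissue_specific,
                 n_gestation_drift = n_gestation_drift,
                 n_blood_divergent = n_blood_divergent,
                 samples_per_group = samples_per_group,
                 m_methylated = m_methylated, m_unmethylated = m_unmethylated,
                 fidelity = fidelity, noise_sd = noise_sd,
                 background_mix = background_mix,
                 tissue_low = tissue_low, tissue_high = tissue_high,
                 gestation_mid = gestation_mid, gestation_term = gestation_term,
                 blood_logit_shift = blood_logit_shift,
                 seed = as.integer(seed)),
            class = "SimConfig")
}

#' Simulate a beta-value dataset with known ground truth
#'
#' Generates a probes x samples beta matrix where every probe class has a
#' group-wise expected value (see [expected_beta()] for imprinted probes)
#' and each observation is `plogis(qlogis(expected) + N(0, noise_sd))`
#' (expected values clamped to \[1e-6, 1 - 1e-6\] before the logit;
#' `noise_sd = 0` returns the expected values untouched). Reproducible per
#' seed.
#'
#' @param cfg a [sim_config()].
#' @return list with elements `beta` (a [BetaMatrix]), `sample_sheet`,
#'   `annotation`, `truth` (data.frame probe_id / class / origin),
#'   `expected` (probes x groups matrix of noise-free values) and `config`.
#' @export
simulate_dataset <- function(cfg = sim_config()) {
  stopifnot(inherits(cfg, "SimConfig"))
  groups <- names(cfg$samples_per_group)

  classes <- c(rep("background", cfg$n_background),
               rep("maternal_dmr", cfg$n_maternal_dmr),
               rep("paternal_dmr", cfg$n_paternal_dmr),
               rep("tissue_specific", cfg$n_tissue_specific),
               rep("gestation_drift", cfg$n_gestation_drift),
               rep("blood_divergent", cfg$n_blood_divergent))
  n_probes <- length(classes)
  probe_id <- sprintf("cgSIM%06d", seq_len(n_probes))

  .with_seed(cfg$seed, function() {
    # noise-free expected value per probe x group
    E <- matrix(NA_real_, n_probes, length(groups),
                dimnames = list(probe_id, groups))
    bgl <- classes %in% c("background", "blood_divergent")
    nbg <- sum(bgl)
    if (nbg > 0) {
      comp <- stats::runif(nbg) < cfg$background_mix$weight_low
      centre <- ifelse(comp, cfg$background_mix$low, cfg$background_mix$high)
      level <- stats::plogis(stats::rnorm(nbg, stats::qlogis(centre),
                                          cfg$background_mix$logit_sd))
      E[bgl, ] <- level         # shared across every group
      bld <- which(classes == "blood_divergent")
      if (length(bld) && "maternal_blood" %in% groups)
        E[bld, "maternal_blood"] <-
          stats::plogis(stats::qlogis(E[bld, groups[1]]) + cfg$blood_logit_shift)
    }
    for (g in groups) {
      dose <- .GROUP_DOSAGE[[g]]
      imp <- classes == "maternal_dmr"
      if (any(imp))
        E[imp, g] <- expected_beta("maternal", dose["maternal"], dose["paternal"],
                                   cfg$m_methylated, cfg$m_unmethylated,
                                   cfg$fidelity)
      imp <- classes == "paternal_dmr"
      if (any(imp))
        E[imp, g] <- expected_beta("paternal", dose["maternal"], dose["paternal"],
                                   cfg$m_methylated, cfg$m_unmethylated,
                                   cfg$fidelity)
      tis <- classes == "tissue_specific"
      if (any(tis))
        E[tis, g] <- if (g %in% .PLACENTAL_GROUPS) cfg$tissue_high else cfg$tissue_low
      ges <- classes == "gestation_drift"
      if (any(ges))
        E[ges, g] <- if (g == "placenta_term") cfg$gestation_term else cfg$gestation_mid
    }

    sample_id <- unlist(lapply(groups, function(g)
      sprintf("%s_%02d", g, seq_len(cfg$samples_per_group[[g]]))),
      use.names = FALSE)
    grp_of <- rep(groups, cfg$samples_per_group)

    X <- E[, grp_of, drop = FALSE]
    colnames(X) <- sample_id
    if (cfg$noise_sd > 0) {
      eps <- 1e-6
      L <- stats::qlogis(pmin(pmax(X, eps), 1 - eps))
      X <- stats::plogis(L + stats::rnorm(length(L), 0, cfg$noise_sd))
    }

    sheet <- data.frame(sample_id = sample_id, group = grp_of,
                        sex = "unknown", gestational_age = NA_real_,
                        stringsAsFactors = FALSE)
    gene_prefix <- c(background = "BG", maternal_dmr = "IMPM",
                     paternal_dmr = "IMPP", tissue_specific = "TSP",
                     gestation_drift = "GST", blood_divergent = "BLD")
    within_class <- stats::ave(seq_len(n_probes), classes, FUN = seq_along)
    ann <- data.frame(
      probe_id = probe_id,
      gene_symbol = sprintf("%s%05d", gene_prefix[classes], within_class),
      chromosome = as.character(rep_len(1:22, n_probes)),
      position = 10000 + 1000 * (seq_len(n_probes) - 1) %/% 22,
      stringsAsFactors = FALSE)
    truth <- data.frame(probe_id = probe_id, class = classes,
                        origin = ifelse(classes == "maternal_dmr", "maternal",
                                        ifelse(classes == "paternal_dmr",
                                               "paternal", NA_character_)),
                        stringsAsFactors = FALSE)
    list(beta = BetaMatrix(X), sample_sheet = sheet,
         annotation = validate_probe_annotation(ann), truth = truth,
         expected = E, config = cfg)
  })
}

#' Simulate a fully null dataset
#'
#' Same sampling scheme as [simulate_dataset()] but with every structured
#' probe class zeroed out: all probes are shared-background, so any call
#' by a downstream screen is a false positive. Used for FDR calibration.
#'
#' @param cfg a [sim_config()]; its structured probe counts are ignored
#'   and folded into the background count.
#' @return as [simulate_dataset()]; `truth$class` is all `"background"`.
#' @export
simulate_null_dataset <- function(cfg = sim_config()) {
  stopifnot(inherits(cfg, "SimConfig"))
  total <- cfg$n_background + cfg$n_maternal_dmr + cfg$n_paternal_dmr +
    cfg$n_tissue_specific + cfg$n_gestation_drift + cfg$n_blood_divergent
  cfg$n_background <- total
  cfg$n_maternal_dmr <- cfg$n_paternal_dmr <- 0
  cfg$n_tissue_specific <- cfg$n_gestation_drift <- cfg$n_blood_divergent <- 0
  simulate_dataset(cfg)
}
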