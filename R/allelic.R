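# Parent-of-origin validation logic: informative mother-child SNP pairs,
# allele parentage, allelic-expression ratios and clone-level bisulphite
# conversion filtering.

.parse_genotype <- function(g) {
  a <- if (length(g) == 2) toupper(as.character(g))
       else sort(strsplit(toupper(as.character(g)), "")[[1]])
  if (length(a) != 2 || !all(a %in% c("A", "C", "G", "T")))
    stop("genotype must be two alleles from {A,C,G,T}, e.g. \"AG\"")
  sort(a)
}

#' Is a mother-child SNP pair informative for parental origin?
#'
#' Informative iff the child is heterozygous and the mother homozygous,
#' which lets each child allele be assigned to a parent. A child carrying
#' no maternal allele (e.g. mother AA, child GG) is a Mendelian
#' inconsistency and raises an error.
#'
#' @param maternal_genotype,child_genotype unordered allele pairs, given
#'   as a 2-character string (`"AG"`) or a length-2 character vector.
#' @return logical.
#' @examples
#' is_informative("GG", "AG")  # TRUE
#' is_informative("AG", "AG")  # FALSE
#' @export
is_informative <- function(maternal_genotype, child_genotype) {
  m <- .parse_genotype(maternal_genotype)
  k <- .parse_genotype(child_genotype)
  if (length(intersect(k, m)) == 0)
    stop(sprintf("Mendelian inconsistency: mother %s, child %s share no allele",
                 paste(m, collapse = ""), paste(k, collapse = "")))
  k[1] != k[2] && m[1] == m[2]
}

#' Infer the maternal and paternal alleles of an informative pair
#'
#' The maternal allele is the child allele present in the homozygous
#' mother; the paternal allele is the other one.
#'
#' @inheritParams is_informative
#' @return named character vector `c(maternal = ..., paternal = ...)`.
#' @examples
#' infer_parental_alleles("GG", "AG")  # maternal G, paternal A
#' @export
infer_parental_alleles <- function(maternal_genotype, child_genotype) {
  if (!is_informative(maternal_genotype, child_genotype))
    stop("pair is not informative (need heterozygous child, homozygous mother)")
  m <- .parse_genotype(maternal_genotype)
  k <- .parse_genotype(child_genotype)
  mat <- intersect(k, m)
  c(maternal = mat, paternal = setdiff(k, mat))
}

#' Minor-allele fraction of a two-allele measurement
#'
#' min(a, b) / (a + b), in \[0, 0.5\]; symmetric in its arguments. The
#' measurement can be peak intensities, read counts or clone counts.
#'
#' @param a,b non-negative allele quantities (vectorized).
#' @return minor-allele fraction(s).
#' @export
allelic_ratio <- function(a, b) {
  if (any(a < 0, na.rm = TRUE) || any(b < 0, na.rm = TRUE))
    stop("allele measures must be non-negative")
  if (any(a + b == 0, na.rm = TRUE))
    stop("undefined ratio: both allele measures are zero")
  pmin(a, b) / (a + b)
}

#' Call monoallelic (allelically biased) expression
#'
#' TRUE iff the minor-allele fraction is strictly below the threshold
#' (default 0.3).
#'
#' @param ratio minor-allele fraction(s) in \[0, 0.5\].
#' @param threshold strict upper bound; default 0.3.
#' @return logical vector.
#' @export
call_monoallelic <- function(ratio, threshold = 0.3) {
  if (any(ratio < 0 | ratio > 0.5, na.rm = TRUE))
    stop("ratio must lie in [0, 0.5]")
  ratio < threshold
}

#' Concordance of expressed-allele parentage with a DMR's origin
#'
#' Promoter methylation is assumed to silence its allele, so expression
#' from the parent opposite the methylated (DMR-origin) parent is
#' `"matched"`; expression from the same parent is `"opposite"`.
#'
#' @param expressed_allele_parent `"maternal"` or `"paternal"`
#'   (vectorized).
#' @param dmr_origin `"maternal"` or `"paternal"` (vectorized).
#' @return character vector, `"matched"` or `"opposite"`.
#' @examples
#' expression_concordance("paternal", "maternal")  # matched
#' @export
expression_concordance <- function(expressed_allele_parent, dmr_origin) {
  ok <- c("maternal", "paternal")
  if (!all(expressed_allele_parent %in% ok) || !all(dmr_origin %in% ok))
    stop("labels must be 'maternal' or 'paternal'")
  ifelse(expressed_allele_parent != dmr_origin, "matched", "opposite")
}

#' Filter bisulphite clones by conversion rate
#'
#' Retains clones whose bisulphite conversion rate is at least
#' `min_conversion` (inclusive boundary: a clone at exactly the threshold
#' survives; default 0.8).
#'
#' @param clones data.frame with a `conversion_rate` column in \[0,1\].
#' @param min_conversion minimum acceptable conversion rate.
#' @return the retained rows of `clones`.
#' @export
filter_clones <- function(clones, min_conversion = 0.8) {
  if (length(min_conversion) != 1 || min_conversion < 0 || min_conversion > 1)
    stop("min_conversion must lie in [0,1]")
  if (nrow(clones) == 0) return(clones)
  if (is.null(clones$conversion_rate)) stop("clones need a conversion_rate column")
  if (any(clones$conversion_rate < 0 | clones$conversion_rate > 1, na.rm = TRUE))
    stop("conversion rates must lie in [0,1]")
  clones[!is.na(clones$conversion_rate) &
           clones$conversion_rate >= min_conversion, , drop = FALSE]
}
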