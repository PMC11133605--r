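# Generics and accessors.

#' Extract the dosage matrix of a genotype panel
#'
#' @param x a [GenotypePanel-class].
#' @return numeric matrix, variants in rows, individuals in columns.
#' @export
setGeneric("dosages", function(x) standardGeneric("dosages"))

#' @rdname dosages
#' @export
setMethod("dosages", "GenotypePanel", function(x) assay(x, "dosage"))

#' Variant metadata of a genotype panel
#'
#' @param x a [GenotypePanel-class].
#' @return data.frame with `variant`, `chrom`, `pos`, `ref`, `alt`, `eaf`,
#'   `id` columns.
#' @export
setGeneric("variantInfo", function(x) standardGeneric("variantInfo"))

#' @rdname variantInfo
#' @export
setMethod("variantInfo", "GenotypePanel", function(x) {
  df <- as.data.frame(rowData(x))
  df$variant <- rownames(x)
  rownames(df) <- NULL
  df[, c("variant", "chrom", "pos", "ref", "alt", "eaf", "id")]
})

#' Individual identifiers of a genotype panel
#'
#' @param x a [GenotypePanel-class].
#' @export
setGeneric("individualIds", function(x) standardGeneric("individualIds"))

#' @rdname individualIds
#' @export
setMethod("individualIds", "GenotypePanel", function(x) colnames(x))

#' Number of SNPs in an instrument or estimate
#'
#' @param x a [HarmonizedInstrument-class] or [MREstimate-class].
#' @export
setGeneric("nSnps", function(x) standardGeneric("nSnps"))

#' @rdname nSnps
#' @export
setMethod("nSnps", "HarmonizedInstrument", function(x) nrow(x@snps))

#' @rdname nSnps
#' @export
setMethod("nSnps", "MREstimate", function(x) x@nSnps)

#' Per-SNP effect table of a harmonized instrument
#'
#' @param x a [HarmonizedInstrument-class].
#' @return data.frame of aligned exposure/outcome effects.
#' @export
setGeneric("instrumentSnps", function(x) standardGeneric("instrumentSnps"))

#' @rdname instrumentSnps
#' @export
setMethod("instrumentSnps", "HarmonizedInstrument", function(x) x@snps)

#' Harmonization provenance log
#'
#' @param x a [HarmonizedInstrument-class].
#' @return data.frame with one row per drop/flip/copy decision.
#' @export
setGeneric("provenance", function(x) standardGeneric("provenance"))

#' @rdname provenance
#' @export
setMethod("provenance", "HarmonizedInstrument", function(x) x@provenance)

#' Score model entries
#'
#' @param x a [ScoreModel-class].
#' @export
setGeneric("scoreEntries", function(x) standardGeneric("scoreEntries"))

#' @rdname scoreEntries
#' @export
setMethod("scoreEntries", "ScoreModel", function(x) x@entries)

#' Polygenic score values
#'
#' @param x a [PgsVector-class].
#' @return named numeric vector of standardized scores.
#' @export
setGeneric("pgsValues", function(x) standardGeneric("pgsValues"))

#' @rdname pgsValues
#' @export
setMethod("pgsValues", "PgsVector", function(x) x@values)

#' Ground truth accessor
#'
#' @param x a [VirtualStudy-class].
#' @export
setGeneric("groundTruth", function(x) standardGeneric("groundTruth"))

#' @rdname groundTruth
#' @export
setMethod("groundTruth", "VirtualStudy", function(x) x@truth)
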