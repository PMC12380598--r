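#' Genome annotation for CNV association analyses
#'
#' Holds the coordinate frame every range-based operation works in: chromosome
#' lengths, chromosome-arm boundaries (the centromere splits each chromosome
#' into a p and a q arm), gene intervals flagged for detectable RNA expression,
#' and a blacklist of excluded regions. All coordinates are 0-based half-open
#' internally and stored as \linkS4class{GRanges} (1-based closed), converted
#' at the I/O boundary.
#'
#' @slot seqinfo A \link[GenomeInfoDb]{Seqinfo} with chromosome lengths.
#' @slot arms \code{GRanges} tiling each chromosome outside the centromere,
#'   with metadata column \code{arm} (e.g. \code{"chr12p"}).
#' @slot genes \code{GRanges} with metadata columns \code{gene_id} and
#'   \code{expressed} (logical; detectable RNA expression).
#' @slot blacklist \code{GRanges} of regions excluded from CNV analysis.
#'
#' @seealso \code{\link{GenomeAnnotation}} (constructor),
#'   \code{\link{toyGenomeAnnotation}}
#' @export
setClass("GenomeAnnotation",
  slots = c(
    seqinfo = "Seqinfo",
    arms = "GRanges",
    genes = "GRanges",
    blacklist = "GRanges"
  )
)

setValidity("GenomeAnnotation", function(object) {
  msg <- character()
  sl <- GenomeInfoDb::seqlengths(object@seqinfo)
  chk_within <- function(gr, what) {
    bad <- !(as.character(seqnames(gr)) %in% names(sl))
    if (any(bad))
      return(sprintf("%s on chromosomes absent from seqinfo: %s",
                     what, paste(unique(as.character(seqnames(gr))[bad]), collapse = ", ")))
    over <- end(gr) > sl[as.character(seqnames(gr))]
    if (any(over)) return(sprintf("%d %s extend beyond chromosome ends", sum(over), what))
    character()
  }
  msg <- c(msg, chk_within(object@arms, "arms"), chk_within(object@genes, "genes"),
           chk_within(object@blacklist, "blacklist intervals"))
  if (length(object@arms) && is.null(object@arms$arm))
    msg <- c(msg, "arms must carry an 'arm' metadata column")
  if (length(object@genes)) {
    if (is.null(object@genes$gene_id) || is.null(object@genes$expressed))
      msg <- c(msg, "genes must carry 'gene_id' and 'expressed' metadata columns")
    else if (anyDuplicated(object@genes$gene_id))
      msg <- c(msg, "gene_id values must be unique")
  }
  if (length(msg)) msg else TRUE
})

#' Construct a GenomeAnnotation
#'
#' @param chrom_lengths Named integer vector of chromosome lengths (bp).
#' @param arms \code{GRanges} of arm intervals with an \code{arm} metadata
#'   column, or a data.frame with columns \code{chrom, start, end, arm}
#'   (0-based half-open).
#' @param genes \code{GRanges} with \code{gene_id} and \code{expressed}
#'   metadata columns, or a data.frame with columns
#'   \code{chrom, start, end, gene_id, expressed}.
#' @param blacklist \code{GRanges} or data.frame (\code{chrom, start, end}) of
#'   excluded regions; may be empty.
#' @return A \linkS4class{GenomeAnnotation}.
#' @examples
#' ann <- toyGenomeAnnotation()
#' chromArms(ann)
#' @export
GenomeAnnotation <- function(chrom_lengths, arms, genes,
                             blacklist = GRanges()) {
  si <- Seqinfo(seqnames = names(chrom_lengths),
                seqlengths = unname(as.integer(chrom_lengths)))
  as_gr <- function(x) {
    if (is(x, "GRanges")) return(x)
    gr <- GRanges(x$chrom, IRanges(x$start + 1L, x$end))
    extra <- setdiff(names(x), c("chrom", "start", "end"))
    for (cc in extra) mcols(gr)[[cc]] <- x[[cc]]
    gr
  }
  new("GenomeAnnotation", seqinfo = si, arms = as_gr(arms),
      genes = as_gr(genes), blacklist = as_gr(blacklist))
}

#' @describeIn GenomeAnnotation Chromosome arm intervals.
#' @param x A \code{GenomeAnnotation}.
#' @export
setMethod("chromArms", "GenomeAnnotation", function(x) x@arms)

#' @describeIn GenomeAnnotation Gene intervals; optionally only genes flagged
#'   as expressed.
#' @param expressed.only Logical; restrict to genes with detectable expression.
#' @export
setMethod("annotatedGenes", "GenomeAnnotation", function(x, expressed.only = FALSE) {
  g <- x@genes
  if (expressed.only) g[g$expressed] else g
})

#' @describeIn GenomeAnnotation Blacklisted regions.
#' @export
setMethod("blacklistRegions", "GenomeAnnotation", function(x) x@blacklist)

#' Chromosome lengths of a GenomeAnnotation
#' @param x A \code{GenomeAnnotation}.
#' @return Named integer vector of lengths in bp.
#' @export
chromLengths <- function(x) GenomeInfoDb::seqlengths(x@seqinfo)

setMethod("show", "GenomeAnnotation", function(object) {
  cat("GenomeAnnotation with", length(chromLengths(object)), "chromosomes,",
      length(object@arms), "arms,", length(object@genes), "genes",
      sprintf("(%d expressed),", sum(object@genes$expressed)),
      length(object@blacklist), "blacklist intervals\n")
})

#' Patient cohort with MRD measurements
#'
#' Container for per-patient measurable residual disease (MRD) values at the
#' three clinical timepoints: mid-induction (~day 15), end of induction
#' (EOI, ~day 29) and end of consolidation (EOC, ~day 79). MRD is stored as a
#' fraction in [0, 1]; percent-scale inputs must be converted at the I/O
#' boundary. Missing values mean the patient was not assessed at that
#' timepoint and are excluded from that timepoint's analyses.
#'
#' @slot patients A \link[S4Vectors]{DataFrame} with columns
#'   \code{patient_id}, \code{mrd_mid}, \code{mrd_eoi}, \code{mrd_eoc}
#'   (numeric fractions or NA) and \code{assays} (comma-separated subset of
#'   wgs, array, panel, rnaseq).
#'
#' @seealso \code{\link{classifyResponse}} for the response-group rules.
#' @export
setClass("MRDCohort", slots = c(patients = "DataFrame"))

setValidity("MRDCohort", function(object) {
  p <- object@patients
  need <- c("patient_id", "mrd_mid", "mrd_eoi", "mrd_eoc", "assays")
  if (!all(need %in% colnames(p)))
    return(paste("missing columns:", paste(setdiff(need, colnames(p)), collapse = ", ")))
  if (anyDuplicated(p$patient_id)) return("patient_id values must be unique")
  for (tp in c("mrd_mid", "mrd_eoi", "mrd_eoc")) {
    v <- p[[tp]]
    bad <- !is.na(v) & (v < 0 | v > 1)
    if (any(bad))
      return(sprintf("%s outside [0,1] for patient(s): %s", tp,
                     paste(p$patient_id[bad], collapse = ", ")))
  }
  TRUE
})

#' Construct an MRDCohort
#'
#' @param patients data.frame (or DataFrame) with columns \code{patient_id},
#'   \code{mrd_mid}, \code{mrd_eoi}, \code{mrd_eoc} (fractions in [0,1], NA =
#'   not assessed) and optionally \code{assays} (comma-separated).
#' @return An \linkS4class{MRDCohort}.
#' @examples
#' coh <- MRDCohort(data.frame(patient_id = c("P1", "P2"),
#'                             mrd_mid = c(0.2, 0.01),
#'                             mrd_eoi = c(0.005, 0),
#'                             mrd_eoc = c(0.001, 0)))
#' responseLabels(coh, "eoi")
#' @export
MRDCohort <- function(patients) {
  p <- as(patients, "DataFrame")
  if (is.null(p$assays)) p$assays <- rep("", nrow(p))
  p$patient_id <- as.character(p$patient_id)
  new("MRDCohort", patients = p)
}

#' @describeIn MRDCohort Patient identifiers.
#' @param x An \code{MRDCohort}.
#' @export
setMethod("patientIDs", "MRDCohort", function(x) x@patients$patient_id)

#' @describeIn MRDCohort MRD fractions at one timepoint, named by patient.
#' @param timepoint One of \code{"mid"}, \code{"eoi"}, \code{"eoc"}.
#' @export
setMethod("mrdValues", "MRDCohort", function(x, timepoint) {
  timepoint <- match.arg(timepoint, c("mid", "eoi", "eoc"))
  setNames(x@patients[[paste0("mrd_", timepoint)]], x@patients$patient_id)
})

#' @describeIn MRDCohort Number of patients.
#' @export
setMethod("length", "MRDCohort", function(x) nrow(x@patients))

#' Assays available per patient
#' @param x An \code{MRDCohort}.
#' @return Named list of character vectors (subsets of wgs/array/panel/rnaseq).
#' @export
patientAssays <- function(x) {
  stopifnot(is(x, "MRDCohort"))
  setNames(strsplit(x@patients$assays, ",", fixed = TRUE), x@patients$patient_id)
}

setMethod("show", "MRDCohort", function(object) {
  cat("MRDCohort with", length(object), "patients\n")
  for (tp in c("mid", "eoi", "eoc")) {
    lab <- responseLabels(object, tp)
    tb <- table(lab, useNA = "no")
    cat(sprintf("  %-3s: %s (%d missing)\n", tp,
                paste(sprintf("%s=%d", names(tb), as.integer(tb)), collapse = " "),
                sum(is.na(lab))))
  }
})

#' Reference catalog of single-base-substitution signatures
#'
#' A 96 x S column-stochastic matrix of signature profiles over the canonical
#' pyrimidine-strand trinucleotide channels (6 substitution classes x 16
#' flanking contexts, COSMIC row order; see \code{\link{sbsContexts}}).
#'
#' @slot profiles Numeric matrix, 96 rows named by context (e.g.
#'   \code{"A[C>A]A"}), one column per signature; columns sum to 1.
#' @seealso \code{\link{fitExposures}}, \code{\link{syntheticSignatureCatalog}}
#' @export
setClass("SignatureCatalog", slots = c(profiles = "matrix"))

setValidity("SignatureCatalog", function(object) {
  m <- object@profiles
  if (nrow(m) != 96L) return("profile matrix must have exactly 96 rows")
  if (!identical(rownames(m), sbsContexts()))
    return("rows must be the 96 canonical contexts in COSMIC order")
  if (any(m < 0)) return("profiles must be non-negative")
  cs <- colSums(m)
  if (any(abs(cs - 1) > 1e-6))
    return("each signature column must sum to 1 (tolerance 1e-6)")
  if (is.null(colnames(m)) || anyDuplicated(colnames(m)))
    return("signatures must have unique column names")
  TRUE
})

#' Construct a SignatureCatalog
#'
#' Rows are matched and reordered by context label, so any row order in the
#' input is accepted.
#'
#' @param profiles Numeric matrix with 96 rows named like \code{"A[C>A]A"} and
#'   one named column per signature; columns must sum to 1.
#' @return A \linkS4class{SignatureCatalog}.
#' @export
SignatureCatalog <- function(profiles) {
  profiles <- as.matrix(profiles)
  ctx <- sbsContexts()
  if (is.null(rownames(profiles)) || !setequal(rownames(profiles), ctx))
    stop("profiles must have the 96 canonical context row labels")
  new("SignatureCatalog", profiles = profiles[ctx, , drop = FALSE])
}

#' @describeIn SignatureCatalog Signature names.
#' @param x A \code{SignatureCatalog}.
#' @export
setMethod("signatureNames", "SignatureCatalog", function(x) colnames(x@profiles))

#' @describeIn SignatureCatalog The 96 x S profile matrix.
#' @export
setMethod("profileMatrix", "SignatureCatalog", function(x) x@profiles)

setMethod("show", "SignatureCatalog", function(object) {
  cat("SignatureCatalog:", ncol(object@profiles), "signatures x 96 channels\n")
  cat(" ", paste(colnames(object@profiles), collapse = ", "), "\n")
})
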