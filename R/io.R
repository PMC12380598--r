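.write_tsv <- function(x, path, row.names = FALSE) {
  write.table(x, path, sep = "\t", quote = FALSE, row.names = row.names,
              col.names = TRUE)
}

.read_tsv <- function(path, ...) {
  if (!file.exists(path)) stop("file not found: ", path)
  read.delim(path, sep = "\t", stringsAsFactors = FALSE,
             na.strings = c("", "NA"), check.names = FALSE, ...)
}

.require_cols <- function(df, cols, path) {
  miss <- setdiff(cols, names(df))
  if (length(miss))
    stop("missing required column(s) in ", path, ": ",
         paste(miss, collapse = ", "))
}

#' Read / write an MRD table
#'
#' TSV with columns patient_id, mrd_mid, mrd_eoi, mrd_eoc (fractions in
#' [0,1]; empty = missing) and optionally assays (comma-separated).
#'
#' @param path File path.
#' @return \code{readMRD}: an \linkS4class{MRDCohort}.
#' @export
readMRD <- function(path) {
  df <- .read_tsv(path)
  .require_cols(df, c("patient_id", "mrd_mid", "mrd_eoi", "mrd_eoc"), path)
  MRDCohort(df)
}

#' @rdname readMRD
#' @param cohort An \linkS4class{MRDCohort}.
#' @export
writeMRD <- function(cohort, path) {
  .write_tsv(as.data.frame(cohort@patients), path)
  invisible(path)
}

#' Read / write CNV segment tables
#'
#' BED-derived TSV with columns chrom, start, end, patient_id, cnv_type,
#' source. On disk coordinates are 0-based half-open (BED convention); in
#' memory they are 1-based closed GRanges. Set \code{one_based = TRUE} for
#' 1-based inclusive input, converted by -1 on start.
#'
#' @param path File path.
#' @param one_based Input uses 1-based inclusive coordinates.
#' @return \code{readSegments}: a \code{GRanges} of CNV segments.
#' @export
readSegments <- function(path, one_based = FALSE) {
  df <- .read_tsv(path)
  .require_cols(df, c("chrom", "start", "end", "patient_id", "cnv_type",
                      "source"), path)
  start1 <- if (one_based) df$start else df$start + 1L
  gr <- GRanges(df$chrom, IRanges(start1, df$end))
  mcols(gr) <- DataFrame(df[setdiff(names(df), c("chrom", "start", "end"))])
  validateSegments(gr)
}

#' @rdname readSegments
#' @param segments \code{GRanges} of CNV segments.
#' @export
writeSegments <- function(segments, path) {
  df <- data.frame(chrom = as.character(seqnames(segments)),
                   start = start(segments) - 1L, end = end(segments),
                   as.data.frame(mcols(segments)))
  .write_tsv(df, path)
  invisible(path)
}

#' Read a BED file of intervals
#'
#' Minimal BED3(+) reader (0-based half-open on disk, 1-based GRanges in
#' memory); no track lines.
#'
#' @param path File path.
#' @return \code{GRanges}.
#' @export
readBED <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- read.delim(path, header = FALSE, stringsAsFactors = FALSE)
  GRanges(df[[1]], IRanges(df[[2]] + 1L, df[[3]]))
}

#' Read / write genome annotation files
#'
#' The annotation bundle is four TSVs in one directory:
#' \code{chrom_lengths.tsv} (chrom, length), \code{arms.tsv} (chrom, start,
#' end, arm; 0-based half-open), \code{genes.tsv} (chrom, start, end,
#' gene_id, expressed) and \code{blacklist.bed} (BED3).
#'
#' @param dir Directory path.
#' @return \code{readGenomeAnnotation}: a \linkS4class{GenomeAnnotation}.
#' @export
readGenomeAnnotation <- function(dir) {
  cl <- .read_tsv(file.path(dir, "chrom_lengths.tsv"))
  arms <- .read_tsv(file.path(dir, "arms.tsv"))
  genes <- .read_tsv(file.path(dir, "genes.tsv"))
  genes$expressed <- as.logical(genes$expressed)
  bl_path <- file.path(dir, "blacklist.bed")
  bl <- if (file.exists(bl_path)) readBED(bl_path) else GRanges()
  GenomeAnnotation(setNames(cl$length, cl$chrom), arms = arms, genes = genes,
                   blacklist = bl)
}

#' @rdname readGenomeAnnotation
#' @param annotation A \linkS4class{GenomeAnnotation}.
#' @export
writeGenomeAnnotation <- function(annotation, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  sl <- chromLengths(annotation)
  .write_tsv(data.frame(chrom = names(sl), length = unname(sl)),
             file.path(dir, "chrom_lengths.tsv"))
  arms <- chromArms(annotation)
  .write_tsv(data.frame(chrom = as.character(seqnames(arms)),
                        start = start(arms) - 1L, end = end(arms),
                        arm = arms$arm),
             file.path(dir, "arms.tsv"))
  g <- annotatedGenes(annotation)
  .write_tsv(data.frame(chrom = as.character(seqnames(g)),
                        start = start(g) - 1L, end = end(g),
                        gene_id = g$gene_id, expressed = g$expressed),
             file.path(dir, "genes.tsv"))
  bl <- blacklistRegions(annotation)
  if (length(bl))
    write.table(data.frame(as.character(seqnames(bl)), start(bl) - 1L, end(bl)),
                file.path(dir, "blacklist.bed"), sep = "\t", quote = FALSE,
                row.names = FALSE, col.names = FALSE)
  invisible(dir)
}

#' Read / write variant call tables
#'
#' Flat TSV with columns patient_id, gene, variant_class, coding.
#'
#' @param path File path.
#' @return \code{readVariants}: data.frame of variant calls.
#' @export
readVariants <- function(path) {
  df <- .read_tsv(path)
  .require_cols(df, c("patient_id", "gene", "variant_class", "coding"), path)
  df$coding <- as.logical(df$coding)
  df
}

#' @rdname readVariants
#' @param variants data.frame of variant calls.
#' @export
writeVariants <- function(variants, path) {
  .write_tsv(variants, path)
  invisible(path)
}

#' Read SNVs for context counting
#'
#' Either a TSV (sample_id, chrom, pos, ref, alt; 1-based positions) or a
#' minimal VCF 4.x subset (one substitution per row; the sample id taken
#' from an \code{INFO} key \code{SAMPLE=}).
#'
#' @param path File path.
#' @param format \code{"tsv"} (default, by extension) or \code{"vcf"}.
#' @return data.frame(sample_id, chrom, pos, ref, alt).
#' @export
readSNVs <- function(path, format = c("auto", "tsv", "vcf")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "auto")
    format <- if (grepl("\\.vcf$", path, ignore.case = TRUE)) "vcf" else "tsv"
  if (format == "tsv") {
    df <- .read_tsv(path)
    .require_cols(df, c("sample_id", "chrom", "pos", "ref", "alt"), path)
    return(df)
  }
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "##")]
  if (!length(lines) || !startsWith(lines[1], "#CHROM"))
    stop("not a VCF: missing #CHROM header in ", path)
  if (length(lines) == 1L)
    return(data.frame(sample_id = character(), chrom = character(),
                      pos = integer(), ref = character(), alt = character()))
  f <- strsplit(lines[-1], "\t", fixed = TRUE)
  info <- vapply(f, `[`, character(1), 8L)
  sm <- sub(".*SAMPLE=([^;]+).*", "\\1", info)
  data.frame(sample_id = sm,
             chrom = vapply(f, `[`, character(1), 1L),
             pos = as.integer(vapply(f, `[`, character(1), 2L)),
             ref = vapply(f, `[`, character(1), 4L),
             alt = vapply(f, `[`, character(1), 5L))
}

#' Write SNVs as a minimal VCF
#'
#' @param snvs data.frame(sample_id, chrom, pos, ref, alt).
#' @param path Output path.
#' @export
writeSNVsVcf <- function(snvs, path) {
  hdr <- c("##fileformat=VCFv4.2",
           "##INFO=<ID=SAMPLE,Number=1,Type=String,Description=\"Sample id\">",
           paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
                 sep = "\t"))
  body <- paste(snvs$chrom, snvs$pos, ".", snvs$ref, snvs$alt, ".", "PASS",
                paste0("SAMPLE=", snvs$sample_id), sep = "\t")
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Read / write a counts matrix
#'
#' TSV, first column \code{gene} then one column per sample.
#'
#' @param path File path.
#' @return \code{readCounts}: integer matrix, genes x samples.
#' @export
readCounts <- function(path) {
  df <- .read_tsv(path)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  storage.mode(m) <- "numeric"
  m
}

#' @rdname readCounts
#' @param counts Matrix, genes x samples.
#' @export
writeCounts <- function(counts, path) {
  .write_tsv(data.frame(gene = rownames(counts), counts, check.names = FALSE),
             path)
  invisible(path)
}

#' Read / write gene sets in GMT format
#'
#' @param path File path.
#' @return \code{readGMT}: named list of character vectors.
#' @export
readGMT <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  out <- lapply(strsplit(lines, "\t", fixed = TRUE), function(f)
    f[-(1:2)])
  names(out) <- vapply(strsplit(lines, "\t", fixed = TRUE), `[`, character(1), 1L)
  out
}

#' @rdname readGMT
#' @param sets Named list of character vectors.
#' @export
writeGMT <- function(sets, path) {
  writeLines(vapply(names(sets), function(nm)
    paste(c(nm, "na", sets[[nm]]), collapse = "\t"), character(1)), path)
  invisible(path)
}

#' Read / write a signature catalog
#'
#' TSV with first column \code{context} (labels like \code{"A[C>A]A"}; any
#' row order, reordered on read) and one column per signature.
#'
#' @param path File path.
#' @return \code{readSignatures}: a \linkS4class{SignatureCatalog}.
#' @export
readSignatures <- function(path) {
  df <- .read_tsv(path)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  SignatureCatalog(m)
}

#' @rdname readSignatures
#' @param signatures A \linkS4class{SignatureCatalog}.
#' @export
writeSignatures <- function(signatures, path) {
  m <- profileMatrix(signatures)
  .write_tsv(data.frame(context = rownames(m), m, check.names = FALSE), path)
  invisible(path)
}

#' Write / read a simulated cohort bundle
#'
#' Serializes every component of a \code{\link{simulateCohort}} bundle into
#' the plain-text formats the readers consume, plus \code{truth.json}
#' recording the planted parameters.
#'
#' @param bundle A cohort bundle list.
#' @param dir Directory (created if needed).
#' @return \code{readCohortBundle}: the bundle list (without \code{truth}'s
#'   non-serializable pieces re-typed; matrices come back as written).
#' @export
writeCohortBundle <- function(bundle, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  writeMRD(bundle$cohort, file.path(dir, "mrd.tsv"))
  writeGenomeAnnotation(bundle$annotation, file.path(dir, "annotation"))
  for (src in unique(bundle$segments$source))
    writeSegments(bundle$segments[bundle$segments$source == src],
                  file.path(dir, paste0("segments_", src, ".tsv")))
  writeVariants(bundle$variants, file.path(dir, "variants.tsv"))
  .write_tsv(bundle$snvs, file.path(dir, "snvs.tsv"))
  writeXStringSet(bundle$reference, file.path(dir, "reference.fa"))
  writeCounts(bundle$counts, file.path(dir, "counts.tsv"))
  writeGMT(bundle$gene_sets, file.path(dir, "gene_sets.gmt"))
  .write_tsv(bundle$screens, file.path(dir, "screens.tsv"))
  truth <- bundle$truth
  truth$true_exposures <- as.data.frame(truth$true_exposures)
  jsonlite::write_json(truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}

#' @rdname writeCohortBundle
#' @export
readCohortBundle <- function(dir) {
  seg_files <- list.files(dir, "^segments_.*\\.tsv$", full.names = TRUE)
  segs <- do.call(c, lapply(seg_files, readSegments))
  list(cohort = readMRD(file.path(dir, "mrd.tsv")),
       annotation = readGenomeAnnotation(file.path(dir, "annotation")),
       segments = sort(segs),
       variants = readVariants(file.path(dir, "variants.tsv")),
       snvs = .read_tsv(file.path(dir, "snvs.tsv")),
       reference = readDNAStringSet(file.path(dir, "reference.fa")),
       counts = readCounts(file.path(dir, "counts.tsv")),
       gene_sets = readGMT(file.path(dir, "gene_sets.gmt")),
       screens = .read_tsv(file.path(dir, "screens.tsv")),
       truth = jsonlite::read_json(file.path(dir, "truth.json")))
}
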