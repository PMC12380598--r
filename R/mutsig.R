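#' Canonical 96 trinucleotide substitution channels
#'
#' The conventional COSMIC SBS row order: the six pyrimidine-strand
#' substitution classes (C>A, C>G, C>T, T>A, T>C, T>G), each with its 16
#' flanking-base contexts in alphabetical order.
#'
#' @return Character vector of 96 labels like \code{"A[C>A]A"}.
#' @export
sbsContexts <- function() {
  subs <- c("C>A", "C>G", "C>T", "T>A", "T>C", "T>G")
  bases <- c("A", "C", "G", "T")
  unlist(lapply(subs, function(s)
    as.vector(t(outer(bases, bases, function(f5, f3)
      paste0(f5, "[", s, "]", f3))))))
}

.complement <- c(A = "T", C = "G", G = "C", T = "A")

.revcomp3 <- function(tri) {
  # reverse complement of 3-mers, vectorized on character
  vapply(strsplit(tri, ""), function(b)
    paste0(.complement[b[3]], .complement[b[2]], .complement[b[1]]),
    character(1))
}

#' Build 96-channel mutation catalogs from SNVs and a reference
#'
#' Each SNV is placed in its pyrimidine-strand trinucleotide context: the
#' reference trinucleotide around the site is read from the FASTA, and
#' purine-reference variants (A or G) are reverse-complemented to the
#' pyrimidine strand before binning, so that e.g. a G>T call with flanks
#' T_G_C lands in channel \code{G[C>A]A}.
#'
#' Record-level problems are collected, reported via a warning and returned
#' in the \code{errors} attribute: reference-base mismatches against the
#' FASTA, positions at a contig edge (no flanking base) and unknown contigs.
#'
#' @param snvs data.frame with columns \code{sample_id}, \code{chrom},
#'   \code{pos} (1-based), \code{ref}, \code{alt} (single bases).
#' @param reference A named \link[Biostrings]{DNAStringSet} (names =
#'   contigs) or the path to a FASTA file.
#' @param samples Sample universe for the catalog columns; defaults to the
#'   samples present in \code{snvs}.
#' @return Integer matrix, 96 channels x samples, with the canonical
#'   \code{\link{sbsContexts}} row order. Attribute \code{errors} is a
#'   data.frame of skipped records (possibly empty).
#' @export
countContexts <- function(snvs, reference, samples = NULL) {
  if (is.character(reference) && length(reference) == 1L)
    reference <- readDNAStringSet(reference)
  names(reference) <- sub("\\s.*$", "", names(reference))
  need <- c("sample_id", "chrom", "pos", "ref", "alt")
  miss <- setdiff(need, names(snvs))
  if (length(miss)) stop("snvs lack column(s): ", paste(miss, collapse = ", "))
  if (is.null(samples)) samples <- sort(unique(as.character(snvs$sample_id)))
  ctx <- sbsContexts()
  out <- matrix(0L, 96L, length(samples), dimnames = list(ctx, samples))
  if (!nrow(snvs)) return(structure(out, errors = data.frame()))

  chrom <- as.character(snvs$chrom)
  pos <- as.integer(snvs$pos)
  ref <- toupper(as.character(snvs$ref))
  alt <- toupper(as.character(snvs$alt))
  err <- character(nrow(snvs))

  known <- chrom %in% names(reference)
  err[!known] <- "unknown contig"
  lens <- setNames(Biostrings::width(reference), names(reference))
  edge <- known & (pos < 2L | pos > lens[chrom] - 1L)
  err[edge] <- "contig edge"
  ok <- known & !edge
  tri <- rep(NA_character_, nrow(snvs))
  for (cc in unique(chrom[ok])) {
    i <- which(ok & chrom == cc)
    seq_str <- as.character(reference[[cc]])
    tri[i] <- substring(seq_str, pos[i] - 1L, pos[i] + 1L)
  }
  mism <- ok & substring(tri, 2L, 2L) != ref
  err[mism] <- "ref mismatch"
  ok <- ok & !mism
  badalt <- ok & (!alt %in% c("A", "C", "G", "T") | alt == ref)
  err[badalt] <- "invalid alt"
  ok <- ok & !badalt

  if (any(ok)) {
    pur <- ok & ref %in% c("A", "G")
    tri[pur] <- .revcomp3(tri[pur])
    ref[pur] <- .complement[ref[pur]]
    alt[pur] <- .complement[alt[pur]]
    channel <- paste0(substring(tri, 1L, 1L), "[", ref, ">", alt, "]",
                      substring(tri, 3L, 3L))
    ci <- match(channel[ok], ctx)
    si <- match(as.character(snvs$sample_id)[ok], samples)
    tb <- table(factor(ci, levels = seq_len(96L)),
                factor(si, levels = seq_along(samples)))
    out <- out + matrix(as.integer(tb), 96L, length(samples),
                        dimnames = dimnames(out))
  }
  errors <- data.frame(row = which(err != ""), chrom = chrom[err != ""],
                       pos = pos[err != ""], reason = err[err != ""])
  if (nrow(errors))
    warning(nrow(errors), " SNV record(s) skipped (",
            paste(unique(errors$reason), collapse = ", "), ")")
  structure(out, errors = errors)
}

#' Synthetic reference signature catalog
#'
#' A small, fully synthetic stand-in for a reference SBS catalog, built from
#' the well-known dominant channels of the signatures discussed in ALL
#' genomics: an SBS1-like clock signature (C>T at NpCpG), SBS2-like and
#' SBS13-like APOBEC signatures (C>T and C>G at TpCpN), a broad SBS8-like
#' C>A signature, and a flat background. These are not the COSMIC profiles;
#' they share only the headline channel structure and are intended for
#' simulation, testing and method illustration. Real catalogs can be loaded
#' with \code{\link{readSignatures}}.
#'
#' @return A \linkS4class{SignatureCatalog} with columns SBS1, SBS2, SBS8,
#'   SBS13, FLAT.
#' @export
syntheticSignatureCatalog <- function() {
  ctx <- sbsContexts()
  mk <- function(peaks, flat_mass) {
    v <- rep(flat_mass / 96, 96)
    names(v) <- ctx
    v[names(peaks)] <- v[names(peaks)] + peaks
    v / sum(v)
  }
  sbs1 <- mk(setNames(rep(0.22, 4), c("A[C>T]G", "C[C>T]G", "G[C>T]G", "T[C>T]G")), 0.12)
  sbs2 <- mk(c("T[C>T]A" = 0.25, "T[C>T]C" = 0.25, "T[C>T]T" = 0.35), 0.15)
  sbs13 <- mk(c("T[C>G]A" = 0.25, "T[C>G]C" = 0.20, "T[C>G]T" = 0.40), 0.15)
  ca <- grep("C>A", ctx, fixed = TRUE, value = TRUE)
  sbs8 <- mk(setNames(rep(0.7 / 16, 16), ca), 0.3)
  flat <- rep(1 / 96, 96); names(flat) <- ctx
  SignatureCatalog(cbind(SBS1 = sbs1, SBS2 = sbs2, SBS8 = sbs8,
                         SBS13 = sbs13, FLAT = flat))
}

.cosine_dist <- function(a, b) {
  na <- sqrt(sum(a^2)); nb <- sqrt(sum(b^2))
  if (na == 0 || nb == 0) return(1)
  1 - sum(a * b) / (na * nb)
}

#' Refit signature exposures by non-negative least squares
#'
#' Solves \eqn{\min_w \|y - S w\|_2} subject to \eqn{w \ge 0} for each
#' sample catalog \eqn{y} against the signature profile matrix \eqn{S}
#' (Lawson-Hanson NNLS). Contribution fractions are the normalized weights;
#' the reconstruction residual is reported as the cosine distance between
#' the catalog and its reconstruction.
#'
#' @param catalog 96-vector or 96 x N matrix of channel counts (rows in
#'   canonical order or named by context).
#' @param signatures A \linkS4class{SignatureCatalog}.
#' @return List with \code{weights} (signatures x samples),
#'   \code{fractions} (columns sum to 1 for non-empty catalogs),
#'   \code{residual} (cosine distance per sample) and \code{empty} (logical:
#'   zero catalogs, flagged and given zero exposures).
#' @export
fitExposures <- function(catalog, signatures) {
  stopifnot(is(signatures, "SignatureCatalog"))
  S <- profileMatrix(signatures)
  if (is.null(dim(catalog))) catalog <- matrix(catalog, ncol = 1,
                                               dimnames = list(names(catalog), "sample1"))
  if (nrow(catalog) != 96L) stop("catalog must have 96 rows")
  if (!is.null(rownames(catalog))) {
    if (!setequal(rownames(catalog), rownames(S)))
      stop("catalog row labels do not match the 96 canonical contexts")
    catalog <- catalog[rownames(S), , drop = FALSE]
  }
  if (any(catalog < 0)) stop("catalog counts must be non-negative")
  ns <- ncol(S)
  W <- matrix(0, ns, ncol(catalog),
              dimnames = list(colnames(S), colnames(catalog)))
  resid <- setNames(rep(NA_real_, ncol(catalog)), colnames(catalog))
  empty <- setNames(colSums(catalog) == 0, colnames(catalog))
  for (j in seq_len(ncol(catalog))) {
    y <- catalog[, j]
    if (empty[j]) { resid[j] <- 0; next }
    W[, j] <- pracma::lsqnonneg(S, y)$x
    resid[j] <- .cosine_dist(y, as.vector(S %*% W[, j]))
  }
  fr <- W
  tot <- colSums(W)
  nz <- tot > 0
  fr[, nz] <- sweep(W[, nz, drop = FALSE], 2, tot[nz], "/")
  list(weights = W, fractions = fr, residual = resid, empty = empty)
}

#' Correlate signature exposures with MRD
#'
#' Spearman rank correlation between per-sample signature contribution
#' fractions and MRD at a chosen timepoint; samples with missing MRD are
#' dropped.
#'
#' @param exposures Result of \code{\link{fitExposures}}, or a fractions
#'   matrix (signatures x samples, columns named by patient).
#' @param cohort An \linkS4class{MRDCohort}.
#' @param timepoint \code{"mid"} (default; the timepoint where APOBEC
#'   exposure association is strongest), \code{"eoi"} or \code{"eoc"}.
#' @return data.frame with \code{signature}, \code{rho}, \code{p}, \code{n}.
#' @export
exposureMrdCorrelation <- function(exposures, cohort, timepoint = "mid") {
  fr <- if (is.list(exposures)) exposures$fractions else exposures
  mrd <- mrdValues(cohort, timepoint)
  common <- intersect(colnames(fr), names(mrd)[!is.na(mrd)])
  if (length(common) < 3) stop("need >= 3 samples with both exposure and MRD")
  do.call(rbind, lapply(rownames(fr), function(sig) {
    ct <- spearmanCor(fr[sig, common], mrd[common])
    data.frame(signature = sig, rho = ct$rho, p = ct$p.value, n = ct$n)
  }))
}
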