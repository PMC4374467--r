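#' Read a rotated-layout cross file
#'
#' Layout: row 1 marker names (after the `id`, `sex`, `cross_direction`
#' columns), row 2 chromosome per marker, row 3 cM position, then one row
#' per individual with genotype codes `A` (homozygote), `H`
#' (heterozygote), `-` (missing).
#'
#' @param path CSV file path.
#' @return a [Backcross-class].
#' @export
readCross <- function(path) {
  raw <- read.csv(path, header = TRUE, stringsAsFactors = FALSE,
                  check.names = FALSE, colClasses = "character")
  fixed <- c("id", "sex", "cross_direction")
  if (!identical(names(raw)[1:3], fixed)) {
    stop("first three columns must be id, sex, cross_direction")
  }
  markers <- names(raw)[-(1:3)]
  if (anyDuplicated(markers)) stop("duplicate marker names")
  chr <- as.character(raw[1, -(1:3)])
  pos <- as.numeric(raw[2, -(1:3)])
  map <- GeneticMap(markers, chr, pos)
  if (!identical(map@markers$marker, markers)) {
    stop("markers are not ordered by chromosome and increasing cM position")
  }
  body <- raw[-(1:2), , drop = FALSE]
  codes <- as.matrix(body[, -(1:3), drop = FALSE])
  bad <- which(matrix(!(codes %in% c("A", "H", "-")), nrow(codes)), arr.ind = TRUE)
  if (nrow(bad)) {
    stop(sprintf("invalid genotype code '%s' for individual %s, marker %s",
                 codes[bad[1, 1], bad[1, 2]], body$id[bad[1, 1]],
                 markers[bad[1, 2]]))
  }
  geno <- matrix(NA_integer_, nrow(codes), ncol(codes),
                 dimnames = list(body$id, markers))
  geno[codes == "A"] <- 0L
  geno[codes == "H"] <- 1L
  covars <- data.frame(sex = as.integer(body$sex),
                       cross_direction = as.integer(body$cross_direction),
                       row.names = body$id)
  Backcross(map, geno, covars)
}

#' @rdname readCross
#' @param cross a [Backcross-class].
#' @export
writeCross <- function(cross, path) {
  m <- cross@map@markers
  codes <- matrix("-", nrow(cross@geno), ncol(cross@geno))
  codes[!is.na(cross@geno) & cross@geno == 0L] <- "A"
  codes[!is.na(cross@geno) & cross@geno == 1L] <- "H"
  hdr <- rbind(c("", "", "", m$chr),
               c("", "", "", format(m$pos, digits = 12, trim = TRUE)))
  body <- cbind(rownames(cross@geno),
                as.character(cross@covariates$sex),
                as.character(cross@covariates$cross_direction), codes)
  out <- rbind(hdr, body)
  colnames(out) <- c("id", "sex", "cross_direction", m$marker)
  write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read/write landmark coordinates in long CSV form
#'
#' Columns: `specimen_id`, `landmark`, `x`, `y`, `z` (mm).  Landmark order
#' follows first appearance; every specimen must carry every landmark.
#'
#' @param path CSV file path.
#' @return k x 3 x n array with dimnames (landmark, axis, specimen).
#' @export
readLandmarks <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  lms <- unique(df$landmark)
  ids <- unique(df$specimen_id)
  arr <- array(NA_real_, c(length(lms), 3, length(ids)),
               dimnames = list(lms, c("x", "y", "z"), ids))
  idx <- cbind(match(df$landmark, lms), match(df$specimen_id, ids))
  for (a in 1:3) arr[cbind(idx[, 1], a, idx[, 2])] <- df[[c("x", "y", "z")[a]]]
  if (anyNA(arr)) stop("missing landmark/specimen combinations")
  arr
}

#' @rdname readLandmarks
#' @param coords k x 3 x n landmark array.
#' @export
writeLandmarks <- function(coords, path) {
  k <- dim(coords)[1]; n <- dim(coords)[3]
  dn <- dimnames(coords)
  lms <- if (!is.null(dn[[1]])) dn[[1]] else paste0("L", seq_len(k))
  ids <- if (!is.null(dn[[3]])) dn[[3]] else sprintf("spec%03d", seq_len(n))
  df <- data.frame(
    specimen_id = rep(ids, each = k), landmark = rep(lms, n),
    x = as.vector(coords[, 1, ]), y = as.vector(coords[, 2, ]),
    z = as.vector(coords[, 3, ]))
  for (cl in c("x", "y", "z")) df[[cl]] <- signif(df[[cl]], 12)
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read/write the symmetry and region metadata file
#'
#' JSON with fields `pairs` (list of 0-based (left, right) index pairs),
#' `midline` (0-based indices) and `regions` (landmark label -> list of
#' region names).  Indices are converted to 1-based internally.
#'
#' @param path JSON file path.
#' @param landmarks landmark labels, in array order.
#' @return list: `sym` (a [SymmetryMap-class]), `regions`
#'   (a [RegionMap-class] or NULL).
#' @export
readShapeMetadata <- function(path, landmarks = NULL) {
  j <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  pairs <- matrix(as.integer(as.matrix(j$pairs)), ncol = 2) + 1L
  sym <- SymmetryMap(pairs, as.integer(j$midline) + 1L)
  regions <- NULL
  if (!is.null(j$regions)) {
    if (is.null(landmarks)) landmarks <- names(j$regions)
    regions <- RegionMap(lapply(landmarks, function(lm) j$regions[[lm]]))
  }
  list(sym = sym, regions = regions)
}

#' @rdname readShapeMetadata
#' @param sym a [SymmetryMap-class].
#' @param regions optional [RegionMap-class].
#' @export
writeShapeMetadata <- function(sym, path, regions = NULL, landmarks = NULL) {
  out <- list(pairs = unname(sym@pairs - 1L), midline = sym@midline - 1L)
  if (!is.null(regions)) {
    if (is.null(landmarks)) landmarks <- paste0("L", seq_along(regions@regions))
    out$regions <- setNames(regions@regions, landmarks)
  }
  jsonlite::write_json(out, path, auto_unbox = FALSE)
  invisible(path)
}

#' Write a complete synthetic fixture bundle
#'
#' Emits the cross CSV, long landmark CSV, metadata JSON, covariate CSV,
#' anchor CSV and ground-truth JSON into a directory; all numeric text at
#' 12 significant digits, so a read-back round trip reproduces the arrays.
#'
#' @param dir output directory (created if needed).
#' @param cross a [Backcross-class].
#' @param coords k x 3 x n landmark array.
#' @param sym a [SymmetryMap-class].
#' @param covariates covariate data.frame.
#' @param regions optional [RegionMap-class].
#' @param anchors optional anchor data.frame.
#' @param truth optional ground-truth list (serialized as JSON).
#' @return the directory path, invisibly.
#' @export
writeFixtureBundle <- function(dir, cross, coords, sym, covariates,
                               regions = NULL, anchors = NULL, truth = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  writeCross(cross, file.path(dir, "cross.csv"))
  writeLandmarks(coords, file.path(dir, "landmarks.csv"))
  writeShapeMetadata(sym, file.path(dir, "metadata.json"), regions = regions,
                     landmarks = dimnames(coords)[[1]])
  cv <- data.frame(id = rownames(covariates), covariates, row.names = NULL)
  write.csv(cv, file.path(dir, "covariates.csv"), row.names = FALSE, quote = FALSE)
  if (!is.null(anchors)) {
    write.csv(anchors, file.path(dir, "anchors.csv"), row.names = FALSE, quote = FALSE)
  }
  if (!is.null(truth)) {
    jsonlite::write_json(truth, file.path(dir, "truth.json"),
                         auto_unbox = TRUE, digits = NA, force = TRUE)
  }
  invisible(dir)
}

#' Export a scan result as CSV
#' @param scan a [ScanResult-class].
#' @param path output CSV path.
#' @export
writeScanResult <- function(scan, path) {
  write.csv(scan@table, path, row.names = FALSE)
  invisible(path)
}

#' Export a permutation result (maxima CSV + summary JSON)
#' @param perm a [PermutationResult-class].
#' @param path output path stem; writes `<path>.csv` and `<path>.json`.
#' @export
writePermutationResult <- function(perm, path) {
  write.csv(data.frame(max_score = perm@maxima), paste0(path, ".csv"),
            row.names = FALSE)
  jsonlite::write_json(
    list(alpha = perm@alpha, threshold = perm@threshold,
         n_perm = length(perm@maxima), seed = perm@seed),
    paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Export credible intervals as BED (0-based half-open)
#'
#' @param intervals data.frame from [qtlIntervals()] with bp bounds.
#' @param path output BED path.
#' @export
writeIntervalsBed <- function(intervals, path) {
  if (is.null(intervals$lower_bp)) stop("intervals need bp bounds")
  bed <- data.frame(chrom = intervals$chr,
                    start = format(round(intervals$lower_bp - 1), scientific = FALSE, trim = TRUE),
                    end = format(round(intervals$upper_bp), scientific = FALSE, trim = TRUE),
                    name = sprintf("qtl_%s_%.6gcM", intervals$chr, intervals$pos))
  utils::write.table(bed, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Export a per-landmark displacement field as CSV
#'
#' @param displacement k x 3 matrix (e.g. from [backTransform()]).
#' @param path output CSV path.
#' @export
writeDisplacements <- function(displacement, path) {
  df <- data.frame(landmark = rownames(displacement),
                   dx = displacement[, 1], dy = displacement[, 2],
                   dz = displacement[, 3],
                   magnitude = sqrt(rowSums(displacement^2)),
                   row.names = NULL)
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Tabular report of a fitted multiple-QTL model
#'
#' One row per QTL with its position, closest marker, conditional logP and
#' credible interval (cM and, when available, bp) -- the usual mapping
#' table layout.
#'
#' @param model a [QTLModel-class] from [fitQTLModel()] or the searches.
#' @param intervals data.frame from [qtlIntervals()] for the same loci.
#' @param map a [GeneticMap-class] (for the closest marker).
#' @return data.frame, one row per QTL.
#' @export
qtlReport <- function(model, intervals, map) {
  loci <- model@loci
  if (!nrow(loci)) return(data.frame())
  tt <- model@termTests
  out <- do.call(rbind, lapply(seq_len(nrow(loci)), function(j) {
    mc <- map@markers[map@markers$chr == loci$chr[j], , drop = FALSE]
    closest <- mc$marker[which.min(abs(mc$pos - loci$pos[j]))]
    term <- sprintf("QTL_%s@%.6g", loci$chr[j], loci$pos[j])
    iv <- intervals[intervals$chr == loci$chr[j] &
                      abs(intervals$pos - loci$pos[j]) < 1e-6, , drop = FALSE]
    data.frame(qtl = sprintf("qtl%d", j), closest_marker = closest,
               chr = loci$chr[j], pos_cM = loci$pos[j],
               logP = tt$logP[match(term, tt$term)],
               lower_cM = if (nrow(iv)) iv$lower[1] else NA_real_,
               upper_cM = if (nrow(iv)) iv$upper[1] else NA_real_,
               lower_bp = if (nrow(iv) && !is.null(iv$lower_bp)) iv$lower_bp[1] else NA_real_,
               upper_bp = if (nrow(iv) && !is.null(iv$upper_bp)) iv$upper_bp[1] else NA_real_,
               stringsAsFactors = FALSE)
  }))
  out
}
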