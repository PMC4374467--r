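#' Read a gene annotation
#'
#' Accepts a BED file (0-based half-open; converted to 1-based inclusive)
#' or a 4-column CSV (`symbol`, `chr`, `start`, `end`, already 1-based
#' inclusive).
#'
#' @param path file path.
#' @param format "bed" or "csv" (guessed from the extension by default).
#' @return data.frame: `symbol`, `chr`, `start`, `end` (1-based inclusive).
#' @export
readGeneAnnotation <- function(path, format = c("auto", "bed", "csv")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.bed$", path, ignore.case = TRUE)) "bed" else "csv"
  }
  if (format == "bed") {
    gr <- rtracklayer::import(path, format = "BED")
    df <- data.frame(symbol = gr$name,
                     chr = as.character(GenomicRanges::seqnames(gr)),
                     start = GenomicRanges::start(gr),  # import is 1-based inclusive
                     end = GenomicRanges::end(gr),
                     stringsAsFactors = FALSE)
  } else {
    df <- read.csv(path, stringsAsFactors = FALSE)
    names(df)[1:4] <- c("symbol", "chr", "start", "end")
  }
  if (any(df$start > df$end)) stop("gene start must be <= end")
  if (anyDuplicated(df$symbol)) stop("gene symbols must be unique")
  df
}

#' Genes overlapping QTL credible intervals
#'
#' A gene is a candidate when its span overlaps any interval by at least
#' 1 bp (`rule = "any"`) or is fully contained in one (`rule = "within"`);
#' genes spanning several intervals count once.
#'
#' @param annotation data.frame from [readGeneAnnotation()] (1-based
#'   inclusive `start`/`end`).
#' @param intervals data.frame with `chr`, `lower_bp`, `upper_bp`
#'   (e.g. from [qtlIntervals()] with anchors).
#' @param rule overlap rule, "any" (default) or "within".
#' @return character vector of candidate gene symbols.
#' @export
genesInIntervals <- function(annotation, intervals, rule = c("any", "within")) {
  rule <- match.arg(rule)
  if (is.null(intervals$lower_bp) || is.null(intervals$upper_bp) ||
      anyNA(intervals$lower_bp) || anyNA(intervals$upper_bp)) {
    stop("intervals need bp bounds; convert cM endpoints with cmToBp() first")
  }
  genes <- GenomicRanges::GRanges(annotation$chr,
                                  IRanges::IRanges(annotation$start, annotation$end))
  ivs <- GenomicRanges::GRanges(as.character(intervals$chr),
                                IRanges::IRanges(intervals$lower_bp, intervals$upper_bp))
  hits <- GenomicRanges::findOverlaps(genes, ivs,
                                      type = if (rule == "any") "any" else "within")
  unique(annotation$symbol[S4Vectors::queryHits(hits)])
}

#' Hypergeometric enrichment of a training gene set in QTL intervals
#'
#' Exact upper-tail probability P(X >= k) of drawing at least k training
#' genes when n candidate genes are drawn from a genome of N genes
#' containing K training genes.
#'
#' @param N genes in the genome background.
#' @param K training genes in the background.
#' @param n candidate genes found in the intervals.
#' @param k training genes among the candidates.
#' @return list: `N`, `K`, `n`, `k`, `p` (upper tail), `expected`
#'   (expected overlap n*K/N), `foldEnrichment`.
#' @export
hypergeomEnrichment <- function(N, K, n, k) {
  if (!(k >= 0 && k <= min(K, n) && n <= N && K <= N)) {
    stop("inconsistent counts: need 0 <= k <= min(K, n) <= N")
  }
  p <- phyper(k - 1, K, N - K, n, lower.tail = FALSE)
  exp0 <- n * K / N
  list(N = N, K = K, n = n, k = k, p = p, expected = exp0,
       foldEnrichment = if (exp0 > 0) k / exp0 else NA_real_)
}

#' Full interval-to-enrichment pipeline
#'
#' Collects candidate genes in the intervals, counts how many are in the
#' training list, and runs the hypergeometric test against a background of
#' `N` genome genes.
#'
#' @inheritParams genesInIntervals
#' @param training character vector of training gene symbols.
#' @param N background gene count (the number of known genes on the
#'   mapped chromosomes); defaults to `nrow(annotation)`.
#' @return list: `candidates`, `overlap` (candidate training genes), and
#'   the fields of [hypergeomEnrichment()].
#' @export
enrichmentTest <- function(annotation, intervals, training,
                           N = nrow(annotation), rule = "any") {
  cand <- genesInIntervals(annotation, intervals, rule = rule)
  ov <- intersect(cand, training)
  res <- hypergeomEnrichment(N = N, K = length(unique(training)),
                             n = length(cand), k = length(ov))
  c(list(candidates = cand, overlap = ov), res)
}
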