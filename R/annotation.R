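#' @importFrom GenomicRanges findOverlaps seqnames start end
#' @importFrom S4Vectors queryHits subjectHits
NULL

.strip_chr <- function(x) sub("^chr", "", as.character(x))

#' Build an overlap index over retroelement loci
#'
#' Wraps a validated locus `GRanges` (from [readAnnotation()] or built in
#' code) for point queries. Overlap queries are served by the nested
#' containment list behind `GenomicRanges::findOverlaps`, i.e. O(log n + k)
#' per query. An empty annotation is valid and returns no hits.
#'
#' @param loci `GRanges` with mcols `locus_id`, `family`, `class`.
#' @return The index object consumed by [annotateProbes()].
#' @export
buildIntervalIndex <- function(loci) {
  stopifnot(is(loci, "GRanges"))
  need <- c("locus_id", "family", "class")
  miss <- setdiff(need, names(mcols(loci)))
  if (length(miss))
    stop("loci need mcols: ", paste(miss, collapse = ", "))
  if (anyDuplicated(mcols(loci)$locus_id))
    stop("duplicated locus ids in annotation")
  if (!all(mcols(loci)$class %in% CLASS_VOCAB))
    stop("locus class outside the vocabulary ",
         paste(CLASS_VOCAB, collapse = "/"))
  structure(list(loci = loci), class = "RetroIndex")
}

#' Annotate probes to retroelement loci
#'
#' A probe is annotated to a locus iff its (single-base, 1-based) cytosine
#' coordinate lies within `[start, end]` on the same chromosome. Strand is
#' ignored: methylation at a CpG is measured on both strands and locus
#' containment of a point is strand-symmetric. Probes hitting several loci
#' keep all hits (deduplicated by locus id).
#'
#' Chromosome naming must agree between probes and loci
#' (`chr1` vs `1` is a hard error) unless `chr_alias = TRUE`, which
#' normalizes both sides by stripping a leading `"chr"`.
#'
#' @param probes `GRanges` of width-1 probe positions with mcol `probe_id`
#'   (see [readManifest()]).
#' @param index Index from [buildIntervalIndex()], or a locus `GRanges`.
#' @param chr_alias Normalize `chr` prefixes before matching
#'   (default `FALSE`, i.e. mismatched conventions are an error).
#' @return A `DataFrame`, one row per probe: `probe_id`, `is_retro`,
#'   `n_hits`, and list-columns `hits`, `hit_families`, `hit_classes`.
#'   `metadata(x)$report` holds the annotated count and the fraction of the
#'   manifest annotated.
#' @export
annotateProbes <- function(probes, index, chr_alias = FALSE) {
  if (is(index, "GRanges")) index <- buildIntervalIndex(index)
  stopifnot(inherits(index, "RetroIndex"), is(probes, "GRanges"))
  loci <- index$loci
  pchr <- as.character(seqnames(probes))
  lchr <- as.character(seqnames(loci))
  if (chr_alias) {
    pchr <- .strip_chr(pchr)
    lchr <- .strip_chr(lchr)
  } else if (length(probes) && length(loci)) {
    p_has <- grepl("^chr", pchr)
    l_has <- grepl("^chr", lchr)
    if ((all(p_has) && !any(l_has)) || (!any(p_has) && all(l_has)))
      stop("chromosome naming mismatch between probes and loci ",
           "('chr1' vs '1'); set chr_alias = TRUE to normalize")
  }
  # strand- and naming-agnostic overlap on normalized copies
  p2 <- GRanges(pchr, IRanges(start(probes), width = 1L))
  l2 <- GRanges(lchr, IRanges(start(loci), end(loci)))
  ov <- findOverlaps(p2, l2, ignore.strand = TRUE)
  qh <- queryHits(ov)
  sh <- subjectHits(ov)
  lid <- mcols(loci)$locus_id
  hits <- split(lid[sh], factor(qh, levels = seq_along(probes)))
  fams <- split(mcols(loci)$family[sh], factor(qh, levels = seq_along(probes)))
  clss <- split(mcols(loci)$class[sh], factor(qh, levels = seq_along(probes)))
  # dedupe hits by locus id, keeping family/class aligned
  dd <- lapply(seq_along(hits), function(i) !duplicated(hits[[i]]))
  hits <- lapply(seq_along(hits), function(i) unname(hits[[i]][dd[[i]]]))
  fams <- lapply(seq_along(fams), function(i) unname(fams[[i]][dd[[i]]]))
  clss <- lapply(seq_along(clss), function(i) unname(clss[[i]][dd[[i]]]))
  n_hits <- lengths(hits)
  out <- DataFrame(probe_id = mcols(probes)$probe_id,
                   is_retro = n_hits > 0L, n_hits = n_hits)
  out$hits <- hits
  out$hit_families <- fams
  out$hit_classes <- clss
  metadata(out)$report <- list(
    n_probes = length(probes), n_annotated = sum(n_hits > 0L),
    fraction_annotated = if (length(probes)) sum(n_hits > 0L) / length(probes)
                         else NA_real_)
  out
}

#' Summarize an annotation by repeat family and class
#'
#' A probe hitting loci in two classes counts once in each class but once
#' in the distinct total; the same rule applies per family.
#'
#' @param annotations Output of [annotateProbes()].
#' @return List with `by_class` and `by_family` count data.frames and
#'   `n_annotated`, the number of distinct annotated probes.
#' @export
summarizeAnnotation <- function(annotations) {
  retro <- annotations[annotations$is_retro, , drop = FALSE]
  per_class <- table(unlist(lapply(retro$hit_classes, unique)))
  per_family <- table(unlist(lapply(retro$hit_families, unique)))
  as_df <- function(tb, nm) {
    df <- data.frame(names(tb), as.integer(tb), stringsAsFactors = FALSE)
    names(df) <- c(nm, "n_probes")
    df[order(-df$n_probes, df[[nm]]), , drop = FALSE]
  }
  list(by_class = as_df(per_class, "class"),
       by_family = as_df(per_family, "family"),
       n_annotated = nrow(retro))
}

#' Restrict a beta matrix to retroelement probes
#'
#' Keeps the rows of `beta` whose probes are annotated to at least one
#' locus whose class intersects `classes` (default: the full vocabulary).
#' Row order is preserved. Retaining zero probes is a hard error, because
#' clock training on an empty design is impossible.
#'
#' @param beta Probes x samples matrix.
#' @param annotations Output of [annotateProbes()].
#' @param classes Character subset of
#'   `HERV, LINE, LTR, SINE, DNA, Unknown`.
#' @return Row-subset matrix; `attr(x, "n_retained")` gives the count.
#' @export
selectRetroProbes <- function(beta, annotations, classes = CLASS_VOCAB) {
  if (!all(classes %in% CLASS_VOCAB))
    stop("classes must be a subset of ", paste(CLASS_VOCAB, collapse = "/"))
  keep_probe <- annotations$probe_id[
    annotations$is_retro &
      vapply(annotations$hit_classes,
             function(cl) any(cl %in% classes), logical(1))]
  keep <- rownames(beta) %in% keep_probe
  if (!any(keep))
    stop("no probes retained for classes {",
         paste(classes, collapse = ", "),
         "}; clock training is impossible on an empty design")
  out <- beta[keep, , drop = FALSE]
  attr(out, "n_retained") <- sum(keep)
  message(sprintf("retained %d of %d probes", sum(keep), nrow(beta)))
  out
}
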