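# Shared fixture builders and independent oracles. Everything here is
# deliberately naive (double loops, direct formulas) so tests check the
# package against code that shares nothing with the implementation.

makeProbes <- function(chrom, pos, probe_id = sprintf("cg%05d", seq_along(pos))) {
  GenomicRanges::GRanges(chrom, IRanges::IRanges(pos, width = 1L),
                         probe_id = probe_id, platform = "custom")
}

makeLoci <- function(chrom, start, end,
                     locus_id = sprintf("locus%03d", seq_along(start)),
                     family = rep("HERVK", length(start)),
                     class = rep("HERV", length(start))) {
  GenomicRanges::GRanges(chrom, IRanges::IRanges(start, end),
                         locus_id = locus_id, family = family, class = class)
}

# brute-force all-pairs probe/locus containment
bruteAnnotate <- function(probes, loci) {
  pc <- as.character(GenomicRanges::seqnames(probes))
  pp <- GenomicRanges::start(probes)
  lc <- as.character(GenomicRanges::seqnames(loci))
  ls <- GenomicRanges::start(loci)
  le <- GenomicRanges::end(loci)
  lid <- S4Vectors::mcols(loci)$locus_id
  out <- list()
  for (i in seq_along(probes)) {
    for (j in seq_along(loci)) {
      if (pc[i] == lc[j] && ls[j] <= pp[i] && pp[i] <= le[j])
        out[[length(out) + 1L]] <- data.frame(
          probe_id = S4Vectors::mcols(probes)$probe_id[i],
          locus_id = lid[j], stringsAsFactors = FALSE)
    }
  }
  if (!length(out))
    return(data.frame(probe_id = character(), locus_id = character()))
  do.call(rbind, out)
}

hitKey <- function(df) sort(paste(df$probe_id, df$locus_id))

annotationHits <- function(ann) {
  idx <- which(ann$is_retro)
  if (!length(idx))
    return(data.frame(probe_id = character(), locus_id = character()))
  do.call(rbind, lapply(idx, function(i)
    data.frame(probe_id = ann$probe_id[i], locus_id = ann$hits[[i]],
               stringsAsFactors = FALSE)))
}

# elastic-net objective as stated: (1/2n)RSS + lambda(alpha L1 + (1-alpha)/2 L2^2)
# with the penalty on the standardized-coefficient scale
enetObjective <- function(X, y, a0, b, lambda, alpha) {
  n <- nrow(X)
  s <- sqrt(colMeans(sweep(X, 2, colMeans(X))^2))
  bt <- b * s
  r <- y - a0 - drop(X %*% b)
  sum(r^2) / (2 * n) +
    lambda * (alpha * sum(abs(bt)) + (1 - alpha) / 2 * sum(bt^2))
}

randomProblem <- function(n, p, n_signal = min(5L, p), noise = 1) {
  X <- matrix(rnorm(n * p), n, p, dimnames = list(NULL, paste0("f", seq_len(p))))
  b <- c(rnorm(n_signal, 0, 2), rep(0, p - n_signal))
  list(X = X, y = drop(X %*% b) + rnorm(n, 0, noise))
}

# hypergeometric upper tail by direct binomial-coefficient enumeration
hyperTailEnum <- function(a, K, nq, N) {
  ks <- max(a, 0L):min(K, nq)
  if (a > min(K, nq)) return(0)
  sum(choose(K, ks) * choose(N - K, nq - ks)) / choose(N, nq)
}

# hand step-up BH
bhStepUp <- function(p) {
  m <- length(p)
  o <- order(p)
  q_sorted <- rev(cummin(rev(m * p[o] / seq_len(m))))
  pmin(q_sorted, 1)[order(o)]
}

tinyClock <- function(coefs = c(cg1 = 20, cg2 = -5), intercept = 10,
                      transform = ageTransform("identity"),
                      means = NULL) {
  retroclock:::ClockModel("tiny", "custom", intercept, coefs, transform,
    trainingMeans = if (is.null(means))
      stats::setNames(rep(0.5, length(coefs)), names(coefs)) else means)
}
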