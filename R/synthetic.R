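#' @importFrom stats runif rnorm rbinom rnbinom plogis setNames
NULL

FAMILY_POOL <- list(
  HERV = c("HERVK", "HERVH", "HERVL", "ERVLE", "MER41", "HML2"),
  LINE = c("L1FLnI", "L1PA2", "L1HS", "L2a"),
  LTR  = c("LTR7", "MLT1A", "MSTA", "THE1B"),
  SINE = c("AluY", "AluSx", "MIRb"))

.cytoband <- function(chrom, pos, chrom_length) {
  arm <- if (pos < chrom_length / 2) "p" else "q"
  paste0(sub("^chr", "", chrom), arm, sample.int(36, 1L))
}

#' Simulate a probe manifest and matching retroelement annotation
#'
#' Places random retroelement loci (classes HERV, LINE, LTR, SINE, with
#' Telescope-style family_band locus names) on a small synthetic genome,
#' then places probes so that a configurable fraction falls inside a
#' locus. The returned truth table records ground-truth probe-to-locus
#' containment computed by a direct per-probe scan, so it can serve as an
#' oracle for coordinate-based annotation.
#'
#' @param n_probes,n_loci Numbers of probes and loci.
#' @param inside_fraction Fraction of probes placed inside loci (0 to 1).
#' @param chroms,chrom_length The synthetic genome.
#' @param locus_size Min/max locus width (bp).
#' @param platform Platform tag for the manifest.
#' @param seed Integer seed fixing the whole stream.
#' @return List: `probes` (manifest `GRanges`, as [readManifest()]
#'   returns), `loci` (annotation `GRanges`, as [readAnnotation()]
#'   returns), `truth` (data.frame `probe_id`, `locus_id`, one row per
#'   true containment).
#' @export
simulateManifestAnnotation <- function(n_probes = 1000, n_loci = 120,
    inside_fraction = 0.5, chroms = paste0("chr", 1:5),
    chrom_length = 2e6, locus_size = c(500, 8000),
    platform = "custom", seed = 1) {
  stopifnot(inside_fraction >= 0, inside_fraction <= 1)
  set.seed(as.integer(seed))
  cls <- rep_len(names(FAMILY_POOL), n_loci)
  lchr <- sample(chroms, n_loci, replace = TRUE)
  width <- sample(locus_size[[1L]]:locus_size[[2L]], n_loci, replace = TRUE)
  lstart <- vapply(width, function(w)
    sample.int(chrom_length - w, 1L), integer(1))
  fam <- vapply(cls, function(cl) sample(FAMILY_POOL[[cl]], 1L), character(1))
  locus_id <- vapply(seq_len(n_loci), function(i)
    paste0(fam[[i]], "_", .cytoband(lchr[[i]], lstart[[i]], chrom_length),
           ".", i), character(1))
  loci <- GRanges(lchr, IRanges(lstart, width = width),
                  strand = sample(c("+", "-"), n_loci, replace = TRUE),
                  locus_id = locus_id, family = fam, class = cls)

  n_in <- round(inside_fraction * n_probes)
  if (n_in > 0L && n_loci == 0L)
    stop("cannot place probes inside loci: annotation is empty")
  pchr <- character(n_probes); ppos <- integer(n_probes)
  if (n_in > 0L) {
    host <- sample.int(n_loci, n_in, replace = TRUE)
    pchr[seq_len(n_in)] <- lchr[host]
    ppos[seq_len(n_in)] <- lstart[host] +
      vapply(width[host], function(w) sample.int(w, 1L) - 1L, integer(1))
  }
  inside_any <- function(chrom, pos) {
    sel <- lchr == chrom
    any(lstart[sel] <= pos & pos <= lstart[sel] + width[sel] - 1L)
  }
  i <- n_in
  tries <- 0L
  while (i < n_probes) {
    ch <- sample(chroms, 1L); po <- sample.int(chrom_length, 1L)
    if (!inside_any(ch, po)) {
      i <- i + 1L
      pchr[[i]] <- ch; ppos[[i]] <- po
    }
    tries <- tries + 1L
    if (tries > 200L * n_probes)
      stop("cannot place probes outside loci: genome saturated")
  }
  probe_id <- sprintf("cg%08d", sample.int(1e7, n_probes))
  probes <- GRanges(pchr, IRanges(ppos, width = 1L), probe_id = probe_id,
                    platform = platform)
  # ground truth by direct scan, per probe
  truth <- do.call(rbind, lapply(seq_len(n_probes), function(j) {
    sel <- which(lchr == pchr[[j]] & lstart <= ppos[[j]] &
                   ppos[[j]] <= lstart + width - 1L)
    if (!length(sel)) return(NULL)
    data.frame(probe_id = probe_id[[j]], locus_id = locus_id[sel],
               stringsAsFactors = FALSE)
  }))
  if (is.null(truth))
    truth <- data.frame(probe_id = character(), locus_id = character(),
                        stringsAsFactors = FALSE)
  list(probes = probes, loci = loci, truth = truth)
}

#' Simulate a methylation cohort with a planted age signal
#'
#' Ages are uniform on `age_range`. A random causal subset of probes
#' carries a linear age effect on the logit scale,
#' `logit(beta_ij) = a_j + b_j (t_i - mean(t)) + blocks + noise`, with
#' `b_j = +/- effect_scale` and `t` either age in years or the
#' relative-age scale `log(age + 2)` (`age_basis = "log_offset"`, which
#' the multi-species design uses so that cross-species training on the
#' log-offset response is exercised). Non-causal probes are
#' age-independent. The inverse logit guarantees betas in (0, 1).
#'
#' Optional structure: `n_donors` groups samples into donors (one age per
#' donor, a donor-level logit shift with sd `donor_sd_logit`, tissues
#' cycled within donors); `species_lifespans` (named vector of maximum
#' ages) assigns each donor a species and draws its age uniformly over
#' that species' lifespan.
#'
#' @param n_samples,n_probes,n_causal Cohort dimensions.
#' @param age_range Years (ignored when `species_lifespans` is given).
#' @param effect_scale Causal slope magnitude, logit units per unit of
#'   `t` (per year, or per log-year under `log_offset`).
#' @param noise_sd_logit Probe-level noise sd on the logit scale.
#' @param baseline_logit_range Uniform range of probe baselines.
#' @param age_basis `"years"` or `"log_offset"` for the causal predictor.
#' @param n_donors,n_tissues,species_lifespans,donor_sd_logit Optional
#'   block structure (see Details).
#' @param seed Integer seed fixing the whole stream.
#' @return List: `beta` (probes x samples), `metadata` (`sample_id`,
#'   `age`, `donor_id`, `species`, `tissue`), `causal` (probe ids),
#'   `effects` (named signed slopes).
#' @export
simulateMethylationCohort <- function(n_samples = 600, n_probes = 3000,
    n_causal = 150, age_range = c(12, 100), effect_scale = 0.02,
    noise_sd_logit = 0.5, baseline_logit_range = c(-3, 3),
    age_basis = c("years", "log_offset"), n_donors = NULL, n_tissues = NULL,
    species_lifespans = NULL, donor_sd_logit = 0, seed = 1) {
  age_basis <- match.arg(age_basis)
  stopifnot(n_causal <= n_probes, age_range[[1L]] < age_range[[2L]])
  set.seed(as.integer(seed))
  sample_id <- sprintf("S%04d", seq_len(n_samples))

  if (!is.null(species_lifespans) && is.null(n_donors))
    n_donors <- max(2L, n_samples %/% 3L)
  if (!is.null(n_donors)) {
    donor <- sprintf("D%03d", rep_len(seq_len(n_donors), n_samples))
    if (!is.null(species_lifespans)) {
      sp_of_donor <- rep_len(names(species_lifespans), n_donors)
      species <- sp_of_donor[as.integer(sub("D", "", donor))]
      L <- species_lifespans[species]
      donor_age <- setNames(runif(n_donors, 0.1, 1), sprintf("D%03d",
                            seq_len(n_donors)))
      age <- donor_age[donor] * unname(L)
    } else {
      species <- NA_character_
      donor_age <- setNames(runif(n_donors, age_range[[1L]],
                                  age_range[[2L]]),
                            sprintf("D%03d", seq_len(n_donors)))
      age <- unname(donor_age[donor])
    }
    tissue <- if (is.null(n_tissues)) NA_character_
      else paste0("tissue", stats::ave(seq_len(n_samples), donor,
                  FUN = function(i) rep_len(seq_len(n_tissues), length(i))))
    donor_shift <- setNames(rnorm(n_donors, 0, donor_sd_logit),
                            sprintf("D%03d", seq_len(n_donors)))
    shift <- unname(donor_shift[donor])
  } else {
    donor <- NA_character_; species <- NA_character_
    tissue <- NA_character_
    age <- runif(n_samples, age_range[[1L]], age_range[[2L]])
    shift <- 0
  }
  t_i <- if (age_basis == "years") age else log(age + 2)
  tc <- t_i - mean(t_i)

  probe_id <- sprintf("cg%08d", sample.int(1e7, n_probes))
  a_j <- runif(n_probes, baseline_logit_range[[1L]],
               baseline_logit_range[[2L]])
  causal_idx <- sort(sample.int(n_probes, n_causal))
  b_j <- numeric(n_probes)
  b_j[causal_idx] <- sample(c(-1, 1), n_causal, replace = TRUE) *
    effect_scale
  logit <- outer(a_j, rep(1, n_samples)) + outer(b_j, tc) +
    matrix(shift, n_probes, n_samples, byrow = TRUE) +
    matrix(rnorm(n_probes * n_samples, 0, noise_sd_logit),
           n_probes, n_samples)
  beta <- plogis(logit)
  dimnames(beta) <- list(probe_id, sample_id)
  metadata <- data.frame(sample_id = sample_id, age = unname(age),
                         donor_id = donor, species = species,
                         tissue = tissue, stringsAsFactors = FALSE)
  list(beta = beta, metadata = metadata, causal = probe_id[causal_idx],
       effects = setNames(b_j[causal_idx], probe_id[causal_idx]))
}

#' Simulate replicate predictions with known reliability
#'
#' Subject means are drawn around a cohort mean with variance
#' `sigma2_between`; replicates scatter around their subject mean with
#' variance `sigma2_within`, so the true intraclass correlation is
#' `sigma2_between / (sigma2_between + sigma2_within)` (recorded in
#' `attr(x, "true_icc")`).
#'
#' @param n_subjects,n_replicates Design size (e.g. 30 x 2 for a
#'   replicate-blood reliability study).
#' @param sigma2_between,sigma2_within Variance components (years^2).
#' @param cohort_mean Mean predicted age (years).
#' @param seed Integer seed.
#' @return Data.frame: `sample_id`, `subject_id`, `predicted_age`.
#' @export
simulateReplicates <- function(n_subjects = 30, n_replicates = 2,
    sigma2_between = 9, sigma2_within = 1, cohort_mean = 50, seed = 1) {
  stopifnot(sigma2_between >= 0, sigma2_within >= 0)
  set.seed(as.integer(seed))
  subj <- sprintf("P%03d", seq_len(n_subjects))
  mu <- rnorm(n_subjects, cohort_mean, sqrt(sigma2_between))
  df <- data.frame(
    sample_id = sprintf("%s_r%d", rep(subj, each = n_replicates),
                        rep(seq_len(n_replicates), n_subjects)),
    subject_id = rep(subj, each = n_replicates),
    predicted_age = rep(mu, each = n_replicates) +
      rnorm(n_subjects * n_replicates, 0, sqrt(sigma2_within)),
    stringsAsFactors = FALSE)
  attr(df, "true_icc") <- if (sigma2_between + sigma2_within == 0) NA_real_
    else sigma2_between / (sigma2_between + sigma2_within)
  df
}

#' Simulate a retroelement expression cohort
#'
#' Negative-binomial counts for locus-level retroelement expression with
#' log-normal library sizes. Causal loci have a log-mean linear in age
#' (slope `+/- effect_scale` per year around the cohort mean age);
#' relative abundances are renormalized per sample so library size and
#' composition behave like RNA-seq quantification output.
#'
#' @param n_samples,n_loci,n_causal Cohort dimensions.
#' @param age_range Years.
#' @param effect_scale Causal log-expression slope per year.
#' @param dispersion NB size parameter (smaller = noisier).
#' @param lib_size_meanlog,lib_size_sdlog Log-normal library sizes.
#' @param seed Integer seed.
#' @return List: `counts` (loci x samples, integer), `metadata`,
#'   `causal` (locus ids).
#' @export
simulateExpressionCohort <- function(n_samples = 160, n_loci = 500,
    n_causal = 40, age_range = c(20, 74), effect_scale = 0.015,
    dispersion = 8, lib_size_meanlog = log(2e6), lib_size_sdlog = 0.3,
    seed = 1) {
  stopifnot(n_causal <= n_loci)
  set.seed(as.integer(seed))
  sample_id <- sprintf("S%04d", seq_len(n_samples))
  age <- runif(n_samples, age_range[[1L]], age_range[[2L]])
  cls <- rep_len(c("HERV", "LINE"), n_loci)
  fam <- vapply(cls, function(cl) sample(FAMILY_POOL[[cl]], 1L),
                character(1))
  locus_id <- paste0(fam, "_", rep_len(c(1:22), n_loci),
                     sample(c("p", "q"), n_loci, TRUE),
                     sample.int(36, n_loci, TRUE), ".", seq_len(n_loci))
  base <- rnorm(n_loci, 0, 1.5)
  causal_idx <- sort(sample.int(n_loci, n_causal))
  b <- numeric(n_loci)
  b[causal_idx] <- sample(c(-1, 1), n_causal, replace = TRUE) * effect_scale
  loggm <- outer(base, rep(1, n_samples)) + outer(b, age - mean(age))
  w <- exp(loggm)
  probs <- sweep(w, 2L, colSums(w), "/")
  lib <- exp(rnorm(n_samples, lib_size_meanlog, lib_size_sdlog))
  mu <- sweep(probs, 2L, lib, "*")
  counts <- matrix(rnbinom(n_loci * n_samples, mu = mu, size = dispersion),
                   n_loci, n_samples, dimnames = list(locus_id, sample_id))
  metadata <- data.frame(sample_id = sample_id, age = age,
                         stringsAsFactors = FALSE)
  list(counts = counts, metadata = metadata, causal = locus_id[causal_idx])
}
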