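#' @importFrom utils read.csv read.delim write.table count.fields
#' @importFrom S4Vectors metadata metadata<- mcols mcols<- DataFrame
#' @importFrom GenomicRanges GRanges
#' @importFrom IRanges IRanges
NULL

NA_TOKENS <- c("NA", "NaN", "")

.pick_column <- function(df, aliases, what, path) {
  hit <- aliases[aliases %in% names(df)]
  if (!length(hit))
    stop(sprintf("%s: no column for %s (looked for %s)", path, what,
                 paste(aliases, collapse = ", ")))
  hit[[1L]]
}

#' Read an array probe manifest
#'
#' Parses a CSV manifest into a `GRanges` of width-1 probe positions
#' (1-based, the interrogated cytosine). Column names are matched against
#' configurable aliases so both Illumina-style (`IlmnID`, `CHR`, `MAPINFO`)
#' and plain (`probe_id`, `chrom`, `pos`) headers work. Rows with a missing
#' coordinate are dropped and counted in `metadata(x)$report`; duplicated
#' probe ids are an error.
#'
#' @param path CSV file path.
#' @param platform Platform tag stored with each probe
#'   (`EPICv1`, `EPICv2`, `450K`, `Mammal40` or `custom`).
#' @param aliases Named list of accepted column names for `probe_id`,
#'   `chrom` and `pos`.
#' @return `GRanges` with mcols `probe_id`, `platform`;
#'   `metadata(x)$report` lists `n_total`, `n_kept`, `n_dropped` and the
#'   dropped line numbers.
#' @export
readManifest <- function(path,
    platform = c("custom", "EPICv1", "EPICv2", "450K", "Mammal40"),
    aliases = list(
      probe_id = c("probe_id", "IlmnID", "Name", "probeID"),
      chrom    = c("chrom", "CHR", "chr", "Chromosome", "seqnames"),
      pos      = c("pos", "MAPINFO", "position", "Position"))) {
  platform <- match.arg(platform)
  df <- read.csv(path, check.names = FALSE, na.strings = NA_TOKENS,
                 colClasses = "character")
  id_col <- .pick_column(df, aliases$probe_id, "probe_id", path)
  chr_col <- .pick_column(df, aliases$chrom, "chrom", path)
  pos_col <- .pick_column(df, aliases$pos, "pos", path)

  dup <- unique(df[[id_col]][duplicated(df[[id_col]])])
  dup <- dup[!is.na(dup)]
  if (length(dup))
    stop(sprintf("%s: duplicated probe ids: %s", path,
                 paste(utils::head(dup, 10), collapse = ", ")))

  pos_raw <- df[[pos_col]]
  keep <- !(is.na(pos_raw) | is.na(df[[chr_col]]) | is.na(df[[id_col]]))
  pos_num <- suppressWarnings(as.numeric(pos_raw[keep]))
  bad <- which(is.na(pos_num) | pos_num != round(pos_num) | pos_num < 1)
  if (length(bad)) {
    lines <- which(keep)[bad] + 1L  # +1 for the header line
    stop(sprintf("%s: non-integer or invalid position at line(s) %s", path,
                 paste(utils::head(lines, 10), collapse = ", ")))
  }
  gr <- GRanges(df[[chr_col]][keep],
                IRanges(as.integer(pos_num), width = 1L),
                probe_id = df[[id_col]][keep], platform = platform)
  metadata(gr)$report <- list(
    n_total = nrow(df), n_kept = sum(keep), n_dropped = sum(!keep),
    dropped_lines = which(!keep) + 1L)
  gr
}

#' Guess a retroelement class from a family label
#'
#' Maps a repeat family string (e.g. `"HERVK"`, `"L1FLnI"`, `"AluY"`) onto
#' the closed class vocabulary `HERV, LINE, LTR, SINE, DNA, Unknown`.
#' @param family Character vector of family labels.
#' @return Character vector of classes.
#' @export
classFromFamily <- function(family) {
  cls <- rep("Unknown", length(family))
  f <- ifelse(is.na(family), "", family)
  cls[grepl("^(HERV|ERV|HML|MER4)", f, ignore.case = TRUE)] <- "HERV"
  cls[grepl("^(L1|L2|LINE|CR1|RTE)", f, ignore.case = TRUE)] <- "LINE"
  cls[grepl("^(LTR|MLT|MST|THE|HARL)", f, ignore.case = TRUE)] <- "LTR"
  cls[grepl("^(Alu|SINE|MIR|SVA)", f, ignore.case = TRUE)] <- "SINE"
  cls[grepl("^(DNA|hAT|TcMar|Merlin|PiggyBac)", f, ignore.case = TRUE)] <- "DNA"
  cls
}

.coerce_class <- function(cls) {
  cls[is.na(cls) | !cls %in% CLASS_VOCAB] <- "Unknown"
  cls
}

#' Read a retroelement locus annotation
#'
#' Loads locus-level retroelement annotations from GTF (1-based inclusive),
#' BED6 (0-based half-open; converted on import) or a plain CSV with
#' columns `locus` (or `locus_id`), `chrom`, `start`, `end` and optional
#' `strand`, `family`, `class`. All coordinates are normalized to 1-based
#' inclusive internally. The repeat class is taken from `class_field` when
#' present and otherwise inferred from the family label via
#' [classFromFamily()]; values outside the closed vocabulary become
#' `Unknown`.
#'
#' @param path Annotation file.
#' @param dialect One of `"gtf"`, `"bed6"`, `"csv"`.
#' @param id_field,family_field,class_field GTF attribute (or CSV column)
#'   names to use; the first present wins for `id_field`.
#' @return `GRanges` with mcols `locus_id`, `family`, `class`.
#' @export
readAnnotation <- function(path, dialect = c("gtf", "bed6", "csv"),
    id_field = c("locus_id", "gene_id", "transcript_id", "ID", "Name"),
    family_field = "family",
    class_field = c("class", "repClass")) {
  dialect <- match.arg(dialect)
  if (dialect == "gtf") {
    gr <- rtracklayer::import(path, format = "gtf")
    mc <- mcols(gr)
    idc <- id_field[id_field %in% names(mc)]
    if (!length(idc))
      stop(sprintf("%s: no locus id attribute among %s", path,
                   paste(id_field, collapse = ", ")))
    locus_id <- as.character(mc[[idc[[1L]]]])
    fam <- if (family_field %in% names(mc))
      as.character(mc[[family_field]]) else NA_character_
    clc <- class_field[class_field %in% names(mc)]
    cls <- if (length(clc)) as.character(mc[[clc[[1L]]]])
           else classFromFamily(fam)
  } else if (dialect == "bed6") {
    gr <- rtracklayer::import(path, format = "bed")
    locus_id <- as.character(mcols(gr)$name)
    fam <- sub("_.*$", "", locus_id)
    cls <- classFromFamily(fam)
  } else {
    df <- read.csv(path, check.names = FALSE, na.strings = NA_TOKENS)
    idc <- c("locus", "locus_id")[c("locus", "locus_id") %in% names(df)]
    need <- c("chrom", "start", "end")
    miss <- setdiff(need, names(df))
    if (!length(idc) || length(miss))
      stop(sprintf("%s: CSV annotation needs locus/locus_id, chrom, start, end",
                   path))
    if (any(df$start > df$end))
      stop(sprintf("%s: start > end at row(s) %s", path,
                   paste(utils::head(which(df$start > df$end), 10),
                         collapse = ", ")))
    strand <- if ("strand" %in% names(df)) df$strand else "*"
    strand[is.na(strand) | !strand %in% c("+", "-")] <- "*"
    gr <- GRanges(df$chrom, IRanges(df$start, df$end), strand = strand)
    locus_id <- as.character(df[[idc[[1L]]]])
    fam <- if (family_field %in% names(df))
      as.character(df[[family_field]]) else NA_character_
    clc <- class_field[class_field %in% names(df)]
    cls <- if (length(clc)) as.character(df[[clc[[1L]]]])
           else classFromFamily(fam)
  }
  if (anyDuplicated(locus_id))
    stop(sprintf("%s: duplicated locus ids: %s", path,
                 paste(utils::head(unique(locus_id[duplicated(locus_id)]), 10),
                       collapse = ", ")))
  fam <- rep_len(ifelse(is.na(fam), "Unknown", fam), length(gr))
  mcols(gr) <- DataFrame(locus_id = locus_id, family = fam,
                         class = .coerce_class(rep_len(cls, length(gr))))
  gr
}

#' Read a beta-value matrix
#'
#' TSV with probe ids in the first column and one column per sample.
#' Missing values may be encoded `NA`, `NaN` or the empty string. Every
#' non-missing value must lie in \[0, 1\]; violations are reported with
#' the offending probe and sample. Ragged rows are a format error.
#'
#' @param path TSV file path.
#' @return Numeric matrix, probes x samples, with dimnames.
#' @export
readBetaMatrix <- function(path) {
  nf <- count.fields(path, sep = "\t", quote = "\"")
  if (length(unique(nf)) != 1L)
    stop(sprintf("%s: ragged rows (field counts %s)", path,
                 paste(unique(nf), collapse = ", ")))
  df <- read.delim(path, check.names = FALSE, na.strings = NA_TOKENS,
                   stringsAsFactors = FALSE)
  if (ncol(df) < 2L)
    stop(sprintf("%s: need a probe id column plus at least one sample", path))
  probes <- as.character(df[[1L]])
  if (anyDuplicated(probes))
    stop(sprintf("%s: duplicated probe ids", path))
  m <- as.matrix(df[, -1L, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- probes
  if (anyDuplicated(colnames(m)))
    stop(sprintf("%s: duplicated sample ids", path))
  bad <- which(!is.na(m) & (m < 0 | m > 1), arr.ind = TRUE)
  if (nrow(bad))
    stop(sprintf("%s: beta value out of [0,1] at probe '%s', sample '%s' (%g)",
                 path, probes[bad[1L, 1L]], colnames(m)[bad[1L, 2L]],
                 m[bad[1L, , drop = FALSE]]))
  m
}

#' Write a beta-value matrix as TSV
#' @param beta Numeric probes x samples matrix with dimnames.
#' @param path Output path.
#' @export
writeBetaMatrix <- function(beta, path) {
  df <- data.frame(probe_id = rownames(beta), beta, check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
              na = "NA")
  invisible(path)
}

#' Read sample metadata
#'
#' CSV with at least `sample_id` and `age` (years); optional columns such
#' as `donor_id`, `group`, `species`, `tissue`, `timepoint` and
#' `replicate_of` are carried through untouched.
#'
#' @param path CSV file path.
#' @return A data.frame keyed by unique `sample_id`.
#' @export
readSampleMetadata <- function(path) {
  df <- read.csv(path, check.names = FALSE, na.strings = NA_TOKENS,
                 stringsAsFactors = FALSE)
  id_col <- .pick_column(df, c("sample_id", "sample", "id"), "sample_id", path)
  age_col <- .pick_column(df, c("age", "Age", "chronological_age"), "age",
                          path)
  names(df)[match(c(id_col, age_col), names(df))] <- c("sample_id", "age")
  df$sample_id <- as.character(df$sample_id)
  if (anyDuplicated(df$sample_id))
    stop(sprintf("%s: duplicated sample ids", path))
  df$age <- as.numeric(df$age)
  if (any(df$age < 0, na.rm = TRUE))
    stop(sprintf("%s: negative ages", path))
  df
}

.sidecar_path <- function(path) {
  if (grepl("\\.csv$", path, ignore.case = TRUE))
    sub("\\.csv$", ".json", path, ignore.case = TRUE)
  else paste0(path, ".json")
}

#' Serialize a clock model
#'
#' Writes a CSV of `(term, coefficient, training_mean)` whose first row is
#' `"(Intercept)"`, plus a JSON sidecar (same basename, `.json`) holding
#' the clock name, platform, age-transform spec, training-set size, seed
#' and the CpG list. Coefficients are written to full double precision so
#' that `readClockModel(writeClockModel(m))` is field-for-field identity.
#'
#' @param model A [ClockModel-class].
#' @param path CSV output path.
#' @return `path`, invisibly.
#' @export
writeClockModel <- function(model, path) {
  stopifnot(is(model, "ClockModel"))
  validObject(model)
  cf <- model@coefficients
  tm <- model@trainingMeans
  fmt <- function(x) ifelse(is.na(x), NA_character_, sprintf("%.17g", x))
  df <- data.frame(
    term = c("(Intercept)", names(cf)),
    coefficient = fmt(c(model@intercept, unname(cf))),
    training_mean = fmt(c(NA_real_,
      if (length(tm)) unname(tm[names(cf)]) else rep(NA_real_, length(cf)))),
    stringsAsFactors = FALSE)
  if (!length(tm)) df$training_mean <- NULL
  write.table(df, path, sep = ",", quote = FALSE, row.names = FALSE,
              na = "NA")
  sidecar <- list(name = model@name, platform = model@platform,
    transform = list(kind = model@transform@kind,
                     offset = model@transform@offset),
    n_train = model@nTrain, seed = model@seed, cpgs = as.list(names(cf)))
  jsonlite::write_json(sidecar, .sidecar_path(path), auto_unbox = TRUE,
                       digits = NA, null = "null", na = "null")
  invisible(path)
}

#' Deserialize a clock model
#'
#' Counterpart of [writeClockModel()]. A coefficient CSV without a
#' `training_mean` column loads with imputation disabled (empty training
#' means). A sidecar CpG list inconsistent with the CSV terms is a
#' consistency error, as is a CSV whose first term is not `"(Intercept)"`.
#'
#' @param path CSV path written by [writeClockModel()].
#' @return A [ClockModel-class].
#' @export
readClockModel <- function(path) {
  df <- read.csv(path, check.names = FALSE, na.strings = NA_TOKENS,
                 stringsAsFactors = FALSE)
  if (!all(c("term", "coefficient") %in% names(df)))
    stop(sprintf("%s: coefficient file needs 'term' and 'coefficient'", path))
  if (nrow(df) == 0L || df$term[[1L]] != "(Intercept)")
    stop(sprintf("%s: first term must be '(Intercept)'", path))
  intercept <- as.numeric(df$coefficient[[1L]])
  cf <- as.numeric(df$coefficient[-1L])
  names(cf) <- df$term[-1L]
  cf <- cf[cf != 0]
  tm <- numeric()
  if ("training_mean" %in% names(df)) {
    tm <- as.numeric(df$training_mean[-1L])
    names(tm) <- df$term[-1L]
    tm <- tm[!is.na(tm)]
    if (!all(names(cf) %in% names(tm))) tm <- numeric()  # imputation disabled
  }
  sc_path <- .sidecar_path(path)
  name <- "clock"; platform <- "custom"
  transform <- ageTransform("identity")
  n_train <- NA_integer_; seed <- NA_integer_
  if (file.exists(sc_path)) {
    sc <- jsonlite::read_json(sc_path)
    if (!is.null(sc$cpgs)) {
      side <- unlist(sc$cpgs, use.names = FALSE)
      if (!setequal(side, names(cf)))
        stop(sprintf("%s: sidecar CpG list inconsistent with CSV (e.g. %s)",
          sc_path,
          paste(utils::head(c(setdiff(side, names(cf)),
                              setdiff(names(cf), side)), 5), collapse = ", ")))
    }
    if (!is.null(sc$name)) name <- sc$name
    if (!is.null(sc$platform)) platform <- sc$platform
    if (!is.null(sc$transform))
      transform <- ageTransform(sc$transform$kind,
        if (is.null(sc$transform$offset)) 2 else sc$transform$offset)
    if (!is.null(sc$n_train)) n_train <- as.integer(sc$n_train)
    if (!is.null(sc$seed)) seed <- as.integer(sc$seed)
  }
  ClockModel(name, platform, intercept, cf, transform, tm, n_train, seed)
}
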