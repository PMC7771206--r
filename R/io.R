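# Readers and writers for the plain-text formats the pipeline exchanges.
#
# Coordinate conventions are centralized here: peak files are BED-style
# 0-based half-open; gene TSS and promoter windows are 1-based inclusive.
# Matrices are TSV with a feature-id first column and one column per sample.

#' Read a feature-by-sample matrix from TSV
#'
#' @param path TSV file; first column feature ids, remaining columns samples.
#' @return numeric matrix with feature rownames and sample colnames.
#' @export
read_matrix_tsv <- function(path) {
  dt <- data.table::fread(path, sep = "\t", header = TRUE, data.table = FALSE)
  if (ncol(dt) < 2L) stop_invalid("matrix file %s has no sample columns", path)
  ids <- as.character(dt[[1L]])
  if (anyDuplicated(ids)) stop_invalid("duplicate feature ids in %s", path)
  m <- as.matrix(dt[, -1L, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- ids
  m
}

#' Write a feature-by-sample matrix to TSV
#'
#' @param m numeric matrix with rownames and colnames.
#' @param path output file.
#' @param id_col name for the feature-id column.
#' @export
write_matrix_tsv <- function(m, path, id_col = "feature_id") {
  stopifnot(is.matrix(m), !is.null(rownames(m)), !is.null(colnames(m)))
  dt <- data.table::data.table(rownames(m), m)
  data.table::setnames(dt, c(id_col, colnames(m)))
  data.table::fwrite(dt, path, sep = "\t")
  invisible(path)
}

#' Read a peak atlas
#'
#' Accepts either a headered TSV with columns `peak_id`, `chrom`, `start`,
#' `end`, `summit`, or headerless BED6+1 whose 7th column is the summit
#' offset from `start`. Coordinates are 0-based half-open; the summit is an
#' absolute 0-based position.
#'
#' @param path peak file.
#' @return data.frame with columns `peak_id`, `chrom`, `start`, `end`,
#'   `summit`.
#' @export
read_peaks <- function(path) {
  first <- readLines(path, n = 1L)
  headered <- grepl("peak_id", first, fixed = TRUE)
  if (headered) {
    df <- data.table::fread(path, sep = "\t", header = TRUE, data.table = FALSE)
    need <- c("peak_id", "chrom", "start", "end", "summit")
    if (!all(need %in% names(df))) {
      stop_invalid("peak TSV %s lacks columns: %s", path,
                   paste(setdiff(need, names(df)), collapse = ", "))
    }
    df <- df[, need]
  } else {
    df <- data.table::fread(path, sep = "\t", header = FALSE, data.table = FALSE)
    if (ncol(df) < 7L) stop_invalid("BED peak file %s needs 7 columns", path)
    df <- data.frame(peak_id = as.character(df[[4L]]), chrom = df[[1L]],
                     start = df[[2L]], end = df[[3L]],
                     summit = df[[2L]] + df[[7L]], stringsAsFactors = FALSE)
  }
  validate_peaks(df)
  df
}

validate_peaks <- function(peaks) {
  stopifnot(is.data.frame(peaks))
  if (any(peaks$start >= peaks$end)) stop_invalid("peak with start >= end")
  if (any(peaks$summit < peaks$start | peaks$summit >= peaks$end)) {
    stop_invalid("peak summit outside [start, end)")
  }
  if (anyDuplicated(peaks$peak_id)) stop_invalid("duplicate peak ids")
  invisible(peaks)
}

#' Write a peak atlas as headered TSV
#' @param peaks peak data.frame.
#' @param path output file.
#' @export
write_peaks <- function(peaks, path) {
  data.table::fwrite(
    peaks[, c("peak_id", "chrom", "start", "end", "summit")], path, sep = "\t")
  invisible(path)
}

#' Read a gene annotation TSV
#'
#' Four columns: `gene_id`, `chrom`, `tss` (1-based), `strand` (`+`/`-`).
#' @param path gene TSV.
#' @return data.frame of the four columns.
#' @export
read_genes <- function(path) {
  df <- data.table::fread(path, sep = "\t", header = TRUE, data.table = FALSE)
  need <- c("gene_id", "chrom", "tss", "strand")
  if (!all(need %in% names(df))) {
    stop_invalid("gene TSV %s lacks columns: %s", path,
                 paste(setdiff(need, names(df)), collapse = ", "))
  }
  df <- df[, need]
  validate_genes(df)
  df
}

validate_genes <- function(genes) {
  if (!all(genes$strand %in% c("+", "-"))) stop_invalid("gene strand must be + or -")
  if (any(genes$tss < 1)) stop_invalid("gene tss must be >= 1 (1-based)")
  if (anyDuplicated(genes$gene_id)) stop_invalid("duplicate gene ids")
  invisible(genes)
}

#' Convert a GFF3 gene annotation to the 4-column TSS TSV
#'
#' Extracts `gene`-type records; the TSS is the start for `+` strand genes
#' and the end for `-` strand genes (both 1-based).
#'
#' @param gff_path GFF3 file.
#' @param out_path optional TSV destination; when given the table is written
#'   there as well as returned.
#' @return gene annotation data.frame.
#' @export
genes_from_gff <- function(gff_path, out_path = NULL) {
  lines <- readLines(gff_path)
  lines <- lines[!startsWith(lines, "#") & nzchar(lines)]
  f <- strsplit(lines, "\t", fixed = TRUE)
  f <- f[vapply(f, length, 0L) >= 9L]
  f <- f[vapply(f, function(x) x[3] == "gene", logical(1))]
  if (length(f) == 0L) stop_invalid("no gene records in %s", gff_path)
  attr_id <- function(a) {
    m <- regmatches(a, regexec("ID=([^;]+)", a))[[1]]
    if (length(m) == 2L) m[2] else NA_character_
  }
  df <- data.frame(
    gene_id = vapply(f, function(x) attr_id(x[9]), character(1)),
    chrom = vapply(f, `[`, character(1), 1L),
    start = as.integer(vapply(f, `[`, character(1), 4L)),
    end = as.integer(vapply(f, `[`, character(1), 5L)),
    strand = vapply(f, `[`, character(1), 7L),
    stringsAsFactors = FALSE
  )
  df$tss <- ifelse(df$strand == "+", df$start, df$end)
  df <- df[, c("gene_id", "chrom", "tss", "strand")]
  validate_genes(df)
  if (!is.null(out_path)) data.table::fwrite(df, out_path, sep = "\t")
  df
}

#' Read a cohort table (sample id, epithelial proportion)
#'
#' Accepts the two-column TSV path (the headered `sample_id`/`proportion`
#' layout); a `group` column, if present, is recomputed from the cutoff.
#'
#' @param path cohort TSV.
#' @param cutoff high/low boundary for the group column.
#' @return cohort data.frame.
#' @export
read_cohort <- function(path, cutoff = 0.5) {
  df <- data.table::fread(path, sep = "\t", header = TRUE, data.table = FALSE)
  if (!all(c("sample_id", "proportion") %in% names(df))) {
    stop_invalid("cohort TSV %s needs columns sample_id, proportion", path)
  }
  make_cohort(df$sample_id, df$proportion, cutoff)
}

#' Write a cohort table
#' @param cohort cohort data.frame.
#' @param path output TSV.
#' @export
write_cohort <- function(cohort, path) {
  data.table::fwrite(cohort, path, sep = "\t")
  invisible(path)
}

#' Read a survival table
#'
#' Columns `sample_id`, `time_days` (or `time`), `event` (1 = death observed,
#' 0 = censored).
#' @param path survival TSV.
#' @return data.frame with columns `sample_id`, `time`, `event`.
#' @export
read_survival <- function(path) {
  df <- data.table::fread(path, sep = "\t", header = TRUE, data.table = FALSE)
  tcol <- intersect(c("time_days", "time"), names(df))[1]
  if (is.na(tcol) || !all(c("sample_id", "event") %in% names(df))) {
    stop_invalid("survival TSV %s needs sample_id, time_days, event", path)
  }
  out <- data.frame(sample_id = as.character(df$sample_id),
                    time = as.numeric(df[[tcol]]),
                    event = as.integer(df$event), stringsAsFactors = FALSE)
  validate_survival(out)
  out
}

validate_survival <- function(surv) {
  if (any(surv$time <= 0)) stop_invalid("survival times must be positive")
  if (!all(surv$event %in% c(0L, 1L))) stop_invalid("event must be 0 or 1")
  invisible(surv)
}

#' Write a survival table
#' @param surv survival data.frame (`sample_id`, `time`, `event`).
#' @param path output TSV.
#' @export
write_survival <- function(surv, path) {
  out <- data.frame(sample_id = surv$sample_id, time_days = surv$time,
                    event = surv$event)
  data.table::fwrite(out, path, sep = "\t")
  invisible(path)
}

#' Read / write label masks as integer TSV grids
#'
#' Masks are stored as headerless TSV matrices of integer labels
#' (0 = background, 1 = epithelial, 2 = stromal) so that fixtures stay
#' plain text.
#'
#' @param path mask file.
#' @return integer matrix.
#' @export
read_mask <- function(path) {
  m <- as.matrix(data.table::fread(path, sep = "\t", header = FALSE,
                                   data.table = FALSE))
  storage.mode(m) <- "integer"
  dimnames(m) <- NULL
  m
}

#' @rdname read_mask
#' @param mask integer label matrix.
#' @export
write_mask <- function(mask, path) {
  data.table::fwrite(data.table::as.data.table(mask), path, sep = "\t",
                     col.names = FALSE)
  invisible(path)
}

#' Read a gene-set collection in GMT format
#'
#' One set per line: name, description, then member gene ids, tab-separated.
#' @param path GMT file.
#' @return named list of character vectors of gene ids.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- vapply(parts, length, 0L) < 3L
  if (any(bad)) stop_invalid("GMT line without members in %s", path)
  sets <- lapply(parts, function(x) unique(x[-(1:2)]))
  names(sets) <- vapply(parts, `[`, character(1), 1L)
  if (anyDuplicated(names(sets))) stop_invalid("duplicate set names in %s", path)
  sets
}
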