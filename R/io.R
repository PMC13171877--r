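#' Read a somatic mutation table (MAF subset)
#'
#' Expects a tab-separated file with at least the columns
#' \code{Hugo_Symbol}, \code{Tumor_Sample_Barcode} and
#' \code{Variant_Classification}; \code{HGVSp_Short} is used for the protein
#' change when present. Optional \code{Cohort} / \code{Site} columns populate
#' the sample annotation table; otherwise cohort and site are \code{NA} and
#' must be supplied separately. Gzipped files are read transparently.
#'
#' Variants whose class is outside \code{\link{variant_vocabulary}} are kept
#' but flagged (column \code{known_class}); silent-class filtering happens
#' downstream, never at read time.
#'
#' @param path file path (optionally .gz).
#' @return list with \code{records} (data.frame: gene, sample, variant_class,
#'   protein_change, known_class) and \code{annotations} (data.frame: sample,
#'   cohort, site).
#' @export
read_maf <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE,
                          comment.char = "#")
  need <- c("Hugo_Symbol", "Tumor_Sample_Barcode", "Variant_Classification")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop_fmt("MAF file %s is missing mandatory column(s): %s",
             path, paste(miss, collapse = ", "))
  pc <- if ("HGVSp_Short" %in% names(df)) as.character(df$HGVSp_Short) else ""
  pc[is.na(pc)] <- ""
  records <- data.frame(
    gene = as.character(df$Hugo_Symbol),
    sample = as.character(df$Tumor_Sample_Barcode),
    variant_class = as.character(df$Variant_Classification),
    protein_change = pc,
    stringsAsFactors = FALSE)
  if (any(!nzchar(records$gene)) || any(!nzchar(records$sample)))
    stop_fmt("MAF file %s has empty gene or sample identifiers", path)
  records$known_class <- records$variant_class %in% variant_vocabulary()
  if (!all(records$known_class))
    warning(sprintf("unknown variant class(es) retained: %s",
                    paste(unique(records$variant_class[!records$known_class]),
                          collapse = ", ")))
  samp <- unique(records$sample)
  ann <- data.frame(sample = samp,
                    cohort = NA_character_, site = NA_character_,
                    stringsAsFactors = FALSE)
  if ("Cohort" %in% names(df))
    ann$cohort <- as.character(df$Cohort[match(samp, df$Tumor_Sample_Barcode)])
  if ("Site" %in% names(df))
    ann$site <- as.character(df$Site[match(samp, df$Tumor_Sample_Barcode)])
  list(records = records, annotations = ann)
}

#' Write mutation records as a MAF-style TSV
#'
#' @param records data.frame as produced by \code{\link{read_maf}}.
#' @param path output path.
#' @param annotations optional sample annotations; when given, Cohort/Site
#'   columns are added so the file round-trips.
#' @export
write_maf <- function(records, path, annotations = NULL) {
  out <- data.frame(Hugo_Symbol = records$gene,
                    Tumor_Sample_Barcode = records$sample,
                    Variant_Classification = records$variant_class,
                    HGVSp_Short = records$protein_change,
                    stringsAsFactors = FALSE)
  if (!is.null(annotations)) {
    i <- match(out$Tumor_Sample_Barcode, annotations$sample)
    out$Cohort <- annotations$cohort[i]
    out$Site <- annotations$site[i]
  }
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read copy-number segments (SEG)
#'
#' Accepts the usual SEG layout: sample, chromosome, start, end in the first
#' four columns and the segment mean in the last. Input coordinates are
#' 1-based inclusive and are converted once, here, to the package-internal
#' 0-based half-open convention.
#'
#' @param path file path (optionally .gz).
#' @return data.frame(sample, chrom, start, end, value), 0-based half-open.
#' @export
read_seg <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (nrow(df) == 0L)
    return(data.frame(sample = character(), chrom = character(),
                      start = numeric(), end = numeric(), value = numeric(),
                      stringsAsFactors = FALSE))
  if (ncol(df) < 5L) stop_fmt("SEG file %s needs at least 5 columns", path)
  val <- suppressWarnings(as.numeric(df[[ncol(df)]]))
  if (anyNA(val))
    stop_fmt("SEG file %s: non-numeric segment value at line %d",
             path, which(is.na(val))[1] + 1L)
  start <- suppressWarnings(as.numeric(df[[3]]))
  end <- suppressWarnings(as.numeric(df[[4]]))
  if (anyNA(start) || anyNA(end))
    stop_fmt("SEG file %s: non-numeric coordinates", path)
  bad <- which(start >= end)
  if (length(bad))
    stop_fmt("SEG file %s: start >= end at line %d", path, bad[1] + 1L)
  data.frame(sample = as.character(df[[1]]), chrom = as.character(df[[2]]),
             start = start - 1, end = end, value = val,
             stringsAsFactors = FALSE)
}

#' Write copy-number segments (SEG)
#'
#' Converts the internal 0-based half-open coordinates back to 1-based
#' inclusive on output.
#'
#' @param segments data.frame as from \code{\link{read_seg}}.
#' @param path output path.
#' @export
write_seg <- function(segments, path) {
  out <- data.frame(Sample = segments$sample, Chromosome = segments$chrom,
                    Start = segments$start + 1, End = segments$end,
                    Segment_Mean = segments$value, stringsAsFactors = FALSE)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read an expression matrix (TSV, genes x samples)
#'
#' First column holds gene symbols; values must be non-negative and finite
#' (declared scale: log2(normalized expression + 1)).
#'
#' @param path file path (optionally .gz).
#' @return numeric matrix, genes in rows.
#' @export
read_expression <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  genes <- as.character(df[[1]])
  if (anyDuplicated(genes))
    stop_fmt("expression file %s: duplicate gene label '%s'",
             path, genes[duplicated(genes)][1])
  m <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- genes
  if (any(!is.finite(m)))
    stop_fmt("expression file %s contains non-finite values", path)
  if (any(m < 0))
    stop_fmt(paste("expression file %s contains negative values;",
                   "supply log2(x + 1) transformed non-negative expression"),
             path)
  m
}

#' Write an expression matrix as TSV
#' @param m numeric matrix, genes in rows.
#' @param path output path.
#' @param label name of the leading identifier column.
#' @export
write_expression <- function(m, path, label = "gene") {
  df <- data.frame(rownames(m), m, check.names = FALSE,
                   stringsAsFactors = FALSE)
  names(df)[1] <- label
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read gene sets in GMT format
#'
#' One set per line: name, description, then member genes, tab-separated.
#'
#' @param path file path (optionally .gz).
#' @return named list of character vectors.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  sets <- lapply(lines, function(l) {
    f <- strsplit(l, "\t", fixed = TRUE)[[1]]
    if (length(f) < 3L)
      stop_fmt("GMT line with fewer than 3 fields: '%s'", substr(l, 1, 40))
    unique(f[-(1:2)])
  })
  names(sets) <- vapply(lines, function(l)
    strsplit(l, "\t", fixed = TRUE)[[1]][1], character(1))
  sets
}

#' Write gene sets in GMT format
#' @param sets named list of character vectors.
#' @param path output path.
#' @export
write_gmt <- function(sets, path) {
  lines <- vapply(names(sets), function(n)
    paste(c(n, n, sets[[n]]), collapse = "\t"), character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Parse "chrom:start-end" peak labels
#'
#' Labels are BED-convention 0-based half-open; start must be < end.
#'
#' @param labels character vector.
#' @return data.frame(chrom, start, end).
#' @export
parse_peak_labels <- function(labels) {
  m <- regmatches(labels, regexec("^(.+):([0-9]+)-([0-9]+)$", labels))
  bad <- which(lengths(m) != 4L)
  if (length(bad))
    stop_fmt("malformed peak label '%s'", labels[bad[1]])
  chrom <- vapply(m, `[`, character(1), 2)
  start <- as.numeric(vapply(m, `[`, character(1), 3))
  end <- as.numeric(vapply(m, `[`, character(1), 4))
  bad <- which(start >= end)
  if (length(bad))
    stop_fmt("peak label '%s' has start >= end", labels[bad[1]])
  data.frame(chrom = chrom, start = start, end = end,
             stringsAsFactors = FALSE)
}

#' Read an ATAC peak-count matrix (TSV)
#'
#' Row labels are "chrom:start-end" peak coordinates (0-based half-open);
#' values are normalized read counts, non-negative.
#'
#' @param path file path (optionally .gz).
#' @return numeric matrix, peaks in rows; peak coordinates in
#'   \code{attr(, "peaks")}.
#' @export
read_peak_counts <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  labels <- as.character(df[[1]])
  if (anyDuplicated(labels))
    stop_fmt("peak-count file %s: duplicate peak '%s'",
             path, labels[duplicated(labels)][1])
  peaks <- parse_peak_labels(labels)
  m <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- labels
  if (any(!is.finite(m)) || any(m < 0))
    stop_fmt("peak-count file %s must hold finite non-negative counts", path)
  attr(m, "peaks") <- peaks
  m
}

#' Write an ATAC peak-count matrix as TSV
#' @param m peak-count matrix with "chrom:start-end" row labels.
#' @param path output path.
#' @export
write_peak_counts <- function(m, path) {
  write_expression(m, path, label = "peak")
  invisible(path)
}
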