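#' Read a numeric matrix from a TSV file
#'
#' Reads a tab-separated matrix with row identifiers in the first column and
#' sample identifiers in the header, the layout used throughout the package
#' for expression, enrichment-score, beta-value, miRNA and mutation-context
#' matrices.
#'
#' @param path Path to a TSV file.
#' @return Numeric matrix with rownames and colnames.
#' @export
read_matrix_tsv <- function(path) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- as.character(df[[1]])
  storage.mode(m) <- "double"
  m
}

#' Write a numeric matrix to a TSV file
#'
#' @param m Matrix with rownames and colnames.
#' @param path Output path.
#' @param id_column Name of the first (identifier) column.
#' @export
write_matrix_tsv <- function(m, path, id_column = "id") {
  df <- data.frame(rownames(m), m, check.names = FALSE,
                   stringsAsFactors = FALSE)
  colnames(df) <- c(id_column, colnames(m))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a gene-set collection from a GMT file
#'
#' Standard GMT layout: one set per line, tab-separated as
#' \code{name<TAB>description<TAB>gene1<TAB>gene2...}.
#'
#' @param path Path to a GMT file.
#' @return Named list of character vectors of gene identifiers.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  sets <- lapply(lines, function(l) {
    parts <- strsplit(l, "\t", fixed = TRUE)[[1]]
    if (length(parts) < 3)
      stop("malformed GMT line (need name, description, >=1 gene)")
    unique(parts[-(1:2)])
  })
  names(sets) <- vapply(lines, function(l)
    strsplit(l, "\t", fixed = TRUE)[[1]][1], character(1))
  if (anyDuplicated(names(sets)))
    stop("duplicate set names in GMT file")
  sets
}

#' Write a gene-set collection to a GMT file
#'
#' @param sets Named list of character vectors.
#' @param path Output path.
#' @param descriptions Optional character vector of set descriptions.
#' @export
write_gmt <- function(sets, path, descriptions = NULL) {
  if (is.null(descriptions)) descriptions <- rep("na", length(sets))
  lines <- mapply(function(name, desc, genes)
    paste(c(name, desc, genes), collapse = "\t"),
    names(sets), descriptions, sets)
  writeLines(lines, path)
  invisible(path)
}

#' Read copy-number segments from a SEG file
#'
#' Tab-separated with header: Sample, Chromosome, Start, End, Num_Probes,
#' Segment_Mean (Num_Probes optional). Segment means are log2(copy-number/2).
#'
#' @param path Path to a SEG file.
#' @return data.frame with columns sample, chromosome, start, end,
#'   segment_mean (and n_probes when present).
#' @export
read_seg <- function(path) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          check.names = FALSE, stringsAsFactors = FALSE)
  cn <- tolower(colnames(df))
  need <- c("sample", "chromosome", "start", "end")
  idx <- match(need, cn)
  mean_idx <- grep("segment[._ ]?mean", cn)
  if (anyNA(idx) || length(mean_idx) != 1)
    stop("SEG file must have Sample, Chromosome, Start, End, Segment_Mean")
  out <- data.frame(sample = as.character(df[[idx[1]]]),
                    chromosome = as.character(df[[idx[2]]]),
                    start = as.numeric(df[[idx[3]]]),
                    end = as.numeric(df[[idx[4]]]),
                    segment_mean = as.numeric(df[[mean_idx]]),
                    stringsAsFactors = FALSE)
  np <- grep("num[._ ]?probes", cn)
  if (length(np) == 1) out$n_probes <- as.integer(df[[np]])
  out
}

#' Write copy-number segments to a SEG file
#'
#' @param segments data.frame as returned by [read_seg()].
#' @param path Output path.
#' @export
write_seg <- function(segments, path) {
  df <- data.frame(Sample = segments$sample,
                   Chromosome = segments$chromosome,
                   Start = segments$start,
                   End = segments$end,
                   Num_Probes = if (is.null(segments$n_probes)) NA_integer_
                                else segments$n_probes,
                   Segment_Mean = segments$segment_mean)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a clinical survival table
#'
#' TSV with columns sample, time, event (event coded 0/1).
#'
#' @param path Path to a TSV file.
#' @return data.frame with columns sample, time, event.
#' @export
read_clinical <- function(path) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  stopifnot(all(c("sample", "time", "event") %in% colnames(df)))
  df$sample <- as.character(df$sample)
  df$time <- as.numeric(df$time)
  df$event <- as.integer(df$event)
  df
}
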