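#' Read / write SEG files
#'
#' SEG is tab-separated with columns `Sample`, `Chromosome`, `Start`,
#' `End`, `Num_Probes`, `Segment_Mean` and 1-based inclusive coordinates
#' on disk; internally everything is 0-based half-open, so `Start` becomes
#' `start - 1` on read and `start + 1` on write. Chromosome names are
#' taken verbatim. Overlapping segments within one sample are a
#' validation error.
#'
#' @param path file path.
#' @param labels optional named vector (`"tumor"`/`"normal"` per sample);
#'   defaults to all `"tumor"`.
#' @return `read_seg`: a `segment_set`. `write_seg`: the path, invisibly.
#' @export
read_seg <- function(path, labels = NULL) {
  df <- tryCatch(
    read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE,
               colClasses = c("character", "character", "numeric", "numeric",
                              "numeric", "numeric")),
    error = function(e) stop("malformed SEG file ", path, ": ",
                             conditionMessage(e))
  )
  if (ncol(df) != 6L) stop("SEG file must have 6 columns, found ", ncol(df))
  names(df) <- c("Sample", "Chromosome", "Start", "End",
                 "Num_Probes", "Segment_Mean")
  bad <- which(!is.finite(df$Segment_Mean) | df$Start > df$End)
  if (length(bad)) {
    stop("malformed SEG record at line ", bad[1] + 1L, " of ", path)
  }
  segments <- data.frame(sample = df$Sample, chromosome = df$Chromosome,
                         start = df$Start - 1, end = df$End,
                         log2_ratio = df$Segment_Mean,
                         stringsAsFactors = FALSE)
  samples <- unique(segments$sample)
  if (is.null(labels)) {
    labels <- setNames(rep("tumor", length(samples)), samples)
  }
  out <- structure(list(segments = segments, labels = labels,
                        carriers = list()),
                   class = "segment_set")
  validate_segment_set(out)
  out
}

#' @rdname read_seg
#' @param segments a `segment_set`.
#' @export
write_seg <- function(segments, path) {
  validate_segment_set(segments)
  s <- segments$segments
  df <- data.frame(Sample = s$sample, Chromosome = s$chromosome,
                   Start = format(s$start + 1, scientific = FALSE, trim = TRUE),
                   End = format(s$end, scientific = FALSE, trim = TRUE),
                   Num_Probes = pmax(1, round((s$end - s$start) / 1e3)),
                   Segment_Mean = s$log2_ratio)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read / write gene annotation (GTF-lite)
#'
#' One `gene` feature line per gene: tab-separated GTF fields with
#' 1-based inclusive coordinates on disk (converted to internal 0-based
#' half-open) and attributes `gene_id`, `biotype`, `driver`.
#'
#' @param path file path.
#' @return `read_genes`: a gene data frame (`gene_id`, `chromosome`,
#'   `start`, `end`, `strand`, `biotype`, `driver`, `tss`).
#' @export
read_genes <- function(path) {
  lines <- readLines(path)
  lines <- lines[!grepl("^#", lines) & nzchar(lines)]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf != 9L)) {
    stop("malformed GTF-lite line ", which(nf != 9L)[1], " in ", path)
  }
  attr_get <- function(a, key) {
    m <- regmatches(a, regexec(paste0(key, ' "([^"]*)"'), a))
    vapply(m, function(x) if (length(x) == 2) x[2] else NA_character_,
           character(1))
  }
  attrs <- vapply(fields, `[[`, character(1), 9L)
  strand <- vapply(fields, `[[`, character(1), 7L)
  if (!all(strand %in% c("+", "-"))) {
    stop("unknown strand in ", path)
  }
  genes <- data.frame(
    gene_id = attr_get(attrs, "gene_id"),
    chromosome = vapply(fields, `[[`, character(1), 1L),
    start = as.numeric(vapply(fields, `[[`, character(1), 4L)) - 1,
    end = as.numeric(vapply(fields, `[[`, character(1), 5L)),
    strand = strand,
    biotype = attr_get(attrs, "biotype"),
    driver = attr_get(attrs, "driver") == "TRUE",
    stringsAsFactors = FALSE
  )
  if (anyDuplicated(genes$gene_id)) stop("duplicate gene ids in ", path)
  if (any(is.na(genes$gene_id)) || any(is.na(genes$biotype))) {
    stop("missing gene_id/biotype attribute in ", path)
  }
  genes$tss <- ifelse(genes$strand == "+", genes$start, genes$end)
  genes
}

#' @rdname read_genes
#' @param genes gene data frame (as in a `genome_spec`).
#' @export
write_genes <- function(genes, path) {
  lines <- sprintf(
    '%s\tscnalnc\tgene\t%s\t%s\t.\t%s\t.\tgene_id "%s"; biotype "%s"; driver "%s";',
    genes$chromosome,
    format(genes$start + 1, scientific = FALSE, trim = TRUE),
    format(genes$end, scientific = FALSE, trim = TRUE),
    genes$strand, genes$gene_id, genes$biotype, genes$driver)
  writeLines(lines, path)
  invisible(path)
}

#' Read / write BED intervals
#'
#' BED is 0-based half-open on disk, matching the internal convention:
#' no coordinate conversion. BED4/BED6 accepted; missing `score`/`strand`
#' filled with `0`/`"."`.
#'
#' @param path file path.
#' @return `read_bed`: data frame (`chromosome`, `start`, `end`, `name`,
#'   `score`, `strand`).
#' @export
read_bed <- function(path) {
  df <- read.table(path, sep = "\t", stringsAsFactors = FALSE)
  if (ncol(df) < 3L) stop("BED file needs >= 3 columns: ", path)
  names(df) <- c("chromosome", "start", "end", "name",
                 "score", "strand")[seq_len(min(6L, ncol(df)))]
  df <- df[, seq_len(min(6L, ncol(df))), drop = FALSE]
  if (!"name" %in% names(df)) df$name <- "."
  if (!"score" %in% names(df)) df$score <- 0
  if (!"strand" %in% names(df)) df$strand <- "."
  bad <- which(!(df$start >= 0 & df$start < df$end))
  if (length(bad)) stop("invalid BED interval at line ", bad[1], " of ", path)
  df[, c("chromosome", "start", "end", "name", "score", "strand")]
}

#' @rdname read_bed
#' @param intervals interval data frame.
#' @export
write_bed <- function(intervals, path) {
  df <- data.frame(
    chromosome = intervals$chromosome,
    start = format(intervals$start, scientific = FALSE, trim = TRUE),
    end = format(intervals$end, scientific = FALSE, trim = TRUE),
    name = if (is.null(intervals$name)) "." else intervals$name,
    score = if (is.null(intervals$score)) 0 else intervals$score,
    strand = if (is.null(intervals$strand)) "." else intervals$strand)
  write.table(df, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read / write labeled matrices (TSV)
#'
#' Layout: header row `id<TAB>sample ids...`, second row
#' `label<TAB>tumor/normal...`, then one row per gene/CpG. Row and column
#' ids must be unique.
#'
#' @param path file path.
#' @return `read_matrix`: a `labeled_matrix` (list of `values`, `labels`).
#' @export
read_matrix <- function(path) {
  lines <- readLines(path, n = 2L)
  header <- strsplit(lines[1], "\t", fixed = TRUE)[[1]]
  labrow <- strsplit(lines[2], "\t", fixed = TRUE)[[1]]
  if (labrow[1] != "label") stop("matrix file lacks a label row: ", path)
  samples <- header[-1]
  if (anyDuplicated(samples)) stop("duplicate sample ids in ", path)
  labels <- setNames(labrow[-1], samples)
  df <- read.table(path, sep = "\t", skip = 2L, stringsAsFactors = FALSE,
                   colClasses = c("character", rep("numeric", length(samples))))
  if (anyDuplicated(df[[1]])) stop("duplicate row ids in ", path)
  values <- as.matrix(df[, -1, drop = FALSE])
  dimnames(values) <- list(df[[1]], samples)
  structure(list(values = values, labels = labels), class = "labeled_matrix")
}

#' @rdname read_matrix
#' @param mat a `labeled_matrix` (or list with `values` and `labels`).
#' @export
write_matrix <- function(mat, path) {
  v <- mat$values
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(c("id", colnames(v)), collapse = "\t"), con)
  writeLines(paste(c("label", mat$labels[colnames(v)]), collapse = "\t"), con)
  body <- cbind(rownames(v), format(v, scientific = FALSE, trim = TRUE,
                                    digits = 15))
  writeLines(apply(body, 1, paste, collapse = "\t"), con)
  invisible(path)
}

#' Read / write gene-set GMT files
#'
#' One signature per line: name, description, then member gene ids,
#' tab-separated. Empty signatures are an error.
#'
#' @param path file path.
#' @return `read_gmt`: named list of character vectors.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  short <- lengths(fields) < 3L
  if (any(short)) stop("empty signature at line ", which(short)[1],
                       " of ", path)
  sets <- lapply(fields, function(x) x[-(1:2)])
  names(sets) <- vapply(fields, `[[`, character(1), 1L)
  if (anyDuplicated(names(sets))) stop("duplicate signature names in ", path)
  sets
}

#' @rdname read_gmt
#' @param sets named list of character vectors.
#' @export
write_gmt <- function(sets, path) {
  if (any(lengths(sets) == 0L)) stop("refusing to write an empty signature")
  lines <- vapply(seq_along(sets), function(i) {
    paste(c(names(sets)[i], "na", sets[[i]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}
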