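#' Genomic regions and overlap machinery
#'
#' Regions throughout the package are plain data.frames with columns
#' `chrom`, `start`, `end` (0-based, half-open, as in BED) and an optional
#' `name`. Overlap means >= 1 bp intersection.
#'
#' @param chrom character vector of chromosome names
#' @param start,end 0-based half-open coordinates, `start < end`
#' @param name optional region identifiers
#' @return a `data.frame` with columns chrom, start, end and, if supplied,
#'   name
#' @export
region <- function(chrom, start, end, name = NULL) {
  start <- as.numeric(start)
  end <- as.numeric(end)
  if (any(start < 0)) stop("region start must be >= 0")
  if (any(start >= end)) stop("region start must be < end")
  out <- data.frame(chrom = as.character(chrom), start = start, end = end,
                    stringsAsFactors = FALSE)
  if (!is.null(name)) out$name <- as.character(name)
  out
}

# Pairs (query index, subject index) with >= 1 bp intersection on 0-based
# half-open intervals. IRanges is 1-based closed, hence the +1 on starts.
overlap_pairs <- function(query, subject) {
  if (nrow(query) == 0L || nrow(subject) == 0L) {
    return(data.frame(query = integer(0), subject = integer(0)))
  }
  qr <- IRanges::IRanges(start = query$start + 1L, end = query$end)
  sr <- IRanges::IRanges(start = subject$start + 1L, end = subject$end)
  out <- vector("list", 0L)
  for (ch in unique(query$chrom)) {
    qi <- which(query$chrom == ch)
    si <- which(subject$chrom == ch)
    if (length(si) == 0L) next
    hits <- IRanges::findOverlaps(qr[qi], sr[si], minoverlap = 1L)
    out[[ch]] <- data.frame(query = qi[S4Vectors::queryHits(hits)],
                            subject = si[S4Vectors::subjectHits(hits)])
  }
  if (length(out) == 0L) {
    return(data.frame(query = integer(0), subject = integer(0)))
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Read a BED file of peaks
#'
#' Expects at least three whitespace-separated columns (chrom, start, end);
#' a fourth column is taken as the peak name. Coordinates are validated as
#' 0-based half-open.
#'
#' @param path file path
#' @return data.frame of regions (possibly zero rows)
#' @export
read_bed <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) {
    return(data.frame(chrom = character(0), start = numeric(0),
                      end = numeric(0), name = character(0)))
  }
  fields <- strsplit(trimws(lines), "[ \t]+")
  n <- vapply(fields, length, 1L)
  bad <- which(n < 3L)
  if (length(bad)) stop("malformed BED line ", bad[1], " in ", path)
  chrom <- vapply(fields, `[[`, "", 1L)
  start <- suppressWarnings(as.numeric(vapply(fields, `[[`, "", 2L)))
  end <- suppressWarnings(as.numeric(vapply(fields, `[[`, "", 3L)))
  bad <- which(is.na(start) | is.na(end) | start < 0 | start >= end)
  if (length(bad)) stop("invalid coordinates at BED line ", bad[1], " in ", path)
  name <- ifelse(n >= 4L, vapply(fields, function(f) f[min(4L, length(f))], ""),
                 paste0("peak", seq_along(fields)))
  region(chrom, start, end, name)
}

#' Read a chromatin-loop table
#'
#' Tab-separated with header: chrom1, start1, end1, chrom2, start2, end2,
#' reads, fdr. Anchors are 0-based half-open.
#'
#' @param path file path
#' @return data.frame of loops
#' @export
read_loops <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  need <- c("chrom1", "start1", "end1", "chrom2", "start2", "end2",
            "reads", "fdr")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("loop table missing columns: ",
                         paste(miss, collapse = ", "))
  bad <- which(df$start1 >= df$end1 | df$start2 >= df$end2 |
                 df$start1 < 0 | df$start2 < 0)
  if (length(bad)) stop("invalid anchor coordinates at loop table line ",
                        bad[1] + 1L, " in ", path)
  if (any(df$reads < 0) || any(df$reads != round(df$reads))) {
    stop("loop read counts must be non-negative integers")
  }
  if (any(df$fdr < 0 | df$fdr > 1)) stop("loop FDR must lie in [0, 1]")
  df
}

#' Read a gene annotation table
#'
#' Tab-separated with header: gene_id, chrom, tss, strand, length. One TSS
#' per gene is required; multi-TSS genes must be resolved upstream.
#'
#' @param path file path
#' @return data.frame with one row per gene
#' @export
read_annotation <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  need <- c("gene_id", "chrom", "tss", "strand", "length")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("annotation missing columns: ",
                         paste(miss, collapse = ", "))
  if (anyDuplicated(df$gene_id)) {
    stop("annotation must have one row (one TSS) per gene; duplicated: ",
         paste(unique(df$gene_id[duplicated(df$gene_id)])[1:3], collapse = ", "))
  }
  df
}

#' Read an integrated-signal table
#'
#' Tab-separated with header; first column `region_id`, remaining columns
#' one per assay, values non-negative integrated signal.
#'
#' @param path file path
#' @return data.frame with rownames = region ids and one numeric column per
#'   assay
#' @export
read_signal <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE, check.names = FALSE)
  if (names(df)[1] != "region_id") stop("signal table must start with region_id")
  rn <- df$region_id
  df <- df[, -1, drop = FALSE]
  if (any(as.matrix(df) < 0)) stop("signal values must be non-negative")
  rownames(df) <- rn
  df
}

#' @rdname read_bed
#' @param regions data.frame of regions to write
#' @export
write_bed <- function(regions, path) {
  df <- data.frame(regions$chrom, format_coord(regions$start),
                   format_coord(regions$end))
  if (!is.null(regions$name)) df$name <- regions$name
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

# fixed notation so rewrites are byte-identical
format_coord <- function(x) format(x, scientific = FALSE, trim = TRUE)

write_tsv <- function(df, path, row_names = FALSE) {
  num <- vapply(df, is.numeric, TRUE)
  df[num] <- lapply(df[num], function(x) format(x, scientific = FALSE,
                                                trim = TRUE, digits = 15))
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = row_names, col.names = TRUE)
  invisible(path)
}
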