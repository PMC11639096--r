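## On-disk formats.  All coordinates everywhere in this package are 0-based
## half-open (BED convention); bin i spans [i*bin_size, (i+1)*bin_size).
## Contact matrices are stored as plain-text COO triplets "chrom i j count"
## with i <= j (upper triangle), one matrix per chromosome per sample.

#' Construct a binned contact matrix
#'
#' A `contact_matrix` holds the upper triangle of a symmetric per-chromosome
#' raw-count matrix as sparse (i, j, count) triplets with 0-based bin indices
#' `i <= j`.  Entries supplied in the lower triangle are folded onto the
#' upper triangle; duplicated pixels are summed.
#'
#' @param chrom Chromosome name.
#' @param bin_size Bin size in bp.
#' @param n_bins Number of bins on the chromosome.
#' @param i,j Integer 0-based bin indices.
#' @param count Non-negative contact counts, same length as `i`.
#' @return An object of class `contact_matrix` with fields `chrom`,
#'   `bin_size`, `n_bins` and a data frame `counts` with columns `i`, `j`,
#'   `count` (zero-count entries dropped).
#' @export
contact_matrix <- function(chrom, bin_size, n_bins, i = integer(),
                           j = integer(), count = numeric()) {
  stopifnot(length(i) == length(j), length(j) == length(count))
  if (length(count) && any(count < 0)) stop("negative contact counts")
  if (length(i) && (any(i < 0L) || any(j < 0L) ||
                    any(i >= n_bins) || any(j >= n_bins)))
    stop("bin index out of bounds [0, n_bins)")
  ii <- pmin(i, j); jj <- pmax(i, j)
  keep <- count != 0
  ii <- ii[keep]; jj <- jj[keep]; cc <- count[keep]
  if (length(ii)) {
    key <- ii * n_bins + jj
    agg <- rowsum(cc, group = key, reorder = TRUE)
    key <- as.numeric(rownames(agg))
    ii <- as.integer(key %/% n_bins)
    jj <- as.integer(key %% n_bins)
    cc <- as.numeric(agg[, 1L])
  }
  structure(list(chrom = chrom, bin_size = as.integer(bin_size),
                 n_bins = as.integer(n_bins),
                 counts = data.frame(i = as.integer(ii), j = as.integer(jj),
                                     count = cc)),
            class = "contact_matrix")
}

#' @export
print.contact_matrix <- function(x, ...) {
  cat(sprintf("contact_matrix: %s, %d bins of %d bp, %d stored pixels, total %.4g\n",
              x$chrom, x$n_bins, x$bin_size, nrow(x$counts), sum(x$counts$count)))
  invisible(x)
}

#' Convert a contact matrix to a dense symmetric matrix
#'
#' @param cm A [contact_matrix()].
#' @return A dense `n_bins x n_bins` symmetric numeric matrix.
#' @export
as_dense <- function(cm) {
  n <- cm$n_bins
  M <- matrix(0, n, n)
  if (nrow(cm$counts)) {
    idx <- cbind(cm$counts$i + 1L, cm$counts$j + 1L)
    M[idx] <- cm$counts$count
    M[idx[, c(2, 1), drop = FALSE]] <- cm$counts$count
  }
  M
}

#' Build a contact matrix from a dense symmetric matrix
#'
#' @param M Dense symmetric matrix of counts.
#' @param chrom Chromosome name.
#' @param bin_size Bin size in bp.
#' @return A [contact_matrix()].
#' @export
dense_to_contacts <- function(M, chrom, bin_size) {
  n <- nrow(M)
  up <- which(upper.tri(M, diag = TRUE) & M != 0, arr.ind = TRUE)
  contact_matrix(chrom, bin_size, n,
                 i = up[, 1] - 1L, j = up[, 2] - 1L, count = M[up])
}

#' Parse a COO contact-matrix file
#'
#' Reads whitespace-delimited lines `chrom i j count` with 0-based bin
#' indices.  Lower-triangle entries are folded onto the upper triangle and
#' duplicate pixels summed.
#'
#' @param path File path.
#' @param bin_size Bin size in bp.
#' @param chrom_length Chromosome length in bp; `n_bins = ceiling(chrom_length
#'   / bin_size)`.
#' @return A [contact_matrix()].
#' @export
parse_contacts <- function(path, bin_size, chrom_length) {
  n_bins <- as.integer(ceiling(chrom_length / bin_size))
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) {
    return(contact_matrix("chr", bin_size, n_bins))
  }
  fields <- strsplit(trimws(lines), "[ \t]+")
  nf <- lengths(fields)
  if (any(nf != 4L))
    stop(sprintf("malformed contact line %d: expected 4 fields, got %d",
                 which(nf != 4L)[1], nf[nf != 4L][1]))
  m <- matrix(unlist(fields), ncol = 4, byrow = TRUE)
  i <- suppressWarnings(as.integer(m[, 2]))
  j <- suppressWarnings(as.integer(m[, 3]))
  cnt <- suppressWarnings(as.numeric(m[, 4]))
  bad <- which(is.na(i) | is.na(j) | is.na(cnt))
  if (length(bad))
    stop(sprintf("malformed contact line %d: non-numeric field", bad[1]))
  if (any(i >= n_bins | j >= n_bins | i < 0 | j < 0))
    stop(sprintf("bin index out of bounds at line %d (n_bins = %d)",
                 which(i >= n_bins | j >= n_bins | i < 0 | j < 0)[1], n_bins))
  if (any(cnt < 0))
    stop(sprintf("negative count at line %d", which(cnt < 0)[1]))
  chrom <- m[1, 1]
  contact_matrix(chrom, bin_size, n_bins, i = i, j = j, count = cnt)
}

#' Write a contact matrix as COO text
#'
#' Round-trips with [parse_contacts()] entry for entry.
#'
#' @param cm A [contact_matrix()].
#' @param path Output path.
#' @export
serialize_contacts <- function(cm, path) {
  df <- cm$counts
  con <- file(path, open = "w")
  on.exit(close(con))
  if (nrow(df))
    writeLines(sprintf("%s\t%d\t%d\t%s", cm$chrom, df$i, df$j,
                       format(df$count, digits = 15, trim = TRUE,
                              scientific = FALSE)), con)
  invisible(path)
}

#' Parse a BED3/BED6 interval file
#'
#' @param path Tab-delimited BED file with 3 to 6 columns.
#' @return A data frame with columns `chrom`, `start`, `end` and, when
#'   present, `name`, `score`, `strand`; 0-based half-open coordinates
#'   preserved, file order preserved.
#' @export
parse_intervals <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (!length(lines))
    return(data.frame(chrom = character(), start = integer(),
                      end = integer()))
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 3L)) stop(sprintf("BED line %d has fewer than 3 columns",
                                 which(nf < 3L)[1]))
  ncol <- min(nf)
  m <- t(vapply(fields, function(f) f[seq_len(ncol)], character(ncol)))
  start <- suppressWarnings(as.numeric(m[, 2]))
  end <- suppressWarnings(as.numeric(m[, 3]))
  if (anyNA(start) || anyNA(end) || any(start != floor(start)) ||
      any(end != floor(end)))
    stop("non-integer BED coordinates")
  if (any(start >= end))
    stop(sprintf("invalid interval at line %d: start >= end",
                 which(start >= end)[1]))
  out <- data.frame(chrom = m[, 1], start = as.integer(start),
                    end = as.integer(end))
  if (ncol >= 4) out$name <- m[, 4]
  if (ncol >= 5) {
    sc <- suppressWarnings(as.numeric(m[, 5]))
    if (any(!is.finite(sc) & m[, 5] != ".")) stop("non-finite BED score")
    out$score <- sc
  }
  if (ncol >= 6) {
    if (!all(m[, 6] %in% c("+", "-", "."))) stop("invalid strand field")
    out$strand <- m[, 6]
  }
  out
}

#' Write intervals as BED
#'
#' @param intervals Data frame with `chrom`, `start`, `end` and optional
#'   `name`, `score`, `strand` columns.
#' @param path Output path.
#' @export
serialize_intervals <- function(intervals, path) {
  cols <- intersect(c("chrom", "start", "end", "name", "score", "strand"),
                    names(intervals))
  write.table(intervals[, cols, drop = FALSE], path, sep = "\t",
              quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Write a per-bin track as bedGraph
#'
#' @param chrom Chromosome name.
#' @param bin_size Bin size in bp.
#' @param values One value per bin; `NA` allowed.
#' @param path Output path.
#' @param skip_missing Drop `NA` bins instead of writing `nan` tokens.
#' @export
serialize_track <- function(chrom, bin_size, values, path,
                            skip_missing = FALSE) {
  n <- length(values)
  start <- (seq_len(n) - 1L) * bin_size
  end <- start + bin_size
  keep <- if (skip_missing) !is.na(values) else rep(TRUE, n)
  val <- ifelse(is.na(values[keep]), "nan",
                format(values[keep], digits = 7, trim = TRUE,
                       scientific = FALSE))
  writeLines(sprintf("%s\t%d\t%d\t%s", chrom, start[keep], end[keep], val),
             path)
  invisible(path)
}

#' Parse a bedGraph track back to per-bin values
#'
#' @param path bedGraph file written by [serialize_track()].
#' @param bin_size Bin size in bp.
#' @param n_bins Number of bins; positions absent from the file become `NA`.
#' @return Numeric vector of length `n_bins`.
#' @export
parse_track <- function(path, bin_size, n_bins) {
  out <- rep(NA_real_, n_bins)
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (!length(lines)) return(out)
  m <- do.call(rbind, strsplit(lines, "\t", fixed = TRUE))
  idx <- as.integer(as.numeric(m[, 2]) / bin_size) + 1L
  out[idx] <- suppressWarnings(as.numeric(m[, 4]))  # "nan" -> NaN
  out[is.nan(out)] <- NA_real_
  out
}

#' Write anchor pairs (loops) as BEDPE
#'
#' Emits `chrom1 start1 end1 chrom2 start2 end2 name score strand1 strand2`
#' followed by any extra numeric columns present in `pairs` (observed counts,
#' expected components, q-values, ...).
#'
#' @param pairs Data frame with columns `chrom1`, `start1`, `end1`, `chrom2`,
#'   `start2`, `end2` plus optional extra columns.
#' @param path Output path.
#' @export
serialize_pairs <- function(pairs, path) {
  req <- c("chrom1", "start1", "end1", "chrom2", "start2", "end2")
  if (nrow(pairs)) {
    stopifnot(all(req %in% names(pairs)))
    same <- pairs$chrom1 == pairs$chrom2
    if (any(same & pairs$start1 > pairs$start2))
      stop("anchor1 must sort before anchor2")
    extra <- setdiff(names(pairs), req)
    df <- data.frame(pairs$chrom1, pairs$start1, pairs$end1,
                     pairs$chrom2, pairs$start2, pairs$end2,
                     name = ".", score = ".", strand1 = ".", strand2 = ".")
    for (cl in extra) df[[cl]] <- pairs[[cl]]
    write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                col.names = FALSE)
  } else {
    file.create(path)
  }
  invisible(path)
}

#' Parse a BEDPE file written by [serialize_pairs()]
#'
#' @param path BEDPE file.
#' @param extra_names Names for columns beyond the standard 10.
#' @return Data frame with the six coordinate columns and any extras.
#' @export
parse_pairs <- function(path, extra_names = NULL) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  base <- data.frame(chrom1 = character(), start1 = integer(),
                     end1 = integer(), chrom2 = character(),
                     start2 = integer(), end2 = integer())
  if (!length(lines)) return(base)
  m <- do.call(rbind, strsplit(lines, "\t", fixed = TRUE))
  out <- data.frame(chrom1 = m[, 1], start1 = as.integer(m[, 2]),
                    end1 = as.integer(m[, 3]), chrom2 = m[, 4],
                    start2 = as.integer(m[, 5]), end2 = as.integer(m[, 6]))
  if (ncol(m) > 10) {
    for (k in 11:ncol(m)) {
      nm <- if (!is.null(extra_names) && k - 10 <= length(extra_names))
        extra_names[k - 10] else paste0("extra", k - 10)
      out[[nm]] <- as.numeric(m[, k])
    }
  }
  out
}

#' Parse a gene-by-sample counts table
#'
#' Expects a TSV with header `gene chrom start end <sample1> <sample2> ...`.
#'
#' @param path Counts TSV.
#' @param sample_ids Optional character vector; when given, count columns are
#'   aligned to this order and a missing sample is an error.
#' @return List with `counts` (integer matrix, genes x samples) and
#'   `genes` (data frame gene/chrom/start/end).
#' @export
parse_counts <- function(path, sample_ids = NULL) {
  df <- read.table(path, header = TRUE, sep = "\t", check.names = FALSE,
                   stringsAsFactors = FALSE)
  req <- c("gene", "chrom", "start", "end")
  stopifnot(all(req %in% names(df)))
  if (anyDuplicated(df$gene)) stop("duplicate gene ids in counts table")
  cnt <- as.matrix(df[, setdiff(names(df), req), drop = FALSE])
  if (any(cnt < 0)) stop("negative count in counts table")
  if (any(cnt != floor(cnt))) stop("non-integer count in counts table")
  rownames(cnt) <- df$gene
  if (!is.null(sample_ids)) {
    missing <- setdiff(sample_ids, colnames(cnt))
    if (length(missing))
      stop("counts table lacks sample column(s): ",
           paste(missing, collapse = ", "))
    cnt <- cnt[, sample_ids, drop = FALSE]
  }
  list(counts = cnt, genes = df[, req])
}

#' Write a counts table readable by [parse_counts()]
#'
#' @param counts Integer matrix, genes x samples, with dimnames.
#' @param genes Data frame with `gene`, `chrom`, `start`, `end` rows aligned
#'   to `counts`.
#' @param path Output path.
#' @export
serialize_counts <- function(counts, genes, path) {
  stopifnot(nrow(counts) == nrow(genes))
  df <- cbind(genes[, c("gene", "chrom", "start", "end")],
              as.data.frame(counts, check.names = FALSE))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
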