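# I/O for domain lists, subcompartment annotations and binned contact
# matrices. All genomic coordinates are 0-based half-open (BED convention);
# bin indices in sparse-triple files are 0-based.

#' Read a BED-like contact-domain list
#'
#' Parses a tab-separated BED3+ file into a domain table. Coordinates are
#' 0-based half-open; intervals are returned sorted by (chrom, start, end)
#' and given stable ids of the form \code{chrom:start-end}.
#'
#' @param path Path to a tab-separated file with at least three columns:
#'   chrom, start, end. Further columns are ignored.
#' @return A data.frame with columns \code{chrom}, \code{start}, \code{end},
#'   \code{id} and \code{subcompartment} (all \code{NA} here; see
#'   \code{\link{assign_subcompartments}}).
#' @export
read_domains <- function(path) {
  lines <- read_bed_lines(path, min_cols = 3L, what = "domain list")
  if (nrow(lines) == 0L) {
    warning("empty domain file: ", path)
    return(empty_domains())
  }
  df <- data.frame(chrom = lines$chrom, start = lines$start, end = lines$end,
                   stringsAsFactors = FALSE)
  df <- df[order(df$chrom, df$start, df$end), , drop = FALSE]
  rownames(df) <- NULL
  df$id <- paste0(df$chrom, ":", df$start, "-", df$end)
  df$subcompartment <- NA_character_
  df
}

#' Read a subcompartment annotation
#'
#' Parses a BED4 file whose fourth column carries a subcompartment label
#' (A1, A2, B1, B2, B3 or B4).
#'
#' @param path Path to a tab-separated BED4 file.
#' @param labels Allowed labels; lines with other labels raise an error.
#' @return A data.frame with columns \code{chrom}, \code{start}, \code{end},
#'   \code{label}, sorted by (chrom, start).
#' @export
read_subcompartments <- function(path,
                                 labels = c("A1", "A2", "B1", "B2", "B3", "B4")) {
  lines <- read_bed_lines(path, min_cols = 4L, what = "subcompartment annotation")
  if (nrow(lines) == 0L) {
    warning("empty subcompartment file: ", path)
    return(data.frame(chrom = character(), start = integer(), end = integer(),
                      label = character(), stringsAsFactors = FALSE))
  }
  bad <- which(!(lines$extra %in% labels))
  if (length(bad) > 0L) {
    stop("unknown subcompartment label '", lines$extra[bad[1L]],
         "' on line ", lines$line[bad[1L]], " of ", path)
  }
  df <- data.frame(chrom = lines$chrom, start = lines$start, end = lines$end,
                   label = lines$extra, stringsAsFactors = FALSE)
  df <- df[order(df$chrom, df$start), , drop = FALSE]
  rownames(df) <- NULL
  df
}

# Shared BED-ish parser: validates column count and integer coordinates,
# reporting offending line numbers.
read_bed_lines <- function(path, min_cols, what) {
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- readLines(path)
  raw <- raw[nzchar(trimws(raw))]
  raw <- raw[!startsWith(raw, "#") & !startsWith(raw, "track")]
  if (length(raw) == 0L) {
    return(data.frame(chrom = character(), start = integer(), end = integer(),
                      extra = character(), line = integer(),
                      stringsAsFactors = FALSE))
  }
  parts <- strsplit(raw, "\t", fixed = TRUE)
  out <- data.frame(chrom = NA_character_, start = NA_integer_,
                    end = NA_integer_, extra = NA_character_,
                    line = seq_along(raw), stringsAsFactors = FALSE)
  for (i in seq_along(parts)) {
    p <- parts[[i]]
    if (length(p) < min_cols) {
      stop("line ", i, " of ", path, ": expected >= ", min_cols,
           " tab-separated columns in ", what, ", found ", length(p))
    }
    s <- suppressWarnings(as.numeric(p[2L]))
    e <- suppressWarnings(as.numeric(p[3L]))
    if (is.na(s) || is.na(e) || s != floor(s) || e != floor(e)) {
      stop("line ", i, " of ", path, ": non-integer coordinates '",
           p[2L], "', '", p[3L], "'")
    }
    if (s < 0 || s >= e) {
      stop("line ", i, " of ", path, ": invalid interval [", s, ", ", e,
           ") (need 0 <= start < end)")
    }
    out$chrom[i] <- p[1L]
    out$start[i] <- as.integer(s)
    out$end[i] <- as.integer(e)
    if (length(p) >= 4L) out$extra[i] <- p[4L]
  }
  out
}

empty_domains <- function() {
  data.frame(chrom = character(), start = integer(), end = integer(),
             id = character(), subcompartment = character(),
             stringsAsFactors = FALSE)
}

#' Write a domain table as BED
#'
#' Writes BED3 (or BED4 with the subcompartment label when any domain is
#' labeled). Inverse of \code{\link{read_domains}} up to column selection.
#'
#' @param domains Domain table as returned by \code{\link{read_domains}}.
#' @param path Output path.
#' @export
write_domains <- function(domains, path) {
  cols <- domains[, c("chrom", "start", "end"), drop = FALSE]
  if ("subcompartment" %in% names(domains) &&
      any(!is.na(domains$subcompartment))) {
    cols$label <- ifelse(is.na(domains$subcompartment), "NA",
                         domains$subcompartment)
  }
  utils::write.table(cols, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Construct a binned contact matrix
#'
#' Container for a symmetric (cis) or rectangular (trans) binned Hi-C
#' intensity matrix.
#'
#' @param mat Numeric or \code{Matrix} matrix of nonnegative intensities;
#'   rows index bins of \code{chrom_row}, columns bins of \code{chrom_col}.
#' @param chrom_row,chrom_col Chromosome names; equal for cis matrices.
#' @param bin_size Bin size in bp.
#' @param normalized Logical; \code{TRUE} once balanced.
#' @return An object of class \code{contact_matrix}.
#' @export
contact_matrix <- function(mat, chrom_row, chrom_col = chrom_row,
                           bin_size, normalized = FALSE) {
  mat <- methods::as(methods::as(Matrix::Matrix(mat, sparse = TRUE),
                                 "generalMatrix"), "CsparseMatrix")
  if (any(mat@x < 0)) stop("contact matrix has negative intensities")
  cis <- identical(chrom_row, chrom_col)
  if (cis) {
    if (nrow(mat) != ncol(mat)) stop("cis contact matrix must be square")
    asym <- max(abs(mat - Matrix::t(mat)))
    if (asym > 1e-6 * max(1, max(abs(mat@x), 0))) {
      stop("cis contact matrix asymmetric beyond tolerance (max deviation ",
           format(asym), ")")
    }
  }
  structure(list(mat = mat, chrom_row = chrom_row, chrom_col = chrom_col,
                 bin_size = as.numeric(bin_size), cis = cis,
                 normalized = normalized),
            class = "contact_matrix")
}

#' @export
print.contact_matrix <- function(x, ...) {
  cat(sprintf("contact_matrix: %s x %s, %d x %d bins of %g bp, %s\n",
              x$chrom_row, x$chrom_col, nrow(x$mat), ncol(x$mat),
              x$bin_size, if (x$normalized) "normalized" else "raw counts"))
  invisible(x)
}

#' Read a binned contact matrix from text
#'
#' Sparse-triple files have lines \code{bin_i<TAB>bin_j<TAB>value} with
#' 0-based bin indices; dense files are whitespace-separated matrices.
#' Cis matrices are symmetrized: a triple given only as (i, j) is mirrored
#' to (j, i); triples present in both orientations must agree. Dense cis
#' input must be symmetric to within 1e-6.
#'
#' @param path Input path.
#' @param bin_size Bin size in bp.
#' @param format \code{"sparse"} (triples) or \code{"dense"}.
#' @param chrom_row,chrom_col Chromosome names; equal means cis.
#' @param n_bins Number of bins; for sparse input defaults to the largest
#'   index seen plus one. Length 2 for trans matrices.
#' @return A \code{\link{contact_matrix}}.
#' @export
read_contact_matrix <- function(path, bin_size, format = c("sparse", "dense"),
                                chrom_row, chrom_col = chrom_row,
                                n_bins = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  cis <- identical(chrom_row, chrom_col)
  if (format == "dense") {
    mat <- as.matrix(utils::read.table(path, header = FALSE))
    dimnames(mat) <- NULL
    if (any(mat < 0)) stop("negative intensity in ", path)
    return(contact_matrix(mat, chrom_row, chrom_col, bin_size))
  }
  tr <- utils::read.table(path, header = FALSE, sep = "\t",
                          col.names = c("i", "j", "value"))
  if (nrow(tr) > 0 && any(tr$value < 0)) {
    stop("negative intensity on line ", which(tr$value < 0)[1L], " of ", path)
  }
  if (is.null(n_bins)) {
    n_bins <- if (nrow(tr) == 0L) 1L else max(tr$i, tr$j) + 1L
  }
  nr <- n_bins[1L]
  nc <- if (length(n_bins) > 1L) n_bins[2L] else n_bins[1L]
  if (cis && nrow(tr) > 0L) {
    # canonicalize to (lo, hi); conflicting duplicate orientations are errors
    lo <- pmin(tr$i, tr$j); hi <- pmax(tr$i, tr$j)
    key <- paste(lo, hi)
    agg <- tapply(tr$value, key, function(v) {
      if (max(v) - min(v) > 1e-6 * max(1, max(abs(v)))) NA_real_ else v[1L]
    })
    if (anyNA(agg)) {
      stop("conflicting symmetric entries in cis sparse matrix ", path)
    }
    kk <- strsplit(names(agg), " ", fixed = TRUE)
    lo <- vapply(kk, function(k) as.integer(k[1L]), integer(1))
    hi <- vapply(kk, function(k) as.integer(k[2L]), integer(1))
    off <- lo != hi
    mat <- Matrix::sparseMatrix(
      i = c(lo, hi[off]) + 1L, j = c(hi, lo[off]) + 1L,
      x = c(as.numeric(agg), as.numeric(agg)[off]), dims = c(nr, nc))
  } else {
    mat <- Matrix::sparseMatrix(i = tr$i + 1L, j = tr$j + 1L, x = tr$value,
                                dims = c(nr, nc))
  }
  contact_matrix(mat, chrom_row, chrom_col, bin_size)
}

#' Write a contact matrix as sparse triples
#'
#' Cis matrices are written as their upper triangle (including diagonal);
#' trans matrices in full. 0-based bin indices. Inverse of
#' \code{\link{read_contact_matrix}} for the sparse format.
#'
#' @param cm A \code{\link{contact_matrix}}.
#' @param path Output path.
#' @export
write_contact_matrix <- function(cm, path) {
  m <- methods::as(cm$mat, "TsparseMatrix")
  i <- m@i; j <- m@j; x <- m@x
  if (cm$cis) {
    keep <- i <= j
    i <- i[keep]; j <- j[keep]; x <- x[keep]
  }
  ord <- order(i, j)
  utils::write.table(data.frame(i = i[ord], j = j[ord], x = x[ord]),
                     path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Balance a raw contact matrix to equal row sums
#'
#' Computes a positive diagonal scaling D such that D M D has equal row
#' (and, by symmetry, column) sums, the fixed point of Knight-Ruiz-style
#' matrix balancing. Rows with zero total are excluded from the balancing
#' and left as zero rows. The scaling is normalized so row sums equal 1.
#'
#' @param cm A cis \code{\link{contact_matrix}} of raw counts.
#' @param tol Relative tolerance on the spread of row sums.
#' @param max_iter Maximum number of iterations.
#' @return A normalized \code{contact_matrix}; excluded (all-zero) row
#'   indices (1-based) are available as \code{attr(, "excluded")}.
#' @export
kr_balance <- function(cm, tol = 1e-8, max_iter = 2000L) {
  if (!inherits(cm, "contact_matrix")) stop("cm must be a contact_matrix")
  if (!cm$cis) stop("balancing requires a square cis matrix")
  M <- cm$mat
  rs <- Matrix::rowSums(M)
  keep <- rs > 0
  excluded <- which(!keep)
  A <- M[keep, keep, drop = FALSE]
  n <- nrow(A)
  d <- rep(1, n)
  resid <- Inf
  for (it in seq_len(max_iter)) {
    r <- d * as.numeric(A %*% d)     # current row sums of D A D
    resid <- max(abs(r - 1))
    if (resid <= tol) break
    d <- d / sqrt(r)
  }
  if (resid > tol) {
    stop("matrix balancing did not converge in ", max_iter,
         " iterations (last residual ", format(resid), ")")
  }
  dfull <- rep(0, nrow(M))
  dfull[keep] <- d
  D <- Matrix::Diagonal(x = dfull)
  out <- contact_matrix(D %*% M %*% D, cm$chrom_row, cm$chrom_col,
                        cm$bin_size, normalized = TRUE)
  attr(out, "excluded") <- excluded
  out
}
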