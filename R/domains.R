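# Domain-level operations: internal-domain filtering, subcompartment
# labeling, and the length-normalized domain-pair interaction I(a,b).

#' Remove internal (nested) contact domains
#'
#' Drops every domain strictly contained in another domain on the same
#' chromosome; nested domains duplicate the interactions of their parent
#' and are excluded to avoid double counting. Exact duplicate intervals
#' are collapsed to one. The operation is idempotent.
#'
#' @param domains Domain table (see \code{\link{read_domains}}).
#' @return The filtered domain table, sorted by (chrom, start, end), with
#'   counts of removed domains in \code{attr(, "report")}.
#' @export
filter_internal_domains <- function(domains) {
  if (nrow(domains) == 0L) return(domains)
  domains <- domains[order(domains$chrom, domains$start, domains$end), ,
                     drop = FALSE]
  dup <- duplicated(domains[, c("chrom", "start", "end")])
  n_dup <- sum(dup)
  domains <- domains[!dup, , drop = FALSE]
  keep <- rep(TRUE, nrow(domains))
  for (chrom in unique(domains$chrom)) {
    idx <- which(domains$chrom == chrom)
    ir <- IRanges::IRanges(start = domains$start[idx] + 1L,
                           end = domains$end[idx])
    ov <- IRanges::findOverlaps(ir, ir, type = "within")
    q <- S4Vectors::queryHits(ov); s <- S4Vectors::subjectHits(ov)
    # within-hits against a distinct, non-identical interval => internal
    internal <- q != s & !(IRanges::start(ir)[q] == IRanges::start(ir)[s] &
                           IRanges::end(ir)[q] == IRanges::end(ir)[s])
    keep[idx[unique(q[internal])]] <- FALSE
  }
  out <- domains[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "report") <- list(n_input = nrow(domains) + n_dup,
                              n_duplicates = n_dup,
                              n_internal = sum(!keep),
                              n_kept = nrow(out))
  out
}

#' Assign subcompartment labels to domains
#'
#' In \code{"single"} mode a domain is labeled only when every annotation
#' interval it overlaps carries the same label; otherwise it stays
#' unassigned. In \code{"majority"} mode the label with the largest
#' overlapped bp wins; exact ties leave the domain unassigned and are
#' reported.
#'
#' @param domains Domain table.
#' @param annotation Subcompartment table (see
#'   \code{\link{read_subcompartments}}); intervals must not overlap each
#'   other within a chromosome.
#' @param mode \code{"single"} or \code{"majority"}.
#' @return A list with \code{domains} (labeled table) and \code{report}
#'   (counts, assigned fraction, tie count).
#' @export
assign_subcompartments <- function(domains, annotation,
                                   mode = c("single", "majority")) {
  mode <- match.arg(mode)
  check_annotation_disjoint(annotation)
  labels <- rep(NA_character_, nrow(domains))
  ties <- 0L
  if (nrow(domains) > 0L && nrow(annotation) > 0L) {
    for (chrom in unique(domains$chrom)) {
      di <- which(domains$chrom == chrom)
      ai <- which(annotation$chrom == chrom)
      if (length(ai) == 0L) next
      dr <- IRanges::IRanges(domains$start[di] + 1L, domains$end[di])
      ar <- IRanges::IRanges(annotation$start[ai] + 1L, annotation$end[ai])
      ov <- IRanges::findOverlaps(dr, ar)
      q <- S4Vectors::queryHits(ov); s <- S4Vectors::subjectHits(ov)
      if (length(q) == 0L) next
      wid <- IRanges::width(IRanges::pintersect(dr[q], ar[s]))
      lab <- annotation$label[ai[s]]
      for (k in unique(q)) {
        sel <- q == k
        labs <- lab[sel]
        if (mode == "single") {
          u <- unique(labs)
          if (length(u) == 1L) labels[di[k]] <- u
        } else {
          bp <- tapply(wid[sel], labs, sum)
          best <- which(bp == max(bp))
          if (length(best) == 1L) {
            labels[di[k]] <- names(bp)[best]
          } else {
            ties <- ties + 1L
          }
        }
      }
    }
  }
  domains$subcompartment <- labels
  list(domains = domains,
       report = list(n_total = nrow(domains),
                     n_assigned = sum(!is.na(labels)),
                     fraction_assigned = if (nrow(domains) > 0)
                       mean(!is.na(labels)) else NA_real_,
                     n_ties = ties,
                     mode = mode))
}

check_annotation_disjoint <- function(annotation) {
  for (chrom in unique(annotation$chrom)) {
    ai <- which(annotation$chrom == chrom)
    ar <- IRanges::IRanges(annotation$start[ai] + 1L, annotation$end[ai])
    ov <- IRanges::findOverlaps(ar, ar)
    q <- S4Vectors::queryHits(ov); s <- S4Vectors::subjectHits(ov)
    bad <- q < s & annotation$label[ai[q]] != annotation$label[ai[s]]
    if (any(bad)) {
      stop("overlapping annotation intervals with different labels on ",
           chrom)
    }
  }
  invisible(TRUE)
}

# Bins whose midpoint falls inside [start, end); 1-based indices into the
# binned matrix. Sub-bin boundary effects are ignored by construction.
domain_bins <- function(start, end, bin_size) {
  first <- ceiling(start / bin_size - 0.5)
  last <- ceiling(end / bin_size - 0.5) - 1
  if (last < first) return(integer(0))
  seq.int(first, last) + 1L
}

#' Average interaction frequency between two domains
#'
#' I(a, b) is the sum of the contact-matrix entries shared by domains a
#' and b divided by the product of their genomic lengths in bp. A bin
#' belongs to a domain when its midpoint lies inside the domain interval.
#'
#' @param cm A \code{\link{contact_matrix}} covering the chromosome(s) of
#'   \code{a} and \code{b} (a on rows, b on columns for trans).
#' @param a,b Single-row domain tables or lists with \code{chrom},
#'   \code{start}, \code{end}.
#' @return The interaction intensity (units intensity per bp^2),
#'   symmetric in its arguments for cis matrices.
#' @export
domain_interaction <- function(cm, a, b) {
  if (a$chrom != cm$chrom_row || b$chrom != cm$chrom_col) {
    stop("domains ", a$chrom, "/", b$chrom,
         " do not match matrix chromosomes ", cm$chrom_row, "/", cm$chrom_col)
  }
  bi <- domain_bins(a$start, a$end, cm$bin_size)
  bj <- domain_bins(b$start, b$end, cm$bin_size)
  if (length(bi) == 0L || length(bj) == 0L ||
      max(bi) > nrow(cm$mat) || max(bj) > ncol(cm$mat)) {
    stop("domain outside matrix extent")
  }
  s <- sum(cm$mat[bi, bj, drop = FALSE])
  s / (as.numeric(a$end - a$start) * as.numeric(b$end - b$start))
}

#' Construct a domain-level interaction matrix
#'
#' Low-level constructor for the weighted adjacency of a domain network.
#'
#' @param values Numeric matrix of I(a, b) values; for cis networks the
#'   diagonal (self pairs) is stored as \code{NA}.
#' @param domains_row,domains_col Ordered domain tables labelling rows and
#'   columns; identical for cis.
#' @param kind \code{"cis"} or \code{"trans"}.
#' @return An object of class \code{domain_interaction_matrix}.
#' @export
domain_interaction_matrix <- function(values, domains_row,
                                      domains_col = domains_row,
                                      kind = c("cis", "trans")) {
  kind <- match.arg(kind)
  values <- as.matrix(values)
  if (nrow(values) != nrow(domains_row) || ncol(values) != nrow(domains_col)) {
    stop("values dimensions do not match domain tables")
  }
  if (kind == "cis") diag(values) <- NA_real_
  if (any(values < 0, na.rm = TRUE)) stop("negative interaction values")
  dimnames(values) <- list(domains_row$id, domains_col$id)
  structure(list(values = values, domains_row = domains_row,
                 domains_col = domains_col, kind = kind),
            class = "domain_interaction_matrix")
}

#' @export
print.domain_interaction_matrix <- function(x, ...) {
  cat(sprintf("domain_interaction_matrix (%s): %d x %d domains, mean I = %g\n",
              x$kind, nrow(x$values), ncol(x$values),
              mean(x$values, na.rm = TRUE)))
  invisible(x)
}

#' Build all cis and trans domain interaction matrices
#'
#' Computes I(a, b) for every domain pair covered by the supplied contact
#' matrices: one symmetric cis network per chromosome and one rectangular
#' trans network per chromosome pair.
#'
#' @param matrices Named list of \code{\link{contact_matrix}} objects;
#'   names \code{"<chrom>"} for cis and \code{"<chromA>|<chromB>"} for
#'   trans entries.
#' @param domains Filtered, optionally labeled domain table.
#' @return A list with named lists \code{cis} (per chromosome) and
#'   \code{trans} (per pair) of \code{domain_interaction_matrix} objects.
#' @export
build_interaction_matrices <- function(matrices, domains) {
  chroms <- unique(domains$chrom)
  cis <- list()
  trans <- list()
  for (ci in seq_along(chroms)) {
    ca <- chroms[ci]
    da <- domains[domains$chrom == ca, , drop = FALSE]
    if (!ca %in% names(matrices)) stop("missing cis matrix for ", ca)
    cis[[ca]] <- domain_interaction_matrix(
      block_interactions(matrices[[ca]], da, da), da, da, kind = "cis")
    for (cj in seq_along(chroms)) {
      if (cj <= ci) next
      cb <- chroms[cj]
      db <- domains[domains$chrom == cb, , drop = FALSE]
      key <- paste0(ca, "|", cb)
      cm <- matrices[[key]]
      flip <- FALSE
      if (is.null(cm)) {
        cm <- matrices[[paste0(cb, "|", ca)]]
        flip <- TRUE
      }
      if (is.null(cm)) stop("missing trans matrix for pair ", ca, "|", cb)
      vals <- if (flip) t(block_interactions(cm, db, da))
              else block_interactions(cm, da, db)
      trans[[key]] <- domain_interaction_matrix(vals, da, db, kind = "trans")
    }
  }
  list(cis = cis, trans = trans)
}

# Vectorized I(a,b) over all row/column domain pairs: aggregate the binned
# matrix with 0/1 membership matrices, then divide by the length products.
block_interactions <- function(cm, drow, dcol) {
  A <- membership_matrix(drow, cm$bin_size, nrow(cm$mat))
  B <- membership_matrix(dcol, cm$bin_size, ncol(cm$mat))
  S <- as.matrix(A %*% cm$mat %*% Matrix::t(B))
  L <- outer(as.numeric(drow$end - drow$start),
             as.numeric(dcol$end - dcol$start))
  S / L
}

membership_matrix <- function(domains, bin_size, n_bins) {
  ii <- integer(0); jj <- integer(0)
  for (k in seq_len(nrow(domains))) {
    b <- domain_bins(domains$start[k], domains$end[k], bin_size)
    if (length(b) == 0L || max(b) > n_bins) {
      stop("domain ", domains$id[k], " outside matrix extent")
    }
    ii <- c(ii, rep(k, length(b))); jj <- c(jj, b)
  }
  Matrix::sparseMatrix(i = ii, j = jj, x = 1, dims = c(nrow(domains), n_bins))
}

#' Pool interaction values from a set of networks
#'
#' Collects all I(a, b) values: the upper off-diagonal triangle of each
#' cis network, or every cell of each trans network.
#'
#' @param nets A list of \code{domain_interaction_matrix} objects, or the
#'   \code{cis}/\code{trans} sublists returned by
#'   \code{\link{build_interaction_matrices}}.
#' @return Numeric vector of interaction intensities.
#' @export
pool_interactions <- function(nets) {
  if (inherits(nets, "domain_interaction_matrix")) nets <- list(nets)
  unlist(lapply(nets, function(net) {
    v <- net$values
    if (net$kind == "cis") v[upper.tri(v)] else as.numeric(v)
  }), use.names = FALSE)
}

#' Cis/trans mean interaction ratio
#'
#' Ratio of the mean intra-chromosomal to the mean inter-chromosomal
#' domain-pair interaction intensity; around 850 in GM12878 at contact
#' domain resolution.
#'
#' @param cis_values,trans_values Pooled I values (see
#'   \code{\link{pool_interactions}}).
#' @return A single dimensionless ratio.
#' @export
cis_trans_ratio <- function(cis_values, trans_values) {
  if (length(cis_values) == 0L || length(trans_values) == 0L) {
    stop("both cis and trans pools must be non-empty")
  }
  mt <- mean(trans_values)
  if (mt == 0) stop("trans pool mean is zero")
  mean(cis_values) / mt
}
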