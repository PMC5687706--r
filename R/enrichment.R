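# Subcompartment-resolved enrichment of domain interactions, top
# interactor selection, and compartment composition.

#' Subcompartment interaction enrichment heatmap
#'
#' For every unordered pair of subcompartment labels (i, j), computes the
#' mean interaction <H(i,j)> over all domain pairs carrying those labels,
#' the background H0 = mean of <H(i,j)> over the observed label pairs,
#' and the relative excess H_ij = (<H(i,j)> - H0) / H0. By construction
#' the H_ij average to zero over the observed label pairs. Unlabeled
#' domains are excluded; label pairs with no observations are reported
#' as missing, not zero.
#'
#' @param nets List of \code{\link{domain_interaction_matrix}} objects of
#'   one kind (all cis or all trans).
#' @param scope \code{"cis"} or \code{"trans"}; networks of the other
#'   kind are rejected.
#' @return A list of class \code{enrichment_heatmap}: \code{labels},
#'   symmetric matrices \code{mean_I} and \code{H}, scalar \code{H0},
#'   \code{n_pairs} (observation counts) and \code{missing_pairs}.
#' @export
subcompartment_enrichment <- function(nets, scope = c("cis", "trans")) {
  scope <- match.arg(scope)
  if (inherits(nets, "domain_interaction_matrix")) nets <- list(nets)
  sums <- list(); counts <- list()
  seen <- character(0)
  for (net in nets) {
    if (net$kind != scope) {
      stop("network kind ", net$kind, " does not match scope ", scope)
    }
    lr <- net$domains_row$subcompartment
    lc <- net$domains_col$subcompartment
    v <- net$values
    if (net$kind == "cis") v[lower.tri(v, diag = TRUE)] <- NA_real_
    ok <- which(!is.na(v) & outer(!is.na(lr), !is.na(lc)), arr.ind = TRUE)
    if (nrow(ok) == 0L) next
    li <- lr[ok[, 1L]]; lj <- lc[ok[, 2L]]
    key <- paste(pmin(li, lj), pmax(li, lj), sep = "|")
    vals <- v[ok]
    s <- tapply(vals, key, sum)
    n <- tapply(vals, key, length)
    for (k in names(s)) {
      sums[[k]] <- (sums[[k]] %||% 0) + s[[k]]
      counts[[k]] <- (counts[[k]] %||% 0) + n[[k]]
    }
    seen <- union(seen, c(li, lj))
  }
  labels <- sort(seen)
  if (length(labels) < 2L) stop("fewer than two subcompartment labels present")
  mean_I <- matrix(NA_real_, length(labels), length(labels),
                   dimnames = list(labels, labels))
  n_pairs <- matrix(0L, length(labels), length(labels),
                    dimnames = list(labels, labels))
  for (k in names(sums)) {
    lab <- strsplit(k, "|", fixed = TRUE)[[1L]]
    m <- sums[[k]] / counts[[k]]
    mean_I[lab[1L], lab[2L]] <- m; mean_I[lab[2L], lab[1L]] <- m
    n_pairs[lab[1L], lab[2L]] <- counts[[k]]
    n_pairs[lab[2L], lab[1L]] <- counts[[k]]
  }
  ut <- upper.tri(mean_I, diag = TRUE)
  observed <- ut & !is.na(mean_I)
  H0 <- mean(mean_I[observed])
  H <- (mean_I - H0) / H0
  missing <- which(ut & is.na(mean_I), arr.ind = TRUE)
  missing_pairs <- if (nrow(missing) > 0L) {
    paste(labels[missing[, 1L]], labels[missing[, 2L]], sep = "|")
  } else character(0)
  structure(list(labels = labels, mean_I = mean_I, H = H, H0 = H0,
                 N_c = sum(observed), n_pairs = n_pairs,
                 missing_pairs = missing_pairs, scope = scope),
            class = "enrichment_heatmap")
}

#' @export
print.enrichment_heatmap <- function(x, ...) {
  cat(sprintf("enrichment_heatmap (%s): %d labels, H0 = %g, N_c = %d\n",
              x$scope, length(x$labels), x$H0, x$N_c))
  print(round(x$H, 3))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Select the top interacting domains
#'
#' Ranks domains by their mean interaction with partners in scope (cis:
#' the other domains on the same chromosome; trans: all domains on other
#' chromosomes) and returns the top ceiling(fraction * N). Ties at the
#' cut are broken by (chrom, start) for determinism and flagged.
#'
#' @param nets List of \code{domain_interaction_matrix} objects of one
#'   kind covering the domains of interest.
#' @param fraction Fraction of domains to keep, in (0, 1].
#' @return A domain table (rows of the networks' domain tables) with a
#'   \code{mean_I} column, sorted by decreasing \code{mean_I};
#'   \code{attr(, "ties")} flags a tie at the cutoff.
#' @export
top_interactors <- function(nets, fraction = 0.05) {
  if (fraction <= 0 || fraction > 1) stop("fraction must be in (0, 1]")
  if (inherits(nets, "domain_interaction_matrix")) nets <- list(nets)
  sums <- list(); counts <- list(); dom <- list()
  add <- function(ids, d, s, n) {
    for (k in seq_along(ids)) {
      id <- ids[k]
      sums[[id]] <<- (sums[[id]] %||% 0) + s[k]
      counts[[id]] <<- (counts[[id]] %||% 0) + n[k]
      if (is.null(dom[[id]])) dom[[id]] <<- d[k, , drop = FALSE]
    }
  }
  for (net in nets) {
    v <- net$values
    add(net$domains_row$id, net$domains_row,
        rowSums(v, na.rm = TRUE), rowSums(!is.na(v)))
    if (net$kind == "trans") {
      add(net$domains_col$id, net$domains_col,
          colSums(v, na.rm = TRUE), colSums(!is.na(v)))
    }
  }
  ids <- names(sums)
  df <- do.call(rbind, dom[ids])
  df$mean_I <- unlist(sums[ids]) / unlist(counts[ids])
  ord <- order(-df$mean_I, df$chrom, df$start)
  df <- df[ord, , drop = FALSE]
  n_keep <- ceiling(fraction * nrow(df))
  tie <- n_keep < nrow(df) && df$mean_I[n_keep] == df$mean_I[n_keep + 1L]
  out <- df[seq_len(n_keep), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "ties") <- tie
  out
}

#' Subcompartment composition of a domain set
#'
#' Fraction of domains carrying each subcompartment label; unassigned
#' domains are reported under \code{"N.A."}. Fractions sum to 1.
#'
#' @param domains Domain table with a \code{subcompartment} column.
#' @return Named numeric vector of fractions.
#' @export
compartment_composition <- function(domains) {
  if (nrow(domains) == 0L) stop("empty domain set")
  lab <- domains$subcompartment
  lab[is.na(lab)] <- "N.A."
  tab <- table(lab)
  as.numeric(tab) / nrow(domains) -> frac
  names(frac) <- names(tab)
  frac[order(names(frac))]
}
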