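# Seeded synthetic genome generator: domain lists with nested children,
# block-wise subcompartment annotations, and planted cis/trans domain
# interaction networks with the statistical structure of lymphoblastoid
# Hi-C contact-domain data (power-law cis intensities, exponential trans
# intensities ~850x weaker, optional banded trans enrichment and
# homotypic/A1 boosts).

#' Specification of a synthetic contact-domain genome
#'
#' Parameter carrier for \code{\link{generate_genome}}. Defaults emulate
#' the published GM12878 contact-domain statistics: exponentially
#' distributed domain lengths with median 185 kb, ~35\% internally
#' nested domains, power-law cis intensities with exponent gamma = 2,
#' exponential trans intensities with the cis/trans mean ratio scaled to
#' 850, homotypic cis enrichment, A1-biased trans enrichment and a band
#' of trans-enriched consecutive domains.
#'
#' @param n_chromosomes Number of chromosomes.
#' @param domains_per_chromosome Top-level domains per chromosome.
#' @param domain_length_median Median domain length, bp.
#' @param min_domain_length Hard floor on domain length, bp.
#' @param internal_fraction Probability a domain spawns one strictly
#'   nested child.
#' @param gamma Cis intensity power-law exponent (> 1).
#' @param cis_xmin Minimum cis intensity before rescaling.
#' @param trans_I0 Exponential scale of trans intensities.
#' @param cis_trans_ratio Target mean cis/trans ratio; cis intensities
#'   are rescaled globally to realize it exactly. \code{NULL} disables
#'   rescaling.
#' @param band_fraction Fraction of consecutive source-domain rows in
#'   each trans matrix forming an enriched band (0 = no bands).
#' @param band_amplitude Multiplier applied to band rows.
#' @param homotypic_boost Multiplier for cis pairs sharing a label.
#' @param a1_trans_boost Multiplier for trans A1-A1 pairs.
#' @param subcompartment_block_length Consecutive domains per label
#'   block; labels cycle A1, A2, B1, B2, B3.
#' @param bin_size Bin size (bp) domain boundaries are snapped to.
#' @param seed Default seed for \code{\link{generate_genome}}.
#' @return A list of class \code{synthetic_genome_spec}.
#' @export
synthetic_genome_spec <- function(n_chromosomes = 5L,
                                  domains_per_chromosome = 200L,
                                  domain_length_median = 185000,
                                  min_domain_length = 50000,
                                  internal_fraction = 0.35,
                                  gamma = 2.0,
                                  cis_xmin = 1,
                                  trans_I0 = 1e-8,
                                  cis_trans_ratio = 850,
                                  band_fraction = 0.1,
                                  band_amplitude = 2,
                                  homotypic_boost = 2,
                                  a1_trans_boost = 2,
                                  subcompartment_block_length = 3L,
                                  bin_size = 10000,
                                  seed = 0L) {
  spec <- list(n_chromosomes = as.integer(n_chromosomes),
               domains_per_chromosome = as.integer(domains_per_chromosome),
               domain_length_median = domain_length_median,
               min_domain_length = min_domain_length,
               internal_fraction = internal_fraction,
               gamma = gamma, cis_xmin = cis_xmin, trans_I0 = trans_I0,
               cis_trans_ratio = cis_trans_ratio,
               band_fraction = band_fraction,
               band_amplitude = band_amplitude,
               homotypic_boost = homotypic_boost,
               a1_trans_boost = a1_trans_boost,
               subcompartment_block_length =
                 as.integer(subcompartment_block_length),
               bin_size = bin_size, seed = as.integer(seed))
  stopifnot(spec$n_chromosomes >= 1, spec$domains_per_chromosome >= 2,
            spec$internal_fraction >= 0, spec$internal_fraction <= 1,
            spec$band_fraction >= 0, spec$band_fraction <= 1,
            spec$gamma > 1, spec$cis_xmin > 0, spec$trans_I0 > 0,
            spec$band_amplitude >= 1, spec$homotypic_boost >= 1,
            spec$a1_trans_boost >= 1, spec$min_domain_length >= spec$bin_size)
  structure(spec, class = c("synthetic_genome_spec", "list"))
}

# Pareto draw with density ~ x^-gamma above xmin (shape gamma - 1).
rpareto <- function(n, xmin, gamma) {
  xmin * stats::runif(n)^(-1 / (gamma - 1))
}

#' Generate a synthetic contact-domain genome
#'
#' Draws domain lengths from an exponential distribution (snapped to the
#' bin size, floored), tiles each chromosome with them, nests a child
#' domain inside a random subset, assigns subcompartment labels in
#' consecutive blocks, and plants domain-level interaction intensities:
#' Pareto (power-law) in cis, exponential in trans, with the configured
#' homotypic, A1 and band enrichments. Cis intensities are rescaled so
#' the realized mean cis/trans ratio equals the target exactly. Fully
#' reproducible from the seed.
#'
#' @param spec A \code{\link{synthetic_genome_spec}}.
#' @param seed Seed; defaults to \code{spec$seed}.
#' @return A list of class \code{synthetic_genome}: \code{domains} (all
#'   domains including nested children), \code{annotation}
#'   (subcompartment table), \code{nets} (\code{cis}/\code{trans} lists
#'   of \code{\link{domain_interaction_matrix}} objects over the
#'   top-level domains), \code{chrom_lengths}, \code{spec}, \code{seed}.
#' @export
generate_genome <- function(spec = synthetic_genome_spec(),
                            seed = spec$seed) {
  set.seed(seed)
  chroms <- paste0("chr", seq_len(spec$n_chromosomes))
  bs <- spec$bin_size
  rate <- log(2) / spec$domain_length_median
  dom_list <- list(); ann_list <- list(); child_list <- list()
  chrom_lengths <- numeric(0)
  lab_cycle <- c("A1", "A2", "B1", "B2", "B3")
  for (ch in chroms) {
    nd <- spec$domains_per_chromosome
    len <- as.integer(pmax(round(stats::rexp(nd, rate) / bs) * bs,
                           spec$min_domain_length))
    start <- as.integer(cumsum(c(0, len[-nd])))
    end <- start + len
    block <- ((seq_len(nd) - 1L) %/% spec$subcompartment_block_length)
    lab <- lab_cycle[(block %% length(lab_cycle)) + 1L]
    d <- data.frame(chrom = ch, start = start, end = end,
                    id = paste0(ch, ":", start, "-", end),
                    subcompartment = lab, stringsAsFactors = FALSE)
    dom_list[[ch]] <- d
    chrom_lengths[ch] <- sum(len)
    # annotation: merge consecutive same-label domains into one interval
    brk <- c(TRUE, lab[-1] != lab[-nd])
    grp <- cumsum(brk)
    ann_list[[ch]] <- data.frame(
      chrom = ch,
      start = tapply(start, grp, min),
      end = tapply(end, grp, max),
      label = tapply(lab, grp, function(x) x[1L]),
      stringsAsFactors = FALSE)
    # nested children, strictly contained, on the bin grid
    has_child <- stats::runif(nd) < spec$internal_fraction
    kids <- lapply(which(has_child), function(k) {
      nb <- len[k] / bs
      if (nb < 2) return(NULL)
      nbc <- sample.int(nb - 1L, 1L)
      off <- sample.int(nb - nbc + 1L, 1L) - 1L
      cs <- as.integer(start[k] + off * bs)
      ce <- as.integer(cs + nbc * bs)
      data.frame(chrom = ch, start = cs, end = ce,
                 id = paste0(ch, ":", cs, "-", ce),
                 subcompartment = NA_character_, stringsAsFactors = FALSE)
    })
    child_list[[ch]] <- do.call(rbind, kids)
  }
  domains_top <- do.call(rbind, dom_list)
  children <- do.call(rbind, child_list)
  domains_all <- rbind(domains_top, children)
  domains_all <- domains_all[!duplicated(domains_all$id), , drop = FALSE]
  domains_all <- domains_all[order(domains_all$chrom, domains_all$start,
                                   domains_all$end), , drop = FALSE]
  rownames(domains_all) <- NULL
  annotation <- do.call(rbind, ann_list)
  rownames(annotation) <- NULL

  # cis networks: symmetric Pareto intensities, homotypic pairs boosted
  cis <- list()
  for (ch in chroms) {
    d <- dom_list[[ch]]
    n <- nrow(d)
    v <- matrix(0, n, n)
    np <- n * (n - 1) / 2
    draws <- rpareto(np, spec$cis_xmin, spec$gamma)
    same <- outer(d$subcompartment, d$subcompartment, "==")[upper.tri(v)]
    draws[same] <- draws[same] * spec$homotypic_boost
    v[upper.tri(v)] <- draws
    v <- v + t(v)
    cis[[ch]] <- domain_interaction_matrix(v, d, d, kind = "cis")
  }
  # trans networks: exponential intensities, band rows and A1-A1 boosted
  trans <- list()
  if (spec$n_chromosomes >= 2L) {
    for (i in seq_len(spec$n_chromosomes - 1L)) {
      for (j in (i + 1L):spec$n_chromosomes) {
        da <- dom_list[[chroms[i]]]; db <- dom_list[[chroms[j]]]
        na <- nrow(da); nb <- nrow(db)
        v <- matrix(stats::rexp(na * nb, rate = 1 / spec$trans_I0), na, nb)
        if (spec$band_fraction > 0) {
          nband <- max(1L, round(spec$band_fraction * na))
          b0 <- sample.int(na - nband + 1L, 1L)
          v[b0:(b0 + nband - 1L), ] <- v[b0:(b0 + nband - 1L), ] *
            spec$band_amplitude
        }
        if (spec$a1_trans_boost > 1) {
          a1 <- outer(da$subcompartment == "A1", db$subcompartment == "A1",
                      FUN = "&")
          v[a1] <- v[a1] * spec$a1_trans_boost
        }
        trans[[paste0(chroms[i], "|", chroms[j])]] <-
          domain_interaction_matrix(v, da, db, kind = "trans")
      }
    }
  }
  # global cis scale realizing the target mean cis/trans ratio exactly
  if (!is.null(spec$cis_trans_ratio) && length(trans) > 0L) {
    mc <- mean(pool_interactions(cis))
    mt <- mean(pool_interactions(trans))
    if (mt <= 0) stop("infeasible spec: zero mean trans intensity")
    s <- spec$cis_trans_ratio * mt / mc
    for (ch in names(cis)) cis[[ch]]$values <- cis[[ch]]$values * s
  }
  structure(list(domains = domains_all, annotation = annotation,
                 nets = list(cis = cis, trans = trans),
                 chrom_lengths = chrom_lengths, spec = spec, seed = seed),
            class = "synthetic_genome")
}

#' @export
print.synthetic_genome <- function(x, ...) {
  cat(sprintf("synthetic_genome: %d chromosomes, %d domains (%d nested), seed %d\n",
              x$spec$n_chromosomes, nrow(x$domains),
              nrow(x$domains) - sum(vapply(x$nets$cis,
                function(n) nrow(n$domains_row), integer(1))),
              x$seed))
  invisible(x)
}

#' Derive bin-level contact matrices from planted domain interactions
#'
#' Inverse of \code{\link{build_interaction_matrices}} for end-to-end
#' I/O testing: each domain pair's total intensity I(a, b) * L_a * L_b
#' is spread uniformly over its bin block, so recomputing I(a, b) from
#' the binned matrices recovers the planted values exactly. Domain
#' boundaries not on the bin grid are snapped with a warning.
#'
#' @param genome A \code{synthetic_genome}, or a list with
#'   \code{nets} and \code{chrom_lengths}.
#' @param bin_size Bin size in bp; defaults to the generating spec's.
#' @return Named list of \code{\link{contact_matrix}} objects
#'   (\code{"<chrom>"} cis, \code{"<chromA>|<chromB>"} trans).
#' @export
generate_bin_matrix <- function(genome, bin_size = genome$spec$bin_size) {
  out <- list()
  for (ch in names(genome$nets$cis)) {
    net <- genome$nets$cis[[ch]]
    out[[ch]] <- fill_bins(net, bin_size,
                           n_row = genome$chrom_lengths[[ch]] / bin_size,
                           n_col = genome$chrom_lengths[[ch]] / bin_size)
  }
  for (key in names(genome$nets$trans)) {
    net <- genome$nets$trans[[key]]
    pair <- strsplit(key, "|", fixed = TRUE)[[1L]]
    out[[key]] <- fill_bins(net, bin_size,
                            n_row = genome$chrom_lengths[[pair[1L]]] / bin_size,
                            n_col = genome$chrom_lengths[[pair[2L]]] / bin_size)
  }
  out
}

fill_bins <- function(net, bin_size, n_row, n_col) {
  n_row <- ceiling(n_row); n_col <- ceiling(n_col)
  dr <- net$domains_row; dc <- net$domains_col
  snap <- function(x) round(x / bin_size) * bin_size
  if (any(dr$start != snap(dr$start) | dr$end != snap(dr$end))) {
    warning("domain boundaries snapped to the bin grid")
  }
  ii <- list(); jj <- list(); xx <- list(); k <- 0L
  for (a in seq_len(nrow(dr))) {
    ba <- domain_bins(snap(dr$start[a]), snap(dr$end[a]), bin_size)
    La <- dr$end[a] - dr$start[a]
    for (b in seq_len(nrow(dc))) {
      val <- net$values[a, b]
      if (is.na(val) || val == 0) next
      bb <- domain_bins(snap(dc$start[b]), snap(dc$end[b]), bin_size)
      Lb <- dc$end[b] - dc$start[b]
      cell <- val * La * Lb / (length(ba) * length(bb))
      k <- k + 1L
      grid <- expand.grid(i = ba, j = bb)
      ii[[k]] <- grid$i; jj[[k]] <- grid$j
      xx[[k]] <- rep(cell, nrow(grid))
    }
  }
  mat <- Matrix::sparseMatrix(i = unlist(ii) %||% integer(0),
                              j = unlist(jj) %||% integer(0),
                              x = unlist(xx) %||% numeric(0),
                              dims = c(n_row, n_col))
  contact_matrix(mat, net$domains_row$chrom[1L],
                 net$domains_col$chrom[1L], bin_size, normalized = TRUE)
}

#' Write a synthetic genome to disk
#'
#' Emits the same plain-text formats the readers consume: a BED3 domain
#' list, a BED4 subcompartment annotation, sparse-triple contact
#' matrices (one per chromosome and pair) and a JSON copy of the spec.
#'
#' @param genome A \code{synthetic_genome}.
#' @param dir Output directory (created if needed).
#' @param bin_matrices Optional precomputed result of
#'   \code{\link{generate_bin_matrix}}; computed on the fly otherwise.
#' @return The directory path, invisibly.
#' @export
write_synthetic_genome <- function(genome, dir, bin_matrices = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_domains(genome$domains, file.path(dir, "domains.bed"))
  ann <- genome$annotation
  utils::write.table(ann, file.path(dir, "subcompartments.bed"), sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  if (is.null(bin_matrices)) bin_matrices <- generate_bin_matrix(genome)
  for (key in names(bin_matrices)) {
    fn <- paste0("matrix_", gsub("|", "_", key, fixed = TRUE), ".tsv")
    write_contact_matrix(bin_matrices[[key]], file.path(dir, fn))
  }
  jsonlite::write_json(unclass(genome$spec), file.path(dir, "spec.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
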