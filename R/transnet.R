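# Chromosome-pair interaction structure: pairwise chromosome matrix,
# RSS-elbow clustering, the differential interaction score DR with its
# bootstrap null, and coherent-sign run lengths.

#' Chromosome-pair interaction matrix
#'
#' Total trans interaction intensity between every chromosome pair,
#' normalized by the product of the two chromosomes' genomic lengths.
#'
#' @param trans_nets Named list of trans
#'   \code{\link{domain_interaction_matrix}} objects, names
#'   \code{"<chromA>|<chromB>"}, covering every pair of \code{chroms}.
#' @param chrom_lengths Named numeric vector of chromosome lengths (bp).
#' @return A symmetric matrix (diagonal \code{NA}) of class
#'   \code{chrom_pair_matrix}, in units intensity per bp^2.
#' @export
chrom_pair_matrix <- function(trans_nets, chrom_lengths) {
  chroms <- names(chrom_lengths)
  m <- matrix(NA_real_, length(chroms), length(chroms),
              dimnames = list(chroms, chroms))
  for (i in seq_along(chroms)) {
    for (j in seq_along(chroms)) {
      if (j <= i) next
      key <- paste0(chroms[i], "|", chroms[j])
      net <- trans_nets[[key]] %||% trans_nets[[paste0(chroms[j], "|", chroms[i])]]
      if (is.null(net)) stop("missing trans network for pair ", key)
      val <- sum(net$values) / (chrom_lengths[[i]] * chrom_lengths[[j]])
      m[i, j] <- val; m[j, i] <- val
    }
  }
  structure(m, class = c("chrom_pair_matrix", class(m)))
}

#' RSS elbow analysis of chromosome-pair interactions
#'
#' Clusters chromosomes by k-means on the rows of the pair matrix
#' (diagonal imputed as 0) and inspects the residual-sum-of-squares
#' curve RSS(k). The elbow is the k maximizing the discrete second
#' difference RSS(k-1) - 2 RSS(k) + RSS(k+1); its strength is that
#' second difference divided by RSS(1). A strength below \code{cutoff}
#' yields the verdict "no evident clusters".
#'
#' @param pair_matrix A \code{\link{chrom_pair_matrix}} (or plain
#'   symmetric matrix).
#' @param k_max Largest k examined; must be below the chromosome count.
#' @param restarts k-means restarts per k (\code{nstart}).
#' @param cutoff Minimum elbow strength for an "evident clusters" call.
#' @param seed Seed for the k-means initializations.
#' @return A list with \code{rss} (named by k), \code{elbow_k},
#'   \code{strength} and \code{verdict}.
#' @export
rss_elbow <- function(pair_matrix, k_max = NULL, restarts = 10L,
                      cutoff = 0.1, seed = 0L) {
  x <- unclass(pair_matrix)
  x[is.na(x)] <- 0
  n <- nrow(x)
  if (is.null(k_max)) k_max <- n - 1L
  if (k_max < 3L || k_max > n) {
    stop("k_max must be in [3, number of chromosomes]")
  }
  set.seed(seed)
  rss <- vapply(seq_len(k_max), function(k) {
    if (k == 1L) {
      sum(scale(x, scale = FALSE)^2)
    } else if (k >= n) {
      0  # every chromosome its own cluster
    } else {
      stats::kmeans(x, centers = k, nstart = restarts,
                    iter.max = 100L)$tot.withinss
    }
  }, numeric(1))
  names(rss) <- seq_len(k_max)
  ks <- 2:(k_max - 1L)
  second <- rss[ks - 1L] - 2 * rss[ks] + rss[ks + 1L]
  elbow_k <- ks[which.max(second)]
  strength <- max(second) / rss[1L]
  list(rss = rss, elbow_k = elbow_k, strength = unname(strength),
       verdict = if (strength >= cutoff) "clusters"
                 else "no evident clusters")
}

#' Differential interaction score DR
#'
#' For each domain k of the source chromosome, S_k is the sum of its
#' interactions with all domains of the target chromosome, and
#' DR_k = (S_k - <S>) / <S> with <S> the mean of the S_k. DR measures a
#' domain's excess trans interaction relative to the chromosome-pair
#' average; its mean is zero by construction and its standard deviation
#' (population convention) quantifies along-chromosome structure.
#'
#' @param pair_net A trans \code{\link{domain_interaction_matrix}};
#'   source domains on rows (in genomic order), target domains on
#'   columns.
#' @return An object of class \code{dr_profile}: \code{S}, \code{mean_S},
#'   \code{DR} (named by domain id, genomic order), \code{sigma},
#'   \code{run_lengths}, \code{mean_run} and the chromosome names.
#' @export
dr_score <- function(pair_net) {
  ord <- order(pair_net$domains_row$start)
  v <- pair_net$values[ord, , drop = FALSE]
  S <- rowSums(v, na.rm = TRUE)
  mean_S <- mean(S)
  if (mean_S <= 0) stop("degenerate pair network: <S> = 0")
  DR <- (S - mean_S) / mean_S
  runs <- if (all(DR == 0)) {
    list(run_lengths = integer(0), mean_run = NA_real_)
  } else {
    sign_run_lengths(DR)
  }
  structure(list(source_chrom = pair_net$domains_row$chrom[1L],
                 target_chrom = pair_net$domains_col$chrom[1L],
                 S = S, mean_S = mean_S, DR = DR,
                 sigma = sqrt(mean(DR^2)),
                 run_lengths = runs$run_lengths,
                 mean_run = runs$mean_run),
            class = "dr_profile")
}

#' @export
print.dr_profile <- function(x, ...) {
  cat(sprintf("dr_profile: %s vs %s, %d domains, sigma = %.4f, mean run = %.2f\n",
              x$source_chrom, x$target_chrom, length(x$DR), x$sigma,
              x$mean_run))
  invisible(x)
}

#' Bootstrap shuffle of a pair network
#'
#' Permutes the positions of all interaction values uniformly at random
#' across the matrix cells (upper triangle for cis, mirrored), leaving
#' the multiset of intensities unchanged. The null model for DR and
#' run-length statistics.
#'
#' @param pair_net A \code{\link{domain_interaction_matrix}}.
#' @param seed Integer seed; same seed, same permutation.
#' @return A \code{domain_interaction_matrix} with permuted values.
#' @export
bootstrap_shuffle <- function(pair_net, seed = 0L) {
  set.seed(seed)
  v <- pair_net$values
  if (pair_net$kind == "cis") {
    ut <- upper.tri(v)
    v[ut] <- sample(v[ut])
    v[lower.tri(v)] <- t(v)[lower.tri(v)]
  } else {
    v[] <- sample(as.numeric(v))
  }
  out <- pair_net
  out$values <- v
  out
}

#' Coherent-sign run lengths of a DR profile
#'
#' Lengths of maximal runs of constant sign along the genomic order —
#' the number of consecutive domains between zero crossings of DR. Exact
#' zeros terminate the current run and belong to none, so the run
#' lengths plus the zero count sum to the profile length. The run-size
#' histogram is summarized by an exponential decay fitted to the log
#' counts.
#'
#' @param dr Numeric DR values in genomic order, or a \code{dr_profile}.
#' @return A list with \code{run_lengths}, \code{n_zero},
#'   \code{mean_run} and \code{decay} (exponential scale of the run-size
#'   distribution, in domains; \code{NA} when inestimable).
#' @export
sign_run_lengths <- function(dr) {
  if (inherits(dr, "dr_profile")) dr <- dr$DR
  if (length(dr) == 0L || all(dr == 0)) stop("all-zero or empty DR profile")
  s <- sign(dr)
  runs <- integer(0)
  cur_sign <- 0; cur_len <- 0L
  for (v in s) {
    if (v == 0) {
      if (cur_len > 0L) runs <- c(runs, cur_len)
      cur_sign <- 0; cur_len <- 0L
    } else if (v == cur_sign) {
      cur_len <- cur_len + 1L
    } else {
      if (cur_len > 0L) runs <- c(runs, cur_len)
      cur_sign <- v; cur_len <- 1L
    }
  }
  if (cur_len > 0L) runs <- c(runs, cur_len)
  tab <- table(runs)
  decay <- NA_real_
  if (length(tab) >= 3L) {
    sizes <- as.numeric(names(tab))
    fit <- stats::lm(log(as.numeric(tab)) ~ sizes)
    slope <- stats::coef(fit)[2L]
    if (is.finite(slope) && slope < 0) decay <- -1 / slope
  }
  list(run_lengths = runs, n_zero = sum(s == 0), mean_run = mean(runs),
       decay = unname(decay))
}

#' DR with a bootstrap null
#'
#' Computes the DR profile of a pair network and, over \code{replicates}
#' seeded shuffles, the null distribution of sigma and mean run length.
#'
#' @param pair_net A trans \code{\link{domain_interaction_matrix}}.
#' @param replicates Number of bootstrap shuffles.
#' @param seed Base seed; replicate r uses \code{seed + r}.
#' @return A list with \code{profile} (the \code{dr_profile}),
#'   \code{sigma_rand} and \code{mean_run_rand} (means over replicates)
#'   and the per-replicate vectors.
#' @export
dr_bootstrap <- function(pair_net, replicates = 100L, seed = 0L) {
  profile <- dr_score(pair_net)
  sig <- numeric(replicates); run <- numeric(replicates)
  for (r in seq_len(replicates)) {
    p <- dr_score(bootstrap_shuffle(pair_net, seed = seed + r))
    sig[r] <- p$sigma
    run[r] <- p$mean_run
  }
  list(profile = profile, sigma = profile$sigma,
       sigma_rand = mean(sig), mean_run = profile$mean_run,
       mean_run_rand = mean(run), replicates = replicates, seed = seed,
       sigma_rand_all = sig, mean_run_rand_all = run)
}
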