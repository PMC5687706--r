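# End-to-end orchestration: from a config (synthetic spec or input
# paths) to tables and a summary of all headline statistics.

#' Build an analysis configuration
#'
#' Exactly one of \code{synthetic} (a
#' \code{\link{synthetic_genome_spec}}) or \code{paths} must be active.
#' \code{paths} is a list with \code{domains}, \code{subcompartments}
#' and \code{matrices} (named list of sparse-triple paths, names
#' \code{"<chrom>"} / \code{"<chromA>|<chromB>"}), plus
#' \code{chrom_lengths} (named bp vector).
#'
#' @param synthetic A \code{synthetic_genome_spec}, or \code{NULL}.
#' @param paths Input path list, or \code{NULL}.
#' @param bin_size Bin size in bp for matrices read from disk.
#' @param percentiles Trans-distribution percentiles at which
#'   connectivity is evaluated.
#' @param top_fraction Fraction for top-interactor selection.
#' @param bootstrap_replicates Bootstrap shuffles for the DR null.
#' @param dr_pairs List of length-2 chromosome-name vectors for DR
#'   profiles, or \code{"first"} (the first chromosome pair).
#' @param stages Character vector of enabled stages, a subset of
#'   \code{c("networks", "enrichment", "transnet")}; domain loading and
#'   interaction-matrix construction always run.
#' @param assignment_mode Subcompartment assignment mode (see
#'   \code{\link{assign_subcompartments}}).
#' @param seed Master seed for all randomness.
#' @return A list of class \code{analysis_config}.
#' @export
analysis_config <- function(synthetic = synthetic_genome_spec(),
                            paths = NULL,
                            bin_size = 10000,
                            percentiles = c(25, 75),
                            top_fraction = 0.05,
                            bootstrap_replicates = 100L,
                            dr_pairs = "first",
                            stages = c("networks", "enrichment", "transnet"),
                            assignment_mode = "single",
                            seed = 0L) {
  if (is.null(synthetic) == is.null(paths)) {
    stop("exactly one of 'synthetic' or 'paths' must be given")
  }
  if (any(percentiles < 0 | percentiles > 100)) {
    stop("percentiles must lie in [0, 100]")
  }
  structure(list(synthetic = synthetic, paths = paths, bin_size = bin_size,
                 percentiles = percentiles, top_fraction = top_fraction,
                 bootstrap_replicates = as.integer(bootstrap_replicates),
                 dr_pairs = dr_pairs, stages = stages,
                 assignment_mode = assignment_mode, seed = as.integer(seed)),
            class = "analysis_config")
}

#' Run the full contact-domain network analysis
#'
#' Loads or generates the inputs, filters internal domains, assigns
#' subcompartment labels, builds the domain interaction networks, and
#' runs the enabled stages: connectivity and tail fits with the
#' rescaled-collapse table ("networks"), subcompartment enrichment,
#' top interactors and composition ("enrichment"), and the
#' chromosome-pair matrix, RSS elbow, DR profiles with bootstrap null
#' and run lengths ("transnet"). All tables are written under
#' \code{outdir} together with \code{summary.json} (headline numbers)
#' and \code{manifest.json} (parameters and seed).
#'
#' @param config An \code{\link{analysis_config}}.
#' @param outdir Output directory; created if needed. \code{NULL} skips
#'   file output.
#' @return A list with all stage results and the \code{summary} list,
#'   invisibly.
#' @export
run_analysis <- function(config, outdir = NULL) {
  stopifnot(inherits(config, "analysis_config"))
  if (!is.null(outdir)) dir.create(outdir, showWarnings = FALSE,
                                   recursive = TRUE)
  summary <- list(seed = config$seed)
  res <- list()

  # --- load or generate -------------------------------------------------
  if (!is.null(config$synthetic)) {
    genome <- generate_genome(config$synthetic, seed = config$seed)
    domains_all <- genome$domains
    annotation <- genome$annotation
    chrom_lengths <- genome$chrom_lengths
  } else {
    p <- config$paths
    domains_all <- read_domains(p$domains)
    annotation <- read_subcompartments(p$subcompartments)
    chrom_lengths <- unlist(p$chrom_lengths)
  }
  domains <- filter_internal_domains(domains_all)
  filt_report <- attr(domains, "report")
  asg <- assign_subcompartments(domains, annotation,
                                mode = config$assignment_mode)
  domains <- asg$domains
  summary$n_domains_input <- nrow(domains_all)
  summary$n_domains_kept <- nrow(domains)
  summary$fraction_assigned <- asg$report$fraction_assigned

  if (!is.null(config$synthetic)) {
    nets <- genome$nets
    # the generator plants intensities for the filtered top-level set;
    # restrict the labeled table to it
    keep <- domains$id %in% unlist(lapply(nets$cis,
      function(n) n$domains_row$id))
    nets <- relabel_nets(nets, domains[keep, , drop = FALSE])
  } else {
    mats <- list()
    for (key in names(p$matrices)) {
      pair <- strsplit(key, "|", fixed = TRUE)[[1L]]
      cr <- pair[1L]; cc <- if (length(pair) > 1L) pair[2L] else pair[1L]
      nb <- ceiling(unname(chrom_lengths[c(cr, cc)]) / config$bin_size)
      mats[[key]] <- read_contact_matrix(p$matrices[[key]], config$bin_size,
                                         format = "sparse", chrom_row = cr,
                                         chrom_col = cc, n_bins = nb)
    }
    nets <- build_interaction_matrices(mats, domains)
  }
  res$domains <- domains
  res$nets <- nets

  cis_pool <- pool_interactions(nets$cis)
  trans_pool <- pool_interactions(nets$trans)
  summary$cis_trans_ratio <- cis_trans_ratio(cis_pool, trans_pool)

  # --- networks ---------------------------------------------------------
  if ("networks" %in% config$stages) {
    conn <- list()
    for (pct in config$percentiles) {
      thr <- interaction_threshold(trans_pool, pct)
      conn[[as.character(pct)]] <- list(
        percentile = pct, threshold = thr,
        cis = connectivity(nets$cis, thr)$n_mean,
        trans = connectivity(nets$trans, thr)$n_mean)
    }
    res$connectivity <- conn
    summary$n_mean <- lapply(conn, function(ci) {
      list(cis = ci$cis, trans = ci$trans)
    })
    fits <- lapply(names(nets$cis), function(ch) {
      fit_power_law(pool_interactions(nets$cis[[ch]]))
    })
    names(fits) <- names(nets$cis)
    res$cis_fits <- fits
    res$cis_fit_pool <- fit_power_law(cis_pool)
    res$trans_fit_pool <- fit_exponential(trans_pool)
    res$trans_comparison <- lapply(nets$trans, function(net) {
      compare_tail_models(pool_interactions(net))
    })
    summary$gamma_per_chrom <- vapply(fits, function(f) f$gamma, numeric(1))
    summary$gamma_pool <- res$cis_fit_pool$gamma
    summary$trans_I0 <- res$trans_fit_pool$I0
    summary$trans_exp_r2 <- mean(vapply(res$trans_comparison,
      function(x) x$exponential$r_squared, numeric(1)), na.rm = TRUE)
    summary$trans_exponential_fraction <- mean(vapply(res$trans_comparison,
      function(x) x$classification == "exponential", logical(1)))
    if (length(nets$cis) >= 2L) {
      res$collapse <- rescale_collapse(lapply(nets$cis, pool_interactions))
    }
  }

  # --- enrichment -------------------------------------------------------
  if ("enrichment" %in% config$stages &&
      sum(!is.na(domains$subcompartment)) > 0L) {
    res$enrichment_cis <- subcompartment_enrichment(nets$cis, "cis")
    res$enrichment_trans <- subcompartment_enrichment(nets$trans, "trans")
    res$top_cis <- top_interactors(nets$cis, config$top_fraction)
    res$top_trans <- top_interactors(nets$trans, config$top_fraction)
    res$composition <- list(
      all = compartment_composition(domains),
      top_cis = compartment_composition(res$top_cis),
      top_trans = compartment_composition(res$top_trans))
    summary$H0_cis <- res$enrichment_cis$H0
    summary$H0_trans <- res$enrichment_trans$H0
  }

  # --- transnet ---------------------------------------------------------
  if ("transnet" %in% config$stages && length(nets$trans) > 0L) {
    cpm <- chrom_pair_matrix(nets$trans, chrom_lengths)
    res$chrom_pair_matrix <- cpm
    if (nrow(cpm) >= 4L) {
      res$elbow <- rss_elbow(cpm, seed = config$seed)
      summary$elbow_k <- res$elbow$elbow_k
      summary$elbow_strength <- res$elbow$strength
      summary$elbow_verdict <- res$elbow$verdict
    }
    pairs <- config$dr_pairs
    if (identical(pairs, "first")) {
      pairs <- list(strsplit(names(nets$trans)[1L], "|", fixed = TRUE)[[1L]])
    }
    res$dr <- list()
    for (pr in pairs) {
      key <- paste0(pr[1L], "|", pr[2L])
      net <- nets$trans[[key]] %||% nets$trans[[paste0(pr[2L], "|", pr[1L])]]
      if (is.null(net)) stop("no trans network for DR pair ", key)
      res$dr[[key]] <- dr_bootstrap(net, config$bootstrap_replicates,
                                    seed = config$seed)
    }
    first <- res$dr[[1L]]
    summary$sigma_dr <- first$sigma
    summary$sigma_dr_rand <- first$sigma_rand
    summary$mean_run <- first$mean_run
    summary$mean_run_rand <- first$mean_run_rand
  }

  res$summary <- summary
  res$filter_report <- filt_report
  res$assignment_report <- asg$report

  if (!is.null(outdir)) write_analysis(res, config, outdir)
  invisible(res)
}

relabel_nets <- function(nets, domains) {
  lab <- stats::setNames(domains$subcompartment, domains$id)
  fix <- function(net) {
    net$domains_row$subcompartment <- unname(lab[net$domains_row$id])
    net$domains_col$subcompartment <- unname(lab[net$domains_col$id])
    net
  }
  list(cis = lapply(nets$cis, fix), trans = lapply(nets$trans, fix))
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

write_analysis <- function(res, config, outdir) {
  dom <- res$domains
  dom$length <- dom$end - dom$start
  write_tsv(dom, file.path(outdir, "domains.tsv"))
  if (!is.null(res$connectivity)) {
    write_tsv(do.call(rbind, lapply(res$connectivity, function(ci) {
      data.frame(percentile = ci$percentile, threshold = ci$threshold,
                 n_mean_cis = ci$cis, n_mean_trans = ci$trans)
    })), file.path(outdir, "connectivity.tsv"))
  }
  if (!is.null(res$cis_fits)) {
    write_tsv(do.call(rbind, lapply(names(res$cis_fits), function(ch) {
      f <- res$cis_fits[[ch]]
      data.frame(chrom = ch, family = f$family, gamma = f$gamma,
                 xmin = f$xmin, r_squared = f$r_squared,
                 ks = f$ks_distance, n_tail = f$n_tail,
                 converged = f$converged)
    })), file.path(outdir, "cis_fits.tsv"))
  }
  if (!is.null(res$collapse)) {
    write_tsv(res$collapse, file.path(outdir, "collapse.tsv"))
  }
  for (scope in c("cis", "trans")) {
    hm <- res[[paste0("enrichment_", scope)]]
    if (is.null(hm)) next
    idx <- which(upper.tri(hm$H, diag = TRUE), arr.ind = TRUE)
    write_tsv(data.frame(label_i = hm$labels[idx[, 1L]],
                         label_j = hm$labels[idx[, 2L]],
                         mean_I = hm$mean_I[idx], H = hm$H[idx],
                         n_pairs = hm$n_pairs[idx]),
              file.path(outdir, paste0("enrichment_", scope, ".tsv")))
  }
  if (!is.null(res$composition)) {
    comp <- do.call(rbind, lapply(names(res$composition), function(set) {
      fr <- res$composition[[set]]
      data.frame(set = set, label = names(fr), fraction = as.numeric(fr))
    }))
    write_tsv(comp, file.path(outdir, "composition.tsv"))
  }
  if (!is.null(res$chrom_pair_matrix)) {
    m <- unclass(res$chrom_pair_matrix)
    write_tsv(data.frame(chrom = rownames(m), m, check.names = FALSE),
              file.path(outdir, "chrom_pairs.tsv"))
  }
  for (key in names(res$dr)) {
    d <- res$dr[[key]]
    fn <- paste0("dr_", gsub("|", "_", key, fixed = TRUE), ".tsv")
    write_tsv(data.frame(id = names(d$profile$DR), S = d$profile$S,
                         DR = d$profile$DR),
              file.path(outdir, fn))
  }
  jsonlite::write_json(res$summary, file.path(outdir, "summary.json"),
                       auto_unbox = TRUE, digits = NA)
  manifest <- list(
    package_version = as.character(utils::packageVersion("chromnet")),
    seed = config$seed, bin_size = config$bin_size,
    percentiles = config$percentiles, top_fraction = config$top_fraction,
    bootstrap_replicates = config$bootstrap_replicates,
    stages = config$stages,
    mode = if (is.null(config$synthetic)) "paths" else "synthetic",
    synthetic_spec = if (is.null(config$synthetic)) NULL
                     else unclass(config$synthetic))
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(outdir)
}
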