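# End-to-end pipeline: simulate (or read) inputs, derive all per-bin
# scores, build the crossover map, sites, partitions, enrichment tables,
# pileups, the feature matrix, PCA, the three recombination models and the
# compartment-masked P(s) loop-length estimates; write per-stage TSVs and
# a machine-readable results JSON.

#' Assemble a pipeline run configuration
#'
#' Either a `simulate` block (arguments for [sim_config()]) or an
#' `inputs` block (file paths) must be present. The single `seed` is
#' fanned out to every stochastic step via [derive_seed()].
#'
#' @param ... Configuration fields overriding the defaults, or a single
#'   list of them.
#' @param path Optional YAML file to read the configuration from
#'   (overridden by `...`).
#' @return List of class `run_config`.
#' @export
run_config <- function(..., path = NULL) {
  defaults <- list(
    simulate = list(),
    inputs = NULL,
    bin_size = 5000,
    stages = c("ES", "zygonema", "pachynema"),
    compartment_stage = "ES",
    flank_bins_profile = 100L,
    flank_bins_matrix = 100L,
    n_boot = 1000L,
    alpha = 0.001,
    enrich_alpha = 0.01,
    loop_search_range = c(1e5, 1e7),
    seed = 0L,
    out_dir = NULL)
  cfg <- defaults
  if (!is.null(path)) {
    cfg <- utils::modifyList(cfg, yaml::read_yaml(path))
  }
  dots <- list(...)
  if (length(dots) == 1L && is.null(names(dots)) && is.list(dots[[1L]])) {
    dots <- dots[[1L]]
  }
  cfg <- utils::modifyList(cfg, dots)
  if (is.null(cfg$simulate) && is.null(cfg$inputs)) {
    stop("config needs a 'simulate' block or an 'inputs' block")
  }
  structure(cfg, class = "run_config")
}

#' Run the full analysis pipeline
#'
#' Executes, in order: simulate (optional) -> bin-tracks -> hic-scores per
#' stage -> crossover score map -> sites -> partitions -> enrichment ->
#' pileups -> feature matrix -> PCA -> models -> P(s)/loop lengths.
#' Results are written as TSVs plus a `results.json` whose content is
#' bitwise-identical across reruns with the same seed. Stages that need
#' Hi-C are skipped (and listed as skipped) when no contact data is
#' configured.
#'
#' @param config A [run_config()] (or list coercible to one).
#' @return Invisibly, a list with `results` (what `results.json` holds)
#'   and `objects` (the in-memory intermediates).
#' @export
run_all <- function(config) {
  if (!inherits(config, "run_config")) config <- run_config(config)
  out_dir <- config$out_dir %||% tempfile("meiorec_run_")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  res <- list(stages = list())
  mark <- function(stage, status = "done") {
    res$stages[[stage]] <<- status
  }
  stages <- config$stages

  ## 1. simulate / load inputs ------------------------------------------
  synthetic <- !is.null(config$simulate)
  if (synthetic) {
    sim_args <- config$simulate
    if (is.null(sim_args$seed)) {
      sim_args$seed <- derive_seed(config$seed, "simulate")
    }
    scfg <- do.call(sim_config, sim_args)
    stages <- intersect(stages, names(scfg$compartment_strength))
    sim <- simulate_all(scfg, stages = stages)
    bins <- sim$bins
    chip_tracks <- sim$peaks$tracks
    prdm9_peaks <- sim$peaks$prdm9_peaks
    dmc1_peaks <- sim$peaks$dmc1_peaks
    crossovers <- sim$crossovers
    chromhmm <- sim$chromhmm
    contacts <- sim$contacts
    mark("simulate")
  } else {
    sim <- NULL
    inp <- config$inputs
    bins <- make_bins(read_chromsizes(inp$chromsizes), config$bin_size)
    chip_tracks <- lapply(inp$bedgraphs %||% list(), function(p) {
      read_bedgraph(p)
    })
    chip_tracks <- Map(function(bg, nm) map_bedgraph_to_bins(bg, bins, nm),
                       chip_tracks, names(chip_tracks))
    prdm9_peaks <- read_bed(inp$peaks$prdm9)
    dmc1_peaks <- read_bed(inp$peaks$dmc1)
    crossovers <- read_bed_headered(inp$crossovers)
    chromhmm <- read_segmentation(inp$chromhmm)
    contacts <- lapply(inp$contacts %||% list(), function(x) {
      read_contacts(x$triplets, bins, trans_path = x$trans,
                    balance = isTRUE(x$balance))
    })
    stages <- names(contacts)
    mark("simulate", "skipped")
  }
  have_hic <- length(stages) > 0L && length(contacts) > 0L
  res$n_bins <- nrow(bins)
  res$chromosomes <- names(chromsizes_of(bins))

  ## 2. bin tracks -------------------------------------------------------
  states <- chromhmm_overlap_tracks(chromhmm, bins)
  state_tracks <- lapply(colnames(states), function(st) {
    binned_track(states[, st], paste0("state_", st), "coverage")
  })
  names(state_tracks) <- paste0("state_", colnames(states))
  activity_ref <- binned_track(
    states[, "promoter"] + states[, "prom_enh"] +
      states[, "enh_gene_body"] + states[, "gene_body"],
    "activity_ref", "score")
  mark("bin_tracks")

  ## 3. Hi-C scores per stage -------------------------------------------
  hic_tracks <- list()
  comp_labels <- NULL
  if (have_hic) {
    for (stg in stages) {
      cm <- contacts[[stg]]
      hic_tracks[[paste0("cis_total_", stg)]] <- cis_total_ratio(cm)
      hic_tracks[[paste0("compartment_", stg)]] <-
        fine_grain_compartment(cm, activity_ref)
      hic_tracks[[paste0("insulation_", stg)]] <- insulation_score(cm)
      hic_tracks[[paste0("fire_", stg)]] <- fire_score(cm)
    }
    comp_stage <- if (config$compartment_stage %in% stages) {
      config$compartment_stage
    } else stages[1L]
    comp_score <- hic_tracks[[paste0("compartment_", comp_stage)]]
    comp_labels <- compartment_labels(as.numeric(comp_score), nrow(bins))
    res$compartment_stage <- comp_stage
    for (stg in stages) {
      df <- data.frame(bin_id = bins$bin_id)
      for (w in c("cis_total", "compartment", "insulation", "fire")) {
        df[[w]] <- as.numeric(hic_tracks[[paste0(w, "_", stg)]])
      }
      data.table::fwrite(df, file.path(out_dir,
                                       paste0("hic_scores_", stg, ".tsv")),
                         sep = "\t")
    }
    mark("hic_scores")
  } else {
    mark("hic_scores", "skipped")
  }

  ## 4. crossover score map ---------------------------------------------
  xo_score <- crossover_score_map(crossovers, bins)
  write_bedgraph(xo_score, bins, file.path(out_dir, "crossover_score.bedgraph"))
  res$n_crossovers <- nrow(crossovers)
  mark("xo_score")

  ## 5. sites ------------------------------------------------------------
  score_tracks <- c(list(prdm9_score = chip_tracks$prdm9,
                         dmc1_score = chip_tracks$dmc1,
                         crossover_score = xo_score),
                    hic_tracks)
  prdm9_sites <- define_sites(prdm9_peaks, bins, score_tracks, "PRDM9")
  dsb_sites <- define_sites(dmc1_peaks, bins, score_tracks, "DSB")
  joint_sites <- union_sites(prdm9_sites, dsb_sites)
  for (nm in c("prdm9_sites", "dsb_sites", "joint_sites")) {
    data.table::fwrite(as.data.frame(get(nm)),
                       file.path(out_dir, paste0(nm, ".tsv")), sep = "\t")
  }
  res$n_prdm9_sites <- nrow(prdm9_sites)
  res$n_dsb_sites <- nrow(dsb_sites)
  res$n_joint_sites <- nrow(joint_sites)
  mark("sites")

  ## 6. partitions --------------------------------------------------------
  part_prdm9 <- partition_quartiles(prdm9_sites, "dmc1_score")
  part_dsb <- partition_quartiles(dsb_sites, "crossover_score")
  res$partition_sizes <- list(prdm9 = length(part_prdm9$top),
                              dsb = length(part_dsb$top))
  mark("partitions")

  ## variables used for enrichment and features --------------------------
  chip_named <- chip_tracks[intersect(c("rnapii", "ctcf", "cohesin"),
                                      names(chip_tracks))]
  feature_vars <- c(hic_tracks, chip_named, state_tracks)
  enrich_vars <- c(list(prdm9 = chip_tracks$prdm9, dmc1 = chip_tracks$dmc1,
                        crossover_score = xo_score),
                   feature_vars)

  ## 7. enrichment --------------------------------------------------------
  if (have_hic) {
    enr <- list(
      prdm9 = enrichment_summary(part_prdm9, prdm9_sites, enrich_vars,
                                 valid = bins$valid,
                                 alpha = config$enrich_alpha),
      dsb = enrichment_summary(part_dsb, dsb_sites, enrich_vars,
                               valid = bins$valid,
                               alpha = config$enrich_alpha))
    for (nm in names(enr)) {
      data.table::fwrite(enr[[nm]],
                         file.path(out_dir, paste0("enrichment_", nm, ".tsv")),
                         sep = "\t")
    }
    res$enrichment <- enr
    mark("enrichment")
  } else {
    mark("enrichment", "skipped")
  }

  ## 8. pileups -----------------------------------------------------------
  if (have_hic) {
    prof_summaries <- list()
    pf <- config$flank_bins_profile
    for (stg in stages) {
      for (w in c("cis_total", "compartment")) {
        trk <- hic_tracks[[paste0(w, "_", stg)]]
        for (pp in list(list(nm = "prdm9", part = part_prdm9, st = prdm9_sites),
                        list(nm = "dsb", part = part_dsb, st = dsb_sites))) {
          key <- paste(w, stg, pp$nm, sep = "_")
          top_sites <- pp$st[pp$st$bin_id %in% pp$part$top, , drop = FALSE]
          bot_sites <- pp$st[pp$st$bin_id %in% pp$part$bottom, , drop = FALSE]
          p_top <- pileup_track(trk, top_sites, bins, pf,
                                n_boot = config$n_boot,
                                seed = derive_seed(config$seed,
                                                   paste0("boot:", key, ":top")))
          p_bot <- pileup_track(trk, bot_sites, bins, pf,
                                n_boot = config$n_boot,
                                seed = derive_seed(config$seed,
                                                   paste0("boot:", key, ":bot")))
          cmp <- compare_profiles(p_top, p_bot, n_boot = config$n_boot,
                                  seed = derive_seed(config$seed,
                                                     paste0("cmp:", key)))
          data.table::fwrite(
            cbind(as.data.frame(p_top)[, c("offset_bp", "mean", "lo", "hi")],
                  bottom_mean = p_bot$mean),
            file.path(out_dir, paste0("profile_", key, ".tsv")), sep = "\t")
          prof_summaries[[key]] <- as.list(cmp$summary)
        }
      }
    }
    pile_center <- list()
    for (stg in stages) {
      for (pp in list(list(nm = "prdm9", part = part_prdm9, st = prdm9_sites),
                      list(nm = "dsb", part = part_dsb, st = dsb_sites))) {
        for (grp in c("top", "bottom")) {
          ids <- pp$part[[grp]]
          ss <- pp$st[pp$st$bin_id %in% ids, , drop = FALSE]
          pm <- pileup_matrix(contacts[[stg]], ss, config$flank_bins_matrix)
          key <- paste(stg, pp$nm, grp, sep = "_")
          ctr <- pm$flank_bins + 1L
          pile_center[[key]] <- list(center_oe = pm$mat[ctr, ctr],
                                     n_sites = pm$n_sites)
        }
      }
    }
    res$profile_summaries <- prof_summaries
    res$pileup_matrix_centers <- pile_center
    mark("pileups")
  } else {
    mark("pileups", "skipped")
  }

  ## 9-11. features, PCA, models -----------------------------------------
  if (have_hic) {
    joint_meta <- joint_sites
    fm <- build_feature_matrix(joint_meta, feature_vars, bins)
    pca <- run_pca(fm, n_components = 4L)
    models <- fit_recombination_models(pca, fm, alpha_base = config$alpha)
    data.table::fwrite(
      data.frame(feature = rownames(pca$loadings), pca$loadings),
      file.path(out_dir, "pca_loadings.tsv"), sep = "\t")
    res$feature_matrix <- list(n_rows = nrow(fm), n_cols = ncol(fm),
                               n_dropped_rows = attr(fm, "dropped_rows"),
                               dropped_cols = attr(fm, "dropped_cols"))
    res$pca_explained_var <- as.numeric(
      utils::head(pca$explained_var, 10L))
    res$models <- lapply(unclass(models), function(m) {
      list(selected = m$selected, coef = as.list(m$coef),
           t = as.list(m$t), p = as.list(m$p),
           r2 = m$r2, naive_r2 = m$naive_r2, n_obs = m$n_obs)
    })
    mark("features"); mark("pca"); mark("models")
  } else {
    fm <- NULL; pca <- NULL; models <- NULL
    mark("features", "skipped"); mark("pca", "skipped")
    mark("models", "skipped")
  }

  ## 12. P(s) and loop lengths -------------------------------------------
  if (have_hic) {
    loops <- list()
    for (stg in stages) {
      ll <- compartment_loop_lengths(contacts[[stg]], comp_labels,
                                     search_range = config$loop_search_range)
      write_ps_curve(ll$ps_A, file.path(out_dir, paste0("ps_A_", stg, ".tsv")))
      write_ps_curve(ll$ps_B, file.path(out_dir, paste0("ps_B_", stg, ".tsv")))
      loops[[stg]] <- list(loop_A = ll$loop_A, loop_B = ll$loop_B,
                           ratio_BA = ll$ratio_BA)
    }
    res$loops <- loops
    mark("ps_loops")
  } else {
    mark("ps_loops", "skipped")
  }

  ## ground-truth recovery diagnostics (synthetic runs only) -------------
  if (synthetic && have_hic) {
    truth_num <- ifelse(sim$truth$compartment == "A", 1, -1)
    rec <- list()
    for (stg in stages) {
      sc <- as.numeric(hic_tracks[[paste0("compartment_", stg)]])
      rec[[stg]] <- suppressWarnings(
        stats::cor(sc, truth_num, use = "pairwise.complete.obs"))
    }
    res$recovery <- list(compartment_r = rec)
  }

  res$skipped <- names(res$stages)[unlist(res$stages) == "skipped"]
  jsonlite::write_json(res, file.path(out_dir, "results.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       na = "null")
  invisible(list(results = res, out_dir = out_dir,
                 objects = list(sim = sim, bins = bins,
                                contacts = if (have_hic) contacts else NULL,
                                tracks = c(chip_tracks, hic_tracks,
                                           state_tracks),
                                states = states, xo_score = xo_score,
                                prdm9_sites = prdm9_sites,
                                dsb_sites = dsb_sites,
                                joint_sites = joint_sites,
                                part_prdm9 = part_prdm9,
                                part_dsb = part_dsb,
                                fm = fm, pca = pca, models = models)))
}

#' Union of two site sets (joint PRDM9-DSB sites)
#'
#' @param prdm9_sites,dsb_sites [define_sites()] outputs over the same
#'   bins.
#' @return A `site_set` over the union of bin ids with membership flags
#'   `is_prdm9`, `is_dsb`.
#' @export
union_sites <- function(prdm9_sites, dsb_sites) {
  all_ids <- sort(union(prdm9_sites$bin_id, dsb_sites$bin_id))
  base <- rbind(as.data.frame(prdm9_sites), as.data.frame(dsb_sites))
  base <- base[!duplicated(base$bin_id), , drop = FALSE]
  base <- base[match(all_ids, base$bin_id), , drop = FALSE]
  base$is_prdm9 <- all_ids %in% prdm9_sites$bin_id
  base$is_dsb <- all_ids %in% dsb_sites$bin_id
  rownames(base) <- NULL
  attr(base, "label") <- "joint"
  class(base) <- c("site_set", "data.frame")
  base
}
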