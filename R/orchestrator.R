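#' Configuration for a full calibration study
#'
#' Bundles every stage's settings into one reproducible object. The master
#' `seed` fans out deterministically to per-stage seeds, so two runs with
#' the same configuration produce identical artifacts.
#'
#' @param sim A [sim_config()] for synthetic input, or `NULL` when reading
#'   files.
#' @param spectra_path,concentrations_path CSV inputs, used when `sim` is
#'   `NULL`.
#' @param screening List: `enabled`, `confidence`, `rule`, `k`
#'   (`NULL` = variance rule), `q_method`.
#' @param partition List: `validation_fraction`, `ks_basis`.
#' @param preprocess List: `space` (option grid for
#'   [enumerate_pipelines()]), `ncomp_range`.
#' @param wavesel List: `region` (`c(lo, hi)` in cm^-1 or `NULL`),
#'   `n_intervals`, `bin_width`, `ga` (a [ga_config()]), `ipls_top` (how
#'   many top iPLS intervals seed the GA population).
#' @param models Named list of model specs (or per-protein spec lists) as
#'   accepted by [run_model_comparison()].
#' @param schemes Evaluation schemes passed through to
#'   [run_model_comparison()].
#' @param seed Master seed.
#' @return A `study_config` list.
#' @export
study_config <- function(sim = sim_config(),
                         spectra_path = NULL, concentrations_path = NULL,
                         screening = list(enabled = TRUE, confidence = 0.99,
                                          rule = "and", k = NULL,
                                          q_method = "jm"),
                         partition = list(validation_fraction = 0.30,
                                          ks_basis = "spectra"),
                         preprocess = list(space = default_pipeline_space(),
                                           ncomp_range = 1:20),
                         wavesel = list(region = c(1000, 3000),
                                        n_intervals = 20L, bin_width = 17L,
                                        ga = ga_config(), ipls_top = 3L),
                         models = list(pls = model_spec("pls", n_components = 10L),
                                       svr = model_spec("svr", kernel = "linear",
                                                        C = 100, epsilon = 0.05),
                                       ridge = model_spec("ridge", alpha = 1e-3),
                                       lr = model_spec("lr")),
                         schemes = c("KS", "RS", "LORO", "LOSO"),
                         seed = 1L) {
  cfg <- list(sim = sim, spectra_path = spectra_path,
              concentrations_path = concentrations_path,
              screening = screening, partition = partition,
              preprocess = preprocess, wavesel = wavesel,
              models = models, schemes = schemes, seed = as.integer(seed))
  class(cfg) <- "study_config"
  cfg
}

#' Run the full calibration study
#'
#' Executes the stages in their canonical order: load or simulate spectra;
#' screen outliers (T2/Q gates); partition into calibration/validation
#' (Kennard-Stone); search the preprocessing grid on that split; select
#' wavenumbers per protein (region restriction, binning, iPLS-seeded GA on
#' the calibration spectra); then evaluate every model family under every
#' scheme, both raw and with the optimal preprocessing plus GA mask.
#'
#' @param cfg A [study_config()].
#' @param out_dir Optional directory; when given, stage artifacts (CSV
#'   tables, JSON masks, a YAML provenance record) are written there.
#' @return A list with `spectra` (post-screening), `concentrations`,
#'   `screening` report, `split`, `pipeline_search`, `wavenumber_selection`
#'   (per protein), and `report` (data.frame with a `condition` column,
#'   `raw` vs `op_ga`).
#' @export
run_pipeline <- function(cfg, out_dir = NULL) {
  stopifnot(inherits(cfg, "study_config"))
  if (!is.null(out_dir) && !dir.exists(out_dir))
    dir.create(out_dir, recursive = TRUE)
  say <- function(fmt, ...) message(sprintf(paste0("[mirwhey] ", fmt), ...))

  # --- input ---------------------------------------------------------
  if (!is.null(cfg$sim)) {
    sim <- cfg$sim
    sim$seed <- derive_seed(cfg$seed, 11L)
    gen <- generate_dataset(sim)
    s <- gen$spectra; conc <- gen$truth$concentrations
    say("simulated %d spectra / %d samples", n_spectra(s), n_samples(s))
  } else {
    s <- read_spectra(cfg$spectra_path)
    conc <- read_concentrations(cfg$concentrations_path)
    say("loaded %d spectra / %d samples", n_spectra(s), n_samples(s))
  }

  # --- screening ------------------------------------------------------
  screen_rep <- NULL
  if (isTRUE(cfg$screening$enabled)) {
    screen_rep <- flag_outliers(s, conc, k = cfg$screening$k,
                                confidence = cfg$screening$confidence %||% 0.99,
                                rule = cfg$screening$rule %||% "and",
                                q_method = cfg$screening$q_method %||% "jm")
    n_flagged <- sum(screen_rep$flagged)
    s <- remove_outliers(s, screen_rep)
    say("screening flagged %d spectra; %d survive", n_flagged, n_spectra(s))
  }

  # --- partition ------------------------------------------------------
  split <- ks_split(s, conc, basis = cfg$partition$ks_basis %||% "spectra",
                    validation_fraction =
                      cfg$partition$validation_fraction %||% 0.30)
  tr <- match(split$calibration_ids, s$spectrum_id)
  va <- match(split$validation_ids, s$spectrum_id)
  yj <- join_concentrations(s, conc)
  Y <- as.matrix(yj[, c("beta_lg", "alpha_la")])
  say("Kennard-Stone split: %d calibration / %d validation",
      length(tr), length(va))

  # --- preprocessing search ------------------------------------------
  search <- search_best_pipeline(
    cal = list(X = s$absorbance[tr, , drop = FALSE],
               Y = Y[tr, , drop = FALSE]),
    val = list(X = s$absorbance[va, , drop = FALSE],
               Y = Y[va, , drop = FALSE]),
    space = cfg$preprocess$space,
    ncomp_range = cfg$preprocess$ncomp_range %||% 1:20,
    wavenumbers = s$wavenumbers)
  best_pipe <- search$pipelines[[search$winner]]
  say("preprocessing winner: %s (ncomp %d)",
      format(best_pipe), search$results$ncomp[search$winner])

  # --- wavenumber selection (per protein) ----------------------------
  ws <- cfg$wavesel
  region <- ws$region
  s_sel <- if (!is.null(region))
    restrict_region(s, min(region), max(region)) else s
  # wavenumber selection operates on preprocessed calibration spectra
  fp_sel <- fit_pipeline(best_pipe, s_sel$absorbance[tr, , drop = FALSE],
                         s_sel$wavenumbers)
  binned <- bin_wavenumbers(fp_sel$X, bin_width = ws$bin_width %||% 17L,
                            wavenumbers = s_sel$wavenumbers)
  sel <- list()
  for (protein in c("beta_lg", "alpha_la")) {
    ycal <- Y[tr, if (protein == "beta_lg") 1 else 2]
    rank <- ipls_rank(fp_sel$X, ycal,
                      n_intervals = ws$n_intervals %||% 20L,
                      fold_seed = derive_seed(cfg$seed, 23L))
    top <- rank$rank_order[seq_len(min(ws$ipls_top %||% 3L,
                                       length(rank$rank_order)))]
    top_cols <- unlist(lapply(top, function(i)
      rank$intervals$start[i]:rank$intervals$end[i]))
    init_bins <- which(vapply(binned$index_map, function(ix)
      any(ix %in% top_cols), logical(1)))
    ga_cfg <- ws$ga %||% ga_config()
    ga_cfg$seed <- derive_seed(cfg$seed,
                               if (protein == "beta_lg") 31L else 37L)
    ga <- ga_select(binned, ycal, ga_cfg, init_bins = init_bins)
    idx_region <- expand_selection(ga$mask, binned)
    # map region-restricted column indices back to the full axis
    full_idx <- match(s_sel$wavenumbers[idx_region], s$wavenumbers)
    sel[[protein]] <- list(ipls = rank, ga = ga,
                           region_indices = idx_region,
                           mask_indices = full_idx,
                           wavenumbers = s$wavenumbers[full_idx])
    say("%s: GA kept %d of %d bins (%d data points)",
        protein, sum(ga$mask), length(ga$mask), length(full_idx))
  }

  # --- model comparison ----------------------------------------------
  raw_rep <- run_model_comparison(s, conc, cfg$models,
                                  validation_fraction =
                                    cfg$partition$validation_fraction %||% 0.30,
                                  seed = derive_seed(cfg$seed, 41L),
                                  schemes = cfg$schemes)
  raw_rep$condition <- "raw"
  proc_rep <- run_model_comparison(
    s, conc, cfg$models, pipeline = best_pipe,
    masks = list(beta_lg = sel$beta_lg$mask_indices,
                 alpha_la = sel$alpha_la$mask_indices),
    validation_fraction = cfg$partition$validation_fraction %||% 0.30,
    seed = derive_seed(cfg$seed, 41L), schemes = cfg$schemes)
  proc_rep$condition <- "op_ga"
  report <- rbind(raw_rep, proc_rep)

  out <- list(spectra = s, concentrations = conc, screening = screen_rep,
              split = split, pipeline_search = search,
              best_pipeline = best_pipe, wavenumber_selection = sel,
              report = report, seed = cfg$seed)

  if (!is.null(out_dir)) {
    utils::write.csv(report, file.path(out_dir, "model_comparison.csv"),
                     row.names = FALSE)
    utils::write.csv(search$results,
                     file.path(out_dir, "preprocessing_search.csv"),
                     row.names = FALSE)
    if (!is.null(screen_rep))
      utils::write.csv(as.data.frame(screen_rep),
                       file.path(out_dir, "screening_report.csv"),
                       row.names = FALSE)
    for (protein in names(sel))
      jsonlite::write_json(
        list(protein = protein,
             selected_bins = which(sel[[protein]]$ga$mask),
             selected_wavenumbers = sel[[protein]]$wavenumbers),
        file.path(out_dir, paste0("selected_", protein, ".json")),
        auto_unbox = TRUE, digits = NA)
    yaml::write_yaml(list(seed = cfg$seed,
                          n_spectra = n_spectra(s),
                          winner_pipeline = format(best_pipe),
                          schemes = cfg$schemes),
                     file.path(out_dir, "provenance.yaml"))
  }
  invisible(out)
}
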