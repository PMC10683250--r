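#' Default pipeline configuration
#'
#' Assembles the configuration consumed by [run_pipeline()]: phantom
#' cohort sizes and spec, registration schedule, PRM thresholds, network
#' config, training epochs, and stratification thresholds.  Any element
#' can be overridden through `...` (nested lists are merged).
#'
#' @param out_dir artifact directory.
#' @param seed global seed; per-subject phantom seeds derive from it.
#' @param ... overrides merged into the defaults.
#' @return A nested list of class `pipeline_config`.
#' @export
pipeline_config <- function(out_dir = "prm-out", seed = 1L, ...) {
  cfg <- list(
    out_dir = out_dir,
    seed = as.integer(seed),
    phantom = list(n_train = 16L, n_test = 8L, spec = list()),
    registration = list(levels = 3L, control_spacing = c(16, 8, 4),
                        iters = 40L),
    thresholds = list(insp_cut = -950, exp_cut = -856),
    net = list(),
    train = list(epochs_expgen = 10L, epochs_prmgen = 15L),
    stratify = list(thresholds = c(15, 20, 25)))
  over <- list(...)
  cfg <- utils::modifyList(cfg, over)
  class(cfg) <- "pipeline_config"
  cfg
}

.cfg_hash <- function(cfg) {
  f <- tempfile()
  on.exit(unlink(f))
  writeLines(paste(deparse(unclass(cfg)), collapse = "\n"), f)
  unname(tools::md5sum(f))
}

.stage_marker <- function(out_dir, stage) {
  file.path(out_dir, paste0(".", stage, ".done.json"))
}

.stage_done <- function(out_dir, stage, hash) {
  mk <- .stage_marker(out_dir, stage)
  if (!file.exists(mk)) return(FALSE)
  info <- tryCatch(jsonlite::read_json(mk), error = function(e) NULL)
  identical(info$config_hash, hash)
}

.mark_stage <- function(out_dir, stage, hash, seed) {
  jsonlite::write_json(
    list(stage = stage, config_hash = hash, seed = seed,
         package_version = as.character(utils::packageVersion("lungprm")),
         time = format(Sys.time(), "%Y-%m-%dT%H:%M:%S")),
    .stage_marker(out_dir, stage), auto_unbox = TRUE)
}

.require_artifact <- function(path, stage) {
  if (!file.exists(path))
    stop("missing artifact ", path, ": run stage '", stage, "' first")
  path
}

.subject_paths <- function(out_dir, i) {
  base <- file.path(out_dir, "phantom")
  list(insp = file.path(base, sprintf("s%02d_insp.nii.gz", i)),
       exp = file.path(base, sprintf("s%02d_exp.nii.gz", i)),
       mask = file.path(base, sprintf("s%02d_mask.nii.gz", i)),
       truth = file.path(base, sprintf("s%02d_truth.nii.gz", i)),
       field = file.path(base, sprintf("s%02d_field.rds", i)))
}

.load_sample <- function(out_dir, i) {
  p <- .subject_paths(out_dir, i)
  for (f in unlist(p)) .require_artifact(f, "phantom")
  insp <- read_volume(p$insp, phase = "inspiratory")
  expv <- read_volume(p$exp, phase = "expiratory")
  maskv <- read_volume(p$mask, clamp = FALSE)
  truthv <- read_volume(p$truth, clamp = FALSE)
  list(insp = insp, exp = expv,
       mask = lung_mask(maskv$voxels > 0.5, spacing = maskv$spacing),
       truth = prm_map(array(as.integer(round(truthv$voxels)),
                             dim(truthv$voxels)), spacing = truthv$spacing),
       field = readRDS(p$field))
}

#' Run the PRM pipeline
#'
#' Executes the requested stages in dependency order: `phantom`
#' (synthetic cohort), `register` (FFD registration of each test pair),
#' `prm` (ground-truth PRM + report), `train_expgen`, `train_prmgen`,
#' `predict`, `evaluate` (SSIM/RMSE/Dice/correlations), `stratify`
#' (ROC of predicted vs ground-truth fSAD).  Stage outputs are files
#' under `cfg$out_dir`; completed stages are skipped unless `force`.
#'
#' @param cfg a [pipeline_config].
#' @param stages character vector of stages to run.
#' @param force recompute even when a stage is up to date.
#' @return Invisibly, the artifact directory.
#' @export
run_pipeline <- function(cfg = pipeline_config(),
                         stages = c("phantom", "register", "prm",
                                    "train_expgen", "train_prmgen",
                                    "predict", "evaluate", "stratify"),
                         force = FALSE) {
  stopifnot(inherits(cfg, "pipeline_config"))
  all_stages <- c("phantom", "register", "prm", "train_expgen",
                  "train_prmgen", "predict", "evaluate", "stratify")
  stages <- match.arg(stages, all_stages, several.ok = TRUE)
  stages <- all_stages[all_stages %in% stages]
  out <- cfg$out_dir
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  hash <- .cfg_hash(cfg)
  n_tr <- cfg$phantom$n_train; n_te <- cfg$phantom$n_test
  n_all <- n_tr + n_te
  test_ids <- n_tr + seq_len(n_te)
  netcfg <- do.call(net_config, cfg$net)

  run_stage <- function(stage, fun) {
    if (!force && .stage_done(out, stage, hash)) {
      message("stage '", stage, "' up to date")
      return(invisible(NULL))
    }
    fun()
    .mark_stage(out, stage, hash, cfg$seed)
  }

  if ("phantom" %in% stages) run_stage("phantom", function() {
    dir.create(file.path(out, "phantom"), showWarnings = FALSE)
    for (i in seq_len(n_all)) {
      spec <- do.call(phantom_spec,
                      utils::modifyList(cfg$phantom$spec,
                                        list(seed = cfg$seed * 1000L + i)))
      ph <- generate_phantom(spec)
      p <- .subject_paths(out, i)
      write_volume(ph$insp, p$insp)
      write_volume(ph$exp, p$exp)
      write_volume(ph$mask, p$mask)
      write_volume(ph$truth, p$truth)
      saveRDS(ph$field, p$field)
    }
    jsonlite::write_json(list(n_train = n_tr, n_test = n_te,
                              seed = cfg$seed, config_hash = hash),
                         file.path(out, "phantom", "manifest.json"),
                         auto_unbox = TRUE)
  })

  if ("register" %in% stages) run_stage("register", function() {
    dir.create(file.path(out, "register"), showWarnings = FALSE)
    for (i in test_ids) {
      s <- .load_sample(out, i)
      fld <- register_ffd(s$insp, s$exp, s$mask,
                          levels = cfg$registration$levels,
                          control_spacing = cfg$registration$control_spacing,
                          iters = cfg$registration$iters)
      saveRDS(fld, file.path(out, "register", sprintf("s%02d_field.rds", i)))
    }
  })

  if ("prm" %in% stages) run_stage("prm", function() {
    dir.create(file.path(out, "prm"), showWarnings = FALSE)
    thr <- prm_thresholds(cfg$thresholds$insp_cut, cfg$thresholds$exp_cut)
    rows <- NULL
    for (i in seq_len(n_all)) {
      s <- .load_sample(out, i)
      exp_reg <- warp_volume(s$exp, s$field)
      res <- classify_prm(s$insp, exp_reg, s$mask, thr)
      write_volume(res$map, file.path(out, "prm", sprintf("s%02d_prm.nii.gz", i)))
      rows <- rbind(rows, data.frame(
        subject = i, pct_normal = res$pct_normal, pct_fsad = res$pct_fsad,
        pct_emph = res$pct_emph, laa856 = laa856(exp_reg, s$mask),
        ei = ei_ratio(exp_reg, s$insp, s$mask)))
    }
    utils::write.csv(rows, file.path(out, "prm", "report.csv"),
                     row.names = FALSE)
  })

  if ("train_expgen" %in% stages) run_stage("train_expgen", function() {
    samples <- lapply(seq_len(n_tr), function(i) .load_sample(out, i))
    ck <- train_expiratory_generator(samples, netcfg, seed = cfg$seed,
                                     epochs = cfg$train$epochs_expgen)
    saveRDS(ck, file.path(out, "expgen.rds"))
    utils::write.csv(ck$history, file.path(out, "expgen_log.csv"),
                     row.names = FALSE)
  })

  if ("train_prmgen" %in% stages) run_stage("train_prmgen", function() {
    samples <- lapply(seq_len(n_tr), function(i) .load_sample(out, i))
    expgen <- if (netcfg$input_mode == "generated_exp")
      readRDS(.require_artifact(file.path(out, "expgen.rds"), "train_expgen"))
    else NULL
    ck <- train_prm_generator(samples, expgen, netcfg, seed = cfg$seed,
                              epochs = cfg$train$epochs_prmgen)
    saveRDS(ck, file.path(out, "prmgen.rds"))
    utils::write.csv(ck$history, file.path(out, "prmgen_log.csv"),
                     row.names = FALSE)
  })

  if ("predict" %in% stages) run_stage("predict", function() {
    dir.create(file.path(out, "predict"), showWarnings = FALSE)
    expgen <- readRDS(.require_artifact(file.path(out, "expgen.rds"),
                                        "train_expgen"))
    prmgen <- readRDS(.require_artifact(file.path(out, "prmgen.rds"),
                                        "train_prmgen"))
    for (i in test_ids) {
      s <- .load_sample(out, i)
      pr <- predict_prm(s$insp, s$mask, expgen, prmgen)
      write_volume(pr$pred, file.path(out, "predict",
                                      sprintf("s%02d_pred.nii.gz", i)))
      write_volume(pr$gen_exp, file.path(out, "predict",
                                         sprintf("s%02d_genexp.nii.gz", i)))
    }
  })

  if ("evaluate" %in% stages) run_stage("evaluate", function() {
    expgen <- readRDS(.require_artifact(file.path(out, "expgen.rds"),
                                        "train_expgen"))
    prmgen <- readRDS(.require_artifact(file.path(out, "prmgen.rds"),
                                        "train_prmgen"))
    rows <- NULL
    reals <- list(); gens <- list(); masks <- list()
    for (i in test_ids) {
      s <- .load_sample(out, i)
      pr <- predict_prm(s$insp, s$mask, expgen, prmgen)
      exp_reg <- warp_volume(s$exp, s$field)
      reals <- c(reals, list(exp_reg)); gens <- c(gens, list(pr$gen_exp))
      masks <- c(masks, list(s$mask))
      pf <- prm_fractions(pr$pred)
      tf <- prm_fractions(s$truth)
      rows <- rbind(rows, data.frame(
        subject = i,
        ssim = ssim(exp_reg, pr$gen_exp, mask = s$mask),
        rmse_hu = rmse(exp_reg, pr$gen_exp, mask = s$mask),
        dice_normal = dice(s$truth, pr$pred, 1L),
        dice_fsad = dice(s$truth, pr$pred, 2L),
        dice_emph = dice(s$truth, pr$pred, 3L),
        gt_fsad = tf$pct_fsad, pred_fsad = pf$pct_fsad,
        gt_emph = tf$pct_emph, pred_emph = pf$pct_emph,
        threshold_hu = pr$threshold))
    }
    utils::write.csv(rows, file.path(out, "metrics.csv"), row.names = FALSE)
    summ <- list(
      ssim = mean(rows$ssim), rmse_hu = rmse(reals, gens, masks),
      dice_normal = mean(rows$dice_normal),
      dice_fsad = mean(rows$dice_fsad), dice_emph = mean(rows$dice_emph),
      r_emph = tryCatch(pearson_r(rows$gt_emph, rows$pred_emph),
                        error = function(e) NA_real_),
      r_fsad = tryCatch(pearson_r(rows$gt_fsad, rows$pred_fsad),
                        error = function(e) NA_real_),
      threshold_hu = mean(rows$threshold_hu),
      config_hash = hash, seed = cfg$seed)
    jsonlite::write_json(summ, file.path(out, "metrics.json"),
                         auto_unbox = TRUE, digits = NA)
  })

  if ("stratify" %in% stages) run_stage("stratify", function() {
    mfile <- .require_artifact(file.path(out, "metrics.csv"), "evaluate")
    rows <- utils::read.csv(mfile)
    res <- list()
    for (th in cfg$stratify$thresholds) {
      lab <- binarize_fsad(rows$gt_fsad, th)
      entry <- if (length(unique(lab)) < 2L)
        list(auc = NA, note = "single class at this threshold")
      else {
        rr <- roc_auc(rows$pred_fsad, lab)
        list(auc = rr$auc, cutoff = rr$cutoff,
             sensitivity = rr$sens_at_cutoff,
             specificity = rr$spec_at_cutoff)
      }
      res[[sprintf("threshold_%g", th)]] <- entry
    }
    res$config_hash <- hash
    jsonlite::write_json(res, file.path(out, "strat.json"),
                         auto_unbox = TRUE, digits = NA)
  })

  invisible(out)
}
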