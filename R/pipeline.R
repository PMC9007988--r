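# Configuration-driven orchestration: simulate -> morphometry -> staging
# and simulate -> fit -> compare chains, with per-stage derived seeds and a
# manifest of every produced file.

stageSeed <- function(globalSeed, name) {
  h <- 0
  for (ch in utf8ToInt(name)) h <- (h * 31 + ch) %% 1000003
  as.integer((globalSeed + h) %% 2147483647)
}

readPipelineConfig <- function(config) {
  if (is.list(config)) return(config)
  if (!file.exists(config)) stop("config file not found: ", config)
  if (grepl("\\.json$", config, ignore.case = TRUE))
    jsonlite::read_json(config, simplifyVector = TRUE)
  else yaml::read_yaml(config)
}

validatePipelineConfig <- function(cfg) {
  if (is.null(cfg$outDir)) stop("config needs outDir")
  stages <- cfg$stages
  if (is.null(stages)) stages <- list()
  known <- c("simulate_tissue", "simulate_organ", "simulate_growth",
             "simulate_survival", "morphometry", "staging", "growth_fit",
             "survival_analysis")
  for (st in stages) {
    if (is.null(st$name) || is.null(st$type))
      stop("every stage needs a name and a type")
    if (!st$type %in% known)
      stop("unknown stage type: ", st$type)
  }
  stochastic <- c("simulate_tissue", "simulate_organ", "simulate_growth",
                  "simulate_survival", "growth_fit")
  if (any(vapply(stages, function(s) s$type %in% stochastic, TRUE)) &&
      is.null(cfg$seed))
    stop("a global seed is mandatory when any stage is stochastic")
  cfg$stages <- stages
  cfg
}

#' Run a configured analysis pipeline
#'
#' Executes the configured stages in order, writing each stage's outputs
#' under `outDir/<stage name>/` and a `manifest.json` listing every
#' produced file with its MD5 hash plus the resolved configuration. All
#' randomness flows from the global seed through per-stage derived seeds
#' (stage name hashed into the seed), so a rerun with the same config and
#' seed reproduces identical hashes for deterministic stages.
#'
#' Stage types: `simulate_tissue` (params: `samples` = list of
#' `list(id, class)`, plus [tissuePhantomSpec()] overrides),
#' `simulate_organ`, `simulate_growth` ([growthCohortSpec()] params),
#' `simulate_survival` ([survivalCohortSpec()] params), `morphometry`
#' (params: `input` = tissue stage name, `d`), `staging` (params: `input`,
#' `controlClass`, `k`), `growth_fit` (params: `input`, MCMC layout),
#' `survival_analysis` (params: `input`, optional `cutpoint = TRUE`).
#'
#' @param config path to a YAML or JSON configuration file (auto-detected
#'   by extension) or an equivalent list, with fields `seed`, `outDir` and
#'   `stages`.
#' @return the manifest, invisibly (also written as JSON): per stage the
#'   produced files and hashes; a `failure` record if a stage failed.
#' @export
runPipeline <- function(config) {
  cfg <- validatePipelineConfig(readPipelineConfig(config))
  dir.create(cfg$outDir, recursive = TRUE, showWarnings = FALSE)
  manifest <- list(config = cfg, stages = list())
  stageDir <- function(nm) {
    d <- file.path(cfg$outDir, nm)
    dir.create(d, recursive = TRUE, showWarnings = FALSE)
    d
  }
  record <- function(nm, files, info = list()) {
    files <- files[file.exists(files)]
    manifest$stages[[nm]] <<- c(list(
      files = as.list(stats::setNames(unname(tools::md5sum(files)),
                                      basename(files)))), info)
  }
  ok <- TRUE
  for (st in cfg$stages) {
    if (!ok) break
    sdir <- stageDir(st$name)
    seed <- stageSeed(cfg$seed %||% 0L, st$name)
    p <- st$params %||% list()
    res <- try(switch(st$type,
      simulate_tissue = stageSimulateTissue(sdir, p, seed),
      simulate_organ = stageSimulateOrgan(sdir, p, seed),
      simulate_growth = stageSimulateGrowth(sdir, p, seed),
      simulate_survival = stageSimulateSurvival(sdir, p, seed),
      morphometry = stageMorphometry(sdir, p, cfg$outDir),
      staging = stageStaging(sdir, p, cfg$outDir),
      growth_fit = stageGrowthFit(sdir, p, cfg$outDir, seed),
      survival_analysis = stageSurvival(sdir, p, cfg$outDir)
    ), silent = TRUE)
    if (inherits(res, "try-error")) {
      manifest$stages[[st$name]] <-
        list(failure = as.character(attr(res, "condition")$message))
      ok <- FALSE
    } else {
      record(st$name, res$files, res$info %||% list())
    }
  }
  path <- file.path(cfg$outDir, "manifest.json")
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA,
                       force = TRUE)
  invisible(manifest)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stageSimulateTissue <- function(dir, p, seed) {
  samples <- p$samples
  if (is.null(samples)) samples <- list(list(id = "s1", class = "control"))
  over <- p[setdiff(names(p), "samples")]
  rows <- list(); files <- character()
  for (i in seq_along(samples)) {
    sm <- samples[[i]]
    spec <- do.call(tissueClassSpec,
                    c(list(class = sm$class, seed = seed + i), over))
    ph <- generateTissuePhantom(spec)
    ap <- file.path(dir, paste0(sm$id, "_axon.tiff"))
    vp <- file.path(dir, paste0(sm$id, "_vessel.tiff"))
    writeMaskTIFF(ph$axon, ap)
    writeMaskTIFF(ph$vessel, vp)
    tp <- file.path(dir, paste0(sm$id, "_truth.csv"))
    utils::write.csv(ph$truth, tp, row.names = FALSE)
    rows[[i]] <- data.frame(sample_id = sm$id, class = sm$class,
                            axon_path = ap, vessel_path = vp,
                            stringsAsFactors = FALSE)
    files <- c(files, ap, vp, paste0(ap, ".json"), paste0(vp, ".json"), tp)
  }
  mf <- file.path(dir, "samples.csv")
  utils::write.csv(do.call(rbind, rows), mf, row.names = FALSE)
  list(files = c(files, mf))
}

stageSimulateOrgan <- function(dir, p, seed) {
  org <- do.call(generateOrganVolume, c(p, list(seed = seed)))
  files <- character()
  for (nm in c("nerve", "organ", "tumor")) {
    fp <- file.path(dir, paste0(nm, ".tiff"))
    writeMaskTIFF(org[[nm]], fp)
    files <- c(files, fp, paste0(fp, ".json"))
  }
  tp <- file.path(dir, "truth.json")
  jsonlite::write_json(org$truth, tp, auto_unbox = TRUE, digits = NA)
  list(files = c(files, tp))
}

stageSimulateGrowth <- function(dir, p, seed) {
  spec <- do.call(growthCohortSpec, c(p, list(seed = seed)))
  cohort <- generateGrowthCohort(spec)
  cp <- file.path(dir, "cohort.csv")
  mp <- file.path(dir, "truth_mouse.csv")
  gp <- file.path(dir, "truth_group.csv")
  utils::write.csv(cohort$data, cp, row.names = FALSE)
  utils::write.csv(cohort$truth$mouse, mp, row.names = FALSE)
  utils::write.csv(cohort$truth$group, gp, row.names = FALSE)
  list(files = c(cp, mp, gp))
}

stageSimulateSurvival <- function(dir, p, seed) {
  spec <- do.call(survivalCohortSpec, c(p, list(seed = seed)))
  cohort <- generateSurvivalCohort(spec)
  cp <- file.path(dir, "survival.csv")
  utils::write.csv(cohort$data, cp, row.names = FALSE)
  list(files = cp)
}

stageMorphometry <- function(dir, p, outRoot) {
  input <- p$input %||% "tissue"
  mf <- file.path(outRoot, input, "samples.csv")
  if (!file.exists(mf)) stop("morphometry input not found: ", mf)
  manifest <- utils::read.csv(mf, stringsAsFactors = FALSE)
  prof <- batchMorphometry(manifest, d = p$d %||% 2)
  pp <- file.path(dir, "profiles.csv")
  utils::write.csv(prof, pp, row.names = FALSE)
  list(files = pp)
}

stageStaging <- function(dir, p, outRoot) {
  input <- p$input %||% "morphometry"
  pf <- file.path(outRoot, input, "profiles.csv")
  if (!file.exists(pf)) stop("staging input not found: ", pf)
  prof <- utils::read.csv(pf, stringsAsFactors = FALSE)
  z <- zscoreMatrix(prof, controlClass = p$controlClass %||% "control")
  pc <- pcaEmbed(prof)
  hc <- hierarchicalCluster(prof, k = p$k %||% 3,
                            referenceLabels = prof$class)
  zp <- file.path(dir, "zmatrix.csv")
  sp <- file.path(dir, "scores.csv")
  lp <- file.path(dir, "labels.csv")
  dp <- file.path(dir, "dendrogram.json")
  utils::write.csv(as.data.frame(z), zp)
  utils::write.csv(as.data.frame(pc$scores), sp)
  utils::write.csv(data.frame(sample_id = prof$sample_id,
                              class = prof$class, cluster = hc$labels),
                   lp, row.names = FALSE)
  jsonlite::write_json(list(merge = hc$tree$merge, height = hc$tree$height,
                            order = hc$tree$order,
                            labels = prof$sample_id),
                       dp, digits = NA)
  list(files = c(zp, sp, lp, dp), info = list(ari = hc$ari))
}

stageGrowthFit <- function(dir, p, outRoot, seed) {
  input <- p$input %||% "growth"
  cf <- file.path(outRoot, input, "cohort.csv")
  if (!file.exists(cf)) stop("growth_fit input not found: ", cf)
  cohort <- utils::read.csv(cf, stringsAsFactors = FALSE)
  fit <- fitGompertzHierarchy(cohort, chains = p$chains %||% 4,
                              warmup = p$warmup %||% 1000,
                              draws = p$draws %||% 1000, seed = seed,
                              onBadFit = p$onBadFit %||% "error")
  dm <- drawMatrix(fit)
  long <- data.frame(
    chain = rep(seq_along(fit@draws),
                each = nrow(fit@draws[[1]]) * ncol(dm)),
    iter = rep(rep(seq_len(nrow(fit@draws[[1]])), each = ncol(dm)),
               times = length(fit@draws)),
    parameter = rep(colnames(dm), times = nrow(dm)),
    value = as.numeric(t(dm)))
  dp <- file.path(dir, "draws.csv")
  utils::write.csv(long, dp, row.names = FALSE)
  summary <- list(
    medians = as.list(apply(dm, 2, stats::median)),
    rhat_max = max(fit@diagnostics$rhat),
    ess_min = min(fit@diagnostics$ess),
    p_logb = if (length(fit@groups) == 2)
      groupDifferenceProbability(fit, "log_b") else NA,
    p_a = if (length(fit@groups) == 2)
      groupDifferenceProbability(fit, "a") else NA)
  sp <- file.path(dir, "summary.json")
  jsonlite::write_json(summary, sp, auto_unbox = TRUE, digits = NA)
  list(files = c(dp, sp))
}

stageSurvival <- function(dir, p, outRoot) {
  input <- p$input %||% "survival_sim"
  cf <- file.path(outRoot, input, "survival.csv")
  if (!file.exists(cf)) stop("survival_analysis input not found: ", cf)
  dat <- utils::read.csv(cf, stringsAsFactors = FALSE)
  files <- character(); info <- list()
  groups <- unique(dat$group)
  kmTabs <- lapply(groups, function(g) {
    km <- kmEstimate(dat$time[dat$group == g], dat$event[dat$group == g])
    cbind(group = g, km$table)
  })
  kp <- file.path(dir, "km.csv")
  utils::write.csv(do.call(rbind, kmTabs), kp, row.names = FALSE)
  files <- c(files, kp)
  summary <- list()
  if (length(groups) == 2) {
    A <- dat[dat$group == groups[1], ]; B <- dat[dat$group == groups[2], ]
    lr <- logrankHazardRatio(A$time, A$event, B$time, B$event)
    summary$logrank <- list(chisq = lr$chisq, p = lr$p,
                            hrBA = lr$hrBA, hrAB = lr$hrAB)
  }
  if (isTRUE(p$cutpoint) && "marker" %in% names(dat)) {
    cutp <- suppressWarnings(
      survivalCutpoint(dat$time, dat$event, dat$marker))
    summary$cutpoint <- cutp[c("threshold", "statistic", "nLow", "nHigh")]
  }
  sp <- file.path(dir, "summary.json")
  jsonlite::write_json(summary, sp, auto_unbox = TRUE, digits = NA)
  list(files = c(files, sp))
}
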