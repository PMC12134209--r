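# Condition presets: named mixtures of nuclear patterns (and optionally
# cell-cycle stages) from which whole populations of synthetic nuclei are
# drawn. The packaged presets encode the printed condition proportions the
# pipeline is expected to recover.

#' Condition preset for population simulation
#'
#' @param name preset name.
#' @param pattern_mixture named probabilities over
#'   `c("Enriched", "Even", "Excluded")`; must sum to 1.
#' @param fold_ranges named list of length-2 fold intervals per pattern.
#'   Consistency with the classifier band (half-width `delta` around 1) is
#'   enforced: the Enriched range lies strictly above `1 + delta`, Excluded
#'   strictly below `1 - delta`, Even inside the band.
#' @param stage_mixture optional named probabilities over cell-cycle stages
#'   (`scheme` decides the stage vocabulary).
#' @param scheme "none", "markers" or "fucci" (see [simulation_config()]).
#' @param clover_fold optional Clover enrichment fold; when given, a CLOVER
#'   channel is rendered with this fold at chromocenters.
#' @param delta classifier band half-width used for the consistency check.
#' @param config_overrides named list of [simulation_config()] arguments
#'   overriding its defaults for every nucleus of the population (the
#'   packaged presets use a 2x-binned voxel size to keep 300-nucleus runs
#'   fast).
#' @return a `condition_preset` object.
#' @export
condition_preset <- function(name, pattern_mixture,
                             fold_ranges = list(Enriched = c(1.4, 2.5),
                                                Even = c(0.95, 1.1),
                                                Excluded = c(0.6, 0.78)),
                             stage_mixture = NULL,
                             scheme = c("none", "markers", "fucci"),
                             clover_fold = NULL,
                             delta = 0.2,
                             config_overrides = list()) {
  scheme <- match.arg(scheme)
  stopifnot(is.numeric(pattern_mixture),
            all(names(pattern_mixture) %in% PATTERN_LABELS),
            all(pattern_mixture >= 0))
  if (abs(sum(pattern_mixture) - 1) > 1e-9) {
    chr_stop("chromofied_config_error", "pattern_mixture must sum to 1")
  }
  if (!is.null(stage_mixture)) {
    if (abs(sum(stage_mixture) - 1) > 1e-9) {
      chr_stop("chromofied_config_error", "stage_mixture must sum to 1")
    }
  }
  for (lab in names(pattern_mixture)[pattern_mixture > 0]) {
    rng <- fold_ranges[[lab]]
    if (is.null(rng)) {
      chr_stop("chromofied_config_error",
               paste0("no fold range for pattern ", lab))
    }
    ok <- switch(lab,
                 Enriched = rng[1L] > 1 + delta,
                 Excluded = rng[2L] < 1 - delta,
                 Even = rng[1L] > 1 - delta && rng[2L] < 1 + delta)
    if (!ok) {
      chr_stop("chromofied_config_error",
               paste0("fold range for ", lab,
                      " is inconsistent with the classifier band"))
    }
  }
  structure(list(name = name, pattern_mixture = pattern_mixture,
                 fold_ranges = fold_ranges, stage_mixture = stage_mixture,
                 scheme = scheme, clover_fold = clover_fold, delta = delta,
                 config_overrides = config_overrides),
            class = "condition_preset")
}

#' @export
print.condition_preset <- function(x, ...) {
  cat(sprintf("<condition_preset> %s (scheme %s)\n", x$name, x$scheme))
  cat("  patterns:", paste(sprintf("%s %.0f%%", names(x$pattern_mixture),
                                   100 * x$pattern_mixture), collapse = ", "),
      "\n")
  if (!is.null(x$stage_mixture)) {
    cat("  stages:  ", paste(sprintf("%s %.0f%%", names(x$stage_mixture),
                                     100 * x$stage_mixture), collapse = ", "),
        "\n")
  }
  invisible(x)
}

# desk-scale acquisition: 2x-binned voxel relative to the 0.172/0.08 um
# confocal default, so a 300-nucleus population stays within minutes of CPU
desk_overrides <- function() {
  list(voxel_size = c(0.344, 0.16, 0.16))
}

#' Packaged condition presets
#'
#' Presets encoding the printed condition proportions of the study the
#' pipeline is benchmarked against:
#' \describe{
#'   \item{ESC_H3.1_endogenous}{mouse ESCs, endogenous H3.1/2: 70% Enriched,
#'     30% Even.}
#'   \item{H3.3_endogenous}{endogenous H3.3 (all cell lines): 75% Even,
#'     25% Excluded.}
#'   \item{differentiated_H3.1}{NPC/3T3, endogenous H3.1/2: 85% Enriched,
#'     15% Even.}
#'   \item{HIRA_wt}{ESCs expressing TALE-HIRA-wt (Clover-positive): 43%
#'     Enriched, 57% Even; a CLOVER channel is rendered above the 1.2 gate.}
#'   \item{FUCCI_G2 / FUCCI_earlyG1}{FUCCI ESCs staged G2 (95% Enriched) or
#'     early G1 (5% Enriched).}
#'   \item{diff_stage_G1 / EarlyS / MidS / LateS / G2}{differentiated cells
#'     per marker-scheme stage: 95% Enriched in G1, 50% in early S, 85% in
#'     mid-S, late-S and G2.}
#' }
#' @return named list of [condition_preset()] objects.
#' @export
chromofied_presets <- function() {
  ov <- desk_overrides()
  stage1 <- function(stage) setNames(1, stage)
  list(
    ESC_H3.1_endogenous = condition_preset(
      "ESC_H3.1_endogenous", c(Enriched = 0.70, Even = 0.30, Excluded = 0),
      config_overrides = ov),
    H3.3_endogenous = condition_preset(
      "H3.3_endogenous", c(Enriched = 0, Even = 0.75, Excluded = 0.25),
      config_overrides = ov),
    differentiated_H3.1 = condition_preset(
      "differentiated_H3.1", c(Enriched = 0.85, Even = 0.15, Excluded = 0),
      config_overrides = ov),
    HIRA_wt = condition_preset(
      "HIRA_wt", c(Enriched = 0.43, Even = 0.57, Excluded = 0),
      clover_fold = 2, config_overrides = ov),
    FUCCI_G2 = condition_preset(
      "FUCCI_G2", c(Enriched = 0.95, Even = 0.05, Excluded = 0),
      stage_mixture = stage1("G2"), scheme = "fucci", config_overrides = ov),
    FUCCI_earlyG1 = condition_preset(
      "FUCCI_earlyG1", c(Enriched = 0.05, Even = 0.95, Excluded = 0),
      stage_mixture = stage1("EarlyG1"), scheme = "fucci",
      config_overrides = ov),
    diff_stage_G1 = condition_preset(
      "diff_stage_G1", c(Enriched = 0.95, Even = 0.05, Excluded = 0),
      stage_mixture = stage1("G1"), scheme = "markers",
      config_overrides = ov),
    diff_stage_EarlyS = condition_preset(
      "diff_stage_EarlyS", c(Enriched = 0.50, Even = 0.50, Excluded = 0),
      stage_mixture = stage1("EarlyS"), scheme = "markers",
      config_overrides = ov),
    diff_stage_MidS = condition_preset(
      "diff_stage_MidS", c(Enriched = 0.85, Even = 0.15, Excluded = 0),
      stage_mixture = stage1("MidS"), scheme = "markers",
      config_overrides = ov),
    diff_stage_LateS = condition_preset(
      "diff_stage_LateS", c(Enriched = 0.85, Even = 0.15, Excluded = 0),
      stage_mixture = stage1("LateS"), scheme = "markers",
      config_overrides = ov),
    diff_stage_G2 = condition_preset(
      "diff_stage_G2", c(Enriched = 0.85, Even = 0.15, Excluded = 0),
      stage_mixture = stage1("G2"), scheme = "markers",
      config_overrides = ov)
  )
}

#' Generate a population of synthetic nuclei from a preset
#'
#' Pattern labels are drawn first (a single `sample()` call, so an
#' independent multinomial draw under the same seed reproduces them), then
#' stages, per-nucleus folds within the label's fold range, and per-nucleus
#' generator seeds.
#'
#' @param preset a [condition_preset()].
#' @param n number of nuclei (>= 0).
#' @param seed integer seed for the whole population.
#' @return list of `n` elements, each a [generate_nucleus()] result whose
#'   `truth$pattern` holds the drawn label.
#' @export
generate_population <- function(preset, n, seed = 1L) {
  stopifnot(inherits(preset, "condition_preset"), n >= 0)
  if (n == 0L) return(list())
  withr::with_seed(seed, {
    labels <- sample(names(preset$pattern_mixture), n, replace = TRUE,
                     prob = preset$pattern_mixture)
    stages <- if (!is.null(preset$stage_mixture)) {
      sample(names(preset$stage_mixture), n, replace = TRUE,
             prob = preset$stage_mixture)
    } else rep(NA_character_, n)
    folds <- vapply(labels, function(lab) {
      rng <- preset$fold_ranges[[lab]]
      runif(1L, rng[1L], rng[2L])
    }, numeric(1L))
    seeds <- sample.int(2147483646L, n)
  })
  out <- vector("list", n)
  for (i in seq_len(n)) {
    cf <- c(SIGNAL = unname(folds[i]))
    if (!is.null(preset$clover_fold)) {
      cf <- c(cf, CLOVER = unname(preset$clover_fold))
    }
    args <- modifyList(
      list(channel_folds = cf,
           stage = if (is.na(stages[i])) NULL else stages[i],
           scheme = preset$scheme, seed = seeds[i]),
      preset$config_overrides)
    cfg <- do.call(simulation_config, args)
    res <- generate_nucleus(cfg)
    res$truth$pattern <- labels[i]
    out[[i]] <- res
  }
  out
}
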