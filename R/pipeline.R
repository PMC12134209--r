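# End-to-end orchestration: segmentation -> enrichment -> pattern and
# cell-cycle calls -> proportion tables, with per-stage counts logged and
# every exclusion accounted for.

#' Default analysis parameters
#'
#' All tunable thresholds of the imaging pipeline in one list: `delta` and
#' `k_min` (pattern rule), `gate_threshold` (Clover positivity), `k`
#' (chromocenter threshold stringency), `smooth_sigma`,
#' `min_nucleus_volume`, `min_domain_volume` (segmentation),
#' `theta_ring` / `theta_n` / `theta_per` / `ring_um` / `rim_um` (EdU
#' sub-staging), `fucci_thresholds`, `marker_k_sd`.
#' @return named list of defaults.
#' @export
default_params <- function() {
  list(delta = 0.2, k_min = 3L, gate_threshold = 1.2, k = 2,
       smooth_sigma = 0.3, min_nucleus_volume = 50, min_domain_volume = 0.15,
       theta_ring = 0.5, theta_n = 10L, theta_per = 0.5, ring_um = 0.5,
       rim_um = 1, marker_k_sd = 3,
       fucci_thresholds = list(hcdt1 = c(60, 200), geminin = c(60, 200)))
}

#' Analyze one image stack end to end
#'
#' Segments nuclei and chromocenters, computes SIGNAL enrichment, classifies
#' the pattern, gates on Clover when present, and stages the cell cycle when
#' marker (EdU/Aurora-B) or FUCCI (hCdt1/Geminin) channels are present.
#'
#' @param stack an [image_stack()].
#' @param params parameter list, see [default_params()].
#' @param stack_id identifier copied into the output rows.
#' @return data.frame with one row per segmented nucleus: ids, n_domains,
#'   ratio_global, pattern label and callability, Clover ratio/gate, stage,
#'   and the staging scheme.
#' @export
analyze_stack <- function(stack, params = default_params(), stack_id = 1L) {
  p <- modifyList(default_params(), params)
  nuclei <- segment_nuclei(stack, smooth_sigma = p$smooth_sigma,
                           min_nucleus_volume = p$min_nucleus_volume)
  rows <- list()
  for (nuc in nuclei) {
    domains <- segment_chromocenters(stack, nuc, k = p$k,
                                     min_domain_volume = p$min_domain_volume)
    enr <- compute_enrichment(stack, "SIGNAL", nuc, domains)
    call <- classify_pattern(enr, delta = p$delta, k_min = p$k_min)
    clover_ratio <- NA_real_
    tale_positive <- NA
    if (has_channel(stack, "CLOVER")) {
      gate <- gate_tale(compute_enrichment(stack, "CLOVER", nuc, domains),
                        threshold = p$gate_threshold)
      clover_ratio <- gate$clover_ratio
      tale_positive <- gate$positive
    }
    stage <- NA_character_
    scheme <- "none"
    if (has_channel(stack, "EDU") && has_channel(stack, "AURORAB")) {
      scheme <- "markers"
      edu_pos <- marker_positive(stack, "EDU", nuc, nuclei, p$marker_k_sd)
      aur_pos <- marker_positive(stack, "AURORAB", nuc, nuclei, p$marker_k_sd)
      pat <- if (edu_pos) {
        classify_edu_pattern(stack, nuc, domains, theta_ring = p$theta_ring,
                             theta_n = p$theta_n, theta_per = p$theta_per,
                             ring_um = p$ring_um, rim_um = p$rim_um)
      } else NULL
      stage <- stage_by_markers(edu_pos, aur_pos, pat, nuc$nucleus_id)$stage
    } else if (has_channel(stack, "HCDT1") && has_channel(stack, "GEMININ")) {
      scheme <- "fucci"
      sc <- stage_fucci(nuclear_mean_intensity(stack, "HCDT1", nuc),
                        nuclear_mean_intensity(stack, "GEMININ", nuc),
                        thresholds = p$fucci_thresholds, nuc$nucleus_id)
      stage <- sc$stage
    }
    rows[[length(rows) + 1L]] <- data.frame(
      stack_id = stack_id, nucleus_id = nuc$nucleus_id,
      volume = nuc$volume, n_domains = domains$n_domains,
      ratio_global = enr$ratio_global,
      label = if (call$callable) call$label else NA_character_,
      callable = call$callable, clover_ratio = clover_ratio,
      tale_positive = tale_positive, stage = stage, scheme = scheme)
  }
  if (length(rows) == 0L) {
    return(data.frame(stack_id = integer(), nucleus_id = integer(),
                      volume = numeric(), n_domains = integer(),
                      ratio_global = numeric(), label = character(),
                      callable = logical(), clover_ratio = numeric(),
                      tale_positive = logical(), stage = character(),
                      scheme = character()))
  }
  do.call(rbind, rows)
}

#' Analyze a list of stacks (e.g. a generated population)
#'
#' @param stacks list of [image_stack()] objects, or a population from
#'   [generate_population()] (whose `truth$pattern` is then carried along as
#'   `true_label`).
#' @param params parameter list, see [default_params()].
#' @return data.frame of per-nucleus rows (see [analyze_stack()]), plus
#'   `true_label`/`true_stage` columns when ground truth is available.
#' @export
analyze_stacks <- function(stacks, params = default_params()) {
  out <- vector("list", length(stacks))
  for (i in seq_along(stacks)) {
    el <- stacks[[i]]
    truth <- NULL
    stk <- el
    if (is.list(el) && !inherits(el, "image_stack") && !is.null(el$stack)) {
      stk <- el$stack
      truth <- el$truth
    }
    df <- analyze_stack(stk, params, stack_id = i)
    if (!is.null(truth) && nrow(df) > 0L) {
      df$true_label <- truth$pattern
      df$true_stage <- if (is.null(truth$stage)) NA_character_
                       else truth$stage
    }
    out[[i]] <- df
  }
  out <- out[vapply(out, nrow, 1L) > 0L]
  if (length(out) == 0L) return(analyze_stack(NULL)[0, ])
  do.call(rbind, out)
}

#' Run the imaging pipeline from a run configuration
#'
#' @param config list (see [read_run_config()]) with entries: either
#'   `preset` + `n` (simulate a population) or `input_dir` (directory of
#'   stacks written by [write_image_stack()]); `seed`; optional parameter
#'   overrides matching [default_params()]; optional `out_dir`.
#' @return result bundle: `nuclei` (per-nucleus table), `proportions`
#'   (from [aggregate_proportions()] over callable, TALE-gated nuclei),
#'   `log` (per-stage counts: stacks, nuclei found, uncallable, gated out),
#'   and the echoed `config`. When `out_dir` is set, `nuclei.tsv`,
#'   `proportions.tsv` and `config.txt` are written there.
#' @export
run_imaging_pipeline <- function(config) {
  params <- modifyList(default_params(),
                       config[intersect(names(config),
                                        names(default_params()))])
  if (!is.null(config$preset)) {
    presets <- chromofied_presets()
    if (!config$preset %in% names(presets)) {
      chr_stop("chromofied_config_error",
               paste0("unknown preset: ", config$preset))
    }
    preset <- presets[[config$preset]]
    if (!is.null(preset$clover_fold) || isTRUE(config$gate)) {
      # gating needs a Clover channel; presets with clover_fold render one
      if (is.null(preset$clover_fold) && isTRUE(config$gate)) {
        chr_stop("chromofied_config_error",
                 "gating requested but the preset renders no CLOVER channel")
      }
    }
    pop <- generate_population(preset, config$n %||% 100L,
                               seed = config$seed %||% 1L)
    stacks <- pop
  } else if (!is.null(config$input_dir)) {
    paths <- list.files(config$input_dir, pattern = "\\.tiff?$",
                        full.names = TRUE)
    paths <- paths[!grepl("\\.labels\\.tiff?$", paths)]
    if (length(paths) == 0L) {
      chr_stop("chromofied_data_error",
               paste0("no TIFF stacks under ", config$input_dir))
    }
    stacks <- lapply(paths, read_image_stack)
    if (isTRUE(config$gate) &&
        !all(vapply(stacks, has_channel, TRUE, role = "CLOVER"))) {
      chr_stop("chromofied_config_error",
               "gating requested but stacks lack a CLOVER channel")
    }
  } else {
    chr_stop("chromofied_config_error",
             "config needs either `preset` or `input_dir`")
  }
  nuclei <- analyze_stacks(stacks, params)
  gated <- nuclei
  n_gated_out <- 0L
  if ("tale_positive" %in% names(nuclei) && any(!is.na(nuclei$tale_positive))) {
    keep <- is.na(nuclei$tale_positive) | nuclei$tale_positive
    n_gated_out <- sum(!keep)
    gated <- nuclei[keep, ]
  }
  callable <- gated[gated$callable, ]
  calls <- lapply(seq_len(nrow(callable)), function(i) {
    structure(list(nucleus_id = callable$nucleus_id[i],
                   label = callable$label[i], callable = TRUE),
              class = "pattern_call")
  })
  props <- aggregate_proportions(calls)
  log <- list(n_stacks = length(stacks), n_nuclei = nrow(nuclei),
              n_uncallable = sum(!nuclei$callable),
              n_gated_out = n_gated_out)
  bundle <- list(nuclei = nuclei, proportions = props, log = log,
                 config = config)
  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
    write.table(nuclei, file.path(config$out_dir, "nuclei.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    write.table(props$replicates,
                file.path(config$out_dir, "proportions.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    write_run_config(c(config, params[setdiff(names(params),
                                              names(config))]),
                     file.path(config$out_dir, "config.txt"))
  }
  bundle
}

#' Run the repeat pipeline from a run configuration
#'
#' @param config list with `annotation` (BED path or [repeat_annotation()]),
#'   `ip` / `input` (fragment BED paths or [fragment_set()]s),
#'   `exclude_classes` (default trf/dust), `class` (summary class, default
#'   GSAT_MM), `pseudocount`, optional `out_dir`.
#' @return bundle with `counts`, `enrichment`, `summary`, `log`, `config`.
#' @export
run_repeat_pipeline <- function(config) {
  if (is.null(config$annotation) || is.null(config$ip) ||
      is.null(config$input)) {
    chr_stop("chromofied_config_error",
             "repeat config needs `annotation`, `ip` and `input`")
  }
  ann <- if (inherits(config$annotation, "repeat_annotation")) {
    config$annotation
  } else read_repeat_bed(config$annotation)
  ip <- if (inherits(config$ip, "fragment_set")) config$ip
        else read_fragment_bed(config$ip, "IP")
  inp <- if (inherits(config$input, "fragment_set")) config$input
         else read_fragment_bed(config$input, "input")
  excl <- config$exclude_classes %||% c("trf", "dust")
  ann_f <- filter_repeat_classes(ann, excl)
  counts <- repeat_count_matrix(
    list(IP = count_fragment_overlaps(ip, ann_f),
         input = count_fragment_overlaps(inp, ann_f)),
    roles = c(IP = "IP", input = "input"), pairing = c(IP = "input"))
  enr <- normalize_zscore(counts, ann_f,
                          pseudocount = config$pseudocount %||% 0)
  cls <- config$class %||% "GSAT_MM"
  summ <- summarize_repeat_class(enr, ann_f, cls)
  log <- list(n_repeats_total = nrow(ann), n_repeats_kept = nrow(ann_f),
              n_filtered = nrow(ann) - nrow(ann_f),
              n_ip_fragments = nrow(ip$fragments),
              n_input_fragments = nrow(inp$fragments))
  bundle <- list(counts = counts, enrichment = enr, summary = summ,
                 log = log, config = config)
  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
    for (st in names(enr$stages)) {
      write.table(data.frame(repeat_id = enr$repeat_id, enr$stages[[st]],
                             check.names = FALSE),
                  file.path(config$out_dir, paste0(st, ".tsv")), sep = "\t",
                  quote = FALSE, row.names = FALSE)
    }
    write.table(summ, file.path(config$out_dir, "class_summary.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
  }
  bundle
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Read / write a flat key-value run configuration
#'
#' Format: `key = value` lines, `[section]` headers ignored as grouping
#' sugar, `#` comments. Values are parsed as numbers when they look
#' numeric, as logicals for true/false, else kept as strings.
#'
#' @param path file path.
#' @param config named list (for writing; nested lists are flattened with
#'   `.`-joined keys).
#' @return `read_run_config` returns a named list.
#' @export
read_run_config <- function(path) {
  lines <- readLines(path)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !grepl("^\\[", lines)]
  out <- list()
  for (ln in lines) {
    kv <- strsplit(ln, "=", fixed = TRUE)[[1L]]
    if (length(kv) < 2L) {
      chr_stop("chromofied_config_error",
               paste0("malformed config line: ", ln))
    }
    key <- trimws(kv[1L])
    val <- trimws(paste(kv[-1L], collapse = "="))
    num <- suppressWarnings(as.numeric(val))
    out[[key]] <- if (!is.na(num)) num
                  else if (tolower(val) %in% c("true", "false")) {
                    tolower(val) == "true"
                  } else val
  }
  out
}

#' @rdname read_run_config
#' @export
write_run_config <- function(config, path) {
  flat <- unlist(config)
  writeLines(c("[run]", paste(names(flat), "=", as.character(flat))), path)
  invisible(path)
}
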