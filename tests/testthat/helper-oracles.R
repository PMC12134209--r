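# Independent brute-force oracles and small fixture builders. These
# deliberately re-derive every quantity from first principles (explicit
# loops over voxels / interval pairs) and never call the package's own
# computation path for the value they check.

# small, fast simulation config for unit tests (nucleus ~75 um^3)
tiny_config <- function(...) {
  args <- modifyList(list(nucleus_radii = c(2, 3, 3),
                          voxel_size = c(0.4, 0.25, 0.25),
                          n_chromocenters = c(5L, 8L),
                          chromocenter_radius = c(0.55, 0.05)),
                     list(...))
  do.call(simulation_config, args)
}

noiseless <- list(poisson = FALSE, gaussian_sd = 0)

# 3D-FIED by exhaustive voxel listing: collect the intensity of every voxel
# of every mask into plain vectors, then average.
fied_oracle <- function(x, nucleus_mask, domain_labels) {
  stopifnot(identical(dim(x), dim(nucleus_mask)))
  outside_vals <- c()
  domain_vals <- list()
  all_domain_vals <- c()
  d <- dim(x)
  for (k in seq_len(d[3L])) for (j in seq_len(d[2L])) for (i in seq_len(d[1L])) {
    lab <- domain_labels[i, j, k]
    if (lab > 0L) {
      domain_vals[[as.character(lab)]] <-
        c(domain_vals[[as.character(lab)]], x[i, j, k])
      all_domain_vals <- c(all_domain_vals, x[i, j, k])
    } else if (nucleus_mask[i, j, k]) {
      outside_vals <- c(outside_vals, x[i, j, k])
    }
  }
  mean_out <- mean(outside_vals)
  ids <- sort(as.integer(names(domain_vals)))
  list(ratio_global = mean(all_domain_vals) / mean_out,
       per_domain = vapply(as.character(ids),
                           function(id) mean(domain_vals[[id]]) / mean_out,
                           numeric(1L)),
       ids = ids)
}

# all-pairs interval intersection on 0-based half-open coordinates
overlap_oracle <- function(frag_df, ann_df) {
  counts <- setNames(integer(nrow(ann_df)), ann_df$repeat_id)
  for (i in seq_len(nrow(frag_df))) {
    for (j in seq_len(nrow(ann_df))) {
      if (frag_df$chrom[i] == ann_df$chrom[j] &&
          max(frag_df$start[i], ann_df$start[j]) <
            min(frag_df$end[i], ann_df$end[j])) {
        counts[j] <- counts[j] + 1L
      }
    }
  }
  counts
}

# direct enumeration of the pattern rule on a ratio tuple
pattern_rule_oracle <- function(ratios, delta = 0.2, k_min = 3L) {
  above <- 0L
  below <- 0L
  for (r in ratios) {
    if (r > 1 + delta) above <- above + 1L
    if (r < 1 - delta) below <- below + 1L
  }
  if (above >= k_min) "Enriched" else if (below >= k_min) "Excluded" else "Even"
}

# 3-repeat worked normalization fixture with values frozen from an
# independent spreadsheet-style calculation (performed before the
# implementation was written against it)
norm_fixture <- function() {
  ann <- repeat_annotation(data.frame(
    chrom = "chr1", start = c(0L, 1000L, 2000L),
    end = c(100L, 1200L, 2400L),
    repeat_id = c("r1", "r2", "r3"),
    class_label = c("GSAT_MM", "L1", "L1")))
  counts <- repeat_count_matrix(
    list(IP = setNames(c(30L, 40L, 30L), ann$repeat_id),
         input = setNames(c(10L, 40L, 50L), ann$repeat_id)),
    roles = c(IP = "IP", input = "input"), pairing = c(IP = "input"))
  expected <- list(
    cpm_input = c(1e5, 4e5, 5e5),
    cpm_ip = c(3e5, 4e5, 3e5),
    perbp_input = c(1000, 2000, 1250),
    perbp_ip = c(3000, 2000, 750),
    ratio = c(3, 1, 0.6),
    log2 = c(1.584962500721156, 0, -0.736965594166206),
    zscore = c(1.097603067348950, -0.238236516472549, -0.859366550876401))
  list(ann = ann, counts = counts, expected = expected)
}
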