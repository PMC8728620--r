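# End-to-end orchestration: generate -> tier 1 (melt) -> tier 2 (ddPCR + CNV
# qPCR) -> tier 3 (LC-WGS) -> screening report, with per-stage seeds and
# on-disk artifacts.

#' Build a validated screening run configuration
#'
#' @param n cohort size
#' @param class_mix named class counts (`exact = TRUE`) or prevalences
#' @param exact exact class counts instead of multinomial assignment
#' @param profile noise profile name or object (see [noise_profile()])
#' @param threshold_mode primary referral mode, `"sd_rule"` or `"conservative"`
#' @param k SD multiplier for the sd_rule normal range
#' @param measurement `"melt"` runs the full melt-curve simulation and
#'   quantifier; `"ratio"` feeds the drawn ratios to tier 1 directly
#' @param storage_years archival storage of the cohort (years)
#' @param cinq_controls number of storage-matched ddPCR control wells
#' @param cinq_guard guard band added to the ddPCR control min/max range
#' @param total_droplets droplets per ddPCR well
#' @param tier2_template_sd biological scatter of the tier-2 template fraction
#' @param cnv_ct_sd,cnv_ct_sd_well total and independent per-well Ct SD
#' @param coverage LC-WGS mean reads per bin at 2 copies
#' @param reflex `"extremes"` reflexes the lowest and highest CNV-ratio
#'   outliers (outside the 2-copy range) to LC-WGS; `"all_outliers"` reflexes
#'   every non-2-copy call
#' @param seed master seed; every stochastic stage receives a derived sub-seed
#' @param outdir optional output directory for on-disk artifacts
#' @return validated config list (class `"screen_config"`)
#' @export
screen_config <- function(n = 16579,
                          class_mix = c(AS_deletion = 2, PWS_deletion = 1,
                                        PWS_UPD_or_ID = 1, Dup15q_idic15 = 1),
                          exact = TRUE,
                          profile = "calibrated",
                          threshold_mode = c("sd_rule", "conservative"),
                          k = 3,
                          measurement = c("melt", "ratio"),
                          storage_years = 5,
                          cinq_controls = 20,
                          cinq_guard = 0.05,
                          total_droplets = 20000,
                          tier2_template_sd = 0.005,
                          cnv_ct_sd = 0.15,
                          cnv_ct_sd_well = 0.035,
                          coverage = 100,
                          reflex = c("extremes", "all_outliers"),
                          seed = 1,
                          outdir = NULL) {
  threshold_mode <- match.arg(threshold_mode)
  measurement <- match.arg(measurement)
  reflex <- match.arg(reflex)
  if (is.character(profile)) profile <- noise_profile(profile)
  stopifnot(inherits(profile, "noise_profile"), n >= 1, k > 0,
            cinq_controls >= 1, cinq_guard >= 0, total_droplets >= 100,
            cnv_ct_sd_well <= cnv_ct_sd, coverage > 0)
  structure(
    list(n = n, class_mix = class_mix, exact = exact, profile = profile,
         threshold_mode = threshold_mode, k = k, measurement = measurement,
         storage_years = storage_years, cinq_controls = cinq_controls,
         cinq_guard = cinq_guard, total_droplets = total_droplets,
         tier2_template_sd = tier2_template_sd,
         cnv_ct_sd = cnv_ct_sd, cnv_ct_sd_well = cnv_ct_sd_well,
         coverage = coverage, reflex = reflex, seed = seed, outdir = outdir),
    class = "screen_config"
  )
}

# Reference calibration standards for the melt quantifier (noise-free spike
# series; the template fraction of a standard is its known mix).
.melt_reference_calibration <- function() {
  mixes <- c(0, 0.25, 0.5, 0.75, 1)
  fit_calibration(lapply(mixes, function(m) {
    simulate_melt(m, noise_sd = 0, role = "spike_standard", known_mix = m)
  }))
}

# Tier-1 measurement over plates: simulate each plate's control and sample
# melt curves (with a shared plate effect on the template scale), quantify and
# plate-correct. Returns a methylation_calls data.frame aligned to `cohort`.
.measure_tier1_melt <- function(cohort, templates, profile, calibration, seed) {
  plates <- split(seq_len(nrow(cohort)), cohort$plate_id)
  std_mix <- c(0, 0.5, 1)
  with_seed(seed, {
    res <- lapply(names(plates), function(pid) {
      idx <- plates[[pid]]
      delta <- stats::rnorm(1, sd = profile$plate_effect_sd)
      ctrl <- c(
        list(simulate_melt(clamp01(1 + delta), noise_sd = profile$melt_fluor_sd,
                           well_id = "CTRL_PWS", plate_id = pid, role = "pws_control")),
        lapply(seq_along(std_mix), function(i) {
          simulate_melt(clamp01(std_mix[i] + delta), noise_sd = profile$melt_fluor_sd,
                        well_id = sprintf("STD%d", i), plate_id = pid,
                        role = "spike_standard", known_mix = std_mix[i])
        })
      )
      smp <- lapply(seq_along(idx), function(j) {
        simulate_melt(clamp01(templates[idx[j]] + delta),
                      noise_sd = profile$melt_fluor_sd,
                      well_id = sprintf("W%03d", j), plate_id = pid,
                      sample_id = cohort$sample_id[idx[j]], role = "sample")
      })
      quantify_plate(c(ctrl, smp), calibration)
    })
    calls <- do.call(rbind, res)
    calls[match(cohort$sample_id, calls$sample_id), , drop = FALSE]
  })
}

# Tier-2 ddPCR on the referred samples against a storage-matched control range.
.tier2_cinq <- function(cohort, flagged_ids, cfg, seeds) {
  ctrl_templates <- with_seed(seeds[1], {
    clamp01(0.5 + cfg$profile$conversion_failure * 0.5 +
              stats::rnorm(cfg$cinq_controls, sd = cfg$tier2_template_sd))
  })
  ctrl_wells <- do.call(rbind, with_seed(seeds[2], {
    lapply(seq_along(ctrl_templates), function(i) {
      simulate_droplets(ctrl_templates[i], total_droplets = cfg$total_droplets,
                        sample_id = sprintf("CINQCTRL%02d", i))
    })
  }))
  ref <- cinq_reference_range(ctrl_wells, expand = cfg$cinq_guard,
                              min_wells = min(20, cfg$cinq_controls))
  idx <- match(flagged_ids, cohort$sample_id)
  eff <- cohort$effective_meth[idx]
  calls <- with_seed(seeds[3], {
    do.call(rbind, lapply(seq_along(idx), function(j) {
      tmpl <- clamp01(eff[j] + cfg$profile$conversion_failure * (1 - eff[j]) +
                        stats::rnorm(1, sd = cfg$tier2_template_sd))
      well <- simulate_droplets(tmpl, total_droplets = cfg$total_droplets,
                                sample_id = flagged_ids[j])
      call_cinq(well, ref)
    }))
  })
  if (is.null(calls)) {
    calls <- data.frame(sample_id = character(0), lambda_meth = numeric(0),
                        lambda_unmeth = numeric(0), ratio = numeric(0),
                        confirmed = logical(0), ref_low = numeric(0),
                        ref_high = numeric(0), qc_flags = character(0),
                        stringsAsFactors = FALSE)
  }
  list(calls = calls, reference_range = ref)
}

# Tier-2 CNV qPCR on the referred samples.
.tier2_cnv <- function(cohort, flagged_ids, cfg, seed) {
  curves <- default_cnv_curves()
  idx <- match(flagged_ids, cohort$sample_id)
  sub_seeds <- if (length(idx)) derive_seeds(seed, length(idx)) else integer(0)
  ratios <- vapply(seq_along(idx), function(j) {
    prof <- cn_profile_of(cohort$genotype[idx[j]])
    cn <- 2L
    if (!is.null(prof)) {
      hit <- prof$start <= 25200000 & prof$end > 25200000
      if (any(hit)) cn <- prof$copies[which(hit)[1]]
    }
    simulate_cnv_measurement(cn, curves = curves, ct_sd = cfg$cnv_ct_sd,
                             ct_sd_well = cfg$cnv_ct_sd_well,
                             seed = sub_seeds[j])$cnv_ratio
  }, numeric(1))
  classify_cnv(ratios, sample_id = flagged_ids)
}

# Tier-3 LC-WGS on the reflexed samples.
.tier3_lcwgs <- function(cohort, reflex_ids, bands, cfg, seed) {
  sub_seeds <- if (length(reflex_ids)) derive_seeds(seed, length(reflex_ids)) else integer(0)
  calls <- lapply(seq_along(reflex_ids), function(j) {
    idx <- match(reflex_ids[j], cohort$sample_id)
    track <- simulate_bins(cn_profile_of(cohort$genotype[idx]),
                           coverage = cfg$coverage, seed = sub_seeds[j])
    segs <- segment_and_call(track)
    band <- switch(bands[j], low_band = "low", high_band = "high", NA_character_)
    assign_breakpoints(segs, meth_band = band)
  })
  names(calls) <- reflex_ids
  calls
}

.condition_of <- function(band, copy_class) {
  ifelse(band == "low_band", "AS",
         ifelse(!is.na(copy_class) & copy_class >= 3, "Dup15q", "PWS"))
}

#' Run the full tiered screening workflow
#'
#' Generates a synthetic cohort, measures first-tier methylation (melt-curve
#' quantification with plate correction by default), flags samples outside the
#' normal range, confirms flags by droplet-digital-PCR methylation and CNV
#' qPCR, reflexes CNV outliers to LC-WGS subtype typing, and assembles the
#' screening report. Deterministic under the config seed. When
#' `config$outdir` is set, the sample sheet, per-tier call tables, segment BED
#' (+ HGVS sidecar), JSON report and a stage log are written there.
#'
#' @param config a [screen_config()]
#' @return object of class `"screen_report"`
#' @export
#' @examples
#' \donttest{
#' rep <- run_screen(screen_config(n = 2000, seed = 7))
#' print(rep)
#' }
run_screen <- function(config = screen_config()) {
  stopifnot(inherits(config, "screen_config"))
  seeds <- derive_seeds(config$seed, 8)
  log <- character(0)
  say <- function(fmt, ...) {
    log <<- c(log, sprintf(fmt, ...))
  }

  cohort <- make_cohort(config$n, config$class_mix, exact = config$exact,
                        storage_years = config$storage_years, seed = seeds[1])
  say("stage=generate n_in=0 n_out=%d", nrow(cohort))

  templates <- draw_measured_ratios(cohort, config$profile, seed = seeds[2])
  calls <- if (config$measurement == "melt") {
    calibration <- .melt_reference_calibration()
    .measure_tier1_melt(cohort, templates, config$profile, calibration, seeds[3])
  } else {
    out <- data.frame(sample_id = cohort$sample_id, well_id = NA_character_,
                      plate_id = cohort$plate_id, ratio = templates,
                      method = "MSQMA", qc_flags = "", stringsAsFactors = FALSE)
    class(out) <- c("methylation_calls", "data.frame")
    out
  }
  say("stage=tier1_measure n_in=%d n_out=%d", nrow(cohort), nrow(calls))

  thr_sd <- compute_thresholds(calls$ratio, k = config$k, min_n = min(100, config$n))
  thr_cons <- conservative_thresholds()
  scr_sd <- screen_cohort(calls, thr_sd)
  scr_cons <- screen_cohort(calls, thr_cons)
  primary <- if (config$threshold_mode == "sd_rule") scr_sd else scr_cons
  tier1 <- primary$calls
  flagged_ids <- tier1$sample_id[tier1$referred]
  say("stage=tier1_call n_in=%d n_out=%d", nrow(calls), length(flagged_ids))

  cinq <- .tier2_cinq(cohort, flagged_ids, config, seeds[4:6])
  say("stage=tier2_cinq n_in=%d n_out=%d", length(flagged_ids),
      sum(cinq$calls$confirmed))

  cnv <- .tier2_cnv(cohort, flagged_ids, config, seeds[7])
  say("stage=tier2_cnv n_in=%d n_out=%d", length(flagged_ids),
      sum(!is.na(cnv$copy_class) & cnv$copy_class != 2L))

  # third-tier reflex: CNV-ratio extremes (or all outliers) among the flags
  non2 <- which(is.na(cnv$copy_class) | cnv$copy_class != 2L)
  reflex_idx <- if (config$reflex == "extremes" && nrow(cnv) > 0) {
    intersect(c(which.min(cnv$cnv_ratio), which.max(cnv$cnv_ratio)), non2)
  } else non2
  reflex_ids <- cnv$sample_id[reflex_idx]
  band_of <- tier1$band[match(reflex_ids, tier1$sample_id)]
  tier3 <- .tier3_lcwgs(cohort, reflex_ids, band_of, config, seeds[8])
  say("stage=tier3_lcwgs n_in=%d n_out=%d", length(reflex_ids), length(tier3))

  confirmed_ids <- cinq$calls$sample_id[cinq$calls$confirmed &
                                          !nzchar(cinq$calls$qc_flags)]
  conditions <- NULL
  if (length(confirmed_ids)) {
    conditions <- .condition_of(
      tier1$band[match(confirmed_ids, tier1$sample_id)],
      cnv$copy_class[match(confirmed_ids, cnv$sample_id)]
    )
    names(conditions) <- confirmed_ids
  }
  flow <- tier_flow(tier1, cinq$calls, conditions)
  say("stage=report n_in=%d n_out=%d", length(flagged_ids), flow$counts$n_confirmed)

  report <- structure(
    list(cohort = cohort, tier1_calls = calls,
         thresholds = list(sd_rule = thr_sd, conservative = thr_cons),
         tier1 = list(sd_rule = scr_sd, conservative = scr_cons),
         flagged_ids = flagged_ids,
         tier2_cinq = cinq$calls, cinq_reference_range = cinq$reference_range,
         tier2_cnv = cnv, tier3 = tier3,
         conditions = conditions, flow = flow,
         config = config, seed = config$seed, log = log,
         version = as.character(utils::packageVersion("imprintscreen"))),
    class = "screen_report"
  )
  if (!is.null(config$outdir)) write_screen_artifacts(report, config$outdir)
  report
}

#' @export
print.screen_report <- function(x, ...) {
  s <- x$tier1[[x$config$threshold_mode]]$summary
  cat("Chromosome 15 imprinting-disorder screen\n")
  cat(sprintf("  cohort: %d newborns (profile: %s, %s thresholds)\n",
              x$flow$counts$n_screened, x$config$profile$name,
              x$config$threshold_mode))
  cat(sprintf("  tier 1: %d flagged (%.2f%%)\n", s$n_referred, s$percent_referred))
  cat(sprintf("  tier 2: %d confirmed by ddPCR; %d CNV outliers\n",
              x$flow$counts$n_confirmed,
              sum(!is.na(x$tier2_cnv$copy_class) & x$tier2_cnv$copy_class != 2L)))
  cat(sprintf("  tier 3: %d samples typed by LC-WGS\n", length(x$tier3)))
  for (id in names(x$tier3)) {
    cat(sprintf("    %s: %s\n", id, x$tier3[[id]]$label))
  }
  for (nm in names(x$flow$per_condition)) {
    pc <- x$flow$per_condition[[nm]]
    cat(sprintf("  %s prevalence: %s\n", nm, pc$prevalence$label))
  }
  invisible(x)
}

#' @export
summary.screen_report <- function(object, ...) {
  list(
    counts = object$flow$counts,
    thresholds = object$thresholds$sd_rule[c("mean", "sd", "lower", "upper")],
    percent_referred = object$tier1[[object$config$threshold_mode]]$summary$percent_referred,
    conditions = if (is.null(object$conditions)) character(0) else table(object$conditions),
    per_condition = lapply(object$flow$per_condition, function(pc) pc$prevalence$label),
    tier3 = vapply(object$tier3, function(sc) sc$label, character(1))
  )
}

#' Histogram of first-tier methylation ratios with the normal-range bounds
#' @param x a `screen_report`
#' @param ... passed to [graphics::hist()]
#' @return invisibly, the histogram object
#' @export
plot.screen_report <- function(x, ...) {
  h <- graphics::hist(x$tier1_calls$ratio, breaks = 100,
                      main = "First-tier SNRPN methylation ratios",
                      xlab = "methylation ratio", ...)
  thr <- x$thresholds$sd_rule
  graphics::abline(v = c(thr$lower, thr$mean, thr$upper), lty = c(2, 1, 2))
  invisible(h)
}

#' Write the on-disk artifacts of a screening run
#'
#' Sample sheet (TSV, truth columns flagged), tier-1/2 call tables (TSV),
#' LC-WGS segments as BED (0-based half-open) plus an HGVS sidecar TSV
#' (1-based inclusive), the report as JSON, and the stage log.
#'
#' @param report a `screen_report`
#' @param outdir output directory (created if missing)
#' @return `outdir`, invisibly
#' @export
write_screen_artifacts <- function(report, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  p <- function(f) file.path(outdir, f)
  write_sample_sheet(report$cohort, p("sample_sheet.tsv"))
  utils::write.table(report$tier1[[report$config$threshold_mode]]$calls,
                     p("tier1_calls.tsv"), sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(report$tier2_cinq, p("tier2_cinq.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(report$tier2_cnv, p("tier2_cnv.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  beds <- do.call(rbind, lapply(names(report$tier3), function(id) {
    segs <- report$tier3[[id]]$segments
    if (nrow(segs) == 0) return(NULL)
    data.frame(chrom = "NC_000015.9", chromStart = segs$start, chromEnd = segs$end,
               name = sprintf("%s_CN%d", id, segs$copies), score = segs$copies,
               strand = ".", stringsAsFactors = FALSE)
  }))
  if (is.null(beds)) {
    beds <- data.frame(chrom = character(0), chromStart = numeric(0),
                       chromEnd = numeric(0), name = character(0),
                       score = numeric(0), strand = character(0))
  }
  utils::write.table(beds, p("tier3_segments.bed"), sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  hg <- do.call(rbind, lapply(names(report$tier3), function(id) {
    segs <- report$tier3[[id]]$segments
    if (nrow(segs) == 0) return(NULL)
    data.frame(sample_id = id, hgvs = segs$hgvs, copies = segs$copies,
               subtype = report$tier3[[id]]$label, stringsAsFactors = FALSE)
  }))
  if (!is.null(hg)) {
    utils::write.table(hg, p("tier3_hgvs.tsv"), sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  jsonlite::write_json(report_as_list(report), p("report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  writeLines(report$log, p("run.log"))
  invisible(outdir)
}

#' Serializable summary of a screening report
#' @param report a `screen_report`
#' @return nested list suitable for JSON export
#' @export
report_as_list <- function(report) {
  thr <- report$thresholds$sd_rule
  list(
    provenance = list(seed = report$seed, version = report$version,
                      profile = report$config$profile$name,
                      threshold_mode = report$config$threshold_mode,
                      n = report$config$n),
    counts = report$flow$counts,
    thresholds = list(mean = thr$mean, sd = thr$sd, k = thr$k,
                      lower = thr$lower, upper = thr$upper),
    percent_referred = report$tier1[[report$config$threshold_mode]]$summary$percent_referred,
    overall_prevalence = report$flow$overall$prevalence[
      c("fraction", "one_in_n", "ci_low", "ci_high", "label")],
    per_condition = lapply(report$flow$per_condition, function(pc) {
      list(n_confirmed = pc$n_confirmed,
           one_in_n = pc$prevalence$one_in_n, label = pc$prevalence$label,
           ci_low = pc$prevalence$ci_low, ci_high = pc$prevalence$ci_high)
    }),
    tier3 = lapply(report$tier3, function(sc) {
      list(label = sc$label, breakpoints = as.list(sc$breakpoints),
           hgvs = as.list(sc$segments$hgvs))
    })
  )
}
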