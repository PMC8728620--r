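# Synthetic newborn cohorts: class assignment, measurement-noise profiles and
# sample-sheet serialization.

#' Measurement-noise profiles for the first-tier methylation assay
#'
#' A profile describes how a sample's *measured* methylation ratio scatters
#' around its genotype expectation:
#'
#' * `conversion_failure`: fraction of unmethylated cytosines that escape
#'   bisulfite conversion and therefore read as methylated. Shifts the measured
#'   centre to `m + eps * (1 - m)`; with the default 0.02 a euploid control
#'   (m = 0.5) centres at 0.51, the observed population mean.
#' * `control_sd`: base normal SD of control-population scatter (biology +
#'   storage + assay), before tail broadening.
#' * `affected_sd`: scatter applied to non-control classes.
#' * `tail_weight_per_year` / `tail_df_base`: archival dried blood spots stored
#'   at room temperature develop heavier distribution tails. With probability
#'   `w = min(tail_weight_per_year * storage_years, 0.2)` a sample's noise is
#'   drawn from an unscaled Student-t with `df = max(3, tail_df_base -
#'   storage_years)` (scaled by `control_sd`) instead of the normal component.
#'
#' The `"archival"` profile reproduces the population distribution observed on
#' long-stored newborn blood spots (mean 0.51, SD 0.085 at 5 storage years,
#' ~0.5% of mass beyond 3 empirical SDs). The `"calibrated"` profile is the
#' separation-guaranteed setting used for end-to-end tier-flow reproduction:
#' narrower control scatter (SD 0.05), technical-only scatter on affected
#' classes (SD 0.01) and no storage tails, so every disease class sits several
#' SDs clear of the thresholds it must cross (see the methods vignette for the
#' margin analysis).
#'
#' @param profile `"archival"` or `"calibrated"`
#' @return list of noise parameters (class `"noise_profile"`)
#' @export
noise_profile <- function(profile = c("archival", "calibrated")) {
  profile <- match.arg(profile)
  out <- switch(profile,
    archival = list(
      name = "archival",
      conversion_failure = 0.02,
      control_sd = 0.0776,
      affected_sd = 0.0776,
      tail_weight_per_year = 0.02,
      tail_df_base = 8,
      melt_fluor_sd = 0.003,
      plate_effect_sd = 0.01
    ),
    calibrated = list(
      name = "calibrated",
      conversion_failure = 0.02,
      control_sd = 0.05,
      affected_sd = 0.01,
      tail_weight_per_year = 0,
      tail_df_base = 8,
      melt_fluor_sd = 0.002,
      plate_effect_sd = 0.005
    )
  )
  structure(out, class = "noise_profile")
}

#' Generate a synthetic newborn cohort
#'
#' Assigns each of `n` newborns a latent genotype class, either multinomially
#' from prevalences or as exact counts (the reproducible mode used when a study
#' tier flow is being re-created). Samples not covered by `class_mix` are
#' controls.
#'
#' @param n cohort size (>= 1)
#' @param class_mix named numeric vector over `genotype_classes()$name`.
#'   With `exact = FALSE`: prevalences in \[0, 1\]; any unnamed remainder goes to
#'   `control`, and the total (including an explicit `control` entry) must not
#'   exceed 1. With `exact = TRUE`: integer case counts; the remainder of the
#'   cohort is controls.
#' @param exact logical; exact class counts instead of multinomial draws
#' @param storage_years archival storage time (drives tail broadening); recycled
#' @param mosaic_fraction abnormal-cell fraction for mosaic classes; recycled
#' @param tissue sample tissue label; recycled
#' @param plate_size samples per assay plate for plate-id assignment
#' @param seed integer seed (reproducible cohorts)
#' @return data.frame of class `"imprint_cohort"`: `sample_id`, `plate_id`,
#'   `tissue`, `storage_years`, plus latent-truth columns `genotype`,
#'   `mosaic_fraction`, `true_meth`, `effective_meth` (maskable on export).
#' @export
#' @examples
#' co <- make_cohort(100, c(AS_deletion = 2), exact = TRUE, seed = 1)
#' table(co$genotype)
make_cohort <- function(n, class_mix = NULL, exact = FALSE,
                        storage_years = 5, mosaic_fraction = 1,
                        tissue = "NBS", plate_size = 92, seed = NULL) {
  stopifnot(n >= 1)
  cls <- genotype_classes()
  if (is.null(class_mix)) class_mix <- numeric(0)
  if (length(class_mix) && (is.null(names(class_mix)) || any(!nzchar(names(class_mix))))) {
    stop("class_mix must be a named vector")
  }
  bad <- setdiff(names(class_mix), cls$name)
  if (length(bad)) stop("unknown genotype class in class_mix: ", paste(bad, collapse = ", "))

  if (exact) {
    counts <- as.integer(round(class_mix))
    if (any(counts < 0)) stop("exact class counts must be nonnegative")
    names(counts) <- names(class_mix)
    n_ctrl <- n - sum(counts[names(counts) != "control"])
    if (n_ctrl < 0) stop("exact class counts exceed cohort size n")
    counts <- counts[names(counts) != "control"]
    genotype <- c(rep(names(counts), counts), rep("control", n_ctrl))
  } else {
    p <- class_mix
    if (!("control" %in% names(p))) {
      rest <- 1 - sum(p)
      if (rest < -1e-8) stop("class_mix prevalences exceed 1")
      p <- c(p, control = max(rest, 0))
    }
    if (abs(sum(p) - 1) > 1e-8) stop("class_mix prevalences must sum to 1")
    genotype <- with_seed(seed, sample(names(p), n, replace = TRUE, prob = p))
    seed <- if (is.null(seed)) NULL else derive_seeds(seed, 2)[2]
  }

  # place affected samples at scattered positions so plate assignment is not
  # degenerate, keeping the draw reproducible
  ord <- with_seed(seed, sample.int(n))
  genotype <- genotype[order(ord)]

  mf <- rep_len(mosaic_fraction, n)
  mf[!genotype %in% "PWS_mosaic" & mf != 1] <- 1  # non-mosaic classes are clonal
  out <- data.frame(
    sample_id = sprintf("S%06d", seq_len(n)),
    plate_id = sprintf("P%04d", ((seq_len(n) - 1L) %/% plate_size) + 1L),
    tissue = rep_len(tissue, n),
    storage_years = rep_len(storage_years, n),
    genotype = genotype,
    mosaic_fraction = mf,
    stringsAsFactors = FALSE
  )
  out$true_meth <- cls$true_meth[match(out$genotype, cls$name)]
  out$effective_meth <- true_methylation(out$genotype, out$mosaic_fraction)
  class(out) <- c("imprint_cohort", "data.frame")
  out
}

#' Copy-number profile of a cohort sample
#' @param genotype genotype class name
#' @return data.frame (`start`, `end`, `copies`) of non-diploid regions, or
#'   `NULL` for an all-2-copy genome
#' @export
cn_profile_of <- function(genotype) {
  cls <- genotype_classes()
  cls$cn_profile[[match(genotype, cls$name)]]
}

#' Draw measured first-tier methylation ratios for a cohort
#'
#' Applies the bisulfite conversion-failure shift, then per-sample scatter from
#' the noise profile (normal core plus storage-driven Student-t tails),
#' truncated to \[0, 1\]. These are the template ratios entering the melt assay,
#' or directly the measured ratios when the melt stage is bypassed.
#'
#' @param cohort an `imprint_cohort`
#' @param profile a `noise_profile()` (or its name)
#' @param seed integer seed
#' @return numeric vector of ratios in \[0, 1\], one per sample
#' @export
draw_measured_ratios <- function(cohort, profile = noise_profile("archival"),
                                 seed = NULL) {
  if (is.character(profile)) profile <- noise_profile(profile)
  n <- nrow(cohort)
  centre <- cohort$effective_meth +
    profile$conversion_failure * (1 - cohort$effective_meth)
  sd <- ifelse(cohort$genotype == "control", profile$control_sd, profile$affected_sd)
  w <- pmin(profile$tail_weight_per_year * cohort$storage_years, 0.2)
  df <- pmax(3, profile$tail_df_base - cohort$storage_years)
  with_seed(seed, {
    tail <- stats::runif(n) < w
    eps <- ifelse(tail, stats::rt(n, df = df), stats::rnorm(n))
    clamp01(centre + sd * eps)
  })
}

#' Write a cohort sample sheet (TSV)
#'
#' Latent-truth columns are prefixed `truth_` so that evaluation code can mask
#' them from callers; `mask_truth = TRUE` drops them entirely.
#' @param cohort an `imprint_cohort`
#' @param path output file path
#' @param mask_truth drop latent-truth columns
#' @return `path`, invisibly
#' @export
write_sample_sheet <- function(cohort, path, mask_truth = FALSE) {
  stopifnot(nrow(cohort) >= 1)
  df <- as.data.frame(cohort)
  truth_cols <- c("genotype", "mosaic_fraction", "true_meth", "effective_meth")
  names(df)[match(truth_cols, names(df))] <- paste0("truth_", truth_cols)
  if (mask_truth) df <- df[, !startsWith(names(df), "truth_"), drop = FALSE]
  num <- vapply(df, is.numeric, logical(1))
  df[num] <- lapply(df[num], function(x) format(x, digits = 17, trim = TRUE, scientific = FALSE))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a cohort sample sheet written by [write_sample_sheet()]
#' @param path sample-sheet path
#' @return `imprint_cohort` data.frame (truth columns restored when present)
#' @export
read_sample_sheet <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE,
                          colClasses = NA)
  names(df) <- sub("^truth_", "", names(df))
  if (!is.null(df$plate_id)) df$plate_id <- as.character(df$plate_id)
  class(df) <- c("imprint_cohort", "data.frame")
  df
}

#' @export
print.imprint_cohort <- function(x, ...) {
  cat("Synthetic newborn cohort:", nrow(x), "samples\n")
  if ("genotype" %in% names(x)) {
    tab <- sort(table(x$genotype), decreasing = TRUE)
    cat("  classes:", paste(sprintf("%s=%d", names(tab), tab), collapse = ", "), "\n")
  }
  cat("  plates:", length(unique(x$plate_id)),
      " storage (years):", paste(unique(x$storage_years), collapse = ", "), "\n")
  invisible(x)
}
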