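# Genotype classes of the chromosome 15 imprinting disorders and the
# parent-of-origin methylation model.
#
# The SNRPN promoter is methylated on the maternal allele and unmethylated on
# the paternal allele, so the expected methylation fraction of a genotype is
# (methylated maternal copies) / (total copies) over the imprinted region:
#   control                        1/2
#   PWS (paternal loss, any kind)  1/1 -> 1.0
#   AS  (maternal loss)            0/2 -> 0.0 (deletion: 0/1)
#   AS by UBE3A point mutation     1/2 (imprinting intact; a known blind spot)
#   maternal interstitial dup      2/3
#   idic15 (supernumerary)         3/4
#   tricentric 15                  5/7 (assumed; not an empirically anchored value)

# Breakpoint landmarks on NC_000015.9 (approximate, as commonly drawn).
.BP_DEFAULT <- c(
  BP1 = 22300000, BP2 = 23100000, BP3 = 28300000,
  BP4 = 30300000, BP5 = 32250000
)

#' Default BP1-BP5 breakpoint coordinates (NC_000015.9)
#'
#' Approximate recurrent breakpoint locations on 15q11-q13 used for snapping
#' copy-number segment boundaries. Override per analysis if a different build
#' or annotation is needed.
#' @return named numeric vector (BP1..BP5, base pairs, 1-based landmark positions)
#' @export
default_bp_map <- function() .BP_DEFAULT

.CN_REGION <- list(
  del_typeII = c(.BP_DEFAULT[["BP2"]], .BP_DEFAULT[["BP3"]]),
  del_typeI  = c(.BP_DEFAULT[["BP1"]], .BP_DEFAULT[["BP3"]]),
  dup_core   = c(.BP_DEFAULT[["BP2"]], .BP_DEFAULT[["BP3"]]),
  idic_main  = c(22550000, 30100000),
  idic_shoulder = c(30300000, 32250000)
)

.cn_profile <- function(regions, copies) {
  data.frame(
    start = vapply(regions, `[`, numeric(1), 1L),
    end = vapply(regions, `[`, numeric(1), 2L),
    copies = as.integer(copies),
    row.names = NULL
  )
}

#' Genotype class table for chromosome 15 imprinting disorders
#'
#' One row per representable genotype: its expected SNRPN promoter methylation
#' fraction under the parent-of-origin model and its copy-number profile over
#' 15q11-q13 (regions not listed are 2 copies). Prevalences default to zero;
#' cohort generation supplies the mix.
#'
#' @return data.frame with columns `name`, `true_meth`, and a list-column
#'   `cn_profile` of data.frames (`start`, `end`, `copies`; 0-based half-open).
#' @export
#' @examples
#' genotype_classes()$name
genotype_classes <- function() {
  cls <- data.frame(
    name = c(
      "control", "PWS_deletion", "PWS_UPD_or_ID", "PWS_mosaic",
      "AS_deletion", "AS_nondeletion", "AS_UBE3A_mutation",
      "Dup15q_interstitial_maternal", "Dup15q_idic15", "Dup15q_tricentric"
    ),
    true_meth = c(0.5, 1, 1, 1, 0, 0, 0.5, 2 / 3, 3 / 4, 5 / 7),
    stringsAsFactors = FALSE
  )
  cls$cn_profile <- list(
    NULL,                                                  # control
    .cn_profile(.CN_REGION["del_typeII"], 1L),             # PWS_deletion
    NULL,                                                  # PWS_UPD_or_ID
    NULL,                                                  # PWS_mosaic
    .cn_profile(.CN_REGION["del_typeII"], 1L),             # AS_deletion
    NULL,                                                  # AS_nondeletion
    NULL,                                                  # AS_UBE3A_mutation
    .cn_profile(.CN_REGION["dup_core"], 3L),               # interstitial dup
    .cn_profile(.CN_REGION[c("idic_main", "idic_shoulder")], c(4L, 3L)),
    .cn_profile(.CN_REGION["idic_main"], 7L)               # tricentric
  )
  cls
}

#' Expected methylation fraction of a genotype class
#'
#' Parent-of-origin arithmetic, blended with the 0.5 euploid baseline for
#' mosaic cases: `f * class_meth + (1 - f) * 0.5`.
#'
#' @param class character, one of `genotype_classes()$name` (vectorised)
#' @param mosaic_fraction fraction of cells carrying the abnormality, in \[0, 1\]
#' @return methylation fraction in \[0, 1\]
#' @export
#' @examples
#' true_methylation("Dup15q_interstitial_maternal")  # 2/3
#' true_methylation("PWS_mosaic", mosaic_fraction = 0.5)  # 0.75
true_methylation <- function(class, mosaic_fraction = 1) {
  cls <- genotype_classes()
  idx <- match(class, cls$name)
  if (anyNA(idx)) {
    stop("unknown genotype class: ", paste(class[is.na(idx)], collapse = ", "))
  }
  if (any(mosaic_fraction < 0 | mosaic_fraction > 1)) {
    stop("mosaic_fraction must be in [0, 1]")
  }
  m <- mosaic_fraction * cls$true_meth[idx] + (1 - mosaic_fraction) * 0.5
  clamp01(m)
}
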